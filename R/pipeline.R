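#' Run the full P450 survey on one genome
#'
#' Chains every stage: candidate screening (signature regions + reference
#' similarity), clan/family/subfamily assignment, chromosome distribution,
#' cluster detection and gene structure, paralog pairing, collinear-block
#' chaining over the full-proteome anchor set, duplication-mode
#' classification, Ka/Ks estimation with selection regimes and recent-WGD
#' flagging, and (when expression inputs are given) the flavonoid candidate
#' screen and retention classification.
#'
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param cds CDS tibble (`id`, `sequence`).
#' @param models Gene-model tibble (as from [read_gff3()]).
#' @param references Labelled reference tibble
#'   (as from [read_reference_fasta()]).
#' @param counts Optional count tibble for [compute_fpkm()].
#' @param metabolites Optional metabolite series tibble.
#' @param id_config An [identification_config()].
#' @param nom_config A [nomenclature_config()].
#' @param clu_config A [cluster_config()].
#' @param syn_config A [synteny_config()].
#' @param evo_config An [evolution_config()].
#' @param assoc_config An [association_config()].
#' @param evidence Optional external evidence tibble.
#' @return An object of class `p450_survey`: a list with elements `screen`,
#'   `assignments`, `classification`, `distribution`, `clusters`,
#'   `structure`, `pairs`, `blocks`, `calls`, `recent_wgd`, and (if
#'   expression inputs were given) `fpkm`, `flavonoid_screen`, `retention`.
#' @export
survey_p450s <- function(proteins, cds, models, references,
                         counts = NULL, metabolites = NULL,
                         id_config = identification_config(),
                         nom_config = nomenclature_config(),
                         clu_config = cluster_config(),
                         syn_config = synteny_config(),
                         evo_config = evolution_config(),
                         assoc_config = association_config(),
                         evidence = NULL) {
  screen <- screen_candidates(proteins, references, evidence, id_config)
  kept <- proteins[proteins$id %in% screen$id[screen$kept], , drop = FALSE]
  assignments <- assign_family(kept, references, nom_config)
  classification <- summarize_classification(assignments)
  distribution <- chromosome_distribution(models, assignments)
  clusters <- detect_clusters(models, assignments, clu_config)
  structure_stats <- gene_structure_stats(
    models[models$gene_id %in% kept$id, , drop = FALSE])
  pairs <- find_paralog_pairs(kept, assignments, syn_config)
  anchors <- identity_pairs(proteins, syn_config$pair_min_identity)
  blocks <- chain_collinear_blocks(anchors, gene_rank(models), syn_config)
  calls <- if (nrow(pairs) > 0) {
    classify_modes(pairs, blocks, gene_rank(models), syn_config) |>
      kaks_table(cds, config = evo_config)
  } else NULL
  recent <- if (!is.null(calls)) flag_recent_wgd(calls, evo_config) else NULL

  out <- list(screen = screen, assignments = assignments,
              classification = classification, distribution = distribution,
              clusters = clusters, structure = structure_stats,
              pairs = pairs, blocks = blocks, calls = calls,
              recent_wgd = recent)
  if (!is.null(counts) && !is.null(metabolites)) {
    fpkm <- compute_fpkm(counts)
    fam_fpkm <- fpkm[fpkm$gene_id %in% kept$id, , drop = FALSE]
    out$fpkm <- fpkm
    out$flavonoid_screen <- screen_flavonoid_candidates(fam_fpkm, metabolites,
                                                        assoc_config)
    if (!is.null(calls) && nrow(calls) > 0) {
      out$retention <- classify_retention(fpkm, calls)
    }
  }
  structure(out, class = "p450_survey")
}

#' @export
print.p450_survey <- function(x, ...) {
  total <- x$classification[x$classification$clan == "total", ]
  cat("P450 genome survey\n")
  cat("  candidates kept: ", sum(x$screen$kept), " of ", nrow(x$screen), "\n",
      sep = "")
  cat("  A-type share:    ",
      if (nrow(total)) sprintf("%.1f%%", total$pct_A) else "NA", "\n", sep = "")
  cat("  gene clusters:   ", nrow(x$clusters), "\n", sep = "")
  cat("  paralog pairs:   ", nrow(x$pairs), "\n", sep = "")
  if (!is.null(x$calls)) {
    tab <- table(x$calls$mode)
    cat("  duplication modes: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$flavonoid_screen)) {
    cat("  flavonoid candidates: ", length(x$flavonoid_screen$candidates),
        "\n", sep = "")
  }
  invisible(x)
}
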