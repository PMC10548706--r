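#' Gene-cluster detection configuration
#'
#' A cluster is a maximal run of at least `min_size` family-assigned genes
#' on one chromosome in which each adjacent pair of members is separated by
#' at most `max_intervening_genes` non-member genes and at most
#' `max_gap_bp` base pairs. `grouping = "same_family"` restricts runs to a
#' single family label; the default pools all assigned genes.
#'
#' @param min_size Minimum members per cluster (default 3).
#' @param max_intervening_genes Maximum non-member genes between adjacent
#'   members (default 10).
#' @param max_gap_bp Maximum base-pair gap between adjacent members
#'   (default 200000).
#' @param grouping `"any_family"` (default) or `"same_family"`.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(min_size = 3L, max_intervening_genes = 10L,
                           max_gap_bp = 200000L,
                           grouping = c("any_family", "same_family")) {
  grouping <- match.arg(grouping)
  stopifnot(min_size >= 2, max_gap_bp > 0)
  structure(list(min_size = as.integer(min_size),
                 max_intervening_genes = as.integer(max_intervening_genes),
                 max_gap_bp = as.integer(max_gap_bp), grouping = grouping),
            class = "cluster_config")
}

#' Per-chromosome gene counts and densities
#'
#' @param models Gene-model tibble (as from [read_gff3()]).
#' @param assignments Optional [assign_family()] output; when given, only
#'   assigned genes (family not `NEW_FAMILY`) are counted.
#' @param chromosome_lengths Optional named vector of chromosome lengths in
#'   bp; defaults to the maximum gene end per chromosome.
#' @return Tibble: `chromosome`, `n_genes`, `genes_per_mb`.
#' @export
chromosome_distribution <- function(models, assignments = NULL,
                                    chromosome_lengths = NULL) {
  if (!is.null(assignments)) {
    keep <- assignments$query_id[assignments$family != "NEW_FAMILY"]
    models <- models[models$gene_id %in% keep, , drop = FALSE]
  }
  tab <- models |>
    dplyr::group_by(chromosome = .data$chromosome) |>
    dplyr::summarise(n_genes = dplyr::n(), max_end = max(.data$end),
                     .groups = "drop") |>
    dplyr::arrange(.data$chromosome)
  len <- if (is.null(chromosome_lengths)) tab$max_end
         else unname(chromosome_lengths[tab$chromosome])
  tab |>
    dplyr::mutate(genes_per_mb = .data$n_genes / (len / 1e6)) |>
    dplyr::select("chromosome", "n_genes", "genes_per_mb")
}

# run finder over one chromosome's ordered gene table
find_runs <- function(chrom_tab, member, config) {
  idx <- which(member)
  if (length(idx) == 0) return(list())
  ok_link <- function(i, j) {
    (j - i - 1) <= config$max_intervening_genes &&
      (chrom_tab$start[j] - chrom_tab$end[i]) <= config$max_gap_bp
  }
  runs <- list()
  cur <- idx[1]
  for (k in seq_along(idx)[-1]) {
    if (ok_link(idx[k - 1], idx[k])) {
      cur <- c(cur, idx[k])
    } else {
      runs <- c(runs, list(cur))
      cur <- idx[k]
    }
  }
  c(runs, list(cur))
}

#' Detect family gene clusters along chromosomes
#'
#' Implements the rule in [cluster_config()]. Genes lacking a family
#' assignment never seed or join clusters. Reported clusters are maximal.
#'
#' @param models Gene-model tibble.
#' @param assignments [assign_family()] output (only `query_id` and
#'   `family` are used); rows with `NEW_FAMILY` are ignored.
#' @param config A [cluster_config()].
#' @return Tibble: `cluster_id`, `chromosome`, `start`, `end`,
#'   `n_members`, `member_gene_ids` (list), `families` (list).
#' @export
detect_clusters <- function(models, assignments, config = cluster_config()) {
  fam <- assignments[assignments$family != "NEW_FAMILY" &
                       !is.na(assignments$family), c("query_id", "family")]
  models <- models |> dplyr::arrange(.data$chromosome, .data$start)
  out <- list()
  for (chrom in unique(models$chromosome)) {
    tab <- models[models$chromosome == chrom, , drop = FALSE]
    fam_of <- fam$family[match(tab$gene_id, fam$query_id)]
    groups <- if (config$grouping == "same_family") {
      stats::na.omit(unique(fam_of))
    } else "any"
    for (g in groups) {
      member <- if (identical(g, "any")) !is.na(fam_of) else
        !is.na(fam_of) & fam_of == g
      for (run in find_runs(tab, member, config)) {
        if (length(run) < config$min_size) next
        out <- c(out, list(tibble::tibble(
          chromosome = chrom,
          start = tab$start[run[1]],
          end = tab$end[run[length(run)]],
          n_members = length(run),
          member_gene_ids = list(tab$gene_id[run]),
          families = list(unname(fam_of[run])))))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(cluster_id = character(), chromosome = character(),
                          start = integer(), end = integer(),
                          n_members = integer(),
                          member_gene_ids = list(), families = list()))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chromosome, .data$start) |>
    dplyr::mutate(cluster_id = sprintf("cluster%03d", dplyr::row_number()),
                  .before = 1)
}

#' Exon/intron structure statistics
#'
#' Introns are counted between consecutive CDS segments (in transcription
#' order); the phase of each intron is the cumulative CDS length 5' of the
#' intron modulo 3. Exon counts refer to CDS-bearing exons.
#'
#' @param models Gene-model tibble with non-empty `cds_segments`.
#' @return Tibble: `gene_id`, `n_exons`, `n_introns`, `intron_phases`
#'   (list of integer vectors, each phase in 0-2).
#' @export
gene_structure_stats <- function(models) {
  rows <- purrr::map(seq_len(nrow(models)), function(i) {
    seg <- models$cds_segments[[i]]
    if (is.null(seg) || nrow(seg) == 0) {
      abort(paste0("gene_structure_stats: no CDS segments for ",
                   models$gene_id[i]))
    }
    lens <- abs(seg[, "end"] - seg[, "start"]) + 1
    n <- nrow(seg)
    phases <- if (n > 1) as.integer(cumsum(lens)[-n] %% 3) else integer(0)
    tibble::tibble(gene_id = models$gene_id[i], n_exons = n,
                   n_introns = n - 1L, intron_phases = list(phases))
  })
  dplyr::bind_rows(rows)
}
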