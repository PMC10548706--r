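#' Synteny and duplication-mode configuration
#'
#' @param pair_min_identity Identity floor for paralog pairs (default 0.40).
#' @param min_block Minimum anchors per collinear block (default 5).
#' @param max_gene_gap Maximum rank gap between consecutive anchors of a
#'   chain, on both axes (default 25).
#' @param proximal_max_intervening Maximum intervening genes for a proximal
#'   duplicate (default 10); tandem means zero intervening genes.
#' @return A list of class `synteny_config`.
#' @export
synteny_config <- function(pair_min_identity = 0.40, min_block = 5L,
                           max_gene_gap = 25L,
                           proximal_max_intervening = 10L) {
  stopifnot(min_block >= 2, proximal_max_intervening >= 1)
  structure(list(pair_min_identity = pair_min_identity,
                 min_block = as.integer(min_block),
                 max_gene_gap = as.integer(max_gene_gap),
                 proximal_max_intervening = as.integer(proximal_max_intervening)),
            class = "synteny_config")
}

#' Rank genes along each chromosome
#'
#' @param models Gene-model tibble.
#' @return Tibble `gene_id`, `chromosome`, `rank` (1-based position in
#'   start-coordinate order within the chromosome).
#' @export
gene_rank <- function(models) {
  models |>
    dplyr::arrange(.data$chromosome, .data$start) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chromosome", "rank")
}

#' Find within-family paralog pairs
#'
#' All unordered pairs of proteins sharing a family label with global
#' identity at or above the configured floor; each pair appears once with
#' `gene_a < gene_b`.
#'
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param assignments [assign_family()] output (`query_id`, `family`).
#' @param config A [synteny_config()].
#' @param scoring An [alignment_scoring()].
#' @return Tibble `gene_a`, `gene_b`, `identity`, `aligned_length`.
#' @export
find_paralog_pairs <- function(proteins, assignments,
                               config = synteny_config(),
                               scoring = alignment_scoring()) {
  fam <- assignments$family[match(proteins$id, assignments$query_id)]
  keep <- !is.na(fam) & fam != "NEW_FAMILY"
  out <- list()
  for (f in unique(fam[keep])) {
    sub <- proteins[keep & fam == f, , drop = FALSE]
    if (nrow(sub) < 2) next
    out <- c(out, list(identity_pairs(sub, config$pair_min_identity, scoring,
                                      prefilter = FALSE)))
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          identity = numeric(), aligned_length = integer()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$gene_a, .data$gene_b)
}

# lexicographically-smallest maximum-cardinality chain among anchors sorted
# by (rx, ry); compatibility: strictly increasing on both axes with rank
# gaps at most max_gap. Returns indices into the sorted table.
best_chain <- function(rx, ry, max_gap) {
  n <- length(rx)
  if (n == 0) return(integer(0))
  compat <- function(i, j) {
    rx[j] > rx[i] && ry[j] > ry[i] &&
      (rx[j] - rx[i]) <= max_gap && (ry[j] - ry[i]) <= max_gap
  }
  f <- rep(1L, n)
  for (i in n:1) {
    for (j in seq_len(n)) {
      if (j > i && compat(i, j) && f[j] + 1L > f[i]) f[i] <- f[j] + 1L
    }
  }
  lmax <- max(f)
  chain <- integer(0)
  need <- lmax
  prev <- 0L
  for (step in seq_len(lmax)) {
    for (i in seq_len(n)) {
      if (f[i] == need && !(i %in% chain) &&
          (prev == 0L || (i > prev && compat(prev, i)))) {
        chain <- c(chain, i)
        prev <- i
        need <- need - 1L
        break
      }
    }
  }
  chain
}

#' Chain anchors into collinear blocks
#'
#' For each chromosome pair and orientation, finds maximum-cardinality
#' chains of anchors whose gene ranks are strictly monotone on both axes
#' (decreasing on the second axis for inverted blocks) with rank gaps at
#' most `max_gene_gap`; chains with at least `min_block` anchors are
#' reported. Each anchor belongs to at most one block: chains are extracted
#' best-first (longest, ties to the `same` orientation, then the
#' lexicographically smallest anchor sequence), removing their anchors.
#'
#' @param anchors Anchor-pair tibble (`gene_a`, `gene_b`), e.g. from
#'   [identity_pairs()] over the full proteome.
#' @param gene_order [gene_rank()] output covering every anchor gene.
#' @param config A [synteny_config()].
#' @return Tibble: `block_id`, `chrom_a`, `chrom_b`, `orientation`,
#'   `n_anchors`, `anchors` (list of tibbles `gene_a`, `gene_b`, `rank_a`,
#'   `rank_b`).
#' @export
chain_collinear_blocks <- function(anchors, gene_order,
                                   config = synteny_config()) {
  if (nrow(anchors) == 0) {
    return(tibble::tibble(block_id = character(), chrom_a = character(),
                          chrom_b = character(), orientation = character(),
                          n_anchors = integer(), anchors = list()))
  }
  loc <- function(g) {
    i <- match(g, gene_order$gene_id)
    if (anyNA(i)) {
      abort(paste0("gene(s) missing from gene order: ",
                   paste(unique(g[is.na(i)]), collapse = ", ")))
    }
    gene_order[i, ]
  }
  la <- loc(anchors$gene_a)
  lb <- loc(anchors$gene_b)
  # orient each anchor: first axis = smaller chromosome (or smaller rank
  # when intra-chromosomal)
  flip <- la$chromosome > lb$chromosome |
    (la$chromosome == lb$chromosome & la$rank > lb$rank)
  tab <- tibble::tibble(
    gene_a = ifelse(flip, anchors$gene_b, anchors$gene_a),
    gene_b = ifelse(flip, anchors$gene_a, anchors$gene_b),
    chrom_a = ifelse(flip, lb$chromosome, la$chromosome),
    chrom_b = ifelse(flip, la$chromosome, lb$chromosome),
    rank_a = ifelse(flip, lb$rank, la$rank),
    rank_b = ifelse(flip, la$rank, lb$rank))

  blocks <- list()
  for (key in unique(paste(tab$chrom_a, tab$chrom_b))) {
    sub <- tab[paste(tab$chrom_a, tab$chrom_b) == key, , drop = FALSE]
    sub <- dplyr::arrange(sub, .data$rank_a, .data$rank_b)
    repeat {
      if (nrow(sub) == 0) break
      same <- best_chain(sub$rank_a, sub$rank_b, config$max_gene_gap)
      inv <- best_chain(sub$rank_a, -sub$rank_b, config$max_gene_gap)
      use_same <- length(same) >= length(inv)
      chain <- if (use_same) same else inv
      if (length(chain) < config$min_block) break
      blocks <- c(blocks, list(tibble::tibble(
        chrom_a = sub$chrom_a[1], chrom_b = sub$chrom_b[1],
        orientation = if (use_same) "same" else "inverted",
        n_anchors = length(chain),
        anchors = list(sub[chain, c("gene_a", "gene_b", "rank_a", "rank_b")]))))
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  if (length(blocks) == 0) {
    return(tibble::tibble(block_id = character(), chrom_a = character(),
                          chrom_b = character(), orientation = character(),
                          n_anchors = integer(), anchors = list()))
  }
  dplyr::bind_rows(blocks) |>
    dplyr::arrange(.data$chrom_a, .data$chrom_b,
                   dplyr::desc(.data$n_anchors)) |>
    dplyr::mutate(block_id = sprintf("block%03d", dplyr::row_number()),
                  .before = 1)
}

#' Classify paralog pairs into five duplication modes
#'
#' Fixed precedence WGD > TD > PD > TRD > DSD: a pair that is itself an
#' anchor inside a collinear block is whole-genome derived (WGD); otherwise
#' adjacent genes on one chromosome are tandem (TD); within
#' `proximal_max_intervening` intervening genes, proximal (PD); a pair with
#' exactly one member inside any collinear block (the ancestral locus, a
#' single-genome stand-in for outgroup dating) is transposed (TRD);
#' everything else is dispersed (DSD).
#'
#' @param pairs Paralog-pair tibble (`gene_a`, `gene_b`).
#' @param blocks [chain_collinear_blocks()] output, ideally built from the
#'   full-genome anchor set.
#' @param gene_order [gene_rank()] output.
#' @param config A [synteny_config()].
#' @return `pairs` with added `mode` (`WGD`/`TD`/`PD`/`TRD`/`DSD`) and
#'   `evidence` columns.
#' @export
classify_modes <- function(pairs, blocks, gene_order,
                           config = synteny_config()) {
  anchor_keys <- character(0)
  anchor_block <- character(0)
  block_genes <- character(0)
  for (i in seq_len(nrow(blocks))) {
    a <- blocks$anchors[[i]]
    keys <- paste(pmin(a$gene_a, a$gene_b), pmax(a$gene_a, a$gene_b))
    anchor_keys <- c(anchor_keys, keys)
    anchor_block <- c(anchor_block, rep(blocks$block_id[i], length(keys)))
    block_genes <- c(block_genes, a$gene_a, a$gene_b)
  }
  block_genes <- unique(block_genes)
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    ia <- match(ga, gene_order$gene_id)
    ib <- match(gb, gene_order$gene_id)
    if (is.na(ia)) abort(paste0("gene missing from gene order: ", ga))
    if (is.na(ib)) abort(paste0("gene missing from gene order: ", gb))
    key <- paste(min(ga, gb), max(ga, gb))
    hit <- match(key, anchor_keys)
    same_chrom <- gene_order$chromosome[ia] == gene_order$chromosome[ib]
    intervening <- if (same_chrom) {
      abs(gene_order$rank[ia] - gene_order$rank[ib]) - 1L
    } else NA_integer_
    in_block <- c(ga, gb) %in% block_genes
    if (!is.na(hit)) {
      mode <- "WGD"; ev <- paste0("anchor in ", anchor_block[hit])
    } else if (same_chrom && intervening == 0L) {
      mode <- "TD"; ev <- "adjacent ranks"
    } else if (same_chrom && intervening <= config$proximal_max_intervening) {
      mode <- "PD"; ev <- paste0(intervening, " intervening genes")
    } else if (sum(in_block) == 1L) {
      mode <- "TRD"
      ev <- paste0("ancestral locus: ", c(ga, gb)[in_block])
    } else {
      mode <- "DSD"; ev <- "no collinearity or proximity evidence"
    }
    tibble::tibble(mode = mode, evidence = ev)
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(rows))
}
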