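#' Alignment scoring configuration
#'
#' Scoring used by the global protein aligner: a substitution matrix from
#' [Biostrings] plus affine gap penalties. A gap of length `k` costs
#' `gap_open + (k - 1) * gap_extend`.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open Gap opening penalty (positive number, default 10).
#' @param gap_extend Gap extension penalty (positive number, default 1).
#' @return A list with the resolved scoring matrix and penalties.
#' @export
alignment_scoring <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  stopifnot(gap_open > 0, gap_extend > 0)
  mat <- get_scoring_matrix(matrix)
  structure(list(matrix_name = matrix, matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

get_scoring_matrix <- function(name) {
  key <- paste0("scoring_", name)
  if (is.null(the[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    the[[key]] <- as.matrix(e[[name]])
  }
  the[[key]]
}

seq_to_idx <- function(seq, mat) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(mat))
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    abort(paste0("sequence contains residues absent from the scoring matrix: ",
                 paste(bad, collapse = ", ")))
  }
  idx - 1L
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine (Gotoh) gap penalties and a
#' deterministic traceback: on equal scores the diagonal step is preferred,
#' then the gap consuming `a`, then the gap consuming `b`.
#'
#' @param a,b Protein sequence strings.
#' @param scoring An [alignment_scoring()] object.
#' @return A list with `score`, the two aligned strings (`aln_a`, `aln_b`,
#'   gaps as `-`), `identity` (identical columns / alignment columns after
#'   trimming terminal-gap columns) and `aligned_length` (columns after
#'   trimming).
#' @details The pair is aligned in a canonical orientation (lexicographically
#'   smaller sequence first) before the tie-break applies, so identity and
#'   aligned length are exactly symmetric in `a` and `b`.
#' @export
align_global <- function(a, b, scoring = alignment_scoring()) {
  stopifnot(nzchar(a), nzchar(b))
  if (a > b) {
    res <- align_global(b, a, scoring)
    return(list(score = res$score, aln_a = res$aln_b, aln_b = res$aln_a,
                identity = res$identity,
                aligned_length = res$aligned_length))
  }
  mat <- scoring$matrix
  res <- nw_align_cpp(seq_to_idx(a, mat), seq_to_idx(b, mat), mat,
                      scoring$gap_open, scoring$gap_extend)
  syms <- c(rownames(mat), "-")
  gap_code <- length(syms) - 1L
  col_a <- res$aln_a
  col_b <- res$aln_b
  ch_a <- syms[ifelse(col_a < 0, gap_code, col_a) + 1L]
  ch_b <- syms[ifelse(col_b < 0, gap_code, col_b) + 1L]
  stats <- alignment_identity(col_a, col_b)
  list(score = res$score,
       aln_a = paste(ch_a, collapse = ""),
       aln_b = paste(ch_b, collapse = ""),
       identity = stats$identity,
       aligned_length = stats$aligned_length)
}

# identity over alignment columns after trimming terminal-gap columns;
# inputs are the index vectors with -1 marking gaps
alignment_identity <- function(col_a, col_b) {
  gap <- col_a < 0 | col_b < 0
  keep <- if (all(gap)) logical(0) else seq(min(which(!gap)), max(which(!gap)))
  if (length(keep) == 0) {
    return(list(identity = 0, aligned_length = 0L))
  }
  id <- sum(col_a[keep] == col_b[keep] & col_a[keep] >= 0)
  list(identity = id / length(keep), aligned_length = length(keep))
}

#' Percent identity between two protein sequences
#'
#' Convenience wrapper around [align_global()] returning just the identity
#' fraction and the trimmed alignment length.
#'
#' @inheritParams align_global
#' @return A one-row tibble with columns `identity` and `aligned_length`.
#' @export
global_identity <- function(a, b, scoring = alignment_scoring()) {
  res <- align_global(a, b, scoring)
  tibble::tibble(identity = res$identity, aligned_length = res$aligned_length)
}

# k-mer codes for the prefilter (k = 6 over a 25-symbol packing)
kmer_codes <- function(seq, k = 6L) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  chars <- utf8ToInt(seq) - 64L                  # A -> 1 ... Z -> 26
  idx <- vapply(seq_len(k) - 1L, function(o) chars[(1L + o):(n - k + 1L + o)],
                integer(n - k + 1L))
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  as.integer(idx %*% 27L^(seq_len(k) - 1L) %% .Machine$integer.max)
}

#' All-vs-all identity pairs above a floor
#'
#' Computes global identity for every unordered pair of proteins and keeps
#' pairs at or above `min_identity`. A shared-6-mer prefilter skips the full
#' alignment for pairs that share fewer than `prefilter_min_kmers` exact
#' 6-mers; this is a speed heuristic only (unrelated random proteins share
#' essentially none) and can be disabled with `prefilter = FALSE`.
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param min_identity Identity floor (fraction).
#' @param scoring An [alignment_scoring()] object.
#' @param prefilter Use the shared-k-mer prefilter?
#' @param prefilter_min_kmers Minimum shared 6-mers to attempt alignment.
#' @return Tibble `gene_a`, `gene_b` (with `gene_a < gene_b`), `identity`,
#'   `aligned_length`.
#' @export
identity_pairs <- function(proteins, min_identity = 0.4,
                           scoring = alignment_scoring(),
                           prefilter = TRUE, prefilter_min_kmers = 8L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  n <- nrow(proteins)
  if (n < 2) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          identity = numeric(), aligned_length = integer()))
  }
  ids <- proteins$id
  seqs <- proteins$sequence
  codes <- if (prefilter) lapply(seqs, kmer_codes) else NULL
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (prefilter &&
          shared_kmer_count_cpp(codes[[i]], codes[[j]]) < prefilter_min_kmers) {
        next
      }
      res <- global_identity(seqs[i], seqs[j], scoring)
      if (res$identity >= min_identity) {
        k <- k + 1L
        a <- ids[i]; b <- ids[j]
        if (a > b) { tmp <- a; a <- b; b <- tmp }
        out[[k]] <- tibble::tibble(gene_a = a, gene_b = b,
                                   identity = res$identity,
                                   aligned_length = res$aligned_length)
      }
    }
  }
  if (k == 0L) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          identity = numeric(), aligned_length = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out[seq_len(k)]), .data$gene_a, .data$gene_b)
}
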