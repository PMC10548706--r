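# Independent brute-force oracles used to check the package's algorithms.

# sliding-window consensus matcher: all match starts, one position at a time
naive_scan_starts <- function(seq, consensus) {
  toks <- p450tools:::consensus_tokens(consensus)
  w <- length(toks)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < w) return(integer(0))
  ok <- rep(TRUE, n - w + 1L)
  for (o in seq_len(w)) {
    t <- toks[o]
    if (t == "X") next
    allowed <- if (startsWith(t, "[")) {
      strsplit(gsub("[^A-Z/]", "", t), "/")[[1]]
    } else t
    ok <- ok & chars[o:(n - w + o)] %in% allowed
  }
  which(ok)
}

# exhaustive global-alignment enumeration under affine gaps; returns the
# optimal score and the set of identities attained by optimal alignments
# (identity = matches / columns after trimming terminal-gap columns)
brute_align <- function(a, b, S, gap_open = 10, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  env <- new.env()
  env$best <- -Inf
  env$ids <- numeric(0)
  rec <- function(i, j, last, score, col, first_m, last_m, matches) {
    if (i > na && j > nb) {
      id <- if (is.na(first_m)) 0 else matches / (last_m - first_m + 1)
      if (score > env$best) { env$best <- score; env$ids <- id }
      else if (score == env$best) env$ids <- c(env$ids, id)
      return(invisible())
    }
    if (i <= na && j <= nb) {
      m <- matches + (A[i] == B[j])
      rec(i + 1L, j + 1L, "M", score + S[A[i], B[j]], col + 1L,
          if (is.na(first_m)) col else first_m, col, m)
    }
    if (i <= na) {
      rec(i + 1L, j, "X",
          score - (if (identical(last, "X")) gap_extend else gap_open),
          col + 1L, first_m, last_m, matches)
    }
    if (j <= nb) {
      rec(i, j + 1L, "Y",
          score - (if (identical(last, "Y")) gap_extend else gap_open),
          col + 1L, first_m, last_m, matches)
    }
  }
  rec(1L, 1L, "", 0, 1L, NA_integer_, NA_integer_, 0L)
  list(score = env$best, identities = unique(env$ids))
}

# exhaustive chain search: all strictly increasing chains with rank gaps at
# most max_gap; returns the maximum-cardinality chain that is
# lexicographically smallest in sorted-anchor order
brute_best_chain <- function(rx, ry, max_gap) {
  n <- length(rx)
  if (n == 0) return(integer(0))
  compat <- function(i, j) {
    rx[j] > rx[i] && ry[j] > ry[i] &&
      (rx[j] - rx[i]) <= max_gap && (ry[j] - ry[i]) <= max_gap
  }
  best <- list(len = 0L, chain = integer(0))
  consider <- function(chain) {
    if (length(chain) < best$len) return(invisible())
    if (length(chain) > best$len) {
      best <<- list(len = length(chain), chain = chain)
      return(invisible())
    }
    for (k in seq_along(chain)) {     # equal length: lexicographic
      if (chain[k] < best$chain[k]) {
        best <<- list(len = length(chain), chain = chain)
        return(invisible())
      }
      if (chain[k] > best$chain[k]) return(invisible())
    }
  }
  rec <- function(chain) {
    consider(chain)
    last <- if (length(chain)) chain[length(chain)] else 0L
    for (j in seq_len(n)) {
      if (j > last && (length(chain) == 0 || compat(chain[length(chain)], j))) {
        rec(c(chain, j))
      }
    }
  }
  rec(integer(0))
  best$chain
}

# 9-mutation enumeration of per-codon synonymous site fractions
ng86_site_oracle <- function(codon, stop_mutations = "exclude") {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    nsyn <- 0; nvalid <- 0
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (gc[[mut]] == "*") {
        if (stop_mutations == "nonsynonymous") nvalid <- nvalid + 1
        next
      }
      nvalid <- nvalid + 1
      if (gc[[mut]] == gc[[codon]]) nsyn <- nsyn + 1
    }
    if (nvalid > 0) s <- s + nsyn / nvalid
  }
  s
}

# O(n^2) exhaustive cluster finder: for every pair of member positions,
# check every adjacent link, then report maximal runs
brute_clusters <- function(starts, ends, member, max_intervening, max_gap_bp,
                           min_size) {
  idx <- which(member)
  if (length(idx) == 0) return(list())
  linked <- function(i, j) {
    (j - i - 1) <= max_intervening && (starts[j] - ends[i]) <= max_gap_bp
  }
  runs <- list()
  k <- 1
  while (k <= length(idx)) {
    run <- idx[k]
    while (k < length(idx) && linked(idx[k], idx[k + 1])) {
      k <- k + 1
      run <- c(run, idx[k])
    }
    if (length(run) >= min_size) runs[[length(runs) + 1]] <- run
    k <- k + 1
  }
  runs
}

aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_protein_str <- function(len) paste(sample(aa20, len, TRUE), collapse = "")

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  as.matrix(e$BLOSUM62)
}
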