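#' Molecular-evolution configuration
#'
#' @param wgd_ks_window Inclusive Ks window flagging pairs from the recent
#'   whole-genome duplication (default `c(0.15, 0.30)`).
#' @param stop_mutations How single-base mutations creating stop codons
#'   enter the NG86 site denominators: `"exclude"` (default) drops them
#'   from the per-position mutation count; `"nonsynonymous"` counts them as
#'   nonsynonymous.
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(wgd_ks_window = c(0.15, 0.30),
                             stop_mutations = c("exclude", "nonsynonymous")) {
  stop_mutations <- match.arg(stop_mutations)
  stopifnot(length(wgd_ks_window) == 2, wgd_ks_window[1] < wgd_ks_window[2])
  structure(list(wgd_ks_window = wgd_ks_window,
                 stop_mutations = stop_mutations),
            class = "evolution_config")
}

genetic_code <- function() {
  if (is.null(the$gcode)) the$gcode <- Biostrings::GENETIC_CODE
  the$gcode
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' Translate CDS sequences with the standard genetic code
#'
#' @param cds Character vector of CDS strings (length divisible by 3,
#'   sense codons only; a terminal stop codon is allowed and dropped).
#' @return Character vector of protein sequences.
#' @export
translate_cds <- function(cds) {
  gc <- genetic_code()
  vapply(cds, function(s) {
    if (nchar(s) %% 3 != 0) abort("CDS length not divisible by 3")
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aas <- gc[cods]
    if (anyNA(aas)) abort("CDS contains non-ACGT codons")
    n <- length(aas)
    if (aas[n] == "*") aas <- aas[-n]
    if (any(aas == "*")) abort("internal stop codon in CDS")
    paste(aas, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# per-codon NG86 synonymous-site fractions and mutation neighbourhoods
ng86_codon_table <- function(stop_mutations = "exclude") {
  key <- paste0("ng86_", stop_mutations)
  if (!is.null(the[[key]])) return(the[[key]])
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  codons <- sense_codons()
  s_frac <- numeric(length(codons))
  names(s_frac) <- codons
  syn_mut <- nonsyn_mut <- stats::setNames(vector("list", length(codons)), codons)
  for (cod in codons) {
    aa <- gc[[cod]]
    s <- 0
    syn <- nsy <- character(0)
    for (pos in 1:3) {
      nsyn <- 0; nvalid <- 0
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- b
        if (gc[[mut]] == "*") {
          if (stop_mutations == "nonsynonymous") nvalid <- nvalid + 1
          next
        }
        nvalid <- nvalid + 1
        if (gc[[mut]] == aa) {
          nsyn <- nsyn + 1
          syn <- c(syn, mut)
        } else {
          nsy <- c(nsy, mut)
        }
      }
      if (nvalid > 0) s <- s + nsyn / nvalid
    }
    s_frac[[cod]] <- s
    syn_mut[[cod]] <- syn
    nonsyn_mut[[cod]] <- nsy
  }
  the[[key]] <- list(s_frac = s_frac, syn_mut = syn_mut,
                     nonsyn_mut = nonsyn_mut)
  the[[key]]
}

# observed synonymous/nonsynonymous differences between two sense codons,
# averaged with equal weights over all orderings of the single-base steps;
# orderings passing through a stop codon are discarded (all-blocked pairs
# fall back to including them).
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0("pair_", c1, c2)
  if (!is.null(the[[key]])) return(the[[key]])
  gc <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- if (length(pos) == 1) list(pos) else {
    if (length(pos) == 2) list(pos, rev(pos)) else {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    }
  }
  walk <- function(order, allow_stops) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*" && !allow_stops) return(NULL)
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  counts <- purrr::compact(purrr::map(perms, walk, allow_stops = FALSE))
  if (length(counts) == 0) {
    counts <- purrr::map(perms, walk, allow_stops = TRUE)
  }
  res <- colMeans(do.call(rbind, counts))
  the[[key]] <- res
  res
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue column of the aligned protein pair is replaced by the
#' corresponding codon of its CDS; residue gaps become whole-codon (`---`)
#' gaps. The translation of each CDS must equal its ungapped protein row
#' (checked; a terminal stop codon on the CDS is stripped first).
#'
#' @param aln_a,aln_b Aligned protein strings (gaps as `-`), e.g. from
#'   [align_global()].
#' @param cds_a,cds_b CDS strings for the two proteins.
#' @param gene_a,gene_b Ids used in error messages.
#' @return A list of class `codon_alignment`: `codons_a`, `codons_b`
#'   (character vectors, `---` for gaps), `n_codons_ungapped`, and the ids.
#' @export
codon_align <- function(aln_a, aln_b, cds_a, cds_b,
                        gene_a = "a", gene_b = "b") {
  strip_stop <- function(s) {
    gcn <- genetic_code()
    if (nchar(s) %% 3 == 0 && nchar(s) >= 3) {
      last <- substr(s, nchar(s) - 2, nchar(s))
      if (!is.na(gcn[last]) && gcn[last] == "*") {
        return(substr(s, 1, nchar(s) - 3))
      }
    }
    s
  }
  row <- function(aln, cds, gene) {
    cds <- strip_stop(cds)
    prot <- gsub("-", "", aln)
    if (nchar(cds) != 3 * nchar(prot)) {
      abort(paste0("codon_align: CDS length of ", gene,
                   " (", nchar(cds), ") is not 3x its aligned protein (",
                   nchar(prot), " residues)"))
    }
    tr <- translate_cds(cds)
    if (tr != prot) {
      bad <- which(strsplit(tr, "")[[1]] != strsplit(prot, "")[[1]])[1]
      abort(paste0("codon_align: translation mismatch for ", gene,
                   " at residue ", bad))
    }
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    cols <- strsplit(aln, "")[[1]]
    out <- character(length(cols))
    k <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- cods[k] }
    }
    out
  }
  ca <- row(aln_a, cds_a, gene_a)
  cb <- row(aln_b, cds_b, gene_b)
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 codons_a = ca, codons_b = cb,
                 n_codons_ungapped = sum(ca != "---" & cb != "---")),
            class = "codon_alignment")
}

#' Nei-Gojobori (1986) Ka/Ks estimation
#'
#' Synonymous and nonsynonymous site counts come from single-base mutation
#' enumeration per codon (stop-codon mutations handled per
#' [evolution_config()]), averaged over the two sequences; observed
#' differences in multi-substitution codons are averaged with equal weights
#' over all orderings of the single steps, discarding orderings through
#' stop codons. Proportions are Jukes-Cantor corrected,
#' `d = -(3/4) log(1 - (4/3) p)`; a proportion at or above 3/4 sets the
#' `saturated` flag and leaves that estimate undefined.
#'
#' @param aln A [codon_align()] result.
#' @param config An [evolution_config()].
#' @return One-row tibble: `gene_a`, `gene_b`, `S_sites`, `N_sites`, `Sd`,
#'   `Nd`, `Ka`, `Ks`, `ratio`, `saturated`.
#' @export
ng86 <- function(aln, config = evolution_config()) {
  keep <- aln$codons_a != "---" & aln$codons_b != "---"
  ca <- aln$codons_a[keep]
  cb <- aln$codons_b[keep]
  if (length(ca) == 0) abort("ng86: empty ungapped alignment")
  tab <- ng86_codon_table(config$stop_mutations)
  bad <- c(ca, cb)[!c(ca, cb) %in% names(tab$s_frac)]
  if (length(bad) > 0) {
    abort(paste0("ng86: non-sense codons in alignment: ",
                 paste(unique(bad), collapse = ", ")))
  }
  S <- (sum(tab$s_frac[ca]) + sum(tab$s_frac[cb])) / 2
  N <- 3 * length(ca) - S
  d <- purrr::map2(ca, cb, codon_pair_diffs)
  Sd <- sum(vapply(d, `[[`, numeric(1), "sd"))
  Nd <- sum(vapply(d, `[[`, numeric(1), "nd"))
  jc <- function(p) {
    if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc(ps)
  Ka <- jc(pn)
  saturated <- is.na(Ks) || is.na(Ka)
  ratio <- if (!saturated && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  tibble::tibble(gene_a = aln$gene_a, gene_b = aln$gene_b,
                 S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 Ka = Ka, Ks = Ks, ratio = ratio, saturated = saturated)
}

#' Estimate Ka/Ks for a pair of CDS sequences
#'
#' Convenience route: translate both CDS, align the proteins globally,
#' back-translate to codons and run [ng86()].
#'
#' @param cds_a,cds_b CDS strings.
#' @param gene_a,gene_b Ids for the output row.
#' @param scoring An [alignment_scoring()].
#' @param config An [evolution_config()].
#' @return One-row tibble as from [ng86()].
#' @export
kaks_pair <- function(cds_a, cds_b, gene_a = "a", gene_b = "b",
                      scoring = alignment_scoring(),
                      config = evolution_config()) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  al <- align_global(pa, pb, scoring)
  ng86(codon_align(al$aln_a, al$aln_b, cds_a, cds_b, gene_a, gene_b), config)
}

#' Estimate Ka/Ks for a table of gene pairs
#'
#' @param pairs Tibble with `gene_a`, `gene_b` (extra columns carried
#'   through).
#' @param cds CDS tibble (`id`, `sequence`).
#' @param scoring An [alignment_scoring()].
#' @param config An [evolution_config()].
#' @return `pairs` joined with the [ng86()] estimates and the selection
#'   `regime` from [classify_selection()].
#' @export
kaks_table <- function(pairs, cds, scoring = alignment_scoring(),
                       config = evolution_config()) {
  est <- purrr::map(seq_len(nrow(pairs)), function(i) {
    sa <- cds$sequence[match(pairs$gene_a[i], cds$id)]
    sb <- cds$sequence[match(pairs$gene_b[i], cds$id)]
    if (is.na(sa) || is.na(sb)) {
      abort(paste0("kaks_table: missing CDS for pair ",
                   pairs$gene_a[i], " / ", pairs$gene_b[i]))
    }
    kaks_pair(sa, sb, pairs$gene_a[i], pairs$gene_b[i], scoring, config)
  }) |> dplyr::bind_rows()
  out <- dplyr::left_join(pairs, est, by = c("gene_a", "gene_b"))
  classify_selection(out)
}

#' Classify the selection regime from the Ka/Ks ratio
#'
#' Ka/Ks above 1 indicates positive (Darwinian) selection, equal to 1
#' (within 1e-9) neutral evolution, below 1 purifying selection; an
#' undefined ratio yields `undefined`.
#'
#' @param estimates Tibble with a `ratio` column.
#' @return `estimates` with an added `regime` column.
#' @export
classify_selection <- function(estimates) {
  r <- estimates$ratio
  estimates$regime <- dplyr::case_when(
    is.na(r) ~ "undefined",
    abs(r - 1) <= 1e-9 ~ "neutral",
    r > 1 ~ "positive",
    TRUE ~ "purifying")
  estimates
}

#' Flag duplicate pairs from the recent whole-genome duplication
#'
#' WGD-mode pairs whose Ks falls inside the configured window (endpoints
#' inclusive).
#'
#' @param calls Tibble with `mode` and `Ks` columns (e.g.
#'   [classify_modes()] output joined with [kaks_table()] estimates).
#' @param config An [evolution_config()].
#' @return The subset of `calls` flagged as recent-WGD pairs.
#' @export
flag_recent_wgd <- function(calls, config = evolution_config()) {
  w <- config$wgd_ks_window
  calls[!is.na(calls$Ks) & calls$mode == "WGD" &
          calls$Ks >= w[1] & calls$Ks <= w[2], , drop = FALSE]
}
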