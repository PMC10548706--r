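#' P450 signature region consensus patterns
#'
#' The four conserved regions diagnostic of cytochrome P450s, with the
#' A-type vs non-A-type variant consensi for the heme-binding, PERF and
#' I-helix regions. In a consensus, `X` matches any residue (including `X`
#' itself) and `[D/E]` matches exactly `D` or `E`. Every A-type consensus is
#' a strict specialisation of its non-A counterpart, so A-type matches are
#' tested first when classifying. The K-helix region has no published
#' A/non-A split; its consensus defaults to the canonical `EXXR` and is
#' configurable.
#'
#' @param khelix Consensus for the K-helix region (default `"EXXR"`).
#' @return Tibble with columns `region` (`heme`, `perf`, `ihelix`,
#'   `khelix`), `variant` (`A`, `nonA`, `generic`) and `consensus`.
#' @export
signature_patterns <- function(khelix = "EXXR") {
  stopifnot(nzchar(khelix))
  tibble::tibble(
    region = c("heme", "heme", "perf", "perf", "ihelix", "ihelix", "khelix"),
    variant = c("A", "nonA", "A", "nonA", "A", "nonA", "generic"),
    consensus = c("PFGXGRRXCXG", "XFXXGXRXCXG",
                  "FXPERF", "FXPXRX",
                  "AGXDT", "AGX[D/E]T",
                  khelix))
}

# split a consensus into single-position tokens: letters, X, or [A/B] groups
consensus_tokens <- function(consensus) {
  toks <- regmatches(consensus,
                     gregexpr("\\[[A-Z](/[A-Z])+\\]|[A-Z]", consensus))[[1]]
  if (paste(toks, collapse = "") != consensus) {
    abort(paste0("malformed consensus pattern: ", consensus))
  }
  toks
}

consensus_to_regex <- function(consensus) {
  toks <- consensus_tokens(consensus)
  parts <- vapply(toks, function(t) {
    if (t == "X") "."
    else if (startsWith(t, "[")) paste0("[", gsub("[^A-Z]", "", t), "]")
    else t
  }, character(1))
  list(regex = paste(parts, collapse = ""), width = length(toks))
}

# all match start positions (overlapping allowed) of a consensus in seq
consensus_starts <- function(seq, consensus) {
  cr <- consensus_to_regex(consensus)
  if (nchar(seq) < cr$width) return(integer(0))
  m <- gregexpr(paste0("(?=", cr$regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

scan_one <- function(seq, patterns) {
  hits <- purrr::pmap(patterns, function(region, variant, consensus) {
    st <- consensus_starts(seq, consensus)
    if (length(st) == 0) return(NULL)
    w <- consensus_to_regex(consensus)$width
    tibble::tibble(region = region, variant = variant,
                   start = st, end = st + w - 1L,
                   match = substring(seq, st, st + w - 1L))
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble::tibble(region = character(), variant = character(),
                          start = integer(), end = integer(),
                          match = character()))
  }
  # a window matching the A-specific consensus is reported once, as A
  hits |>
    dplyr::mutate(pref = match(.data$variant, c("A", "nonA", "generic"))) |>
    dplyr::arrange(.data$region, .data$start, .data$pref) |>
    dplyr::distinct(.data$region, .data$start, .keep_all = TRUE) |>
    dplyr::select("region", "variant", "start", "end", "match")
}

#' Scan protein sequences for the four P450 signature regions
#'
#' Reports every match start (overlapping matches allowed) of each region's
#' consensus. A window that matches the A-specific consensus is labelled
#' `variant = "A"`; a window matching only the non-A consensus is labelled
#' `"nonA"`; K-helix hits are `"generic"`. An empty sequence yields a
#' zero-hit profile, not an error.
#'
#' @param proteins Tibble with columns `id` and `sequence` (as from
#'   [read_fasta()]), or a character vector of sequences (names used as ids).
#' @param patterns A [signature_patterns()] tibble.
#' @return Tibble with one row per protein: `id`, `hits` (list of per-hit
#'   tibbles with `region`, `variant`, `start`, `end`, `match`) and
#'   `n_regions` (regions with at least one hit, 0-4).
#' @export
scan_signatures <- function(proteins, patterns = signature_patterns()) {
  if (is.character(proteins)) {
    ids <- names(proteins) %||% paste0("seq", seq_along(proteins))
    proteins <- tibble::tibble(id = ids, sequence = unname(proteins))
  }
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  hits <- purrr::map(proteins$sequence, scan_one, patterns = patterns)
  tibble::tibble(
    id = proteins$id,
    hits = hits,
    n_regions = vapply(hits, function(h) length(unique(h$region)), integer(1)))
}

#' Classify proteins as A-type or non-A-type from their signature profile
#'
#' A protein with at least one A-specific region match is `A`; otherwise one
#' with at least one non-A match is `nonA`; a zero-hit profile (or
#' generic-only hits) is `unclassified`. Because every A-type consensus also
#' satisfies its non-A counterpart, A-type is tested first — ties are
#' impossible.
#'
#' @param profiles Output of [scan_signatures()].
#' @return `profiles` with an added `type` column
#'   (`A`/`nonA`/`unclassified`).
#' @export
classify_type <- function(profiles) {
  stopifnot("hits" %in% names(profiles))
  profiles$type <- vapply(profiles$hits, function(h) {
    if (any(h$variant == "A")) "A"
    else if (any(h$variant == "nonA")) "nonA"
    else "unclassified"
  }, character(1))
  profiles
}
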