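#' Candidate identification configuration
#'
#' Filters used by [screen_candidates()]. A candidate is kept when it is at
#' least `min_length` residues long, carries domain-type evidence (at least
#' `min_regions` signature regions, or an ingested `domain_scan` evidence
#' row with E-value at or below `evalue_max`) and similarity evidence (an
#' ingested `similarity` row passing `evalue_max`, or internal global
#' identity of at least `similarity_min_identity` over at least
#' `similarity_min_aligned` aligned residues to some reference protein).
#' The internal identity route stands in for an external aligner's E-value
#' so the dual-evidence intersection can run self-contained.
#'
#' @param min_length Minimum protein length in residues (default 100).
#' @param evalue_max E-value ceiling for ingested evidence (default 1e-10).
#' @param min_regions Minimum signature regions for internal domain
#'   evidence (default 1).
#' @param similarity_min_identity Identity floor for internal similarity
#'   evidence (fraction, default 0.30).
#' @param similarity_min_aligned Minimum aligned residues for internal
#'   similarity evidence (default 150).
#' @return A list of class `identification_config`.
#' @export
identification_config <- function(min_length = 100L, evalue_max = 1e-10,
                                  min_regions = 1L,
                                  similarity_min_identity = 0.30,
                                  similarity_min_aligned = 150L) {
  stopifnot(min_length >= 1,
            similarity_min_identity > 0, similarity_min_identity < 1)
  structure(list(min_length = as.integer(min_length), evalue_max = evalue_max,
                 min_regions = as.integer(min_regions),
                 similarity_min_identity = similarity_min_identity,
                 similarity_min_aligned = as.integer(similarity_min_aligned)),
            class = "identification_config")
}

#' Screen a proteome for high-confidence P450 candidates
#'
#' Applies the dual-evidence rule described in [identification_config()]:
#' candidates must show both domain-type evidence (signature regions or an
#' external domain scan) and similarity evidence (external hit or internal
#' identity to a reference P450), and must not be fragments shorter than
#' `min_length`. Every rejected protein carries a reason code.
#'
#' @param records Protein tibble (`id`, `sequence`).
#' @param references Reference P450 protein tibble (`id`, `sequence`);
#'   required unless external similarity evidence covers the screen.
#' @param evidence Optional evidence tibble from [read_evidence_table()]
#'   (rows of both sources may be mixed).
#' @param config An [identification_config()].
#' @param patterns A [signature_patterns()] tibble.
#' @param scoring An [alignment_scoring()] for the internal identity route.
#' @return Tibble: `id`, `length`, `n_regions`, `type`, `kept`, `reasons`
#'   (comma-joined codes, empty when kept) plus a `hits` list column with
#'   the signature profile.
#' @export
screen_candidates <- function(records, references = NULL, evidence = NULL,
                              config = identification_config(),
                              patterns = signature_patterns(),
                              scoring = alignment_scoring()) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  has_sim_evidence <- !is.null(evidence) && any(evidence$source == "similarity")
  if ((is.null(references) || nrow(references) == 0) && !has_sim_evidence) {
    abort("screen_candidates needs a reference set or external similarity evidence")
  }
  profiles <- classify_type(scan_signatures(records, patterns))
  dom_ids <- sim_ids <- character(0)
  if (!is.null(evidence)) {
    ok <- evidence$evalue <= config$evalue_max
    dom_ids <- unique(evidence$query_id[ok & evidence$source == "domain_scan"])
    sim_ids <- unique(evidence$query_id[ok & evidence$source == "similarity"])
  }

  internal_similarity <- function(seq) {
    if (is.null(references) || nrow(references) == 0) return(FALSE)
    for (r in references$sequence) {
      res <- global_identity(seq, r, scoring)
      if (res$identity >= config$similarity_min_identity &&
          res$aligned_length >= config$similarity_min_aligned) {
        return(TRUE)
      }
    }
    FALSE
  }

  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    seq <- records$sequence[i]
    len <- nchar(seq)
    nreg <- profiles$n_regions[i]
    reasons <- character(0)
    too_short <- len < config$min_length
    if (too_short) reasons <- c(reasons, "too_short")
    has_domain <- nreg >= config$min_regions || id %in% dom_ids
    if (!has_domain) reasons <- c(reasons, "no_domain")
    # the alignment is only paid for when the cheap filters pass
    has_sim <- if (id %in% sim_ids) TRUE
      else if (too_short || !has_domain) NA
      else internal_similarity(seq)
    if (isFALSE(has_sim)) reasons <- c(reasons, "no_similarity")
    tibble::tibble(id = id, length = len, n_regions = nreg,
                   type = profiles$type[i],
                   kept = !too_short && has_domain && isTRUE(has_sim),
                   reasons = paste(reasons, collapse = ","),
                   hits = profiles$hits[i])
  })
  dplyr::bind_rows(rows)
}

# average residue masses (Da); water added once per chain
residue_masses <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
water_mass <- 18.0153

# EMBOSS pKa set used for the isoelectric point
pka_emboss <- c(Nterm = 8.6, Cterm = 3.6,
                C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5,
                Y = 10.1)

net_charge_at <- function(counts, pH) {
  pos <- c(Nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
           H = unname(counts["H"]))
  neg <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
           C = unname(counts["C"]), Y = unname(counts["Y"]))
  q_pos <- sum(pos / (1 + 10^(pH - pka_emboss[names(pos)])))
  q_neg <- sum(neg / (1 + 10^(pka_emboss[names(neg)] - pH)))
  q_pos - q_neg
}

#' Physicochemical summary of protein sequences
#'
#' Molecular weight is the sum of average residue masses plus one water
#' mass; `X` contributes the mean of the 20 standard residue masses. The
#' isoelectric point is the pH at which the Henderson-Hasselbalch net
#' charge (free termini plus D, E, C, Y side chains against H, K, R, using
#' the EMBOSS pKa set) crosses zero, located by bisection; sequences
#' containing `X` get `NA` for pI.
#'
#' @param proteins Protein tibble (`id`, `sequence`) or character vector.
#' @return Tibble: `id`, `length`, `molecular_weight` (Da),
#'   `isoelectric_point` (pH units).
#' @export
physchem <- function(proteins) {
  if (is.character(proteins)) {
    ids <- names(proteins) %||% paste0("seq", seq_along(proteins))
    proteins <- tibble::tibble(id = ids, sequence = unname(proteins))
  }
  if (any(!nzchar(proteins$sequence))) {
    abort("physchem: empty sequence")
  }
  rows <- purrr::map2(proteins$id, proteins$sequence, function(id, seq) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    masses <- residue_masses[chars]
    masses[chars == "X"] <- mean(residue_masses)
    if (anyNA(masses)) abort(paste0("physchem: invalid residues in ", id))
    mw <- sum(masses) + water_mass
    pi <- if (any(chars == "X")) NA_real_ else {
      counts <- vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                       function(a) sum(chars == a), numeric(1))
      lo <- 0; hi <- 14
      while (hi - lo > 1e-4) {
        mid <- (lo + hi) / 2
        if (net_charge_at(counts, mid) > 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    tibble::tibble(id = id, length = nchar(seq),
                   molecular_weight = mw, isoelectric_point = pi)
  })
  dplyr::bind_rows(rows)
}
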