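#' Clan membership map for plant CYP families
#'
#' The ten-clan, 48-family layout observed in Rosaceae P450 complements:
#' the CYP71 clan (all A-type, 19 families), four multi-family non-A clans
#' (CYP72, CYP85, CYP86) and six single-family clans (CYP51, CYP74, CYP97,
#' CYP710, CYP711, CYP727). Family-to-clan placement for the multi-family
#' clans follows the standard plant P450 clan tables.
#'
#' @return Tibble with columns `family`, `clan`, `type` (`A`/`nonA`).
#' @export
clan_family_map <- function() {
  fam <- function(nums) paste0("CYP", nums)
  a_fams <- fam(c(71, 73, 75, 76, 77, 78, 79, 81, 82, 84, 89, 92, 93, 98,
                  701, 703, 706, 712, 736))
  clans <- list(
    CYP71 = a_fams,
    CYP51 = fam(51),
    CYP72 = fam(c(72, 714, 715, 721, 734, 735, 749)),
    CYP74 = fam(74),
    CYP85 = fam(c(85, 87, 88, 90, 707, 716, 718, 720, 722, 724, 728, 729, 733)),
    CYP86 = fam(c(86, 94, 704)),
    CYP97 = fam(97),
    CYP710 = fam(710),
    CYP711 = fam(711),
    CYP727 = fam(727))
  purrr::imap(clans, function(fams, clan) {
    tibble::tibble(family = fams, clan = clan,
                   type = if (clan == "CYP71") "A" else "nonA")
  }) |> dplyr::bind_rows()
}

#' Nomenclature thresholds
#'
#' The canonical P450 naming tiers expressed as strict identity thresholds:
#' two sequences above 40% identity are in the same family, above 55% the
#' same subfamily, and above 95% they are allelic variants; at 40% or below
#' the query may represent a new family.
#'
#' @param family_min Family threshold (fraction, default 0.40).
#' @param subfamily_min Subfamily threshold (default 0.55).
#' @param allelic_min Allelic-variant threshold (default 0.95).
#' @param scoring An [alignment_scoring()] object.
#' @return A list of class `nomenclature_config`.
#' @export
nomenclature_config <- function(family_min = 0.40, subfamily_min = 0.55,
                                allelic_min = 0.95,
                                scoring = alignment_scoring()) {
  stopifnot(0 < family_min, family_min < subfamily_min,
            subfamily_min < allelic_min, allelic_min < 1)
  structure(list(family_min = family_min, subfamily_min = subfamily_min,
                 allelic_min = allelic_min, scoring = scoring),
            class = "nomenclature_config")
}

#' Read a labelled reference FASTA
#'
#' Reference headers carry their labels as whitespace-separated `key=value`
#' pairs, e.g. `>ref1 clan=CYP71 family=CYP71 subfamily=CYP71A type=A`.
#'
#' @param path Path to the reference FASTA.
#' @return Tibble with columns `id`, `sequence`, `clan`, `family`,
#'   `subfamily`, `type`.
#' @export
read_reference_fasta <- function(path) {
  recs <- read_fasta(path, kind = "protein")
  get_tag <- function(desc, key) {
    m <- stringr::str_match(desc, paste0("\\b", key, "=(\\S+)"))[, 2]
    m
  }
  out <- tibble::tibble(
    id = recs$id, sequence = recs$sequence,
    clan = get_tag(recs$description, "clan"),
    family = get_tag(recs$description, "family"),
    subfamily = get_tag(recs$description, "subfamily"),
    type = get_tag(recs$description, "type"))
  if (anyNA(out$family)) {
    abort("reference FASTA headers must carry family= labels")
  }
  out
}

#' Assign clan/family/subfamily tiers by identity to labelled references
#'
#' Each query is aligned to every reference; the best reference maximises
#' identity (ties broken by higher aligned length, then lexicographic
#' reference id). Identity strictly above the allelic threshold makes the
#' query an allelic variant of the best reference's subfamily; above the
#' subfamily threshold it joins that subfamily; above the family threshold,
#' the family only; at or below the family threshold the call is
#' `NEW_FAMILY` with clan `unassigned`. Clan and A/non-A type are inherited
#' from the best reference whenever a family is assigned; a message is
#' emitted when the top three references disagree on clan
#' (neighbour-consistency check in lieu of tree-based confirmation).
#'
#' @param queries Protein tibble (`id`, `sequence`).
#' @param references Labelled reference tibble as from
#'   [read_reference_fasta()].
#' @param config A [nomenclature_config()].
#' @return Tibble: `query_id`, `best_ref_id`, `identity`, `aligned_length`,
#'   `clan`, `family`, `subfamily`, `allelic_variant`, `type`.
#' @export
assign_family <- function(queries, references, config = nomenclature_config()) {
  if (is.null(references) || nrow(references) == 0) {
    abort("assign_family: empty reference list")
  }
  stopifnot(all(c("id", "sequence", "family") %in% names(references)))
  rows <- purrr::map(seq_len(nrow(queries)), function(i) {
    hits <- purrr::map(seq_len(nrow(references)), function(j) {
      res <- global_identity(queries$sequence[i], references$sequence[j],
                             config$scoring)
      tibble::tibble(ref_id = references$id[j], identity = res$identity,
                     aligned_length = res$aligned_length)
    }) |> dplyr::bind_rows() |>
      dplyr::arrange(dplyr::desc(.data$identity),
                     dplyr::desc(.data$aligned_length), .data$ref_id)
    best <- hits[1, ]
    ref <- references[references$id == best$ref_id, ]
    # neighbour consistency: only references themselves above the family
    # threshold can meaningfully dispute the clan
    top3 <- utils::head(hits[hits$identity > config$family_min, ], 3)
    top3_clans <- references$clan[match(top3$ref_id, references$id)]
    if (length(unique(stats::na.omit(top3_clans))) > 1) {
      inform(paste0("query ", queries$id[i],
                    ": top references disagree on clan (",
                    paste(unique(top3_clans), collapse = ", "), ")"))
    }
    idt <- best$identity
    tier <- if (idt > config$allelic_min) "allelic"
      else if (idt > config$subfamily_min) "subfamily"
      else if (idt > config$family_min) "family"
      else "new_family"
    tibble::tibble(
      query_id = queries$id[i],
      best_ref_id = best$ref_id,
      identity = idt,
      aligned_length = best$aligned_length,
      clan = if (tier == "new_family") "unassigned" else ref$clan,
      family = if (tier == "new_family") "NEW_FAMILY" else ref$family,
      subfamily = if (tier %in% c("allelic", "subfamily")) ref$subfamily
                  else NA_character_,
      allelic_variant = tier == "allelic",
      type = if (tier == "new_family") NA_character_ else ref$type)
  })
  dplyr::bind_rows(rows)
}

#' Summarise a set of family assignments
#'
#' Counts genes per clan and family, split by A-type / non-A-type, with a
#' totals row and the A-type percentage of each row's genes.
#'
#' @param assignments Output of [assign_family()] (or any tibble with
#'   `clan`, `family`, `type` columns).
#' @return Tibble: `clan`, `family`, `n_genes`, `n_A`, `n_nonA`, `pct_A`.
#'   The final row (`clan = "total"`) aggregates everything.
#' @export
summarize_classification <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble::tibble(clan = "total", family = "total", n_genes = 0L,
                          n_A = 0L, n_nonA = 0L, pct_A = NA_real_))
  }
  per <- assignments |>
    dplyr::group_by(.data$clan, .data$family) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     n_A = sum(.data$type == "A", na.rm = TRUE),
                     n_nonA = sum(.data$type == "nonA", na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$clan, .data$family)
  total <- tibble::tibble(clan = "total", family = "total",
                          n_genes = nrow(assignments),
                          n_A = sum(per$n_A), n_nonA = sum(per$n_nonA))
  dplyr::bind_rows(per, total) |>
    dplyr::mutate(pct_A = 100 * .data$n_A / .data$n_genes)
}
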