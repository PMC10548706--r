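#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flavonoid screen result
#'
#' @param x A `flavonoid_screen` object.
#' @param ... Unused.
#' @return The per-gene association tibble (r, p and q per metabolite
#'   series, stage-filter and candidate flags).
#' @method tidy flavonoid_screen
#' @export
tidy.flavonoid_screen <- function(x, ...) {
  x$per_gene
}

#' One-row summary of a flavonoid screen
#'
#' @param x A `flavonoid_screen` object.
#' @param ... Unused.
#' @return One-row tibble with the screened/passing counts and the
#'   thresholds used.
#' @method glance flavonoid_screen
#' @export
glance.flavonoid_screen <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$per_gene),
                 n_expressed = length(x$expressed),
                 n_stage1 = length(x$stage1),
                 n_stage2 = length(x$stage2),
                 n_candidates = length(x$candidates),
                 min_fpkm = x$config$min_fpkm,
                 alpha = x$config$alpha)
}

#' Tidy a P450 survey
#'
#' @param x A `p450_survey` object.
#' @param ... Unused.
#' @return The family-assignment tibble joined with the screen's kept flag.
#' @method tidy p450_survey
#' @export
tidy.p450_survey <- function(x, ...) {
  dplyr::left_join(x$assignments,
                   dplyr::select(x$screen, "id", "length", "n_regions",
                                 "kept"),
                   by = c(query_id = "id"))
}

#' One-row summary of a P450 survey
#'
#' @param x A `p450_survey` object.
#' @param ... Unused.
#' @return One-row tibble of headline counts.
#' @method glance p450_survey
#' @export
glance.p450_survey <- function(x, ...) {
  total <- x$classification[x$classification$clan == "total", ]
  tibble::tibble(
    n_screened = nrow(x$screen),
    n_kept = sum(x$screen$kept),
    n_families = length(unique(
      x$assignments$family[x$assignments$family != "NEW_FAMILY"])),
    pct_A = if (nrow(total)) total$pct_A else NA_real_,
    n_clusters = nrow(x$clusters),
    n_pairs = nrow(x$pairs),
    n_blocks = nrow(x$blocks),
    n_recent_wgd = if (is.null(x$recent_wgd)) 0L else nrow(x$recent_wgd))
}
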