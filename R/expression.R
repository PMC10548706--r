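#' Association-screen configuration
#'
#' @param min_fpkm Expression floor applied before any correlation
#'   (default 10); genes whose stage summary falls below it are removed.
#' @param stage_rule Stage summary the floor applies to: `"max"` (default;
#'   a gene strongly expressed in any one stage survives) or `"mean"`.
#' @param alpha Two-sided p-value threshold (default 0.05).
#' @param require_positive_r Keep only positively correlated genes?
#'   (default `FALSE`).
#' @return A list of class `association_config`.
#' @export
association_config <- function(min_fpkm = 10, stage_rule = c("max", "mean"),
                               alpha = 0.05, require_positive_r = FALSE) {
  stage_rule <- match.arg(stage_rule)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(min_fpkm = min_fpkm, stage_rule = stage_rule,
                 alpha = alpha, require_positive_r = require_positive_r),
            class = "association_config")
}

#' Compute FPKM from a count table
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length[g] * total_counts[s])`, the
#' per-sample library size being the column sum of the full table. When a
#' `replicate_map` is supplied (tibble `sample`, `group`), replicate
#' columns are averaged after normalisation.
#'
#' @param counts Tibble: `gene_id`, `length_bp`, then one integer column
#'   per sample.
#' @param replicate_map Optional tibble mapping sample columns to groups.
#' @return Tibble: `gene_id` plus one FPKM column per sample (or group),
#'   with attribute `provenance = "computed"`.
#' @export
compute_fpkm <- function(counts, replicate_map = NULL) {
  stopifnot(all(c("gene_id", "length_bp") %in% names(counts)))
  if (any(is.na(counts$length_bp) | counts$length_bp <= 0)) {
    abort("compute_fpkm: every gene needs a positive length_bp")
  }
  samples <- setdiff(names(counts), c("gene_id", "length_bp"))
  mat <- as.matrix(counts[samples])
  totals <- colSums(mat)
  if (any(totals <= 0)) abort("compute_fpkm: zero total counts in a sample")
  fpkm <- sweep(mat, 2, totals, "/") * 1e9 / counts$length_bp
  out <- tibble::as_tibble(fpkm)
  out <- dplyr::bind_cols(tibble::tibble(gene_id = counts$gene_id), out)
  if (!is.null(replicate_map)) {
    stopifnot(all(c("sample", "group") %in% names(replicate_map)))
    grouped <- purrr::map(unique(replicate_map$group), function(g) {
      cols <- replicate_map$sample[replicate_map$group == g]
      tibble::tibble(!!g := rowMeans(as.matrix(out[cols])))
    })
    out <- dplyr::bind_cols(tibble::tibble(gene_id = counts$gene_id), grouped)
  }
  attr(out, "provenance") <- "computed"
  out
}

#' Pearson correlation with a two-sided t test
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))`; the two-sided p-value is the tail
#' of the t distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both non-constant.
#' @return One-row tibble: `r`, `t_stat`, `p_two_sided`, `n`.
#' @export
pearson_two_sided <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("pearson_two_sided: length mismatch")
  if (n < 3) abort("pearson_two_sided: need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("pearson_two_sided: correlation undefined for a constant vector")
  }
  pearson_from_r(cor(x, y), n)
}

#' Two-sided p-value from a correlation coefficient
#'
#' The t transform applied directly to a printed/known `r` and `n`.
#'
#' @param r Pearson coefficient in `[-1, 1]`.
#' @param n Number of paired observations (`>= 3`).
#' @return One-row tibble: `r`, `t_stat`, `p_two_sided`, `n`.
#' @export
pearson_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  tibble::tibble(r = r, t_stat = t_stat, p_two_sided = p, n = as.integer(n))
}

#' Two-stage screen of expression against flavonoid content
#'
#' Stage 0 removes genes whose FPKM stage summary is below `min_fpkm`.
#' Stage 1 keeps genes correlated with the total flavonoid series at
#' `p < alpha`; stage 2 repeats the test against the sum of the major
#' flavonoid components. Benjamini-Hochberg q-values are reported as extra
#' columns for reference; candidacy uses the raw p-values.
#'
#' @param expr FPKM tibble (`gene_id` + one column per stage).
#' @param series Metabolite tibble: `stage`, `total_flavonoid`,
#'   `component_sum` (stages must match the expression columns).
#' @param config An [association_config()].
#' @return Object of class `flavonoid_screen`: a list with `per_gene`
#'   (gene-level tibble with r/p/q per series and the three set flags),
#'   `expressed`, `stage1`, `stage2`, `candidates` (id vectors; candidates
#'   = stage-1 AND stage-2) and `config`.
#' @export
screen_flavonoid_candidates <- function(expr, series,
                                        config = association_config()) {
  stages <- setdiff(names(expr), "gene_id")
  shared <- intersect(stages, as.character(series$stage))
  if (length(shared) < 3) {
    abort("screen_flavonoid_candidates: fewer than 3 shared stages")
  }
  series <- series[match(shared, as.character(series$stage)), ]
  mat <- as.matrix(expr[shared])
  summary_fun <- if (config$stage_rule == "max") matrixStats_rowMax else rowMeans
  stage_summary <- summary_fun(mat)
  expressed <- stage_summary >= config$min_fpkm

  assoc <- purrr::map(seq_len(nrow(expr)), function(i) {
    if (!expressed[i] || sd(mat[i, ]) == 0) {
      return(tibble::tibble(r_total = NA_real_, p_total = NA_real_,
                            r_components = NA_real_, p_components = NA_real_))
    }
    a1 <- pearson_two_sided(mat[i, ], series$total_flavonoid)
    a2 <- pearson_two_sided(mat[i, ], series$component_sum)
    tibble::tibble(r_total = a1$r, p_total = a1$p_two_sided,
                   r_components = a2$r, p_components = a2$p_two_sided)
  }) |> dplyr::bind_rows()

  pass <- function(r, p) {
    ok <- !is.na(p) & p < config$alpha
    if (config$require_positive_r) ok & !is.na(r) & r > 0 else ok
  }
  per_gene <- dplyr::bind_cols(
    tibble::tibble(gene_id = expr$gene_id,
                   stage_summary_fpkm = stage_summary,
                   expressed = expressed),
    assoc) |>
    dplyr::mutate(
      q_total = p.adjust(.data$p_total, method = "BH"),
      q_components = p.adjust(.data$p_components, method = "BH"),
      stage1 = pass(.data$r_total, .data$p_total),
      stage2 = pass(.data$r_components, .data$p_components),
      candidate = .data$stage1 & .data$stage2)

  structure(list(per_gene = per_gene,
                 expressed = per_gene$gene_id[per_gene$expressed],
                 stage1 = per_gene$gene_id[per_gene$stage1],
                 stage2 = per_gene$gene_id[per_gene$stage2],
                 candidates = per_gene$gene_id[per_gene$candidate],
                 stages = shared,
                 config = config),
            class = "flavonoid_screen")
}

matrixStats_rowMax <- function(m) apply(m, 1, max)

#' @export
print.flavonoid_screen <- function(x, ...) {
  cat("Flavonoid association screen\n")
  cat("  stages:        ", paste(x$stages, collapse = ", "), "\n")
  cat("  genes passing FPKM floor:", length(x$expressed), "\n")
  cat("  stage-1 candidates (total flavonoid):", length(x$stage1), "\n")
  cat("  stage-2 candidates (component sum):  ", length(x$stage2), "\n")
  cat("  intersection:", length(x$candidates), "\n")
  invisible(x)
}

#' Classify the retention mechanism of a duplicate pair
#'
#' A stage counts as expressed at FPKM of at least `expressed_min`. Rules
#' in order: one copy silent everywhere while the other is expressed
#' somewhere - specialisation or nonfunctionalisation (indistinguishable
#' without an outgroup); both expressed with disjoint expressed-stage sets
#' - subfunctionalisation; correlation at or above `dosage_min_r` with both
#' copies expressed in at least half the stages - dosage balance; otherwise
#' unclassified.
#'
#' @param expr FPKM tibble (`gene_id` + stage columns).
#' @param pairs Tibble `gene_a`, `gene_b`.
#' @param expressed_min Expressed-stage FPKM threshold (default 1).
#' @param dosage_min_r Correlation threshold for dosage balance
#'   (default 0.8).
#' @return `pairs` with added `mechanism`, `r_pair`, `n_expressed_a`,
#'   `n_expressed_b` columns.
#' @export
classify_retention <- function(expr, pairs, expressed_min = 1,
                               dosage_min_r = 0.8) {
  stages <- setdiff(names(expr), "gene_id")
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    e1 <- as.numeric(expr[match(pairs$gene_a[i], expr$gene_id), stages])
    e2 <- as.numeric(expr[match(pairs$gene_b[i], expr$gene_id), stages])
    if (anyNA(e1) || anyNA(e2)) {
      abort(paste0("classify_retention: missing expression for pair ",
                   pairs$gene_a[i], " / ", pairs$gene_b[i]))
    }
    classify_retention_pair(e1, e2, expressed_min, dosage_min_r)
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(rows))
}

#' @rdname classify_retention
#' @param e1,e2 FPKM stage vectors of one duplicate pair (equal length).
#' @export
classify_retention_pair <- function(e1, e2, expressed_min = 1,
                                    dosage_min_r = 0.8) {
  if (length(e1) != length(e2)) {
    abort("classify_retention_pair: stage vectors differ in length")
  }
  on1 <- e1 >= expressed_min
  on2 <- e2 >= expressed_min
  r <- if (sd(e1) > 0 && sd(e2) > 0) cor(e1, e2) else NA_real_
  half <- length(e1) / 2
  mech <- if (xor(any(on1), any(on2))) {
    "specialization_or_nonfunctionalization"
  } else if (any(on1) && any(on2) && !any(on1 & on2)) {
    "subfunctionalization"
  } else if (!is.na(r) && r >= dosage_min_r &&
             sum(on1) >= half && sum(on2) >= half) {
    "dosage_balance"
  } else {
    "unclassified"
  }
  tibble::tibble(mechanism = mech, r_pair = r,
                 n_expressed_a = sum(on1), n_expressed_b = sum(on2))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; against the calibrator
#' sample, `ddCt = dCt_sample - dCt_calibrator`; the fold change is
#' `2^-ddCt` (exactly 1 for the calibrator itself).
#'
#' @param ct Tibble with columns `gene`, `sample`, `ct`.
#' @param reference_gene Reference (housekeeping) gene id, measured in
#'   every sample.
#' @param calibrator_sample Calibrator sample id.
#' @return Tibble: `gene`, `sample`, `fold_change` (reference gene
#'   excluded).
#' @export
relative_expression_ddct <- function(ct, reference_gene, calibrator_sample) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  samples <- unique(ct$sample)
  if (!calibrator_sample %in% samples) {
    abort("relative_expression_ddct: calibrator sample not present")
  }
  ref <- ct[ct$gene == reference_gene, ]
  if (!all(samples %in% ref$sample)) {
    abort(paste0("relative_expression_ddct: reference gene missing in: ",
                 paste(setdiff(samples, ref$sample), collapse = ", ")))
  }
  ref_ct <- setNames(ref$ct, ref$sample)
  targets <- ct[ct$gene != reference_gene, ]
  targets |>
    dplyr::mutate(dct = .data$ct - unname(ref_ct[.data$sample])) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(fold_change = 2^-(.data$dct -
                                      .data$dct[.data$sample == calibrator_sample])) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "sample", "fold_change")
}
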