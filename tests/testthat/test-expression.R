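test_that("FPKM matches its definition and is library-size invariant", {
  counts <- tibble::tibble(gene_id = c("g1", "filler"),
                           length_bp = c(1000, 1000),
                           s1 = c(10, 1e6 - 10))
  f <- compute_fpkm(counts)
  expect_equal(f$s1[1], 10)

  # multiplying a sample's counts by a constant changes nothing
  counts2 <- counts
  counts2$s1 <- counts2$s1 * 7
  expect_equal(compute_fpkm(counts2)$s1, f$s1)

  # random tables equal an independent two-line reimplementation
  set.seed(31)
  tab <- tibble::tibble(gene_id = paste0("g", 1:40),
                        length_bp = sample(300:3000, 40),
                        a = rpois(40, 500), b = rpois(40, 800))
  got <- compute_fpkm(tab)
  mat <- as.matrix(tab[, c("a", "b")])
  want <- t(t(mat) / colSums(mat)) * 1e9 / tab$length_bp
  expect_equal(as.matrix(got[, c("a", "b")]), want, ignore_attr = TRUE)

  expect_error(compute_fpkm(tibble::tibble(gene_id = "g", length_bp = NA,
                                           s1 = 5)), "length_bp")

  # replicates averaged after normalisation
  reps <- tibble::tibble(gene_id = c("g1", "g2"), length_bp = c(1000, 1000),
                         r1 = c(10, 90), r2 = c(30, 70))
  rmap <- tibble::tibble(sample = c("r1", "r2"), group = c("s", "s"))
  avg <- compute_fpkm(reps, rmap)
  norm <- compute_fpkm(reps)
  expect_equal(avg$s, rowMeans(as.matrix(norm[, c("r1", "r2")])))
})

test_that("Pearson p-values match the t transform and its properties", {
  x <- 1:5
  perfect <- pearson_two_sided(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p_two_sided, 1e-12)

  printed <- pearson_from_r(0.87, 5)
  expect_gt(printed$p_two_sided, 0.053)
  expect_lt(printed$p_two_sided, 0.056)

  # closed-form tail equals numerical integration of the t density
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    r <- runif(1, -0.95, 0.95)
    p <- pearson_from_r(r, n)$p_two_sided
    tstat <- abs(r) * sqrt((n - 2) / (1 - r^2))
    quad <- 2 * stats::integrate(function(t) stats::dt(t, n - 2), tstat, Inf,
                                 rel.tol = 1e-10)$value
    expect_equal(p, quad, tolerance = 1e-6)
  }

  # p decreasing in |r| for fixed n, and in n for fixed |r|
  rs <- seq(0.1, 0.9, by = 0.1)
  ps <- vapply(rs, function(r) pearson_from_r(r, 6)$p_two_sided, numeric(1))
  expect_true(all(diff(ps) < 0))
  ns <- 4:12
  pn <- vapply(ns, function(n) pearson_from_r(0.5, n)$p_two_sided, numeric(1))
  expect_true(all(diff(pn) < 0))

  expect_error(pearson_two_sided(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_two_sided(1:4, 1:5), "length mismatch")
})

test_that("the two-stage screen filters on FPKM then correlation", {
  expr <- tibble::tibble(
    gene_id = c("low", "driver", "flat"),
    `1` = c(9.9, 10, 50), `2` = c(5, 20, 50), `3` = c(2, 40, 50),
    `4` = c(1, 80, 50), `5` = c(0.5, 160, 50))
  series <- tibble::tibble(stage = as.character(1:5),
                           total_flavonoid = c(10, 20, 40, 80, 160) * 3,
                           component_sum = c(10, 20, 40, 80, 160) * 1.5)
  scr <- screen_flavonoid_candidates(expr, series)
  expect_false("low" %in% scr$expressed)
  expect_true("driver" %in% scr$stage1)
  expect_true("driver" %in% scr$stage2)
  expect_equal(scr$candidates, "driver")
  pg <- tidy(scr)
  expect_equal(pg$r_total[pg$gene_id == "driver"], 1)

  # monotonicity: lowering alpha or raising the floor never adds candidates
  scr_tight <- screen_flavonoid_candidates(
    expr, series, association_config(alpha = 0.01))
  expect_true(all(scr_tight$candidates %in% scr$candidates))
  scr_high <- screen_flavonoid_candidates(
    expr, series, association_config(min_fpkm = 100))
  expect_true(all(scr_high$candidates %in% scr$candidates))

  expect_error(
    screen_flavonoid_candidates(expr[, 1:3],
                                series[1:2, ]), "fewer than 3")
})

test_that("retention mechanisms follow the rule order and are symmetric", {
  expect_equal(classify_retention_pair(c(10, 10, 0, 0, 0),
                                       c(0, 0, 10, 10, 10))$mechanism,
               "subfunctionalization")
  expect_equal(classify_retention_pair(c(5, 5, 5, 5, 5) + 0:4 / 10,
                                       c(6, 6, 6, 6, 6) + 0:4 / 10)$mechanism,
               "dosage_balance")
  expect_equal(classify_retention_pair(c(50, 40, 60, 55, 45),
                                       rep(0, 5))$mechanism,
               "specialization_or_nonfunctionalization")
  expect_equal(classify_retention_pair(c(10, 0, 10, 0, 10),
                                       c(0, 10, 10, 0, 0))$mechanism,
               "unclassified")
  # symmetry up to copy roles
  for (pair in list(list(c(10, 10, 0, 0, 0), c(0, 0, 10, 10, 10)),
                    list(c(50, 40, 60, 55, 45), rep(0, 5)))) {
    expect_equal(classify_retention_pair(pair[[1]], pair[[2]])$mechanism,
                 classify_retention_pair(pair[[2]], pair[[1]])$mechanism)
  }
  expect_error(classify_retention_pair(1:4, 1:5), "length")
})

test_that("2^-ddCt folds calibrate and cancel constant shifts", {
  ct <- tibble::tibble(
    gene = rep(c("ref", "target"), each = 2),
    sample = rep(c("cal", "trt"), 2),
    ct = c(20, 21, 24, 23))   # dCt: cal 4, trt 2
  out <- relative_expression_ddct(ct, "ref", "cal")
  expect_equal(out$fold_change[out$sample == "cal"], 1.0)
  expect_equal(out$fold_change[out$sample == "trt"], 4.0)

  shifted <- ct
  shifted$ct[shifted$sample == "trt"] <- shifted$ct[shifted$sample == "trt"] + 3
  out2 <- relative_expression_ddct(shifted, "ref", "cal")
  expect_equal(out2$fold_change, out$fold_change)

  expect_error(relative_expression_ddct(ct[ct$gene != "ref", ], "ref", "cal"),
               "reference gene")
})
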