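test_that("codon alignment back-translates and validates", {
  aln <- codon_align("MK", "MK", "ATGAAA", "ATGAAG")
  expect_equal(aln$codons_a, c("ATG", "AAA"))
  expect_equal(aln$codons_b, c("ATG", "AAG"))
  expect_equal(aln$n_codons_ungapped, 2L)

  gap <- codon_align("MK-", "MKV", "ATGAAA", "ATGAAAGTT")
  expect_equal(gap$codons_a[3], "---")

  expect_error(codon_align("MK", "MK", "ATGAAAGTT", "ATGAAG"), "not 3x")
  expect_error(codon_align("MV", "MK", "ATGAAA", "ATGAAG"),
               "translation mismatch.*residue 2")

  # generator round-trip: translations always re-verify
  set.seed(41)
  for (i in 1:20) {
    cds <- paste(sample(p450tools:::sense_codons(), 50, TRUE), collapse = "")
    mut <- evolve_cds(cds, 0.2, 0.5, seed = i)
    expect_silent(
      al <- align_global(translate_cds(cds), translate_cds(mut)))
    expect_s3_class(ng86(codon_align(al$aln_a, al$aln_b, cds, mut)),
                    "tbl_df")
  }
})

test_that("NG86 per-codon site fractions equal 9-mutation enumeration", {
  for (mode in c("exclude", "nonsynonymous")) {
    tab <- p450tools:::ng86_codon_table(mode)
    for (cod in p450tools:::sense_codons()) {
      expect_equal(tab$s_frac[[cod]], ng86_site_oracle(cod, mode),
                   label = paste(cod, mode))
    }
  }
})

test_that("NG86 reproduces the worked example and basic identities", {
  same <- kaks_pair("ATGGCTCAT", "ATGGCTCAT")
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_true(is.na(same$ratio))

  ex <- kaks_pair("GGTGCTCAT", "GGCGCTCAT")
  expect_equal(ex$S_sites, 7 / 3)
  expect_equal(ex$N_sites, 20 / 3)
  expect_equal(ex$Sd, 1)
  expect_equal(ex$Nd, 0)
  expect_equal(ex$Ka, 0)
  expect_equal(ex$Ks, -3 / 4 * log(1 - 4 / 3 * 3 / 7), tolerance = 1e-9)
  expect_equal(ex$Ks, 0.6355, tolerance = 1e-4)
})

test_that("NG86 is symmetric and conserves site counts", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    a <- paste(sample(p450tools:::sense_codons(), n, TRUE), collapse = "")
    b <- as.character(evolve_cds(a, runif(1, 0, 0.5), runif(1, 0, 1),
                                 seed = i))
    ab <- kaks_pair(a, b)
    ba <- kaks_pair(b, a)
    expect_equal(ab$Ks, ba$Ks)
    expect_equal(ab$Ka, ba$Ka)
    expect_equal(ab$S_sites + ab$N_sites, 3 * n)
  }
})

test_that("selection regimes follow the Ka/Ks boundaries", {
  est <- tibble::tibble(ratio = c(0.3, 1.4, 1, NA))
  expect_equal(classify_selection(est)$regime,
               c("purifying", "positive", "neutral", "undefined"))
})

test_that("recent-WGD flagging applies the Ks window and mode filter", {
  calls <- tibble::tibble(
    gene_a = c("a", "b", "c", "d", "e"),
    gene_b = c("x", "y", "z", "w", "v"),
    mode = c("WGD", "WGD", "WGD", "TD", "WGD"),
    Ks = c(0.2, 0.5, 0.15, 0.2, NA))
  flagged <- flag_recent_wgd(calls)
  expect_equal(flagged$gene_a, c("a", "c"))   # endpoints inclusive, TD excluded
})

test_that("simulated divergence is recovered monotonically", {
  set.seed(43)
  base <- paste(sample(p450tools:::sense_codons(), 300, TRUE), collapse = "")
  ladder <- c(0.05, 0.1, 0.2, 0.3, 0.45, 0.6, 0.8)
  est <- vapply(seq_along(ladder), function(i) {
    mean(vapply(1:3, function(r) {
      mut <- evolve_cds(base, ladder[i], 0.2, seed = 100 * i + r)
      kaks_pair(base, as.character(mut))$Ks
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(est, ladder, method = "spearman"), 0.95)

  # ks_target 0 leaves the sequence untouched; omega 0 gives Ka exactly 0
  expect_equal(as.character(evolve_cds(base, 0, 1, seed = 1)), base)
  mut0 <- evolve_cds(base, 0.3, 0, seed = 2)
  expect_equal(kaks_pair(base, as.character(mut0))$Ka, 0)
  expect_error(evolve_cds(base, -1, 0.2), "ks_target")
  expect_error(evolve_cds(base, 0.1, -0.2), "omega")
})
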