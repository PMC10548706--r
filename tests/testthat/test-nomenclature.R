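test_that("global identity matches self, symmetry and the frozen example", {
  set.seed(3)
  for (i in 1:20) {
    s <- random_protein_str(sample(10:60, 1))
    expect_equal(global_identity(s, s)$identity, 1.0)
  }
  # exhaustive enumeration over all alignments of AAAA/AAAT gives 0.75
  expect_equal(global_identity("AAAA", "AAAT")$identity, 0.75)

  for (i in 1:100) {
    a <- random_protein_str(sample(10:50, 1))
    b <- random_protein_str(sample(10:50, 1))
    expect_equal(global_identity(a, b)$identity,
                 global_identity(b, a)$identity)
  }
})

test_that("family assignment applies the 40/55/95 tiers with clan inheritance", {
  set.seed(71)
  pats <- signature_patterns()
  f1 <- p450tools:::make_founder("A", 320, pats)$protein
  f2 <- p450tools:::make_founder("nonA", 320, pats)$protein
  refs <- tibble::tibble(
    id = c("refA", "refB"), sequence = c(f1, f2),
    clan = c("CYP71", "CYP72"), family = c("CYP75", "CYP72"),
    subfamily = c("CYP75A", "CYP72A"), type = c("A", "nonA"))

  q <- tibble::tibble(
    id = c("allelic", "family_only", "new"),
    sequence = c(p450tools:::mutate_to_identity(f1, 0.97, integer(0)),
                 p450tools:::mutate_to_identity(f1, 0.45, integer(0)),
                 random_protein_str(320)))
  out <- suppressMessages(assign_family(q, refs))
  expect_equal(out$family, c("CYP75", "CYP75", "NEW_FAMILY"))
  expect_equal(out$subfamily, c("CYP75A", NA, NA))
  expect_equal(out$allelic_variant, c(TRUE, FALSE, FALSE))
  expect_equal(out$clan, c("CYP71", "CYP71", "unassigned"))
  expect_true(is.na(out$type[3]))

  # invariance to reference order (documented tie-break aside)
  out2 <- suppressMessages(assign_family(q, refs[2:1, ]))
  expect_equal(out$family, out2$family)
  expect_equal(out$best_ref_id, out2$best_ref_id)

  expect_error(assign_family(q, refs[0, ]), "empty reference")
})

test_that("assignment tier is non-decreasing in identity", {
  set.seed(72)
  pats <- signature_patterns()
  f1 <- p450tools:::make_founder("A", 300, pats)$protein
  refs <- tibble::tibble(id = "ref", sequence = f1, clan = "CYP71",
                         family = "CYP71", subfamily = "CYP71A", type = "A")
  targets <- c(0.30, 0.47, 0.62, 0.97)
  q <- tibble::tibble(
    id = paste0("q", seq_along(targets)),
    sequence = vapply(targets, function(t) {
      p450tools:::mutate_to_identity(f1, t, integer(0))
    }, character(1)))
  out <- suppressMessages(assign_family(q, refs))
  tier_rank <- function(o) {
    ifelse(o$allelic_variant, 4L,
           ifelse(!is.na(o$subfamily), 3L,
                  ifelse(o$family != "NEW_FAMILY", 2L, 1L)))
  }
  expect_equal(tier_rank(out), sort(tier_rank(out)))
})

test_that("classification summaries reproduce the A-type share arithmetic", {
  empty <- summarize_classification(
    tibble::tibble(clan = character(), family = character(),
                   type = character()))
  expect_equal(empty$n_genes, 0L)

  asg <- tibble::tibble(
    clan = c(rep("CYP71", 152), rep("CYP72", 186)),
    family = c(rep("CYP71", 152), rep("CYP72", 186)),
    type = c(rep("A", 152), rep("nonA", 186)))
  tab <- summarize_classification(asg)
  total <- tab[tab$clan == "total", ]
  expect_equal(total$n_genes, 338L)
  expect_equal(round(total$pct_A, 1), 45.0)

  # synthetic cohort: summary equals the planted family histogram
  sim <- default_sim()
  sv <- default_survey()
  tab2 <- summarize_classification(sv$assignments)
  truth <- sim$truth$genes
  truth_counts <- table(truth$family[!is.na(truth$family)])
  for (fam in names(truth_counts)) {
    expect_equal(sum(tab2$n_genes[tab2$family == fam]),
                 unname(truth_counts[[fam]]), label = fam)
  }
})
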