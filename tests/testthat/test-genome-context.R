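mk_models <- function(chrom, starts, ends, ids = NULL) {
  ids <- ids %||% sprintf("g%02d", seq_along(starts))
  tibble::tibble(gene_id = ids, chromosome = chrom, strand = "+",
                 start = starts, end = ends,
                 exons = purrr::map2(starts, ends,
                                     ~ cbind(start = .x, end = .y)),
                 cds_segments = purrr::map2(starts, ends,
                                            ~ cbind(start = .x, end = .y)),
                 cds_complete = TRUE)
}

test_that("chromosome distribution computes densities and ignores order", {
  m <- mk_models("chr1", 1000, 2000)
  d <- chromosome_distribution(m, chromosome_lengths = c(chr1 = 1e6))
  expect_equal(d$genes_per_mb, 1.0)

  sim <- default_sim()
  d1 <- chromosome_distribution(sim$models)
  d2 <- chromosome_distribution(sim$models[sample(nrow(sim$models)), ])
  expect_equal(d1, d2)

  # per-chromosome counts equal the generator's plan
  truth <- sim$truth$genes
  expected <- table(truth$chromosome)
  expect_equal(stats::setNames(d1$n_genes, d1$chromosome),
               stats::setNames(as.integer(expected), names(expected)))
  expect_equal(sum(d1$n_genes), nrow(truth))
})

test_that("cluster detection applies the gap rule and minimum size", {
  asg <- function(ids) tibble::tibble(query_id = ids, family = "CYP71")
  two <- mk_models("chr1", c(1000, 3000), c(2000, 4000))
  expect_equal(nrow(detect_clusters(two, asg(two$gene_id))), 0)

  # three members, separated by 2 intervening non-family genes each
  starts <- seq(1000, by = 10000, length.out = 9)
  nine <- mk_models("chr1", starts, starts + 2000)
  members <- nine$gene_id[c(1, 4, 7)]
  cl <- detect_clusters(nine, asg(members))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 3L)
  expect_equal(cl$member_gene_ids[[1]], members)
})

test_that("cluster detection agrees with an exhaustive run-finder", {
  set.seed(55)
  cfg <- cluster_config()
  for (rep in 1:200) {
    n <- sample(8:30, 1)
    starts <- cumsum(sample(1000:250000, n, TRUE))
    ends <- starts + sample(500:3000, n, TRUE)
    member <- runif(n) < 0.4
    m <- mk_models("chr1", starts, ends)
    asg <- tibble::tibble(query_id = m$gene_id[member], family = "CYP71")
    got <- detect_clusters(m, asg, cfg)
    want <- brute_clusters(starts, ends, member,
                           cfg$max_intervening_genes, cfg$max_gap_bp,
                           cfg$min_size)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$member_gene_ids[[k]], m$gene_id[want[[k]]])
    }
  }
})

test_that("cluster invariants hold on the simulated genome", {
  sim <- default_sim()
  sv <- default_survey()
  cl <- sv$clusters
  expect_true(all(cl$n_members >= 3))
  fam_ids <- sv$assignments$query_id[sv$assignments$family != "NEW_FAMILY"]
  expect_true(all(unlist(cl$member_gene_ids) %in% fam_ids))
  # planted clusters are all recovered exactly
  planted <- sim$truth$clusters
  for (i in seq_len(nrow(planted))) {
    hit <- vapply(cl$member_gene_ids, function(m) {
      setequal(m, planted$member_gene_ids[[i]])
    }, logical(1))
    expect_true(any(hit), label = planted$cluster_id[i])
  }
})

test_that("intron counts and phases follow cumulative CDS length mod 3", {
  single <- mk_models("chr1", 100, 199)
  st <- gene_structure_stats(single)
  expect_equal(st$n_introns, 0L)
  expect_equal(st$intron_phases[[1]], integer(0))

  two_ex <- function(l1, l2) tibble::tibble(
    gene_id = "g", chromosome = "chr1", strand = "+",
    start = 1L, end = 1000L,
    exons = list(cbind(start = c(1, 500), end = c(l1, 499 + l2))),
    cds_segments = list(cbind(start = c(1, 500), end = c(l1, 499 + l2))),
    cds_complete = TRUE)
  expect_equal(gene_structure_stats(two_ex(9, 6))$intron_phases[[1]], 0L)
  expect_equal(gene_structure_stats(two_ex(10, 5))$intron_phases[[1]], 1L)

  # minus strand in transcription order gives the same phases
  minus <- tibble::tibble(
    gene_id = "g", chromosome = "chr1", strand = "-",
    start = 1L, end = 1000L,
    exons = list(cbind(start = c(900, 100), end = c(909, 104))),
    cds_segments = list(cbind(start = c(900, 100), end = c(909, 104))),
    cds_complete = TRUE)
  expect_equal(gene_structure_stats(minus)$intron_phases[[1]], 1L)

  no_cds <- single
  no_cds$cds_segments <- list(NULL)
  expect_error(gene_structure_stats(no_cds), "no CDS")
})
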