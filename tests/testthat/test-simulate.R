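test_that("identity targeting lands within the stated band", {
  set.seed(91)
  base <- random_protein_str(320)
  for (i in 1:20) {
    mut <- p450tools:::mutate_to_identity(base, 0.60, integer(0))
    idt <- global_identity(base, mut)$identity
    expect_gte(idt, 0.58)
    expect_lte(idt, 0.62)
  }
})

test_that("generated outputs parse through the format readers cleanly", {
  sim <- default_sim()
  dir <- withr::local_tempdir()
  write_simulated_genome <- p450tools:::write_simulated_genome
  write_simulated_genome(sim, dir)
  expect_no_warning(prot <- read_fasta(file.path(dir, "proteome.faa")))
  expect_no_warning(cds <- read_fasta(file.path(dir, "cds.fna")))
  expect_equal(prot$sequence, sim$proteins$sequence)
  expect_equal(cds$sequence, sim$cds$sequence)
  models <- read_gff3(file.path(dir, "genes.gff3"))
  models <- models[match(sim$models$gene_id, models$gene_id), ]
  expect_equal(models$start, sim$models$start)
  expect_equal(models$strand, sim$models$strand)
  refs <- read_reference_fasta(file.path(dir, "references.faa"))
  expect_equal(refs$family, sim$references$family)
  # ground truth covers every generated gene and planted pair gene
  expect_setequal(sim$truth$genes$gene_id, sim$proteins$id)
  expect_true(all(c(sim$truth$pairs$gene_a, sim$truth$pairs$gene_b) %in%
                    sim$truth$genes$gene_id))
})

test_that("CDS sets translate exactly to their proteomes", {
  sim <- default_sim()
  expect_equal(translate_cds(sim$cds$sequence), sim$proteins$sequence)
})

test_that("the planted collinear segment is recovered as a block", {
  sim <- default_sim()
  sv <- default_survey()
  wgd_pairs <- sim$truth$pairs[sim$truth$pairs$mode == "WGD", ]
  key <- paste(wgd_pairs$gene_a, wgd_pairs$gene_b)
  covered <- vapply(seq_len(nrow(sv$blocks)), function(i) {
    a <- sv$blocks$anchors[[i]]
    sum(paste(pmin(a$gene_a, a$gene_b), pmax(a$gene_a, a$gene_b)) %in% key)
  }, numeric(1))
  expect_gte(max(covered, 0), 6)
})

test_that("expression simulation plants recoverable drivers and patterns", {
  sim <- default_sim()
  # noise-free: screen returns the drivers with r = 1
  cfg <- sim$config
  cfg$expression$noise <- "none"
  sim0 <- sim
  sim0$config <- cfg
  ex0 <- simulate_expression(sim0, seed = 5)
  fp0 <- compute_fpkm(ex0$counts)
  fam <- sim$truth$genes$gene_id[!is.na(sim$truth$genes$family)]
  scr0 <- screen_flavonoid_candidates(fp0[fp0$gene_id %in% fam, ],
                                      ex0$metabolites)
  expect_true(all(ex0$labels$drivers %in% scr0$candidates))
  pg <- tidy(scr0)
  expect_equal(pg$r_total[pg$gene_id %in% ex0$labels$drivers],
               rep(1, length(ex0$labels$drivers)), tolerance = 1e-3)

  # planted retention classes recovered exactly in the noise-free setting
  ret0 <- classify_retention(fp0, ex0$labels$retention)
  expect_equal(ret0$mechanism, ex0$labels$retention$class)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_scattered_per_family = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_genome(cfg, seed = 77, dir = d1)
  s2 <- simulate_genome(cfg, seed = 77, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  e1 <- simulate_expression(s1, seed = 9, dir = file.path(d1, "expr"))
  e2 <- simulate_expression(s2, seed = 9, dir = file.path(d2, "expr"))
  for (f in list.files(file.path(d1, "expr"))) {
    expect_identical(readLines(file.path(d1, "expr", f)),
                     readLines(file.path(d2, "expr", f)), label = f)
  }
  # a different seed changes the output
  s3 <- simulate_genome(cfg, seed = 78)
  expect_false(identical(s1$proteins$sequence, s3$proteins$sequence))
})
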