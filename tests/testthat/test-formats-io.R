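test_that("FASTA parsing handles single records, order and failure modes", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1", "MKV"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, "g1")
  expect_equal(recs$sequence, "MKV")
  expect_equal(recs$kind, "protein")

  writeLines(c(">g1", "MKV", ">g1", "MAV"), f)
  expect_error(read_fasta(f), "duplicate.*g1")

  writeLines(character(0), f)
  expect_warning(out <- read_fasta(f), "empty")
  expect_equal(nrow(out), 0)

  writeLines(c(">c1 some cds", "ATGGCT"), f)
  cds <- read_fasta(f)
  expect_equal(cds$kind, "cds")
  expect_equal(cds$description, "some cds")
})

test_that("FASTA write/read round-trips 1000 wrapped records losslessly", {
  set.seed(5)
  recs <- tibble::tibble(
    id = sprintf("r%04d", 1:1000),
    description = "",
    sequence = vapply(sample(30:200, 1000, TRUE), random_protein_str,
                      character(1)),
    kind = "protein")
  f <- withr::local_tempfile(fileext = ".faa")
  write_fasta(recs, f, wrap = 60)
  back <- read_fasta(f, kind = "protein")
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("GFF3 parsing respects strand transcription order and linkage", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t199\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t101\t199\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t101\t199\t.\t+\t.\tID=gA.t1.e1;Parent=gA.t1",
    "chr1\tsrc\tCDS\t101\t199\t.\t+\t.\tID=gA.t1.c1;Parent=gA.t1",
    "chr2\tsrc\tgene\t101\t401\t.\t-\t.\tID=gB",
    "chr2\tsrc\tmRNA\t101\t401\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr2\tsrc\texon\t101\t200\t.\t-\t.\tID=gB.t1.e1;Parent=gB.t1",
    "chr2\tsrc\texon\t301\t401\t.\t-\t.\tID=gB.t1.e2;Parent=gB.t1",
    "chr2\tsrc\tCDS\t101\t200\t.\t-\t.\tID=gB.t1.c1;Parent=gB.t1",
    "chr2\tsrc\tCDS\t301\t401\t.\t-\t.\tID=gB.t1.c2;Parent=gB.t1"), f)
  models <- read_gff3(f)
  expect_equal(models$gene_id, c("gA", "gB"))
  expect_equal(unname(models$exons[[1]][, "start"]), 101)
  # minus strand: transcription order is descending coordinates
  expect_equal(unname(models$exons[[2]][, "start"]), c(301, 101))
  expect_true(all(models$cds_complete))

  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tCDS\t1\t9\t.\t+\t.\tID=x;Parent=ghost"), f)
  expect_error(read_gff3(f), "without a parent")
})

test_that("GFF3 write/read round-trip is the identity on simulated models", {
  sim <- default_sim()
  models <- utils::head(sim$models, 12)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(models, f)
  back <- read_gff3(f)
  back <- back[match(models$gene_id, back$gene_id), ]
  expect_equal(back$chromosome, models$chromosome)
  expect_equal(back$strand, models$strand)
  expect_equal(back$start, models$start)
  expect_equal(back$end, models$end)
  for (i in seq_len(nrow(models))) {
    expect_equal(unname(back$cds_segments[[i]]), unname(models$cds_segments[[i]]))
  }
})

test_that("evidence tables parse both dialects and skip junk", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("q1", "r1", "98.0", "450", "3", "0", "1", "450", "1",
                   "450", "1e-50", "200"), f)
  rows <- read_evidence_table(f, "blast_outfmt6")
  expect_equal(rows$query_id, "q1")
  expect_equal(rows$evalue, 1e-50)
  expect_equal(rows$source, "similarity")
  expect_equal(rows$region_start, 1L)

  writeLines(c("# comment", "# another"), f)
  expect_equal(nrow(read_evidence_table(f, "blast_outfmt6")), 0)
  expect_error(read_evidence_table(f, "nonsense"))

  # round-trip 50 synthesized outfmt6 rows
  set.seed(9)
  ev <- 10^-runif(50, 5, 60)
  lines <- sprintf("q%02d r1 90.0 300 5 0 1 300 1 300 %.6e %.1f",
                   1:50, ev, runif(50, 50, 300))
  writeLines(lines, f)
  rows <- read_evidence_table(f, "blast_outfmt6")
  expect_equal(rows$evalue, as.numeric(sprintf("%.6e", ev)))

  # domtblout: 21+ whitespace fields, i-Evalue at column 13
  dom <- paste("prot1 - 400 PF00067 - 450 1.2e-40 130.5 0.1 1 1",
               "2.0e-38 1.5e-35 120.0 0.1 5 440 10 390 8 395 0.95 -")
  writeLines(dom, f)
  rows <- read_evidence_table(f, "hmmsearch_domtblout")
  expect_equal(rows$query_id, "prot1")
  expect_equal(rows$evalue, 1.5e-35)
  expect_equal(rows$source, "domain_scan")
  expect_equal(c(rows$region_start, rows$region_end), c(10L, 390L))
})
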