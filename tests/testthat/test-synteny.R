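test_that("paralog pairing is within-family, thresholded and complete", {
  seq1 <- random_protein_str(200)
  prot <- tibble::tibble(id = c("a", "b"), sequence = c(seq1, seq1))
  asg <- tibble::tibble(query_id = c("a", "b"), family = "CYP71")
  pairs <- find_paralog_pairs(prot, asg)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$identity, 1.0)
  expect_equal(pairs$gene_a, "a")

  # k well-conserved members -> k(k-1)/2 pairs
  set.seed(61)
  base <- random_protein_str(200)
  k <- 5
  prot_k <- tibble::tibble(
    id = paste0("m", 1:k),
    sequence = vapply(1:k, function(i) {
      p450tools:::mutate_to_identity(base, 0.9, integer(0))
    }, character(1)))
  asg_k <- tibble::tibble(query_id = prot_k$id, family = "CYP71")
  expect_equal(nrow(find_paralog_pairs(prot_k, asg_k)), k * (k - 1) / 2)

  # equals brute-force all-vs-all with the same threshold
  sim <- default_sim()
  fam_ids <- sim$truth$genes$gene_id[!is.na(sim$truth$genes$family) &
                                       sim$truth$genes$family == "CYP86"]
  sub <- sim$proteins[sim$proteins$id %in% fam_ids, ]
  asg_sub <- tibble::tibble(query_id = sub$id, family = "CYP86")
  got <- find_paralog_pairs(sub, asg_sub)
  want <- list()
  for (i in seq_len(nrow(sub) - 1)) {
    for (j in (i + 1):nrow(sub)) {
      idt <- global_identity(sub$sequence[i], sub$sequence[j])$identity
      if (idt >= 0.4) {
        want[[length(want) + 1]] <- sort(c(sub$id[i], sub$id[j]))
      }
    }
  }
  expect_equal(nrow(got), length(want))
})

test_that("chaining reports maximal diagonals and respects min_block", {
  order5 <- tibble::tibble(gene_id = c(paste0("a", 1:5), paste0("b", 1:5)),
                           chromosome = rep(c("c1", "c2"), each = 5),
                           rank = rep(1:5, 2))
  anchors <- tibble::tibble(gene_a = paste0("a", 1:5),
                            gene_b = paste0("b", 1:5))
  blocks <- chain_collinear_blocks(anchors, order5)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_anchors, 5L)
  expect_equal(blocks$orientation, "same")

  expect_equal(nrow(chain_collinear_blocks(anchors[1:4, ], order5)), 0)
})

test_that("DP chaining equals exhaustive chain enumeration on small instances", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    rx <- sample(1:40, n)
    ry <- sample(1:40, n)
    o <- order(rx, ry)
    rx <- rx[o]; ry <- ry[o]
    gap <- sample(c(5L, 10L, 25L), 1)
    got <- p450tools:::best_chain(rx, ry, gap)
    want <- brute_best_chain(rx, ry, gap)
    expect_equal(got, want, label = paste("rep", rep))
  }
})

test_that("adding a compatible anchor never shortens the best chain", {
  set.seed(78)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    rx <- sort(sample(1:30, n))
    ry <- sample(1:30, n)
    len0 <- length(p450tools:::best_chain(rx, ry, 25L))
    # append an anchor beyond all existing ones (compatible with any chain)
    len1 <- length(p450tools:::best_chain(c(rx, max(rx) + 1L),
                                          c(ry, max(ry) + 1L), 25L))
    expect_gte(len1, len0)
  }
})

test_that("duplication modes follow the documented precedence", {
  gene_order <- tibble::tibble(
    gene_id = c(paste0("c1g", 1:20), paste0("c2g", 1:20)),
    chromosome = rep(c("c1", "c2"), each = 20),
    rank = rep(1:20, 2))
  anchors <- tibble::tibble(gene_a = paste0("c1g", 1:6),
                            gene_b = paste0("c2g", 1:6))
  blocks <- chain_collinear_blocks(anchors, gene_order)
  expect_equal(nrow(blocks), 1)

  pairs <- tibble::tibble(
    gene_a = c("c1g1", "c1g10", "c1g10", "c1g2", "c1g15"),
    gene_b = c("c2g1", "c1g11", "c1g16", "c2g15", "c2g16"))
  calls <- classify_modes(pairs, blocks, gene_order)
  expect_equal(calls$mode, c("WGD", "TD", "PD", "TRD", "DSD"))

  # anchor pair in a block stays WGD even when also proximal
  prox_order <- tibble::tibble(gene_id = paste0("g", 1:12),
                               chromosome = "c1", rank = 1:12)
  prox_anchors <- tibble::tibble(gene_a = paste0("g", 1:5),
                                 gene_b = paste0("g", 7:11))
  prox_blocks <- chain_collinear_blocks(prox_anchors, prox_order)
  expect_equal(nrow(prox_blocks), 1)
  call <- classify_modes(tibble::tibble(gene_a = "g1", gene_b = "g7"),
                         prox_blocks, prox_order)
  expect_equal(call$mode, "WGD")

  expect_error(
    classify_modes(tibble::tibble(gene_a = "zz", gene_b = "c1g1"),
                   blocks, gene_order),
    "missing from gene order: zz")
})

test_that("every pair gets exactly one mode, independent of input order", {
  sim <- default_sim()
  sv <- default_survey()
  truth_pairs <- sim$truth$pairs[, c("gene_a", "gene_b")]
  calls <- classify_modes(truth_pairs, sv$blocks, gene_rank(sim$models))
  expect_equal(nrow(calls), nrow(truth_pairs))
  expect_true(all(calls$mode %in% c("WGD", "TD", "PD", "TRD", "DSD")))
  shuffled <- classify_modes(truth_pairs[rev(seq_len(nrow(truth_pairs))), ],
                             sv$blocks, gene_rank(sim$models))
  expect_equal(dplyr::arrange(calls, gene_a, gene_b),
               dplyr::arrange(shuffled, gene_a, gene_b))
})
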