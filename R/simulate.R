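#' Simulation configuration
#'
#' Defaults describe the synthetic genome every pipeline stage is tested
#' against: five chromosomes of 40 gene slots; six CYP families (three
#' A-type, three non-A) whose founders carry the planted signature motifs;
#' scattered family members mutated to an identity ladder spanning the
#' naming tiers; a planted whole-genome-duplicated segment, two tandem
#' arrays, proximal, transposed and dispersed copies diverged at controlled
#' Ks and Ka/Ks; and a five-stage expression experiment with planted
#' retention classes and metabolite driver genes.
#'
#' @param n_chromosomes Number of chromosomes (default 5).
#' @param genes_per_chromosome Gene slots per chromosome (default 40).
#' @param protein_codons Founder protein length in codons (default 320).
#' @param families Tibble `family`, `clan`, `type` for the simulated
#'   families (default three A-type CYP71-clan families and three non-A).
#' @param n_scattered_per_family Ladder members per family (default 5).
#' @param identity_ladder Identity targets for scattered members; defaults
#'   keep at least five points away from the 40/55/95 thresholds.
#' @param wgd_segment_size Genes in the duplicated segment (default 8).
#' @param wgd_family_genes Family genes inside the segment (default 2).
#' @param wgd_ks,wgd_omega Divergence of the segmental duplicates
#'   (defaults 0.22 and 0.15: inside the recent-WGD Ks window, purifying).
#' @param tandem_array_size,n_tandem_arrays Tandem arrays (two arrays of
#'   three adjacent copies).
#' @param tandem_ks,tandem_omega Divergence of tandem copies (0.05, 0.3).
#' @param n_proximal,proximal_intervening,proximal_ks Proximal copies (two
#'   pairs, five intervening genes, Ks 0.10).
#' @param n_transposed,transposed_ks Transposed copies of segment genes
#'   (two, Ks 0.40).
#' @param n_dispersed,dispersed_ks Dispersed copies (two, Ks 0.60).
#' @param single_gene_omega Ka/Ks for proximal/transposed/dispersed copies
#'   (default 0.2).
#' @param extra_cluster_size,extra_cluster_gap One additional planted gene
#'   cluster (4 members, 2 intervening genes between neighbours).
#' @param decoy_motif_rate Fraction of decoys carrying one planted
#'   signature motif (default 0; such decoys still fail the similarity
#'   evidence).
#' @param syn_scramble Probability that an unchanged residue of a ladder
#'   member receives a random synonymous codon (default 0.3).
#' @param min_family_spacing Minimum rank spacing between scattered family
#'   genes on a chromosome, so no unplanned clusters form (default 12).
#' @param expression A list of expression-simulation settings; see
#'   [simulate_expression()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_chromosomes = 8L, genes_per_chromosome = 40L, protein_codons = 320L,
    families = NULL, n_scattered_per_family = 5L,
    identity_ladder = c(0.33, 0.47, 0.62, 0.75, 0.88),
    wgd_segment_size = 8L, wgd_family_genes = 2L,
    wgd_ks = 0.22, wgd_omega = 0.15,
    n_tandem_arrays = 2L, tandem_array_size = 3L,
    tandem_ks = 0.05, tandem_omega = 0.3,
    n_proximal = 2L, proximal_intervening = 5L, proximal_ks = 0.10,
    n_transposed = 2L, transposed_ks = 0.40,
    n_dispersed = 2L, dispersed_ks = 0.60,
    single_gene_omega = 0.2,
    extra_cluster_size = 4L, extra_cluster_gap = 2L,
    decoy_motif_rate = 0,
    syn_scramble = 0.3,
    min_family_spacing = 7L,
    expression = list()) {
  if (is.null(families)) {
    families <- tibble::tibble(
      family = c("CYP71", "CYP75", "CYP98", "CYP72", "CYP85", "CYP86"),
      clan = c("CYP71", "CYP71", "CYP71", "CYP72", "CYP85", "CYP86"),
      type = c("A", "A", "A", "nonA", "nonA", "nonA"))
  }
  expr_defaults <- list(
    stage_labels = c("15", "45", "90", "120", "145"),
    depth = 2e7, noise = "poisson",
    n_drivers = 5L, driver_profile = c(8, 25, 60, 120, 200),
    metabolite_scale = c(2.5, 1.2), metabolite_noise_frac = 0.17,
    n_sf_pairs = 2L, n_dosage_pairs = 2L, n_silenced_pairs = 2L,
    n_background = 20L, background_length = 2000L,
    background_fpkm = 25000)
  expression <- utils::modifyList(expr_defaults, expression)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              protein_codons = as.integer(protein_codons),
              families = families,
              n_scattered_per_family = as.integer(n_scattered_per_family),
              identity_ladder = identity_ladder,
              wgd_segment_size = as.integer(wgd_segment_size),
              wgd_family_genes = as.integer(wgd_family_genes),
              wgd_ks = wgd_ks, wgd_omega = wgd_omega,
              n_tandem_arrays = as.integer(n_tandem_arrays),
              tandem_array_size = as.integer(tandem_array_size),
              tandem_ks = tandem_ks, tandem_omega = tandem_omega,
              n_proximal = as.integer(n_proximal),
              proximal_intervening = as.integer(proximal_intervening),
              proximal_ks = proximal_ks,
              n_transposed = as.integer(n_transposed),
              transposed_ks = transposed_ks,
              n_dispersed = as.integer(n_dispersed),
              dispersed_ks = dispersed_ks,
              single_gene_omega = single_gene_omega,
              extra_cluster_size = as.integer(extra_cluster_size),
              extra_cluster_gap = as.integer(extra_cluster_gap),
              decoy_motif_rate = decoy_motif_rate,
              syn_scramble = syn_scramble,
              min_family_spacing = as.integer(min_family_spacing),
              expression = expression)
  structure(cfg, class = "simulation_config")
}

amino_acids <- function() names(residue_masses)

codons_for <- function(aa) {
  gc <- genetic_code()
  names(gc)[gc == aa]
}

random_cds_for_protein <- function(protein) {
  aas <- strsplit(protein, "")[[1]]
  paste(vapply(aas, function(a) {
    opts <- codons_for(a)
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

random_protein <- function(len) {
  paste(sample(amino_acids(), len, replace = TRUE), collapse = "")
}

# instantiate a consensus (X -> random residue, [A/B] -> named choice)
instantiate_consensus <- function(consensus) {
  toks <- consensus_tokens(consensus)
  paste(vapply(toks, function(t) {
    if (t == "X") sample(amino_acids(), 1)
    else if (startsWith(t, "[")) {
      opts <- strsplit(gsub("[^A-Z/]", "", t), "/")[[1]]
      sample(opts, 1)
    } else t
  }, character(1)), collapse = "")
}

# motif layout (residue offsets within the founder protein, N- to C-terminal
# order as in real P450s: I-helix, K-helix, PERF, heme-binding)
motif_layout <- function(protein_codons) {
  stopifnot(protein_codons >= 240)
  c(ihelix = as.integer(protein_codons * 0.56),
    khelix = as.integer(protein_codons * 0.72),
    perf = as.integer(protein_codons * 0.82),
    heme = as.integer(protein_codons * 0.90))
}

# build a family founder carrying the four signature regions
make_founder <- function(type, protein_codons, patterns) {
  prot <- random_protein(protein_codons)
  layout <- motif_layout(protein_codons)
  pick <- function(region) {
    cand <- patterns[patterns$region == region &
                       patterns$variant %in% c(type, "generic"), ]
    instantiate_consensus(cand$consensus[1])
  }
  # non-A founders must not accidentally instantiate the A-specific pattern
  repeat {
    motifs <- vapply(names(layout), pick, character(1))
    ok <- TRUE
    if (type == "nonA") {
      for (reg in c("heme", "perf", "ihelix")) {
        a_pat <- consensus_to_regex(
          patterns$consensus[patterns$region == reg &
                               patterns$variant == "A"])$regex
        if (grepl(paste0("^", a_pat, "$"), motifs[[reg]])) ok <- FALSE
      }
    }
    if (ok) break
  }
  protected <- integer(0)
  for (reg in names(layout)) {
    start <- layout[[reg]]
    m <- motifs[[reg]]
    substr(prot, start, start + nchar(m) - 1L) <- m
    protected <- c(protected, start:(start + nchar(m) - 1L))
  }
  # scrub any accidental extra signature matches outside the planted ones
  prot <- scrub_extra_motifs(prot, patterns, keep = protected)
  list(protein = prot, protected = protected)
}

# remove signature matches (outside `keep`) by re-randomising the window
scrub_extra_motifs <- function(prot, patterns, keep = integer(0)) {
  for (iter in 1:100) {
    dirty <- FALSE
    for (i in seq_len(nrow(patterns))) {
      cr <- consensus_to_regex(patterns$consensus[i])
      for (st in consensus_starts(prot, patterns$consensus[i])) {
        span <- st:(st + cr$width - 1L)
        if (all(span %in% keep)) next
        free <- setdiff(span, keep)
        repl <- sample(setdiff(amino_acids(), c("G", "R", "F", "P")),
                       length(free), replace = TRUE)
        for (k in seq_along(free)) {
          substr(prot, free[k], free[k]) <- repl[k]
        }
        dirty <- TRUE
      }
    }
    if (!dirty) return(prot)
  }
  abort("scrub_extra_motifs: failed to remove accidental signature matches")
}

# mutate a founder protein to an identity target, avoiding protected sites
mutate_to_identity <- function(protein, target, protected) {
  len <- nchar(protein)
  k <- round((1 - target) * len)
  free <- setdiff(seq_len(len), protected)
  if (k > length(free)) {
    abort("mutate_to_identity: identity target below the protected-site floor")
  }
  pos <- sample(free, k)
  chars <- strsplit(protein, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(amino_acids(), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# CDS for a mutated member: keep the founder codon for unchanged residues
# (synonymous scramble with probability syn_scramble), new random codon
# otherwise
member_cds <- function(member_prot, founder_prot, founder_cds, syn_scramble) {
  ma <- strsplit(member_prot, "")[[1]]
  fa <- strsplit(founder_prot, "")[[1]]
  cods <- substring(founder_cds, seq(1, nchar(founder_cds), 3),
                    seq(3, nchar(founder_cds), 3))
  out <- character(length(ma))
  for (i in seq_along(ma)) {
    if (ma[i] == fa[i]) {
      out[i] <- if (runif(1) < syn_scramble) {
        opts <- codons_for(ma[i])
        opts[sample.int(length(opts), 1)]
      } else cods[i]
    } else {
      opts <- codons_for(ma[i])
      out[i] <- opts[sample.int(length(opts), 1)]
    }
  }
  paste(out, collapse = "")
}

#' Evolve a CDS to a target synonymous divergence
#'
#' Applies single-base substitutions as two Poisson event streams: a
#' synonymous stream with expectation `ks_target` times the sequence's NG86
#' synonymous site count, and a nonsynonymous stream with expectation
#' `omega` times `ks_target` times the nonsynonymous site count. Each event
#' picks uniformly among the currently possible single-base changes of its
#' class; changes creating stop codons are never candidates. Realised event
#' counts are attached as attributes `realized_syn` / `realized_nonsyn`.
#'
#' @param cds A stop-free sense-codon CDS string.
#' @param ks_target Expected synonymous substitutions per synonymous site.
#' @param omega Ka/Ks ratio of the mutation process.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return The mutated CDS string.
#' @export
evolve_cds <- function(cds, ks_target, omega, seed = NULL) {
  if (ks_target < 0) abort("evolve_cds: ks_target must be >= 0")
  if (omega < 0) abort("evolve_cds: omega must be >= 0")
  with_seed(seed, {
    tab <- ng86_codon_table("exclude")
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    if (any(!cods %in% names(tab$s_frac))) {
      abort("evolve_cds: CDS contains stop or invalid codons")
    }
    S <- sum(tab$s_frac[cods])
    N <- 3 * length(cods) - S
    n_syn <- rpois(1, ks_target * S)
    n_non <- rpois(1, omega * ks_target * N)
    events <- sample(rep(c("s", "n"), c(n_syn, n_non)))
    for (ev in events) {
      opts_per <- if (ev == "s") tab$syn_mut[cods] else tab$nonsyn_mut[cods]
      counts <- lengths(opts_per)
      total <- sum(counts)
      if (total == 0) next
      pick <- sample.int(total, 1)
      idx <- findInterval(pick - 1L, cumsum(counts)) + 1L
      within <- pick - c(0L, cumsum(counts))[idx]
      cods[idx] <- opts_per[[idx]][within]
    }
    out <- paste(cods, collapse = "")
    attr(out, "realized_syn") <- n_syn
    attr(out, "realized_nonsyn") <- n_non
    out
  })
}

# deterministic slot plan for planted structures; errors when infeasible
plan_slots <- function(config) {
  nc <- config$n_chromosomes
  gpc <- config$genes_per_chromosome
  need <- config$wgd_segment_size + 10
  if (nc < 5 || gpc < max(need, 40)) {
    abort("simulate_genome: config infeasible (need >= 5 chromosomes of >= 40 slots)")
  }
  if (config$n_tandem_arrays > 2 || config$n_proximal > 2 ||
      config$n_transposed > 2 || config$n_dispersed > 2) {
    abort("simulate_genome: the default slot plan supports at most 2 of each single-gene event")
  }
  list(
    wgd_src = list(chrom = 1L, ranks = 11:(10 + config$wgd_segment_size)),
    wgd_dst = list(chrom = 2L, ranks = 21:(20 + config$wgd_segment_size)),
    tandem = list(list(chrom = 3L, ranks = 5:(4 + config$tandem_array_size)),
                  list(chrom = 4L, ranks = 10:(9 + config$tandem_array_size))),
    proximal = list(
      list(chrom = 3L, parent = 20L,
           copy = 21L + config$proximal_intervening),
      list(chrom = 4L, parent = 25L,
           copy = 26L + config$proximal_intervening)),
    transposed_copy = list(list(chrom = 5L, rank = 22L),
                           list(chrom = 5L, rank = 30L)),
    dispersed = list(
      list(parent = list(chrom = 4L, rank = 39L),
           copy = list(chrom = 5L, rank = 38L)),
      list(parent = list(chrom = 1L, rank = 35L),
           copy = list(chrom = 3L, rank = 35L))),
    cluster = list(chrom = 5L,
                   ranks = 5L + (0:(config$extra_cluster_size - 1)) *
                     (config$extra_cluster_gap + 1L)))
}

#' Simulate a genome with planted ground truth
#'
#' Generates a proteome, CDS set, gene models and a labelled reference set
#' in which every downstream signal is planted and recorded: signature
#' motifs and A/non-A types, family identity ladders, gene clusters, a
#' collinear duplicated segment, tandem/proximal/transposed/dispersed
#' copies with controlled Ks and Ka/Ks. See [simulation_config()] for the
#' knobs.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the same seed reproduces byte-identical
#'   outputs.
#' @param dir Optional output directory; when given, writes
#'   `proteome.faa`, `cds.fna`, `genes.gff3`, `references.faa`,
#'   `truth_genes.tsv` and `truth_pairs.tsv`.
#' @return A list: `proteins`, `cds` (record tibbles), `models`
#'   (gene-model tibble), `references` (labelled reference tibble), `truth`
#'   (list of `genes`, `pairs`, `clusters` tibbles) and `config`.
#' @export
simulate_genome <- function(config = simulation_config(), seed = 1L,
                            dir = NULL) {
  with_seed(seed, simulate_genome_impl(config, dir))
}

simulate_genome_impl <- function(config, dir) {
  patterns <- signature_patterns()
  slots <- plan_slots(config)
  nfam <- nrow(config$families)
  founders <- purrr::map(seq_len(nfam), function(i) {
    f <- make_founder(config$families$type[i], config$protein_codons, patterns)
    f$cds <- random_cds_for_protein(f$protein)
    f
  })
  names(founders) <- config$families$family

  # occupancy grid and gene registry
  used <- matrix(FALSE, config$n_chromosomes, config$genes_per_chromosome)
  genes <- list()     # per gene: id, chrom, rank, protein, cds, family,...
  gene_seq <- 0L
  add_gene <- function(chrom, rank, protein, cds, family, tier, type, role,
                       cluster_id = NA_character_,
                       identity_target = NA_real_) {
    if (used[chrom, rank]) {
      abort(paste0("simulate_genome: slot collision at chr", chrom,
                   " rank ", rank, " (infeasible config)"))
    }
    used[chrom, rank] <<- TRUE
    gene_seq <<- gene_seq + 1L
    id <- sprintf("g%03d", gene_seq)
    genes[[id]] <<- list(id = id, chrom = chrom, rank = rank,
                         protein = protein, cds = cds, family = family,
                         tier = tier, type = type, role = role,
                         cluster_id = cluster_id,
                         identity_target = identity_target)
    id
  }
  fam_info <- function(f) config$families[config$families$family == f, ]
  truth_pairs <- list()
  add_pair <- function(a, b, mode, ks, omega) {
    truth_pairs[[length(truth_pairs) + 1L]] <<- tibble::tibble(
      gene_a = min(a, b), gene_b = max(a, b), mode = mode,
      ks_target = ks, omega_target = omega)
  }
  # members keep the founder's planted motifs; accidental extra matches of
  # the type-diagnostic regions are scrubbed (the short K-helix consensus
  # recurs by chance and is left alone to keep identity targets tight)
  diagnostic <- patterns[patterns$region != "khelix", ]
  member_from_founder <- function(family, identity) {
    fo <- founders[[family]]
    prot <- mutate_to_identity(fo$protein, identity, fo$protected)
    prot <- scrub_extra_motifs(prot, diagnostic, keep = fo$protected)
    cds <- member_cds(prot, fo$protein, fo$cds, config$syn_scramble)
    list(protein = prot, cds = cds)
  }
  evolve_member <- function(parent, ks, omega) {
    cds <- evolve_cds(parent$cds, ks, omega)
    list(protein = translate_cds(cds), cds = as.character(cds))
  }
  tier_of <- function(identity) {
    if (identity > 0.95) "allelic"
    else if (identity > 0.55) "subfamily"
    else if (identity > 0.40) "family"
    else "new_family"
  }

  # --- WGD segment: family genes at the ends, decoys between -------------
  seg_n <- config$wgd_segment_size
  fam_offsets <- if (config$wgd_family_genes >= 2) {
    c(0L, seg_n - 1L)[seq_len(config$wgd_family_genes)]
  } else if (config$wgd_family_genes == 1) 0L else integer(0)
  wgd_families <- c("CYP98", "CYP72")
  seg_src_ids <- character(seg_n)
  seg_dst_ids <- character(seg_n)
  trd_parents <- character(0)
  for (k in seq_len(seg_n)) {
    off <- k - 1L
    if (off %in% fam_offsets) {
      fam <- wgd_families[match(off, fam_offsets)]
      fi <- fam_info(fam)
      m <- member_from_founder(fam, 0.88)
      src <- add_gene(slots$wgd_src$chrom, slots$wgd_src$ranks[k],
                      m$protein, m$cds, fam, "subfamily", fi$type, "wgd_src",
                      identity_target = 0.88)
      cp <- evolve_member(m, config$wgd_ks, config$wgd_omega)
      dst <- add_gene(slots$wgd_dst$chrom, slots$wgd_dst$ranks[k],
                      cp$protein, cp$cds, fam, "subfamily", fi$type, "wgd_dst")
      add_pair(src, dst, "WGD", config$wgd_ks, config$wgd_omega)
      trd_parents <- c(trd_parents, src)
    } else {
      prot <- scrub_extra_motifs(
        random_protein(sample(200:350, 1)), patterns)
      cds <- random_cds_for_protein(prot)
      src <- add_gene(slots$wgd_src$chrom, slots$wgd_src$ranks[k],
                      prot, cds, NA_character_, NA_character_,
                      NA_character_, "wgd_src_decoy")
      cp <- evolve_member(list(protein = prot, cds = cds),
                          config$wgd_ks, config$wgd_omega)
      dst <- add_gene(slots$wgd_dst$chrom, slots$wgd_dst$ranks[k],
                      cp$protein, cp$cds, NA_character_, NA_character_,
                      NA_character_, "wgd_dst_decoy")
      add_pair(src, dst, "WGD", config$wgd_ks, config$wgd_omega)
    }
    seg_src_ids[k] <- src; seg_dst_ids[k] <- dst
  }

  # --- tandem arrays (planted clusters) ----------------------------------
  truth_clusters <- list()
  tandem_fams <- c("CYP71", "CYP75")
  for (t in seq_len(config$n_tandem_arrays)) {
    sl <- slots$tandem[[t]]
    fam <- tandem_fams[(t - 1) %% length(tandem_fams) + 1]
    fi <- fam_info(fam)
    base <- member_from_founder(fam, 0.85)
    ids <- character(config$tandem_array_size)
    cur <- base
    for (k in seq_len(config$tandem_array_size)) {
      if (k > 1) cur <- evolve_member(cur, config$tandem_ks, config$tandem_omega)
      ids[k] <- add_gene(sl$chrom, sl$ranks[k], cur$protein, cur$cds, fam,
                         "subfamily", fi$type, "tandem",
                         cluster_id = paste0("planted_tandem", t),
                         identity_target = if (k == 1) 0.85 else NA_real_)
    }
    for (k in seq_len(config$tandem_array_size - 1)) {
      add_pair(ids[k], ids[k + 1], "TD", config$tandem_ks, config$tandem_omega)
    }
    if (config$tandem_array_size >= 3) {
      add_pair(ids[1], ids[3], "PD", 2 * config$tandem_ks, config$tandem_omega)
    }
    truth_clusters[[length(truth_clusters) + 1L]] <- tibble::tibble(
      cluster_id = paste0("planted_tandem", t),
      chromosome = paste0("chr", sl$chrom),
      member_gene_ids = list(ids))
  }

  # --- proximal pairs ----------------------------------------------------
  for (p in seq_len(config$n_proximal)) {
    sl <- slots$proximal[[p]]
    fam <- "CYP85"
    fi <- fam_info(fam)
    parent <- member_from_founder(fam, 0.80)
    pid <- add_gene(sl$chrom, sl$parent, parent$protein, parent$cds, fam,
                    "subfamily", fi$type, "proximal_parent",
                    identity_target = 0.80)
    cp <- evolve_member(parent, config$proximal_ks, config$single_gene_omega)
    cid <- add_gene(sl$chrom, sl$copy, cp$protein, cp$cds, fam,
                    "subfamily", fi$type, "proximal_copy")
    add_pair(pid, cid, "PD", config$proximal_ks, config$single_gene_omega)
  }

  # --- transposed copies (parents are segment family genes) --------------
  for (t in seq_len(config$n_transposed)) {
    parent_id <- trd_parents[(t - 1) %% length(trd_parents) + 1]
    pg <- genes[[parent_id]]
    sl <- slots$transposed_copy[[t]]
    cp <- evolve_member(list(protein = pg$protein, cds = pg$cds),
                        config$transposed_ks, config$single_gene_omega)
    cid <- add_gene(sl$chrom, sl$rank, cp$protein, cp$cds, pg$family,
                    "subfamily", pg$type, "transposed_copy")
    add_pair(parent_id, cid, "TRD", config$transposed_ks,
             config$single_gene_omega)
  }

  # --- dispersed pairs ---------------------------------------------------
  for (d in seq_len(config$n_dispersed)) {
    sl <- slots$dispersed[[d]]
    fam <- "CYP86"
    fi <- fam_info(fam)
    parent <- member_from_founder(fam, 0.82)
    pid <- add_gene(sl$parent$chrom, sl$parent$rank, parent$protein,
                    parent$cds, fam, "subfamily", fi$type,
                    "dispersed_parent", identity_target = 0.82)
    cp <- evolve_member(parent, config$dispersed_ks, config$single_gene_omega)
    cid <- add_gene(sl$copy$chrom, sl$copy$rank, cp$protein, cp$cds, fam,
                    "subfamily", fi$type, "dispersed_copy")
    add_pair(pid, cid, "DSD", config$dispersed_ks, config$single_gene_omega)
  }

  # --- extra planted cluster (spaced same-family members) ----------------
  cl <- slots$cluster
  cl_ids <- character(config$extra_cluster_size)
  for (k in seq_len(config$extra_cluster_size)) {
    m <- member_from_founder("CYP71", 0.75)
    cl_ids[k] <- add_gene(cl$chrom, cl$ranks[k], m$protein, m$cds, "CYP71",
                          "subfamily", "A", "cluster_member",
                          cluster_id = "planted_cluster1",
                          identity_target = 0.75)
  }
  truth_clusters[[length(truth_clusters) + 1L]] <- tibble::tibble(
    cluster_id = "planted_cluster1", chromosome = paste0("chr", cl$chrom),
    member_gene_ids = list(cl_ids))

  # --- scattered ladder members ------------------------------------------
  fam_ranks <- function(chrom) {
    ranks <- vapply(genes, function(g) {
      if (!is.na(g$family) && g$chrom == chrom) g$rank else NA_integer_
    }, integer(1))
    ranks[!is.na(ranks)]
  }
  next_free_spaced <- function() {
    for (chrom in seq_len(config$n_chromosomes)) {
      fr <- fam_ranks(chrom)
      for (rank in seq_len(config$genes_per_chromosome)) {
        if (used[chrom, rank]) next
        if (length(fr) == 0 ||
            min(abs(fr - rank)) >= config$min_family_spacing) {
          return(c(chrom, rank))
        }
      }
    }
    abort("simulate_genome: no free spaced slot for scattered members")
  }
  for (i in seq_len(nfam)) {
    fam <- config$families$family[i]
    fi <- config$families[i, ]
    for (k in seq_len(config$n_scattered_per_family)) {
      target <- config$identity_ladder[(k - 1) %% length(config$identity_ladder) + 1]
      m <- member_from_founder(fam, target)
      sl <- next_free_spaced()
      add_gene(sl[1], sl[2], m$protein, m$cds,
               if (tier_of(target) == "new_family") NA_character_ else fam,
               tier_of(target), fi$type, "scattered",
               identity_target = target)
    }
  }

  # --- decoys fill the remaining slots -----------------------------------
  for (chrom in seq_len(config$n_chromosomes)) {
    for (rank in seq_len(config$genes_per_chromosome)) {
      if (used[chrom, rank]) next
      len <- sample(150:400, 1)
      prot <- random_protein(len)
      if (runif(1) < config$decoy_motif_rate) {
        motif <- instantiate_consensus(
          patterns$consensus[patterns$region == "heme" &
                               patterns$variant == "nonA"])
        at <- sample(seq_len(len - nchar(motif)), 1)
        substr(prot, at, at + nchar(motif) - 1L) <- motif
        fo_keep <- at:(at + nchar(motif) - 1L)
      } else fo_keep <- integer(0)
      prot <- scrub_extra_motifs(prot, patterns, keep = fo_keep)
      add_gene(chrom, rank, prot, random_cds_for_protein(prot),
               NA_character_, NA_character_, NA_character_, "decoy")
    }
  }

  # --- assemble tibbles, gene models, references -------------------------
  glist <- genes[order(names(genes))]
  gtab <- purrr::map(glist, function(g) {
    tibble::tibble(gene_id = g$id, chromosome = paste0("chr", g$chrom),
                   rank = g$rank, family = g$family, tier = g$tier,
                   type = g$type, role = g$role, cluster_id = g$cluster_id,
                   identity_target = g$identity_target,
                   cds_len = nchar(g$cds),
                   protein = g$protein, cds = g$cds)
  }) |> dplyr::bind_rows()

  models <- purrr::map(seq_len(nrow(gtab)), function(i) {
    g <- gtab[i, ]
    cds_len <- g$cds_len
    n_ex <- sample(1:3, 1)
    cuts <- if (n_ex == 1) cds_len else {
      # split into n_ex chunks of >= 60 bp (not codon-aligned, so intron
      # phases span 0/1/2)
      pts <- sort(sample(seq(60L, cds_len - 60L), n_ex - 1))
      diff(c(0L, pts, cds_len))
    }
    start <- (g$rank - 1L) * 30000L + 1001L
    seg <- matrix(NA_integer_, n_ex, 2,
                  dimnames = list(NULL, c("start", "end")))
    pos <- start
    for (e in seq_len(n_ex)) {
      seg[e, ] <- c(pos, pos + cuts[e] - 1L)
      pos <- pos + cuts[e] + 200L          # 200-bp introns
    }
    strand <- sample(c("+", "-"), 1)
    ord <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
    tibble::tibble(gene_id = g$gene_id, chromosome = g$chromosome,
                   strand = strand,
                   start = start, end = as.integer(max(seg[, "end"])),
                   exons = list(seg[ord, , drop = FALSE]),
                   cds_segments = list(seg[ord, , drop = FALSE]),
                   cds_complete = TRUE)
  }) |> dplyr::bind_rows()

  references <- purrr::map(seq_len(nfam), function(i) {
    fam <- config$families$family[i]
    tibble::tibble(id = paste0("ref_", fam),
                   sequence = founders[[fam]]$protein,
                   clan = config$families$clan[i], family = fam,
                   subfamily = paste0(fam, "A"),
                   type = config$families$type[i])
  }) |> dplyr::bind_rows()

  pairs <- if (length(truth_pairs)) dplyr::bind_rows(truth_pairs) else
    tibble::tibble(gene_a = character(), gene_b = character(),
                   mode = character(), ks_target = numeric(),
                   omega_target = numeric())

  truth <- list(
    genes = dplyr::select(gtab, -"protein", -"cds"),
    pairs = pairs,
    clusters = dplyr::bind_rows(truth_clusters))

  proteins <- tibble::tibble(id = gtab$gene_id, description = "",
                             sequence = gtab$protein, kind = "protein")
  cds <- tibble::tibble(id = gtab$gene_id, description = "",
                        sequence = gtab$cds, kind = "cds")

  out <- list(proteins = proteins, cds = cds, models = models,
              references = references, truth = truth, config = config)
  if (!is.null(dir)) write_simulated_genome(out, dir)
  out
}

write_simulated_genome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$proteins, file.path(dir, "proteome.faa"))
  write_fasta(sim$cds, file.path(dir, "cds.fna"))
  write_gff3(sim$models, file.path(dir, "genes.gff3"))
  refs <- sim$references |>
    dplyr::mutate(description = paste0("clan=", .data$clan,
                                       " family=", .data$family,
                                       " subfamily=", .data$subfamily,
                                       " type=", .data$type))
  write_fasta(refs, file.path(dir, "references.faa"))
  write_tsv_plain(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv_plain(sim$truth$pairs, file.path(dir, "truth_pairs.tsv"))
  invisible(dir)
}

write_tsv_plain <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.list(col)) {
      vapply(col, function(v) paste(v, collapse = ","), character(1))
    } else col
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate stage-wise expression and a metabolite series
#'
#' Every gene receives a stage-mean FPKM profile: planted driver genes
#' share one rising profile that also generates the metabolite series
#' (`total_flavonoid` and `component_sum` are scaled copies of the driver
#' profile plus Gaussian noise whose standard deviation is
#' `metabolite_noise_frac` times the sd of the series); planted retention
#' pairs get complementary (subfunctionalised), parallel (dosage balance)
#' or one-silent (specialisation) profiles; background filler genes absorb
#' the library so computed FPKM values sit on the intended scale. Counts
#' are Poisson around `mean FPKM x length_kb x depth / 1e6` (or exact
#' rounded means with `noise = "none"`).
#'
#' @param sim A [simulate_genome()] result (its `truth$genes` and
#'   `truth$pairs` are used), or a list with a compatible `truth` element.
#' @param seed Integer seed.
#' @param dir Optional directory; writes `counts.tsv`, `metabolites.tsv`
#'   and `truth_expression.tsv`.
#' @return A list: `counts` (tibble `gene_id`, `length_bp`, stage
#'   columns), `metabolites` (tibble `stage`, `total_flavonoid`,
#'   `component_sum`), and `labels` (list with `drivers`, `retention`
#'   tibble, `profiles` tibble of true stage means).
#' @export
simulate_expression <- function(sim, seed = 1L, dir = NULL) {
  config <- sim$config$expression
  if (length(config$stage_labels) < 3) {
    abort("simulate_expression: need at least 3 stages")
  }
  with_seed(seed, simulate_expression_impl(sim, config, dir))
}

simulate_expression_impl <- function(sim, config, dir) {
  genes <- sim$truth$genes
  stages <- config$stage_labels
  ns <- length(stages)
  scale_profile <- function(p) p[seq_len(ns)] # profiles are length >= ns

  # choose drivers among scattered family members (deterministic order)
  scattered <- genes$gene_id[genes$role == "scattered" & !is.na(genes$family)]
  drivers <- utils::head(scattered, config$n_drivers)

  # retention pairs from planted duplications (skip driver overlap)
  pairs <- sim$truth$pairs
  pool <- pairs[!(pairs$gene_a %in% drivers | pairs$gene_b %in% drivers), ]
  take <- function(n, not_in) {
    ok <- !(pool$gene_a %in% not_in | pool$gene_b %in% not_in)
    utils::head(which(ok), n)
  }
  used <- character(0)
  sf_i <- take(config$n_sf_pairs, used)
  used <- c(used, pool$gene_a[sf_i], pool$gene_b[sf_i])
  do_i <- take(config$n_dosage_pairs, used)
  used <- c(used, pool$gene_a[do_i], pool$gene_b[do_i])
  si_i <- take(config$n_silenced_pairs, used)
  retention <- dplyr::bind_rows(
    tibble::tibble(gene_a = pool$gene_a[sf_i], gene_b = pool$gene_b[sf_i],
                   class = "subfunctionalization"),
    tibble::tibble(gene_a = pool$gene_a[do_i], gene_b = pool$gene_b[do_i],
                   class = "dosage_balance"),
    tibble::tibble(gene_a = pool$gene_a[si_i], gene_b = pool$gene_b[si_i],
                   class = "specialization_or_nonfunctionalization"))

  half <- ceiling(ns / 2)
  base_patterns <- list(
    rising = function() scale_profile(c(5, 15, 40, 90, 180)) * runif(1, 0.5, 2),
    falling = function() rev(scale_profile(c(5, 15, 40, 90, 180))) * runif(1, 0.5, 2),
    flat = function() rep(runif(1, 15, 60), ns),
    low = function() rep(runif(1, 0.05, 0.5), ns))

  profiles <- stats::setNames(vector("list", nrow(genes)), genes$gene_id)
  for (i in seq_len(config$n_drivers)) {
    if (i > length(drivers)) break
    profiles[[drivers[i]]] <- config$driver_profile[seq_len(ns)] *
      runif(1, 0.8, 1.5)
  }
  sf_shape_a <- c(rep(1, half), rep(0, ns - half))
  for (i in seq_len(nrow(retention))) {
    a <- retention$gene_a[i]; b <- retention$gene_b[i]
    if (retention$class[i] == "subfunctionalization") {
      lev <- runif(2, 20, 60)
      profiles[[a]] <- sf_shape_a * lev[1]
      profiles[[b]] <- (1 - sf_shape_a) * lev[2]
    } else if (retention$class[i] == "dosage_balance") {
      shape <- scale_profile(c(20, 40, 80, 40, 20))
      profiles[[a]] <- shape * runif(1, 0.8, 1.5)
      profiles[[b]] <- shape * runif(1, 0.8, 1.5)
    } else {
      profiles[[a]] <- scale_profile(c(50, 40, 60, 55, 45)) * runif(1, 0.8, 1.5)
      profiles[[b]] <- rep(0, ns)
    }
  }
  for (g in genes$gene_id) {
    if (is.null(profiles[[g]])) {
      pat <- sample(names(base_patterns), 1)
      profiles[[g]] <- base_patterns[[pat]]()
    }
  }

  # background filler genes keep the library on a realistic scale
  bg <- tibble::tibble(
    gene_id = sprintf("bg%03d", seq_len(config$n_background)),
    length_bp = config$background_length)
  for (g in bg$gene_id) profiles[[g]] <- rep(config$background_fpkm, ns)

  lengths_bp <- c(stats::setNames(genes$cds_len, genes$gene_id),
                  stats::setNames(bg$length_bp, bg$gene_id))
  all_ids <- names(lengths_bp)
  mean_mat <- do.call(rbind, profiles[all_ids])
  count_mean <- mean_mat * (lengths_bp / 1e3) * (config$depth / 1e6)
  counts_mat <- if (config$noise == "poisson") {
    matrix(rpois(length(count_mean), lambda = count_mean),
           nrow = nrow(count_mean))
  } else round(count_mean)
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = all_ids, length_bp = unname(lengths_bp)),
    tibble::as_tibble(stats::setNames(as.data.frame(counts_mat), stages)))

  driver_profile <- config$driver_profile[seq_len(ns)]
  noise_sd <- function(series) config$metabolite_noise_frac * sd(series)
  tf <- config$metabolite_scale[1] * driver_profile
  cs <- config$metabolite_scale[2] * driver_profile
  if (config$noise != "none") {
    tf <- tf + rnorm(ns, 0, noise_sd(tf))
    cs <- cs + rnorm(ns, 0, noise_sd(cs))
  }
  metabolites <- tibble::tibble(stage = stages,
                                total_flavonoid = pmax(tf, 0),
                                component_sum = pmax(cs, 0))

  profile_tab <- tibble::tibble(
    gene_id = all_ids,
    profile = purrr::map(all_ids, ~ unname(profiles[[.x]])))
  out <- list(counts = counts, metabolites = metabolites,
              labels = list(drivers = drivers, retention = retention,
                            profiles = profile_tab))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_plain(counts, file.path(dir, "counts.tsv"))
    write_tsv_plain(metabolites, file.path(dir, "metabolites.tsv"))
    write_tsv_plain(
      tibble::tibble(gene_id = drivers, label = "driver") |>
        dplyr::bind_rows(tibble::tibble(gene_id = retention$gene_a,
                                        label = retention$class),
                         tibble::tibble(gene_id = retention$gene_b,
                                        label = retention$class)),
      file.path(dir, "truth_expression.tsv"))
  }
  out
}
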