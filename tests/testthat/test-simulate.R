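test_that("simulation output is byte-identical for a fixed seed", {
  cfg <- smallSimConfig(n_true_mutations = 100L, n_bleed_errors = 200L,
                        n_cluster_errors = 20L, n_recurrent_errors = 4L)
  a <- simulateCallSets(cfg)
  b <- simulateCallSets(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(callTable(a$observed), callTable(b$observed))
  expect_identical(a$ledger, b$ledger)
})

test_that("ledger tags partition the observed set and counts match the config", {
  sim <- smallSim()
  cfg <- sim$config
  expect_equal(nrow(sim$ledger), nCalls(sim$observed))
  cnt <- ledgerCounts(sim$ledger)
  expect_equal(cnt[["true_mutation"]], cfg$n_true_mutations)
  expect_equal(cnt[["bleed_error"]], cfg$n_bleed_errors)
  expect_equal(cnt[["cluster_error"]],
               cfg$n_cluster_errors * cfg$cluster_size)
  expect_equal(cnt[["recurrent_error"]],
               cfg$n_recurrent_errors * cfg$recurrent_sample_count)
})

test_that("every injected bleed call is recovered by the classifier with its sampled distance", {
  sim <- smallSim()
  runs <- findRuns(sim$genome, sim$config$min_run_length)
  bl <- ledgerSubset(sim, "bleed_error")
  cls <- classifyBleed(bl, runs, sim$config$proximity_window)
  expect_equal(cls$summary$n_bleed, nCalls(bl))  # recall 100%
  ## classifier distances equal the generator's sampled distances
  led <- sim$ledger[sim$ledger$tag == "bleed_error", ]
  lkey <- paste(led$chrom, led$pos, led$sample_id, led$alt)
  bkey <- paste(cls$bleed$chrom, cls$bleed$pos, cls$bleed$sample_id,
                cls$bleed$alt)
  expect_equal(cls$bleed$distance, led$distance[match(bkey, lkey)])
  expect_equal(cls$bleed$run_length, led$run_length[match(bkey, lkey)])
})

test_that("homopolymer enrichment is recovered from the seeded genome", {
  density_ratio <- function(enrichment, reps, seeds) {
    n_ig <- n_cds <- bp_ig <- bp_cds <- 0
    for (s in seeds) {
      cfg <- simulationConfig(n_chromosomes = 1L, chrom_length = 200000,
                              n_genes = 40L,
                              homopolymer_enrichment = enrichment,
                              seed = s)
      g <- generateGenome(cfg)
      runs <- findRuns(g$genome, 4)
      runs <- runs[S4Vectors::mcols(runs)$klass == "AT"]
      ann <- g$annotation
      parts <- list(
        intron = GenomicRanges::reduce(GenomicRanges::granges(
          ann[S4Vectors::mcols(ann)$type == "intron"])),
        cds = GenomicRanges::reduce(GenomicRanges::granges(
          ann[S4Vectors::mcols(ann)$type == "CDS"])))
      anchor <- GenomicRanges::resize(runs, 1L)
      n_ig <- n_ig + sum(GenomicRanges::countOverlaps(
        anchor, parts$intron, ignore.strand = TRUE) > 0)
      n_cds <- n_cds + sum(GenomicRanges::countOverlaps(
        anchor, parts$cds, ignore.strand = TRUE) > 0)
      bp_ig <- bp_ig + sum(GenomicRanges::width(parts$intron))
      bp_cds <- bp_cds + sum(GenomicRanges::width(parts$cds))
    }
    list(ratio = (n_ig / bp_ig) / (n_cds / bp_cds),
         n_ig = n_ig, n_cds = n_cds)
  }
  r5 <- density_ratio(5, seeds = 101:112)
  expect_gt(r5$ratio, 3.5)
  expect_lt(r5$ratio, 6.5)
  r1 <- density_ratio(1, seeds = 201:212)
  ## null case: log ratio within 3 s.d. of 0 (Poisson counts)
  se <- 3 * sqrt(1 / r1$n_ig + 1 / r1$n_cds)
  expect_lt(abs(log(r1$ratio)), se)
})

test_that("true mutations follow the closed-form CpG>TpG expectation", {
  cfg <- smallSimConfig(n_true_mutations = 4000L, cpg_rate_multiplier = 10,
                        te_mutation_multiplier = 1)
  g <- generateGenome(cfg)
  truth <- generateTrueMutations(g$genome, g$annotation, cfg, seed = 5)
  m <- 10
  ncg <- sum(vapply(names(g$genome), function(chr) {
    hits <- gregexpr("CG", as.character(g$genome[[chr]]), fixed = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }, 0L))
  n_cpg <- 2 * ncg
  n_non <- sum(Biostrings::width(g$genome)) - n_cpg
  expected <- (n_cpg * m / 3) / (n_non + n_cpg * (m + 2) / 3)
  tab <- callTable(truth)
  iscpg <- logical(nrow(tab))
  for (chr in unique(tab$chrom)) {
    ix <- which(tab$chrom == chr)
    sc <- as.character(g$genome[[chr]])
    nxt <- substring(sc, tab$pos[ix] + 1L, tab$pos[ix] + 1L)
    prv <- substring(sc, tab$pos[ix] - 1L, tab$pos[ix] - 1L)
    iscpg[ix] <- (tab$ref[ix] == "C" & tab$alt[ix] == "T" & nxt == "G") |
      (tab$ref[ix] == "G" & tab$alt[ix] == "A" & prv == "C")
  }
  obs <- mean(iscpg)
  tol <- 4 * sqrt(expected * (1 - expected) / nrow(tab))
  expect_lt(abs(obs - expected), tol)
  ## estimator inverts the share back to the configured multiplier
  expect_gt(estimateCpGMultiplier(truth, g$genome), 7)
  expect_lt(estimateCpGMultiplier(truth, g$genome), 13)
})

test_that("degenerate generator settings behave as specified", {
  cfg <- smallSimConfig(te_fraction_intergenic = 0)
  g <- generateGenome(cfg)
  expect_equal(sum(S4Vectors::mcols(g$annotation)$type == "TE"), 0L)

  cfg0 <- smallSimConfig(n_true_mutations = 0L)
  g0 <- generateGenome(cfg0)
  expect_equal(nCalls(generateTrueMutations(g0$genome, g0$annotation,
                                            cfg0, seed = 1)), 0L)
  cfgbig <- smallSimConfig(n_true_mutations = 10000000L)
  expect_error(generateTrueMutations(g0$genome, g0$annotation, cfgbig,
                                     seed = 1), "exceeds genome size")
  expect_error(simulationConfig(cluster_span = 1L), "cluster_span")
  expect_error(simulationConfig(bleed_length_slope = 0), "slope")
  expect_error(generateGenome(smallSimConfig(n_genes = 100000L)),
               "exceed available space")
})

test_that("full strand bias leaves exactly one dead strand on every bleed call", {
  cfg <- smallSimConfig(bleed_strand_bias = 1, n_bleed_errors = 300L)
  g <- generateGenome(cfg)
  bl <- injectBleedErrors(g$genome, cfg, seed = 9)
  tab <- callTable(bl$callset)
  expect_true(all(xor(tab$fwd_support == 0L, tab$rev_support == 0L)))
})

test_that("bleed alleles copy the run base with the documented patterns", {
  sim <- smallSim()
  led <- sim$ledger[sim$ledger$tag == "bleed_error", ]
  snv <- nchar(led$ref) == 1L & nchar(led$alt) == 1L
  expect_true(all(led$alt[snv] %in% c("A", "T")))
  expect_true(all(led$ref[snv] != led$alt[snv]))
  ## indels insert or delete the run base
  ins <- nchar(led$alt) == 2L
  del <- nchar(led$ref) == 2L
  expect_true(all(substr(led$alt[ins], 2, 2) %in% c("A", "T")))
  expect_true(all(substr(led$ref[del], 2, 2) %in% c("A", "T")))
})

test_that("constructed mis-mapping clusters and recurrent sites are detectable as built", {
  cfg <- smallSimConfig(n_true_mutations = 0L, n_bleed_errors = 0L,
                        n_cluster_errors = 5L, n_recurrent_errors = 0L)
  sim <- simulateCallSets(cfg)
  expect_equal(nCalls(sim$observed), 10L)
  cl <- findClusters(sim$observed, window = cfg$cluster_span)
  expect_equal(nrow(cl$clusters), 5L)
  expect_equal(cl$pct_clustered, 100.0)

  cfg2 <- smallSimConfig(n_true_mutations = 0L, n_bleed_errors = 0L,
                         n_cluster_errors = 0L, n_recurrent_errors = 6L,
                         recurrent_sample_count = 12L)
  sim2 <- simulateCallSets(cfg2)
  rec <- findRecurrent(sim2$observed, sample_threshold = 10L)
  expect_equal(nrow(rec$sites), 6L)
  expect_true(all(rec$sites$n_samples == 12L))
  expect_true(all(rec$flagged))

  cfg3 <- smallSimConfig(n_true_mutations = 0L, n_bleed_errors = 0L,
                         n_cluster_errors = 0L, n_recurrent_errors = 0L)
  sim3 <- simulateCallSets(cfg3)
  expect_equal(nCalls(sim3$observed), 0L)
})
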