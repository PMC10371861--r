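test_that("region assignment is an exhaustive partition by precedence", {
  sim <- smallSim()
  region <- assignRegion(sim$observed, sim$annotation)
  expect_equal(length(region), nCalls(sim$observed))
  expect_true(all(region %in% c("CDS", "intron", "TE", "centromere",
                                "intergenic")))
  parts <- mutbleed:::regionPartition(sim$annotation)
  expect_equal(sum(vapply(parts, function(p)
    sum(as.numeric(GenomicRanges::width(p))), 0)),
    sum(Biostrings::width(sim$genome)))
  cs_bad <- snvCalls("q", "chrX", 5L, "A", "T")
  expect_error(assignRegion(cs_bad, sim$annotation), "unannotated")
})

test_that("bleed-contaminated call sets inflate the intron:CDS rate ratio", {
  sim <- smallSim()
  rr_obs <- regionRates(sim$observed, sim$annotation, sim$genome,
                        spectra = FALSE)
  rr_tru <- regionRates(sim$truth, sim$annotation, sim$genome,
                        spectra = FALSE)
  expect_gt(rr_obs$intron_cds_ratio, 1.3)
  expect_gt(rr_obs$intron_cds_ratio, rr_tru$intron_cds_ratio)
  expect_lt(rr_tru$intron_cds_ratio, 1.6)
  expect_gt(rr_tru$intron_cds_ratio, 0.5)
})

test_that("paired rate tests drop unusable classes and adjust df", {
  x <- runif(96, 0, 1e-3)
  same <- pairedRateTest(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$mean_ratio, 1)
  expect_equal(same$df, 95)
  y <- x * 2
  y[1:6] <- NA
  dropped <- pairedRateTest(x, y)
  expect_equal(dropped$df, 89)
  expect_equal(dropped$n_dropped, 6)
  expect_error(pairedRateTest(x[1:12], c(rep(NA, 11), 1e-3)), "usable")
})

test_that("TE-elevated rates are detected by the paired dinucleotide test", {
  cfg <- smallSimConfig(n_true_mutations = 6000L,
                        te_mutation_multiplier = 4)
  g <- generateGenome(cfg)
  truth <- generateTrueMutations(g$genome, g$annotation, cfg, seed = 13)
  parts <- mutbleed:::regionPartition(g$annotation)
  sp_te <- diSpectrum(truth, g$genome, region = parts$TE)
  sp_ig <- diSpectrum(truth, g$genome, region = parts$intergenic)
  pt <- pairedRateTest(normalizedRates(sp_te), normalizedRates(sp_ig))
  expect_lt(pt$p_value, 0.05)
  expect_gt(pt$ratio_of_means, 2.5)
  expect_lt(pt$ratio_of_means, 6)
})

test_that("gene-class rates use a bp-proportional chi-square with df 3", {
  sim <- smallSim()
  rep <- geneClassRates(sim$truth, sim$annotation, feature = "CDS")
  expect_equal(rep$df, 3)
  expect_equal(nrow(rep$table), 4)
  expect_equal(sum(rep$table$n_genes),
               sum(!is.na(S4Vectors::mcols(sim$annotation)$gene_class) &
                     S4Vectors::mcols(sim$annotation)$type == "gene"))
  bad_map <- data.frame(gene_id = c("g1", "g1"),
                        class = c("essential", "environmental"))
  expect_error(geneClassRates(sim$truth, sim$annotation, bad_map), "two")
})

test_that("a doubled essential-gene rate is detected as heterogeneity", {
  cfg <- smallSimConfig(n_true_mutations = 5000L,
                        essential_rate_multiplier = 2,
                        te_mutation_multiplier = 1,
                        cpg_rate_multiplier = 1)
  g <- generateGenome(cfg)
  truth <- generateTrueMutations(g$genome, g$annotation, cfg, seed = 3)
  rep <- geneClassRates(truth, g$annotation, feature = "CDS")
  expect_lt(rep$p_value, 0.05)
  expect_equal(which.max(rep$table$rate),
               which(rep$table$class == "essential"))
})

test_that("metagene binning conserves events and respects strand orientation", {
  g <- tinyGenome(chr1 = strrep("A", 10000))
  ann <- tinyAnnotation(g, chrom = c("chr1", "chr1"),
                        start = c(4001, 4001), end = c(6000, 6000),
                        type = c("gene", "exon"), strand = "-",
                        gene_id = c("g1", "g1"))
  ## TSS of the minus-strand gene is at 6000; an event 10 bp 5' of the
  ## TSS sits at 6010 and must land in the bin covering offset -10
  ev <- data.frame(chrom = "chr1", pos = 6010L)
  mp <- metageneProfile(ev, ann, window_bp = 1000L, bin_bp = 100L)
  hit <- mp$tss[mp$tss$count > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$offset_start, -100)
  expect_error(metageneProfile(ev, ann, window_bp = 50L, bin_bp = 100L),
               "window")

  ## conservation: density * bin * anchors sums to in-window events
  set.seed(6)
  ev2 <- data.frame(chrom = "chr1", pos = sample.int(10000L, 500L))
  mp2 <- metageneProfile(ev2, ann, window_bp = 1000L, bin_bp = 100L)
  in_window <- sum(ev2$pos >= 5000 & ev2$pos <= 6999)
  expect_equal(sum(mp2$tss$density) * 100 * mp2$n_anchors, in_window)

  ## events confined to the gene body leave upstream bins empty
  ev3 <- data.frame(chrom = "chr1", pos = 4001:6000)
  mp3 <- metageneProfile(ev3, ann, window_bp = 1000L, bin_bp = 100L)
  expect_true(all(mp3$tss$density[mp3$tss$offset_start < 0] == 0))
})

test_that("uniform events give a flat metagene profile", {
  sim <- smallSim()
  set.seed(9)
  n <- 60000L
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  chrom <- sample(names(sim$genome), n, TRUE, prob = lens)
  ev <- data.frame(chrom = chrom,
                   pos = ceiling(runif(n) * lens[chrom]))
  mp <- metageneProfile(ev, sim$annotation, window_bp = 2000L,
                        bin_bp = 200L)
  d <- mp$tss$density
  expect_lt((max(d) - min(d)) / mean(d), 0.5)
})

test_that("simulated homopolymer errors are reproducible and follow run weights", {
  sim <- smallSim()
  runs <- findRuns(sim$genome, 4)
  a <- simulateHomopolymerErrors(sim$genome, runs, 2000L, 0.27, seed = 5)
  b <- simulateHomopolymerErrors(sim$genome, runs, 2000L, 0.27, seed = 5)
  expect_identical(a, b)

  ## slope 0: errors proportional to run bp, so the run-length profile of
  ## attributed errors matches the bp share of each length
  at <- runs[S4Vectors::mcols(runs)$klass == "AT"]
  e0 <- simulateHomopolymerErrors(sim$genome, runs, 20000L, 0, seed = 6)
  cls <- classifyBleed(
    CallSet("e", e0$chrom, e0$pos, "N", "A", paste0("S", seq_len(nrow(e0))),
            5L, 5L, var_class = rep("SNV", nrow(e0))),
    at, require_allele_match = FALSE)
  bp_share <- tapply(GenomicRanges::width(at),
                     S4Vectors::mcols(at)$length, sum)
  bp_share <- bp_share / sum(bp_share)
  obs_share <- table(factor(cls$bleed$run_length,
                            levels = names(bp_share))) / nrow(cls$bleed)
  expect_lt(max(abs(as.numeric(obs_share) - as.numeric(bp_share))), 0.05)
})

test_that("TE metagene density is high outside transcribed domains", {
  sim <- smallSim()
  tm <- teMetagene(sim$annotation, window_bp = 2000L, bin_bp = 200L)
  upstream <- mean(tm$tss$density[tm$tss$offset_start < -400])
  body <- mean(tm$tss$density[tm$tss$offset_start >= 0])
  expect_gt(upstream, body)
  downstream <- mean(tm$tts$density[tm$tts$offset_start >= 400])
  body_tts <- mean(tm$tts$density[tm$tts$offset_start < 0])
  expect_gt(downstream, body_tts)

  g <- tinyGenome(chr1 = strrep("A", 1000))
  ann <- tinyAnnotation(g, chrom = c("chr1", "chr1"),
                        start = c(101, 101), end = c(400, 400),
                        type = c("gene", "exon"), gene_id = c("g1", "g1"))
  expect_error(teMetagene(ann, 500L, 100L), "no TEs")
})

test_that("simulated errors reproduce the injected-call metagene profile", {
  sim <- smallSim()
  runs <- findRuns(sim$genome, 4)
  bl <- ledgerSubset(sim, "bleed_error")
  mp_inj <- metageneProfile(bl, sim$annotation, 2000L, 200L)
  err <- simulateHomopolymerErrors(sim$genome, runs, 50000L, 0.27,
                                   seed = 99)
  mp_sim <- metageneProfile(err, sim$annotation, 2000L, 200L)
  expect_gt(cor(mp_inj$tss$density, mp_sim$tss$density), 0.6)
  expect_gt(cor(mp_inj$tts$density, mp_sim$tts$density), 0.6)
})
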