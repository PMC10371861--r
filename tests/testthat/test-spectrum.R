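test_that("mononucleotide spectra collapse purine classes onto pyrimidines", {
  cs <- snvCalls("q", "chr1", c(5L, 9L), c("G", "C"), c("A", "T"))
  sp <- monoSpectrum(cs)
  expect_equal(unname(sp$counts6[["C>T"]]), 2)
  expect_equal(sum(sp$counts12), 2)
  empty <- monoSpectrum(CallSet("e"))
  expect_true(all(empty$counts6 == 0))
})

test_that("dinucleotide classes follow the source/position/result definition", {
  g <- tinyGenome(chr1 = "GCATG")
  ## C>T at position 2: 5' dinuc GC (second -> T), 3' dinuc CA (first -> T)
  cs <- snvCalls("q", "chr1", 2L, "C", "T")
  sp <- diSpectrum(cs, g, flank = "3prime")
  cnt <- spectrumCounts(sp)
  expect_equal(unname(cnt[["CA>TA"]]), 1)
  expect_equal(sum(cnt), 1)
  sp5 <- diSpectrum(cs, g, flank = "5prime")
  expect_equal(unname(spectrumCounts(sp5)[["GC>GT"]]), 1)
  spb <- diSpectrum(cs, g, flank = "both")
  expect_equal(sum(spectrumCounts(spb)), 2)
  expect_equal(spb@n_classified, 1)

  ## a G>A with a 3' A resolves to AA and feeds the AA/TT share
  g2 <- tinyGenome(chr1 = "TTGAA")
  cs2 <- snvCalls("q", "chr1", 3L, "G", "A")
  sp2 <- diSpectrum(cs2, g2, flank = "3prime")
  expect_equal(unname(spectrumCounts(sp2)[["GA>AA"]]), 1)
  expect_gt(shareAATT(sp2), 0)
})

test_that("class assignments conserve the SNV count, edge calls excluded", {
  g <- tinyGenome(chr1 = "ACGTACGTAC")
  ## calls at both chromosome ends plus interior; indel ignored
  cs <- CallSet("q", rep("chr1", 4), c(1L, 5L, 10L, 7L),
                c("A", "A", "C", "G"), c("G", "T", "A", "GA"),
                paste0("S", 1:4), 5L, 5L)
  sp <- diSpectrum(cs, g, flank = "both")
  expect_equal(sp@n_classified + sp@n_edge_excluded, 3)
  expect_equal(sp@n_edge_excluded, 0)  # ends still have one usable flank
  sp3 <- diSpectrum(cs, g, flank = "5prime")
  expect_equal(sp3@n_edge_excluded, 1)  # position 1 has no 5' flank
})

test_that("context counting uses overlapping windows", {
  g <- tinyGenome(chr1 = "AAAA")
  sp <- diSpectrum(CallSet("e"), g)
  expect_equal(unname(contextCounts(sp)[["AA"]]), 3)
})

test_that("the collapsed spectrum is invariant under reverse complementation", {
  sim <- smallSim()
  tab <- callTable(sim$truth)
  tab <- tab[tab$var_class == "SNV", ]
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  rc_genome <- Biostrings::reverseComplement(sim$genome)
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rc <- CallSet("rc", tab$chrom, lens[tab$chrom] - tab$pos + 1L,
                comp(tab$ref), comp(tab$alt), tab$sample_id,
                tab$fwd_support, tab$rev_support)
  a <- collapseSpectrum(diSpectrum(sim$truth, sim$genome))
  b <- collapseSpectrum(diSpectrum(rc, rc_genome))
  expect_equal(a, b)
})

test_that("spectrum comparison gives df 95 and calibrated p-values", {
  set.seed(21)
  p <- rgamma(96, 2); p <- p / sum(p)
  mk <- function(counts) {
    cls <- mutbleed:::class96()
    new("DiSpectrum96", classes = cls, counts = as.numeric(counts),
        context_bp = setNames(rep(1000, 16), mutbleed:::DINUCS),
        normalized_rate = as.numeric(counts) / 1000,
        n_classified = sum(counts), n_edge_excluded = 0, flank = "both")
  }
  a <- mk(rmultinom(1, 6000, p)[, 1] + 1)
  b <- mk(rmultinom(1, 6000, p)[, 1] + 1)
  cmp <- compareSpectra(a, b)
  expect_equal(cmp$df, 95)
  expect_equal(nrow(cmp$residuals), 96)

  same <- compareSpectra(a, a)
  expect_equal(unname(same$chi2), 0)
  expect_error(compareSpectra(a, mk(rep(0, 96))), "empty")

  ## under the same multinomial, p-values are uniform
  pvals <- replicate(400, {
    x <- mk(rmultinom(1, 5000, p)[, 1])
    y <- mk(rmultinom(1, 5000, p)[, 1])
    suppressWarnings(compareSpectra(x, y)$p_value)
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("artifact-heavy spectra inflate the AA/TT resolved-end share", {
  sim <- smallSim()
  s_obs <- shareAATT(diSpectrum(sim$observed, sim$genome))
  s_tru <- shareAATT(diSpectrum(sim$truth, sim$genome))
  expect_gt(s_obs, s_tru + 5)
})

test_that("CpG>TpG rates per CG are compared between regions", {
  ## one CpG transition in each of two equal-CG regions: ratio 1
  g <- tinyGenome(chr1 = paste0(strrep("ACGT", 25),    # gene body
                                strrep("ACGT", 25)))   # intergenic
  ann <- tinyAnnotation(g, chrom = c("chr1", "chr1", "chr1"),
                        start = c(1, 1, 151), end = c(100, 100, 200),
                        type = c("gene", "exon", "TE"),
                        gene_id = c("g1", "g1", NA))
  cs <- snvCalls("q", "chr1", c(122L, 178L), "C", "T",
                 sample_id = c("S1", "S2"))
  r <- cpgTpgRatio(cs, g, ann, region_a = "TE", region_b = "intergenic_nonTE")
  expect_equal(unname(r$ratio), 1, tolerance = 1e-9)
  ## a region with no CG errors out
  gA <- tinyGenome(chr1 = paste0(strrep("ACGT", 25), strrep("A", 100)))
  annA <- tinyAnnotation(gA, chrom = c("chr1", "chr1", "chr1"),
                         start = c(1, 1, 151), end = c(100, 100, 200),
                         type = c("gene", "exon", "TE"),
                         gene_id = c("g1", "g1", NA))
  expect_error(cpgTpgRatio(cs, gA, annA), "no CG")
})

test_that("the configured TE mutation multiplier is recovered from CpG rates", {
  cfg <- smallSimConfig(n_true_mutations = 6000L,
                        te_mutation_multiplier = 5)
  g <- generateGenome(cfg)
  truth <- generateTrueMutations(g$genome, g$annotation, cfg, seed = 31)
  r <- cpgTpgRatio(truth, g$genome, g$annotation)
  expect_gt(r$ratio, 3.2)
  expect_lt(r$ratio, 7.2)
})
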