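test_that("the canonical bleed patterns are classified with their adjacency", {
  ## interrupted run: the G inside AAAAGAAAA read as A
  g <- tinyGenome(chr1 = "CCAAAAGAAAACC")
  runs <- findRuns(g, 4)
  cs <- snvCalls("q", "chr1", 7L, "G", "A")
  cls <- classifyBleed(cs, runs)
  expect_equal(cls$summary$n_bleed, 1L)
  expect_equal(cls$bleed$distance, 0L)
  expect_equal(cls$bleed$adjacency, "adjacent")

  ## base just past the run end: AAAAC read as AAAAA
  g2 <- tinyGenome(chr1 = "GGAAAACTTGG")
  cs2 <- snvCalls("q", "chr1", 7L, "C", "A")
  cls2 <- classifyBleed(cs2, findRuns(g2, 4))
  expect_equal(cls2$bleed$adjacency, "adjacent")
  expect_equal(cls2$bleed$run_base, "A")

  ## far from any run, or wrong allele: not bleed
  g3 <- tinyGenome(chr1 = paste0("GGAAAAGG", strrep("CT", 20)))
  cs3 <- snvCalls("q", "chr1", 30L, "C", "T")
  expect_equal(classifyBleed(cs3, findRuns(g3, 4))$summary$n_bleed, 0L)
  cs4 <- snvCalls("q", "chr1", 7L, "G", "C")
  expect_equal(classifyBleed(cs4, findRuns(g3, 4))$summary$n_bleed, 0L)

  ## single-base deletion of the run base inside the run: within
  cs5 <- CallSet("q", "chr1", 4L, "AA", "A", "S1", 5L, 5L)
  cls5 <- classifyBleed(cs5, findRuns(g3, 4))
  expect_equal(cls5$bleed$adjacency, "within")
  expect_equal(cls5$bleed$distance, 0L)
})

test_that("co-read bleed errors beyond the run cluster together", {
  ## AAAAACACACA read as AAAAAAAAAAA: three putative C>A calls
  g <- tinyGenome(chr1 = "GGGGGAAAAACACACAGGGG")
  runs <- findRuns(g, 4)
  cs <- snvCalls("q", "chr1", c(11L, 13L, 15L), "C", "A",
                 sample_id = rep("S1", 3))
  cls <- bleedClusters(classifyBleed(cs, runs))
  expect_equal(cls$summary$n_bleed, 3L)
  expect_equal(unname(cls$counts["within_adjacent"]), 1L)
  expect_equal(unname(cls$counts["nearby"]), 2L)
  expect_equal(unname(cls$counts["nearby_clustered"]), 2L)

  ## a single isolated nearby call is not flagged
  cs1 <- snvCalls("q", "chr1", 13L, "C", "A")
  cls1 <- bleedClusters(classifyBleed(cs1, runs))
  expect_equal(unname(cls1$counts["nearby_clustered"]), 0L)
})

test_that("bleed classification invariants hold on simulated data", {
  sim <- smallSim()
  runs <- findRuns(sim$genome, 4)
  cls <- bleedClusters(classifyBleed(sim$observed, runs,
                                     annotation = sim$annotation))
  b <- cls$bleed
  ## every flagged call has a qualifying A/T run within the window
  expect_true(all(b$distance <= 5L))
  expect_true(all(b$run_base %in% c("A", "T")))
  ## adjacency categories partition the bleed calls
  expect_equal(sum(b$adjacency %in% c("within", "adjacent")) +
                 sum(b$adjacency == "nearby"), nrow(b))
  ## the GC-run fraction stays near zero on A/T-biased data
  expect_lt(cls$summary$fraction_other_klass, 0.05)
  ## recovered bleed fraction is close to the injected fraction
  inj <- sim$config$n_bleed_errors / nCalls(sim$observed)
  tol <- 4 * sqrt(inj * (1 - inj) / nCalls(sim$observed)) + 0.02
  expect_lt(abs(cls$summary$fraction - inj), tol)
})

test_that("run-length regression reproduces an exact doubling construction", {
  ## n_L = 2^(10-L) runs of length L, c_L = L calls at distance 0:
  ## rate(L) = L / (L * 2^(10-L)) = 2^(L-10), an exact log-linear law
  spacer <- strrep("CG", 7)
  seqs <- character(0)
  calls <- NULL
  pos <- 0L
  for (L in 4:7) {
    nL <- 2L^(10L - L)
    for (i in seq_len(nL)) {
      seqs <- c(seqs, spacer, strrep("A", L))
      run_end <- pos + nchar(spacer) + L
      if (i <= L)  # call at the base just past the run end
        calls <- rbind(calls, data.frame(pos = run_end + 1L))
      pos <- run_end
    }
  }
  s <- paste(c(seqs, spacer), collapse = "")
  g <- tinyGenome(chr1 = s)
  runs <- findRuns(g, 4)
  cs <- snvCalls("q", "chr1", calls$pos, "C", "A",
                 sample_id = paste0("S", seq_len(nrow(calls))))
  reg <- suppressWarnings(runLengthRegression(cs, runs))  # perfect fit
  expect_equal(reg$slope, log10(2), tolerance = 1e-10)
  expect_equal(reg$r_squared, 1, tolerance = 1e-10)
  expect_equal(reg$df, 2L)
  expect_error(runLengthRegression(cs[1:2], runs), "usable")
})

test_that("eight run-length bins give six regression degrees of freedom", {
  spacer <- strrep("CG", 7)
  seqs <- character(0); cpos <- integer(0); pos <- 0L
  for (L in 4:11) {
    seqs <- c(seqs, spacer, strrep("T", L))
    run_end <- pos + nchar(spacer) + L
    cpos <- c(cpos, run_end + 1L)
    pos <- run_end
  }
  g <- tinyGenome(chr1 = paste(c(seqs, spacer), collapse = ""))
  cs <- snvCalls("q", "chr1", cpos, "C", "T",
                 sample_id = paste0("S", seq_along(cpos)))
  reg <- runLengthRegression(cs, findRuns(g, 4))
  expect_equal(reg$df, 6L)
})

test_that("bleed-call rates decay with distance from the run boundary", {
  sim <- smallSim()
  runs <- findRuns(sim$genome, 4)
  cls <- classifyBleed(ledgerSubset(sim, "bleed_error"), runs)
  dec <- distanceDecay(cls)
  expect_lt(dec$spearman_rho, 0)
  expect_lt(dec$spearman_p, 0.05)
  ## the histogram equals the generator's sampled distances exactly
  led <- sim$ledger[sim$ledger$tag == "bleed_error", ]
  expect_equal(dec$table$count,
               as.numeric(table(factor(led$distance, levels = 0:5))))

  ## a uniform-distance construction shows no trend
  flat <- data.frame(distance = rep(0:5, each = 10))
  dec0 <- distanceDecay(flat)
  expect_true(is.na(dec0$spearman_rho) || dec0$spearman_p > 0.05)
})
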