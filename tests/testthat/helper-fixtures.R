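## fixtures shared across test files; everything is built in code

DIN <- mutbleed:::DINUCS

tinyGenome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

## minimal annotation from explicit feature rows
tinyAnnotation <- function(genome, chrom, start, end, type,
                           strand = "+", gene_id = NA, gene_class = NA) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = type, gene_id = as.character(gene_id),
    gene_class = as.character(gene_class))
  buildAnnotation(gr, genome)
}

snvCalls <- function(label, chrom, pos, ref, alt,
                     sample_id = paste0("S", seq_along(pos)),
                     fwd = 5L, rev = 5L) {
  CallSet(label, chrom, pos, ref, alt, sample_id, fwd, rev)
}

## a small but complete simulation, cached per session
smallSimConfig <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2L, chrom_length = 250000,
         n_genes = 100L, n_true_mutations = 300L,
         n_bleed_errors = 1200L, n_cluster_errors = 150L,
         n_recurrent_errors = 12L, n_samples = 60L, seed = 7L),
    list(...))
  do.call(simulationConfig, args)
}

smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateCallSets(smallSimConfig())
    cache
  }
})

## default-condition simulation (5 Mb genome, full artifact composition),
## cached; shared by the acceptance suite
accSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCallSets(simulationConfig(seed = 1L))
    cache
  }
})

## ledger subset as a CallSet, keyed join against an observed set
ledgerSubset <- function(sim, tag) {
  led <- sim$ledger[sim$ledger$tag == tag, , drop = FALSE]
  tab <- callTable(sim$observed)
  key <- paste(tab$chrom, tab$pos, tab$sample_id, tab$alt)
  lkey <- paste(led$chrom, led$pos, led$sample_id, led$alt)
  sim$observed[key %in% lkey]
}

## independent oracle: examine every position directly
bruteForceRuns <- function(s, min_len) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- NULL
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[j + 1L] == x[i]) j <- j + 1L
    if (j - i + 1L >= min_len && x[i] %in% c("A", "C", "G", "T"))
      out <- rbind(out, data.frame(start = i, end = j, base = x[i],
                                   stringsAsFactors = FALSE))
    i <- j + 1L
  }
  out
}


## independent oracle: graph components over the all-pairs distance matrix
bruteForceClustered <- function(chrom, pos, window) {
  n <- length(pos)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    chrom[i] == chrom[j] & abs(pos[i] - pos[j]) <= window & i != j)
  in_cluster <- rep(FALSE, n)
  seen <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i
    frontier <- i
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
      seen[frontier] <- TRUE
      comp <- union(comp, nxt)
      frontier <- setdiff(nxt, frontier)
    }
    seen[comp] <- TRUE
    if (length(comp) >= 2L) in_cluster[comp] <- TRUE
  }
  in_cluster
}


## independent oracle: long-time power iteration on a dense uniformized
## transition matrix, no shared code with the package's linear solve
powerIterationPi <- function(Q, tol = 1e-13) {
  dt <- 0.1 / max(abs(diag(Q)))
  P <- diag(16) + dt * Q
  v <- runif(16); v <- v / sum(v)
  repeat {
    v2 <- as.vector(v %*% P)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
}

randomRateMatrix <- function() {
  cls <- mutbleed:::classTable96()
  Q <- matrix(0, 16, 16, dimnames = list(DIN, DIN))
  for (i in seq_len(96)) Q[cls$dinuc[i], cls$resolved[i]] <- rgamma(1, 2)
  diag(Q) <- -rowSums(Q)
  Q
}

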