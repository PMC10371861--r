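#' Simulation configuration
#'
#' Defines the study conditions for the synthetic genome and call sets: a
#' small multi-chromosome genome whose A/T homopolymer runs are enriched in
#' introns and intergenic space relative to CDS, one centromere per
#' chromosome, TEs confined to intergenic space, "true" mutations drawn from
#' a CpG-elevated (and TE-elevated) spectrum, and injected artifact classes
#' (homopolymer bleed errors with run-length-dependent rates, distance
#' decay, strand bias and same-read co-error clusters; mis-mapping clusters;
#' multi-sample recurrent calls).
#'
#' Defaults mirror the composition of a ~4,400-call putative de novo
#' mutation set in which roughly half the calls are homopolymer bleed
#' artifacts, about a quarter sit in tight mis-mapping clusters, and a
#' further tranche recur across implausibly many samples: 400 true
#' mutations, 2,400 bleed errors (rate slope 0.27 per run-length unit,
#' 1 bp distance-decay scale, 80\% single-strand support), 600 mis-mapping
#' pair-clusters (40\% centromeric) and 32 recurrent sites carried by 12
#' samples each, over a 5 Mb genome (5 chromosomes) at 36\% GC with a
#' 5-fold intron/intergenic homopolymer enrichment, a 10-fold CpG>TpG
#' multiplier and a 4-fold TE mutation multiplier.
#'
#' @param n_chromosomes,chrom_length genome shape.
#' @param gc_content genomic GC fraction.
#' @param homopolymer_enrichment fold-enrichment of seeded A/T run density
#'   (runs per bp) in introns+intergenic space relative to CDS.
#' @param homopolymer_base_density seeded runs per CDS bp.
#' @param run_length_range inclusive range of seeded run lengths.
#' @param n_genes,gene_length,n_exons_per_gene gene model; exons are CDS.
#' @param gene_class_weights sampling weights for the four gene classes.
#' @param te_fraction_intergenic fraction of intergenic bp covered by TEs.
#' @param te_length TE block length.
#' @param centromere_fraction fraction of each chromosome, centred.
#' @param n_true_mutations,cpg_rate_multiplier,te_mutation_multiplier,essential_rate_multiplier
#'   true-mutation model: positions uniform except CpG C/G (elevated
#'   \code{cpg_rate_multiplier}-fold toward the transition), TE bp and
#'   essential-gene bp multiplied as configured.
#' @param n_bleed_errors,bleed_length_slope,bleed_decay_scale,bleed_strand_bias,bleed_indel_fraction,bleed_coerror_fraction
#'   bleed-error model (see \code{\link{injectBleedErrors}}).
#' @param n_cluster_errors,cluster_size,cluster_span,cluster_centromere_fraction
#'   mis-mapping cluster model (number of clusters, calls per cluster, bp
#'   span, fraction placed inside centromeres).
#' @param n_recurrent_errors,recurrent_sample_count recurrent-call model.
#' @param n_samples number of samples.
#' @param min_run_length minimum homopolymer run length indexed.
#' @param proximity_window bp window for bleed classification.
#' @param seed master seed; four named substreams (genome, truth, bleed,
#'   cluster) are derived from it.
#' @return a validated list of class \code{mutbleed_config}.
#' @export
simulationConfig <- function(n_chromosomes = 5L,
                             chrom_length = 1e6,
                             gc_content = 0.36,
                             homopolymer_enrichment = 5,
                             homopolymer_base_density = 5e-4,
                             run_length_range = c(4L, 12L),
                             n_genes = 1000L,
                             gene_length = 2000L,
                             n_exons_per_gene = 3L,
                             gene_class_weights = c(essential = 719,
                                                    morphological = 861,
                                                    cellular_biochemical = 297,
                                                    environmental = 522),
                             te_fraction_intergenic = 0.2,
                             te_length = 500L,
                             centromere_fraction = 0.1,
                             n_true_mutations = 400L,
                             cpg_rate_multiplier = 10,
                             te_mutation_multiplier = 4,
                             essential_rate_multiplier = 1,
                             n_bleed_errors = 2400L,
                             bleed_length_slope = 0.27,
                             bleed_decay_scale = 1,
                             bleed_strand_bias = 0.8,
                             bleed_indel_fraction = 0.15,
                             bleed_coerror_fraction = 0.25,
                             n_cluster_errors = 600L,
                             cluster_size = 2L,
                             cluster_span = 10L,
                             cluster_centromere_fraction = 0.4,
                             n_recurrent_errors = 32L,
                             recurrent_sample_count = 12L,
                             n_samples = 100L,
                             min_run_length = 4L,
                             proximity_window = 5L,
                             seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c("gc_content", "te_fraction_intergenic", "centromere_fraction",
             "bleed_strand_bias", "bleed_indel_fraction",
             "bleed_coerror_fraction", "cluster_centromere_fraction")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  counts <- c("n_chromosomes", "chrom_length", "n_genes",
              "n_true_mutations", "n_bleed_errors", "n_cluster_errors",
              "n_recurrent_errors", "recurrent_sample_count", "n_samples")
  for (f in counts) if (cfg[[f]] < 0) stop(f, " must be >= 0")
  if (cfg$bleed_length_slope <= 0) stop("bleed_length_slope must be > 0")
  if (cfg$cluster_span < 2) stop("cluster_span must be >= 2")
  if (cfg$run_length_range[1] < cfg$min_run_length)
    stop("seeded run lengths must be >= min_run_length")
  class(cfg) <- "mutbleed_config"
  cfg
}

#' @export
print.mutbleed_config <- function(x, ...) {
  cat("mutbleed simulation config: ", x$n_chromosomes, " x ",
      format(x$chrom_length, big.mark = ","), " bp genome; ",
      x$n_true_mutations, " true + ", x$n_bleed_errors, " bleed + ",
      x$n_cluster_errors, " x ", x$cluster_size, " cluster + ",
      x$n_recurrent_errors, " x ", x$recurrent_sample_count,
      " recurrent calls; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## cap natural homopolymer runs at maxlen so that every indexed run is a
## seeded one; replacement bases differ from the run base and both
## neighbours, so no pass can create a new long run
breakRuns <- function(x, maxlen) {
  repeat {
    r <- rle(x)
    long <- which(r$lengths > maxlen & r$values %in% BASES)
    if (!length(long)) return(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in long) {
      off <- seq(maxlen + 1L, r$lengths[i], by = maxlen + 1L)
      for (p in starts[i] + off - 1L) {
        cand <- setdiff(BASES, c(r$values[i],
                                 if (p > 1L) x[p - 1L],
                                 if (p < length(x)) x[p + 1L]))
        x[p] <- cand[sample.int(length(cand), 1L)]
      }
    }
  }
}

## sample run-seeding sites inside a set of intervals: interval chosen
## proportional to width, offset uniform, 1 bp flank margin kept, sites
## closer than min_gap discarded
seedSites <- function(gr, n, lens, min_gap = 15L) {
  if (!length(gr) || n == 0L) return(NULL)
  w <- width(gr)
  ok <- w >= max(lens) + 2L
  gr <- gr[ok]; w <- w[ok]
  if (!length(gr)) return(NULL)
  iv <- sample.int(length(gr), n, replace = TRUE, prob = w)
  len <- sample(lens, n, replace = TRUE)
  maxoff <- width(gr)[iv] - len - 1L
  pos <- start(gr)[iv] + 1L + floor(runif(n) * maxoff)
  df <- data.frame(chrom = as.character(seqnames(gr))[iv], pos = pos,
                   len = len, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), ]
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$chrom), function(ix) {
    p <- df$pos[ix]; e <- p + df$len[ix] - 1L
    k <- logical(length(ix)); last_end <- -Inf
    for (j in seq_along(ix)) {
      if (p[j] - last_end > min_gap) { k[j] <- TRUE; last_end <- e[j] }
    }
    ix[k]
  }))
  df[sort(keep), ]
}

#' Generate a synthetic genome and annotation
#'
#' Builds a random genome whose natural homopolymer runs are capped below
#' \code{min_run_length} (so the indexed runs are exactly the seeded ones),
#' then seeds maximal A/T runs of configurable length at a per-bp density
#' \code{homopolymer_enrichment}-fold higher in introns+intergenic space
#' than in CDS, places one centred centromere per chromosome, non-overlapping
#' genes (exons = CDS, introns between them) outside centromeres, and TE
#' blocks confined to intergenic space.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{genome} (\code{DNAStringSet}) and
#'   \code{annotation} (\code{GRanges} incl. synthesized intergenic rows).
#' @export
generateGenome <- function(config) {
  set.seed(substreamSeeds(config$seed)[["genome"]])
  L <- as.integer(config$chrom_length)
  nchr <- config$n_chromosomes
  chroms <- paste0("chr", seq_len(nchr))
  gc <- config$gc_content
  pbase <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  glen <- as.integer(config$gene_length)
  nex <- as.integer(config$n_exons_per_gene)
  exlen <- glen %/% (2L * nex - 1L)
  n_per <- rep(config$n_genes %/% nchr, nchr)
  extra <- config$n_genes %% nchr
  if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L

  seqs <- list()
  feat <- list()
  gidx <- 0L
  for (ci in seq_len(nchr)) {
    chr <- chroms[ci]
    x <- BASES[sample.int(4L, L, replace = TRUE, prob = pbase)]
    x <- breakRuns(x, config$min_run_length - 1L)
    ## centromere: centred fraction of the chromosome
    cw <- round(L * config$centromere_fraction)
    cs <- floor((L - cw) / 2) + 1L
    ce <- cs + cw - 1L
    if (cw > 0)
      feat[[length(feat) + 1L]] <- data.frame(
        chrom = chr, start = cs, end = ce, strand = "*",
        type = "centromere", gene_id = NA, gene_class = NA)
    ## gene slots on the two arms
    slot <- glen + 2000L
    arms <- if (cw > 0) rbind(c(1L, cs - 1L), c(ce + 1L, L)) else
      rbind(c(1L, L))
    nslots <- pmax(0L, (arms[, 2] - arms[, 1] + 1L) %/% slot)
    if (n_per[ci] > sum(nslots))
      stop("requested features exceed available space: ", n_per[ci],
           " genes vs ", sum(nslots), " slots on ", chr)
    pick <- sort(sample.int(sum(nslots), n_per[ci]))
    classes <- sample(names(config$gene_class_weights), n_per[ci],
                      replace = TRUE, prob = config$gene_class_weights)
    for (k in seq_along(pick)) {
      arm <- if (pick[k] <= nslots[1]) 1L else 2L
      within <- pick[k] - if (arm == 2L) nslots[1] else 0L
      base0 <- arms[arm, 1] + (within - 1L) * slot
      gs <- base0 + 1L + floor(runif(1) * (slot - glen - 2L))
      ge <- gs + glen - 1L
      gidx <- gidx + 1L
      gid <- sprintf("gene%04d", gidx)
      str <- sample(c("+", "-"), 1L)
      feat[[length(feat) + 1L]] <- data.frame(
        chrom = chr, start = gs, end = ge, strand = str, type = "gene",
        gene_id = gid, gene_class = classes[k])
      for (e in seq_len(nex)) {
        es <- gs + (e - 1L) * 2L * exlen
        ee <- if (e == nex) ge else es + exlen - 1L
        feat[[length(feat) + 1L]] <- data.frame(
          chrom = chr, start = es, end = ee, strand = str,
          type = c("exon", "CDS"), gene_id = gid, gene_class = classes[k])
        if (e < nex)
          feat[[length(feat) + 1L]] <- data.frame(
            chrom = chr, start = ee + 1L, end = es + 2L * exlen - 1L,
            strand = str, type = "intron", gene_id = gid,
            gene_class = classes[k])
      }
    }
    seqs[[chr]] <- x
  }
  fdf <- do.call(rbind, feat)
  ann <- GRanges(fdf$chrom, IRanges(fdf$start, fdf$end), strand = fdf$strand)
  mcols(ann) <- DataFrame(type = fdf$type, gene_id = fdf$gene_id,
                          gene_class = fdf$gene_class)

  ## TE blocks tile intergenic space; a fraction of blocks become TEs
  lens <- setNames(rep(L, nchr), chroms)
  si <- GenomeInfoDb::Seqinfo(chroms, seqlengths = unname(lens))
  genes <- ann[mcols(ann)$type == "gene"]
  GenomeInfoDb::seqlevels(genes) <- chroms
  GenomeInfoDb::seqinfo(genes) <- si
  inter <- GenomicRanges::gaps(reduce(granges(genes), ignore.strand = TRUE))
  inter <- inter[strand(inter) == "*"]
  if (config$te_fraction_intergenic > 0 && length(inter)) {
    tl <- as.integer(config$te_length)
    blocks <- do.call(rbind, lapply(seq_along(inter), function(i) {
      nb <- width(inter)[i] %/% tl
      if (nb == 0L) return(NULL)
      data.frame(chrom = as.character(seqnames(inter))[i],
                 start = start(inter)[i] + (seq_len(nb) - 1L) * tl,
                 stringsAsFactors = FALSE)
    }))
    nte <- round(config$te_fraction_intergenic * nrow(blocks))
    if (nte > 0) {
      sel <- blocks[sample.int(nrow(blocks), nte), ]
      te <- GRanges(sel$chrom, IRanges(sel$start, width = tl))
      mcols(te) <- DataFrame(type = "TE", gene_id = NA_character_,
                             gene_class = NA_character_)
      ann <- c(ann, te)
    }
  }

  ## seed A/T homopolymer runs: CDS at base density, introns+intergenic at
  ## enrichment-fold that density
  lrange <- seq(config$run_length_range[1], config$run_length_range[2])
  cds <- reduce(granges(ann[mcols(ann)$type == "CDS"]), ignore.strand = TRUE)
  ig <- c(reduce(granges(ann[mcols(ann)$type == "intron"]),
                 ignore.strand = TRUE), inter)
  d0 <- config$homopolymer_base_density
  n_cds <- rpois(1, sum(width(cds)) * d0)
  n_ig <- rpois(1, sum(width(ig)) * d0 * config$homopolymer_enrichment)
  sites <- rbind(seedSites(cds, n_cds, lrange),
                 seedSites(ig, n_ig, lrange))
  if (!is.null(sites) && nrow(sites)) {
    sites$base <- sample(c("A", "T"), nrow(sites), replace = TRUE)
    for (chr in unique(sites$chrom)) {
      x <- seqs[[chr]]
      sub <- sites[sites$chrom == chr, ]
      for (j in seq_len(nrow(sub))) {
        p <- sub$pos[j]; len <- sub$len[j]; b <- sub$base[j]
        x[p:(p + len - 1L)] <- b
        for (fp in c(p - 1L, p + len)) {
          if (fp >= 1L && fp <= L) {
            cand <- setdiff(BASES, c(b, if (fp > 1L) x[fp - 1L],
                                     if (fp < L) x[fp + 1L]))
            x[fp] <- cand[sample.int(length(cand), 1L)]
          }
        }
      }
      seqs[[chr]] <- x
    }
  }
  genome <- DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- chroms
  list(genome = genome,
       annotation = buildAnnotation(ann, genome))
}

## (chrom, pos, sample) collision keys
callKeys <- function(chrom, pos, sample_id) paste(chrom, pos, sample_id)

## hashed key set for collision checks
keyEnv <- function(keys = character(0)) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  for (k in keys) assign(k, TRUE, envir = e)
  e
}
keyTaken <- function(e, keys) vapply(keys, exists, TRUE, envir = e,
                                     inherits = FALSE)
keyAdd <- function(e, keys) for (k in keys) assign(k, TRUE, envir = e)


#' Generate true mutations from a CpG-elevated spectrum
#'
#' Positions are drawn proportional to per-bp weights: 1 everywhere, with C
#' and G bases in CpG context carrying weight (m+2)/3 (m =
#' \code{cpg_rate_multiplier}; conditional on such a site being drawn the
#' transition C>T / G>A is picked with probability m/(m+2), so CpG>TpG
#' events are m-fold elevated over each single non-CpG substitution), TE bp
#' multiplied by \code{te_mutation_multiplier} and essential-gene bp by
#' \code{essential_rate_multiplier}. All calls carry at least two supporting
#' reads on each strand.
#'
#' @param genome \code{DNAStringSet} from \code{\link{generateGenome}}.
#' @param annotation matching annotation \code{GRanges}.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed substream seed; defaults to the config's "truth" substream.
#' @return a \code{CallSet} labelled \code{"truth"}.
#' @export
generateTrueMutations <- function(genome, annotation, config, seed = NULL) {
  if (is.null(seed)) seed <- substreamSeeds(config$seed)[["truth"]]
  set.seed(seed)
  n <- config$n_true_mutations
  if (n == 0L) return(CallSet("truth"))
  gsize <- sum(Biostrings::width(genome))
  if (n > gsize) stop("n_true_mutations exceeds genome size")
  m <- config$cpg_rate_multiplier
  chroms <- names(genome)
  seqchars <- lapply(chroms, chromSeq, genome = genome)
  names(seqchars) <- chroms
  weights <- lapply(chroms, function(chr) {
    s <- seqchars[[chr]]
    L <- nchar(s)
    w <- rep(1, L)
    cg <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (cg[1] != -1L) {
      w[cg] <- (m + 2) / 3
      w[cg + 1L] <- (m + 2) / 3
    }
    for (spec in list(c("TE", config$te_mutation_multiplier),
                      c("gene", config$essential_rate_multiplier))) {
      mult <- as.numeric(spec[2])
      if (mult != 1) {
        gr <- featureIntervals(annotation, spec[1])
        if (spec[1] == "gene")
          gr <- gr[!is.na(mcols(gr)$gene_class) &
                     mcols(gr)$gene_class == "essential"]
        gr <- gr[as.character(seqnames(gr)) == chr]
        if (length(gr)) {
          idx <- unlist(lapply(seq_along(gr), function(i)
            start(gr)[i]:end(gr)[i]))
          w[idx] <- w[idx] * mult
        }
      }
    }
    w
  })
  names(weights) <- chroms
  Wc <- vapply(weights, sum, 0)
  nc <- table(factor(sample(chroms, n, replace = TRUE, prob = Wc),
                     levels = chroms))
  used <- character(0)
  rows <- list()
  p_trans <- m / (m + 2)
  for (chr in chroms) {
    k <- nc[[chr]]
    if (k == 0L) next
    s <- seqchars[[chr]]
    w <- weights[[chr]]
    got <- integer(0)
    while (length(got) < k) {
      cand <- sample.int(nchar(s), 2L * (k - length(got)), replace = TRUE,
                         prob = w)
      cand <- setdiff(unique(cand), got)
      got <- c(got, head(cand, k - length(got)))
    }
    ref <- basesAt(s, got)
    nxt <- basesAt(s, got + 1L)
    prv <- basesAt(s, got - 1L)
    is_cpg <- (ref == "C" & nxt == "G") | (ref == "G" & prv == "C")
    alt <- character(length(got))
    for (j in seq_along(got)) {
      if (ref[j] == "N") { alt[j] <- "A"; next }
      others <- setdiff(BASES, ref[j])
      if (is_cpg[j] && runif(1) < p_trans) {
        alt[j] <- if (ref[j] == "C") "T" else "A"
      } else if (is_cpg[j]) {
        alt[j] <- sample(setdiff(others, if (ref[j] == "C") "T" else "A"), 1L)
      } else {
        alt[j] <- sample(others, 1L)
      }
    }
    smp <- paste0("S", sample.int(config$n_samples, length(got),
                                  replace = TRUE))
    rows[[chr]] <- data.frame(chrom = chr, pos = got, ref = ref, alt = alt,
                              sample_id = smp, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  CallSet("truth", df$chrom, df$pos, df$ref, df$alt, df$sample_id,
          fwd_support = 2L + rpois(nrow(df), 4),
          rev_support = 2L + rpois(nrow(df), 4))
}

#' Inject homopolymer bleed errors
#'
#' Each error picks an A/T run with probability proportional to
#' \code{length * 10^(bleed_length_slope * length)} (so the per-bp error
#' rate at run length L is proportional to \code{10^(slope*L)}, the
#' estimand of the run-length regression), then a position at distance d in
#' [0, proximity_window] from the run boundary with probability proportional
#' to \code{exp(-d / bleed_decay_scale)}; the alternate allele is the run
#' base. A fraction \code{bleed_indel_fraction} are emitted as single-base
#' insertions/deletions of the run base inside the run; a fraction
#' \code{bleed_coerror_fraction} spawn 2-3 co-errors in the same simulated
#' read (same sample, same strand pattern, 2 bp apart); a fraction
#' \code{bleed_strand_bias} have zero supporting reads on one strand.
#'
#' @param genome \code{DNAStringSet}.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed substream seed; defaults to the config's "bleed" substream.
#' @param runs optional precomputed run index from \code{\link{findRuns}}.
#' @param avoid internal: (chrom, pos, sample) keys already taken.
#' @return list with \code{callset} (a \code{CallSet} labelled
#'   \code{"bleed"}) and \code{ledger} (per-call provenance data.frame with
#'   sampled distance, run length and same-read group).
#' @export
injectBleedErrors <- function(genome, config, seed = NULL, runs = NULL,
                              avoid = character()) {
  if (is.null(seed)) seed <- substreamSeeds(config$seed)[["bleed"]]
  set.seed(seed)
  n <- config$n_bleed_errors
  if (n == 0L)
    return(list(callset = CallSet("bleed"),
                ledger = emptyLedger()))
  if (is.null(runs)) runs <- findRuns(genome, config$min_run_length)
  runs <- runs[mcols(runs)$klass == "AT"]
  if (!length(runs)) stop("genome has no A/T runs >= min_run_length")
  win <- config$proximity_window
  rl <- mcols(runs)$length
  wr <- rl * 10^(config$bleed_length_slope * rl)
  pd <- exp(-(0:win) / config$bleed_decay_scale)
  ## per-base character vectors make point lookups O(1)
  seqvecs <- lapply(names(genome), function(chr)
    strsplit(chromSeq(genome, chr), "", fixed = TRUE)[[1]])
  names(seqvecs) <- names(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))

  run_chr <- as.character(seqnames(runs))
  run_s <- start(runs)
  run_e <- end(runs)
  run_b <- mcols(runs)$base
  ## preallocated output buffers
  o_chr <- character(n); o_pos <- integer(n)
  o_ref <- character(n); o_alt <- character(n); o_smp <- character(n)
  o_bias <- logical(n); o_flip <- logical(n)
  o_dist <- integer(n); o_rlen <- integer(n); o_grp <- integer(n)
  used <- keyEnv(avoid)
  grp <- 0L
  run_pool <- sample.int(length(runs), max(64L, 2L * n), replace = TRUE,
                         prob = wr)
  pool_i <- 0L
  next_run <- function() {
    pool_i <<- pool_i + 1L
    if (pool_i > length(run_pool)) {
      run_pool <<- sample.int(length(runs), length(run_pool),
                              replace = TRUE, prob = wr)
      pool_i <<- 1L
    }
    run_pool[pool_i]
  }
  emit <- function(j, chr, p, ref, alt, smp, biased, flip, d, rlen, grp) {
    o_chr[j] <<- chr; o_pos[j] <<- p; o_ref[j] <<- ref; o_alt[j] <<- alt
    o_smp[j] <<- smp; o_bias[j] <<- biased; o_flip[j] <<- flip
    o_dist[j] <<- d; o_rlen[j] <<- rlen; o_grp[j] <<- grp
  }
  total <- 0L
  while (total < n) {
    ri <- next_run()
    chr <- run_chr[ri]
    s <- seqvecs[[chr]]
    rs <- run_s[ri]; re <- run_e[ri]
    base <- run_b[ri]
    smp <- paste0("S", sample.int(config$n_samples, 1L))
    biased <- runif(1) < config$bleed_strand_bias
    flip <- runif(1) < 0.5
    grp <- grp + 1L
    if (runif(1) < config$bleed_indel_fraction) {
      ## single-base indel of the run base, anchored inside the run
      p <- if (rl[ri] >= 2L) rs + sample.int(rl[ri] - 1L, 1L) - 1L else rs
      if (runif(1) < 0.5 && p < re) {
        ref <- paste0(s[p], s[p + 1L]); alt <- base      # deletion
      } else {
        ref <- base; alt <- paste0(base, base)           # insertion
      }
      key <- callKeys(chr, p, smp)
      if (keyTaken(used, key)) next
      keyAdd(used, key)
      total <- total + 1L
      emit(total, chr, p, ref, alt, smp, biased, flip, 0L, rl[ri], grp)
      next
    }
    g <- if (runif(1) < config$bleed_coerror_fraction)
      sample(2:3, 1L) else 1L
    dmax <- win - 2L * (g - 1L)
    d0 <- sample.int(dmax + 1L, 1L, prob = pd[seq_len(dmax + 1L)]) - 1L
    right <- runif(1) < 0.5
    ds <- d0 + 2L * (seq_len(g) - 1L)
    ps <- if (right) re + 1L + ds else rs - 1L - ds
    if (any(ps < 1L | ps > lens[[chr]])) next
    refs <- s[ps]
    if (any(refs == base | refs == "N")) next
    keys <- callKeys(chr, ps, smp)
    if (any(keyTaken(used, keys))) next
    g_take <- min(g, n - total)
    keyAdd(used, keys[seq_len(g_take)])
    for (k in seq_len(g_take))
      emit(total + k, chr, ps[k], refs[k], base, smp, biased, flip,
           ds[k], rl[ri], grp)
    total <- total + g_take
  }
  df <- data.frame(chrom = o_chr, pos = o_pos, ref = o_ref, alt = o_alt,
                   sample_id = o_smp, biased = o_bias, flip = o_flip,
                   tag = "bleed_error", distance = o_dist,
                   run_length = o_rlen, group = o_grp,
                   stringsAsFactors = FALSE)
  nr <- nrow(df)
  fwd <- 2L + rpois(nr, 4); rev <- 2L + rpois(nr, 4)
  dead <- df$biased
  fwd[dead & !df$flip] <- 4L + rpois(sum(dead & !df$flip), 4)
  rev[dead & !df$flip] <- 0L
  rev[dead & df$flip] <- 4L + rpois(sum(dead & df$flip), 4)
  fwd[dead & df$flip] <- 0L
  cs <- CallSet("bleed", df$chrom, df$pos, df$ref, df$alt, df$sample_id,
                fwd, rev)
  led <- df[, c("chrom", "pos", "ref", "alt", "sample_id", "tag",
                "distance", "run_length", "group")]
  list(callset = cs, ledger = led)
}

emptyLedger <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), sample_id = character(), tag = character(),
             distance = integer(), run_length = integer(),
             group = integer(), stringsAsFactors = FALSE)
}

#' Inject mis-mapping clusters and multi-sample recurrent calls
#'
#' Cluster errors are emitted as groups of \code{cluster_size} calls with
#' consecutive spacing of at most \code{cluster_span} bp; a fraction
#' \code{cluster_centromere_fraction} of clusters is placed inside
#' centromeres and the remainder strictly outside. Recurrent errors are
#' emitted as one site carried by \code{recurrent_sample_count} distinct
#' samples. Both artifact classes have strand-balanced read support: they
#' evade per-call strand filters and are caught only by cluster/recurrence
#' screens.
#'
#' @param genome \code{DNAStringSet}.
#' @param annotation annotation \code{GRanges} with centromere rows.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed substream seed; defaults to the config's "cluster" substream.
#' @param avoid internal: (chrom, pos, sample) keys already taken.
#' @return list with \code{callset} (labelled \code{"mismap"}) and
#'   \code{ledger}.
#' @export
injectClusterErrors <- function(genome, annotation, config, seed = NULL,
                                avoid = character()) {
  if (is.null(seed)) seed <- substreamSeeds(config$seed)[["cluster"]]
  set.seed(seed)
  if (config$cluster_span < 2) stop("cluster_span must be >= 2")
  cen <- featureIntervals(annotation, "centromere")
  if (config$n_cluster_errors > 0 && config$cluster_centromere_fraction > 0 &&
      !length(cen))
    stop("annotation has no centromere intervals")
  if (config$n_cluster_errors == 0L && config$n_recurrent_errors == 0L)
    return(list(callset = CallSet("mismap"), ledger = emptyLedger()))
  lens <- setNames(Biostrings::width(genome), names(genome))
  seqchars <- lapply(names(genome), chromSeq, genome = genome)
  names(seqchars) <- names(genome)
  inCen <- function(chr, p) {
    cc <- cen[as.character(seqnames(cen)) == chr]
    any(p >= start(cc) & p <= end(cc))
  }
  used <- keyEnv(avoid)
  rows <- list()
  grp <- 0L
  size <- config$cluster_size
  span <- config$cluster_span
  i <- 0L
  while (i < config$n_cluster_errors) {
    centro <- runif(1) < config$cluster_centromere_fraction
    if (centro) {
      ci <- sample.int(length(cen), 1L, prob = width(cen))
      chr <- as.character(seqnames(cen)[ci])
      p0 <- start(cen)[ci] +
        floor(runif(1) * (width(cen)[ci] - (size - 1L) * span - 1L))
    } else {
      chr <- sample(names(lens), 1L, prob = lens)
      p0 <- 1L + floor(runif(1) * (lens[[chr]] - (size - 1L) * span - 1L))
      if (inCen(chr, p0)) next
    }
    ps <- p0 + c(0L, cumsum(sample.int(span, size - 1L, replace = TRUE)))
    if (any(ps > lens[[chr]])) next
    refs <- basesAt(seqchars[[chr]], ps)
    if (any(refs == "N")) next
    smp <- paste0("S", sample.int(config$n_samples, size, replace = TRUE))
    keys <- callKeys(chr, ps, smp)
    if (any(keyTaken(used, keys))) next
    keyAdd(used, keys)
    grp <- grp + 1L
    i <- i + 1L
    alts <- vapply(refs, function(r) sample(setdiff(BASES, r), 1L), "")
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chr, pos = ps, ref = refs, alt = alts, sample_id = smp,
      tag = "cluster_error", distance = NA_integer_,
      run_length = NA_integer_, group = grp, stringsAsFactors = FALSE)
  }
  j <- 0L
  while (j < config$n_recurrent_errors) {
    chr <- sample(names(lens), 1L, prob = lens)
    p <- sample.int(lens[[chr]], 1L)
    ref <- basesAt(seqchars[[chr]], p)
    if (ref == "N") next
    smp <- paste0("S", sample.int(config$n_samples,
                                  config$recurrent_sample_count))
    keys <- callKeys(chr, p, smp)
    if (any(keyTaken(used, keys))) next
    keyAdd(used, keys)
    grp <- grp + 1L
    j <- j + 1L
    alt <- sample(setdiff(BASES, ref), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chr, pos = p, ref = ref, alt = alt, sample_id = smp,
      tag = "recurrent_error", distance = NA_integer_,
      run_length = NA_integer_, group = grp, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  nr <- nrow(df)
  cs <- CallSet("mismap", df$chrom, df$pos, df$ref, df$alt, df$sample_id,
                2L + rpois(nr, 4), 2L + rpois(nr, 4))
  list(callset = cs,
       ledger = df[, c("chrom", "pos", "ref", "alt", "sample_id", "tag",
                       "distance", "run_length", "group")])
}

#' Run the full synthetic-data generator
#'
#' Generates the genome and annotation, the truth call set, and the three
#' artifact classes, and assembles the observed call set together with a
#' ground-truth ledger tagging every call as \code{true_mutation},
#' \code{bleed_error}, \code{cluster_error} or \code{recurrent_error}.
#' Position collisions between stages are redrawn so the ledger counts equal
#' the configured counts exactly, and a fixed seed makes the whole output
#' reproducible.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{genome}, \code{annotation}, \code{truth}
#'   (CallSet), \code{observed} (CallSet), \code{ledger} (data.frame) and
#'   \code{config}.
#' @export
simulateCallSets <- function(config) {
  seeds <- substreamSeeds(config$seed)
  g <- generateGenome(config)
  truth <- generateTrueMutations(g$genome, g$annotation, config,
                                 seed = seeds[["truth"]])
  ttab <- callTable(truth)
  tled <- if (nrow(ttab)) data.frame(
    chrom = ttab$chrom, pos = ttab$pos, ref = ttab$ref, alt = ttab$alt,
    sample_id = ttab$sample_id, tag = "true_mutation",
    distance = NA_integer_, run_length = NA_integer_, group = NA_integer_,
    stringsAsFactors = FALSE) else emptyLedger()
  avoid <- callKeys(ttab$chrom, ttab$pos, ttab$sample_id)
  bl <- injectBleedErrors(g$genome, config, seed = seeds[["bleed"]],
                          avoid = avoid)
  btab <- callTable(bl$callset)
  avoid <- c(avoid, callKeys(btab$chrom, btab$pos, btab$sample_id))
  cl <- injectClusterErrors(g$genome, g$annotation, config,
                            seed = seeds[["cluster"]], avoid = avoid)
  observed <- concatCallSets("observed", truth, bl$callset, cl$callset)
  ledger <- rbind(tled, bl$ledger, cl$ledger)
  list(genome = g$genome, annotation = g$annotation, truth = truth,
       observed = observed, ledger = ledger, config = config)
}

#' Tag counts of a truth ledger
#' @param ledger a ledger data.frame from \code{\link{simulateCallSets}}.
#' @return named integer vector of per-tag call counts.
#' @export
ledgerCounts <- function(ledger) {
  tab <- table(ledger$tag)
  setNames(as.integer(tab), names(tab))
}
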