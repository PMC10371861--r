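REGION_PRECEDENCE <- c("CDS", "intron", "TE", "centromere", "intergenic")

## disjoint partition of the genome into region classes under a precedence
regionPartition <- function(annotation,
                            precedence = REGION_PRECEDENCE) {
  taken <- NULL
  parts <- list()
  for (cl in precedence) {
    gr <- reduce(granges(featureIntervals(annotation, cl)),
                 ignore.strand = TRUE)
    strand(gr) <- "*"
    if (!is.null(taken) && length(taken))
      gr <- GenomicRanges::setdiff(gr, taken, ignore.strand = TRUE)
    parts[[cl]] <- gr
    taken <- if (is.null(taken)) gr else
      reduce(suppressWarnings(c(taken, gr)), ignore.strand = TRUE)
  }
  parts
}

#' Assign each call one region class
#'
#' Overlapping feature classes are resolved by precedence
#' (CDS > intron > TE > centromere > intergenic by default).
#'
#' @param callset a \code{CallSet}.
#' @param annotation annotation \code{GRanges}.
#' @param precedence class order, highest priority first.
#' @return character vector of region classes, one per call.
#' @export
assignRegion <- function(callset, annotation,
                         precedence = REGION_PRECEDENCE) {
  tab <- callTable(callset)
  if (!nrow(tab)) return(character(0))
  if (!all(tab$chrom %in%
             unique(as.character(seqnames(annotation)))))
    stop("call on unannotated chromosome")
  gr <- GRanges(tab$chrom, IRanges(tab$pos, width = 1L))
  out <- rep(NA_character_, nrow(tab))
  for (cl in precedence) {
    f <- featureIntervals(annotation, cl)
    if (!length(f)) next
    hit <- GenomicRanges::countOverlaps(gr, f, ignore.strand = TRUE) > 0
    out[is.na(out) & hit] <- cl
  }
  out[is.na(out)] <- "intergenic"
  out
}

#' Region-stratified mutation rates
#'
#' Partitions the genome into disjoint region classes by precedence,
#' assigns every call to one class, and reports per-class counts, bp,
#' rates per bp and the 96-class normalized dinucleotide rate vector
#' restricted to each class.
#'
#' @param callset a \code{CallSet}.
#' @param annotation annotation \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @param precedence class order for overlapping features.
#' @param spectra if FALSE, skip the per-region 96-class spectra.
#' @return list with \code{table} (class, bp, n_calls, rate, empty flag),
#'   \code{spectra} (named list of \code{DiSpectrum96}) and
#'   \code{intron_cds_ratio}.
#' @export
regionRates <- function(callset, annotation, genome,
                        precedence = REGION_PRECEDENCE, spectra = TRUE) {
  parts <- regionPartition(annotation, precedence)
  region <- assignRegion(callset, annotation, precedence)
  tab <- data.frame(
    class = precedence,
    bp = vapply(parts, function(p) sum(as.numeric(width(p))), 0),
    n_calls = vapply(precedence, function(cl) sum(region == cl), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$rate <- ifelse(tab$bp > 0, tab$n_calls / tab$bp, NA_real_)
  tab$empty <- tab$n_calls == 0
  specs <- NULL
  if (spectra)
    specs <- lapply(setNames(precedence, precedence), function(cl)
      if (length(parts[[cl]])) diSpectrum(callset, genome,
                                          region = parts[[cl]]) else NULL)
  ratio <- tab$rate[tab$class == "intron"] / tab$rate[tab$class == "CDS"]
  list(table = tab, spectra = specs, intron_cds_ratio = unname(ratio))
}

#' Paired t-test on normalized dinucleotide rate vectors
#'
#' Pairs the 96 per-class normalized rates of two regions; classes where
#' either rate is undefined (zero context) are dropped and the degrees of
#' freedom adjusted. The mean per-class ratio and the ratio of means are
#' both reported (classes with a zero denominator are excluded from the
#' mean ratio and counted).
#'
#' @param rates_a,rates_b numeric(96) normalized rate vectors from the same
#'   spectrum definition (e.g. \code{normalizedRates} of two region
#'   spectra).
#' @return list with \code{t_statistic}, \code{p_value}, \code{df},
#'   \code{mean_ratio}, \code{ratio_of_means}, \code{n_used} and
#'   \code{n_dropped}.
#' @export
pairedRateTest <- function(rates_a, rates_b) {
  ok <- is.finite(rates_a) & is.finite(rates_b)
  if (sum(ok) < 10L) stop("fewer than 10 usable classes")
  if (all(rates_a[ok] == rates_b[ok])) {
    tt <- list(statistic = c(t = 0), p.value = 1,
               parameter = c(df = sum(ok) - 1L))
  } else {
    tt <- t.test(rates_a[ok], rates_b[ok], paired = TRUE)
  }
  denom_ok <- ok & rates_b > 0
  list(t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_ratio = mean(rates_a[denom_ok] / rates_b[denom_ok]),
       ratio_of_means = sum(rates_a[ok]) / sum(rates_b[ok]),
       n_used = sum(ok), n_dropped = sum(!ok),
       n_zero_denominator = sum(ok & !denom_ok))
}

#' Mutation-rate heterogeneity between gene classes
#'
#' Chi-square goodness of fit of per-class call counts against the
#' bp-proportional expectation (rate-homogeneity null), df = classes - 1.
#' Per-gene rates give the class s.e.m. A validity flag is raised when any
#' expected count is below 5.
#'
#' @param callset a \code{CallSet}.
#' @param annotation annotation \code{GRanges} whose gene rows carry
#'   \code{gene_class}, or supply \code{gene_class_map}.
#' @param gene_class_map optional data.frame (gene_id, class); every gene
#'   must map to at most one class.
#' @param feature count calls in \code{"CDS"} or \code{"intron"} space of
#'   each gene.
#' @return list of class \code{geneClassReport}: per-class table (gene
#'   count, bp, calls, rate, sem), \code{chi2}, \code{df}, \code{p_value},
#'   \code{valid}.
#' @export
geneClassRates <- function(callset, annotation, gene_class_map = NULL,
                           feature = c("CDS", "intron")) {
  feature <- match.arg(feature)
  genes <- featureIntervals(annotation, "gene")
  if (is.null(gene_class_map)) {
    gene_class_map <- data.frame(
      gene_id = mcols(genes)$gene_id,
      class = mcols(genes)$gene_class, stringsAsFactors = FALSE)
    gene_class_map <- gene_class_map[!is.na(gene_class_map$class), ]
  }
  if (anyDuplicated(gene_class_map$gene_id))
    stop("a gene maps to two classes")
  feats <- featureIntervals(annotation, feature)
  fmap <- mcols(feats)$gene_id
  cls_of <- setNames(gene_class_map$class, gene_class_map$gene_id)
  classes <- sort(unique(gene_class_map$class))
  cg <- calls(callset)
  hits <- findOverlaps(cg, feats, ignore.strand = TRUE)
  call_gene <- rep(NA_character_, length(cg))
  call_gene[queryHits(hits)] <- fmap[subjectHits(hits)]
  per_class <- lapply(classes, function(cl) {
    gids <- gene_class_map$gene_id[gene_class_map$class == cl]
    fsub <- feats[fmap %in% gids]
    bp_per_gene <- vapply(split(width(fsub), mcols(fsub)$gene_id), sum, 0)
    calls_per_gene <- table(factor(call_gene[call_gene %in% gids],
                                   levels = names(bp_per_gene)))
    gr_rates <- as.numeric(calls_per_gene) / bp_per_gene
    data.frame(class = cl, n_genes = length(gids),
               bp = sum(bp_per_gene),
               n_calls = sum(as.numeric(calls_per_gene)),
               rate = sum(calls_per_gene) / sum(bp_per_gene),
               sem = stats::sd(gr_rates) / sqrt(length(gr_rates)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_class)
  expected <- sum(tab$n_calls) * tab$bp / sum(tab$bp)
  ct <- suppressWarnings(chisq.test(tab$n_calls, p = tab$bp / sum(tab$bp)))
  structure(list(table = tab, chi2 = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 valid = all(expected >= 5), feature = feature),
            class = "geneClassReport")
}

#' @export
print.geneClassReport <- function(x, ...) {
  cat("Gene-class ", x$feature, " rate heterogeneity: chi2 = ",
      format(x$chi2, digits = 4), ", df = ", x$df, ", p = ",
      format(x$p_value, digits = 3),
      if (!x$valid) " (small expected counts: not valid)", "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

## strand-aware anchors of genes
geneAnchors <- function(annotation, anchor) {
  genes <- featureIntervals(annotation, "gene")
  if (!length(genes)) stop("no genes in annotation")
  minus <- as.character(strand(genes)) == "-"
  pos <- ifelse(minus, end(genes), start(genes))
  if (anchor == "TTS") pos <- ifelse(minus, start(genes), end(genes))
  data.frame(chrom = as.character(seqnames(genes)), pos = pos,
             minus = minus, stringsAsFactors = FALSE)
}

## events -> data.frame(chrom, pos)
eventPositions <- function(positions) {
  if (is(positions, "CallSet")) {
    tab <- callTable(positions)
    return(data.frame(chrom = tab$chrom, pos = tab$pos,
                      stringsAsFactors = FALSE))
  }
  if (is(positions, "GRanges"))
    return(data.frame(chrom = as.character(seqnames(positions)),
                      pos = start(positions), stringsAsFactors = FALSE))
  stopifnot(is.data.frame(positions))
  positions[, c("chrom", "pos")]
}

#' Metagene profile of event density around TSS and TTS
#'
#' For every gene, events within \code{window_bp} of the strand-oriented
#' anchor accumulate into bins of \code{bin_bp} (upstream offsets negative;
#' minus-strand genes are flipped). Density is events per bp per anchored
#' gene, so summing density x bin width x gene count recovers the in-window
#' event total.
#'
#' @param positions events: a \code{CallSet}, \code{GRanges} or data.frame
#'   with \code{chrom}, \code{pos}.
#' @param annotation annotation \code{GRanges} with stranded genes.
#' @param window_bp half-window around the anchor.
#' @param bin_bp bin width; must not exceed \code{window_bp}.
#' @return list with \code{tss} and \code{tts} profiles (data.frame:
#'   offset bin start/mid, count, density) and \code{n_anchors}.
#' @export
metageneProfile <- function(positions, annotation, window_bp = 3000L,
                            bin_bp = 100L) {
  if (window_bp < bin_bp) stop("window smaller than bin")
  ev <- eventPositions(positions)
  prof <- function(anchor) {
    an <- geneAnchors(annotation, anchor)
    nb <- 2L * (window_bp %/% bin_bp)
    counts <- numeric(nb)
    ev_gr <- GRanges(ev$chrom, IRanges(ev$pos, width = 1L))
    an_gr <- GRanges(an$chrom, IRanges(pmax(1L, an$pos - window_bp),
                                       an$pos + window_bp - 1L))
    hits <- findOverlaps(ev_gr, an_gr, ignore.strand = TRUE)
    if (length(hits)) {
      off <- ev$pos[queryHits(hits)] - an$pos[subjectHits(hits)]
      off <- ifelse(an$minus[subjectHits(hits)], -off, off)
      keep <- off >= -window_bp & off <= window_bp - 1L
      bin <- (off[keep] + window_bp) %/% bin_bp + 1L
      t <- table(factor(bin, levels = seq_len(nb)))
      counts <- as.numeric(t)
    }
    starts <- seq(-window_bp, window_bp - bin_bp, by = bin_bp)
    data.frame(offset_start = starts, offset_mid = starts + bin_bp / 2,
               count = counts,
               density = counts / (bin_bp * nrow(an)))
  }
  list(tss = prof("TSS"), tts = prof("TTS"),
       n_anchors = nrow(geneAnchors(annotation, "TSS")),
       window_bp = window_bp, bin_bp = bin_bp)
}

#' Simulate homopolymer-associated error positions
#'
#' Samples \code{n_errors} positions using the bleed placement model: a
#' run is chosen with probability proportional to
#' \code{length * 10^(length_slope * length)} (per-bp rate proportional to
#' \code{10^(slope*length)}; slope 0 gives placement proportional to run
#' bp), then a position within \code{proximity_window} of the run boundary
#' with exponentially decaying probability. The output feeds
#' \code{\link{metageneProfile}} directly.
#'
#' @param genome \code{DNAStringSet}.
#' @param runs run index from \code{\link{findRuns}}; A/T runs are used.
#' @param n_errors number of error positions.
#' @param length_slope per-unit-run-length log10 rate increment (>= 0).
#' @param seed random seed.
#' @param decay_scale bp scale of the distance decay.
#' @param proximity_window maximum distance from the run boundary.
#' @return data.frame with \code{chrom}, \code{pos}.
#' @export
simulateHomopolymerErrors <- function(genome, runs, n_errors, length_slope,
                                      seed, decay_scale = 1,
                                      proximity_window = 5L) {
  set.seed(seed)
  at <- runs[mcols(runs)$klass == "AT"]
  if (!length(at)) stop("no A/T runs")
  rl <- mcols(at)$length
  wr <- rl * 10^(length_slope * rl)
  pd <- exp(-(0:proximity_window) / decay_scale)
  lens <- setNames(Biostrings::width(genome), names(genome))
  seqchars <- lapply(names(genome), chromSeq, genome = genome)
  names(seqchars) <- names(genome)
  got <- list()
  n_got <- 0L
  while (n_got < n_errors) {
    k <- max(1024L, ceiling(1.3 * (n_errors - n_got)))
    ri <- sample.int(length(at), k, replace = TRUE, prob = wr)
    d <- sample.int(proximity_window + 1L, k, replace = TRUE,
                    prob = pd) - 1L
    right <- runif(k) < 0.5
    p <- ifelse(right, end(at)[ri] + 1L + d, start(at)[ri] - 1L - d)
    chr <- as.character(seqnames(at))[ri]
    ok <- p >= 1L & p <= lens[chr]
    if (any(ok)) {
      base_ok <- logical(sum(ok))
      pp <- p[ok]; cc <- chr[ok]; bb <- mcols(at)$base[ri][ok]
      for (ch in unique(cc)) {
        ix <- cc == ch
        base_ok[ix] <- basesAt(seqchars[[ch]], pp[ix]) != bb[ix]
      }
      pp <- pp[base_ok]; cc <- cc[base_ok]
      take <- min(length(pp), n_errors - n_got)
      if (take > 0) {
        got[[length(got) + 1L]] <- data.frame(
          chrom = cc[seq_len(take)], pos = pp[seq_len(take)],
          stringsAsFactors = FALSE)
        n_got <- n_got + take
      }
    }
  }
  do.call(rbind, got)
}

#' Metagene profile of TE density around TSS and TTS
#'
#' Per-bin TE bp per bp per anchored gene, with the same orientation rules
#' as \code{\link{metageneProfile}}.
#'
#' @param annotation annotation \code{GRanges} with gene and TE rows.
#' @param window_bp,bin_bp window and bin sizes.
#' @return list with \code{tss}, \code{tts} profiles and \code{n_anchors}.
#' @export
teMetagene <- function(annotation, window_bp = 3000L, bin_bp = 100L) {
  if (window_bp < bin_bp) stop("window smaller than bin")
  te <- reduce(granges(featureIntervals(annotation, "TE")),
               ignore.strand = TRUE)
  if (!length(te)) stop("no TEs in annotation")
  prof <- function(anchor) {
    an <- geneAnchors(annotation, anchor)
    nb <- 2L * (window_bp %/% bin_bp)
    starts <- seq(-window_bp, window_bp - bin_bp, by = bin_bp)
    ## oriented bins for each gene x bin
    gi <- rep(seq_len(nrow(an)), each = nb)
    bs <- rep(starts, nrow(an))
    lo <- ifelse(an$minus[gi], an$pos[gi] - (bs + bin_bp) + 1L,
                 an$pos[gi] + bs)
    bins <- GRanges(an$chrom[gi], IRanges(pmax(1L, lo),
                                          pmax(1L, lo) + bin_bp - 1L))
    hits <- findOverlaps(bins, te, ignore.strand = TRUE)
    ov <- GenomicRanges::pintersect(bins[queryHits(hits)],
                                    te[subjectHits(hits)])
    bp <- numeric(length(bins))
    if (length(hits)) {
      agg <- tapply(width(ov), queryHits(hits), sum)
      bp[as.integer(names(agg))] <- agg
    }
    bybin <- rowsum(bp, rep(seq_len(nb), nrow(an)))
    data.frame(offset_start = starts, offset_mid = starts + bin_bp / 2,
               te_bp = as.numeric(bybin),
               density = as.numeric(bybin) / (bin_bp * nrow(an)))
  }
  list(tss = prof("TSS"), tts = prof("TTS"),
       n_anchors = nrow(geneAnchors(annotation, "TSS")),
       window_bp = window_bp, bin_bp = bin_bp)
}
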