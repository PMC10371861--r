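## distance from a position to a run [s, e] (1-based closed):
## 0 inside the run or touching its boundary base, otherwise the number of
## bases strictly between position and run
runDistance <- function(pos, s, e) {
  ifelse(pos >= s & pos <= e, 0L,
         ifelse(pos < s, pmax(0L, s - pos - 1L), pmax(0L, pos - e - 1L)))
}

## the allele a bleed event would copy: alt base for SNVs, the
## inserted/deleted base for single-base indels, NA otherwise
bleedAllele <- function(ref, alt, var_class) {
  out <- rep(NA_character_, length(ref))
  snv <- var_class == "SNV"
  out[snv] <- alt[snv]
  ins <- var_class == "insertion" & nchar(alt) == 2L & nchar(ref) == 1L
  out[ins] <- substr(alt[ins], 2L, 2L)
  del <- var_class == "deletion" & nchar(ref) == 2L & nchar(alt) == 1L
  out[del] <- substr(ref[del], 2L, 2L)
  out
}

#' Classify calls as homopolymer bleed artifacts
#'
#' A call is bleed-type iff a homopolymer run of the requested class lies
#' within \code{proximity_window} bp of it (distance measured from the run
#' boundary) and the call's bleed allele equals the run base: the alternate
#' allele for an SNV, the inserted/deleted base for a single-base indel.
#' Each bleed call records the nearest qualifying run (ties broken toward
#' the lower run coordinate) and an adjacency category: \code{within} (call
#' position inside the run), \code{adjacent} (distance 0 but outside) or
#' \code{nearby} (distance 1..window).
#'
#' @param callset a \code{CallSet}.
#' @param runs run index from \code{\link{findRuns}}.
#' @param proximity_window bp window (default 5).
#' @param klass which run class to test against: \code{"AT"} (default) or
#'   \code{"GC"}.
#' @param annotation optional annotation \code{GRanges}; adds per-region
#'   bleed fractions to the summary.
#' @param require_allele_match if FALSE, proximity alone (any nearby run of
#'   the class) suffices.
#' @return list with \code{bleed} (data.frame of bleed calls: position,
#'   alleles, sample, nearest run, distance, adjacency) and \code{summary}
#'   (counts and fractions overall, for SNVs only, per region class when an
#'   annotation is supplied, and the corresponding fraction near GC runs).
#' @export
classifyBleed <- function(callset, runs, proximity_window = 5L,
                          klass = "AT", annotation = NULL,
                          require_allele_match = TRUE) {
  tab <- callTable(callset)
  n <- nrow(tab)
  sel <- runs[mcols(runs)$klass == klass]
  pick <- classifyBleed1(tab, sel, proximity_window, require_allele_match)
  other <- runs[mcols(runs)$klass == setdiff(c("AT", "GC"), klass)]
  pick_other <- classifyBleed1(tab, other, proximity_window,
                               require_allele_match)
  is_bleed <- !is.na(pick$run_idx)
  bleed <- cbind(tab[is_bleed, , drop = FALSE],
                 pick[is_bleed, c("run_start", "run_end", "run_base",
                                  "run_length", "distance", "adjacency")])
  bleed$call_idx <- which(is_bleed)
  bleed$in_bleed_cluster <- rep(NA, nrow(bleed))
  snv <- tab$var_class == "SNV"
  summary <- list(
    n_calls = n,
    n_bleed = sum(is_bleed),
    fraction = if (n) sum(is_bleed) / n else NA_real_,
    n_bleed_snv = sum(is_bleed & snv),
    fraction_snv = if (any(snv)) sum(is_bleed & snv) / sum(snv) else NA_real_,
    fraction_other_klass =
      if (n) sum(!is.na(pick_other$run_idx)) / n else NA_real_,
    window = proximity_window, klass = klass)
  if (!is.null(annotation) && n) {
    region <- assignRegion(callset, annotation)
    summary$per_region <- vapply(split(is_bleed, region), mean, 0)
  }
  list(bleed = bleed, summary = summary)
}

## nearest qualifying run per call (data.frame result, NA run_idx = none)
classifyBleed1 <- function(tab, sel, window, require_allele_match) {
  n <- nrow(tab)
  out <- data.frame(run_idx = rep(NA_integer_, n), run_start = NA_integer_,
                    run_end = NA_integer_, run_base = NA_character_,
                    run_length = NA_integer_, distance = NA_integer_,
                    adjacency = NA_character_, stringsAsFactors = FALSE)
  if (!n || !length(sel)) return(out)
  allele <- bleedAllele(tab$ref, tab$alt, tab$var_class)
  cand <- which(!is.na(allele))
  if (require_allele_match)
    cand <- cand[allele[cand] %in% unique(mcols(sel)$base)]
  if (!length(cand)) return(out)
  qgr <- GRanges(tab$chrom[cand],
                 IRanges(pmax(1L, tab$pos[cand] - window - 1L),
                         tab$pos[cand] + window + 1L))
  hits <- findOverlaps(qgr, sel)
  if (!length(hits)) return(out)
  qi <- cand[queryHits(hits)]
  si <- subjectHits(hits)
  d <- runDistance(tab$pos[qi], start(sel)[si], end(sel)[si])
  ok <- d <= window
  if (require_allele_match) ok <- ok & mcols(sel)$base[si] == allele[qi]
  qi <- qi[ok]; si <- si[ok]; d <- d[ok]
  if (!length(qi)) return(out)
  ## nearest run per call, ties toward lower run start
  ord <- order(qi, d, start(sel)[si])
  qi <- qi[ord]; si <- si[ord]; d <- d[ord]
  first <- !duplicated(qi)
  qi <- qi[first]; si <- si[first]; d <- d[first]
  out$run_idx[qi] <- si
  out$run_start[qi] <- start(sel)[si]
  out$run_end[qi] <- end(sel)[si]
  out$run_base[qi] <- mcols(sel)$base[si]
  out$run_length[qi] <- mcols(sel)$length[si]
  out$distance[qi] <- d
  within <- tab$pos[qi] >= start(sel)[si] & tab$pos[qi] <= end(sel)[si]
  out$adjacency[qi] <- ifelse(within, "within",
                              ifelse(d == 0L, "adjacent", "nearby"))
  out
}

#' Resolve same-read clusters among nearby bleed calls
#'
#' Bleed calls that are not within/adjacent to their run are flagged as
#' clustered when two or more of them share the same run and alt allele
#' and lie within \code{proximity_window} bp of each other (the signature
#' of several errors produced by one mis-read stretch of a single read).
#'
#' @param bleed_result output of \code{\link{classifyBleed}}.
#' @param proximity_window bp window.
#' @return the input list with \code{in_bleed_cluster} filled in and a
#'   \code{counts} element: calls within/adjacent, remaining nearby calls,
#'   and how many of those cluster.
#' @export
bleedClusters <- function(bleed_result, proximity_window = 5L) {
  b <- bleed_result$bleed
  b$in_bleed_cluster <- FALSE
  nearby <- which(b$adjacency == "nearby")
  if (length(nearby)) {
    key <- paste(b$chrom[nearby], b$run_start[nearby], b$run_end[nearby],
                 b$alt[nearby], sep = "\r")
    for (ix in split(nearby, key)) {
      if (length(ix) < 2L) next
      ix <- ix[order(b$pos[ix])]
      gap <- diff(b$pos[ix]) <= proximity_window
      cid <- cumsum(c(TRUE, !gap))
      for (cl in split(ix, cid))
        if (length(cl) >= 2L) b$in_bleed_cluster[cl] <- TRUE
    }
  }
  bleed_result$bleed <- b
  bleed_result$counts <- c(
    within_adjacent = sum(b$adjacency %in% c("within", "adjacent")),
    nearby = sum(b$adjacency == "nearby"),
    nearby_clustered = sum(b$in_bleed_cluster),
    pct_within_adjacent = pct1(
      sum(b$adjacency %in% c("within", "adjacent")), nrow(b)))
  bleed_result
}

#' Regression of bleed-call rate on homopolymer run length
#'
#' Per run-length bin, rate = (bleed calls attributed to runs of that
#' length) / (total bp of runs of that length); ordinary least squares of
#' log10(rate) on run length at the bin level. Bins with zero calls are
#' dropped and reported.
#'
#' @param callset a \code{CallSet}.
#' @param runs run index from \code{\link{findRuns}} (A/T runs are used).
#' @param length_bins run lengths to use as bins; default every distinct
#'   A/T run length present.
#' @param proximity_window bp window for attributing calls to runs.
#' @param annotation,region_class optionally restrict calls to one region
#'   class (e.g. \code{"intron"}) before fitting.
#' @return list with the per-bin table and \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{p_value}, \code{df} (bins used minus 2) and
#'   \code{n_dropped}.
#' @export
runLengthRegression <- function(callset, runs, length_bins = NULL,
                                proximity_window = 5L, annotation = NULL,
                                region_class = NULL) {
  at <- runs[mcols(runs)$klass == "AT"]
  if (!is.null(region_class)) {
    if (is.null(annotation))
      stop("region_class requires an annotation")
    region <- assignRegion(callset, annotation)
    callset <- callset[region == region_class]
  }
  cls <- classifyBleed(callset, at, proximity_window)
  if (is.null(length_bins))
    length_bins <- sort(unique(mcols(at)$length))
  bp <- vapply(length_bins, function(L)
    sum(width(at)[mcols(at)$length == L]), 0)
  calls <- vapply(length_bins, function(L)
    sum(cls$bleed$run_length == L), 0)
  usable <- bp > 0
  tab <- data.frame(length = length_bins, run_bp = bp, n_calls = calls,
                    rate = ifelse(bp > 0, calls / bp, NA_real_))
  use <- usable & calls > 0
  n_dropped <- sum(usable & calls == 0)
  if (sum(use) < 3L) stop("fewer than 3 usable run-length bins")
  fit <- lm(log10(rate) ~ length, data = tab[use, ])
  sm <- summary(fit)
  list(table = tab,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       df = sum(use) - 2L,
       n_dropped = n_dropped)
}

#' Distance decay of bleed calls from the run boundary
#'
#' Tabulates bleed calls per integer distance from the run boundary
#' (0 = within/adjacent) and reports a Spearman rank correlation of rate
#' against distance as a monotonic-decay check.
#'
#' @param bleed_result output of \code{\link{classifyBleed}}, or the
#'   \code{bleed} data.frame itself.
#' @param proximity_window bp window.
#' @return list with the per-distance table (count, rate = share of bleed
#'   calls) and the Spearman rho and p-value.
#' @export
distanceDecay <- function(bleed_result, proximity_window = 5L) {
  b <- if (is.data.frame(bleed_result)) bleed_result else bleed_result$bleed
  d <- 0:proximity_window
  count <- vapply(d, function(k) sum(b$distance == k), 0)
  tab <- data.frame(distance = d, count = count,
                    rate = if (sum(count)) count / sum(count) else
                      rep(NA_real_, length(d)))
  ct <- tryCatch(
    suppressWarnings(cor.test(tab$count, tab$distance,
                              method = "spearman")),
    error = function(e) list(estimate = NA_real_, p.value = NA_real_))
  list(table = tab, spearman_rho = unname(ct$estimate),
       spearman_p = ct$p.value)
}
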