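#' Find clustered calls
#'
#' Maximal chains of calls on the same chromosome in which consecutive
#' calls are at most \code{window} bp apart; chains of two or more calls
#' are clusters. Clustering is across samples by default (mis-mapping
#' affects a locus, not a sample).
#'
#' @param callset a \code{CallSet}.
#' @param window bp window (default 10).
#' @param per_sample if TRUE, chains are built within each sample.
#' @return list with \code{clusters} (data.frame: id, chrom, start, end,
#'   size), \code{membership} (per-call cluster id, NA if unclustered),
#'   \code{pct_clustered} and the window used.
#' @export
findClusters <- function(callset, window = 10L, per_sample = FALSE) {
  if (window < 1L) stop("window must be >= 1")
  tab <- callTable(callset)
  n <- nrow(tab)
  membership <- rep(NA_integer_, n)
  if (n) {
    grp <- if (per_sample) paste(tab$chrom, tab$sample_id, sep = "\r")
    else tab$chrom
    next_id <- 0L
    for (ix in split(seq_len(n), grp)) {
      ix <- ix[order(tab$pos[ix])]
      if (length(ix) < 2L) next
      chain <- cumsum(c(TRUE, diff(tab$pos[ix]) > window))
      for (cl in split(ix, chain)) {
        if (length(cl) >= 2L) {
          next_id <- next_id + 1L
          membership[cl] <- next_id
        }
      }
    }
  }
  ids <- sort(unique(membership[!is.na(membership)]))
  clusters <- do.call(rbind, lapply(ids, function(id) {
    ix <- which(membership == id)
    data.frame(id = id, chrom = tab$chrom[ix[1]],
               start = min(tab$pos[ix]), end = max(tab$pos[ix]),
               size = length(ix), stringsAsFactors = FALSE)
  }))
  if (is.null(clusters))
    clusters <- data.frame(id = integer(), chrom = character(),
                           start = integer(), end = integer(),
                           size = integer(), stringsAsFactors = FALSE)
  list(clusters = clusters, membership = membership,
       pct_clustered = pct1(sum(!is.na(membership)), n),
       window = window, per_sample = per_sample)
}

#' Find multi-sample recurrent calls
#'
#' Flags sites whose identical (chrom, pos, ref, alt) call occurs in
#' strictly more than \code{sample_threshold} distinct samples.
#'
#' @param callset a \code{CallSet}.
#' @param sample_threshold recurrence cutoff (default 10; a site in 11
#'   samples is flagged, one in 10 is not).
#' @return list with \code{sites} (data.frame of flagged sites and their
#'   sample counts), \code{flagged} (per-call logical) and
#'   \code{pct_recurrent}.
#' @export
findRecurrent <- function(callset, sample_threshold = 10L) {
  tab <- callTable(callset)
  n <- nrow(tab)
  if (!n)
    return(list(sites = data.frame(), flagged = logical(0),
                pct_recurrent = NA_real_,
                sample_threshold = sample_threshold))
  site <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = "\r")
  nshare <- vapply(split(tab$sample_id, site),
                   function(s) length(unique(s)), 0L)
  flagged_sites <- names(nshare)[nshare > sample_threshold]
  flagged <- site %in% flagged_sites
  parts <- strsplit(flagged_sites, "\r", fixed = TRUE)
  sites <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    n_samples = unname(nshare[flagged_sites]),
    stringsAsFactors = FALSE)
  list(sites = sites, flagged = flagged,
       pct_recurrent = pct1(sum(flagged), n),
       sample_threshold = sample_threshold)
}

#' Fraction of calls inside a feature class
#'
#' @param callset a \code{CallSet}.
#' @param annotation annotation \code{GRanges}.
#' @param feature_type feature class, e.g. \code{"centromere"}.
#' @return percent of calls (one decimal) whose position lies inside any
#'   interval of the class.
#' @export
regionFraction <- function(callset, annotation, feature_type) {
  gr <- featureIntervals(annotation, feature_type)
  if (!length(gr)) stop("no '", feature_type, "' intervals in annotation")
  cg <- calls(callset)
  if (!length(cg)) return(NA_real_)
  hit <- GenomicRanges::countOverlaps(cg, gr, ignore.strand = TRUE) > 0
  pct1(sum(hit), length(cg))
}

#' Combined mis-mapping fingerprint report
#'
#' Runs cluster detection, recurrence detection and centromere-fraction
#' measurement on one call set; reports both raw percentages and the
#' cluster percentage after excluding calls at recurrent sites (the
#' mutually-exclusive tally).
#'
#' @param callset a \code{CallSet}.
#' @param annotation optional annotation with centromere intervals.
#' @param window cluster window in bp.
#' @param sample_threshold recurrence cutoff.
#' @param per_sample passed to \code{\link{findClusters}}.
#' @return list of class \code{clusterReport}.
#' @export
clusterReport <- function(callset, annotation = NULL, window = 10L,
                          sample_threshold = 10L, per_sample = FALSE) {
  cl <- findClusters(callset, window, per_sample)
  rec <- findRecurrent(callset, sample_threshold)
  excl <- if (length(rec$flagged) && any(rec$flagged))
    findClusters(callset[!rec$flagged], window, per_sample)$pct_clustered
  else cl$pct_clustered
  pc <- if (!is.null(annotation) &&
            length(featureIntervals(annotation, "centromere")))
    regionFraction(callset, annotation, "centromere") else NA_real_
  structure(list(clusters = cl$clusters, membership = cl$membership,
                 pct_clustered = cl$pct_clustered,
                 pct_clustered_excl_recurrent = excl,
                 pct_recurrent = rec$pct_recurrent,
                 recurrent_sites = rec$sites,
                 pct_centromeric = pc,
                 window = window, sample_threshold = sample_threshold),
            class = "clusterReport")
}

#' @export
print.clusterReport <- function(x, ...) {
  cat("Cluster report: ", x$pct_clustered, "% clustered (window ",
      x$window, " bp), ", x$pct_recurrent, "% recurrent (> ",
      x$sample_threshold, " samples), ",
      if (is.na(x$pct_centromeric)) "centromere fraction n/a" else
        paste0(x$pct_centromeric, "% centromeric"), "\n", sep = "")
  invisible(x)
}
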