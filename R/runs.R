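#' Find maximal homopolymer runs
#'
#' Scans every chromosome for maximal single-base runs of length at least
#' \code{min_run_length}. Each run is labelled \code{AT} or \code{GC} by its
#' base; runs of N are ignored.
#'
#' @param genome a \code{DNAStringSet}.
#' @param min_run_length minimum run length in bp (>= 2).
#' @return a \code{GRanges} sorted by position with metadata columns
#'   \code{base}, \code{length} and \code{klass} (\code{"AT"}/\code{"GC"}).
#' @export
findRuns <- function(genome, min_run_length = 4L) {
  if (min_run_length < 2L) stop("min_run_length must be >= 2")
  out <- lapply(names(genome), function(chr) {
    s <- chromSeq(genome, chr)
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_run_length & r$values %in% BASES
    if (!any(keep)) return(NULL)
    data.frame(chrom = chr, start = ends[keep] - r$lengths[keep] + 1L,
               end = ends[keep], base = r$values[keep],
               length = r$lengths[keep], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(df)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(base = character(0), length = integer(0),
                           klass = character(0))
    return(gr)
  }
  res <- GRanges(factor(df$chrom, levels = names(genome)),
                 IRanges(df$start, df$end))
  mcols(res) <- DataFrame(base = df$base, length = df$length,
                          klass = ifelse(df$base %in% c("A", "T"),
                                         "AT", "GC"))
  BiocGenerics::sort(res, ignore.strand = TRUE)
}
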