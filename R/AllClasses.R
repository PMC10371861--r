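#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand strand<- mcols mcols<- findOverlaps reduce
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors DataFrame queryHits subjectHits
#' @importFrom BiocGenerics sort
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom stats lm coef pt pchisq chisq.test t.test cor cor.test rpois runif setNames
#' @importFrom utils head tail
NULL

DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          function(a, b) paste0(a, b)))

#' CallSet: a labelled collection of putative mutation calls
#'
#' A \code{CallSet} wraps a \code{GRanges} of single-position anchors with
#' metadata columns \code{ref}, \code{alt}, \code{sample_id},
#' \code{fwd_support}, \code{rev_support} (integer, \code{NA} = unknown) and
#' \code{var_class} (\code{"SNV"}, \code{"insertion"} or \code{"deletion"}).
#' Indels are anchored at the base preceding the event, following VCF
#' convention. Calls are kept sorted by (chrom, pos) and exact duplicates on
#' (chrom, pos, ref, alt, sample) are collapsed at construction.
#'
#' @slot label provenance label, e.g. \code{"truth"} or \code{"observed"}.
#' @slot calls \code{GRanges} with the metadata columns described above.
#' @aliases CallSet
#' @exportClass CallSet
setClass("CallSet", slots = c(label = "character", calls = "GRanges"))

.callset_cols <- c("ref", "alt", "sample_id", "fwd_support", "rev_support",
                   "var_class")

setValidity("CallSet", function(object) {
  gr <- object@calls
  miss <- setdiff(.callset_cols, colnames(mcols(gr)))
  if (length(miss))
    return(paste("missing call columns:", paste(miss, collapse = ", ")))
  m <- mcols(gr)
  if (length(gr)) {
    if (any(m$ref == m$alt)) return("ref equals alt for some calls")
    snv <- m$var_class == "SNV"
    if (any(snv & (nchar(m$ref) != 1L | nchar(m$alt) != 1L)))
      return("SNV calls must have single-base ref and alt")
    if (any(!is.na(m$fwd_support) & m$fwd_support < 0) ||
        any(!is.na(m$rev_support) & m$rev_support < 0))
      return("read supports must be >= 0 (NA = unknown)")
    if (!all(m$var_class %in% c("SNV", "insertion", "deletion")))
      return("var_class outside {SNV, insertion, deletion}")
  }
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' Construct a CallSet
#'
#' @param label provenance label.
#' @param chrom,pos,ref,alt,sample_id call fields (vectors, recycled by
#'   \code{GRanges} rules); \code{pos} is the 1-based reference position of
#'   the SNV base or of the base preceding an indel.
#' @param fwd_support,rev_support per-strand supporting-read counts
#'   (\code{NA} for unknown).
#' @param var_class one of \code{"SNV"}, \code{"insertion"},
#'   \code{"deletion"}; inferred from allele lengths when \code{NULL}.
#' @return a \code{CallSet}.
#' @export
CallSet <- function(label, chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    sample_id = character(),
                    fwd_support = NA_integer_, rev_support = NA_integer_,
                    var_class = NULL) {
  n <- length(pos)
  if (is.null(var_class)) {
    var_class <- rep("SNV", n)
    var_class[nchar(alt) > nchar(ref)] <- "insertion"
    var_class[nchar(alt) < nchar(ref)] <- "deletion"
  }
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  mcols(gr) <- DataFrame(
    ref = as.character(ref), alt = as.character(alt),
    sample_id = as.character(sample_id),
    fwd_support = as.integer(rep_len(fwd_support, n)),
    rev_support = as.integer(rep_len(rev_support, n)),
    var_class = var_class)
  newCallSet(label, gr)
}

## shared post-processing: sort, collapse duplicates, validate
newCallSet <- function(label, gr) {
  if (length(gr)) {
    gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
    key <- paste(as.character(seqnames(gr)), start(gr), mcols(gr)$ref,
                 mcols(gr)$alt, mcols(gr)$sample_id, sep = "\r")
    if (anyDuplicated(key)) {
      warning(sum(duplicated(key)),
              " duplicate call(s) collapsed in call set '", label, "'")
      gr <- gr[!duplicated(key)]
    }
  }
  new("CallSet", label = label, calls = gr)
}

#' @describeIn CallSet number of calls
#' @param x,object a \code{CallSet}.
#' @export
nCalls <- function(x) length(x@calls)

#' @describeIn CallSet provenance label
#' @export
callLabel <- function(x) x@label

#' @describeIn CallSet the underlying \code{GRanges} of calls
#' @export
calls <- function(x) x@calls

#' @describeIn CallSet calls as a data.frame (chrom, pos, ref, alt, ...)
#' @export
callTable <- function(x) {
  gr <- x@calls
  cbind(data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                   stringsAsFactors = FALSE),
        as.data.frame(mcols(gr)))
}

setMethod("show", "CallSet", function(object) {
  m <- mcols(object@calls)
  cat("CallSet '", object@label, "': ", length(object@calls), " calls",
      sep = "")
  if (length(object@calls)) {
    cat(" (", sum(m$var_class == "SNV"), " SNV, ",
        sum(m$var_class != "SNV"), " indel; ",
        length(unique(m$sample_id)), " samples)", sep = "")
  }
  cat("\n")
})

#' Subset a CallSet
#' @param x a \code{CallSet}; \code{i} an index into its calls.
#' @param i,j,...,drop standard subsetting arguments (\code{j} unused).
#' @export
setMethod("[", "CallSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x, calls = x@calls[i])
})

#' Concatenate call sets under a new label
#' @param label label for the combined set.
#' @param ... \code{CallSet} objects.
#' @export
concatCallSets <- function(label, ...) {
  grs <- lapply(list(...), calls)
  newCallSet(label, do.call(c, grs))
}

#' DiSpectrum96: the 96-class dinucleotide mutation spectrum
#'
#' Classes are keyed by source dinucleotide (16), mutated position within it
#' (first/second) and resulting base (3 alternatives): 16 x 2 x 3 = 96.
#' \code{context_bp} holds the occurrence count of each source dinucleotide
#' in the evaluated region (overlapping windows), \code{normalized_rate} is
#' counts / context occurrences and \code{resolved} the dinucleotide after
#' applying the mutation.
#'
#' @slot classes data.frame with columns \code{dinuc}, \code{position},
#'   \code{alt}, \code{resolved} (96 rows, fixed order).
#' @slot counts numeric(96) per-class call counts.
#' @slot context_bp named numeric(16) source-dinucleotide occurrences.
#' @slot normalized_rate numeric(96).
#' @slot n_classified,n_edge_excluded SNVs classified / dropped for missing
#'   flanking context at chromosome ends.
#' @slot flank \code{"both"}, \code{"3prime"} or \code{"5prime"} — which
#'   flanking base(s) define each SNV's source dinucleotide.
#' @exportClass DiSpectrum96
setClass("DiSpectrum96",
         slots = c(classes = "data.frame", counts = "numeric",
                   context_bp = "numeric", normalized_rate = "numeric",
                   n_classified = "numeric", n_edge_excluded = "numeric",
                   flank = "character"))

setValidity("DiSpectrum96", function(object) {
  if (nrow(object@classes) != 96L) return("expected exactly 96 classes")
  if (length(object@counts) != 96L || length(object@normalized_rate) != 96L)
    return("counts and normalized_rate must have length 96")
  if (length(object@context_bp) != 16L)
    return("context_bp must cover the 16 dinucleotides")
  if (any(object@counts < 0)) return("negative class counts")
  if (any(object@normalized_rate < 0, na.rm = TRUE))
    return("negative normalized rates")
  TRUE
})

setMethod("show", "DiSpectrum96", function(object) {
  cat("DiSpectrum96: ", sum(object@counts), " class assignments from ",
      object@n_classified, " SNVs (", object@n_edge_excluded,
      " edge-excluded), flank = ", object@flank, "\n", sep = "")
  top <- order(object@counts, decreasing = TRUE)[1:3]
  cls <- object@classes[top, ]
  cat("  top classes:",
      paste0(cls$dinuc, ">", cls$resolved, " (", object@counts[top], ")",
             collapse = ", "), "\n")
})

#' @describeIn DiSpectrum96 per-class counts, named by
#'   \code{source>resolved} dinucleotide
#' @param x a \code{DiSpectrum96}.
#' @export
spectrumCounts <- function(x)
  setNames(x@counts, paste0(x@classes$dinuc, ">", x@classes$resolved))

#' @describeIn DiSpectrum96 per-class normalized rates (counts per source
#'   dinucleotide occurrence)
#' @export
normalizedRates <- function(x)
  setNames(x@normalized_rate, paste0(x@classes$dinuc, ">", x@classes$resolved))

#' @describeIn DiSpectrum96 source-dinucleotide occurrence counts
#' @export
contextCounts <- function(x) x@context_bp

#' @describeIn DiSpectrum96 class definition table
#' @export
spectrumClasses <- function(x) x@classes

#' MutationMatrix16: dinucleotide mutation rate matrix
#'
#' A continuous-time rate matrix on the 16 dinucleotide states. Off-diagonal
#' entries are the normalized single-base mutation rates between
#' dinucleotides differing at exactly one position (structural zeros
#' elsewhere); the diagonal makes each row sum to zero.
#'
#' @slot rates 16 x 16 numeric matrix, dimnames the dinucleotides.
#' @slot states the 16 dinucleotides in fixed lexicographic order.
#' @exportClass MutationMatrix16
setClass("MutationMatrix16",
         slots = c(rates = "matrix", states = "character"))

setValidity("MutationMatrix16", function(object) {
  Q <- object@rates
  if (!all(dim(Q) == c(16L, 16L))) return("rates must be 16 x 16")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) return("negative off-diagonal rates")
  if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q)))))
    return("rows must sum to zero")
  ## only single-base-change transitions may be nonzero
  bad <- off > 0 & !.single_change_mask(object@states)
  if (any(bad)) return("nonzero rate between dinucleotides differing at both positions")
  TRUE
})

.single_change_mask <- function(states) {
  a1 <- substr(states, 1, 1); a2 <- substr(states, 2, 2)
  outer(seq_along(states), seq_along(states), function(i, j)
    (a1[i] == a1[j]) + (a2[i] == a2[j]) == 1L)
}

setMethod("show", "MutationMatrix16", function(object) {
  cat("MutationMatrix16 on", paste(object@states[1:4], collapse = ","),
      "...; total off-diagonal rate",
      format(sum(object@rates[object@rates > 0]), digits = 4), "\n")
})

#' @describeIn MutationMatrix16 the rate matrix
#' @param x a \code{MutationMatrix16}.
#' @export
rateMatrix <- function(x) x@rates
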