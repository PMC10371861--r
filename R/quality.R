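#' Conventional mutation-call filter policy
#'
#' Encodes the conventional quality rules for de novo mutation calls:
#' multiple supporting reads on both strands, a minimum total support, and
#' non-recurrence across samples. Unknown (NA) strand support fails the
#' strand and total-support requirements whenever those thresholds are
#' positive.
#'
#' @param min_support_per_strand minimum supporting reads on each strand.
#' @param min_total_support minimum total supporting reads.
#' @param max_samples_sharing maximum number of distinct samples that may
#'   share the identical (chrom, pos, ref, alt) site; sites seen in more
#'   samples fail (recurrence rule).
#' @return a list of class \code{filterPolicy}.
#' @export
filterPolicy <- function(min_support_per_strand = 2L,
                         min_total_support = 4L,
                         max_samples_sharing = 10L) {
  if (min_support_per_strand < 0 || min_total_support < 0 ||
      max_samples_sharing < 0)
    stop("all policy thresholds must be >= 0")
  structure(list(min_support_per_strand = min_support_per_strand,
                 min_total_support = min_total_support,
                 max_samples_sharing = max_samples_sharing),
            class = "filterPolicy")
}

## logical pass vector for a call table under a policy
policyPass <- function(tab, policy) {
  n <- nrow(tab)
  if (n == 0L) return(logical(0))
  mps <- policy$min_support_per_strand
  mts <- policy$min_total_support
  mss <- policy$max_samples_sharing
  strand_ok <- if (mps == 0L) rep(TRUE, n) else
    !is.na(tab$fwd_support) & !is.na(tab$rev_support) &
    tab$fwd_support >= mps & tab$rev_support >= mps
  total_ok <- if (mts == 0L) rep(TRUE, n) else
    !is.na(tab$fwd_support) & !is.na(tab$rev_support) &
    (tab$fwd_support + tab$rev_support) >= mts
  site <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = "\r")
  nshare <- vapply(split(tab$sample_id, site), function(s)
    length(unique(s)), 0L)[site]
  share_ok <- nshare <= mss
  strand_ok & total_ok & share_ok
}

#' Apply a filter policy to a call set
#'
#' Partitions a call set exactly into calls passing and failing the policy.
#'
#' @param callset a \code{CallSet}.
#' @param policy a \code{\link{filterPolicy}}.
#' @return list with \code{passing} and \code{failing} \code{CallSet}s.
#' @export
applyFilter <- function(callset, policy = filterPolicy()) {
  pass <- policyPass(callTable(callset), policy)
  list(passing = initialize(callset,
                            label = paste0(callLabel(callset), "_pass"),
                            calls = calls(callset)[pass]),
       failing = initialize(callset,
                            label = paste0(callLabel(callset), "_fail"),
                            calls = calls(callset)[!pass]))
}

#' Classify a call set against a reference call set
#'
#' A query call is \emph{concordant} iff the identical
#' (chrom, pos, ref, alt, sample) call is present in the reference and
#' passes the policy there; it is \emph{uncallable} iff its own evidence
#' fails the policy; the remainder are \emph{discordant but callable}.
#' Concordant calls form the high-quality (HQ) set; all other query calls
#' are the low-quality (LQ) set.
#'
#' @param query,reference \code{CallSet}s on the same genome.
#' @param policy a \code{\link{filterPolicy}}.
#' @param ignore_sample if TRUE, concordance matching uses
#'   (chrom, pos, ref, alt) only.
#' @return a list of class \code{concordanceReport} with counts,
#'   one-decimal percentages (computed on the query size) and the
#'   \code{hq_set} / \code{lq_set} partition of the query.
#' @export
classifyConcordance <- function(query, reference, policy = filterPolicy(),
                                ignore_sample = FALSE) {
  qt <- callTable(query)
  rt <- callTable(reference)
  if (nrow(qt) && nrow(rt) &&
      !length(intersect(unique(qt$chrom), unique(rt$chrom))))
    stop("query and reference share no chromosome names")
  keyof <- function(tab) {
    if (ignore_sample) paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = "\r")
    else paste(tab$chrom, tab$pos, tab$ref, tab$alt, tab$sample_id,
               sep = "\r")
  }
  ref_pass_keys <- keyof(rt[policyPass(rt, policy), , drop = FALSE])
  concordant <- keyof(qt) %in% ref_pass_keys
  self_pass <- policyPass(qt, policy)
  uncallable <- !concordant & !self_pass
  discordant <- !concordant & self_pass
  n <- nrow(qt)
  structure(list(
    n_query = n,
    n_concordant = sum(concordant),
    n_uncallable = sum(uncallable),
    n_discordant_callable = sum(discordant),
    pct_concordant = pct1(sum(concordant), n),
    pct_uncallable = pct1(sum(uncallable), n),
    hq_set = initialize(query, label = paste0(callLabel(query), "_hq"),
                        calls = calls(query)[concordant]),
    lq_set = initialize(query, label = paste0(callLabel(query), "_lq"),
                        calls = calls(query)[!concordant])),
    class = "concordanceReport")
}

#' @export
print.concordanceReport <- function(x, ...) {
  cat("Concordance: ", x$n_concordant, "/", x$n_query, " (",
      x$pct_concordant, "%) concordant; ", x$n_uncallable, " (",
      x$pct_uncallable, "%) uncallable; ", x$n_discordant_callable,
      " discordant-but-callable\n", sep = "")
  invisible(x)
}
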