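## the fixed 96-class table: source dinucleotide (16) x mutated position
## (first/second) x resulting base (3)
classTable96 <- function() {
  rows <- list()
  for (d in DINUCS) {
    b <- strsplit(d, "")[[1]]
    for (p in 1:2) {
      for (a in setdiff(BASES, b[p])) {
        res <- b; res[p] <- a
        rows[[length(rows) + 1L]] <- data.frame(
          dinuc = d, position = c("first", "second")[p], alt = a,
          resolved = paste(res, collapse = ""), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

class96 <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- classTable96()
    tab
  }
})

class96Key <- function(dinuc, position, alt) paste(dinuc, position, alt)

#' Mononucleotide mutation spectrum
#'
#' Counts SNVs by ref>alt substitution, both as the raw 12-class table and
#' collapsed to the 6 pyrimidine-centred classes (a G>A call counts as
#' C>T, etc.).
#'
#' @param callset a \code{CallSet}; non-SNV calls are ignored.
#' @return list with \code{counts12} and \code{counts6} named vectors.
#' @export
monoSpectrum <- function(callset) {
  tab <- callTable(callset)
  tab <- tab[tab$var_class == "SNV", , drop = FALSE]
  all12 <- unlist(lapply(BASES, function(r)
    paste0(r, ">", setdiff(BASES, r))))
  c12 <- setNames(numeric(12), all12)
  if (nrow(tab)) {
    t12 <- table(paste0(tab$ref, ">", tab$alt))
    c12[names(t12)] <- as.numeric(t12)
  }
  pur <- substr(all12, 1, 1) %in% c("A", "G")
  coll <- all12
  coll[pur] <- paste0(compBase(substr(all12[pur], 1, 1)), ">",
                      compBase(substr(all12[pur], 3, 3)))
  c6 <- tapply(c12, coll, sum)
  list(counts12 = c12, counts6 = c6[sort(unique(coll[!pur]))])
}

#' 96-class dinucleotide mutation spectrum
#'
#' Classifies every SNV by its source dinucleotide, the mutated position
#' within it and the resulting base. With \code{flank = "both"} (default)
#' each SNV contributes two class assignments — one through its 5' flanking
#' dinucleotide (mutated position "second") and one through its 3' flanking
#' dinucleotide (mutated position "first") — matching the overlapping-window
#' convention used for the genomic context counts, so all 96 classes are
#' populated and the derived 16x16 dinucleotide chain is irreducible.
#' Single-flank conventions are available via \code{flank}. Calls lacking
#' the needed flank at a chromosome end are counted and excluded.
#'
#' @param callset a \code{CallSet}.
#' @param genome \code{DNAStringSet} for context lookup.
#' @param region optional \code{GRanges}; restricts both the calls and the
#'   context counts to the region.
#' @param flank \code{"both"}, \code{"3prime"} or \code{"5prime"}.
#' @return a \code{\linkS4class{DiSpectrum96}}.
#' @export
diSpectrum <- function(callset, genome, region = NULL,
                       flank = c("both", "3prime", "5prime")) {
  flank <- match.arg(flank)
  cls <- class96()
  tab <- callTable(callset)
  tab <- tab[tab$var_class == "SNV", , drop = FALSE]
  if (!is.null(region)) {
    if (!length(region)) stop("empty region")
    gr <- GRanges(tab$chrom, IRanges(tab$pos, width = 1L))
    keep <- GenomicRanges::countOverlaps(gr, region,
                                         ignore.strand = TRUE) > 0
    tab <- tab[keep, , drop = FALSE]
    ctx_seqs <- intervalSeqs(genome, reduce(region, ignore.strand = TRUE))
  } else {
    ctx_seqs <- vapply(names(genome), chromSeq, "", genome = genome)
  }
  context_bp <- countDinucs(ctx_seqs)
  counts <- setNames(numeric(96), class96Key(cls$dinuc, cls$position,
                                             cls$alt))
  n_excl <- 0L
  n_class <- 0L
  if (nrow(tab)) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    prv <- character(nrow(tab)); nxt <- character(nrow(tab))
    for (chr in unique(tab$chrom)) {
      ix <- which(tab$chrom == chr)
      s <- chromSeq(genome, chr)
      prv[ix] <- basesAt(s, tab$pos[ix] - 1L)
      nxt[ix] <- basesAt(s, tab$pos[ix] + 1L)
    }
    use5 <- flank %in% c("both", "5prime") & prv %in% BASES
    use3 <- flank %in% c("both", "3prime") & nxt %in% BASES
    k5 <- class96Key(paste0(prv, tab$ref), "second", tab$alt)[use5]
    k3 <- class96Key(paste0(tab$ref, nxt), "first", tab$alt)[use3]
    for (k in list(k5, k3)) {
      if (length(k)) {
        t <- table(k)
        counts[names(t)] <- counts[names(t)] + as.numeric(t)
      }
    }
    classified <- use5 | use3
    n_class <- sum(classified)
    n_excl <- sum(!classified)
  }
  new("DiSpectrum96", classes = cls, counts = unname(counts),
      context_bp = context_bp,
      normalized_rate = unname(ifelse(context_bp[cls$dinuc] > 0,
                                      counts / context_bp[cls$dinuc],
                                      NA_real_)),
      n_classified = n_class, n_edge_excluded = n_excl, flank = flank)
}

#' Share of resolved mutational events ending AA or TT
#'
#' Percent of the relative normalized mutation rates (normalized rates
#' scaled to sum to one) whose resolved dinucleotide is AA or TT — the
#' signature inflated by A/T homopolymer bleed artifacts.
#'
#' @param spectrum a \code{DiSpectrum96}.
#' @return percent in [0, 100].
#' @export
shareAATT <- function(spectrum) {
  r <- spectrum@normalized_rate
  r[is.na(r)] <- 0
  if (sum(r) == 0) return(NA_real_)
  100 * sum(r[spectrum@classes$resolved %in% c("AA", "TT")]) / sum(r)
}

#' Compare two 96-class spectra
#'
#' Two-sample chi-square on the 2 x 96 count table; classes with zero total
#' count are pooled out (reported), giving df = (classes used) - 1.
#' Per-class standardized residuals are ranked to surface the most
#' discrepant classes.
#'
#' @param a,b \code{DiSpectrum96} objects over the same classes.
#' @return list with \code{chi2}, \code{df}, \code{p_value},
#'   \code{residuals} (data.frame sorted by |residual|),
#'   \code{share_AA_TT} for each spectrum and \code{n_pooled}.
#' @export
compareSpectra <- function(a, b) {
  ca <- a@counts; cb <- b@counts
  if (sum(ca) == 0 || sum(cb) == 0) stop("empty spectrum")
  tot <- ca + cb
  use <- tot > 0
  m <- rbind(ca[use], cb[use])
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  res <- data.frame(
    class = paste0(a@classes$dinuc, ">", a@classes$resolved)[use],
    count_a = ca[use], count_b = cb[use],
    std_residual = ct$stdres[1, ], stringsAsFactors = FALSE)
  res <- res[order(-abs(res$std_residual)), ]
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, residuals = res,
       share_AA_TT = c(a = shareAATT(a), b = shareAATT(b)),
       n_pooled = sum(!use))
}

## region resolution helper: a feature type name, or "intergenic_nonTE"
resolveRegion <- function(annotation, name) {
  if (name == "intergenic_nonTE") {
    ig <- reduce(granges(featureIntervals(annotation, "intergenic")),
                 ignore.strand = TRUE)
    te <- granges(featureIntervals(annotation, "TE"))
    return(GenomicRanges::setdiff(ig, reduce(te, ignore.strand = TRUE),
                                  ignore.strand = TRUE))
  }
  gr <- featureIntervals(annotation, name)
  if (!length(gr)) stop("no '", name, "' intervals in annotation")
  reduce(granges(gr), ignore.strand = TRUE)
}

#' CpG>TpG rate per genomic CG, and its ratio between regions
#'
#' The numerator counts SNVs that are C>T with a 3' G or G>A with a 5' C
#' (the same CpG transition read from the other strand); the denominator is
#' the number of CG occurrences in the region.
#'
#' @param callset a \code{CallSet}.
#' @param genome \code{DNAStringSet}.
#' @param annotation annotation \code{GRanges}.
#' @param region_a,region_b region names: any feature type or
#'   \code{"intergenic_nonTE"}. \code{region_b = NULL} returns a single
#'   rate.
#' @return list with per-region rates and (when two regions are given)
#'   \code{ratio} = rate_a / rate_b.
#' @export
cpgTpgRatio <- function(callset, genome, annotation, region_a = "TE",
                        region_b = "intergenic_nonTE") {
  rate1 <- function(gr) {
    cg <- countDinucs(intervalSeqs(genome, gr))[["CG"]]
    if (cg == 0) stop("region has no CG content")
    tab <- callTable(callset)
    tab <- tab[tab$var_class == "SNV", , drop = FALSE]
    if (!nrow(tab)) return(c(rate = 0, n = 0, cg = cg))
    pos_gr <- GRanges(tab$chrom, IRanges(tab$pos, width = 1L))
    tab <- tab[GenomicRanges::countOverlaps(pos_gr, gr,
                                            ignore.strand = TRUE) > 0, ,
               drop = FALSE]
    n <- 0L
    for (chr in unique(tab$chrom)) {
      ix <- which(tab$chrom == chr)
      s <- chromSeq(genome, chr)
      nxt <- basesAt(s, tab$pos[ix] + 1L)
      prv <- basesAt(s, tab$pos[ix] - 1L)
      n <- n + sum((tab$ref[ix] == "C" & tab$alt[ix] == "T" & nxt == "G") |
                     (tab$ref[ix] == "G" & tab$alt[ix] == "A" & prv == "C"))
    }
    c(rate = n / cg, n = n, cg = cg)
  }
  ra <- rate1(resolveRegion(annotation, region_a))
  if (is.null(region_b))
    return(list(rates = setNames(ra[["rate"]], region_a), detail = ra))
  rb <- rate1(resolveRegion(annotation, region_b))
  list(rates = setNames(c(ra[["rate"]], rb[["rate"]]),
                        c(region_a, region_b)),
       ratio = if (rb[["rate"]] > 0) ra[["rate"]] / rb[["rate"]] else
         NA_real_,
       detail = rbind(ra, rb))
}

#' Estimate the CpG>TpG rate multiplier from a call set
#'
#' Inverts the closed-form expectation of the CpG>TpG call share under the
#' generator's weight model (each CpG C/G site carries weight (m+2)/3 and
#' mutates to the transition with probability m/(m+2); all other sites
#' weight 1 with uniform alternates). Unbiased when other positional
#' multipliers apply equally to CpG and non-CpG sites.
#'
#' @param callset a \code{CallSet} of SNVs.
#' @param genome \code{DNAStringSet}.
#' @return the estimated multiplier m.
#' @export
estimateCpGMultiplier <- function(callset, genome) {
  tab <- callTable(callset)
  tab <- tab[tab$var_class == "SNV", , drop = FALSE]
  ncpg_calls <- 0L
  for (chr in unique(tab$chrom)) {
    ix <- which(tab$chrom == chr)
    s <- chromSeq(genome, chr)
    nxt <- basesAt(s, tab$pos[ix] + 1L)
    prv <- basesAt(s, tab$pos[ix] - 1L)
    ncpg_calls <- ncpg_calls +
      sum((tab$ref[ix] == "C" & tab$alt[ix] == "T" & nxt == "G") |
            (tab$ref[ix] == "G" & tab$alt[ix] == "A" & prv == "C"))
  }
  s_obs <- ncpg_calls / nrow(tab)
  ncg <- countDinucs(vapply(names(genome), chromSeq, "",
                            genome = genome))[["CG"]]
  n_cpg <- 2 * ncg
  n_non <- sum(Biostrings::width(genome)) - n_cpg
  s_obs * (3 * n_non + 2 * n_cpg) / (n_cpg * (1 - s_obs))
}

#' Strand-collapsed 48-class view of a spectrum
#'
#' Merges each class with its reverse complement (source and resolved
#' dinucleotides both reverse-complemented).
#'
#' @param spectrum a \code{DiSpectrum96}.
#' @return data.frame of 48 rows: canonical class key and merged count.
#' @export
collapseSpectrum <- function(spectrum) {
  cls <- spectrum@classes
  key <- paste0(cls$dinuc, ">", cls$resolved)
  rckey <- paste0(revComp(cls$dinuc), ">", revComp(cls$resolved))
  canon <- pmin(key, rckey)
  agg <- tapply(spectrum@counts, canon, sum)
  data.frame(class = names(agg), count = as.numeric(agg),
             stringsAsFactors = FALSE)
}
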