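## internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

compBase <- function(x) chartr("ACGTN", "TGCAN", x)

## reverse complement of short fixed-width strings (vectorized)
revComp <- function(x) {
  n <- nchar(x[1])
  out <- compBase(x)
  if (n == 1L) return(out)
  vapply(strsplit(out, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

## named substream seeds derived from one master seed, so stages can be
## regenerated independently (values kept below 2^31)
substreamSeeds <- function(seed,
                           names = c("genome", "truth", "bleed", "cluster")) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  setNames(sample.int(2147483646L, length(names)), names)
}

## character sequence of one chromosome
chromSeq <- function(genome, chrom) as.character(genome[[chrom]])

## intervals of a given feature type from an annotation GRanges
featureIntervals <- function(annotation, type) {
  annotation[mcols(annotation)$type %in% type]
}

## percent rounded to one decimal, guarded for 0/0
pct1 <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 1)

## dinucleotide occurrence counts over a character sequence set,
## overlapping windows, N-containing windows skipped
countDinucs <- function(seqs) {
  counts <- setNames(numeric(16), DINUCS)
  for (s in seqs) {
    if (nchar(s) < 2L) next
    d <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                              width = 2L)
    counts <- counts + d[DINUCS]
  }
  counts
}

## extract subsequences of intervals (GRanges) from a genome DNAStringSet;
## one character conversion per chromosome
intervalSeqs <- function(genome, gr) {
  out <- character(length(gr))
  if (!length(gr)) return(out)
  sn <- as.character(seqnames(gr))
  for (chr in unique(sn)) {
    idx <- which(sn == chr)
    s <- chromSeq(genome, chr)
    out[idx] <- substring(s, start(gr)[idx], end(gr)[idx])
  }
  out
}

## bases at single positions, clamped lookups return "" outside [1, len]
basesAt <- function(seqchar, pos) {
  out <- rep("", length(pos))
  ok <- pos >= 1L & pos <= nchar(seqchar)
  out[ok] <- substring(seqchar, pos[ok], pos[ok])
  out
}
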