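#' Read a genome assembly from FASTA
#'
#' Loads every record, folds lowercase to uppercase and replaces any symbol
#' outside A,C,G,T,N by N with a warning.
#'
#' @param path path to a FASTA file.
#' @return a \code{\link[Biostrings]{DNAStringSet}} named by record.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !any(startsWith(lines, ">")))
    stop("empty or non-FASTA file: ", path)
  hdr <- grep("^>", lines)
  nm <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  if (anyDuplicated(nm))
    stop("duplicate FASTA record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[seq(hdr[i] + 1L, length.out = bounds[i + 1L] - hdr[i] - 1L)],
          collapse = "")
  }, "")
  seqs <- toupper(seqs)
  nbad <- sum(vapply(gregexpr("[^ACGTN]", seqs),
                     function(m) sum(m > 0), 0L))
  if (nbad > 0) {
    warning(nbad, " non-ACGTN symbol(s) replaced by N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  DNAStringSet(setNames(seqs, nm))
}

#' Write a genome assembly to FASTA
#' @param genome a \code{DNAStringSet}.
#' @param path output path.
#' @export
writeGenome <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Read genome annotation from GFF3
#'
#' Imports gene, exon, CDS, transposable-element and centromere features.
#' Introns are synthesized as gene space minus exon space (per gene) when no
#' intron features are present, and intergenic intervals as the complement
#' of gene space over each chromosome.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @param genome the \code{DNAStringSet} the annotation refers to; used to
#'   validate bounds and to synthesize intergenic space.
#' @return a \code{GRanges} with metadata columns \code{type} (one of
#'   \code{gene, CDS, exon, intron, TE, centromere, intergenic}),
#'   \code{gene_id} and \code{gene_class} (\code{NA} where not applicable).
#' @export
readAnnotation <- function(path, genome) {
  raw <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(raw$type)
  ty[ty %in% c("transposable_element", "transposon", "TE")] <- "TE"
  ty[ty %in% c("centromere")] <- "centromere"
  keep <- ty %in% c("gene", "exon", "CDS", "intron", "TE", "centromere")
  gr <- raw[keep]
  ty <- ty[keep]
  lens <- setNames(Biostrings::width(genome), names(genome))
  sn <- as.character(seqnames(gr))
  if (!all(sn %in% names(lens)))
    stop("annotation references unknown chromosome(s): ",
         paste(unique(sn[!sn %in% names(lens)]), collapse = ", "))
  if (any(end(gr) > lens[sn]) || any(start(gr) < 1L))
    stop("annotation interval exceeds chromosome bounds")
  gene_id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  par <- if (!is.null(gr$Parent)) vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "") else rep(NA_character_, length(gr))
  gene_id[ty != "gene"] <- par[ty != "gene"]
  gene_class <- if (!is.null(gr$gene_class)) as.character(gr$gene_class) else rep(NA_character_, length(gr))
  mcols(gr) <- DataFrame(type = ty, gene_id = gene_id, gene_class = gene_class)
  buildAnnotation(gr, genome)
}

#' Finalize an annotation: synthesize introns and intergenic space
#'
#' @param gr \code{GRanges} with \code{type}, \code{gene_id},
#'   \code{gene_class} metadata columns (gene/exon/CDS/TE/centromere rows).
#' @param genome the genome \code{DNAStringSet}.
#' @return annotation \code{GRanges} including \code{intron} and
#'   \code{intergenic} rows; centromere intervals must not overlap each other.
#' @export
buildAnnotation <- function(gr, genome) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  si <- GenomeInfoDb::Seqinfo(names(lens), seqlengths = unname(lens))
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  GenomeInfoDb::seqinfo(gr) <- si
  ty <- mcols(gr)$type
  cen <- gr[ty == "centromere"]
  if (length(cen) > 1L) {
    hits <- findOverlaps(cen, cen)
    if (any(queryHits(hits) != subjectHits(hits)))
      stop("centromere intervals overlap")
  }
  if (!any(ty == "intron")) {
    genes <- gr[ty == "gene"]
    exons <- gr[ty == "exon"]
    if (length(genes) && length(exons)) {
      introns <- unlist(GenomicRanges::GRangesList(lapply(
        seq_along(genes), function(i) {
          g <- genes[i]
          ex <- exons[!is.na(mcols(exons)$gene_id) &
                        mcols(exons)$gene_id == mcols(genes)$gene_id[i]]
          if (!length(ex)) ex <- subsetByOverlaps(exons, g)
          if (!length(ex)) return(GRanges())  # unknown structure: no introns
          intr <- GenomicRanges::setdiff(granges(g), granges(ex),
                                         ignore.strand = TRUE)
          strand(intr) <- strand(g)
          intr
        })))
      if (length(introns)) {
        gid <- rep(mcols(genes)$gene_id,
                   lengths(GenomicRanges::split(introns,
                     findOverlaps(introns, genes, select = "first"))))
        ## simpler: recompute parent per intron
        gid <- mcols(genes)$gene_id[findOverlaps(introns, genes,
                                                 select = "first")]
        gcl <- mcols(genes)$gene_class[findOverlaps(introns, genes,
                                                    select = "first")]
        mcols(introns) <- DataFrame(type = "intron", gene_id = gid,
                                    gene_class = gcl)
        gr <- c(gr, introns)
      }
    }
  }
  ty <- mcols(gr)$type
  genespace <- reduce(granges(gr[ty == "gene"]), ignore.strand = TRUE)
  strand(genespace) <- "*"
  inter <- GenomicRanges::gaps(genespace)
  inter <- inter[strand(inter) == "*"]
  if (length(inter)) {
    mcols(inter) <- DataFrame(type = "intergenic", gene_id = NA_character_,
                              gene_class = NA_character_)
    gr <- c(gr, inter)
  }
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Write an annotation to GFF3
#' @param annotation annotation \code{GRanges} (synthesized intron and
#'   intergenic rows are omitted; they are re-derived on read).
#' @param path output path.
#' @export
writeAnnotation <- function(annotation, path) {
  ty <- mcols(annotation)$type
  gr <- annotation[!ty %in% c("intron", "intergenic")]
  df <- data.frame(
    seqid = as.character(seqnames(gr)), source = "mutbleed",
    type = ifelse(mcols(gr)$type == "TE", "transposable_element",
                  mcols(gr)$type),
    start = start(gr), end = end(gr), score = ".",
    strand = ifelse(as.character(strand(gr)) == "*", ".",
                    as.character(strand(gr))),
    phase = ".", stringsAsFactors = FALSE)
  attrs <- ifelse(mcols(gr)$type == "gene",
                  paste0("ID=", mcols(gr)$gene_id,
                         ifelse(is.na(mcols(gr)$gene_class), "",
                                paste0(";gene_class=", mcols(gr)$gene_class))),
                  ifelse(is.na(mcols(gr)$gene_id), "ID=feat",
                         paste0("Parent=", mcols(gr)$gene_id)))
  writeLines(c("##gff-version 3",
               apply(cbind(df, attrs), 1, paste, collapse = "\t")), path)
  invisible(path)
}

## ---- VCF ----

#' Read a call set from VCF
#'
#' Produces one \code{MutationCall} per sample carrying a non-reference
#' allele; multi-allelic records are decomposed into one call per alternate
#' allele. Per-strand supporting-read counts are read from the custom FORMAT
#' fields \code{FAD}/\code{RAD}; when absent, supports are recorded as
#' unknown (\code{NA}), which downstream filters treat as failing strand
#' requirements.
#'
#' @param path path to a VCF file.
#' @param label provenance label for the resulting \code{CallSet}.
#' @return a \code{CallSet}.
#' @export
readCallSet <- function(path, label) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) return(CallSet(label))
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx)))
    fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  ok <- !is.na(pos) & !is.na(fix$REF) & !is.na(fix$ALT) & nzchar(fix$ALT)
  nbad <- sum(!ok)
  gtmat <- vcfR::extract.gt(v, element = "GT")
  fadm <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "FAD", as.numeric = TRUE)),
    error = function(e) NULL)
  radm <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "RAD", as.numeric = TRUE)),
    error = function(e) NULL)
  alts <- strsplit(fix$ALT, ",")
  ## decode each distinct genotype string once
  ug <- unique(as.vector(gtmat))
  decode <- lapply(ug, function(g) {
    if (is.na(g)) return(integer())
    al <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    unique(al[!is.na(al) & al > 0L])
  })
  names(decode) <- ug
  rows <- list()
  for (ci in which(lengths(decode) > 0L)) {
    hit <- which(!is.na(gtmat) & gtmat == ug[ci], arr.ind = TRUE)
    if (!nrow(hit)) next
    for (a in decode[[ci]]) {
      i <- hit[, 1]
      valid <- ok[i] & a <= lengths(alts)[i]
      nbad <- nbad + sum(!valid & ok[i])
      hh <- hit[valid, , drop = FALSE]
      if (!nrow(hh)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[hh[, 1]], pos = pos[hh[, 1]],
        ref = fix$REF[hh[, 1]],
        alt = vapply(seq_len(nrow(hh)),
                     function(k) alts[[hh[k, 1]]][a], ""),
        sample_id = colnames(gtmat)[hh[, 2]],
        fwd_support = if (is.null(fadm)) NA_integer_ else
          as.integer(fadm[hh]),
        rev_support = if (is.null(radm)) NA_integer_ else
          as.integer(radm[hh]),
        stringsAsFactors = FALSE)
    }
  }
  if (nbad > 0) warning(nbad, " malformed VCF record(s)/genotype(s) skipped")
  if (!length(rows)) return(CallSet(label))
  df <- do.call(rbind, rows)
  CallSet(label, df$chrom, df$pos, df$ref, df$alt, df$sample_id,
          df$fwd_support, df$rev_support)
}

#' Write a call set to VCF 4.2
#'
#' One record per (chrom, pos, ref, alt); genotype columns per sample with
#' custom FORMAT fields \code{FAD} (forward-strand supporting reads) and
#' \code{RAD} (reverse-strand supporting reads), documented in the header.
#' Unknown supports are written as missing.
#'
#' @param callset a \code{CallSet}.
#' @param genome a \code{DNAStringSet}; each call's ref allele is checked
#'   against the genome at its position.
#' @param path output path.
#' @export
writeCallSet <- function(callset, genome, path) {
  tab <- callTable(callset)
  if (nrow(tab)) {
    for (chr in unique(tab$chrom)) {
      idx <- which(tab$chrom == chr)
      s <- chromSeq(genome, chr)
      got <- substring(s, tab$pos[idx], tab$pos[idx] + nchar(tab$ref[idx]) - 1L)
      bad <- got != tab$ref[idx]
      if (any(bad))
        stop("ref allele mismatches genome at ", chr, ":",
             tab$pos[idx][bad][1])
    }
  }
  samples <- sort(unique(tab$sample_id))
  if (!length(samples)) samples <- "S1"
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(genome), ",length=",
                  Biostrings::width(genome), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=FAD,Number=1,Type=Integer,Description=\"Forward-strand reads supporting the alternate allele\">",
           "##FORMAT=<ID=RAD,Number=1,Type=Integer,Description=\"Reverse-strand reads supporting the alternate allele\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- character(0)
  if (nrow(tab)) {
    key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = "\r")
    ord <- order(match(tab$chrom, names(genome)), tab$pos, tab$ref, tab$alt)
    tab <- tab[ord, ]; key <- key[ord]
    grp <- split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
    body <- vapply(grp, function(ix) {
      rows <- tab[ix, ]
      cells <- setNames(rep("./.", length(samples)), samples)
      fad <- ifelse(is.na(rows$fwd_support), ".",
                    as.character(rows$fwd_support))
      rad <- ifelse(is.na(rows$rev_support), ".",
                    as.character(rows$rev_support))
      cells[rows$sample_id] <- paste("0/1", fad, rad, sep = ":")
      paste(c(rows$chrom[1], rows$pos[1], ".", rows$ref[1], rows$alt[1],
              ".", "PASS", ".", "GT:FAD:RAD", cells), collapse = "\t")
    }, "")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export intervals as BED
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   if (!is.null(mcols(gr)$type)) mcols(gr)$type else ".",
                   0L, ifelse(as.character(strand(gr)) == "*", ".",
                              as.character(strand(gr))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
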