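#' Read a genome assembly from FASTA
#'
#' Reads a multi-record FASTA into a [GenomeAssembly-class]. The molecule id
#' is the first whitespace-delimited word of each header; topology is taken
#' from a \code{[topology=circular]} token anywhere in the header and
#' defaults to linear. Sequences are uppercased; only A/C/G/T/N are accepted.
#'
#' @param path path to a FASTA file.
#' @param name assembly name; defaults to the file name without extension.
#' @return a [GenomeAssembly-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">m1 [topology=circular]", "ACGTACGT", ">m2", "GGCC"), fa)
#' readFastaAssembly(fa)
#' @seealso [writeFastaAssembly()]
#' @export
readFastaAssembly <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop(sprintf(
                     "cannot parse FASTA '%s': %s", path, conditionMessage(e))))
  if (length(seqs) == 0L) stop(sprintf("empty FASTA file: %s", path))
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate molecule id in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  topo <- ifelse(grepl("\\[topology=circular\\]", headers), "circular", "linear")
  chars <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    i <- which(bad)[1L]
    # locate the offending line for the error message
    lines <- readLines(path)
    rec_starts <- grep("^>", lines)
    this <- rec_starts[match(ids[i], sub("\\s.*$", "", sub("^>", "", lines[rec_starts])))]
    nxt <- c(rec_starts, length(lines) + 1L)[which(rec_starts == this) + 1L]
    body <- seq(this + 1L, nxt - 1L)
    off <- body[grepl("[^ACGTNacgtn]", lines[body])][1L]
    stop(sprintf("non-IUPAC character in record '%s' of '%s' (line %d)",
                 ids[i], path, off))
  }
  if (any(!nzchar(chars))) {
    i <- which(!nzchar(chars))[1L]
    stop(sprintf("empty sequence for record '%s' in '%s'", ids[i], path))
  }
  GenomeAssembly(name %||% sub("\\.(fa|fasta|fna)$", "", basename(path)),
                 stats::setNames(chars, ids), topology = topo)
}

#' Write a genome assembly to FASTA
#'
#' Writes uppercase sequence at 70 columns; circular molecules carry a
#' \code{[topology=circular]} header token so that
#' \code{readFastaAssembly(writeFastaAssembly(x))} round-trips exactly.
#'
#' @param x a [GenomeAssembly-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFastaAssembly <- function(x, path) {
  stopifnot(is(x, "GenomeAssembly"))
  seqs <- x@molecules
  names(seqs) <- ifelse(x@topology == "circular",
                        paste0(names(seqs), " [topology=circular]"),
                        names(seqs))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Length of a 1-based inclusive interval
#'
#' The package-wide convention: an interval with start 95 and end 1645 spans
#' 1551 bp (\code{end - start + 1}).
#'
#' @param start,end integer vectors, 1-based inclusive coordinates.
#' @return integer vector of lengths.
#' @examples
#' intervalLength(95, 1645)   # 1551
#' intervalLength(1501, 5739) # 4239
#' @export
intervalLength <- function(start, end) {
  if (any(start < 1L)) stop("start must be >= 1")
  if (any(end < start)) stop("end must be >= start")
  as.integer(end) - as.integer(start) + 1L
}

#' Merge intervals separated by at most a gap
#'
#' Thin wrapper over \code{GenomicRanges::reduce()} that merges ranges on the
#' same molecule whose separation is \code{<= gap}; with \code{gap = 0} only
#' overlapping/abutting ranges merge and the covered position set is
#' preserved.
#'
#' @param gr a \code{GRanges}.
#' @param gap integer \code{>= 0}.
#' @return a sorted \code{GRanges} whose ranges are pairwise separated by
#'   more than \code{gap}.
#' @examples
#' gr <- GenomicRanges::GRanges("m1", IRanges::IRanges(c(1, 5), c(10, 20)))
#' mergeIntervals(gr, gap = 0)
#' @export
mergeIntervals <- function(gr, gap = 0L) {
  if (!is.numeric(gap) || length(gap) != 1L || is.na(gap) || gap < 0)
    stop("'gap' must be a single non-negative integer")
  GenomicRanges::reduce(BiocGenerics::sort(gr), min.gapwidth = gap + 1L)
}

#' Reverse complement of a DNA string
#'
#' @param s character vector over A/C/G/T/N (case preserved as uppercase).
#' @return character vector of reverse complements.
#' @examples
#' revComp("AAAGGGG")  # "CCCCTTT"
#' @export
revComp <- function(s) {
  s <- toupper(s)
  if (any(grepl("[^ACGTN]", s)))
    stop("revComp: sequence contains characters outside {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Read a feature table (TSV or GFF3)
#'
#' TSV input needs columns \code{gene}, \code{molecule}, \code{start},
#' \code{end}, \code{strand}, \code{kind} (1-based inclusive coordinates).
#' GFF3 is accepted read-only via \pkg{rtracklayer}; the feature type column
#' maps onto \code{kind} and \code{gene} is taken from the \code{Name} or
#' \code{ID} attribute.
#'
#' @param path input file.
#' @param format \code{"tsv"} or \code{"gff3"}; guessed from the extension
#'   by default.
#' @return a \code{GRanges} with metadata columns \code{gene} and
#'   \code{kind}.
#' @export
readFeatureTable <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    g <- rtracklayer::import(path, format = "gff3")
    gene <- if (!is.null(g$Name)) g$Name else g$ID
    out <- GenomicRanges::granges(g)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      gene = as.character(gene),
      kind = normalizeFeatureKind(as.character(g$type)))
    return(out)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "molecule", "start", "end", "strand", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("feature table missing column(s): %s", paste(miss, collapse = ", ")))
  GenomicRanges::GRanges(df$molecule,
                         IRanges::IRanges(df$start, df$end),
                         strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"),
                         gene = df$gene,
                         kind = normalizeFeatureKind(df$kind))
}

normalizeFeatureKind <- function(kind) {
  k <- tolower(kind)
  out <- rep("other", length(k))
  out[k %in% c("cds", "gene", "protein_coding")] <- "CDS"
  out[grepl("trna", k)] <- "tRNA"
  out[grepl("rrna", k)] <- "rRNA"
  out[grepl("^orf", k)] <- "ORF"
  out
}

#' Write regions to BED (0-based half-open)
#'
#' In-memory coordinates are 1-based inclusive; on disk BED uses 0-based
#' half-open starts, so \code{chromStart = start - 1}, \code{chromEnd = end}.
#'
#' @param gr a \code{GRanges}; a \code{label} metadata column becomes the
#'   BED name field.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @seealso [readBedRegions()]
#' @export
writeBedRegions <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   chromStart = BiocGenerics::start(gr) - 1L,
                   chromEnd = BiocGenerics::end(gr),
                   name = if (!is.null(gr$label)) gr$label else ".",
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read regions from BED into 1-based inclusive coordinates
#'
#' @param path BED file (at least 3 columns; column 4, when present, becomes
#'   the \code{label} metadata column).
#' @return a \code{GRanges}.
#' @export
readBedRegions <- function(path) {
  if (file.size(path) == 0)
    return(GenomicRanges::GRanges(label = character()))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1L]],
                               IRanges::IRanges(df[[2L]] + 1L, df[[3L]]))
  gr$label <- if (ncol(df) >= 4L) as.character(df[[4L]]) else
    rep(NA_character_, nrow(df))
  gr
}
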