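#' Count consecutive exact tandem copies of a repeat unit
#'
#' Returns the maximum number of back-to-back exact copies of \code{unit}
#' found anywhere in \code{seq} (the leftmost maximal run on ties). Matching
#' is exact and case-insensitive; flanking sequence never contributes.
#'
#' @param seq sequence to scan.
#' @param unit repeat unit (default: the 39-nt CMS unit,
#'   [cmsRepeatUnit()]).
#' @return integer copy count (0 when the unit is absent).
#' @examples
#' countTandemCopies(paste0("CCC", strrep(cmsRepeatUnit(), 3), "CCC"))  # 3
#' @export
countTandemCopies <- function(seq, unit = cmsRepeatUnit()) {
  seq <- toupper(seq); unit <- toupper(unit)
  if (!nzchar(seq)) stop("'seq' must be non-empty")
  u <- nchar(unit)
  hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(unit), Biostrings::DNAString(seq)))
  if (!length(hits)) return(0L)
  # consecutive copies are hits exactly one unit apart
  best <- run <- 1L
  for (i in seq_along(hits)[-1L]) {
    run <- if (hits[i] == hits[i - 1L] + u) run + 1L else 1L
    if (run > best) best <- run
  }
  best
}

#' Classify a CMS ORF by its repeat copy number
#'
#' The orf138 sterility gene family is distinguished by exact 39-bp steps:
#' three tandem copies of the unit in orf138 (138 codons), two in orf125,
#' one in orf112 (112 codons). The ORF must start with ATG, end with a stop
#' codon, and be a multiple of 3 long. When a reference ORF is supplied,
#' SNPs are counted by ungapped comparison outside the repeat tract (the
#' prefix before the run and the suffix after it), so copy-number
#' differences do not inflate the SNP count.
#'
#' @param orfSeq the ORF sequence (ATG..stop).
#' @param unit repeat unit sequence.
#' @param referenceOrf optional reference ORF for SNP counting.
#' @return list: \code{orf_codons} (stop excluded), \code{repeat_copies},
#'   \code{snps_vs_reference} (NA when no reference or when the
#'   outside-tract lengths differ), \code{class} (\code{orf138}/
#'   \code{orf125}/\code{orf112}/\code{unknown}).
#' @examples
#' classifyCmsOrf(plantCmsOrf(3))$class  # "orf138"
#' @export
classifyCmsOrf <- function(orfSeq, unit = cmsRepeatUnit(),
                           referenceOrf = NULL) {
  s <- toupper(orfSeq)
  n <- nchar(s)
  if (n %% 3L != 0L) stop("ORF length must be a multiple of 3")
  if (substr(s, 1L, 3L) != "ATG") stop("ORF must start with ATG")
  last <- substr(s, n - 2L, n)
  if (!last %in% c("TAA", "TAG", "TGA")) stop("ORF must end with a stop codon")
  codons <- n %/% 3L - 1L
  copies <- countTandemCopies(s, unit)
  cls <- switch(as.character(copies),
                "3" = "orf138", "2" = "orf125", "1" = "orf112", "unknown")
  snps <- NA_integer_
  if (!is.null(referenceOrf)) {
    snps <- snpsOutsideTract(s, toupper(referenceOrf), toupper(unit))
  }
  list(orf_codons = codons, repeat_copies = copies,
       snps_vs_reference = snps, class = cls)
}

# ungapped mismatch count between the sequence parts flanking each ORF's
# repeat tract; NA when the flank lengths differ (a non-repeat indel)
snpsOutsideTract <- function(a, b, unit) {
  ta <- tractSpan(a, unit); tb <- tractSpan(b, unit)
  if (is.null(ta) || is.null(tb)) return(NA_integer_)
  preA <- substr(a, 1L, ta[1L] - 1L); preB <- substr(b, 1L, tb[1L] - 1L)
  sufA <- substr(a, ta[2L] + 1L, nchar(a)); sufB <- substr(b, tb[2L] + 1L, nchar(b))
  if (nchar(preA) != nchar(preB) || nchar(sufA) != nchar(sufB))
    return(NA_integer_)
  countMismatches(preA, preB) + countMismatches(sufA, sufB)
}

# start/end of the leftmost maximal tandem run of the unit, or NULL
tractSpan <- function(s, unit) {
  u <- nchar(unit)
  hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(unit), Biostrings::DNAString(s)))
  if (!length(hits)) return(NULL)
  best <- run <- 1L
  bestStart <- hits[1L]
  runStart <- hits[1L]
  for (i in seq_along(hits)[-1L]) {
    if (hits[i] == hits[i - 1L] + u) run <- run + 1L
    else { run <- 1L; runStart <- hits[i] }
    if (run > best) { best <- run; bestStart <- runStart }
  }
  c(bestStart, bestStart + best * u - 1L)
}

countMismatches <- function(a, b) {
  if (!nchar(a)) return(0L)
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Genotype a genome at the CMS locus with the OKB marker
#'
#' Runs in-silico PCR with the OKB primer pair; the three sterility ORFs
#' give amplicons stepping by 39 bp per repeat copy, and ORF-free (fertile)
#' cytoplasm gives no product. The haplotype is read from the number of
#' exact unit copies inside the predicted amplicon, which on exact templates
#' is equivalent to ranking the three product sizes but needs no size
#' calibrator.
#'
#' @param genome a [GenomeAssembly-class].
#' @param pair primer pair; default [okbPrimerPair()].
#' @param maxAmplicon maximum product size, bp.
#' @return list: \code{genotype} (\code{"orf138-type"}, \code{"orf125-type"},
#'   \code{"orf112-type"}, \code{"fertile/none"} or \code{"unknown"}),
#'   \code{product_bp}, \code{repeat_copies}, \code{n_products}.
#' @export
okbGenotype <- function(genome, pair = okbPrimerPair(), maxAmplicon = 2000L) {
  call <- insilicoPCR(genome, pair, maxAmplicon = maxAmplicon)
  if (call$n_products == 0L)
    return(list(genotype = "fertile/none", product_bp = NA_integer_,
                repeat_copies = 0L, n_products = 0L))
  if (!call$present)
    return(list(genotype = "unknown", product_bp = NA_integer_,
                repeat_copies = NA_integer_, n_products = call$n_products))
  copies <- countTandemCopies(call$amplicon)
  genotype <- switch(as.character(copies),
                     "3" = "orf138-type", "2" = "orf125-type",
                     "1" = "orf112-type", "unknown")
  list(genotype = genotype, product_bp = call$product_bp,
       repeat_copies = copies, n_products = call$n_products)
}
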