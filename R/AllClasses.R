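#' GenomeAssembly: a named set of circular/linear sequence molecules
#'
#' Container for one organelle genome assembly: an identifier plus one to
#' eight molecules (plant mitogenomes frequently assemble into one or two
#' circles). Sequences are held as a \link[Biostrings]{DNAStringSet}; the
#' topology of each molecule is recorded separately because FASTA has no
#' topology field.
#'
#' @slot name single character, assembly name (e.g. line identifier).
#' @slot molecules \code{DNAStringSet}, named by molecule id.
#' @slot topology character vector parallel to \code{molecules}, each
#'   \code{"circular"} or \code{"linear"}.
#'
#' @section Coordinate convention:
#' All in-memory coordinates in this package are 1-based and fully inclusive
#' (an interval start 95, end 1645 has length 1551). BED files on disk use
#' the usual 0-based half-open convention; conversion happens only at the
#' file boundary.
#'
#' @seealso [GenomeAssembly()], [readFastaAssembly()]
#' @aliases GenomeAssembly-class
#' @exportClass GenomeAssembly
setClass("GenomeAssembly",
  representation(name = "character",
                 molecules = "DNAStringSet",
                 topology = "character"))

setValidity("GenomeAssembly", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a single non-empty string")
  n <- length(object@molecules)
  if (n < 1L || n > 8L)
    msgs <- c(msgs, "assembly must contain 1-8 molecules")
  ids <- names(object@molecules)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msgs <- c(msgs, "every molecule must have a non-empty id")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicate molecule id: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (any(Biostrings::width(object@molecules) < 1L))
    msgs <- c(msgs, "every molecule must have length >= 1")
  if (length(object@topology) != n)
    msgs <- c(msgs, "'topology' must have one entry per molecule")
  else if (!all(object@topology %in% c("circular", "linear")))
    msgs <- c(msgs, "topology entries must be 'circular' or 'linear'")
  # alphabet restricted to unambiguous bases plus N
  af <- Biostrings::alphabetFrequency(object@molecules, collapse = TRUE)
  bad <- af[setdiff(names(af), c("A", "C", "G", "T", "N"))]
  if (sum(bad) > 0)
    msgs <- c(msgs, sprintf("sequences contain non-ACGTN characters (%s)",
                            paste(names(bad)[bad > 0], collapse = ",")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeAssembly
#'
#' @param name assembly name.
#' @param sequences named character vector or \code{DNAStringSet}; names are
#'   molecule ids.
#' @param topology \code{"circular"} or \code{"linear"}, recycled across
#'   molecules.
#' @return a [GenomeAssembly-class] object.
#' @examples
#' ga <- GenomeAssembly("toy", c(m1 = "ACGTACGT"), topology = "circular")
#' totalLength(ga)
#' @export
GenomeAssembly <- function(name, sequences, topology = "linear") {
  if (is.character(sequences)) {
    seqs <- Biostrings::DNAStringSet(toupper(sequences))
    names(seqs) <- names(sequences)
  } else {
    seqs <- Biostrings::DNAStringSet(sequences)
  }
  topo <- rep_len(topology, length(seqs))
  new("GenomeAssembly", name = name, molecules = seqs, topology = topo)
}

setMethod("show", "GenomeAssembly", function(object) {
  cat(sprintf("GenomeAssembly '%s': %d molecule(s), %s bp total\n",
              object@name, length(object@molecules),
              format(totalLength(object), big.mark = ",")))
  w <- Biostrings::width(object@molecules)
  for (i in seq_along(object@molecules))
    cat(sprintf("  %s  %s bp  (%s)\n", names(object@molecules)[i],
                format(w[i], big.mark = ","), object@topology[i]))
})

#' AlloplasmReport: donor-derived regions of a hybrid genome with totals
#'
#' Result of [extractAlienRegions()]: the donor-class ("alien cytoplasm")
#' regions of a hybrid mitochondrial genome, labelled R1..Rn in
#' molecule-then-coordinate order, with the summed alien length and its
#' percentage of the genome (half-up, 2 decimals).
#'
#' @slot regions \code{GRanges} of donor-class regions; metadata column
#'   \code{label} carries R1..Rn.
#' @slot totalAlienBp integer, sum of region lengths.
#' @slot genomeBp integer, total hybrid genome length.
#' @slot alienFractionPercent numeric, \code{100 * totalAlienBp / genomeBp}
#'   rounded half-up to 2 decimals.
#' @aliases AlloplasmReport-class
#' @exportClass AlloplasmReport
setClass("AlloplasmReport",
  representation(regions = "GRanges",
                 totalAlienBp = "integer",
                 genomeBp = "integer",
                 alienFractionPercent = "numeric"))

setValidity("AlloplasmReport", function(object) {
  msgs <- character()
  if (length(object@regions) &&
      sum(BiocGenerics::width(object@regions)) != object@totalAlienBp)
    msgs <- c(msgs, "totalAlienBp must equal the sum of region widths")
  if (!length(object@regions) && object@totalAlienBp != 0L)
    msgs <- c(msgs, "totalAlienBp must be 0 when there are no regions")
  expect <- roundHalfUp(100 * object@totalAlienBp / object@genomeBp, 2L)
  if (!isTRUE(all.equal(object@alienFractionPercent, expect)))
    msgs <- c(msgs, "alienFractionPercent inconsistent with totals")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AlloplasmReport", function(object) {
  cat(sprintf("AlloplasmReport: %d alien region(s), %s bp (%.2f%% of %s bp)\n",
              length(object@regions),
              format(object@totalAlienBp, big.mark = ","),
              object@alienFractionPercent,
              format(object@genomeBp, big.mark = ",")))
  if (length(object@regions)) {
    df <- as.data.frame(object@regions)
    cat(paste(sprintf("  %-4s %-8s %9d %9d %7d",
                      df$label, df$seqnames, df$start, df$end, df$width),
              collapse = "\n"), "\n")
  }
})

#' TrioTruth: planted ground truth of a synthetic recipient/donor/hybrid trio
#'
#' Ground-truth twin of an alien-cytoplasm table: where the donor-derived
#' segments were planted in the hybrid, which structural variants were
#' applied, and where the CMS ORF construct sits.
#'
#' @slot donorSegments \code{GRanges} on the hybrid; metadata column
#'   \code{label}.
#' @slot svs data.frame describing planted SVs (type, molecule, start, end,
#'   size).
#' @slot cmsOrf \code{GRanges} of length 0 or 1: the planted CMS ORF.
#' @slot cmsCopies integer, tandem copies of the 39-nt unit in that ORF
#'   (0 when absent).
#' @aliases TrioTruth-class
#' @exportClass TrioTruth
setClass("TrioTruth",
  representation(donorSegments = "GRanges",
                 svs = "data.frame",
                 cmsOrf = "GRanges",
                 cmsCopies = "integer"))

setMethod("show", "TrioTruth", function(object) {
  cat(sprintf("TrioTruth: %d donor segment(s) totalling %s bp, %d SV(s), CMS copies %d\n",
              length(object@donorSegments),
              format(sum(BiocGenerics::width(object@donorSegments)),
                     big.mark = ","),
              nrow(object@svs), object@cmsCopies))
})
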