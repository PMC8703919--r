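#' @rdname GenomeAssembly-accessors
#' @export
setGeneric("assemblyName", function(x) standardGeneric("assemblyName"))

#' @rdname GenomeAssembly-accessors
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname GenomeAssembly-accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname GenomeAssembly-accessors
#' @export
setGeneric("moleculeLengths", function(x) standardGeneric("moleculeLengths"))

#' @rdname GenomeAssembly-accessors
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname AlloplasmReport-accessors
#' @export
setGeneric("alienRegions", function(x) standardGeneric("alienRegions"))

#' @rdname AlloplasmReport-accessors
#' @export
setGeneric("totalAlienBp", function(x) standardGeneric("totalAlienBp"))

#' @rdname AlloplasmReport-accessors
#' @export
setGeneric("alienFraction", function(x) standardGeneric("alienFraction"))

#' @rdname TrioTruth-accessors
#' @export
setGeneric("donorSegments", function(x) standardGeneric("donorSegments"))

#' @rdname TrioTruth-accessors
#' @export
setGeneric("plantedSVs", function(x) standardGeneric("plantedSVs"))

#' @rdname TrioTruth-accessors
#' @export
setGeneric("cmsOrfRange", function(x) standardGeneric("cmsOrfRange"))

#' @rdname TrioTruth-accessors
#' @export
setGeneric("cmsCopies", function(x) standardGeneric("cmsCopies"))

#' Accessors for GenomeAssembly
#'
#' @param x a [GenomeAssembly-class].
#' @return \code{assemblyName}: the assembly name; \code{molecules}: the
#'   \code{DNAStringSet}; \code{topology}: named character vector;
#'   \code{moleculeLengths}: named integer vector; \code{totalLength}:
#'   total bp.
#' @name GenomeAssembly-accessors
#' @aliases assemblyName molecules topology moleculeLengths totalLength
NULL

setMethod("assemblyName", "GenomeAssembly", function(x) x@name)
setMethod("molecules", "GenomeAssembly", function(x) x@molecules)
setMethod("topology", "GenomeAssembly", function(x) {
  stats::setNames(x@topology, names(x@molecules))
})
setMethod("moleculeLengths", "GenomeAssembly", function(x) {
  stats::setNames(Biostrings::width(x@molecules), names(x@molecules))
})
setMethod("totalLength", "GenomeAssembly", function(x) {
  sum(Biostrings::width(x@molecules))
})

#' Accessors for AlloplasmReport
#'
#' @param x an [AlloplasmReport-class].
#' @return \code{alienRegions}: labelled \code{GRanges};
#'   \code{totalAlienBp}: integer bp; \code{alienFraction}: percent of the
#'   genome (2 decimals).
#' @name AlloplasmReport-accessors
#' @aliases alienRegions totalAlienBp alienFraction
NULL

setMethod("alienRegions", "AlloplasmReport", function(x) x@regions)
setMethod("totalAlienBp", "AlloplasmReport", function(x) x@totalAlienBp)
setMethod("alienFraction", "AlloplasmReport", function(x) x@alienFractionPercent)

#' Accessors for TrioTruth
#'
#' @param x a [TrioTruth-class].
#' @return \code{donorSegments}: \code{GRanges}; \code{plantedSVs}:
#'   data.frame; \code{cmsOrfRange}: \code{GRanges} (length 0 or 1);
#'   \code{cmsCopies}: integer.
#' @name TrioTruth-accessors
#' @aliases donorSegments plantedSVs cmsOrfRange cmsCopies
NULL

setMethod("donorSegments", "TrioTruth", function(x) x@donorSegments)
setMethod("plantedSVs", "TrioTruth", function(x) x@svs)
setMethod("cmsOrfRange", "TrioTruth", function(x) x@cmsOrf)
setMethod("cmsCopies", "TrioTruth", function(x) x@cmsCopies)
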