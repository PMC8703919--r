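#' Per-position coverage of a hybrid genome by exact matches to a reference
#'
#' A hybrid position is covered when it lies inside at least one exact-match
#' anchor against the reference genome. Coverage masks against the recipient
#' and the donor feed [attributeOrigin()].
#'
#' @param hybrid,ref [GenomeAssembly-class] objects.
#' @param minLen anchor length threshold passed to [findAnchors()].
#' @param anchors optional precomputed anchor data.frame (query = hybrid)
#'   to avoid recomputation.
#' @return named list of logical vectors, one per hybrid molecule.
#' @export
coverageFromAnchors <- function(hybrid, ref, minLen = 100L, anchors = NULL) {
  if (is.null(anchors)) anchors <- findAnchors(hybrid, ref, minLen = minLen)
  lens <- moleculeLengths(hybrid)
  out <- lapply(names(lens), function(m) {
    v <- logical(lens[[m]])
    a <- anchors[anchors$q_mol == m, , drop = FALSE]
    if (nrow(a)) {
      cov <- IRanges::coverage(IRanges::IRanges(a$q_start, a$q_end),
                               width = lens[[m]])
      v <- as.logical(as.vector(cov) > 0L)
    }
    v
  })
  stats::setNames(out, names(lens))
}

#' Attribute every hybrid position to an origin class
#'
#' Combines the donor and recipient coverage masks position-wise:
#' covered by both = \code{shared}, donor only = \code{donor}, recipient
#' only = \code{recipient}, neither = \code{novel}. Runs of equal class are
#' emitted as regions that partition each molecule. "Completely derived
#' from the donor" is thus operationalized as exact donor coverage with
#' zero recipient coverage; shared sequence is never counted as alien, so
#' the alien fraction is a lower bound under ambiguity.
#'
#' @param donorMask,recipientMask coverage masks from
#'   [coverageFromAnchors()] over the same hybrid.
#' @return \code{GRanges} with metadata column \code{origin}.
#' @export
attributeOrigin <- function(donorMask, recipientMask) {
  if (!identical(names(donorMask), names(recipientMask)) ||
      !identical(lengths(donorMask), lengths(recipientMask)))
    stop("donor and recipient masks must cover the same molecules/lengths")
  res <- lapply(names(donorMask), function(m) {
    code <- donorMask[[m]] * 2L + recipientMask[[m]]
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    GenomicRanges::GRanges(m, IRanges::IRanges(starts, ends),
                           origin = c("novel", "recipient", "donor",
                                      "shared")[r$values + 1L])
  })
  out <- suppressWarnings(do.call(c, res))
  out
}

#' Extract the alien-cytoplasm regions and summary statistics
#'
#' Donor-class regions are merged across interruptions of at most \code{gap}
#' bp (absorbing short shared/novel breaks caused by anchor edges), filtered
#' to \code{minRegion} bp, and labelled R1..Rn in molecule-then-coordinate
#' order. The report carries the summed alien length and its percentage of
#' the genome, rounded half-up to 2 decimals. On a circular molecule the
#' pair of regions touching position 1 and the molecule end share one label
#' (a single region crossing the origin).
#'
#' @param regions \code{GRanges} from [attributeOrigin()] (metadata column
#'   \code{origin}), or any \code{GRanges} of donor regions.
#' @param hybrid optional [GenomeAssembly-class]; supplies the genome size
#'   and circular topology.
#' @param genomeBp total genome size; required when \code{hybrid} is
#'   missing.
#' @param gap merge gap, bp.
#' @param minRegion minimum reported region length, bp. The default keeps
#'   every real-scale alien region (the smallest on record is 1551 bp) while
#'   suppressing anchor-edge fragments.
#' @return an [AlloplasmReport-class].
#' @examples
#' gr <- GenomicRanges::GRanges(c("MT1", "MT1"),
#'   IRanges::IRanges(c(95, 9983), c(1645, 13790)), origin = "donor")
#' extractAlienRegions(gr, genomeBp = 257429)
#' @export
extractAlienRegions <- function(regions, hybrid = NULL, genomeBp = NULL,
                                gap = 100L, minRegion = 1000L) {
  gap <- stopifnot_scalar_int(gap, "gap", 0L)
  minRegion <- stopifnot_scalar_int(minRegion, "minRegion", 1L)
  if (is.null(genomeBp)) {
    if (is.null(hybrid)) stop("supply 'hybrid' or 'genomeBp'")
    genomeBp <- totalLength(hybrid)
  }
  don <- if (!is.null(regions$origin))
    regions[regions$origin == "donor"] else regions
  don <- mergeIntervals(don, gap = gap)
  don <- don[BiocGenerics::width(don) >= minRegion]
  # stable molecule-then-coordinate order
  molOrder <- if (!is.null(hybrid)) names(molecules(hybrid)) else
    unique(as.character(GenomicRanges::seqnames(don)))
  ord <- order(match(as.character(GenomicRanges::seqnames(don)), molOrder),
               BiocGenerics::start(don))
  don <- don[ord]
  labels <- if (length(don)) paste0("R", seq_along(don)) else character()
  # a region pair abutting a circular origin is one region, one label
  if (!is.null(hybrid) && length(don) > 1L) {
    lens <- moleculeLengths(hybrid)
    topo <- topology(hybrid)
    for (m in names(lens)) {
      onm <- which(as.character(GenomicRanges::seqnames(don)) == m)
      if (length(onm) > 1L && topo[[m]] == "circular") {
        first <- onm[1L]; last <- onm[length(onm)]
        wrapGap <- (BiocGenerics::start(don)[first] - 1L) +
          (lens[[m]] - BiocGenerics::end(don)[last])
        if (wrapGap <= gap) labels[last] <- labels[first]
      }
    }
    if (anyDuplicated(labels)) {
      u <- unique(labels)
      labels <- paste0("R", match(labels, u))
    }
  }
  don$label <- labels
  total <- if (length(don)) sum(BiocGenerics::width(don)) else 0L
  new("AlloplasmReport",
      regions = don,
      totalAlienBp = as.integer(total),
      genomeBp = as.integer(genomeBp),
      alienFractionPercent = roundHalfUp(100 * total / genomeBp, 2L))
}

#' Tabulate an AlloplasmReport like a published alien-cytoplasm table
#'
#' @param x an [AlloplasmReport-class].
#' @return data.frame with columns Region, Location, Start, End, Length.
#' @export
alloplasmTable <- function(x) {
  gr <- alienRegions(x)
  data.frame(Region = if (length(gr)) gr$label else character(),
             Location = as.character(GenomicRanges::seqnames(gr)),
             Start = BiocGenerics::start(gr),
             End = BiocGenerics::end(gr),
             Length = BiocGenerics::width(gr),
             stringsAsFactors = FALSE)
}

#' Map the alien regions of one hybrid onto another
#'
#' Used when a second alloplasmic line shares the donor: each region of
#' report \code{b} is assigned the labels of the regions of report \code{a}
#' whose sequence it shares, by mapping exact-match anchors between the two
#' hybrids. A region of \code{b} with no counterpart covering at least half
#' of the shorter region is flagged \code{unique}.
#'
#' @param a,b [AlloplasmReport-class] objects for hybrids A and B.
#' @param anchors anchor data.frame from
#'   \code{findAnchors(hybridB, hybridA)} (query = B's hybrid).
#' @return data.frame: \code{b_label}, \code{a_labels} (comma-separated,
#'   \code{""} when unique), \code{unique} (logical).
#' @export
compareRegionSets <- function(a, b, anchors) {
  ra <- alienRegions(a)
  rb <- alienRegions(b)
  out <- data.frame(b_label = character(), a_labels = character(),
                    unique = logical(), stringsAsFactors = FALSE)
  if (!length(rb)) return(out)
  for (i in seq_along(rb)) {
    bs <- BiocGenerics::start(rb)[i]; be <- BiocGenerics::end(rb)[i]
    bm <- as.character(GenomicRanges::seqnames(rb))[i]
    hits <- anchors[anchors$q_mol == bm & anchors$q_end >= bs &
                      anchors$q_start <= be, , drop = FALSE]
    matched <- character()
    if (nrow(hits) && length(ra)) {
      ovBp <- stats::setNames(numeric(length(ra)), ra$label)
      for (h in seq_len(nrow(hits))) {
        qs <- max(hits$q_start[h], bs); qe <- min(hits$q_end[h], be)
        if (hits$strand[h] == "+") {
          ms <- hits$s_start[h] + (qs - hits$q_start[h])
          me <- hits$s_start[h] + (qe - hits$q_start[h])
        } else {
          me <- hits$s_end[h] - (qs - hits$q_start[h])
          ms <- hits$s_end[h] - (qe - hits$q_start[h])
        }
        for (j in seq_along(ra)) {
          if (as.character(GenomicRanges::seqnames(ra))[j] != hits$s_mol[h])
            next
          ov <- min(me, BiocGenerics::end(ra)[j]) -
            max(ms, BiocGenerics::start(ra)[j]) + 1L
          if (ov > 0L) ovBp[j] <- ovBp[j] + ov
        }
      }
      thr <- 0.5 * pmin(be - bs + 1L, BiocGenerics::width(ra))
      matched <- ra$label[ovBp >= thr]
    }
    out <- rbind(out, data.frame(
      b_label = rb$label[i],
      a_labels = paste(matched, collapse = ","),
      unique = !length(matched), stringsAsFactors = FALSE))
  }
  out
}
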