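#' Find maximal exact-match anchors between two genomes
#'
#' Enumerates maximal exact matches (MEMs) of length \code{>= minLen} between
#' every molecule pair of a query and a subject assembly, on both strands.
#' Circular molecules are scanned across the origin: the sequence is extended
#' by \code{minLen - 1} wraparound bases, and anchors crossing the origin are
#' reported split at the origin with coordinates wrapped back into
#' \code{[1, length]}.
#'
#' Exact matching is deliberate: donor-segment attribution in alloplasmic
#' genomes asks whether hybrid sequence is \emph{identical} to a parent, so
#' tolerance enters only through \code{minLen}, not through mismatches.
#'
#' @param qry,sbj [GenomeAssembly-class] objects.
#' @param minLen minimum anchor length, \code{>= 15}. Default 100 bp: long
#'   enough that chance hits are negligible at mitogenome scale, short enough
#'   to tile kb-scale regions.
#' @return data.frame with columns \code{q_mol}, \code{q_start}, \code{q_end},
#'   \code{s_mol}, \code{s_start}, \code{s_end}, \code{strand} (\code{+}/
#'   \code{-}), \code{length}. For \code{-} anchors the query interval matches
#'   the reverse complement of the subject interval.
#' @examples
#' a <- GenomeAssembly("a", c(m = "ACGTACGTACGTACGTACGTACGT"))
#' findAnchors(a, a, minLen = 15)
#' @export
findAnchors <- function(qry, sbj, minLen = 100L) {
  stopifnot(is(qry, "GenomeAssembly"), is(sbj, "GenomeAssembly"))
  minLen <- stopifnot_scalar_int(minLen, "minLen", min = 15L)
  res <- list()
  qn <- names(qry@molecules)
  sn <- names(sbj@molecules)
  for (qi in seq_along(qn)) {
    qseq <- as.character(qry@molecules[[qi]])
    Lq <- nchar(qseq)
    qcirc <- qry@topology[qi] == "circular"
    qext <- if (qcirc && Lq > 1L)
      paste0(qseq, substr(qseq, 1L, min(minLen - 1L, Lq))) else qseq
    for (si in seq_along(sn)) {
      sseq <- as.character(sbj@molecules[[si]])
      Ls <- nchar(sseq)
      scirc <- sbj@topology[si] == "circular"
      sext <- if (scirc && Ls > 1L)
        paste0(sseq, substr(sseq, 1L, min(minLen - 1L, Ls))) else sseq
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") sext else revComp(sext)
        hits <- mem_anchors_cpp(qext, subj, minLen)
        if (!nrow(hits)) next
        anch <- mapAnchorHits(hits, strand, Lq, Ls, nchar(sext))
        if (nrow(anch)) {
          anch$q_mol <- qn[qi]
          anch$s_mol <- sn[si]
          res[[length(res) + 1L]] <- anch
        }
      }
    }
  }
  if (!length(res)) return(emptyAnchorFrame())
  out <- do.call(rbind, res)
  out <- out[, c("q_mol", "q_start", "q_end", "s_mol", "s_start", "s_end",
                 "strand", "length")]
  out <- unique(out)
  out <- out[out$length >= 1L, , drop = FALSE]
  out[order(out$q_mol, out$q_start, out$s_mol, out$s_start), , drop = FALSE]
}

emptyAnchorFrame <- function() {
  data.frame(q_mol = character(), q_start = integer(), q_end = integer(),
             s_mol = character(), s_start = integer(), s_end = integer(),
             strand = character(), length = integer(),
             stringsAsFactors = FALSE)
}

# Map raw extended-coordinate hits back onto the unwrapped molecules,
# splitting anchors that cross a circular origin on either side.
mapAnchorHits <- function(hits, strand, Lq, Ls, LsExt) {
  rows <- vector("list", nrow(hits))
  for (r in seq_len(nrow(hits))) {
    qs <- hits$q_start[r]
    len <- hits$length[r]
    len <- min(len, Lq, Ls)  # circular self-overrun guard
    if (strand == "+") {
      ss <- hits$s_start[r]
      sHi <- NULL
    } else {
      # hit coords are on revcomp(extended subject); map to extended coords
      sHi <- LsExt - hits$s_start[r] + 1L   # subject end in extended coords
      ss <- sHi - len + 1L
    }
    # cut offsets (0-based, last offset of a piece) where a coordinate
    # crosses the unwrapped molecule end
    cuts <- integer()
    if (qs <= Lq && qs + len - 1L > Lq) cuts <- c(cuts, Lq - qs)
    if (strand == "+") {
      if (ss <= Ls && ss + len - 1L > Ls) cuts <- c(cuts, Ls - ss)
    } else {
      sLo <- sHi - len + 1L
      if (sLo <= Ls && sHi > Ls) cuts <- c(cuts, sHi - (Ls + 1L))
    }
    bounds <- sort(unique(c(cuts, len - 1L)))
    o1 <- 0L
    pieces <- vector("list", length(bounds))
    for (p in seq_along(bounds)) {
      o2 <- bounds[p]
      qa <- (qs + o1 - 1L) %% Lq + 1L
      qb <- (qs + o2 - 1L) %% Lq + 1L
      if (strand == "+") {
        sa <- (ss + o1 - 1L) %% Ls + 1L
        sb <- (ss + o2 - 1L) %% Ls + 1L
      } else {
        sb <- (sHi - o1 - 1L) %% Ls + 1L
        sa <- (sHi - o2 - 1L) %% Ls + 1L
      }
      pieces[[p]] <- data.frame(q_start = qa, q_end = qb,
                                s_start = sa, s_end = sb,
                                strand = strand, length = o2 - o1 + 1L,
                                stringsAsFactors = FALSE)
      o1 <- o2 + 1L
    }
    rows[[r]] <- do.call(rbind, pieces)
  }
  do.call(rbind, rows)
}

#' Chain anchors into syntenic blocks
#'
#' Greedy colinear chaining per (query molecule, subject molecule, strand):
#' anchors sorted by query start join the current block while both the query
#' gap and the subject gap to the previous anchor are \code{<= maxGap} and
#' subject order advances in the strand-consistent direction. Blocks made
#' entirely of multi-mapping anchors and fully contained (on the query)
#' inside another block are dropped as repeat noise.
#'
#' @param anchors data.frame from [findAnchors()].
#' @param maxGap maximum joinable gap, bp.
#' @return data.frame of blocks: \code{q_mol}, \code{q_start}, \code{q_end},
#'   \code{s_mol}, \code{s_start}, \code{s_end}, \code{strand},
#'   \code{n_anchors}, \code{anchor_bp}.
#' @export
chainAnchors <- function(anchors, maxGap = 1000L) {
  maxGap <- stopifnot_scalar_int(maxGap, "maxGap", min = 0L)
  if (!nrow(anchors)) return(emptyBlockFrame())
  # multi-mapping: identical query interval appearing with several subject hits
  qkey <- paste(anchors$q_mol, anchors$q_start, anchors$q_end)
  multi <- qkey %in% qkey[duplicated(qkey)]
  blocks <- list()
  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$q_mol, anchors$s_mol, anchors$strand))
  for (idx in groups) {
    a <- anchors[idx, , drop = FALSE]
    m <- multi[idx]
    ord <- order(a$q_start, a$q_end)
    a <- a[ord, , drop = FALSE]; m <- m[ord]
    sgn <- if (a$strand[1L] == "+") 1L else -1L
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      data.frame(q_mol = cur$q_mol, q_start = cur$q_start, q_end = cur$q_end,
                 s_mol = cur$s_mol, s_start = cur$s_start, s_end = cur$s_end,
                 strand = cur$strand, n_anchors = cur$n, anchor_bp = cur$bp,
                 all_multi = cur$all_multi, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(a))) {
      joins <- FALSE
      if (!is.null(cur)) {
        qgap <- a$q_start[i] - cur$q_end - 1L
        sgap <- if (sgn > 0L) a$s_start[i] - cur$s_end - 1L
                else cur$s_start - a$s_end[i] - 1L
        joins <- qgap <= maxGap && qgap >= -maxGap &&
                 sgap <= maxGap && sgap >= -maxGap &&
                 a$q_end[i] > cur$q_end &&
                 (if (sgn > 0L) a$s_end[i] > cur$s_end
                  else a$s_start[i] < cur$s_start)
      }
      if (joins) {
        cur$q_end <- max(cur$q_end, a$q_end[i])
        if (sgn > 0L) cur$s_end <- max(cur$s_end, a$s_end[i])
        else cur$s_start <- min(cur$s_start, a$s_start[i])
        cur$n <- cur$n + 1L
        cur$bp <- cur$bp + a$length[i]
        cur$all_multi <- cur$all_multi && m[i]
      } else {
        blocks[[length(blocks) + 1L]] <- flush(cur)
        cur <- list(q_mol = a$q_mol[i], q_start = a$q_start[i],
                    q_end = a$q_end[i], s_mol = a$s_mol[i],
                    s_start = a$s_start[i], s_end = a$s_end[i],
                    strand = a$strand[i], n = 1L, bp = a$length[i],
                    all_multi = m[i])
      }
    }
    blocks[[length(blocks) + 1L]] <- flush(cur)
  }
  out <- do.call(rbind, blocks)
  # drop repeat-only blocks nested inside another block's query span
  if (any(out$all_multi)) {
    keep <- rep(TRUE, nrow(out))
    for (i in which(out$all_multi)) {
      inside <- out$q_mol == out$q_mol[i] & seq_len(nrow(out)) != i &
        out$q_start <= out$q_start[i] & out$q_end >= out$q_end[i]
      if (any(inside)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out$all_multi <- NULL
  out <- out[order(out$q_mol, out$q_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyBlockFrame <- function() {
  data.frame(q_mol = character(), q_start = integer(), q_end = integer(),
             s_mol = character(), s_start = integer(), s_end = integer(),
             strand = character(), n_anchors = integer(),
             anchor_bp = integer(), stringsAsFactors = FALSE)
}

emptySvFrame <- function() {
  data.frame(type = character(), molecule = character(), start = integer(),
             end = integer(), size = integer(), side = character(),
             stringsAsFactors = FALSE)
}

#' Call structural variants from syntenic blocks
#'
#' Classifies discordances between two genomes from their chained blocks.
#' Per query molecule, the colinear "mainline" is the heaviest increasing
#' run of blocks by subject coordinate (weighted longest increasing
#' subsequence, orientation taken from the strand majority). Then:
#' \itemize{
#'   \item a mainline block whose strand opposes the dominant orientation is
#'     an \code{inversion};
#'   \item a block off the mainline (subject order discordant, or on another
#'     subject molecule) is a \code{translocation}, or \code{trans_inv} when
#'     also strand-flipped;
#'   \item a gap between adjacent mainline blocks present on the query but
#'     not the subject is an \code{insertion}; present on the subject only,
#'     a \code{deletion}. Query gap spans already occupied by a
#'     translocated/inverted block are not double-counted.
#' }
#' Only variants strictly larger than \code{minSize} are reported
#' (a "greater than 1 kb" rule by default).
#'
#' When the query and subject assemblies are supplied, gaps wrapping a
#' circular query origin are analysed as well (a donor segment sitting just
#' after the origin would otherwise escape the insertion scan).
#'
#' @param blocks data.frame from [chainAnchors()].
#' @param minSize strict size threshold, bp.
#' @param slack maximum gap on the opposite genome for a clean
#'   insertion/deletion call, bp. The default matches the default anchor
#'   length: gaps shorter than one anchor cannot be resolved by exact
#'   matching.
#' @param qry,sbj optional [GenomeAssembly-class] objects; needed only for
#'   circular-origin gap analysis.
#' @return data.frame: \code{type} (insertion/deletion/inversion/
#'   translocation/trans_inv), \code{molecule}, \code{start}, \code{end}
#'   (query coordinates except deletions, which carry subject coordinates and
#'   \code{side = "subject"}; an origin-wrapping interval has
#'   \code{start > end}), \code{size}.
#' @export
callSVs <- function(blocks, minSize = 1000L, slack = 100L, qry = NULL,
                    sbj = NULL) {
  minSize <- stopifnot_scalar_int(minSize, "minSize", min = 1L)
  if (!nrow(blocks)) return(emptySvFrame())
  svs <- list()
  for (qm in unique(blocks$q_mol)) {
    b <- blocks[blocks$q_mol == qm, , drop = FALSE]
    b <- b[order(b$q_start), , drop = FALSE]
    # dominant subject molecule and orientation by aligned weight
    w <- b$q_end - b$q_start + 1L
    smain <- names(which.max(tapply(w, b$s_mol, sum)))
    offMol <- b$s_mol != smain
    for (i in which(offMol)) {
      svs[[length(svs) + 1L]] <- data.frame(
        type = "translocation", molecule = qm,
        start = b$q_start[i], end = b$q_end[i],
        size = b$q_end[i] - b$q_start[i] + 1L, side = "query",
        stringsAsFactors = FALSE)
    }
    b2 <- b[!offMol, , drop = FALSE]
    if (!nrow(b2)) next
    w2 <- b2$q_end - b2$q_start + 1L
    domStrand <- if (sum(w2[b2$strand == "+"]) >= sum(w2[b2$strand == "-"]))
      "+" else "-"
    sgn <- if (domStrand == "+") 1L else -1L
    key <- sgn * b2$s_start
    main <- weightedLIS(key, w2)
    inMain <- seq_len(nrow(b2)) %in% main
    for (i in which(!inMain)) {
      flip <- b2$strand[i] != domStrand
      svs[[length(svs) + 1L]] <- data.frame(
        type = if (flip) "trans_inv" else "translocation", molecule = qm,
        start = b2$q_start[i], end = b2$q_end[i],
        size = b2$q_end[i] - b2$q_start[i] + 1L, side = "query",
        stringsAsFactors = FALSE)
    }
    for (i in which(inMain & b2$strand != domStrand)) {
      svs[[length(svs) + 1L]] <- data.frame(
        type = "inversion", molecule = qm,
        start = b2$q_start[i], end = b2$q_end[i],
        size = b2$q_end[i] - b2$q_start[i] + 1L, side = "query",
        stringsAsFactors = FALSE)
    }
    # gap analysis between consecutive mainline blocks
    mb <- b2[sort(main), , drop = FALSE]
    if (nrow(mb) >= 2L) {
      other <- b[!(paste(b$q_start, b$q_end) %in%
                   paste(mb$q_start, mb$q_end)), , drop = FALSE]
      for (i in seq_len(nrow(mb) - 1L)) {
        qgap <- mb$q_start[i + 1L] - mb$q_end[i] - 1L
        sgap <- if (sgn > 0L) mb$s_start[i + 1L] - mb$s_end[i] - 1L
                else mb$s_start[i] - mb$s_end[i + 1L] - 1L
        # discount gap spans covered by displaced blocks (their home):
        # a translocation destination is not an insertion, and its source
        # is not a deletion
        if (qgap > 0L && nrow(other)) {
          gs <- mb$q_end[i] + 1L; ge <- mb$q_start[i + 1L] - 1L
          ov <- pmin(other$q_end, ge) - pmax(other$q_start, gs) + 1L
          qgap <- qgap - sum(pmax(ov, 0L))
        }
        if (sgap > 0L && nrow(other)) {
          ds0 <- if (sgn > 0L) mb$s_end[i] + 1L else mb$s_end[i + 1L] + 1L
          de0 <- if (sgn > 0L) mb$s_start[i + 1L] - 1L else mb$s_start[i] - 1L
          oth <- other[other$s_mol == mb$s_mol[i], , drop = FALSE]
          if (nrow(oth)) {
            ov <- pmin(oth$s_end, de0) - pmax(oth$s_start, ds0) + 1L
            sgap <- sgap - sum(pmax(ov, 0L))
          }
        }
        if (qgap > minSize && sgap <= slack) {
          svs[[length(svs) + 1L]] <- data.frame(
            type = "insertion", molecule = qm,
            start = mb$q_end[i] + 1L, end = mb$q_start[i + 1L] - 1L,
            size = qgap, side = "query", stringsAsFactors = FALSE)
        } else if (sgap > minSize && qgap <= slack) {
          ds <- if (sgn > 0L) mb$s_end[i] + 1L else mb$s_end[i + 1L] + 1L
          de <- if (sgn > 0L) mb$s_start[i + 1L] - 1L else mb$s_start[i] - 1L
          svs[[length(svs) + 1L]] <- data.frame(
            type = "deletion", molecule = mb$s_mol[i],
            start = ds, end = de, size = sgap, side = "subject",
            stringsAsFactors = FALSE)
        }
      }
    }
    # wrap gap across a circular query origin (dominant-plus case)
    if (!is.null(qry) && !is.null(sbj) && nrow(mb) >= 1L && sgn > 0L &&
        qm %in% names(molecules(qry)) &&
        topology(qry)[[qm]] == "circular") {
      Lq <- moleculeLengths(qry)[[qm]]
      last <- nrow(mb)
      qgap <- (Lq - mb$q_end[last]) + (mb$q_start[1L] - 1L)
      sm <- mb$s_mol[1L]
      if (sm %in% names(molecules(sbj))) {
        Ls <- moleculeLengths(sbj)[[sm]]
        sgap <- if (topology(sbj)[[sm]] == "circular")
          (mb$s_start[1L] - mb$s_end[last] - 1L) %% Ls
          else (Ls - mb$s_end[last]) + (mb$s_start[1L] - 1L)
        if (qgap > minSize && sgap <= slack) {
          svs[[length(svs) + 1L]] <- data.frame(
            type = "insertion", molecule = qm,
            start = mb$q_end[last] %% Lq + 1L,
            end = mb$q_start[1L] - 1L,
            size = qgap, side = "query", stringsAsFactors = FALSE)
        } else if (sgap > minSize && qgap <= slack) {
          svs[[length(svs) + 1L]] <- data.frame(
            type = "deletion", molecule = sm,
            start = mb$s_end[last] %% Ls + 1L,
            end = mb$s_start[1L] - 1L,
            size = sgap, side = "subject", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(svs)) return(emptySvFrame())
  out <- do.call(rbind, svs)
  out <- out[out$size > minSize, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# indices of the maximum-weight strictly increasing subsequence
weightedLIS <- function(key, weight) {
  n <- length(key)
  if (!n) return(integer())
  best <- weight
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (key[j] < key[i] && best[j] + weight[i] > best[i]) {
        best[i] <- best[j] + weight[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  path <- integer()
  while (!is.na(i)) { path <- c(i, path); i <- prev[i] }
  path
}

#' Extract a (possibly wrapping) substring from an assembly molecule
#'
#' Utility for pulling anchor or amplicon sequence; on circular molecules a
#' range whose end exceeds the molecule length wraps across the origin.
#'
#' @param x a [GenomeAssembly-class].
#' @param mol molecule id.
#' @param start,end 1-based inclusive coordinates (\code{end} may exceed the
#'   molecule length on circular molecules).
#' @return character sequence.
#' @export
moleculeSubseq <- function(x, mol, start, end) {
  seqc <- as.character(x@molecules[[mol]])
  L <- nchar(seqc)
  if (end <= L) return(substr(seqc, start, end))
  if (topology(x)[[mol]] != "circular")
    stop("range exceeds a linear molecule")
  paste0(substr(seqc, start, L), substr(seqc, 1L, end - L))
}
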