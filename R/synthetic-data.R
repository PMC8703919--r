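#' The 39-nt tandem repeat unit of the orf138 sterility gene family
#'
#' The 3' coding end of the Ogura-family CMS ORFs carries exact tandem
#' copies of this 39-nt unit: three copies in orf138, two in orf125, one in
#' orf112, so haplotypes differ by 39-bp steps.
#'
#' @return the 39-character unit sequence.
#' @examples
#' nchar(cmsRepeatUnit())  # 39
#' @export
cmsRepeatUnit <- function() "AAAGGGGAAATAGAGGGGAAAGAGGAAAAAAAAGAGGGG"

#' The OKB marker primer pair
#'
#' A single primer pair flanking the 39-nt repeat tract of the
#' orf138/orf125/orf112 family; amplicon sizes separate the three haplotypes
#' in 39-bp steps, and fertile (ORF-free) cytoplasm gives no product.
#'
#' @return a one-row primer-pair data.frame (\code{name}, \code{region},
#'   \code{fwd}, \code{rev}, \code{expected_bp}).
#' @export
okbPrimerPair <- function() {
  data.frame(name = "OKB", region = "cms_orf",
             fwd = "TATTTTCTCGGTCCATTTTCCACCTCTT",
             rev = "GAATTTCAGTATGGGTGGCTAGGCGTC",
             expected_bp = NA_integer_, stringsAsFactors = FALSE)
}

# body of the synthetic ORF scaffold: a fixed non-repetitive 96-codon
# sequence in which every codon contains a C (the repeat unit is C-free, so
# no spurious unit copy can overlap the body), with no stop codons and a
# final T so that minimal-edit gap placement against repeat-deleted
# derivatives stays codon-aligned
cmsOrfBody <- function() {
  paste0("TACATCCGCGTCTCTCAAGACCAACAGGCCACCCGCCTCTCTGCCCGTAGCGGCCAACGT",
         "CGTGCTGCGTCGACTAACCGGCTGTACACGACCCTCACGTTCTCCCAACAGCACGCTGCC",
         "ATCGGCCTTCCCCCCGGCACAGACACGAACGCTCCATCTTCAGGCCGCCCTCCGCACCGC",
         "GACCCGTCACTGCCACTCCATACACTGCAATACCCCCCTCATGCACGCACAAACCCAGCA",
         "CACCTTACGGACGTCCATCACCCGTCCATCCAGGCCGCACACGCGACT")
}

#' Build a synthetic CMS ORF with a chosen tandem copy number
#'
#' Returns an open reading frame (ATG ... stop) whose 3' coding end contains
#' exactly \code{copies} exact tandem copies of the 39-nt unit. The scaffold
#' is fixed, so constructs with different copy numbers differ only by whole
#' 39-nt units: 1 copy gives a 112-codon ORF, 2 give 125, 3 give 138
#' (stop codon excluded), mirroring orf112/orf125/orf138.
#'
#' @param copies integer in 1..3.
#' @return ORF sequence (character).
#' @examples
#' nchar(plantCmsOrf(1)) / 3 - 1  # 112 codons
#' nchar(plantCmsOrf(3)) - nchar(plantCmsOrf(1))  # 78
#' @export
plantCmsOrf <- function(copies) {
  copies <- stopifnot_scalar_int(copies, "copies", min = 1L)
  if (copies > 3L) stop("'copies' must be 1, 2 or 3")
  paste0("ATG", cmsOrfBody(), strrep(cmsRepeatUnit(), copies), "CATTGC", "TAA")
}

#' Build a CMS locus construct with OKB primer sites flanking the ORF
#'
#' Embeds [plantCmsOrf()] between the OKB forward site and the reverse
#' complement of the OKB reverse site, so in-silico PCR with
#' [okbPrimerPair()] yields amplicons whose sizes step by 39 bp per repeat
#' copy.
#'
#' @param copies integer in 0..3; 0 returns only the flanks with spacer (a
#'   fertile-like locus without the ORF is then better represented by simply
#'   omitting the construct).
#' @return locus sequence (character).
#' @export
cmsLocusConstruct <- function(copies) {
  copies <- stopifnot_scalar_int(copies, "copies", min = 1L)
  okb <- okbPrimerPair()
  paste0(okb$fwd, "CTCTCTCTCT", plantCmsOrf(copies), "AGAGAGAGAG",
         revComp(okb$rev))
}

# nine alien regions of the Ogura-type alloplasmic mitogenome, used as the
# generator's default planting plan (molecule, 1-based start, length, and
# the number of diagnostic markers allocated per region)
oguraRegionTable <- function() {
  data.frame(
    label = paste0("R", 1:9),
    molecule = c("MT1", "MT1", "MT1", "MT2", "MT2", "MT2", "MT2", "MT2", "MT2"),
    start = c(95L, 9983L, 15679L, 1501L, 7573L, 51431L, 65521L, 167906L, 175701L),
    length = c(1551L, 3808L, 2282L, 4239L, 3818L, 5457L, 1727L, 5916L, 6820L),
    markers = c(2L, 3L, 2L, 4L, 3L, 4L, 2L, 6L, 6L),
    stringsAsFactors = FALSE)
}

#' Configuration for a synthetic recipient/donor/hybrid trio
#'
#' Describes the study conditions the generator emulates: a circular
#' recipient mitogenome backbone, a donor genome that is a diverged copy of
#' part of that backbone plus unique segments, and a hybrid that is the
#' recipient backbone with the donor-unique segments inserted at known
#' positions (optionally split into two circles, with planted structural
#' variants). Defaults reproduce the Ogura-type alloplasmic situation: a
#' 221,811-bp backbone split into 71,998 + 185,431 bp circles carrying nine
#' donor segments at the reported coordinates (35,618 bp, 13.84%), the CMS
#' ORF construct (3 repeat copies) inside R8.
#'
#' @param backboneLength recipient backbone length, bp.
#' @param hybridMoleculeLengths named integer vector of hybrid molecule
#'   lengths (1 or 2 molecules), or \code{NULL} for a single circle sized
#'   \code{backboneLength + sum(insert lengths)}.
#' @param insertSpecs data.frame with columns \code{label}, \code{molecule},
#'   \code{start} (position of the segment in the hybrid; \code{NA} to
#'   auto-place), \code{length}. Zero-row for no inserts.
#' @param svSpecs data.frame with columns \code{type}
#'   (\code{"inversion"}/\code{"translocation"}) and \code{length}.
#' @param divergenceRate per-bp substitution rate between recipient-
#'   homologous and donor-homologous tracts, between 0 and 0.2.
#' @param donorBackboneFraction fraction of the recipient backbone present
#'   (diverged) in the donor, so shared/ambiguous tracts exist.
#' @param cmsCopies tandem copies of the 39-nt unit in the planted CMS ORF
#'   (0 = no ORF planted).
#' @param cmsRegion label of the insert that carries the CMS construct.
#' @param gc target GC content of random sequence (0.5 = uniform).
#' @param seed integer seed; one seed drives the whole generation.
#' @return a \code{TrioConfig} list.
#' @seealso [generateTrio()]
#' @export
trioConfig <- function(backboneLength = 221811L,
                       hybridMoleculeLengths = c(MT1 = 71998L, MT2 = 185431L),
                       insertSpecs = oguraRegionTable()[, c("label", "molecule",
                                                            "start", "length")],
                       svSpecs = data.frame(type = character(),
                                            length = integer()),
                       divergenceRate = 0.02,
                       donorBackboneFraction = 0.6,
                       cmsCopies = 3L,
                       cmsRegion = "R8",
                       gc = 0.5,
                       seed = 1L) {
  backboneLength <- stopifnot_scalar_int(backboneLength, "backboneLength", 1L)
  if (divergenceRate < 0 || divergenceRate > 0.2)
    stop("'divergenceRate' must be in [0, 0.2]")
  if (donorBackboneFraction <= 0 || donorBackboneFraction > 1)
    stop("'donorBackboneFraction' must be in (0, 1]")
  if (!is.data.frame(insertSpecs))
    stop("'insertSpecs' must be a data.frame")
  ins <- insertSpecs
  if (nrow(ins)) {
    if (is.null(ins$label)) ins$label <- paste0("R", seq_len(nrow(ins)))
    if (is.null(ins$molecule)) ins$molecule <- "MT1"
    if (is.null(ins$start)) ins$start <- NA_integer_
    ins$start <- as.integer(ins$start)
    ins$length <- as.integer(ins$length)
    if (any(ins$length < 1L)) stop("insert lengths must be >= 1")
    if (backboneLength < 10L * max(ins$length))
      stop("backboneLength must be >= 10x the largest insert")
  }
  cmsCopies <- stopifnot_scalar_int(cmsCopies, "cmsCopies", 0L)
  if (cmsCopies > 3L) stop("'cmsCopies' must be in 0..3")
  if (cmsCopies > 0L && nrow(ins) && !cmsRegion %in% ins$label)
    stop(sprintf("cmsRegion '%s' is not an insert label", cmsRegion))
  if (!is.null(hybridMoleculeLengths)) {
    if (length(hybridMoleculeLengths) > 2L)
      stop("at most two hybrid molecules are supported")
    if (is.null(names(hybridMoleculeLengths)))
      names(hybridMoleculeLengths) <- paste0("MT", seq_along(hybridMoleculeLengths))
  }
  structure(list(backboneLength = backboneLength,
                 hybridMoleculeLengths = hybridMoleculeLengths,
                 insertSpecs = ins,
                 svSpecs = svSpecs,
                 divergenceRate = divergenceRate,
                 donorBackboneFraction = donorBackboneFraction,
                 cmsCopies = cmsCopies,
                 cmsRegion = cmsRegion,
                 gc = gc,
                 seed = as.integer(seed)),
            class = "TrioConfig")
}

baseProbs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                            T = (1 - gc) / 2)

# substitute each position independently with probability r, always to a
# different base
divergeSequence <- function(seqc, r) {
  if (r <= 0) return(seqc)
  ch <- strsplit(seqc, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < r)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L), "")
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

# does 'insert' share any exact k-mer (either strand) with 'backbone'?
sharesKmer <- function(insert, backbone, k = 31L) {
  nrow(mem_anchors_cpp(backbone, insert, k)) > 0L ||
    nrow(mem_anchors_cpp(backbone, revComp(insert), k)) > 0L
}

#' Generate a recipient/donor/hybrid genome trio with known ground truth
#'
#' Emulates an alloplasmic (cybrid) mitogenome: the recipient is a random
#' circular backbone; the donor carries a diverged copy of part of that
#' backbone plus unique segments; the hybrid is the recipient backbone with
#' the donor-unique segments inserted at exactly known positions, optionally
#' split into two circles, with planted inversions/translocations. Donor
#' segments share no 31-mer with the recipient (rejection sampling) and
#' their first/last bases differ from the displaced backbone neighbours, so
#' planted truth boundaries are exactly recoverable by exact-match
#' attribution.
#'
#' @param cfg a [trioConfig()].
#' @return list with elements \code{recipient}, \code{donor}, \code{hybrid}
#'   ([GenomeAssembly-class]), \code{truth} ([TrioTruth-class]) and
#'   \code{manifest} (the config plus realized layout, serializable to
#'   JSON).
#' @examples
#' trio <- generateTrio(trioConfig(backboneLength = 5000,
#'   hybridMoleculeLengths = NULL,
#'   insertSpecs = data.frame(label = "R1", molecule = "MT1",
#'                            start = 2001, length = 400),
#'   cmsCopies = 0, seed = 7))
#' donorSegments(trio$truth)
#' @export
generateTrio <- function(cfg) {
  stopifnot(inherits(cfg, "TrioConfig"))
  withSeed(cfg$seed, .generateTrio(cfg))
}

.generateTrio <- function(cfg) {
  prob <- baseProbs(cfg$gc)
  backbone <- randomDna(cfg$backboneLength, prob = prob)
  recipient <- GenomeAssembly("recipient", c(R_MT1 = backbone),
                              topology = "circular")
  ins <- cfg$insertSpecs
  # molecule layout: consecutive arcs of the backbone
  if (is.null(cfg$hybridMoleculeLengths)) {
    molLens <- stats::setNames(cfg$backboneLength +
                                 sum(if (nrow(ins)) ins$length else 0L), "MT1")
    if (nrow(ins)) ins$molecule <- "MT1"
  } else {
    molLens <- cfg$hybridMoleculeLengths
  }
  molNames <- names(molLens)
  insBpPerMol <- vapply(molNames, function(m)
    sum(ins$length[ins$molecule == m]), integer(1L))
  backAlloc <- as.integer(molLens) - insBpPerMol
  if (any(backAlloc < 1L))
    stop("hybrid molecule lengths leave no backbone on some molecule")
  if (sum(backAlloc) != cfg$backboneLength)
    stop(sprintf("molecule lengths minus inserts (%d) must equal backboneLength (%d)",
                 sum(backAlloc), cfg$backboneLength))
  arcEnd <- cumsum(backAlloc)
  arcStart <- c(1L, utils::head(arcEnd, -1L) + 1L)

  # auto-place inserts lacking a start: spread evenly along the molecule
  for (m in molNames) {
    sel <- which(ins$molecule == m)
    if (!length(sel)) next
    na <- sel[is.na(ins$start[sel])]
    if (length(na)) {
      slots <- floor(seq(0.15, 0.85, length.out = length(na)) * molLens[[m]])
      ins$start[na] <- as.integer(slots)
    }
    o <- sel[order(ins$start[sel])]
    if (any(ins$start[o] + ins$length[o] - 1L > molLens[[m]]) ||
        any(ins$start[o] < 1L))
      stop(sprintf("insert out of bounds on molecule %s", m))
    if (length(o) > 1L &&
        any(ins$start[o][-1L] <= (ins$start[o] + ins$length[o] - 1L)[-length(o)]))
      stop(sprintf("overlapping inserts on molecule %s", m))
  }

  # generate insert sequences under the recoverability constraints
  insSeq <- character(nrow(ins))
  if (nrow(ins)) {
    arcs <- stats::setNames(substring(backbone, arcStart, arcEnd), molNames)
    for (i in order(match(ins$molecule, molNames), ins$start)) {
      m <- ins$molecule[i]
      sel <- which(ins$molecule == m)
      before <- sel[ins$start[sel] < ins$start[i]]
      arcpos <- ins$start[i] - sum(ins$length[before])  # backbone offset in arc
      arc <- arcs[[m]]
      leftChar <- if (arcpos > 1L) substr(arc, arcpos - 1L, arcpos - 1L)
                  else substr(arc, nchar(arc), nchar(arc))
      rightChar <- if (arcpos <= nchar(arc)) substr(arc, arcpos, arcpos)
                   else substr(arc, 1L, 1L)
      core <- if (cfg$cmsCopies > 0L && identical(ins$label[i], cfg$cmsRegion))
        cmsLocusConstruct(cfg$cmsCopies) else ""
      if (nchar(core) > ins$length[i] - 2L)
        stop(sprintf("insert %s too short for the CMS construct", ins$label[i]))
      ok <- FALSE
      for (try in seq_len(50L)) {
        pad <- ins$length[i] - nchar(core)
        lpad <- pad %/% 2L
        s <- paste0(randomDna(lpad, prob), core, randomDna(pad - lpad, prob))
        if (substr(s, 1L, 1L) == rightChar) next
        if (substr(s, nchar(s), nchar(s)) == leftChar) next
        if (sharesKmer(s, backbone)) next
        ok <- TRUE
        break
      }
      if (!ok) stop(sprintf("could not generate insert %s under the uniqueness constraints",
                            ins$label[i]))
      insSeq[i] <- s
    }
  }

  # assemble hybrid molecules and truth intervals
  hybSeqs <- character(length(molNames))
  segRows <- list()
  cmsRow <- NULL
  for (mi in seq_along(molNames)) {
    m <- molNames[mi]
    arc <- substring(backbone, arcStart[mi], arcEnd[mi])
    sel <- which(ins$molecule == m)
    sel <- sel[order(ins$start[sel])]
    pieces <- character()
    cursor <- 1L   # next backbone (arc) offset to consume
    outpos <- 1L
    for (i in sel) {
      before <- sel[ins$start[sel] < ins$start[i]]
      arcpos <- ins$start[i] - sum(ins$length[before])
      if (arcpos > cursor)
        pieces <- c(pieces, substring(arc, cursor, arcpos - 1L))
      pieces <- c(pieces, insSeq[i])
      segRows[[length(segRows) + 1L]] <- data.frame(
        molecule = m, start = ins$start[i],
        end = ins$start[i] + ins$length[i] - 1L,
        label = ins$label[i], stringsAsFactors = FALSE)
      if (cfg$cmsCopies > 0L && identical(ins$label[i], cfg$cmsRegion)) {
        core <- cmsLocusConstruct(cfg$cmsCopies)
        pad <- ins$length[i] - nchar(core)
        off <- pad %/% 2L
        orfOff <- nchar(okbPrimerPair()$fwd) + 10L  # flank + spacer
        cmsRow <- data.frame(molecule = m,
                             start = ins$start[i] + off + orfOff,
                             end = ins$start[i] + off + orfOff +
                               nchar(plantCmsOrf(cfg$cmsCopies)) - 1L,
                             stringsAsFactors = FALSE)
      }
      cursor <- arcpos
    }
    pieces <- c(pieces, substring(arc, cursor, nchar(arc)))
    hybSeqs[mi] <- paste(pieces, collapse = "")
    stopifnot(nchar(hybSeqs[mi]) == molLens[[mi]])
  }

  segs <- if (length(segRows)) do.call(rbind, segRows) else
    data.frame(molecule = character(), start = integer(), end = integer(),
               label = character(), stringsAsFactors = FALSE)

  # plant structural variants on backbone-only hybrid sequence
  svs <- data.frame(type = character(), molecule = character(),
                    start = integer(), end = integer(), size = integer(),
                    src_start = integer(), src_end = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(cfg$svSpecs)) {
    for (v in seq_len(nrow(cfg$svSpecs))) {
      type <- cfg$svSpecs$type[v]
      L <- as.integer(cfg$svSpecs$length[v])
      mi <- which.max(backAlloc)
      m <- molNames[mi]
      planted <- plantOneSV(hybSeqs[mi], type, L, m, segs, cmsRow, svs)
      hybSeqs[mi] <- planted$seq
      segs <- planted$segs
      cmsRow <- planted$cms
      svs <- planted$svs
    }
  }

  hybrid <- GenomeAssembly("hybrid", stats::setNames(hybSeqs, molNames),
                           topology = "circular")

  # donor: diverged backbone subset with the unique segments inserted
  subLen <- max(1000L, round(cfg$donorBackboneFraction * cfg$backboneLength))
  subLen <- min(subLen, cfg$backboneLength)
  donorBack <- divergeSequence(substring(backbone, 1L, subLen),
                               cfg$divergenceRate)
  donorSeq <- donorBack
  if (nrow(ins)) {
    at <- sort(sample.int(nchar(donorBack) - 1L, nrow(ins), replace = FALSE))
    parts <- character()
    cur <- 1L
    for (i in seq_len(nrow(ins))) {
      parts <- c(parts, substring(donorBack, cur, at[i]), insSeq[i])
      cur <- at[i] + 1L
    }
    parts <- c(parts, substring(donorBack, cur, nchar(donorBack)))
    donorSeq <- paste(parts, collapse = "")
  }
  donor <- GenomeAssembly("donor", c(D_MT1 = donorSeq), topology = "circular")

  truth <- new("TrioTruth",
    donorSegments = if (nrow(segs))
      GenomicRanges::GRanges(segs$molecule,
                             IRanges::IRanges(segs$start, segs$end),
                             label = segs$label)
      else GenomicRanges::GRanges(label = character()),
    svs = svs,
    cmsOrf = if (!is.null(cmsRow))
      GenomicRanges::GRanges(cmsRow$molecule,
                             IRanges::IRanges(cmsRow$start, cmsRow$end))
      else GenomicRanges::GRanges(),
    cmsCopies = cfg$cmsCopies)

  manifest <- list(config = unclass(cfg)[setdiff(names(cfg), "insertSpecs")],
                   insertSpecs = cfg$insertSpecs,
                   moleculeLengths = as.list(molLens),
                   backboneArcs = data.frame(molecule = molNames,
                                             start = arcStart, end = arcEnd),
                   note = paste("two-circle split is an arbitrary cut of the",
                                "backbone, not a repeat-mediated recombination"))
  list(recipient = recipient, donor = donor, hybrid = hybrid, truth = truth,
       manifest = manifest)
}

# plant one inversion or translocation on backbone-only sequence of one
# molecule, keeping truth coordinates (donor segments, CMS ORF, previously
# planted SVs) consistent
plantOneSV <- function(seqc, type, L, mol, segs, cmsRow, svs, margin = 300L) {
  n <- nchar(seqc)
  avoid <- rbind(segs[segs$molecule == mol, c("molecule", "start", "end")],
                 svs[svs$molecule == mol, c("molecule", "start", "end")])
  blocked <- IRanges::IRanges(integer(), integer())
  if (nrow(avoid))
    blocked <- IRanges::IRanges(pmax(avoid$start - margin, 1L),
                                pmin(avoid$end + margin, n))
  free <- IRanges::setdiff(IRanges::IRanges(margin, n - margin), blocked)
  free <- free[IRanges::width(free) >= L + 2L * margin]
  if (!length(free)) stop("no room to plant a structural variant")
  fi <- sample.int(length(free), 1L)
  a <- IRanges::start(free)[fi] + margin +
    sample.int(max(IRanges::width(free)[fi] - L - 2L * margin, 1L), 1L) - 1L
  b <- a + L - 1L
  if (type == "inversion") {
    newseq <- paste0(substring(seqc, 1L, a - 1L),
                     revComp(substring(seqc, a, b)),
                     substring(seqc, b + 1L, n))
    rec <- data.frame(type = "inversion", molecule = mol, start = a, end = b,
                      size = L, src_start = a, src_end = b,
                      stringsAsFactors = FALSE)
    return(list(seq = newseq, segs = segs, cms = cmsRow,
                svs = rbind(svs, rec)))
  }
  if (type != "translocation") stop(sprintf("unknown SV type '%s'", type))
  seg <- substring(seqc, a, b)
  rest <- paste0(substring(seqc, 1L, a - 1L), substring(seqc, b + 1L, n))
  shiftAfter <- function(df, cut, delta) {
    if (is.null(df) || !nrow(df)) return(df)
    hit <- df$molecule == mol & df$start > cut
    df$start[hit] <- df$start[hit] + delta
    df$end[hit] <- df$end[hit] + delta
    df
  }
  segs <- shiftAfter(segs, b, -L)
  cmsRow <- shiftAfter(cmsRow, b, -L)
  svs <- shiftAfter(svs, b, -L)
  # destination: a free position in the excised coordinate system, far from
  # the source, the truth segments and earlier SVs
  nr <- nchar(rest)
  avoid2 <- rbind(segs[segs$molecule == mol, c("start", "end")],
                  svs[svs$molecule == mol, c("start", "end")])
  blocked2 <- IRanges::IRanges(integer(), integer())
  if (nrow(avoid2))
    blocked2 <- IRanges::IRanges(pmax(avoid2$start - margin, 1L),
                                 pmin(avoid2$end + margin, nr))
  # keep the destination well clear of the source: a move shorter than the
  # chaining gap is locally indistinguishable from a small indel
  sep <- 2000L + 2L * margin
  blocked2 <- c(blocked2, IRanges::IRanges(max(a - sep, 1L),
                                           min(a + L + sep, nr)))
  free2 <- IRanges::setdiff(IRanges::IRanges(margin, nr - margin), blocked2)
  free2 <- free2[IRanges::width(free2) >= 2L]
  if (!length(free2)) stop("no room to reinsert a translocated segment")
  fi <- sample.int(length(free2), 1L)
  cpos <- IRanges::start(free2)[fi] +
    sample.int(IRanges::width(free2)[fi], 1L) - 1L
  newseq <- paste0(substring(rest, 1L, cpos), seg,
                   substring(rest, cpos + 1L, nr))
  segs <- shiftAfter(segs, cpos, L)
  cmsRow <- shiftAfter(cmsRow, cpos, L)
  svs <- shiftAfter(svs, cpos, L)
  rec <- data.frame(type = "translocation", molecule = mol,
                    start = cpos + 1L, end = cpos + L, size = L,
                    src_start = a, src_end = b, stringsAsFactors = FALSE)
  list(seq = newseq, segs = segs, cms = cmsRow, svs = rbind(svs, rec))
}

#' Derive a hybrid retaining only a subset of the planted donor segments
#'
#' Builds a "partial alloplasmic" genome from a generated trio by excising
#' the non-kept donor segments from the hybrid sequence, the way a further
#' recombination event would leave only part of the alien cytoplasm. Kept
#' segment sequence is untouched; coordinates shift by the excised widths.
#'
#' @param trio result of [generateTrio()].
#' @param keep character vector of truth segment labels to retain.
#' @param name assembly name for the derived hybrid.
#' @return list with \code{hybrid} ([GenomeAssembly-class]) and \code{truth}
#'   ([TrioTruth-class]) for the derived genome.
#' @export
subsetHybrid <- function(trio, keep, name = "hybrid_subset") {
  segs <- donorSegments(trio$truth)
  stopifnot(all(keep %in% segs$label))
  drop <- segs[!segs$label %in% keep]
  seqs <- character()
  newRows <- list()
  for (m in names(molecules(trio$hybrid))) {
    seqc <- as.character(molecules(trio$hybrid)[[m]])
    dm <- drop[GenomicRanges::seqnames(drop) == m]
    dm <- dm[order(BiocGenerics::start(dm))]
    km <- segs[segs$label %in% keep & GenomicRanges::seqnames(segs) == m]
    if (length(dm)) {
      keepRanges <- IRanges::setdiff(IRanges::IRanges(1L, nchar(seqc)),
                                     IRanges::IRanges(BiocGenerics::start(dm),
                                                      BiocGenerics::end(dm)))
      seqNew <- paste(substring(seqc, IRanges::start(keepRanges),
                                IRanges::end(keepRanges)), collapse = "")
    } else seqNew <- seqc
    if (length(km)) {
      for (i in seq_along(km)) {
        s <- BiocGenerics::start(km)[i]
        shift <- sum(BiocGenerics::width(dm)[BiocGenerics::end(dm) < s])
        newRows[[length(newRows) + 1L]] <- data.frame(
          molecule = m, start = s - shift,
          end = BiocGenerics::end(km)[i] - shift,
          label = km$label[i], stringsAsFactors = FALSE)
      }
    }
    seqs[m] <- seqNew
  }
  nr <- if (length(newRows)) do.call(rbind, newRows) else
    data.frame(molecule = character(), start = integer(), end = integer(),
               label = character(), stringsAsFactors = FALSE)
  truth <- new("TrioTruth",
    donorSegments = if (nrow(nr))
      GenomicRanges::GRanges(nr$molecule, IRanges::IRanges(nr$start, nr$end),
                             label = nr$label)
      else GenomicRanges::GRanges(label = character()),
    svs = plantedSVs(trio$truth)[0L, , drop = FALSE],
    cmsOrf = GenomicRanges::GRanges(),
    cmsCopies = if (length(cmsOrfRange(trio$truth)) &&
                    any(segs$label[segs$label %in% keep] ==
                        trioCmsLabel(trio))) cmsCopies(trio$truth) else 0L)
  list(hybrid = GenomeAssembly(name, seqs,
                               topology = topology(trio$hybrid)),
       truth = truth)
}

trioCmsLabel <- function(trio) {
  cms <- cmsOrfRange(trio$truth)
  if (!length(cms)) return(NA_character_)
  segs <- donorSegments(trio$truth)
  hit <- GenomicRanges::findOverlaps(cms, segs)
  if (length(hit)) segs$label[S4Vectors::subjectHits(hit)[1L]] else NA_character_
}

#' Write a trio's ground truth to BED + JSON
#'
#' Donor segments go to \code{truth.bed} (0-based half-open, label in the
#' name column); structural variants, the CMS ORF interval and copy count go
#' to \code{truth.json}.
#'
#' @param truth a [TrioTruth-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @seealso [readTruth()]
#' @export
writeTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, "truth.bed")
  json <- file.path(dir, "truth.json")
  writeBedRegions(donorSegments(truth), bed)
  cms <- cmsOrfRange(truth)
  jsonlite::write_json(list(
    svs = plantedSVs(truth),
    cms_orf = if (length(cms)) list(
      molecule = as.character(GenomicRanges::seqnames(cms))[1L],
      start = BiocGenerics::start(cms)[1L],
      end = BiocGenerics::end(cms)[1L]) else NULL,
    cms_copies = cmsCopies(truth)),
    json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(bed = bed, json = json))
}

#' Read a trio's ground truth back from BED + JSON
#'
#' @param dir directory written by [writeTruth()].
#' @return a [TrioTruth-class].
#' @export
readTruth <- function(dir) {
  segs <- readBedRegions(file.path(dir, "truth.bed"))
  j <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  svs <- if (is.data.frame(j$svs)) j$svs else
    data.frame(type = character(), molecule = character(), start = integer(),
               end = integer(), size = integer(), src_start = integer(),
               src_end = integer(), stringsAsFactors = FALSE)
  cms <- if (!is.null(j$cms_orf))
    GenomicRanges::GRanges(j$cms_orf$molecule,
                           IRanges::IRanges(j$cms_orf$start, j$cms_orf$end))
    else GenomicRanges::GRanges()
  new("TrioTruth", donorSegments = segs, svs = svs, cmsOrf = cms,
      cmsCopies = as.integer(j$cms_copies))
}
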