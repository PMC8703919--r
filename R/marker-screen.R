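#' Design region-diagnostic primer pairs inside alien regions
#'
#' For each requested region the amplicons tile the region evenly; both
#' primers sit fully inside the region, and neither primer nor its reverse
#' complement occurs anywhere in the recipient genome (scanned across
#' circular origins), so a product diagnoses presence of donor-derived
#' sequence. Primer placement is position-driven with a fixed length;
#' thermodynamics are out of scope. When the tiling position fails the
#' uniqueness check the start slides forward deterministically, so a panel
#' is reproducible given the same inputs and seed.
#'
#' @param report [AlloplasmReport-class] for the hybrid.
#' @param hybrid,recipient [GenomeAssembly-class] objects.
#' @param perRegionCounts named integer vector, markers requested per region
#'   label (names must be report labels; regions omitted get none).
#' @param primerLen primer length (18-30).
#' @param maxAmplicon maximum amplicon size, bp.
#' @param seed integer; kept for provenance (placement itself is
#'   deterministic).
#' @return data.frame panel: \code{name}, \code{region}, \code{fwd},
#'   \code{rev}, \code{expected_bp}.
#' @export
designPanel <- function(report, hybrid, recipient, perRegionCounts,
                        primerLen = 20L, maxAmplicon = 2000L, seed = 1L) {
  primerLen <- stopifnot_scalar_int(primerLen, "primerLen", 18L)
  if (primerLen > 30L) stop("'primerLen' must be 18-30")
  regions <- alienRegions(report)
  bad <- setdiff(names(perRegionCounts), regions$label)
  if (length(bad))
    stop(sprintf("unknown region label(s): %s", paste(bad, collapse = ", ")))
  recSeqs <- vapply(seq_along(molecules(recipient)), function(i) {
    s <- as.character(molecules(recipient)[[i]])
    if (topology(recipient)[i] == "circular")
      paste0(s, substr(s, 1L, primerLen - 1L)) else s
  }, "")
  occursInRecipient <- function(p) {
    rc <- revComp(p)
    any(vapply(recSeqs, function(s)
      grepl(p, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), logical(1L)))
  }
  rows <- list()
  for (lab in names(perRegionCounts)) {
    m <- as.integer(perRegionCounts[[lab]])
    if (m < 1L) next
    i <- which(regions$label == lab)[1L]
    mol <- as.character(GenomicRanges::seqnames(regions))[i]
    rs <- BiocGenerics::start(regions)[i]
    re <- BiocGenerics::end(regions)[i]
    rw <- re - rs + 1L
    sub <- floor(rw / m)
    amp <- min(maxAmplicon, max(2L * primerLen + 40L, min(sub - 20L, 500L)))
    if (sub < amp + 10L)
      stop(sprintf("region %s (%d bp) is too short for %d marker(s)", lab, rw, m))
    regionSeq <- moleculeSubseq(hybrid, mol, rs, re)
    for (k in seq_len(m)) {
      base <- (k - 1L) * sub + 1L
      placed <- FALSE
      for (off in seq(0L, sub - amp - 1L, by = 7L)) {
        p <- base + off
        fwd <- substr(regionSeq, p, p + primerLen - 1L)
        rev <- revComp(substr(regionSeq, p + amp - primerLen, p + amp - 1L))
        if (grepl("N", fwd) || grepl("N", rev)) next
        if (occursInRecipient(fwd) || occursInRecipient(rev)) next
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("%s-%d", lab, k), region = lab, fwd = fwd, rev = rev,
          expected_bp = amp, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place marker %d in region %s", k, lab))
    }
  }
  if (!length(rows))
    return(data.frame(name = character(), region = character(),
                      fwd = character(), rev = character(),
                      expected_bp = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Predict PCR amplification of a primer pair on a genome
#'
#' A product is called wherever the forward primer matches the plus strand
#' and the reverse primer matches the minus strand downstream within
#' \code{maxAmplicon} bp; circular molecules are scanned across the origin.
#' Product size runs from the forward primer's 5' end to the reverse
#' primer's 5' end, inclusive. Exactly one product genome-wide gives
#' \code{present = TRUE}; multiple products are flagged ambiguous
#' (\code{present = FALSE}, \code{n_products >= 2}), the in-silico analogue
#' of a multi-band gel. The inverted orientation (primer sites on a
#' reverse-complemented tract) is detected as well.
#'
#' @param genome a [GenomeAssembly-class].
#' @param pair one-row primer data.frame (\code{fwd}, \code{rev}, optionally
#'   \code{name}).
#' @param maxAmplicon maximum product size, bp.
#' @param maxMismatch allowed mismatches per primer (default 0 = exact
#'   annealing; when positive, the 3'-terminal base must still match).
#' @return list: \code{marker}, \code{genome}, \code{present},
#'   \code{product_bp}, \code{n_products}, and for a unique product its
#'   \code{molecule}, \code{start}, \code{end} (end may wrap past the
#'   molecule length on circular molecules) and \code{amplicon} sequence.
#' @examples
#' g <- GenomeAssembly("t", c(m = paste0("GGGG", "ACGTACGTACGTACGTAC",
#'   strrep("T", 50), revComp("GGCTTGCATGCATGCATG"), "AAAA")))
#' insilicoPCR(g, data.frame(fwd = "ACGTACGTACGTACGTAC",
#'                           rev = "GGCTTGCATGCATGCATG"))$product_bp
#' @export
insilicoPCR <- function(genome, pair, maxAmplicon = 2000L, maxMismatch = 0L) {
  fwd <- toupper(pair$fwd[1L]); rev <- toupper(pair$rev[1L])
  products <- list()
  for (i in seq_along(molecules(genome))) {
    m <- names(molecules(genome))[i]
    seqc <- as.character(molecules(genome)[[i]])
    L <- nchar(seqc)
    circ <- topology(genome)[i] == "circular"
    tmpl <- if (circ) paste0(seqc, substr(seqc, 1L, min(maxAmplicon, L)))
            else seqc
    for (orient in c("fr", "rf")) {
      # "fr": fwd on plus strand, rev on minus; "rf" catches the pair
      # sitting on an inverted tract
      p1 <- if (orient == "fr") fwd else rev
      p2 <- if (orient == "fr") rev else fwd
      s1 <- primerSites(tmpl, p1, maxMismatch)
      s2 <- primerSites(tmpl, revComp(p2), maxMismatch, threePrimeLeft = TRUE)
      if (!length(s1) || !length(s2)) next
      for (f in s1) {
        if (circ && f > L) next  # wrapped duplicate start
        hits <- s2[s2 >= f & (s2 + nchar(p2) - 1L) - f + 1L <= maxAmplicon &
                     s2 + nchar(p2) - 1L > f + nchar(p1) - 1L]
        for (r in hits) {
          products[[length(products) + 1L]] <- list(
            molecule = m, start = f, end = r + nchar(p2) - 1L,
            size = r + nchar(p2) - 1L - f + 1L)
        }
      }
    }
  }
  # deduplicate identical spans found in both orientations
  if (length(products)) {
    key <- vapply(products, function(p)
      paste(p$molecule, p$start, p$end), "")
    products <- products[!duplicated(key)]
  }
  n <- length(products)
  out <- list(marker = if (!is.null(pair$name)) pair$name[1L] else NA_character_,
              genome = assemblyName(genome),
              present = n == 1L,
              product_bp = if (n == 1L) products[[1L]]$size else NA_integer_,
              n_products = n)
  if (n == 1L) {
    p <- products[[1L]]
    out$molecule <- p$molecule
    out$start <- p$start
    out$end <- p$end
    out$amplicon <- moleculeSubseq(genome, p$molecule, p$start, p$end)
  }
  out
}

primerSites <- function(tmpl, pat, maxMismatch, threePrimeLeft = FALSE) {
  if (maxMismatch == 0L) {
    h <- gregexpr(pat, tmpl, fixed = TRUE)[[1L]]
    return(if (h[1L] == -1L) integer() else as.integer(h))
  }
  if (threePrimeLeft) {
    # pattern is the revcomp of a primer: its 3'-terminal base is the first
    # character, so anchor that end instead
    hits <- approx_sites_cpp(revCharStr(tmpl), revCharStr(pat), maxMismatch)
    if (!length(hits)) return(integer())
    return(sort(nchar(tmpl) - (hits + nchar(pat) - 1L) + 1L))
  }
  as.integer(approx_sites_cpp(tmpl, pat, maxMismatch))
}

revCharStr <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                collapse = "")

#' Run a marker panel against one genome
#'
#' @param genome a [GenomeAssembly-class].
#' @param panel data.frame from [designPanel()].
#' @param maxAmplicon,maxMismatch passed to [insilicoPCR()].
#' @return data.frame of amplicon calls: \code{marker}, \code{region},
#'   \code{genome}, \code{present}, \code{product_bp}, \code{n_products}.
#' @export
screenPanel <- function(genome, panel, maxAmplicon = 2000L, maxMismatch = 0L) {
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    r <- insilicoPCR(genome, panel[i, , drop = FALSE],
                     maxAmplicon = maxAmplicon, maxMismatch = maxMismatch)
    data.frame(marker = panel$name[i], region = panel$region[i],
               genome = r$genome, present = r$present,
               product_bp = if (is.null(r$product_bp)) NA_integer_ else
                 r$product_bp,
               n_products = r$n_products, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify a material's cytotype from its marker calls
#'
#' No positive marker = \code{normal} cytoplasm; all positive =
#' \code{full_alloplasmic}; anything in between = \code{partial_alloplasmic}
#' (a line retaining only part of the alien cytoplasm).
#'
#' @param calls data.frame from [screenPanel()] (one row per panel marker).
#' @param panel the panel the calls came from; used to verify completeness.
#' @return list: \code{material}, \code{class}, \code{positive_count},
#'   \code{positive_regions}, \code{pattern} (named logical vector).
#' @export
classifyCytotype <- function(calls, panel) {
  missing <- setdiff(panel$name, calls$marker)
  if (length(missing))
    stop(sprintf("missing call(s) for marker(s): %s",
                 paste(missing, collapse = ", ")))
  calls <- calls[match(panel$name, calls$marker), , drop = FALSE]
  pos <- sum(calls$present)
  cls <- if (pos == 0L) "normal"
         else if (pos == nrow(panel)) "full_alloplasmic"
         else "partial_alloplasmic"
  list(material = calls$genome[1L],
       class = cls,
       positive_count = pos,
       positive_regions = sort(unique(calls$region[calls$present])),
       pattern = stats::setNames(calls$present, calls$marker))
}
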