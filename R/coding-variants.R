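#' Classify a codon change
#'
#' Translates both codons with the standard genetic code (plant mitochondria
#' use it; RNA editing is not modelled) and classifies the change:
#' same residue = \code{synonymous}; different residue = \code{missense};
#' stop gained = \code{nonsense}. A lost stop is reported as missense.
#'
#' @param refCodon,altCodon 3-letter codons over ACGT.
#' @return list with \code{effect}, \code{refAa}, \code{altAa}.
#' @examples
#' annotateEffect("AAA", "AAG")  # synonymous K/K
#' annotateEffect("TGG", "TGA")  # nonsense
#' @export
annotateEffect <- function(refCodon, altCodon) {
  refCodon <- toupper(refCodon); altCodon <- toupper(altCodon)
  for (cd in c(refCodon, altCodon))
    if (nchar(cd) != 3L || grepl("[^ACGT]", cd))
      stop(sprintf("not a valid codon: '%s'", cd))
  code <- Biostrings::GENETIC_CODE
  refAa <- unname(code[refCodon])
  altAa <- unname(code[altCodon])
  effect <- if (refAa == altAa) "synonymous"
    else if (altAa == "*") "nonsense"
    else "missense"
  list(effect = effect, refAa = refAa, altAa = altAa)
}

variantRecord <- function(gene, pos, refNt, altNt, codonIndex, refAa, altAa,
                          effect, codonEnd = codonIndex) {
  data.frame(gene = gene, cds_pos = as.integer(pos), ref_nt = refNt,
             alt_nt = altNt, codon_index = as.integer(codonIndex),
             codon_end = as.integer(codonEnd), ref_aa = refAa,
             alt_aa = altAa, effect = effect, stringsAsFactors = FALSE)
}

emptyVariantFrame <- function() {
  variantRecord(character(), integer(), character(), character(), integer(),
                character(), character(), character(), integer())
}

#' Call variants between two orthologous coding sequences
#'
#' Position-wise comparison of strand-resolved CDS pairs (both 5'..3').
#' Equal-length pairs yield one record per substituted position with the
#' codon index (\code{ceiling(pos / 3)}, 1-based), the two residues and the
#' effect class. A length difference divisible by 3 is resolved as a single
#' in-frame gap placed at the leftmost position minimizing mismatches
#' (one \code{inframe_indel} record with the codon span, plus substitution
#' records for the remaining aligned mismatches). Any other length
#' difference yields a single \code{frameshift} record. Positions with an
#' ambiguous base (N) are skipped with a warning.
#'
#' Coordinates are reported in sequence \code{a}'s frame; the indel record
#' carries the gap position in the longer sequence.
#'
#' @param gene gene name carried into the records.
#' @param seqA,seqB coding sequences.
#' @return data.frame of variant records (zero rows when identical).
#' @examples
#' callCdsVariants("toy", "ATGATTTAA", "ATGCTTTAA")  # I/L missense, codon 2
#' @export
callCdsVariants <- function(gene, seqA, seqB) {
  a <- toupper(seqA); b <- toupper(seqB)
  for (s in c(a, b)) if (grepl("[^ACGTN]", s))
    stop("CDS sequences must be over {A,C,G,T,N}")
  la <- nchar(a); lb <- nchar(b)
  if (la == lb)
    return(substitutionRecords(gene, a, b))
  d <- abs(la - lb)
  if (d %% 3L != 0L)
    return(variantRecord(gene, 1L, "", "", 1L, NA_character_, NA_character_,
                         "frameshift", codonEnd = ceiling(max(la, lb) / 3)))
  shorter <- if (la < lb) a else b
  longer <- if (la < lb) b else a
  g <- leftmostMinimalGap(shorter, longer, d)
  # indel record: gap position and codon span in the longer sequence
  codonFrom <- ceiling((g + 1L) / 3)
  codonTo <- ceiling((g + d) / 3)
  indel <- variantRecord(gene, g + 1L,
                         refNt = if (la > lb) substr(a, g + 1L, g + d) else "",
                         altNt = if (lb > la) substr(b, g + 1L, g + d) else "",
                         codonIndex = codonFrom, refAa = NA_character_,
                         altAa = NA_character_, effect = "inframe_indel",
                         codonEnd = codonTo)
  # substitutions over the aligned (gap-excised) positions
  longerCut <- paste0(substr(longer, 1L, g),
                      substr(longer, g + d + 1L, nchar(longer)))
  subs <- substitutionRecords(gene,
                              if (la < lb) shorter else longerCut,
                              if (la < lb) longerCut else shorter)
  rbind(indel, subs)
}

substitutionRecords <- function(gene, a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  amb <- av == "N" | bv == "N"
  if (any(amb)) {
    warning(sprintf("%s: %d ambiguous position(s) skipped (%s)", gene,
                    sum(amb), paste(utils::head(which(amb), 5L), collapse = ",")))
  }
  diffs <- which(av != bv & !amb)
  if (!length(diffs)) return(emptyVariantFrame())
  n3 <- (length(av) %/% 3L) * 3L
  rows <- lapply(diffs, function(p) {
    ci <- ceiling(p / 3)
    if (p <= n3) {
      refC <- paste(av[(ci * 3L - 2L):(ci * 3L)], collapse = "")
      altC <- paste(bv[(ci * 3L - 2L):(ci * 3L)], collapse = "")
      eff <- if (grepl("N", paste0(refC, altC))) NULL else
        annotateEffect(refC, altC)
    } else eff <- NULL
    variantRecord(gene, p, av[p], bv[p], ci,
                  refAa = if (is.null(eff)) NA_character_ else eff$refAa,
                  altAa = if (is.null(eff)) NA_character_ else eff$altAa,
                  effect = if (is.null(eff)) NA_character_ else eff$effect)
  })
  do.call(rbind, rows)
}

# leftmost 0-based prefix length g such that deleting longer[(g+1)..(g+d)]
# minimizes mismatches against shorter (single in-frame gap placement)
leftmostMinimalGap <- function(shorter, longer, d) {
  sv <- strsplit(shorter, "", fixed = TRUE)[[1L]]
  lv <- strsplit(longer, "", fixed = TRUE)[[1L]]
  n <- length(sv)
  pre <- cumsum(c(0L, sv != lv[seq_len(n)]))          # mismatches in prefix
  sufMis <- sv != lv[d + seq_len(n)]
  suf <- rev(cumsum(c(0L, rev(sufMis))))              # mismatches in suffix
  tot <- pre + suf[seq_len(n + 1L)]
  which.min(tot) - 1L
}

#' Compare the gene inventories of two feature sets
#'
#' Lists genes present in only one of two annotations, by feature kind
#' (e.g. an alloplasmic genome gaining a sterility ORF and donor tRNAs).
#'
#' @param featuresA,featuresB \code{GRanges} from [readFeatureTable()]
#'   (metadata columns \code{gene}, \code{kind}). Duplicate gene names
#'   within one set are a validation error.
#' @return data.frame: \code{gene}, \code{kind}, \code{only_in}
#'   (\code{"a"}/\code{"b"}).
#' @export
diffGeneInventory <- function(featuresA, featuresB) {
  for (nm in c("a", "b")) {
    f <- if (nm == "a") featuresA else featuresB
    if (anyDuplicated(f$gene))
      stop(sprintf("duplicate gene name(s) in feature set '%s': %s", nm,
                   paste(unique(f$gene[duplicated(f$gene)]), collapse = ", ")))
  }
  onlyA <- !featuresA$gene %in% featuresB$gene
  onlyB <- !featuresB$gene %in% featuresA$gene
  out <- rbind(
    data.frame(gene = featuresA$gene[onlyA], kind = featuresA$kind[onlyA],
               only_in = rep("a", sum(onlyA)), stringsAsFactors = FALSE),
    data.frame(gene = featuresB$gene[onlyB], kind = featuresB$kind[onlyB],
               only_in = rep("b", sum(onlyB)), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
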