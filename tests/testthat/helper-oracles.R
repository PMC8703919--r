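# Independent brute-force oracles used to cross-check the package's
# algorithmic primitives on small instances.

# maximal exact matches between two character sequences by exhaustive
# per-diagonal run scanning (quadratic; forward strand)
oracleMemsForward <- function(q, s, minLen) {
  qv <- strsplit(q, "", fixed = TRUE)[[1L]]
  sv <- strsplit(s, "", fixed = TRUE)[[1L]]
  nq <- length(qv); ns <- length(sv)
  out <- list()
  for (d in (-(ns - 1L)):(nq - 1L)) {
    qi <- max(1L, 1L + d); si <- qi - d
    len <- min(nq - qi, ns - si) + 1L
    if (len < minLen) next
    eq <- qv[qi:(qi + len - 1L)] == sv[si:(si + len - 1L)] &
      qv[qi:(qi + len - 1L)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= minLen)
    for (h in hit) {
      out[[length(out) + 1L]] <- data.frame(
        q_start = qi + starts[h] - 1L, q_end = qi + ends[h] - 1L,
        s_start = si + starts[h] - 1L, s_end = si + ends[h] - 1L)
    }
  }
  if (!length(out))
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer()))
  do.call(rbind, out)
}

# both-strand oracle in the anchor data.frame layout
oracleMems <- function(q, s, minLen) {
  fwd <- oracleMemsForward(q, s, minLen)
  if (nrow(fwd)) fwd$strand <- "+"
  rc <- oracleMemsForward(q, revComp(s), minLen)
  if (nrow(rc)) {
    L <- nchar(s)
    tmp <- data.frame(q_start = rc$q_start, q_end = rc$q_end,
                      s_start = L - rc$s_end + 1L, s_end = L - rc$s_start + 1L,
                      strand = "-")
    fwd <- rbind(fwd, tmp)
  }
  if (!nrow(fwd)) return(fwd)
  fwd[order(fwd$q_start, fwd$s_start, fwd$strand), , drop = FALSE]
}

# tandem copy counting by sliding a window over every start position
oracleTandemCopies <- function(seq, unit) {
  seq <- toupper(seq); unit <- toupper(unit)
  u <- nchar(unit); n <- nchar(seq)
  best <- 0L
  for (i in seq_len(max(n - u + 1L, 0L))) {
    k <- 0L
    while (i + (k + 1L) * u - 1L <= n &&
           substr(seq, i + k * u, i + (k + 1L) * u - 1L) == unit) k <- k + 1L
    if (k > best) best <- k
  }
  best
}

# interval union via an explicit boolean position array
oracleUnion <- function(starts, ends, n) {
  v <- logical(n)
  for (i in seq_along(starts)) v[starts[i]:ends[i]] <- TRUE
  r <- rle(v)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1L
  data.frame(start = s[r$values], end = e[r$values])
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# printed coordinates of the nine Ogura-type and four Bel-type alien
# regions (molecule, 1-based inclusive start/end, published length)
oguraRegions <- function() {
  data.frame(
    region = paste0("R", 1:9),
    molecule = c("MT1", "MT1", "MT1", "MT2", "MT2", "MT2", "MT2", "MT2", "MT2"),
    start = c(95, 9983, 15679, 1501, 7573, 51431, 65521, 167906, 175701),
    end = c(1645, 13790, 17960, 5739, 11390, 56887, 67247, 173821, 182520),
    length = c(1551, 3808, 2282, 4239, 3818, 5457, 1727, 5916, 6820))
}

belRegions <- function() {
  data.frame(
    region = c("R7+R1", "R8", "R9", "R10"),
    molecule = c("MT1", "MT2", "MT2", "MT2"),
    start = c(33649, 29996, 37715, 66628),
    end = c(37217, 35831, 44534, 71989),
    length = c(3569, 5836, 6820, 5362))
}

# a small trio configuration used across module tests
smallTrioConfig <- function(seed, nInserts = 3, insertLen = c(1500, 2500, 2000),
                            backbone = 40000, sv = NULL, cms = 0) {
  ins <- if (nInserts > 0)
    data.frame(label = paste0("R", seq_len(nInserts)), molecule = "MT1",
               start = NA_integer_, length = insertLen[seq_len(nInserts)])
  else data.frame(label = character(), molecule = character(),
                  start = integer(), length = integer())
  trioConfig(backboneLength = backbone, hybridMoleculeLengths = NULL,
             insertSpecs = ins,
             svSpecs = if (is.null(sv)) data.frame(type = character(),
                                                   length = integer()) else sv,
             cmsCopies = cms, cmsRegion = if (cms > 0) "R1" else "R8",
             seed = seed)
}

# run the attribution pipeline on a trio and return the report
trioReport <- function(trio, minLen = 100, gap = 100, minRegion = 1000) {
  maskR <- coverageFromAnchors(trio$hybrid, trio$recipient, minLen = minLen)
  maskD <- coverageFromAnchors(trio$hybrid, trio$donor, minLen = minLen)
  extractAlienRegions(attributeOrigin(maskD, maskR), hybrid = trio$hybrid,
                      gap = gap, minRegion = minRegion)
}
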