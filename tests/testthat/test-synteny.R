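test_that("identical molecules give one full-length forward anchor", {
  set.seed(7)
  s <- randomSeq(5000)
  a <- GenomeAssembly("a", c(m = s))
  b <- GenomeAssembly("b", c(m = s))
  an <- findAnchors(a, b, minLen = 100)
  expect_identical(nrow(an), 1L)
  expect_identical(c(an$q_start, an$q_end, an$s_start, an$s_end),
                   c(1L, 5000L, 1L, 5000L))
  expect_identical(an$strand, "+")
})

test_that("anchors equal the brute-force maximal-exact-match oracle", {
  set.seed(31)
  for (rep in 1:5) {
    s <- randomSeq(800)
    # derive a query sharing structure: mutate, invert a chunk, insert
    qv <- strsplit(s, "")[[1]]
    mut <- sample(800, 16)
    qv[mut] <- vapply(qv[mut], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    q <- paste(qv, collapse = "")
    q <- paste0(substr(q, 1, 300), revComp(substr(q, 301, 500)),
                substr(q, 501, 650), randomSeq(80), substr(q, 651, 800))
    got <- findAnchors(GenomeAssembly("q", c(m = q)),
                       GenomeAssembly("s", c(m = s)), minLen = 25)
    want <- oracleMems(q, s, 25)
    gotKey <- sort(paste(got$q_start, got$q_end, got$s_start, got$s_end,
                         got$strand))
    wantKey <- sort(paste(want$q_start, want$q_end, want$s_start, want$s_end,
                          want$strand))
    expect_identical(gotKey, wantKey)
  }
})

test_that("every reported anchor satisfies substring equality", {
  trio <- generateTrio(smallTrioConfig(seed = 17))
  an <- findAnchors(trio$hybrid, trio$donor, minLen = 100)
  expect_gt(nrow(an), 0)
  for (i in sample(nrow(an), min(nrow(an), 40))) {
    qs <- moleculeSubseq(trio$hybrid, an$q_mol[i], an$q_start[i], an$q_end[i])
    ss <- moleculeSubseq(trio$donor, an$s_mol[i], an$s_start[i], an$s_end[i])
    expect_identical(qs, if (an$strand[i] == "+") ss else revComp(ss))
  }
})

test_that("circular molecules are anchored across the origin", {
  set.seed(12)
  s <- randomSeq(4000)
  rot <- paste0(substr(s, 1501, 4000), substr(s, 1, 1500))  # rotation
  a <- GenomeAssembly("rot", c(m = rot), topology = "circular")
  b <- GenomeAssembly("ref", c(m = s), topology = "circular")
  an <- findAnchors(a, b, minLen = 100)
  # full coverage of the rotated molecule despite the split origin
  mask <- coverageFromAnchors(a, b, anchors = an)
  expect_true(all(mask$m))
  for (i in seq_len(nrow(an))) {
    expect_identical(moleculeSubseq(a, "m", an$q_start[i], an$q_end[i]),
                     moleculeSubseq(b, "m", an$s_start[i], an$s_end[i]))
  }
})

test_that("a planted inversion yields a minus-strand central anchor", {
  set.seed(5)
  s <- randomSeq(6000)
  q <- paste0(substr(s, 1, 2250), revComp(substr(s, 2251, 3750)),
              substr(s, 3751, 6000))
  an <- findAnchors(GenomeAssembly("q", c(m = q)),
                    GenomeAssembly("s", c(m = s)), minLen = 100)
  minus <- an[an$strand == "-", ]
  expect_identical(nrow(minus), 1L)
  expect_lte(abs(minus$q_start - 2251), 20)  # boundary chance-match slack
  expect_lte(abs(minus$q_end - 3750), 20)
})

test_that("chaining joins colinear anchors within the gap and not beyond", {
  one <- data.frame(q_mol = "m", q_start = 100L, q_end = 400L, s_mol = "s",
                    s_start = 100L, s_end = 400L, strand = "+", length = 301L)
  b1 <- chainAnchors(one)
  expect_identical(nrow(b1), 1L)
  expect_identical(b1$n_anchors, 1L)
  near <- rbind(one, data.frame(q_mol = "m", q_start = 901L, q_end = 1200L,
                                s_mol = "s", s_start = 901L, s_end = 1200L,
                                strand = "+", length = 300L))
  expect_identical(nrow(chainAnchors(near, maxGap = 1000)), 1L)
  far <- near
  far$q_start[2] <- 5401L; far$q_end[2] <- 5700L
  far$s_start[2] <- 5401L; far$s_end[2] <- 5700L
  expect_identical(nrow(chainAnchors(far, maxGap = 1000)), 2L)
})

test_that("identical genomes produce no structural variant calls", {
  set.seed(4)
  s <- randomSeq(12000)
  a <- GenomeAssembly("a", c(m = s)); b <- GenomeAssembly("b", c(m = s))
  sv <- callSVs(chainAnchors(findAnchors(a, b)))
  expect_identical(nrow(sv), 0L)
})

test_that("a planted inversion is called with accurate size; sub-threshold ones are not", {
  set.seed(9)
  s <- randomSeq(20000)
  q <- paste0(substr(s, 1, 8000), revComp(substr(s, 8001, 9500)),
              substr(s, 9501, 20000))
  sv <- callSVs(chainAnchors(findAnchors(GenomeAssembly("q", c(m = q)),
                                         GenomeAssembly("s", c(m = s)))))
  expect_identical(nrow(sv), 1L)
  expect_identical(sv$type, "inversion")
  expect_lte(abs(sv$size - 1500L), 200L)  # 2x anchor minLen slack
  # 500 bp inversion stays below the strict >1 kb rule
  q2 <- paste0(substr(s, 1, 8000), revComp(substr(s, 8001, 8500)),
               substr(s, 8501, 20000))
  sv2 <- callSVs(chainAnchors(findAnchors(GenomeAssembly("q", c(m = q2)),
                                          GenomeAssembly("s", c(m = s)))))
  expect_identical(nrow(sv2), 0L)
})

test_that("swapping query and subject maps insertions to deletions", {
  trio <- generateTrio(smallTrioConfig(seed = 23, nInserts = 2,
                                       insertLen = c(2000, 3000),
                                       backbone = 30000))
  fw <- callSVs(chainAnchors(findAnchors(trio$hybrid, trio$recipient)))
  bw <- callSVs(chainAnchors(findAnchors(trio$recipient, trio$hybrid)))
  expect_identical(sort(fw$size[fw$type == "insertion"]),
                   sort(bw$size[bw$type == "deletion"]))
  expect_identical(nrow(fw[fw$type == "insertion", ]), 2L)
  expect_identical(nrow(bw[bw$type == "deletion", ]), 2L)
  expect_identical(sum(fw$type == "inversion"), sum(bw$type == "inversion"))
})
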