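test_that("CMS ORF constructs have the canonical codon counts", {
  codons <- vapply(1:3, function(cp) nchar(plantCmsOrf(cp)) / 3 - 1, numeric(1))
  expect_identical(codons, c(112, 125, 138))
  # deleting repeat copies steps the length by whole 39-nt units
  expect_identical(nchar(plantCmsOrf(3)) - nchar(plantCmsOrf(1)), 78L)
  expect_identical(nchar(plantCmsOrf(3)) - nchar(plantCmsOrf(2)), 39L)
  for (cp in 1:3) {
    s <- plantCmsOrf(cp)
    expect_identical(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
    expect_identical(countTandemCopies(s), as.integer(cp))
  }
  expect_error(plantCmsOrf(4), "1, 2 or 3")
  expect_error(plantCmsOrf(0), "copies")
})

test_that("a trio with no inserts or SVs reproduces the recipient exactly", {
  trio <- generateTrio(smallTrioConfig(seed = 3, nInserts = 0, backbone = 8000))
  expect_identical(as.character(molecules(trio$hybrid)[[1]]),
                   as.character(molecules(trio$recipient)[[1]]))
  expect_length(donorSegments(trio$truth), 0)
})

test_that("the default trio plants the nine-region alien complement", {
  trio <- generateTrio(trioConfig(seed = 8))
  segs <- donorSegments(trio$truth)
  expect_length(segs, 9)
  expect_identical(sum(BiocGenerics::width(segs)), 35618L)
  expect_identical(unname(moleculeLengths(trio$hybrid)), c(71998L, 185431L))
  expect_identical(totalLength(trio$hybrid),
                   totalLength(trio$recipient) + 35618L)
  # CMS construct sits inside its designated region
  cms <- cmsOrfRange(trio$truth)
  r8 <- segs[segs$label == "R8"]
  expect_length(cms, 1)
  expect_true(BiocGenerics::start(cms) >= BiocGenerics::start(r8) &&
              BiocGenerics::end(cms) <= BiocGenerics::end(r8))
})

test_that("generation is deterministic: same seed gives identical FASTA", {
  cfg <- smallTrioConfig(seed = 21, backbone = 20000,
                         insertLen = c(1500, 1600, 1700))
  t1 <- generateTrio(cfg)
  t2 <- generateTrio(cfg)
  for (part in c("recipient", "donor", "hybrid")) {
    f1 <- withr::local_tempfile(fileext = ".fa")
    f2 <- withr::local_tempfile(fileext = ".fa")
    writeFastaAssembly(t1[[part]], f1)
    writeFastaAssembly(t2[[part]], f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("planted inserts share no 31-mer with the recipient", {
  trio <- generateTrio(smallTrioConfig(seed = 5))
  segs <- donorSegments(trio$truth)
  for (i in seq_along(segs)) {
    ins <- moleculeSubseq(trio$hybrid,
                          as.character(GenomicRanges::seqnames(segs))[i],
                          BiocGenerics::start(segs)[i],
                          BiocGenerics::end(segs)[i])
    hits <- findAnchors(GenomeAssembly("i", c(x = ins)), trio$recipient,
                        minLen = 31)
    expect_identical(nrow(hits), 0L)
  }
})

test_that("realized divergence behaves like a binomial substitution process", {
  r <- 0.02
  cfg <- trioConfig(backboneLength = 30000, hybridMoleculeLengths = NULL,
                    insertSpecs = data.frame(label = character(),
                                             molecule = character(),
                                             start = integer(),
                                             length = integer()),
                    divergenceRate = r, donorBackboneFraction = 1,
                    cmsCopies = 0, seed = 13)
  for (seed in c(13, 14, 15)) {
    cfg$seed <- seed
    trio <- generateTrio(cfg)
    a <- strsplit(as.character(molecules(trio$recipient)[[1]]), "")[[1]]
    b <- strsplit(as.character(molecules(trio$donor)[[1]]), "")[[1]]
    expect_identical(length(a), length(b))
    n <- length(a)
    mism <- sum(a != b)
    expect_lt(abs(mism - n * r), 4 * sqrt(n * r * (1 - r)))
  }
})

test_that("truth files round-trip through BED + JSON", {
  trio <- generateTrio(smallTrioConfig(seed = 2, cms = 1))
  dir <- withr::local_tempdir()
  writeTruth(trio$truth, dir)
  back <- readTruth(dir)
  expect_identical(BiocGenerics::start(donorSegments(back)),
                   BiocGenerics::start(donorSegments(trio$truth)))
  expect_identical(donorSegments(back)$label, donorSegments(trio$truth)$label)
  expect_identical(cmsCopies(back), cmsCopies(trio$truth))
  expect_identical(BiocGenerics::start(cmsOrfRange(back)),
                   BiocGenerics::start(cmsOrfRange(trio$truth)))
  # empty truth still writes valid files
  t0 <- generateTrio(smallTrioConfig(seed = 4, nInserts = 0, backbone = 8000))
  writeTruth(t0$truth, dir)
  expect_length(donorSegments(readTruth(dir)), 0)
})

test_that("subsetHybrid retains kept segments verbatim at shifted positions", {
  trio <- generateTrio(smallTrioConfig(seed = 6))
  sub <- subsetHybrid(trio, keep = c("R1", "R3"))
  segs <- donorSegments(sub$truth)
  expect_setequal(segs$label, c("R1", "R3"))
  full <- donorSegments(trio$truth)
  for (lab in c("R1", "R3")) {
    a <- full[full$label == lab]; b <- segs[segs$label == lab]
    sA <- moleculeSubseq(trio$hybrid, as.character(GenomicRanges::seqnames(a)),
                         BiocGenerics::start(a), BiocGenerics::end(a))
    sB <- moleculeSubseq(sub$hybrid, as.character(GenomicRanges::seqnames(b)),
                         BiocGenerics::start(b), BiocGenerics::end(b))
    expect_identical(sA, sB)
  }
  expect_identical(totalLength(sub$hybrid),
                   totalLength(trio$hybrid) -
                     sum(BiocGenerics::width(full[full$label == "R2"])))
})
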