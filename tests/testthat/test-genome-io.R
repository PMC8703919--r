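test_that("FASTA round-trip preserves ids, sequences and topology", {
  set.seed(11)
  ga <- GenomeAssembly("trip",
                       c(m1 = randomSeq(523), m2 = randomSeq(210)),
                       topology = c("circular", "linear"))
  fa <- withr::local_tempfile(fileext = ".fa")
  writeFastaAssembly(ga, fa)
  back <- readFastaAssembly(fa, name = "trip")
  expect_identical(names(molecules(back)), c("m1", "m2"))
  expect_identical(as.character(molecules(back)), as.character(molecules(ga)))
  expect_identical(unname(topology(back)), c("circular", "linear"))
})

test_that("molecule sizes are carried losslessly at mitogenome scale", {
  # a single circular chromosome of 219,969 bp must survive a round trip
  set.seed(2)
  ga <- GenomeAssembly("full", c(mt = randomSeq(219969)), topology = "circular")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeFastaAssembly(ga, fa)
  expect_identical(unname(moleculeLengths(readFastaAssembly(fa))), 219969L)
})

test_that("topology is read from the header token and defaults to linear", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">m1 [topology=circular]", "ACGTACGT", ">m2", "GGCC"), fa)
  ga <- readFastaAssembly(fa)
  expect_identical(unname(topology(ga)), c("circular", "linear"))
  expect_identical(as.character(molecules(ga)[["m1"]]), "ACGTACGT")
})

test_that("FASTA parsing rejects malformed input with informative errors", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">m1", "ACGT", ">m1", "GGCC"), fa)
  expect_error(readFastaAssembly(fa), "duplicate molecule id.*m1")
  writeLines(c(">m1", "ACGT", ">m2", "ACGT", "AXGT"), fa)
  expect_error(readFastaAssembly(fa), "record 'm2'.*line 5")
  writeLines(character(), fa)
  expect_error(readFastaAssembly(fa), "empty|parse")
})

test_that("interval lengths follow the 1-based inclusive convention", {
  expect_identical(intervalLength(95, 1645), 1551L)
  expect_identical(intervalLength(1501, 5739), 4239L)
  expect_identical(intervalLength(7, 7), 1L)
  expect_error(intervalLength(0, 5), "start")
  expect_error(intervalLength(10, 5), "end")
})

test_that("interval arithmetic reproduces every published region length", {
  for (tab in list(oguraRegions(), belRegions())) {
    expect_identical(intervalLength(tab$start, tab$end), as.integer(tab$length))
  }
})

test_that("mergeIntervals matches a position-set oracle and is idempotent", {
  expect_length(mergeIntervals(GenomicRanges::GRanges(), gap = 0), 0)
  gr <- GenomicRanges::GRanges("m1", IRanges::IRanges(c(1, 5), c(10, 20)))
  m <- mergeIntervals(gr, gap = 0)
  expect_identical(c(BiocGenerics::start(m), BiocGenerics::end(m)), c(1L, 20L))
  set.seed(99)
  for (rep in 1:5) {
    s <- sample.int(9900, 50)
    e <- pmin(s + sample.int(300, 50), 10000L)
    gr <- GenomicRanges::GRanges("m1", IRanges::IRanges(s, e))
    got <- mergeIntervals(gr[sample.int(50)], gap = 0)  # order-insensitive
    want <- oracleUnion(s, e, 10000L)
    expect_identical(BiocGenerics::start(got), want$start)
    expect_identical(BiocGenerics::end(got), want$end)
    expect_identical(mergeIntervals(got, gap = 0), got)  # idempotent
  }
  expect_error(mergeIntervals(gr, gap = -1), "gap")
})

test_that("revComp complements, reverses and is an involution", {
  expect_identical(revComp("ACGT"), "ACGT")
  expect_identical(revComp("AAAGGGG"), "CCCCTTT")
  set.seed(3)
  x <- randomSeq(211)
  expect_identical(revComp(revComp(x)), x)
  expect_error(revComp("ACGU"), "A,C,G,T,N")
})

test_that("BED files use 0-based half-open on disk and round-trip", {
  tab <- oguraRegions()
  gr <- GenomicRanges::GRanges(tab$molecule, IRanges::IRanges(tab$start, tab$end),
                               label = tab$region)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeBedRegions(gr, bed)
  raw <- read.delim(bed, header = FALSE)
  expect_identical(raw$V2, as.integer(tab$start) - 1L)
  expect_identical(sum(raw$V3 - raw$V2), 35618L)  # half-open arithmetic
  back <- readBedRegions(bed)
  expect_identical(BiocGenerics::start(back), as.integer(tab$start))
  expect_identical(BiocGenerics::end(back), as.integer(tab$end))
  expect_identical(back$label, tab$region)
})

test_that("feature tables read from TSV and GFF3 with normalized kinds", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tmolecule\tstart\tend\tstrand\tkind",
               "atp8\tMT1\t100\t572\t+\tCDS",
               "trnfM-CAU\tMT1\t700\t772\t-\ttRNA",
               "orf138\tMT2\t10\t426\t+\tORF"), tsv)
  ft <- readFeatureTable(tsv)
  expect_identical(ft$gene, c("atp8", "trnfM-CAU", "orf138"))
  expect_identical(ft$kind, c("CDS", "tRNA", "ORF"))
  expect_identical(BiocGenerics::start(ft), c(100L, 700L, 10L))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "MT1\ttest\tCDS\t100\t572\t.\t+\t0\tID=cds1;Name=atp8"), gff)
  fg <- readFeatureTable(gff)
  expect_identical(fg$gene, "atp8")
  expect_identical(fg$kind, "CDS")
})

test_that("assembly validity catches structural problems", {
  expect_error(GenomeAssembly("x", c(m1 = "ACGT", m1 = "GGGG")), "duplicate")
  expect_error(GenomeAssembly("x", c(m1 = "ACRT")), "non-ACGTN")
  expect_error(GenomeAssembly("x", setNames(rep("ACGT", 9), paste0("m", 1:9))),
               "1-8 molecules")
})
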