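test_that("coverage masks reflect anchor support exactly", {
  set.seed(6)
  s <- randomSeq(5000)
  g <- GenomeAssembly("g", c(m = s))
  mask <- coverageFromAnchors(g, g)
  expect_true(all(mask$m))
  empty <- coverageFromAnchors(g, g, anchors = alloplasmy:::emptyAnchorFrame())
  expect_false(any(empty$m))
})

test_that("a planted donor insert is exactly the uncovered recipient span", {
  trio <- generateTrio(smallTrioConfig(seed = 10, nInserts = 1,
                                       insertLen = 2000, backbone = 25000))
  mask <- coverageFromAnchors(trio$hybrid, trio$recipient)
  seg <- donorSegments(trio$truth)
  uncov <- which(!mask[[as.character(GenomicRanges::seqnames(seg))]])
  expect_identical(range(uncov),
                   c(BiocGenerics::start(seg), BiocGenerics::end(seg)))
  expect_identical(length(uncov), 2000L)
})

test_that("origin attribution partitions each molecule without gaps", {
  trio <- generateTrio(smallTrioConfig(seed = 12))
  maskR <- coverageFromAnchors(trio$hybrid, trio$recipient)
  maskD <- coverageFromAnchors(trio$hybrid, trio$donor)
  org <- attributeOrigin(maskD, maskR)
  for (m in names(moleculeLengths(trio$hybrid))) {
    onm <- org[GenomicRanges::seqnames(org) == m]
    expect_identical(sum(BiocGenerics::width(onm)),
                     unname(moleculeLengths(trio$hybrid)[m]))
    expect_identical(min(BiocGenerics::start(onm)), 1L)
    # no overlaps: total width equals span
    expect_identical(max(BiocGenerics::end(onm)),
                     unname(moleculeLengths(trio$hybrid)[m]))
  }
  expect_true(all(org$origin %in% c("recipient", "donor", "shared", "novel")))
})

test_that("degenerate masks give single-class attributions", {
  allT <- list(m = rep(TRUE, 100)); allF <- list(m = rep(FALSE, 100))
  recOnly <- attributeOrigin(allF, allT)
  expect_identical(length(recOnly), 1L)
  expect_identical(recOnly$origin, "recipient")
  shared <- attributeOrigin(allT, allT)
  expect_identical(shared$origin, "shared")
  expect_error(attributeOrigin(allT, list(m = rep(TRUE, 50))), "length")
})

test_that("alien extraction reproduces the published totals from coordinates", {
  tab <- oguraRegions()
  gr <- GenomicRanges::GRanges(tab$molecule,
                               IRanges::IRanges(tab$start, tab$end),
                               origin = "donor")
  rep <- extractAlienRegions(gr, genomeBp = 71998 + 185431)
  expect_identical(totalAlienBp(rep), 35618L)
  expect_identical(alienFraction(rep), 13.84)
  expect_identical(alienRegions(rep)$label, paste0("R", 1:9))
  tab4 <- belRegions()
  gr4 <- GenomicRanges::GRanges(tab4$molecule,
                                IRanges::IRanges(tab4$start, tab4$end),
                                origin = "donor")
  rep4 <- extractAlienRegions(gr4, genomeBp = 65849 + 175791)
  expect_identical(totalAlienBp(rep4), 21587L)
  expect_identical(alienFraction(rep4), 8.93)
  empty <- extractAlienRegions(GenomicRanges::GRanges(), genomeBp = 1000)
  expect_identical(totalAlienBp(empty), 0L)
  expect_identical(alienFraction(empty), 0)
})

test_that("recovered alien regions match planted truth at full scale", {
  trio <- generateTrio(trioConfig(seed = 31))
  rep <- trioReport(trio)
  expect_identical(totalAlienBp(rep), 35618L)
  expect_identical(alienFraction(rep), 13.84)
  got <- alienRegions(rep)
  want <- donorSegments(trio$truth)
  expect_identical(BiocGenerics::start(got), BiocGenerics::start(want))
  expect_identical(BiocGenerics::end(got), BiocGenerics::end(want))
})

test_that("shared sequence is never counted as alien (parsimony lower bound)", {
  # donor carrying the full recipient backbone (undiverged) must not change
  # the alien call: only donor-unique inserts count
  cfgA <- smallTrioConfig(seed = 40)
  trioA <- generateTrio(cfgA)
  cfgB <- cfgA; cfgB$donorBackboneFraction <- 1; cfgB$divergenceRate <- 0
  trioB <- generateTrio(cfgB)
  repA <- trioReport(trioA)
  repB <- trioReport(trioB)
  expect_identical(totalAlienBp(repA), totalAlienBp(repB))
  expect_identical(totalAlienBp(repA),
                   sum(BiocGenerics::width(donorSegments(trioA$truth))))
})

test_that("region correspondence maps a partial line onto the full one", {
  trio <- generateTrio(trioConfig(seed = 19))
  repA <- trioReport(trio)
  sub <- subsetHybrid(trio, keep = c("R1", "R7", "R8", "R9"), name = "bel")
  maskR <- coverageFromAnchors(sub$hybrid, trio$recipient)
  maskD <- coverageFromAnchors(sub$hybrid, trio$donor)
  repB <- extractAlienRegions(attributeOrigin(maskD, maskR),
                              hybrid = sub$hybrid)
  anchors <- findAnchors(sub$hybrid, trio$hybrid)
  corr <- compareRegionSets(repA, repB, anchors)
  expect_identical(nrow(corr), 4L)
  expect_false(any(corr$unique))
  expect_setequal(unlist(strsplit(corr$a_labels, ",")),
                  c("R1", "R7", "R8", "R9"))
  # identity mapping on the full report
  self <- compareRegionSets(repA, repA, findAnchors(trio$hybrid, trio$hybrid))
  expect_false(any(self$unique))
  expect_true(all(mapply(grepl, paste0("\\b", self$b_label, "\\b"),
                         self$a_labels)))
})

test_that("a segment absent from the reference line is flagged unique", {
  trio <- generateTrio(smallTrioConfig(seed = 44, nInserts = 3))
  repA <- trioReport(trio)
  # drop R2 from the reference line's report, then map the full line onto it
  regA <- alienRegions(repA)
  repTrim <- extractAlienRegions(regA[regA$label != "R2"],
                                 hybrid = trio$hybrid)
  anchors <- findAnchors(trio$hybrid, trio$hybrid)
  corr <- compareRegionSets(repTrim, repA, anchors)
  expect_identical(sum(corr$unique), 1L)
})
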