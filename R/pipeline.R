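#' Run the full alloplasm analysis and write a report bundle
#'
#' Orchestrates the pipeline on a recipient/donor/hybrid genome set:
#' exact-match anchoring of the hybrid against both parents, origin
#' attribution, alien-region extraction, structural-variant calling
#' (hybrid vs recipient), marker-panel design and in-silico screening of
#' all three genomes, and OKB CMS genotyping. Every output is a plain text
#' file under \code{outDir}; the JSON summary repeats the headline numbers
#' and the parameters actually used, so a run is reproducible from its own
#' output.
#'
#' @param recipient,donor,hybrid [GenomeAssembly-class] objects (or paths
#'   to FASTA files readable by [readFastaAssembly()]).
#' @param outDir output directory, created if needed.
#' @param minAnchor anchor length threshold, bp.
#' @param gap alien-region merge gap, bp.
#' @param minRegion minimum alien region length, bp.
#' @param svMin strict structural-variant size threshold, bp.
#' @param panelCounts named vector of markers per region label; \code{NULL}
#'   designs 2 per region; \code{NA} entries skip a region.
#' @param maxAmplicon maximum in-silico PCR product, bp.
#' @param seed integer seed recorded in (and driving any randomness of) the
#'   run.
#' @return invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
runFull <- function(recipient, donor, hybrid, outDir,
                    minAnchor = 100L, gap = 100L, minRegion = 1000L,
                    svMin = 1000L, panelCounts = NULL, maxAmplicon = 2000L,
                    seed = 1L) {
  asAssembly <- function(x, nm) if (is(x, "GenomeAssembly")) x else
    readFastaAssembly(x, name = nm)
  recipient <- asAssembly(recipient, "recipient")
  donor <- asAssembly(donor, "donor")
  hybrid <- asAssembly(hybrid, "hybrid")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  anchR <- findAnchors(hybrid, recipient, minLen = minAnchor)
  anchD <- findAnchors(hybrid, donor, minLen = minAnchor)
  writeTsv(anchR, file.path(outDir, "anchors_vs_recipient.tsv"))
  writeTsv(anchD, file.path(outDir, "anchors_vs_donor.tsv"))

  maskR <- coverageFromAnchors(hybrid, recipient, anchors = anchR)
  maskD <- coverageFromAnchors(hybrid, donor, anchors = anchD)
  origin <- attributeOrigin(maskD, maskR)
  report <- extractAlienRegions(origin, hybrid = hybrid, gap = gap,
                                minRegion = minRegion)
  writeTsv(alloplasmTable(report), file.path(outDir, "alien_regions.tsv"))
  writeBedRegions(alienRegions(report), file.path(outDir, "alien_regions.bed"))

  blocks <- chainAnchors(anchR)
  svs <- callSVs(blocks, minSize = svMin, qry = hybrid, sbj = recipient)
  writeTsv(blocks, file.path(outDir, "synteny_blocks.tsv"))
  writeTsv(svs, file.path(outDir, "structural_variants.tsv"))

  panel <- NULL
  screens <- list()
  cytotypes <- list()
  if (length(alienRegions(report))) {
    counts <- panelCounts
    if (is.null(counts))
      counts <- stats::setNames(rep(2L, length(alienRegions(report))),
                                alienRegions(report)$label)
    counts <- counts[!is.na(counts)]
    panel <- designPanel(report, hybrid, recipient, counts,
                         maxAmplicon = maxAmplicon, seed = seed)
    writeTsv(panel, file.path(outDir, "marker_panel.tsv"))
    for (g in list(hybrid, recipient, donor)) {
      calls <- screenPanel(g, panel, maxAmplicon = maxAmplicon)
      screens[[assemblyName(g)]] <- calls
      cytotypes[[assemblyName(g)]] <- classifyCytotype(calls, panel)
    }
    writeTsv(do.call(rbind, screens), file.path(outDir, "marker_calls.tsv"))
    cyto <- do.call(rbind, lapply(cytotypes, function(x)
      data.frame(material = x$material, class = x$class,
                 positive_count = x$positive_count,
                 positive_regions = paste(x$positive_regions, collapse = ","),
                 stringsAsFactors = FALSE)))
    writeTsv(cyto, file.path(outDir, "cytotypes.tsv"))
  }

  haplos <- lapply(list(hybrid, recipient, donor), function(g) {
    h <- okbGenotype(g, maxAmplicon = maxAmplicon)
    data.frame(genome = assemblyName(g), genotype = h$genotype,
               product_bp = h$product_bp, repeat_copies = h$repeat_copies,
               stringsAsFactors = FALSE)
  })
  haplos <- do.call(rbind, haplos)
  writeTsv(haplos, file.path(outDir, "cms_haplotypes.tsv"))

  summary <- list(
    parameters = list(min_anchor = minAnchor, gap = gap,
                      min_region = minRegion, sv_min = svMin,
                      max_amplicon = maxAmplicon, seed = seed),
    genomes = list(recipient = totalLength(recipient),
                   donor = totalLength(donor),
                   hybrid = totalLength(hybrid)),
    total_alien_bp = totalAlienBp(report),
    alien_fraction_percent = alienFraction(report),
    n_alien_regions = length(alienRegions(report)),
    n_svs = nrow(svs),
    n_markers = if (is.null(panel)) 0L else nrow(panel),
    hybrid_cms_genotype = haplos$genotype[haplos$genome == assemblyName(hybrid)])
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, report = report, panel = panel,
                 svs = svs, screens = screens, cytotypes = cytotypes,
                 haplotypes = haplos))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
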