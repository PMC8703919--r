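# alloplasmy

Donor-segment attribution and CMS typing in alloplasmic organelle genomes.

## The problem

Cytoplasmic male sterility (CMS) in brassica crops is usually introduced
from a donor species (radish, in the Ogura system) by interspecific
hybridization or protoplast fusion. The resulting *alloplasmic* line keeps
the crop's nuclear genome but carries a recombinant mitochondrial genome:
mostly recipient backbone, interrupted by donor-derived ("alien") tracts,
one of which harbours the sterility ORF. Excess alien cytoplasm drags in
undesirable traits, so breeders want to know exactly **which** hybrid
sequence is donor-derived, **how much** of the genome it is, and **which
sterility-ORF haplotype** the line carries.

`alloplasmy` answers those questions from assembled genomes alone:

* **Synteny** — maximal exact-match anchors (MUMmer-style, re-implemented in
  Rcpp with circular-origin handling), greedy colinear chaining, and calling
  of insertions, deletions, inversions and translocations above a strict
  \>1 kb threshold.
* **Origin attribution** — every hybrid position is classed by exact-match
  coverage against the two parents: `shared` (both), `donor` (donor only),
  `recipient`, or `novel`. Donor-only runs, merged and filtered, are the
  alien cytoplasm, reported with the total and its percent of the genome.
  "Alien" deliberately means *donor-unique*: shared sequence never counts,
  so the fraction is a parsimony lower bound.
* **Coding variants** — position-wise comparison of orthologous CDS pairs
  with synonymous / missense / nonsense / in-frame-indel / frameshift
  annotation under the standard genetic code.
* **Marker screen** — region-diagnostic primer pairs designed inside alien
  regions (absent from the recipient by construction), in-silico PCR against
  arbitrary genomes, and cytotype classification
  (normal / partial / full alloplasmic) from the presence pattern.
* **CMS haplotyping** — the orf138 family is distinguished by exact tandem
  copies of a 39-nt unit at the 3' coding end: 3 copies = orf138
  (138 codons), 2 = orf125, 1 = orf112. The package counts copies, types
  ORFs, and genotypes whole genomes with the OKB primer pair whose amplicon
  steps by 39 bp per copy.
* **Synthetic trios** — a generator that emulates the whole situation
  (recipient backbone, diverged donor with unique segments, hybrid with
  planted inserts/SVs/CMS ORF) with exactly known ground truth, so every
  stage is testable without external assemblies.

## Worked example

```r
library(alloplasmy)

# a study-scale synthetic trio: 221,811-bp recipient backbone, hybrid split
# into 71,998 + 185,431 bp circles carrying nine donor segments
trio <- generateTrio(trioConfig(seed = 42))

maskR <- coverageFromAnchors(trio$hybrid, trio$recipient)
maskD <- coverageFromAnchors(trio$hybrid, trio$donor)
report <- extractAlienRegions(attributeOrigin(maskD, maskR),
                              hybrid = trio$hybrid)
report
#> AlloplasmReport: 9 alien region(s), 35,618 bp (13.84% of 257,429 bp)
#>   R1   MT1             95      1645    1551
#>   R2   MT1           9983     13790    3808
#>   R3   MT1          15679     17960    2282
#>   R4   MT2           1501      5739    4239
#>   R5   MT2           7573     11390    3818
#>   R6   MT2          51431     56887    5457
#>   R7   MT2          65521     67247    1727
#>   R8   MT2         167906    173821    5916
#>   R9   MT2         175701    182520    6820
```

The nine planted donor segments are recovered at exact base-pair
boundaries: 35,618 bp of alien cytoplasm, 13.84% of the 257,429-bp hybrid
mitogenome. Marker screening and CMS typing continue from the same objects:

```r
panel <- designPanel(report, trio$hybrid, trio$recipient,
                     setNames(c(2,3,2,4,3,4,2,6,6), paste0("R", 1:9)))
nrow(panel)
#> [1] 32

bel <- subsetHybrid(trio, keep = c("R1", "R7", "R8", "R9"), name = "bel")
classifyCytotype(screenPanel(bel$hybrid, panel), panel)$positive_count
#> [1] 16

okbGenotype(trio$hybrid)$genotype
#> [1] "orf138-type"
```

A hybrid keeping only four of the nine regions lights up exactly the 16
markers of those regions (partial alloplasmic); the full hybrid types as
orf138 because its planted CMS ORF carries three copies of the 39-nt unit.

`runFull()` (or `inst/scripts/alloplasmy-cli.R`) chains all stages and
writes a text report bundle: alien-region TSV/BED, SV and synteny tables,
marker matrix, cytotype calls, CMS haplotypes, and a JSON summary.

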