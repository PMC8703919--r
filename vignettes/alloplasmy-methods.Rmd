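---
title: "Methods: donor-segment attribution and CMS typing in alloplasmic mitogenomes"
author: "alloplasmy package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: donor-segment attribution and CMS typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

An alloplasmic CMS line carries a recombinant mitochondrial genome: a
recipient-species backbone interrupted by donor-species tracts, one of which
holds the sterility ORF. The package's central model is deliberately
minimal: a hybrid position is *donor-derived* exactly when it lies inside a
maximal exact match to the donor genome and inside **no** exact match to the
recipient. This operationalizes the breeder's criterion of sequence
"completely derived" from the donor; there is no percent-identity knob in
the default path, and tolerance enters only through the minimum anchor
length. Positions matching both parents are `shared` and never count as
alien, so the reported alien fraction is a parsimony lower bound — in these
intra-family comparisons most genes are conserved, and counting shared
sequence as alien would be unfalsifiable from assemblies alone.

All in-memory coordinates are 1-based and fully inclusive (start 95,
end 1645 spans 1551 bp); BED output converts to 0-based half-open at the
file boundary only. Percentages are rounded half-up to two decimals, the
convention used in published alien-cytoplasm tables.

## Anchoring

`findAnchors()` enumerates maximal exact matches (MEMs) with a k-mer
hash-seeded extension in C++ (`src/anchors.cpp`): every subject window of
the minimum length is indexed, query windows are looked up, seeds are
verified byte-wise (the rolling hash may collide) and extended to
maximality; per-diagonal bookkeeping reports each maximal run once. `N`
never matches, not even another `N`. Circular molecules are extended by
`minLen - 1` wraparound bases; anchors crossing the origin are split at the
origin and reported in unwrapped coordinates, and self-overrun on identical
circles is clipped to the molecule length.

The default `minLen = 100` is a compromise: long enough that chance hits
are negligible against a ~250-kb mitogenome (a specific 100-mer has
vanishing probability of recurring), short enough to tile the kb-scale
regions of interest. The main cost of the choice is resolution: features
smaller than one anchor (sub-100-bp backbone slivers between events) cannot
be resolved, which is why the SV caller's `slack` parameter defaults to the
same 100 bp.

## Chaining and structural variants

`chainAnchors()` performs greedy colinear chaining per molecule pair and
strand with a `maxGap` of 1 kb. Anchors whose query interval maps to
several subject locations are treated as repeat-derived: blocks consisting
only of such anchors and nested inside another block's query span are
dropped rather than down-weighted — a simplification of the usual
unique-anchors-seed-chains heuristic that behaves identically on the
synthetic genomes the package targets, where long repeats are absent.

`callSVs()` classifies discordances from block structure. Per query
molecule the "mainline" is the maximum-weight increasing run of blocks by
subject coordinate; a mainline block with flipped strand is an inversion,
an off-mainline block a translocation (`trans_inv` when also flipped), and
inter-block gaps present on only one genome are insertions/deletions. Gap
spans already occupied by a displaced block are discounted on both genomes,
so a translocation is reported once, not as a spurious
insertion-plus-deletion. The ">1 kb" size rule is implemented strictly
(`size > 1000`). When the assemblies are supplied, the gap wrapping a
circular query origin is analysed too; at a two-circle hybrid's
molecule-split junction, however, the insertion signal is confounded with
the split itself, and a donor segment sitting there (the origin-abutting
R1 situation) is recovered by the attribution path rather than the SV scan.
Two published limitations are accepted as out of reach: published SV
*counts* depend on unstated aligner parameterizations, and breakpoint
precision is inherently `minLen`-limited (anchor ends extend into chance
matches; tests allow a 2x-minLen slack).

## Origin attribution and the alien report

Coverage masks from the two anchor sets are combined position-wise into
`donor` / `recipient` / `shared` / `novel` runs that partition each
molecule. Donor runs are merged across interruptions of at most
`gap = 100` bp (absorbing anchor-edge fragments), filtered at
`minRegion = 1000` bp — the smallest alien region on record is 1551 bp, so
the filter keeps every real-scale region while suppressing edge artifacts —
and labelled R1..Rn in molecule-then-coordinate order. On a circular
molecule a region pair abutting position 1 and the molecule end shares one
label (one region crossing the origin). `compareRegionSets()` maps regions
of a second line onto the first by anchor-mediated sequence identity with a
50%-of-the-shorter reciprocal-overlap rule; unmatched regions are flagged
unique, the signature of donor sequence retained in only one line.

## Coding variants

Orthologous CDS pairs are compared position-wise; codon indices are
`ceiling(pos/3)`, and effects come from translating both codons with the
standard genetic code, which plant mitochondria use. RNA editing is *not*
modelled: the tool reports nucleotide-level truth, and published tables
occasionally contain rows that do not decode under the standard code
(editing or typographic offsets); those are expected disagreements, not
bugs. Length differences divisible by 3 are resolved as a single in-frame
gap at the leftmost minimal-mismatch position (ties break 5'-most); any
other difference is a frameshift record. Positions with `N` are skipped
with a warning.

## Marker screen and in-silico PCR

Primer design is position-driven: amplicons tile each requested region,
both primers sit fully inside it, and a candidate is accepted only if
neither primer nor its reverse complement occurs anywhere in the recipient
(scanned across circular origins). Thermodynamics (Tm, hairpins) are out of
scope — the markers diagnose presence/absence of whole regions, for which
exact 20-mer uniqueness suffices. In-silico PCR calls a product where the
forward primer matches the plus strand and the reverse primer the minus
strand downstream within `maxAmplicon`; product size runs 5' end to 5' end
inclusive. Exactly one product genome-wide is `present`; multi-product
amplifications are scored absent-but-flagged, the in-silico analogue of
rejecting a multi-band gel. Self-reverse-complementary primers legitimately
produce such ambiguity. A mismatch-tolerance knob (with a mandatory
3'-terminal match) exists for robustness studies and is off by default.

## CMS haplotyping

The orf138 family is typed by exact tandem copies of the 39-nt unit
`AAAGGGGAAATAGAGGGGAAAGAGGAAAAAAAAGAGGGG`: 3 copies = orf138 (138 codons),
2 = orf125, 1 = orf112, in 39-bp steps. Copy counting is exact by default
(the haplotypes differ by exact unit steps); `classifyCmsOrf()` checks
frame integrity and, given a reference ORF, counts SNPs by ungapped
comparison of the sequence outside the repeat tract only — whether a
published haplotype's SNPs fall inside or outside the tract is not
documented, so the outside-tract convention is fixed and stated here.
`okbGenotype()` reads the haplotype from the number of unit copies inside
the single OKB amplicon rather than from absolute product size: the real
gene's flanking sequence (hence absolute amplicon size) is not published,
and on exact templates copy count and size rank are equivalent while
needing no calibrator. The 39/78-bp size steps are still asserted in tests.
The scaffold behind `plantCmsOrf()` is synthetic — a fixed non-repetitive
96-codon body in which every codon contains a C (the unit is C-free, so no
spurious copy can straddle the body) and no stop codons occur; class
assignment therefore keys on copy and codon counts, never on the real
gene's non-repeat body. Finer orf138 sub-haplotypes are out of scope (no
sequences published).

## The synthetic generator

`generateTrio()` emulates the study conditions: by default a 221,811-bp
uniform-random circular backbone, a hybrid split into 71,998 + 185,431 bp
circles carrying nine donor segments of 1551/3808/2282/4239/3818/5457/
1727/5916/6820 bp at the published coordinates (35,618 bp, 13.84%), a CMS
construct with three repeat copies inside R8, and a donor that is a
diverged copy of 60% of the backbone (default per-bp substitution rate
0.02, a realistic intra-family mitogenome divergence) plus the unique
segments. Segments are rejection-sampled to share no 31-mer with the
recipient, and their first/last bases differ from the displaced backbone
neighbours so that exact-match attribution recovers planted boundaries to
the base pair — which is why the worked example reproduces the 35,618-bp
total exactly rather than approximately. Planted translocations are kept
well clear of their source (beyond the 1-kb chaining gap): a shorter move
is locally indistinguishable from a small indel at anchor resolution and
would not be a meaningful planted truth. The two-circle split is an
arbitrary cut of the backbone, flagged in the manifest: real multipartite
mitogenomes arise from recombination across large repeats, which the
generator does not model. It also does not model RNA editing,
low-complexity or repeat sequence, chloroplast-derived insertions, or
GC-content structure (a GC knob exists but is cosmetic). Consequently,
passing tests demonstrate correctness of the attribution logic under clean
insert/divergence structure, not robustness to repeat-rich real assemblies.

## Numerical and testing choices

Percent rounding is half-up with a relative-epsilon guard against binary
representation error. A single integer seed drives each generation run via
a save/restore wrapper, so package functions never leak global RNG state
and identical seeds give byte-identical FASTA output. Problem sizes in the
test-suite property checks are the package's own desk-scale choices: the
anchor finder is compared with a quadratic per-diagonal oracle on fifty
random pairs of 600–1100 bp at 2% divergence with a planted inversion;
planted-SV recall/precision runs twenty seeds on 24-kb backbones with a
1.8-kb inversion and a 2.2-kb translocation; alien-region recovery runs
twenty seeds on 70-kb backbones with 1.5–7-kb inserts and requires
position-set Jaccard at least 0.99 against planted truth; the codon-effect
classifier is checked exhaustively over all 549 single-base sense-codon
changes; the repeat counter against a sliding-window oracle on 200 random
constructs. The full-scale (257-kb) trio is exercised end-to-end in the
pipeline tests and the acceptance script.

## Known limitations

Exact-match attribution is blind to donor tracts that have mutated since
transfer (a mismatch-tolerant coverage mode exists but is off by default,
matching the default model of recent transfer); SV classification at
molecule-split junctions is ambiguous by construction; published SV counts
and germplasm screen splits are not reproducible without the original
assemblies and materials, and only the classification rules are
implemented; primer design ignores thermodynamics by design.
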