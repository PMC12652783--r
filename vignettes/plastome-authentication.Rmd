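---
title: "Comparative plastome analysis and authentication-marker design with plastmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis and authentication-marker design with plastmarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastmarker)
```

## The problem

Herbal raw materials are routinely traded sliced or powdered, so closely
related medicinal species — here *Agrimonia* species, the botanical sources
of the drug Agrimoniae Herba — cannot be told apart morphologically.
Chloroplast genomes (plastomes) are compact (~155 kb), uniparentally
inherited, and nearly invariant within species, which makes genome-wide
interspecific differences an ideal substrate for simple PCR assays: a band
of a species-diagnostic size on a gel identifies the species.

`plastmarker` implements the full desk side of that workflow: it takes
assembled, annotated plastomes plus a whole-genome multiple alignment
(e.g. from MAFFT), characterizes the genomes, calls the interspecific
variants, designs PCR markers from the species-specific ones, validates the
markers by in-silico PCR, and summarizes relationships with a distance
phylogeny. A synthetic-genome generator with exact planted truth makes every
stage testable without downloading anything.

## Quadripartite structure

Angiosperm plastomes are circular with four regions: a large and a small
single-copy region (LSC, SSC) separated by two identical inverted repeats
(IRb, IRa). `detect_inverted_repeats()` finds the maximal pair of disjoint
intervals whose sequences are exact reverse complements (k-mer anchors
unique in both the sequence and its reverse complement, grouped by
diagonal, then base-wise extension), and labels the longer gap between them
LSC. Matching is exact by default (`max_mismatch_frac = 0`) because
chloroplast IR copies are kept identical by copy-correction; a tolerance
parameter exists for imperfect assemblies. `N` never matches. Among
equal-length candidates the pair with the smallest start coordinate wins,
which also resolves per-base boundary ties deterministically.

Coordinates are 1-based inclusive everywhere user-facing; all genomes are
assumed (and, by `rotate_genome()`, made) canonical — LSC first, IRb before
SSC — so positions are comparable across species. The detector scans the
linearized sequence, so an assembly whose IR spans the arbitrary origin
should be rotated first; this is the one circularity case the detector does
not resolve on its own.

## Variant model

Variants are read directly off the alignment columns:

* a gap-free column with two or more distinct bases among non-`N` taxa is
  one **SNP** — a pure single-base substitution;
* a maximal run of consecutive columns with an identical per-taxon gap
  pattern, at least one taxon gapped, is one **InDel** event. Its
  `length_bp` is the difference between the longest and shortest ungapped
  allele, so one event contributes one "site" and a separate bp total —
  the dual bookkeeping used for indels throughout the outputs.

Two consequences of this model are deliberate. A substitution that falls
inside an indel footprint is absorbed into the InDel event, keeping the SNP
class pure. And a column polymorphic only because of `N` is not a variant;
`N` taxa are simply ignored at that column. Terminal gap-containing runs
are trimmed before extraction because rotating circular genomes to a common
origin otherwise fabricates indels at the alignment ends. Variants falling
in both IR copies are counted where they occur (twice), matching a
genome-wide variability plot; the tallies are therefore event counts on the
alignment, not collapsed loci.

An event is **species-specific** for taxon *t* when *t*'s allele differs
from the allele shared *identically* by all other taxa (strict rule). With
four taxa a 2-vs-2 split is specific to nobody. Pairwise matrices count,
for each unordered pair, the events at which the two alleles differ, with
`N` excluding the event for that pair only.

The sliding-window profile (defaults 1000 bp window / 200 bp step) anchors
each event at its first alignment column; the coordinate space is
switchable to a reference genome's coordinates, since either convention is
defensible for a genome-wide plot and the alignment axis is the default.

## SNP effects, pseudogenes, SSRs

Coding effects are computed by locating the substitution in annotated CDS
exons, rebuilding the codon, and translating reference versus alternate
with the bacterial/plastid genetic code (NCBI table 11; configurable).
Categories are `intergenic`, `intronic`, `synonymous`, `nonsynonymous`,
`stop_gained`, `stop_lost`. SNPs inside tRNA/rRNA genes have no coding
category and are reported as intergenic — a deliberate simplification,
since downstream marker selection only consumes
nonsynonymous/stop-introducing SNPs. Pseudogene calls come from translating
every CDS: an internal stop strictly before the last codon is a
`premature_stop`; a CDS length not divisible by three is a `frameshift`.

`find_ssrs()` reports maximal perfect tandem repeats of 1-6 bp motifs. The
thresholds (mono >= 10, di >= 6, tri/tetra >= 5, penta/hexa >= 4 units) are
the common plastome-microsatellite convention and are exposed as a
parameter, since no single standard exists. Motifs are canonicalized to the
lexicographically smallest rotation, and a tract is attributed to the
shortest motif explaining it (an `AT` tract is not also reported as
`ATAT`). SSR-overlapping InDels (>= 1 shared bp, in any taxon) are excluded
from marker candidacy: homopolymer/microsatellite length variation is
unstable within species and would make an unreliable marker.

## Marker design

Candidates are species-specific events that survive two filters:
InDels need a length difference of at least 7 bp (small enough products
must still separate on a gel) and no SSR association; SNPs must be
nonsynonymous or stop-introducing, i.e. sites under least risk of being
homoplasic noise and most likely fixed within species.

**Co-dominant InDel markers** amplify in all species, with the target
species yielding a distinct product size. Primers are placed on conserved
flanking windows — alignment columns identical and gap-free across all
taxa — bracketing the event, under the constraints length 18-30 nt, GC
30-70%, Tm 56-65 °C (the gradient-PCR range the assay is optimized in),
amplicon <= 500 bp. All constraints are configurable. The search is
deterministic: the smallest amplicon satisfying everything wins, with a
lexicographic tie-break on the forward primer.

**Dominant allele-specific (ARMS) markers** put one primer's 3'-terminal
base on the diagnostic SNP, equal to the target allele. Because in-silico
(and largely in vitro) extension requires an exactly matched 3' end, only
the target species amplifies. One additional deliberate mismatch is
introduced at offset 3 from the 3' end by a purine-pyrimidine swap; the
policy (offset and substitution choice) is recorded in the marker metadata
since published assays show the modified base only typographically.
Cross-binding screening is a 3'-anchored complementarity check (>= 8 bp
between any two primers of a pair), an in-package stand-in for an online
specificity screen.

Melting temperatures use unified nearest-neighbor thermodynamics
(SantaLucia 1998 parameters; 50 mM monovalent salt via the 0.368·(N−1)·ln[Na+]
entropy correction; 500 nM primer, CT/4 term), reported to 0.1 °C so
results are reproducible bit-for-bit. The reported annealing temperature is
`min(Tm_F, Tm_R) − 3` clamped into the 56-65 °C window.

## In-silico PCR

`scan_primer()` finds all template sites, on both strands and across the
origin of circular templates, where a primer anneals under the rule: the
3'-terminal window (default 3 bases) matches exactly, and at most
`max_mismatch` (default 1) mismatches occur outside it. This rule is what
makes dominant markers dominant — a 3' SNP mismatch kills the site.
Products are every properly inward-oriented site pair within `max_len`
(default 2000 bp), measured 5' end of the forward site through the 5' end
of the reverse site inclusive, the standard PCR product convention. A
marker is classified `codominant` (all taxa amplify, target size unique),
`dominant` (only target amplifies), or `ambiguous`. A sample is called as
the unique reference species whose banding pattern it matches across all
markers, `"unresolved"` otherwise — the product-identification logic of a
gel read-out.

## Phylogeny

Distances are Kimura two-parameter:
`d = -1/2 · ln((1 − 2P − Q) · sqrt(1 − 2Q))` with transition and
transversion proportions `P`, `Q` over usable sites. Sites with a gap or
`N` in either sequence are excluded pairwise (complete deletion would
discard most columns of a whole-plastome alignment). A non-positive
logarithm argument (substitution saturation) is an explicit error rather
than a silent `NaN`.

Trees are canonical Saitou-Nei neighbor joining with deterministic
tie-breaking by taxon order; a negative branch length is clamped to zero
and the deficit moved to its sister branch, preserving the joined pair's
path length. Bootstrap support resamples alignment columns with
replacement, rebuilds the tree per replicate, and reports the percentage of
replicates containing each original bipartition; replicates with undefined
distances are dropped, counted, and warned about. The published analysis
this mirrors fits a maximum-likelihood tree under the same substitution
model; a full ML search is out of scope here, NJ over K2P distances stands
in, and every phylogeny output records that substitution. Species-level
claims (e.g. conspecific individuals clustering) are asserted only on
synthetic data.

## The synthetic truth set

`generate(sim_config(...))` builds a quadripartite ancestor — genes with
valid ORFs (start codon, sense codons, stop), optional two-exon genes,
tRNA/rRNA genes, planted SSR tracts with period-breaking guard bases so
each tract is exactly maximal — and derives four species by planting
events with exact gap bookkeeping. The true alignment is emitted directly,
so tests never depend on an external aligner. Planting is positional, not
a Markovian substitution process: the generator's purpose is recoverable
truth, not evolutionary realism.

The default configuration *is* the study design the package targets:
LSC/SSC/IR of 84,500/18,700/26,000 bp (~155 kb genomes), 79/29/4
protein-coding/tRNA/rRNA genes, 497 SNP events (species-specific counts
118/109/148/96 per taxon plus 26 shared by a sister pair) and 187 InDel
events (49/50/51/37). The published species-specific InDel tallies sum to
more than the published event total, which is internally inconsistent under
any subset reading; the preset keeps the event totals authoritative and
scales the per-taxon InDel splits proportionally. Other fixed choices:
6% of SNPs planted in the IR as mirrored complement pairs (both copies
change identically, preserving IR identity — "predominantly single copy"
in the variability profile); InDel lengths from a mixture (80% 1-6 bp,
20% 7-30 bp) so both excluded and qualifying marker candidates exist; 25%
of single-copy SNPs genic, half of those forced nonsynonymous and 2%
stop-introducing; two SSR-embedded InDels per taxon; one guaranteed clean
(>= 7 bp, non-SSR, 80 bp event-free flanks) marker InDel per taxon; one
premature-stop pseudogene (*infA*-like) and one frameshift pseudogene
(*rps16*-like) in different taxa. Intergenic sequence is drawn at GC 36.9%;
genes use uniform sense codons, which pulls genome-wide GC a few points
above that — a known, accepted artifact.

What passing tests on this generator do **not** show about real data:
alignment correctness (MAFFT's gap placement can differ from the emitted
truth, and published tallies involved manual curation), annotation quality,
intraspecific variation (each species is one haplotype, plus optional
clones with a few private SNPs from `expand_individuals()`), and realistic
homoplasy. They do show that every algorithmic stage is exact on inputs
whose truth is known.

## Numerical and degenerate-input conventions

* Tie-breaks are deterministic everywhere (smallest start coordinate for
  IR candidates, smallest amplicon then lexicographic primer for designs,
  taxon order for NJ joins); reruns are byte-identical, and every output
  file carries its parameter block as header comments.
* Projection of a gapped position reports the flanking pair `p/p+1`
  (`0/1` for a leading gap).
* A sliding window larger than the sequence degenerates to one window; an
  all-gap alignment column, a non-diagnostic SNP offered for ARMS design,
  zero usable sites for a distance, and an all-`N` GC denominator are
  explicit errors.
* Test and example problem sizes are deliberately desk-scale (genomes of
  10-20 kb for unit tests, one ~155 kb preset for integration); they were
  chosen once as representative and are stated in the configs, not tuned.

## Known limitations

GenBank flat-file annotations are not parsed; use GFF3. The IR detector
expects the IR not to span the sequence origin. Marker design assumes the
alignment is correct around the candidate; it does not re-align. In-silico
PCR models primer annealing combinatorially, not thermodynamically — no
primer-dimer free-energy model, no gel-mobility simulation. The phylogeny
module is a distance method; do not read its supports as equivalents of a
likelihood analysis on real data.
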