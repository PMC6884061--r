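---
title: "Methods: homoeolog census, variant multiplicity and synteny in polyploid gene spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog census, variant multiplicity and synteny in polyploid gene spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`polycensus` analyses the gene space of a highly polyploid genome (the
motivating system is a modern sugarcane cultivar, an interspecific
polyploid/aneuploid hybrid with roughly 10--13 chromosome sets) against a
diploid outgroup reference such as sorghum.  Five analyses share one data
model:

1. **Homoeolog census.**  Genes that are single-copy in diploid relatives
   act as *anchors*.  Every polyploid gene copy aligning to an anchor with
   nucleotide identity at least 0.80 and coverage at least 0.70 of *both*
   sequences (inclusive thresholds) joins that anchor's cluster; the
   cluster size is the copy-number estimate.  Copies passing the filters
   for more than one anchor are flagged ambiguous and excluded from counts
   -- exclusion keeps copy-number claims conservative, and a best-hit
   assignment is deliberately not attempted.  Clusters larger than
   `max_copies` (default 20, above any plausible chromosome-set count) are
   discarded with a recorded reason.
2. **Divergence profiling.**  Within each cluster, every unordered member
   pair is globally aligned for the CDS and for upstream windows of 100,
   500 and 1,000 nt ending at the start codon.  Dissimilarity is
   `(mismatches + gap columns) / columns`, the exact complement of
   identity, and per-region medians are pooled over all pairs of all
   clusters.  Upstream records whose aligned spans deviate from the window
   length by more than 20% are discarded as partial alignments; the CDS is
   exempt because its full length is always available.
3. **Indel frame spectrum.**  Gap runs from the CDS pair alignments are
   pooled into a length histogram; a run is frame-preserving iff its
   length is a multiple of 3.  The original procedure extracted pairwise
   combinations from a multiple alignment; this package aligns the pairs
   directly, which removes the MSA dependency and coincides with the MSA
   definition whenever indels do not overlap -- the regime the simulator
   produces and the tests exercise.
4. **Variant multiplicity and large effects.**  At every reference CDS
   position where at least one copy differs, the *multiplicity* is the
   number of distinct alleles among the observed copies (the reference
   allele counts when some copy still carries it): mono- to tetra-allelic.
   Copies with a mapping quality present and not strictly greater than 20
   are excluded, and an anchor yields sites only when at least 2 copies
   remain.  Substitutions are classified by positional rules --
   premature stop, stop loss, start loss, splice disruption (first/last
   2 nt of an intron), frameshift for indels of length not divisible by 3
   -- and validated against an independent mutate--splice--translate
   reference that knows nothing about the rules.  The "homozygous in the
   polyploid" pre-filter of the original large-effect analysis maps to
   multiplicity-1 sites here, the only within-package reading of
   homozygosity across assembled copies.
5. **Synteny blocks and fragmentation null.**  Cross-genome alignments
   passing e-value ≤ 1e-5, coverage ≥ 0.70 (both sides) and identity
   ≥ 0.80 become edges; ortholog groups are connected components under a
   hand-written union--find with path compression (the partition property
   is tested against an independent graph-components implementation).
   Groups with exactly one reference gene and members in all required
   genomes are anchors; anchors are ranked per sequence by coordinate.  A
   *block* is a maximal anchor run whose reference ranks step by exactly
   +1 (forward) or -1 (inverted, strand-discordant) per junction on a
   single reference chromosome; a contig is *fully syntenic* iff it has
   ≥ 2 anchors covered by exactly one block.  Strict rank adjacency is the
   primary definition because it makes "blocks = planted breakpoints + 1"
   an exact identity; a `monotone` relaxation is available behind a flag.
   The Monte Carlo null fragments an unassembled comparison genome in
   *gene space*: per fragment a gene count is drawn from the observed
   genes-per-contig distribution and a uniformly random run of that many
   consecutive genes is taken, because block counting depends only on gene
   content, not base-pair extents.  Per round, the relative frequency of
   fragments per block count is recorded; dispersion across rounds shrinks
   as `1/sqrt(rounds)`.
6. **Expression census.**  A copy is *expressed* iff its abundance is
   strictly greater than 1 (FPKM-scale, but the column is treated as a
   unitless abundance) in at least one sample; sense and antisense
   orientations are tallied independently, and a per-sample mode is
   available.  The headline output is the percentage-frequency table over
   (copies, expressed copies), which sums to 100 by construction.

# The synthetic allopolyploid generator

Because the real analyses run on a multi-gigabase assembly, every stage is
validated on synthetic genomes with fully recorded ground truth.  The
generator is first-class, tested code, and its defaults *are* the study
conditions:

* **Ancestor.**  `generate_ancestor()` builds a diploid gene set on
  chromosomes: random CDSs (ATG, sense codons, one stop; lengths 300--600,
  multiples of 3) plus exactly 1,000 nt of upstream sequence abutting the
  start codon.
* **Copy counts.**  Supported on 1..15 with mode 2--6, matching the
  copy-number range reported for single-copy grass genes in sugarcane.
* **Divergence.**  Substitution rates are *per copy per site*, uniform
  over the three alternative bases (a Jukes--Cantor-like choice; no
  substitution model is prescribed by the motivating study).  Two copies
  independently mutated at rate $r$ differ at a site with probability
  $d(r) = 2r - \tfrac{4}{3}r^2$; `pairwise_to_copy_rate()` inverts this,
  and the default rates are chosen so that expected pairwise divergences
  equal the reported medians: 0.90% (CDS), 1.03% (100 nt), 4.47%
  (500 nt), 7.50% (1,000 nt).  Upstream divergence is implemented as
  three concentric zones (0--100, 100--500, 500--1,000 nt from the start
  codon) whose rates are derived from the window-level targets, because
  the reported statistics are window medians, not a functional form.
* **Separability constraints.**  Background CDS substitutions avoid
  creating stop codons and skip the first and last codon; CDS indels skip
  them too.  This keeps background variation and planted large-effect
  variants separable in the truth record, so the effect classifier can be
  scored exactly.
* **Indels.**  Poisson events per kb with geometric-ish lengths 1--30 and
  a configurable frame-preserving fraction for the CDS (default 0.65,
  frame-preserving more common than frameshift).  The length distribution
  is a stand-in: the motivating study reports only the qualitative shape.
* **Variant sites.**  Planted at distinct interior CDS positions shared
  across copies; the allele-multiplicity distribution defaults to the
  observed class mix (12.03% mono-, 80.8% bi-, 6.2% tri-, 0.97%
  tetra-allelic).  A site of multiplicity $m$ needs $m \le k$ copies, so
  the drawn class is conditioned on the gene's copy count; simulations
  that score class proportions fix $k \ge 4$ so all four classes are
  realisable.  The number of planted sites per gene
  (`snv_sites_per_gene`) is a generator parameter with no counterpart in
  the original study, which observed sites rather than planting them.
* **Genome structure.**  Copies are laid out on homoeologous chromosome
  sets: set $i$ carries copy $i$ of every gene with at least $i$ copies,
  preserving ancestral order -- subgenomes with gene loss.  Inversions
  reverse runs of ≥ 2 copies and flip strands; translocations move runs
  across chromosomes.  Event runs are sampled disjoint and non-adjacent so
  each created junction belongs to exactly one event, and every junction
  is recorded as a breakpoint.  Fragmentation cuts chromosomes into
  contigs following a genes-per-contig distribution (the last contig of a
  chromosome may be truncated); contigs carry upstream + CDS cassettes
  separated by 200 nt of neutral spacer, whose content is immaterial to
  every stage.
* **Expression.**  Copies are expressed with probability `expressed_frac`
  (default 0.7); expressed copies are antisense-only with probability
  `antisense_frac` (default 0.05, antisense transcription is rare).
  Expressed orientations draw log-normal abundances truncated above 1;
  silent sense orientations draw from `[0, 1]`.

What the generator does **not** emulate: read-level noise (abundances are
given directly, not quantified from reads), transposable elements,
tandem duplications, paralogy in the reference, GC heterogeneity, and
assembly errors.  Passing tests therefore demonstrate the correctness of
the analytic machinery under the stated statistical structure, not
robustness to artefacts of real assemblies.

# Numerical and design choices

* **Alignment.**  The affine-gap dynamic programs (global and local) are
  implemented in C++ with a fixed traceback tie order (diagonal, then gap
  in subject, then gap in query) so gap runs -- and hence the indel
  spectrum -- are deterministic.  A gap run of length $L$ costs
  `gap_open + L * gap_extend`; default scores are +1/-1 with gaps -2/-1.
  Scores are validated against an exhaustive enumeration of all gapped
  alignments on short sequences and against an independent aligner
  implementation.  Gap columns count toward alignment length and hence
  reduce identity, matching common local-aligner semantics.  No heuristic
  seeding is attempted at scale; the package shortlists anchor-copy
  candidates by exact shared k-mers (k = 15, sampled every 7 positions, 2
  shared k-mers required) and verifies by full dynamic programming.  Users
  with large inputs supply 12-column tabular alignments from an external
  aligner instead.
* **Coordinates.**  0-based half-open internally; 1-based inclusive in
  GFF3 and tabular files; `sstart > send` encodes the minus strand on
  input, and the conversion is an involution.
* **Coverage.**  Computed from the single best alignment's span, not from
  unions of multiple high-scoring pairs; documented because the original
  description leaves this open.
* **E-values.**  Honoured when consuming external tabular alignments;
  internally produced alignments have no database-size model, so the
  e-value filter passes them and the score column carries the DP score --
  a documented dialect difference.
* **Base-change tallies.**  "Counted according to 4-base changes" is
  implemented as the full 12-cell `ref>alt` table (each distinct
  alternative allele of a site contributes one tally), with a documented
  collapse to 4 reference-base classes, since the fuller table subsumes
  any coarser reading.
* **Enrichment.**  The binomial test uses the upper tail
  $P(X \ge k)$, $X \sim \mathrm{Bin}(n, p)$ with $p$ the background term
  proportion, and flags significance at $P < \alpha$ (the source prints
  "$P > 0.05$", read as a typo for $P < 0.05$).  No multiple-testing
  correction by default, matching the original raw threshold; a
  Benjamini--Hochberg column is available.
* **Degenerate inputs.**  Empty sequences, empty alignments, zero-rate
  configurations, single-member clusters, anchors without ranks and
  fragment sizes exceeding every sequence are all defined errors or
  defined no-ops, covered by tests.
* **Randomness.**  Every stochastic function takes a seed and restores
  the caller's RNG state; the pipeline derives per-stage seeds from one
  root seed by fixed offsets, so stages can be toggled without changing
  each other's streams, and a fixed seed reproduces outputs byte for
  byte.

# Validation problem sizes

The test suite and the acceptance script validate each stage at sizes
chosen to give stable statistics on one CPU: 300 anchor genes for
copy-number recovery and for the divergence gradient (about 200--300
multi-copy clusters and several thousand pair records); ~10,000 planted
CDS indels (8,333 two-copy genes of 600 nt at 1 indel/kb -- the density is
kept low because adjacent gap runs merge during alignment, which would
bias the recovered frame-preserving fraction at higher densities);
~10,000 planted variant sites (400 genes, 6 copies each, 25 sites per
gene); 1,000 random gene models for effect classification; 500/200
random pairs for global/local alignment enumeration; 1,000 random graphs
for the union--find partition property; 150-gene uniform-ploidy genomes
for synteny exactness; and a 1,000-fragment x 20-round fragmentation
null.  Copy numbers are held constant in the synteny simulations because
gene loss on homoeologous chromosome sets breaks strict rank adjacency by
itself; uniform ploidy isolates planted rearrangements as the only
breakpoint source, making the block-count identity exact.  The
multiplicity simulations fix six copies per gene so that tetra-allelic
sites are realisable.

# Known limitations

* Pairwise-combination indel spectra slightly undercount and reshuffle
  events when two indels abut in the same alignment; the effect scales
  with indel density and is kept below the statistical resolution of the
  validation at the default densities.
* Copy-number recovery is reported for the synthetic regime (divergence
  ≤ 5%, no reference paralogy); real assemblies add collapse/duplication
  artefacts the census cannot distinguish from biology.
* The effect classifier's splice rule covers the canonical GT/AG
  dinucleotides only, and classifies indels by their start position when
  they span a boundary.
* `fully_syntenic` requires ≥ 2 anchors, so single-anchor contigs are
  uninformative for synteny and excluded from those denominators.
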