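---
title: "Methods: satellite repeat characterization with satkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite repeat characterization with satkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

satkit characterizes satellite DNA — non-coding tandem repeats organized in
head-to-tail monomer arrays — from the monomer up to the chromosome: tandem
periodicity and monomer extraction, majority-rule consensus building,
higher-order-repeat (HOR) subunit decomposition, monomer diversity and
neighbor-joining dendrograms with a species-specificity score, genome-wide
similarity scanning with satellite–transposable-element (TE) association and
target-site-duplication (TSD) detection, distribution classification along
pseudochromosomes, and copy-number estimation from read-cluster genome
proportions. A seeded synthetic genome generator with machine-readable
planted truth provides the validation substrate; every quantitative claim in
the test suite is a truth-recovery or oracle-equivalence statement on that
substrate plus a small set of published worked numbers.

# Sequence primitives

Coordinates are 0-based half-open everywhere inside the package and 1-based
inclusive only in GFF3 output (`write_gff3()`); BED output stays 0-based
half-open. Sequences are uppercase strings over {A,C,G,T,N}; IUPAC ambiguity
codes other than N are folded to N on FASTA input, with a warning.

Pairwise alignment is plain Needleman–Wunsch / Smith–Waterman with linear gap
penalties, implemented in C++ for speed. Default scoring is match +2,
mismatch −3, gap −5; no scoring scheme is canonical for satellite work, and
these values sit near the tandem-repeat-finding parameter families in common
use. Two deliberate conventions:

* **Identity** = matching columns / all alignment columns, so gap columns
  count against identity, and N matches nothing. This is the strictest
  reproducible definition; published identity percentages rarely state their
  denominator, so values here are internally consistent rather than
  tool-identical.
* **Traceback ties** break diagonal, then up, then left. Alignments are
  therefore byte-deterministic, which the exact oracle tests rely on.

# Synthetic data generator

The generator emulates the statistical structure of a satellite survey:

* `make_random_sequence()` draws i.i.d. bases at a target GC (backbone
  default 38%, a typical plant genome-wide value).
* `apply_mutations()` applies per-site independent substitutions (to a
  uniformly chosen different base), single-base insertions and deletions.
  All rates live in [0, 0.5).
* `build_array()` mutates each copy independently from the shared template
  (star phylogeny) — the simplest model consistent with reporting divergence
  from a consensus. Serial (copy-of-copy) evolution and unequal-crossover
  dynamics are deliberately not modeled.
* `build_te_with_satellite()` plants satellite units inside LTR
  retroelements (one unit embedded per LTR) or TIR DNA elements (units
  tandem or spacer-separated inside the body).
* `assemble_chromosome()` splices features into a backbone; TE insertions
  duplicate the target-site k-mer on both sides, the biological TSD
  mechanism. Insertion sites whose flank context would extend the
  duplication into a longer boundary-anchored exact match are shifted a few
  bases so the planted TSD length is the unique answer — this keeps TSD
  detection well-posed as a ground-truth recovery problem.
* `simulate_clone_set()` cuts PCR-multimer clone sequences between a
  forward-primer 5' end and the reverse-primer 5' end n monomers downstream,
  so clone lengths obey the amplicon ladder law (below).

Family presets (`sat_family_presets()`) mirror the published monomer lengths
(146, 238, 154, 37, 49, 70 bp) and GC contents (18–41%). Their HOR
architecture follows the two arrangements seen in real families: a
**three-part** monomer S1-1 + S1-2 + S2 (two diverged variants of a ~27-bp
subunit followed by a long unique subunit) and a **two-part** monomer
S1 + S2 in which S2 *begins with* a diverged echo of S1. Planted divergences
are 5% between monomer copies and 10–15% between subunit variants. The
15% (three-part) value is below the 33–59% divergence reported between real
S1-1/S1-2 variants: a 27-bp echo at ~50% identity inside an AT-rich monomer
is statistically indistinguishable from background self-similarity (the
null match probability of an AT-rich sequence is ~0.35 per position), so the
generator defaults sit at the detectable end of the 10–50% regime and the
package makes no claim of recovering by-eye subunit calls on real clones.

What the generator does **not** emulate: sequencing error profiles,
chimeric PCR products, nested/fragmented TEs, centromere-scale array
heterogeneity, and library-model dynamics across species. Passing tests
therefore demonstrate correctness of the algorithms under a clean, known
model — not performance on real assemblies.

# Tandem periodicity and monomer extraction

`estimate_period()` maximizes autocorrelation support — the fraction of
positions whose base matches the base one lag away — over a lag range, with
two refinements: a smaller lag within 0.05 support of the maximum is
preferred (sub-multiple resolution), and estimates with support below 0.60
are rejected as non-tandem. At 5–10% planted substitution divergence,
support at the true monomer length is ~0.85–0.90 while random AT-rich
background stays near 0.35, so the 0.60 threshold separates the two regimes
cleanly across the full 36–240 bp monomer range.

`extract_monomers()` cuts an array or multimeric clone either at successive
best local alignments of a reference consensus (each accepted hit is masked
and the search repeated) or at `phase + n × period` in period mode, where
the phase maximizes mean identity between consecutive blocks. A fragment
counts as a monomer only if it is *strictly longer* than half the reference;
shorter terminal fragments are returned as partials (so a clone of 2.5
monomer-lengths yields exactly 2 monomers + 1 partial).

`build_consensus()` aligns monomers with the progressive aligner and takes
per-column majorities, dropping majority-gap columns; ties break in the
fixed order A < C < G < T.

# Dotplots

`wordmatch_segments()` reports maximal diagonal runs in which every k-window
has at most S mismatches (defaults k = 10–12, S = 2–3 for cross-monomer
comparison; k = 8 for sub-monomer structure, since 36-bp monomers cannot
support longer words). `windowed_dotplot()` scores fixed-length windows at
+5/−4 (the classic DNA dotplot matrix), which makes the conventional
window 14 / threshold 27 setting meaningful: at least 7 of 14 positions must
match. Both are verified against dense brute-force window enumeration on
hundreds of random pairs; agreement is exact, not approximate.

# HOR decomposition

HOR subunits in this package are *adjacent diverged duplications*: the
monomer starts with a subunit whose echo immediately follows. The detector
works on the family consensus (majority voting first removes inter-monomer
noise, so the comparison sees the template-level variant divergence):

1. For every lag d from 8 bp to half the monomer, compare positions [0, d)
   with [d, 2d) and count matches M.
2. Test M against Binomial(d, p0), where p0 is the sum of squared base
   frequencies of the consensus *excluding the echo copy* — AT-rich
   monomers have p0 ≈ 0.35, far above the naive 0.25, and including the
   duplication itself would inflate the estimate further. Bonferroni-correct
   over all lags at family-wise alpha 0.05.
3. A lag is also accepted outright when inter-copy identity M/d reaches 0.8,
   the similarity level conventionally used to call satellite homology; this
   adds about 1% false positives summed over the short lags and rescues
   short subunits whose counts are too discrete for the binomial test.
4. Among accepted lags, the most significant wins, except that a smaller
   accepted lag that *divides* it (within ±1) with comparable support takes
   precedence — true sub-multiple resolution that does not let unrelated
   short lags hijack the call.
5. Emission: if the remaining tail (L − 2d) is at least 2d, the model is
   three-part (S1-1, S1-2, S2); otherwise two-part (S1 = [0, d),
   S2 = [d, L), with the echo absorbed into S2). This single rule reproduces
   both published arrangements — the long-tail families report their variant
   pair explicitly, the short-tail families report S1 + S2.

A known, quantified limit: for a 10-bp subunit at 10% variant divergence the
planted echo itself has P(≥8/10 template matches) = 0.93, and 7/10 cannot be
called significant at any false-positive rate compatible with the no-HOR
controls, so per-replicate recovery is capped at ~93% by the planted truth,
not by the detector. The recovery tests use 150 seeded replicates per family
so the measured rate is dominated by the method rather than by sampling
noise. Dinucleotide-shuffled monomers yield multi-subunit calls in ~2–6% of
replicates — the false-positive cost of the detection power above; a rule
that never fired on shuffled AT-rich monomers would also miss most real
short subunits.

`assign_subunit_variants()` clusters subunit instances by average linkage on
pairwise identity and keeps the cut (up to 3 classes) maximizing the
within-minus-between identity gap when it reaches 0.1; otherwise one class.

# Diversity and species specificity

`progressive_msa()` builds a guide tree from fraction-of-common-4-mer
distances (average linkage) and merges profiles with the same scoring and
tie-breaking as the pairwise aligner, so a two-sequence alignment reduces
exactly to `global_align()`. No claim of MAFFT-identical columns is made.

`nj_tree()` is canonical neighbor-joining with lowest-label-pair
tie-breaking and negative branch lengths clamped to zero (flagged).
Neighbor-joining replaces approximate-ML tree building deliberately:
dendrograms are used here only for qualitative clustering, and NJ is
deterministic and exactly testable — it provably inverts additive matrices,
which the suite verifies against random trees and against ape's independent
implementation.

`species_specificity()` operationalizes qualitative "species-specific"
judgments as: score = mean within-species identity − mean between-species
identity in percentage points, with a verdict requiring score ≥ 5 points
*and* at least one species monophyletic in the NJ tree. The 5-point
threshold is this package's choice (configurable); both components are
always reported so users can apply their own criterion.

# Genome scanning and TE association

`scan_similarity()` is seed-and-extend: exact 11-mer seeds are grouped into
diagonal clusters, each candidate window is extended by local alignment, and
hits must reach the identity and query-coverage floors (defaults 0.80/0.80).
Accepted hits trigger an outward walk of one query-length per step so array
interiors are recovered even where divergence happens to destroy every seed
of one monomer. Overlapping same-strand hits (>50% of the shorter) merge,
keeping the best identity. Note that the floors apply to the *local*
alignment of the hit: a copy at 20–30% global divergence can legitimately
crest an 0.80 local-identity floor after end-trimming, so planted-divergence
recall claims are made at 10% (total recall) and 40% (total rejection).

`cluster_hits()` applies the 75%-identity / 75%-of-longer-length
single-linkage rule used for repeat-family grouping, with a majority-rule
consensus per cluster. `detect_tsd()` returns the longest exact match
(2–12 bp) between the left-flank suffix and right-flank prefix anchored at
the element boundaries; fuzzy TSDs are out of scope since TSDs function here
as insertion hallmarks. `classify_association()` calls `tandem_in_te` for
≥2 inside hits with inter-hit gaps ≤25% of the query length,
`dispersed_in_te` for inside hits failing that, and `standalone_array` for
adjacent hits outside any element.

# Distribution along pseudochromosomes

`annotate_chromosomes()` runs the scan per chromosome and strand at the
0.80/0.80 floors — the operationalization of annotation "at 80% similarity"
(the original tool's metric is undocumented, so both knobs are exposed).
Records chain into *runs* when gaps are ≤100 kb (configurable; chosen to
merge arrows within one array cluster at chromosome scale). Per chromosome:

* **absent** — no records;
* **central** — ≥80% of records inside the middle third (a positional proxy
  for the centromere-proximal region of metacentric chromosomes) and ≤2
  runs;
* **dispersed** — records span ≥80% of the chromosome, runs are mostly
  isolated monomers (at least max(3, records/2) runs) and no run holds >30%
  of records;
* **multisite** — otherwise (≥3 clustered runs, or off-center placement).

The run-sparsity condition in "dispersed" is this package's addition: five
small arrays spread along a chromosome would otherwise satisfy both the
multisite and dispersed definitions. The family-level pattern is the modal
per-chromosome pattern among chromosomes carrying records (ties resolve
central > multisite > dispersed). Overlapping same-strand records are merged
before counting, so nested matches are not double-counted.

# Copy number and amplicon ladders

Copy number = ⌊genome size × genome proportion / monomer length⌋.
Truncation, not rounding, is used: it is the only convention that exactly
reproduces the published worked values (10 987, 2 326, 1 905, 1 438, 4 632,
6 618 at a 470-Mb genome). Two published values are *not* reproducible from
their printed inputs under any rounding convention (the 146–147-bp family's
31 439, off by ~500–700, and the 238-bp family's 2 436 vs a computed 2 449);
they are treated as source-table inconsistencies and excluded from exact
checks. The 36–38-bp family reproduces its printed value only at the
midpoint length 37, which is used as the canonical length without asserting
that the original authors computed it that way.

Amplicon ladders for outward-facing primers: first band = (monomer length −
forward-primer start) + reverse-primer 5'-end position; band n adds (n−1)
monomer lengths — so a 146-bp monomer with the published primer geometry
gives 119, 265, 411, … Secondary primer binding sites on the consensus
enumerate as off-ladder cross-products.

# Problem sizes and determinism

The test suite and acceptance script run, by design, at desk scale: the
TE-archetype sweep uses 100 seeds × 4 mini-chromosomes (~8 kb each), HOR
recovery uses 150 replicates × 10 monomers per family, the annotation
scenario uses 12 chromosomes × 1.2 Mb (chromosome length chosen so that
TE-borne single monomers spaced ~130 kb apart fall in separate 100-kb runs),
and oracle equivalence uses 200 random pairs ≤100 bp plus exhaustive
alignment enumeration ≤12 bp. All randomness flows from explicit integer
seeds through a fixed child-seed derivation, so every reported number is
bit-reproducible.

# Known limitations

* Alignment gaps are linear, not affine; protein alphabets and FASTQ input
  are out of scope.
* HORs spanning multiple monomers (dimer-periodic arrays) and
  chromosome-scale HOR haplotypes are not modeled.
* The scanner is desk-scale (Mb chromosomes); it is not a genome-scale
  all-vs-all k-mer indexer.
* De novo TE discovery is out of scope: association calls take element
  bounds from annotation (planted truth in the synthetic setting).
* Real-clone identity ranges and dendrogram topologies from public
  accessions require external downloads and are intentionally not acceptance
  surfaces; the synthetic analogues substitute for them.
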