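# satkit — satellite DNA repeat characterization

satkit is an R toolkit and analysis workflow for characterizing satellite
DNA — non-coding tandem repeats organized in long head-to-tail monomer
arrays — in plant genomes. It is aimed at repeat biologists who have
candidate satellite families (consensus monomers and genome proportions from
read clustering) and want to take them through the full downstream
characterization:

* **Tandem structure** — periodicity detection, monomer extraction from
  multimeric clone sequences, majority-rule consensus building, and
  mismatch-tolerant k-mer / windowed dotplots.
* **Higher-order repeats (HOR)** — decomposition of monomers into internal
  subunits (the S1-1 + S1-2 + S2 and S1 + S2 arrangements typical of
  satellite families), variant classification, and per-species subunit
  statistics.
* **Diversity** — progressive multiple alignment, identity/distance
  matrices with optional primer-region masking, neighbor-joining
  dendrograms, and a species-specificity score.
* **TE association** — seed-and-extend genome scanning, 75%/75%
  single-linkage hit clustering, target-site-duplication (TSD) detection at
  element boundaries, and classification of satellite–transposable-element
  arrangements (tandem-in-TE, dispersed-in-TE, standalone array).
* **Chromosome distribution** — annotation along pseudochromosomes at an
  80% similarity floor and classification of each family's pattern as
  central, multisite, dispersed, or absent.
* **Quantification** — read-cluster copy numbers and PCR amplicon-ladder
  prediction for outward-facing primers.

A seeded synthetic-genome generator plants arrays, HOR structures, TE
insertions with TSDs, and clone sets with machine-readable truth, so every
stage is validated by ground-truth recovery.

## The core quantities

Copy number from read-cluster output:

```
copies = floor( genome_size × genome_proportion / monomer_length )
```

Amplicon ladder of outward-facing primers on a monomer of length L, with the
forward primer starting at position f and the reverse primer's 5' end
projecting to position r:

```
band(n) = (L − f) + r + (n − 1)·L        n = 1, 2, 3, …
```

HOR detection compares the consensus prefix [0, d) with [d, 2d) at every lag
d and accepts a lag when the match count beats a composition-calibrated
binomial null (family-wise α = 0.05) or inter-copy identity reaches 0.8; a
long remaining tail yields a three-part model (S1-1 + S1-2 + S2), a short
one a two-part model (S1 + S2).

## Worked example

Simulate a 146-bp satellite family with a three-part HOR structure, build
its consensus, and decompose it:

```r
library(satkit)

sc <- scenario_hor_monomers("sat1", seed = 11)   # 10 monomers, 5% divergence
hm <- decompose_monomer(sc$monomers)
hm
#> HOR model: lag 27 bp, inter-copy identity 0.89 (p = 5.5e-10)
#>  label start end
#>   S1-1     0  27
#>   S1-2    27  54
#>     S2    54 146
```

The 27-bp duplicated subunit and its boundaries {0, 27, 54, 146} match the
planted truth exactly. Copy numbers from the shipped family descriptors at a
470-Mb genome:

```r
fams <- vaccsat_families()
copy_number(470e6, fams$proportion[fams$family == "VaccSat3"], 154)
#> [1] 10987
```

and the amplicon ladder for the 146-bp family's primer geometry:

```r
primers <- primer_pair(forward_start = 47, forward_end = 67,
                       reverse_start = 0, reverse_end = 20)
predict_amplicon_ladder(primers, 146, n_max = 4)
#> amplicon ladder (monomer 146 bp): 119, 265, 411, 557 bp
```

## The analysis workflow

The `analysis/` scripts re-run the whole study on synthetic data and write
tables under `results/`:

```sh
Rscript analysis/01_simulate.R                # clone sets, TE archetypes, genome
Rscript analysis/02_characterize.R            # consensus, HOR, dendrograms
Rscript analysis/03_te_association.R          # TE calls, TSDs, hit clusters
Rscript analysis/04_chromosome_distribution.R # annotation + patterns
Rscript analysis/05_copy_numbers.R            # copy numbers + ladders
```

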