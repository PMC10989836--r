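---
title: "Designing minimal degenerate primer panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing minimal degenerate primer panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerpanel)
```

## The design problem and the model

`primerpanel` designs one compatible set of degenerate primer pairs for a
large, diverse collection of nucleotide targets — the panel behind an
ultra-multiplex PCR or a targeted-sequencing assay. The pipeline follows
the divide-and-conquer structure that makes this tractable: group the
input by sequence identity, design degenerate primers per group, and
merge the per-group pairs into one panel under dimer and specificity
constraints. Three modelling choices carry the method.

**Mismatch tolerance via the Y-distance.** Hybridization tolerates a
small number of mismatched bases, especially away from the 3' end where
the polymerase extends. The package therefore scores a primer against a
target by the *Y-distance*: the list of positions (1-based from the 5'
end) whose target base is not contained in the primer's IUPAC code. A
target is accepted when the list has at most `max_mismatch` entries
(0–2; default 1) and none lies within the 3'-terminal `coordinate` bases
(default 4; 0 disables). Containment is arithmetic on a value table:
plain bases carry `1 + w/16` with binary weights `w = 1, 2, 4, 8` for A,
G, C, T, degenerate codes the sum of their contained bases. The
fractional bit pattern makes all fifteen values distinct, the integer
part the degeneracy, and `value(d) − value(b)` a table value exactly when
`b` is contained in `d` — the properties the containment test needs, each
verified exhaustively in the test suite.

Tolerated mismatches are what keep degeneracy small. The bundled
`example_ten_targets()` set makes the trade concrete: nine biallelic
positions force an exact-cover primer of degeneracy $2^9 = 512$, while
one tolerated mismatch admits a degeneracy-4 primer covering all ten
targets (codes only at the two recurrent positions; the seven singleton
variants ride on the mismatch budget).

**Nearest-neighbour seeding.** Within each low-entropy alignment window
the designer records per-position base frequencies and adjacent
dinucleotide (nearest-neighbour) counts. Two seeds start the search: the
most frequent window variant, and the Viterbi path maximizing
$\sum_i \log(f_i(b_i)+1) + \sum_i \log(nn_i(b_{i-1},b_i)+1)$ — the
pseudocount keeps zero counts finite, and the NN term lets linked
variation pull the path away from the per-position majority. From each
seed, degeneracy grows greedily one `(position, base)` addition at a
time, always taking the largest gain in mismatch-tolerant coverage
(ties: smaller degeneracy increase, then the 5'-most position, then
alphabetical base), stopping at `coverage_target`, at the `max_degeneracy`
cap, or at zero gain. All visited primers from both seeds are pooled and
the Pareto front (coverage descending, degeneracy ascending) is kept.
Greedy expansion is locally optimal, not globally: on random small
instances it attains the exhaustive optimum in a clear majority of cases
but is not guaranteed to, which the test suite asserts at exactly that
strength.

**Dimer loss and greedy assembly.** Panel compatibility uses an
empirical loss over every ungapped antiparallel complementary run between
two primers,
$\mathrm{loss} = \log_{10}\left(2^{L_r} 2^{GC} / ((2^{d_1}-0.9)(2^{d_2}-0.9))\right)$,
with $L_r$ the run length, $GC$ its G/C count and $d_1, d_2$ the
distances from the run to each primer's 3' end; $\ge 3.96$ is high risk,
$\le 3$ low. Degenerate primers are scored on the worst member pair of
their (capped) expansions — conservative by design, since every expansion
species is present in the tube. Clusters are processed by decreasing
size; a cluster's highest-ranked pair is accepted only if every one of
its primers stays below high risk against all already-accepted primers
(and, when a host FASTA is supplied, shows at most `max_offtarget`
off-target units); otherwise the next-ranked pair is tried, and an
exhausted cluster enters the panel uncovered with its best pair exported
as a cluster-specific alternate. The accepted panel's full pairwise loss
matrix is recomputed afterwards as an independent audit.

## Tunable parameters

| key | default | meaning |
|---|---|---|
| `identity` | 0.8 | clustering identity threshold |
| `max_mismatch` | 1 | Y-distance budget (0–2) |
| `coordinate` | 4 nt | protected 3'-terminal bases |
| `entropy_max` | 3.6 bits | window variant-entropy cutoff |
| `primer_len_min/max` | 18–27 nt | scanned window lengths |
| `max_degeneracy` | 64 | per-primer degeneracy cap |
| `coverage_target` | 0.98 | per-primer design stop |
| `loss_high` / `loss_low` | 3.96 / 3.0 | dimer risk thresholds |
| `tm_diff_max` | 8 °C | midpoint-Tm difference cap within a pair |
| `min_product`–`max_product` | 100–1500 nt | product size range |
| `subsample_n` | 500 | sequences aligned per cluster |

Three defaults deserve their rationale:

* `coverage_target = 0.98` is deliberately above a typical panel-level
  goal of 0.95 because a *pair* covers the intersection of what its two
  primers cover; with roughly independent residual variation at the two
  sites, per-primer coverage must carry headroom
  ($0.98^2 \approx 0.96$).
* `tm_diff_max = 8` °C applies to the midpoint Tm of each primer's
  expansion. The expansion of a degeneracy-64 primer already spans
  several degrees, and multiplex amplicon protocols anneal with
  touchdown ramps, so a plain-primer 5 °C convention would contradict the
  degeneracy the designer is allowed to introduce.
* the entropy cutoff 3.6 bits reads as "about a dozen equi-frequent
  window variants": beyond that, degenerate design has too many variants
  to absorb. Entropy is computed on the distribution of distinct
  window variants, not summed per column — the cutoff then has that
  clean reading, and the estimator is switchable behind
  `window_entropy()`.

Melting temperatures use unified nearest-neighbour thermodynamics with
the $0.368(N-1)\ln[\mathrm{Na^+}]$ entropy salt correction at 50 mM
monovalent salt and 50 nM total oligo ($C_T/4$ pairing term, $C_T/2$ for
self-complementary members), cross-checked in the tests against an
independent published calculator to under 0.5 °C.

## What the synthetic generator emulates — and what it does not

`synth_panel()` builds the study conditions the package validates
against: 8 families × 50 sequences × 500 nt by default. Each family
descends from an independent random ancestor (inter-family identity
≈ 25%) by i.i.d. per-site point mutation at 5%; two 30 nt regions —
a forward and a reverse primer site flanking a ~270 nt product — mutate
at 1% instead ("conserved, with drift"). The 30 nt site width is chosen
so the full scanned primer-length range (18–27 nt) fits inside a
conserved region, as it would in the conserved motifs real panels target;
the 1% residual drift keeps the recovery problem honest (primers must
absorb recurrent variants as codes and ride singletons on the mismatch
budget) rather than letting a perfect-match primer fall out of the
alignment.

The generator does **not** emulate: insertions/deletions at scale (the
aligner handles planted indels, but the study panel is indel-free),
recombination, compositional bias, uneven family abundances, or
sequencing artefacts. Passing the recovery tests therefore shows the
machinery is correct under clean family structure — it does not promise
any particular coverage on real corpora, where conserved regions are
rarer and dirtier.

On these conditions the full pipeline recovers the planted 8-family
partition at identity 0.8, accepts one pair per family, reaches ≥ 95%
accumulated in-silico coverage at one tolerated mismatch, and leaves a
pairwise loss matrix entirely below 3.96 — recomputed from scratch by
`scripts/acceptance.R` and asserted by the acceptance tests. These
problem sizes (400 sequences of 500 nt; subsample 500 so every member
aligns) are the package's validation scale, chosen to keep a full run
around a minute.

## Numerical and degenerate-input choices

* **Ties.** Viterbi ties break toward the lexicographically smaller
  base; greedy-addition ties toward the smaller degeneracy increase,
  then the 5'-most position; cluster processing ties on size break by
  cluster id. Identical inputs and seed reproduce byte-identical primer
  artifacts (asserted end-to-end).
* **Gap-shift extraction.** A window starting or ending on `-` shifts to
  the row's next base and extends along the ungapped sequence until the
  primer length is reached; rows that run out are dropped, and windows
  losing more than half their rows are discarded.
* **Degenerate expansions.** Expansion is exact up to a cap, then a
  seed-controlled uniform sample (flagged as truncated). Dimer scans use
  a worst-case over capped expansions (cap 8); Tm statistics report the
  min/max over the expansion (cap 64).
* **Window budget.** Designing every window is wasteful; per cluster and
  strand the lowest-entropy windows are taken per length (at most two
  overlapping windows per locus within a length, lengths interleaved) up
  to `max_windows = 30`. The per-length interleaving exists so that GC
  differences between loci can be compensated by primer length when
  pairs are Tm-matched.
* **Degenerate inputs.** `U`/lowercase are normalized on input; rows
  containing ambiguity codes are excluded from design matrices but still
  count toward coverage; `-` is illegal inside a primer.
* **Clustering identity estimate.** Identity between a record and a
  cluster representative is estimated as $f^{1/k}$ from the fraction $f$
  of the record's 12-mers found in the representative — the
  per-site-identity scale on which the `identity` threshold is applied
  (raw shared-k-mer fractions are not identities: 5% divergence keeps
  only ~54% of 12-mers).

## Known limitations

* The greedy set assembly is forward-only: it never revisits an accepted
  pair, so an unlucky acceptance order can leave a cluster uncovered
  that a backtracking search would rescue. Cluster-specific alternates
  are exported precisely so a designer can substitute manually.
* Dimer scoring considers ungapped complementary runs only — no bulges,
  loops, or full hybridization free energies — and specificity screening
  requires an exact 9-mer 3'-terminal seed, so off-target sites with a
  mismatch inside the terminal 9-mer are not counted.
* The center-star fallback aligner is adequate for within-cluster
  divergence (members join at ≥ 80% identity) but is not a progressive
  aligner; for distant or indel-rich clusters use `aligner: mafft`.
* Coverage is in-silico: Y-distance acceptance is a hybridization proxy
  and does not model amplification efficiency, polymerase bias, or
  competition between primers.
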