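# primerpanel

Minimal degenerate primer panels for ultra-multiplex PCR and targeted
next-generation sequencing (tNGS).

## The problem

Amplicon-based tNGS enriches hundreds of targets in one PCR, but designing
the primer panel is the hard part when the target collection is large and
diverse (viral genomes are the extreme case: tens of thousands of
sequences, no universally conserved region). A practical panel must
balance four forces at once:

* **coverage** — each primer should amplify as many target variants as
  possible;
* **degeneracy** — IUPAC-coded primers widen coverage but dilute each
  primer species, so degeneracy must stay small;
* **compatibility** — hundreds of co-amplifying primers must not form
  primer dimers;
* **specificity** — primers must not amplify the host background.

`primerpanel` automates the whole design: sequences are clustered by
identity, each cluster is aligned and scanned for low-entropy windows,
degenerate primers are designed per window under a *mismatch-tolerant*
coverage objective, and per-cluster pairs are merged greedily into one
dimer-vetted panel, which is then audited by in-silico PCR.

## The core ideas

**Y-distance.** The literal (Hamming) distance overstates how different a
degenerate primer and a target are: `R` facing an `A` is a literal
difference but a perfect hybridization. The Y-distance lists the 1-based
positions whose target base is *not contained* in the primer's code; its
length is the effective mismatch count. A target is accepted when

```
|Y| <= max_mismatch   and   no mismatch within the 3'-terminal
                            `coordinate` bases
```

Tolerating one such mismatch collapses the degeneracy a primer needs: on
the bundled ten-target demonstration set (`example_ten_targets()`), exact
cover forces degeneracy 2^9 = 512 while one tolerated mismatch admits a
degeneracy-4 primer covering all ten targets.

**IUPAC value table.** Containment checks reduce to arithmetic on a value
table in which each plain base has value `1 + w/16` (binary weights
`w(A),w(G),w(C),w(T) = 1,2,4,8`) and a degenerate code's value is the sum
of its contained bases: `floor(value)` is the degeneracy and
`value(d) - value(b)` is a table value iff `b` is contained in `d`.

**Nearest-neighbour design.** Candidate windows keep their per-position
base frequencies and adjacent-dinucleotide (NN) counts; the seed primer is
the Viterbi path maximizing `sum log(freq+1) + sum log(nn+1)` (plus the
most frequent variant), and degeneracy is grown greedily one
(position, base) at a time, always taking the largest gain in
mismatch-tolerant coverage, until the coverage target, the degeneracy cap,
or zero gain.

**Dimer loss.** Every antiparallel complementary run between two primers
is scored as

```
loss = log10( 2^length * 2^GC / ((2^d1 - 0.9) (2^d2 - 0.9)) )
```

(`length`, `GC`: size and G/C count of the run; `d1`, `d2`: distances to
each primer's 3' end). Pairs with loss >= 3.96 are high risk, <= 3.0 low
risk; greedy assembly only accepts a pair whose primers stay below high
risk against every primer already in the panel.

**Specificity.** Each primer's 3'-terminal 9-mer seeds a host k-mer index;
full sites are verified allowing one mismatch at least 4 nt from the 3'
end, and a facing site pair within the product-size cap counts as one
off-target unit.

## Worked example

```r
library(primerpanel)

# a reproducible synthetic target collection: 8 families x 50 sequences,
# 5% per-site divergence, two planted conserved primer sites per family
panel <- synth_panel(seed = 1)
write_fasta(panel$records, "targets.fa")

res <- run_pipeline("targets.fa", "out", config = list(seed = 1))
nrow(res$set$accepted)       # 8  (one pair per family)
res$evaluation$coverage      # 0.9725 of all 400 targets amplified in silico
max(res$set$loss_matrix)     # 2.616 — every pairwise loss < 3.96
```

The run writes `final_set.tsv` (the panel: one F and one R row per
cluster, with degeneracy, product size, pair coverage and loss audit),
`alternates.tsv` (vetted cluster-specific substitutes), `loss_matrix.tsv`,
`accumulation.tsv` (coverage as pairs are added), `coverage_report.tsv`,
`clusters.tsv` and `manifest.json` into `out/`.

Single pieces are available directly:

```r
degeneracy("CCRCCNGCATRHCCRTTRTACAT")   # 192
ex <- example_degenerate_mismatch()
hamming_dist(ex$primer, ex$target)      # 6 literal differences ...
y_distance(ex$primer, ex$target)        # ... but only position 17 matters
dimer_loss(5, 3, 0, 0)                  # 4.408 -> high risk
```

A thin command-line wrapper ships as `exec/primerpanel`
(`primerpanel all --in targets.fa --out DIR [--config cfg.yaml]`, plus
`cluster`, `design`, `combine`, `evaluate` and `fixtures` subcommands).

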