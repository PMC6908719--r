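---
title: "Peptide-centric GO quantification and temporal dynamics with pepgo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-centric GO quantification and temporal dynamics with pepgo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepgo)
```

## The model

`pepgo` analyses community metaproteomes at the peptide level. The
observed data are peptide spectrum matches (PSMs): each identified
peptide in a mass-spectrometry run carries a spectral count, the number
of spectra assigned to it, used as its abundance proxy. Protein
inference is deliberately avoided — in a community database a tryptic
peptide is typically contained in many homologous proteins, and any
assignment of its spectra to one protein would be arbitrary.

### Functional quantification

Let $P(s)$ be the set of database proteins containing peptide $s$ as an
exact substring, with isoleucine and leucine treated as identical (the
residues are isobaric; fragment spectra cannot distinguish them — a
configuration flag disables the folding). The peptide's GO term set is

$$G(s) \;=\; \mathrm{anc}^{*}\!\Big(\bigcup_{p \in P(s)} \mathrm{GO}(p)\Big),$$

the union of the matched proteins' annotations closed under ancestor
edges (`is_a`, and by default `part_of`) in the GO DAG. Every term in
$G(s)$ — each term once, regardless of how many proteins or DAG paths
carry it — receives the peptide's spectral count. Two invariants follow
and are asserted in the tests: counts are monotone along the DAG
(a parent's count is at least any child's), and removing a peptide
lowers each of its terms by exactly its count.

### Taxonomic assignment

Each protein carries one precomputed top-BLAST-hit taxon. A peptide is
assigned the lowest common ancestor (LCA) of its matched proteins'
taxa: the deepest taxonomy node lying on every member's root path. This
is the peptide's taxonomic resolution limit — a peptide shared by two
genera of one class resolves to that class; one shared across phyla
resolves near the root. Reporting is at **class** rank: the LCA is
rolled up to its class-rank ancestor, and peptides whose LCA sits above
class (or that have no taxon) enter a reserved **Unclassified** bucket.
Peptides whose LCA is not on or under the Bacteria node are removed
before any total is formed; untaxed peptides are also removed by
default (`keep_untaxed = TRUE` reverses this, a deliberately
conservative default).

### Enrichment between runs

For term $t$ with counts $c_A, c_B$ in two runs of totals $N_A, N_B$:

* Laplace-corrected fold change
  $\log_2\!\frac{(c_B+1)/(N_B+1)}{(c_A+1)/(N_A+1)}$. The add-one rule
  (to each count *and* each total) is the canonical Laplace correction;
  it keeps zero counts finite and is antisymmetric under run swap.
* A pooled two-proportion z-test, two-tailed, without continuity
  correction; its $z^2$ equals the 1-df chi-square statistic, which the
  test suite uses as an independent oracle. A degenerate pooled
  proportion (0 or 1) returns $p = 1$.
* Bonferroni correction with family size $m$ = the number of terms
  observed (nonzero) in either run. Correcting over never-observed
  ontology terms would be statistically meaningless; this is a
  documented dialect choice.
* Significance is restricted to **terminal** terms, the most specific
  in the DAG. By default terminality is judged against the tested set
  (no tested strict descendant); `terminal_mode = "ontology"` restricts
  to full-DAG leaves instead. Propagated ancestor counts are heavily
  dependent between terms, so restricting calls to terminal terms keeps
  each call interpretable as "the most specific place the signal
  lives".

### Rates of change and the permutation test

For a matrix of per-run ratios (rows: significant GO terms, or
taxonomic classes; columns: time points at days $d_1 < \dots < d_k$),
the per-row rate is the mean of $|v_{i+1}-v_i|/(d_{i+1}-d_i)$ over
consecutive intervals — a per-day quantity. The describing phrase
"sum of absolute differences divided by the days between time points"
admits a second reading (sum of interval rates, not mean); both are
implemented (`rate_mode = "mean"` is the default, `"sum"` the
alternative) because the two differ by the constant factor
$k-1$ and therefore cancel from the *comparison* of functional and
taxonomic rates, though not from the reported per-day means.

Whether functions change faster than taxonomy is tested by permutation
at the row level: pool the functional and taxonomic rows, reassign them
at random to two groups of the original sizes, and recompute the
difference of group mean rates. The default 10,000 permutations give a
two-sided add-one empirical p-value with floor $1/10001$; the test is
exactly reproducible from its seed. An alternative reading of
"permuted at the row level" — shuffling time points within each
functional row — is implemented behind `perm_mode = "within_row"`
rather than silently guessed. The rate grid defaults to days
$\{0, 1, 6\}$, the intervals named by the describing formula; missing
time points are dropped (interval lengths recomputed), never
interpolated.

### Concordance with 16S data

Peptide-derived class abundances are compared with an OTU-derived class
table by Pearson correlation with a t-distribution p-value on $n-2$
degrees of freedom, pooling class × time-point pairs within an
experiment (so $n$ = classes × time points). The Unclassified bucket is
dropped (it has no 16S counterpart); classes below a display threshold
are *not* dropped by default — `min_fraction` reproduces figure-style
">1 %" filtering when wanted.

## The synthetic-data generator

`simulate_dataset()` generates a complete, statistically controlled
study: reference (GO DAG, taxonomy, proteins) plus a time course of PSM
and 16S tables. Its defaults are the emulated study conditions and are
not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| `n_classes` | 6 | bacterial classes, abundances Gamma(1.2)-distributed (uneven, marine-like) |
| `n_proteins` | 300 | random 120–240-residue proteins, 1–2 GO leaf annotations each |
| `n_go_terms` | 60 | three rooted random DAGs (one per GO aspect) |
| `n_peptides` | 2000 | 9–15-mer substrings of their source proteins |
| `total_spectra_per_run` | 20000 | multinomial total per run |
| `days` | 0, 1, 6, 10 | two treatments: spiked arm and drift-free control |
| `spike_drifts` | 2.2, 3.0, 3.8 | log2 effects on three rare terminal terms |
| `lca_ambiguity_rate` | 0.15 | peptides planted into a second protein of another class |
| `nonbacterial_rate` | 0.02 | peptides from a eukaryote branch, to exercise removal |

Design choices that were genuinely open:

* **Spike trajectories saturate at day 1.** Effects are realized as
  weight multipliers $2^{\delta \cdot \min(d, 1)}$: an exponential
  per-day drift left unsaturated for ten days would let one term absorb
  essentially all spectra, which resembles no real community response.
  The saturating shape matches the bloom-response pattern the design
  emulates: the large changes arrive within the first day and are then
  maintained.
* **Spiked terms are rare leaves.** GO term usage is heavy-tailed
  (Zipf-like annotation sampling), and spiked terms are drawn from
  leaves with baseline spectral share in $[5\times10^{-4}, 3\times10^{-3}]$,
  pairing the largest effect with the rarest term. This keeps the total
  spiked mass small, so the compositional renormalisation of all other
  terms stays mild. At 20,000 spectra per run even a share of
  $5\times10^{-4}$ yields a z-statistic far beyond any Bonferroni
  threshold, so the band costs no power.
* **Ambiguity is planted, not emergent.** Class-ambiguous peptides are
  planted verbatim into a protein of a different class, guaranteeing
  the matcher resolves them to an LCA above class rank. With
  `lca_ambiguity_rate = 0`, every bacterial peptide resolves at genus
  rank and the Unclassified bucket is empty — an exact generator
  invariant used in tests.
* **Truth is analytic.** Expected per-term and per-class proportions
  are computed from the sampling weights, not re-derived through the
  pipeline, so recovery tests compare two independent routes. In
  particular, terms that genuinely change only through compositional
  renormalisation are part of the truth: `truth_eval()` counts as
  negatives only tested terminal terms whose true log2 change is within
  0.15.

What the generator does **not** emulate: spectrum-level noise and FDR
(identification is taken as given, as the pipeline consumes a filtered
PSM table), homology structure in sequences (proteins are i.i.d.
random strings, so substring matching is almost always unambiguous
unless planted), database incompleteness, and run-to-run technical
variation beyond multinomial resampling. Passing tests therefore
validate the statistical machinery and bookkeeping on data whose truth
is known exactly — they do not certify performance on real spectra.

## Numerical and calibration choices

* Empirical p-values use the add-one estimator (never zero); its floor
  $1/(n_\mathrm{perm}+1)$ is asserted, not just documented.
* Ties in enrichment output are broken by GO id for determinism; all
  generator and permutation randomness is seed-controlled
  (`withr::with_seed`, leaving the session RNG untouched).
* Proportion tables must sum to 1 within $10^{-9}$; ratio-matrix cells
  are validated to lie in $[0,1]$ and day grids to be strictly
  increasing.
* Calibration problem sizes were chosen to make the test suite a
  routine desk run: family-wise error over 200 null run pairs sharing
  one reference (each pair two independent multinomials from one weight
  vector, the exact null of the two-proportion test); permutation
  p-value uniformity over 200 exchangeable datasets at 999
  permutations; seed reproducibility and the attainable floor verified
  once at 10,000; spike recovery over 25 regenerated datasets at the
  default 20,000-spectra totals.

## Known limitations

* Spectral counts are closed compositional data: a genuine increase in
  a few terms depresses every other term's share. With large totals the
  proportion test can resolve these renormalisation shifts in highly
  abundant terms — these are real changes in share, and must be read as
  such rather than as independent biological responses.
* The Bonferroni family is the observed term set; results are not
  comparable across analyses with very different observed-term counts.
* The LCA is only as good as the per-protein top-hit taxa; systematic
  database bias propagates directly into the class rollup.
* With few functional rows the permutation test has limited resolution
  (the observed mean is averaged over few rates); the intended
  operating point is a study-scale matrix of ~70 functional rows
  against a handful of classes, which `simulate_ratio_matrix()`
  reproduces for calibration.
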