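# pepgo

Peptide-centric metaproteomics of microbial communities: Gene Ontology
(GO) spectral counting with DAG ancestor propagation, lowest-common-
ancestor (LCA) taxonomy, between-run enrichment testing, and a
permutation comparison of functional versus taxonomic rates of change.

## The problem

Shotgun metaproteomics of a community (e.g., seawater incubations
sampled over days) yields peptide spectrum matches (PSMs) against a
metagenome-predicted protein database. Protein-level inference is
unreliable in communities — one peptide may occur in many homologous
proteins across taxa — so `pepgo` quantifies at the peptide level:

- **Function.** Each peptide is associated with *all* database proteins
  containing it (with isoleucine ≡ leucine, since the residues are
  isobaric). The union of those proteins' GO annotations, closed under
  `is_a`/`part_of` ancestors in the GO DAG, receives the peptide's
  spectral count — once per term, however many proteins or paths carry
  it. Counts are therefore monotone along the DAG:
  `count(parent) ≥ count(child)`.
- **Taxonomy.** Each peptide gets the LCA of its matching proteins'
  top-BLAST-hit taxa. Results are rolled up to **class** rank; peptides
  whose LCA sits above class (or has no taxon) fall into an
  **Unclassified** bucket. Nonbacterial peptides are removed before any
  denominator is formed.
- **Enrichment.** For a GO term with counts `c_A, c_B` in runs with
  totals `N_A, N_B`, the Laplace-corrected log2 fold change is

      log2( ((c_B + 1)/(N_B + 1)) / ((c_A + 1)/(N_A + 1)) )

  tested by the pooled two-proportion z-test (no continuity
  correction), Bonferroni-corrected over the tested family. Only
  **terminal** terms — the most specific observed terms, with no
  observed descendant — can be called significant (default
  `p_bonf < 0.01`).
- **Dynamics.** Ratio matrices (rows = significant GO terms, or
  taxonomic classes; columns = time points) give per-row per-day rates
  `mean_i |v_{i+1} − v_i| / (d_{i+1} − d_i)`. Whether functions change
  faster than taxonomy is tested by pooling both row sets and permuting
  row labels (10,000 times by default), with a two-sided add-one
  empirical p-value.
- **Concordance.** Peptide-derived class abundances are correlated
  (Pearson, class × time-point pairs pooled) against 16S rRNA OTU class
  tables.

A fully controlled synthetic-data generator (`simulate_dataset()`)
emulates the experimental design — two treatments at days 0/1/6/10,
multinomial spectral sampling, spiked functional effects of 2.2–3.8
log2 realized over the first day, class-ambiguous and nonbacterial
peptides — so the entire pipeline is testable without any downloads.

## Worked example

```r
library(pepgo)

cfg <- sim_config(seed = 1)            # default study conditions
sim <- simulate_dataset(cfg)
dir <- tempfile(); manifest <- write_simulation(sim, dir)

summary <- run_pipeline(manifest,
  proteins_fasta   = file.path(dir, "proteins.fasta"),
  annotations_path = file.path(dir, "annotations.tsv"),
  taxonomy_path    = file.path(dir, "taxonomy.tsv"),
  ontology_path    = file.path(dir, "ontology.obo"),
  out_dir = file.path(dir, "results"), n_perm = 10000, seed = 1)
```

```
read 15096 PSM rows over 8 runs
removed 40 nonbacterial/untaxed peptide(s), kept 1958
control control_d0 vs control_d1: 50 terms tested, 0 significant
...
OM OM_d0 vs OM_d1: 50 terms tested, 4 significant
OM rates: functional 0.01123/day (n=4), taxonomic 0.001867/day (n=6),
          permutation p=0.005099
OM peptide/16S concordance r=0.998 (n=24)
```

The control arm (no spiked effects) yields no significant terms; the
treated arm recovers the spiked functions between day 0 and day 1:

```r
enr <- read.delim(file.path(dir, "results",
                            "enrichment_OM_d0_vs_OM_d1.tsv"))
head(subset(enr, is_significant,
            select = c(go_id, count_a, count_b, log2fc, p_bonf)), 4)
#>         go_id count_a count_b  log2fc   p_bonf
#>    GO:0000034      78     571  2.8545 5.45e-83
#>    GO:0000025      27     413  3.8846 1.14e-74
#>    GO:0000057     102     423  2.0399 2.13e-43
#>    GO:0000038   15110   14593 -0.0518 1.72e-08
```

The three spiked leaf terms come back with log2 fold changes close to
their configured 2.2/3.0/3.8 effects. The fourth row shows the flip
side of closed compositional data: a highly abundant term whose share
genuinely (if slightly) declines as the spiked functions expand, which
the test can resolve at these spectral totals. The significant
functions change an order of magnitude faster per day than the class
composition, and the row-label permutation test puts a p-value on that
difference.

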