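small_cfg <- function(...) {
  defaults <- list(seed = 42, n_classes = 4, n_proteins = 80,
                   n_go_terms = 30, n_peptides = 300,
                   total_spectra_per_run = 4000, days = c(0, 1, 6))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

test_that("the generator is deterministic under the seed", {
  s1 <- simulate_dataset(small_cfg())
  s2 <- simulate_dataset(small_cfg())
  expect_identical(s1$psm, s2$psm)
  expect_identical(s1$otu, s2$otu)
  expect_identical(s1$reference$proteins$sequence,
                   s2$reference$proteins$sequence)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1)) {
    if (f == "manifest.tsv") next  # embeds the output paths
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  s3 <- simulate_dataset(small_cfg(seed = 43))
  expect_false(identical(s1$psm, s3$psm))
})

test_that("generated reference passes its own structural validators", {
  ref <- simulate_reference(small_cfg())
  expect_s3_class(ref$dag, "go_dag")       # acyclic + one root per aspect
  expect_length(ref$dag$roots, 3)
  expect_s3_class(ref$tree, "tax_tree")
  expect_equal(sum(ref$class_abundance), 1, tolerance = 1e-12)
  expect_equal(sum(!ref$proteins$is_bacterial), 2)  # 2% of 80, floored
})

test_that("single-class configs put every bacterial protein in that class", {
  ref <- simulate_reference(small_cfg(n_classes = 1))
  cls <- unique(ref$proteins$class_true[ref$proteins$is_bacterial])
  expect_equal(cls, "class01")
})

test_that("each run's spectra sum exactly to the configured total", {
  sim <- simulate_dataset(small_cfg())
  totals <- tapply(sim$psm$spectral_count, sim$psm$run_id, sum)
  expect_true(all(totals == 4000))
  expect_equal(nrow(sim$runs), 6)  # 2 treatments x 3 days
})

test_that("zero ambiguity resolves every bacterial peptide at genus rank", {
  sim <- simulate_dataset(small_cfg(lca_ambiguity_rate = 0))
  expect_false(any(sim$peptides$is_ambiguous))
  expect_false("Unclassified" %in% rownames(sim$truth$class_props))
  # and through the actual matcher: no Unclassified bucket
  ref <- sim$reference
  matcher <- peptide_index(ref$proteins)
  ann <- annotate_peptides(sim$peptides$peptide, matcher, ref$proteins,
                           ref$dag, ref$tree)
  kept <- filter_nonbacterial(ann)$kept
  ca <- class_abundance(kept, sim$psm[sim$psm$peptide %in% kept$peptide, ],
                        sim$runs$run_id[1], ref$tree)
  expect_false("Unclassified" %in% names(ca))
})

test_that("ambiguous peptides match proteins of different classes", {
  sim <- simulate_dataset(small_cfg())
  amb <- which(sim$peptides$is_ambiguous)
  expect_gt(length(amb), 0)
  ref <- sim$reference
  matcher <- peptide_index(ref$proteins)
  i <- amb[1]
  hits <- match_peptide(matcher, sim$peptides$peptide[i])
  expect_true(all(sim$peptides$protein_ids[[i]] %in% hits))
  cls <- unique(ref$proteins$class_true[
    match(sim$peptides$protein_ids[[i]], ref$proteins$id)])
  expect_gt(length(cls), 1)
})

test_that("spiked terms realize their configured log2 effect", {
  cfg <- sim_config(seed = 7, spike_drifts = 2.2)
  sim <- simulate_dataset(cfg)
  sp <- sim$truth$spikes
  expect_equal(nrow(sp), 1)
  tp <- sim$truth$term_props
  realized <- log2(tp[sp$go_id, "OM_d1"] / tp[sp$go_id, "OM_d0"])
  # analytic change: drift minus compositional renormalization (small)
  expect_gt(realized, 2.2 - 0.2)
  expect_lte(realized, 2.2)
  # control arm stays flat
  ctrl <- log2(tp[sp$go_id, "control_d1"] / tp[sp$go_id, "control_d0"])
  expect_equal(ctrl, 0)
  # observed spectral counts agree with the analytic proportions within
  # binomial sampling error (3 sigma at the configured total)
  ann <- sim$peptides; ann$is_bacterial <- !ann$is_nonbacterial
  kept <- ann[!ann$is_nonbacterial, ]
  psm <- sim$psm[sim$psm$peptide %in% kept$peptide, ]
  for (run in c("OM_d0", "OM_d1")) {
    tab <- go_spectral_counts(kept, psm, run)
    p_true <- tp[sp$go_id, run]
    p_obs <- tab$counts[[sp$go_id]] / tab$total_spectra
    se <- sqrt(p_true * (1 - p_true) / tab$total_spectra)
    expect_lt(abs(p_obs - p_true), 3 * se)
  }
})

test_that("class abundance truth is recovered within multinomial error", {
  sim <- simulate_dataset(small_cfg())
  ref <- sim$reference
  matcher <- peptide_index(ref$proteins)
  ann <- annotate_peptides(sim$peptides$peptide, matcher, ref$proteins,
                           ref$dag, ref$tree)
  kept <- filter_nonbacterial(ann)$kept
  psm <- sim$psm[sim$psm$peptide %in% kept$peptide, ]
  run <- "OM_d0"
  ca <- class_abundance(kept, psm, run, ref$tree)
  truth <- sim$truth$class_props[, run]
  n <- sum(psm$spectral_count[psm$run_id == run])
  for (cl in names(truth)) {
    se <- sqrt(truth[[cl]] * (1 - truth[[cl]]) / n)
    got <- if (cl %in% names(ca)) ca[[cl]] else 0
    expect_lt(abs(got - truth[[cl]]), 3 * se + 1e-12)
  }
})

test_that("truth evaluation separates spiked from null terminal terms", {
  sim <- simulate_dataset(sim_config(seed = 5))
  ref <- sim$reference
  kept <- sim$peptides[!sim$peptides$is_nonbacterial, ]
  psm <- sim$psm[sim$psm$peptide %in% kept$peptide, ]
  ta <- go_spectral_counts(kept, psm, "OM_d0")
  tb <- go_spectral_counts(kept, psm, "OM_d1")
  res <- compare_runs(ta, tb, ref$dag)
  ev <- truth_eval(sim, res, "OM_d0", "OM_d1")
  expect_equal(ev$n_pos, 3)
  expect_gte(ev$sensitivity, 0)
  expect_true(is.na(ev$specificity) || ev$specificity <= 1)
  # null dataset: all tested terminal terms are negatives
  null_sim <- simulate_dataset(sim_config(seed = 5,
                                          spike_drifts = numeric(0)))
  kn <- null_sim$peptides[!null_sim$peptides$is_nonbacterial, ]
  pn <- null_sim$psm[null_sim$psm$peptide %in% kn$peptide, ]
  rn <- compare_runs(go_spectral_counts(kn, pn, "OM_d0"),
                     go_spectral_counts(kn, pn, "OM_d1"),
                     null_sim$reference$dag)
  en <- truth_eval(null_sim, rn, "OM_d0", "OM_d1")
  expect_true(is.na(en$sensitivity))
  expect_equal(en$n_neg, sum(rn$is_terminal))
})
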