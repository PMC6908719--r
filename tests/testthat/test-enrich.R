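test_that("Laplace-corrected fold change matches closed forms", {
  expect_identical(laplace_log2fc(3, 9, 1, 19), -2)
  expect_equal(laplace_log2fc(7, 50, 7, 50), 0)
  expect_equal(laplace_log2fc(0, 10, 0, 10), 0)
  expect_error(laplace_log2fc(11, 10, 0, 10), "exceeds")
})

test_that("fold change is antisymmetric under run swap", {
  set.seed(909)
  for (rep in 1:50) {
    na <- sample(10:1000, 1); nb <- sample(10:1000, 1)
    ca <- sample(0:na, 1); cb <- sample(0:nb, 1)
    expect_equal(laplace_log2fc(ca, na, cb, nb),
                 -laplace_log2fc(cb, nb, ca, na))
  }
})

test_that("proportion test matches the chi-square oracle without continuity", {
  set.seed(1010)
  for (rep in 1:50) {
    na <- sample(20:2000, 1); nb <- sample(20:2000, 1)
    ca <- sample(1:(na - 1), 1); cb <- sample(1:(nb - 1), 1)
    p <- proportion_test(ca, na, cb, nb)
    oracle <- stats::prop.test(c(ca, cb), c(na, nb),
                               correct = FALSE)$p.value
    expect_equal(p, oracle, tolerance = 1e-10)
    # symmetric in the two runs
    expect_equal(p, proportion_test(cb, nb, ca, na))
  }
})

test_that("degenerate pooled proportions give p = 1", {
  expect_equal(proportion_test(5, 100, 5, 100), 1)
  expect_equal(proportion_test(0, 50, 0, 80), 1)
  expect_equal(proportion_test(50, 50, 80, 80), 1)
})

test_that("terminal terms are the observed set minus observed ancestors", {
  dag <- toy_dag()
  expect_equal(terminal_terms(dag, c("GO:1", "GO:2", "GO:3")), "GO:3")
  expect_setequal(terminal_terms(dag, c("GO:3", "GO:4")),
                  c("GO:3", "GO:4"))
  expect_error(terminal_terms(dag, "GO:77"), "unknown")
})

test_that("terminal detection matches brute-force descendant scan", {
  set.seed(1111)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    parents <- random_parent_list(n)
    dag <- go_dag(data.frame(id = names(parents), name = names(parents),
                             aspect = "molecular_function"), parents)
    observed <- sample(names(parents), sample(2:n, 1))
    expect_setequal(terminal_terms(dag, observed),
                    brute_terminal(parents, observed))
  }
})

count_table <- function(run, counts, total) {
  structure(list(run_id = run, counts = counts, total_spectra = total),
            class = "go_count_table")
}

test_that("comparing identical tables yields zero fold change, nothing significant", {
  dag <- toy_dag()
  cnt <- c("GO:1" = 50, "GO:2" = 30, "GO:3" = 20)
  res <- compare_runs(count_table("a", cnt, 100),
                      count_table("b", cnt, 100), dag)
  expect_true(all(res$log2fc == 0))
  expect_false(any(res$is_significant))
  expect_equal(attr(res, "n_tested"), 3)
})

test_that("a strong leaf shift is significant after Bonferroni", {
  dag <- toy_dag()
  a <- count_table("a", c("GO:1" = 500, "GO:2" = 100, "GO:3" = 50), 5000)
  b <- count_table("b", c("GO:1" = 1400, "GO:2" = 1050, "GO:3" = 1000),
                   5000)
  res <- compare_runs(a, b, dag)
  r3 <- res[res$go_id == "GO:3", ]
  expect_true(r3$is_terminal)
  expect_true(r3$is_significant)
  expect_gt(r3$log2fc, 3)
  # non-terminal ancestors are never called significant
  expect_false(any(res$is_significant[!res$is_terminal]))
})

test_that("Bonferroni uses the tested family size; single term passes through", {
  dag <- toy_dag()
  a <- count_table("a", c("GO:3" = 5), 100)
  b <- count_table("b", c("GO:3" = 9), 100)
  res <- compare_runs(a, b, dag)
  expect_equal(nrow(res), 1)
  expect_equal(res$p_bonf, res$p_raw)

  a2 <- count_table("a", c("GO:2" = 8, "GO:3" = 5, "GO:4" = 3), 100)
  b2 <- count_table("b", c("GO:2" = 12, "GO:3" = 9, "GO:4" = 1), 100)
  res2 <- compare_runs(a2, b2, dag)
  expect_equal(res2$p_bonf, pmin(1, 3 * res2$p_raw))
})

test_that("terminal_mode ontology restricts calls to full-DAG leaves", {
  dag <- toy_dag()
  a <- count_table("a", c("GO:3" = 5, "GO:2" = 10), 100)
  b <- count_table("b", c("GO:3" = 9, "GO:2" = 12), 100)
  obs_mode <- compare_runs(a, b, dag, terminal_mode = "observed")
  ont_mode <- compare_runs(a, b, dag, terminal_mode = "ontology")
  # GO:3 has an unobserved child GO:5: terminal among observed, not in DAG
  expect_true(obs_mode$is_terminal[obs_mode$go_id == "GO:3"])
  expect_false(ont_mode$is_terminal[ont_mode$go_id == "GO:3"])
})

test_that("tables referencing unknown terms are rejected", {
  dag <- toy_dag()
  bad <- count_table("a", c("GO:777" = 5), 10)
  ok <- count_table("b", c("GO:1" = 5), 10)
  expect_error(compare_runs(bad, ok, dag), "inconsistent")
})

test_that("family-wise error is controlled on null multinomial run pairs", {
  # spec-level calibration at reduced replicate count; the full 200-pair
  # run lives in the acceptance suite
  set.seed(1212)
  sim <- simulate_dataset(sim_config(seed = 77, spike_drifts = numeric(0),
                                     n_peptides = 400, n_proteins = 80,
                                     total_spectra_per_run = 5000,
                                     days = c(0, 1)))
  dag <- sim$reference$dag
  ann <- sim$peptides[!sim$peptides$is_nonbacterial, ]
  ann$is_bacterial <- TRUE
  w <- ann$weight
  any_sig <- vapply(1:50, function(i) {
    mk <- function(run) {
      cnt <- stats::rmultinom(1, 5000, w)[, 1]
      data.frame(peptide = ann$peptide, run_id = run,
                 spectral_count = cnt)[cnt > 0, ]
    }
    ta <- go_spectral_counts(ann, mk("a"), "a")
    tb <- go_spectral_counts(ann, mk("b"), "b")
    any(compare_runs(ta, tb, dag)$is_significant)
  }, logical(1))
  expect_lte(mean(any_sig), 0.01 + 3 * sqrt(0.01 / 50))
})
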