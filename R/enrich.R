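# Between-run GO enrichment: Laplace-corrected log2 fold change, pooled
# two-proportion z-test, Bonferroni correction, terminal-term restriction.

check_counts <- function(count_a, total_a, count_b, total_b) {
  if (any(count_a < 0 | count_b < 0))
    stop("spectral counts must be nonnegative")
  if (any(total_a < 1 | total_b < 1))
    stop("run totals must be at least 1")
  if (any(count_a > total_a | count_b > total_b))
    stop("spectral count exceeds run total")
}

#' Laplace-corrected log2 fold change of a GO term between two runs
#'
#' Adds one pseudocount to each count and each total before forming the
#' ratio of proportions, so terms absent from one run remain finite:
#' `log2(((count_b+1)/(total_b+1)) / ((count_a+1)/(total_a+1)))`.
#' Positive values mean the term is relatively more abundant in run B.
#'
#' @param count_a,count_b term spectral counts in runs A and B.
#' @param total_a,total_b total spectral counts of runs A and B.
#' @return Numeric (vectorized over terms).
#' @export
laplace_log2fc <- function(count_a, total_a, count_b, total_b) {
  check_counts(count_a, total_a, count_b, total_b)
  log2(((count_b + 1) / (total_b + 1)) / ((count_a + 1) / (total_a + 1)))
}

#' Two-tailed pooled test of proportions
#'
#' The classic two-sample z-test without continuity correction:
#' pooled `p = (ca+cb)/(Na+Nb)`,
#' `z = (ca/Na - cb/Nb) / sqrt(p(1-p)(1/Na+1/Nb))`,
#' `p_raw = 2 * (1 - pnorm(|z|))`. When the pooled proportion is 0 or 1
#' the statistic is degenerate and 1 is returned.
#'
#' @inheritParams laplace_log2fc
#' @return Raw two-sided p-value (vectorized over terms).
#' @export
proportion_test <- function(count_a, total_a, count_b, total_b) {
  check_counts(count_a, total_a, count_b, total_b)
  phat <- (count_a + count_b) / (total_a + total_b)
  se <- sqrt(phat * (1 - phat) * (1 / total_a + 1 / total_b))
  z <- (count_a / total_a - count_b / total_b) / se
  p <- 2 * stats::pnorm(-abs(z))
  p[phat <= 0 | phat >= 1] <- 1
  p
}

#' Terminal GO terms of an observed set
#'
#' The most specific members: those with no strict descendant (in the full
#' DAG) also present in `observed`. Equivalently, a term is non-terminal
#' iff it is an ancestor of another observed term.
#'
#' @param dag a [go_dag()].
#' @param observed character vector of GO ids.
#' @return Character vector (subset of `observed`).
#' @export
terminal_terms <- function(dag, observed) {
  stopifnot(inherits(dag, "go_dag"))
  observed <- unique(as.character(observed))
  unknown <- setdiff(observed, dag$ids)
  if (length(unknown)) stop("unknown GO term: ", unknown[1])
  anc_of_observed <- unique(unlist(dag$ancestors[observed], use.names = FALSE))
  setdiff(observed, anc_of_observed)
}

#' Compare two runs' GO count tables
#'
#' Tests every GO term observed (nonzero) in either run: Laplace-corrected
#' log2 fold change (B relative to A), raw two-proportion p-value,
#' Bonferroni correction over the tested family, and a significance call
#' restricted to terminal terms at `p_bonf < alpha`.
#'
#' @param table_a,table_b [go_spectral_counts()] tables from the same
#'   ontology.
#' @param dag the [go_dag()] both tables were computed against.
#' @param alpha family-wise significance level (default 0.01).
#' @param terminal_mode `"observed"` (default): terminality judged against
#'   the tested term set; `"ontology"`: only full-DAG leaves are terminal.
#' @return data.frame, one row per tested term, sorted by `p_bonf` then
#'   `go_id`, with columns `go_id`, `name`, `aspect`, `count_a`,
#'   `total_a`, `count_b`, `total_b`, `log2fc`, `p_raw`, `p_bonf`,
#'   `is_terminal`, `is_significant`.
#' @export
compare_runs <- function(table_a, table_b, dag, alpha = 0.01,
                         terminal_mode = c("observed", "ontology")) {
  stopifnot(inherits(table_a, "go_count_table"),
            inherits(table_b, "go_count_table"),
            inherits(dag, "go_dag"))
  terminal_mode <- match.arg(terminal_mode)
  terms <- sort(union(names(table_a$counts)[table_a$counts > 0],
                      names(table_b$counts)[table_b$counts > 0]))
  unknown <- setdiff(terms, dag$ids)
  if (length(unknown))
    stop("count tables contain terms absent from the ontology (e.g. ",
         unknown[1], "); tables and DAG are inconsistent")
  if (!length(terms))
    return(data.frame(go_id = character(0)))
  ca <- ifelse(terms %in% names(table_a$counts),
               table_a$counts[terms], 0)
  cb <- ifelse(terms %in% names(table_b$counts),
               table_b$counts[terms], 0)
  m <- length(terms)
  log2fc <- laplace_log2fc(ca, table_a$total_spectra,
                           cb, table_b$total_spectra)
  p_raw <- proportion_test(ca, table_a$total_spectra,
                           cb, table_b$total_spectra)
  p_bonf <- pmin(1, m * p_raw)
  term_set <- switch(terminal_mode,
    observed = terminal_terms(dag, terms),
    ontology = intersect(terms, go_leaves(dag)))
  is_terminal <- terms %in% term_set
  res <- data.frame(
    go_id = terms,
    name = unname(dag$name[terms]),
    aspect = unname(dag$aspect[terms]),
    count_a = unname(ca), total_a = table_a$total_spectra,
    count_b = unname(cb), total_b = table_b$total_spectra,
    log2fc = unname(log2fc), p_raw = unname(p_raw),
    p_bonf = unname(p_bonf),
    is_terminal = is_terminal,
    is_significant = is_terminal & p_bonf < alpha,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p_bonf, res$go_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- m
  attr(res, "alpha") <- alpha
  res
}
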