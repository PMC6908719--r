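# Concordance of peptide-derived vs. 16S rRNA class abundances.

#' Align peptide and 16S class-abundance tables
#'
#' Takes the union of class labels, fills missing entries with 0, and
#' drops the `"Unclassified"` bucket (which has no 16S counterpart).
#'
#' @param peptide_table,otu_table named numeric vectors mapping class name
#'   to fraction.
#' @return list with equally ordered numeric vectors `peptide` and `otu`.
#' @export
align_classes <- function(peptide_table, otu_table) {
  labels <- sort(union(names(peptide_table), names(otu_table)))
  labels <- setdiff(labels, "Unclassified")
  if (!length(labels))
    stop("no classes shared after dropping Unclassified")
  pick <- function(v) {
    out <- stats::setNames(rep(0, length(labels)), labels)
    hit <- intersect(names(v), labels)
    out[hit] <- v[hit]
    out
  }
  list(peptide = pick(peptide_table), otu = pick(otu_table))
}

#' Pearson concordance of two aligned abundance vectors
#'
#' Sample Pearson correlation with a two-sided p-value from the
#' t distribution on n - 2 degrees of freedom.
#'
#' @param v1,v2 aligned numeric vectors (length >= 3).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_concordance <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must have equal length")
  n <- length(v1)
  if (n < 3L) stop("at least 3 paired observations are required")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(v1, v2, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Peptide vs. 16S concordance pooled over time points
#'
#' Aligns per-run class tables and pools the class x time-point pairs of
#' one experiment into a single correlation, so `n` equals classes times
#' time points (matching how per-experiment concordance is conventionally
#' reported).
#'
#' @param peptide_tables,otu_tables named lists (same run ids) of named
#'   class-fraction vectors.
#' @param min_fraction optional display-style filter: drop pairs where
#'   both fractions are below this value (default 0, keep all).
#' @return list with `r`, `p`, `n`.
#' @export
concordance_by_experiment <- function(peptide_tables, otu_tables,
                                      min_fraction = 0) {
  runs <- intersect(names(peptide_tables), names(otu_tables))
  if (!length(runs)) stop("no shared runs between peptide and 16S tables")
  v1 <- numeric(0); v2 <- numeric(0)
  for (r in runs) {
    al <- align_classes(peptide_tables[[r]], otu_tables[[r]])
    v1 <- c(v1, al$peptide)
    v2 <- c(v2, al$otu)
  }
  keep <- v1 >= min_fraction | v2 >= min_fraction
  pearson_concordance(v1[keep], v2[keep])
}
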