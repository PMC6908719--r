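# Per-run GO spectral-count tables, per-term taxon proportions,
# class-level relative abundance with the Unclassified sink.

#' Class bucket for one peptide annotation
#'
#' Rolls a peptide's LCA taxon up (or down is impossible) to the class
#' rank; returns `"Unclassified"` when the LCA is missing, above class,
#' or its root path has no class-rank node.
#' @keywords internal
peptide_class <- function(tree, lca_taxon) {
  if (is.na(lca_taxon)) return("Unclassified")
  node <- tax_rank_at(tree, lca_taxon, "class")
  if (is.na(node)) "Unclassified" else unname(tree$name[[node]])
}

obs_for_run <- function(observations, run_id) {
  stopifnot(is.data.frame(observations),
            all(c("peptide", "run_id", "spectral_count") %in% names(observations)))
  observations[observations$run_id == run_id, , drop = FALSE]
}

#' Propagated GO spectral counts for one run
#'
#' Every peptide's spectral count is credited once to each GO term in its
#' ancestor-closed term set, so a parent's count is always at least any
#' child's. `total_spectra` is the run's total over the supplied
#' (post-filter, bacterial) peptides.
#'
#' @param annotations data.frame from [annotate_peptides()] (typically the
#'   `kept` slot of [filter_nonbacterial()]).
#' @param observations PSM data.frame (`peptide`, `run_id`,
#'   `spectral_count`).
#' @param run_id the run to tabulate.
#' @return Object of class `go_count_table`: list with `run_id`, named
#'   numeric `counts`, and `total_spectra`.
#' @export
go_spectral_counts <- function(annotations, observations, run_id) {
  obs <- obs_for_run(observations, run_id)
  miss <- setdiff(obs$peptide, annotations$peptide)
  if (length(miss))
    stop("observation without annotation: ", miss[1])
  idx <- match(obs$peptide, annotations$peptide)
  gl <- annotations$go_ids[idx]
  terms <- unlist(gl, use.names = FALSE)
  cnts <- rep(obs$spectral_count, lengths(gl))
  counts <- if (length(terms)) {
    r <- rowsum(cnts, terms)
    stats::setNames(as.numeric(r), rownames(r))
  } else stats::setNames(numeric(0), character(0))
  counts <- counts[order(names(counts))]
  structure(list(run_id = run_id, counts = counts,
                 total_spectra = sum(obs$spectral_count)),
            class = "go_count_table")
}

#' @export
print.go_count_table <- function(x, ...) {
  cat("go_count_table for run", x$run_id, "—", length(x$counts),
      "GO terms,", x$total_spectra, "spectra\n")
  invisible(x)
}

#' Taxonomic composition of one GO term's spectra
#'
#' Among the peptides contributing spectra to `go_id` in a run, buckets
#' spectral counts by the class-rank rollup of each peptide's LCA
#' (`"Unclassified"` when unresolvable) and divides by the term's
#' propagated spectral count, yielding the proportion of the term's
#' spectra unambiguously attributable to each class.
#'
#' @inheritParams go_spectral_counts
#' @param go_id the GO term.
#' @param tree a [tax_tree()].
#' @param counts optional precomputed [go_spectral_counts()] table for
#'   `run_id`.
#' @return Named numeric vector of proportions summing to 1.
#' @export
taxon_proportions <- function(annotations, observations, run_id, go_id,
                              tree, counts = NULL) {
  if (is.null(counts))
    counts <- go_spectral_counts(annotations, observations, run_id)
  term_total <- counts$counts[go_id]
  if (is.na(term_total) || term_total == 0)
    stop("GO term ", go_id, " has zero spectral count in run ", run_id,
         "; proportions undefined")
  obs <- obs_for_run(observations, run_id)
  idx <- match(obs$peptide, annotations$peptide)
  carries <- vapply(annotations$go_ids[idx],
                    function(g) go_id %in% g, logical(1))
  obs <- obs[carries, , drop = FALSE]
  idx <- idx[carries]
  bucket <- vapply(annotations$lca_taxon[idx], peptide_class,
                   character(1), tree = tree)
  r <- rowsum(obs$spectral_count, bucket)
  props <- stats::setNames(as.numeric(r), rownames(r)) / unname(term_total)
  props[order(names(props))]
}

#' Class-level relative abundance of one run
#'
#' Spectral counts bucketed by the class rollup of each peptide's LCA
#' (`"Unclassified"` when unresolvable), normalized by the run's total
#' bacterial spectra.
#'
#' @inheritParams taxon_proportions
#' @return Named numeric vector of fractions summing to 1.
#' @export
class_abundance <- function(annotations, observations, run_id, tree) {
  obs <- obs_for_run(observations, run_id)
  total <- sum(obs$spectral_count)
  if (total == 0) stop("run ", run_id, " has no retained spectra")
  miss <- setdiff(obs$peptide, annotations$peptide)
  if (length(miss)) stop("observation without annotation: ", miss[1])
  idx <- match(obs$peptide, annotations$peptide)
  bucket <- vapply(annotations$lca_taxon[idx], peptide_class,
                   character(1), tree = tree)
  r <- rowsum(obs$spectral_count, bucket)
  props <- stats::setNames(as.numeric(r), rownames(r)) / total
  props[order(names(props))]
}
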