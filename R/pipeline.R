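# End-to-end orchestration: annotate -> filter -> quantify -> enrich ->
# rate matrices -> permutation -> concordance, with a fixed output layout.

log_line <- function(con, ..., verbose = TRUE) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  if (verbose) message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full peptide-centric analysis pipeline
#'
#' Executes, per treatment: peptide annotation against the protein
#' database, nonbacterial removal, per-run GO spectral-count tables and
#' class abundances, enrichment between sequential time points, ratio
#' matrices for significant GO terms and for taxonomic classes over the
#' `rate_days` grid, the functional-vs-taxonomic rate permutation test,
#' and (when OTU tables are supplied) peptide/16S class concordance.
#' All stage tables are written as TSV plus a machine-readable
#' `summary.json` and a `pipeline.log`.
#'
#' @param manifest data.frame with columns `run_id`, `treatment`, `day`,
#'   `psm_path`, and optionally `otu_path` (NA allowed). Days must be
#'   unique within a treatment.
#' @param proteins_fasta,annotations_path,taxonomy_path,ontology_path
#'   reference file paths (see [read_protein_db()], [read_taxonomy()],
#'   [read_obo()]).
#' @param out_dir output directory (created).
#' @param alpha family-wise significance level for enrichment.
#' @param n_perm permutations for the rate test.
#' @param seed integer seed for the permutation test.
#' @param rate_days day grid used for the rate matrices (runs at other
#'   days are excluded from rate computation only).
#' @param include_part_of,keep_untaxed,terminal_mode,rate_mode,perm_mode
#'   passed through to the respective stages.
#' @param verbose log progress to stderr as well as the logfile.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(manifest, proteins_fasta, annotations_path,
                         taxonomy_path, ontology_path, out_dir,
                         alpha = 0.01, n_perm = 10000, seed = 1L,
                         rate_days = c(0, 1, 6),
                         include_part_of = TRUE, keep_untaxed = FALSE,
                         terminal_mode = "observed",
                         rate_mode = "mean", perm_mode = "rows",
                         verbose = TRUE) {
  stopifnot(is.data.frame(manifest),
            all(c("run_id", "treatment", "day", "psm_path") %in%
                  names(manifest)))
  for (p in c(manifest$psm_path, proteins_fasta, annotations_path,
              taxonomy_path, ontology_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  log_line(logcon, "pepgo ", as.character(utils::packageVersion("pepgo")),
           " | seed=", seed, " alpha=", alpha, " n_perm=", n_perm,
           " rate_days=", paste(rate_days, collapse = ","),
           verbose = verbose)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dag <- stage("ontology", read_obo(ontology_path,
                                    include_part_of = include_part_of))
  tree <- stage("taxonomy", read_taxonomy(taxonomy_path))
  proteins <- stage("protein_db",
                    read_protein_db(proteins_fasta, annotations_path, dag))
  matcher <- peptide_index(proteins)

  psm <- do.call(rbind, lapply(manifest$psm_path, read_psm_table))
  log_line(logcon, "read ", nrow(psm), " PSM rows over ",
           nrow(manifest), " runs", verbose = verbose)

  ann <- stage("annotate",
               annotate_peptides(unique(psm$peptide), matcher, proteins,
                                 dag, tree, keep_untaxed = keep_untaxed))
  unmatched <- ann$peptide[lengths(ann$protein_ids) == 0L]
  if (length(unmatched))
    log_line(logcon, "WARN ", length(unmatched),
             " peptide(s) unmatched in the protein database",
             verbose = verbose)
  flt <- filter_nonbacterial(ann)
  log_line(logcon, "removed ", flt$removed_count,
           " nonbacterial/untaxed peptide(s), kept ", nrow(flt$kept),
           verbose = verbose)
  kept_pep <- flt$kept$peptide
  psm_kept <- psm[psm$peptide %in% kept_pep, , drop = FALSE]

  counts <- lapply(manifest$run_id, function(r)
    go_spectral_counts(flt$kept, psm_kept, r))
  names(counts) <- manifest$run_id
  class_tabs <- lapply(manifest$run_id, function(r)
    class_abundance(flt$kept, psm_kept, r, tree))
  names(class_tabs) <- manifest$run_id

  counts_df <- do.call(rbind, lapply(manifest$run_id, function(r)
    data.frame(run_id = r, go_id = names(counts[[r]]$counts),
               count = unname(counts[[r]]$counts),
               total = counts[[r]]$total_spectra)))
  utils::write.table(counts_df, file.path(out_dir, "go_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  class_df <- do.call(rbind, lapply(manifest$run_id, function(r)
    data.frame(run_id = r, class = names(class_tabs[[r]]),
               fraction = unname(class_tabs[[r]]))))
  utils::write.table(class_df, file.path(out_dir, "class_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(seed = as.integer(seed), alpha = alpha,
                  n_runs = nrow(manifest),
                  peptides_total = nrow(ann),
                  peptides_removed_nonbacterial = flt$removed_count,
                  treatments = list())

  for (trt in unique(manifest$treatment)) {
    runs <- manifest[manifest$treatment == trt, , drop = FALSE]
    runs <- runs[order(runs$day), , drop = FALSE]
    if (anyDuplicated(runs$day)) stop("duplicate day within treatment ", trt)
    trt_sum <- list(treatment = trt, comparisons = list())

    sig_terms <- character(0)
    if (nrow(runs) < 2L) {
      log_line(logcon, "NOTE treatment ", trt,
               " has a single run; enrichment skipped", verbose = verbose)
    } else {
      for (k in seq_len(nrow(runs) - 1L)) {
        a <- runs$run_id[k]; b <- runs$run_id[k + 1L]
        res <- stage("enrich", compare_runs(counts[[a]], counts[[b]], dag,
                                            alpha = alpha,
                                            terminal_mode = terminal_mode))
        fn <- file.path(out_dir,
                        paste0("enrichment_", a, "_vs_", b, ".tsv"))
        utils::write.table(res, fn, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        nsig <- sum(res$is_significant)
        sig_terms <- union(sig_terms, res$go_id[res$is_significant])
        trt_sum$comparisons[[paste0(a, "_vs_", b)]] <-
          list(n_tested = attr(res, "n_tested"), n_significant = nsig)
        log_line(logcon, trt, " ", a, " vs ", b, ": ",
                 attr(res, "n_tested"), " terms tested, ", nsig,
                 " significant", verbose = verbose)
      }
    }
    trt_sum$n_significant_terms <- length(sig_terms)

    rate_runs <- runs[runs$day %in% rate_days, , drop = FALSE]
    if (length(sig_terms) && nrow(rate_runs) >= 2L) {
      func_vals <- lapply(rate_runs$run_id, function(r) {
        v <- counts[[r]]$counts[sig_terms] / counts[[r]]$total_spectra
        v[is.na(v)] <- 0
        stats::setNames(as.numeric(v), sig_terms)
      })
      tax_vals <- lapply(rate_runs$run_id, function(r) {
        v <- class_tabs[[r]]
        v[setdiff(names(v), "Unclassified")]
      })
      fm <- suppressWarnings(build_ratio_matrix(func_vals, rate_runs$day))
      tm <- suppressWarnings(build_ratio_matrix(tax_vals, rate_runs$day))
      fr <- mean_rate(fm, mode = rate_mode)
      tr <- mean_rate(tm, mode = rate_mode)
      perm <- rate_permutation_test(fm, tm, n_perm = n_perm, seed = seed,
                                    perm_mode = perm_mode,
                                    rate_mode = rate_mode)
      utils::write.table(
        data.frame(row_id = names(fr$per_row_rate),
                   rate = unname(fr$per_row_rate)),
        file.path(out_dir, paste0("rates_functional_", trt, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(row_id = names(tr$per_row_rate),
                   rate = unname(tr$per_row_rate)),
        file.path(out_dir, paste0("rates_taxonomic_", trt, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      trt_sum$mean_functional_rate <- fr$mean_rate
      trt_sum$n_functional_rows <- fr$n_rows
      trt_sum$mean_taxonomic_rate <- tr$mean_rate
      trt_sum$n_taxonomic_rows <- tr$n_rows
      trt_sum$rate_permutation <- perm[c("observed_diff", "n_perm",
                                         "p_value", "seed")]
      log_line(logcon, trt, " rates: functional ",
               signif(fr$mean_rate, 4), "/day (n=", fr$n_rows,
               "), taxonomic ", signif(tr$mean_rate, 4), "/day (n=",
               tr$n_rows, "), permutation p=", signif(perm$p_value, 4),
               verbose = verbose)
    }

    if ("otu_path" %in% names(runs)) {
      ok <- !is.na(runs$otu_path) & nzchar(runs$otu_path)
      if (any(ok)) {
        otu_tabs <- lapply(runs$otu_path[ok], function(p) {
          df <- utils::read.delim(p, stringsAsFactors = FALSE)
          stats::setNames(df$fraction, df$class)
        })
        names(otu_tabs) <- runs$run_id[ok]
        conc <- stage("concordance",
                      concordance_by_experiment(class_tabs[runs$run_id[ok]],
                                                otu_tabs))
        trt_sum$concordance <- conc
        log_line(logcon, trt, " peptide/16S concordance r=",
                 signif(conc$r, 3), " (n=", conc$n, ")", verbose = verbose)
      }
    }
    summary$treatments[[trt]] <- trt_sum
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
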