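# Synthetic-data generator: reference proteins with GO/taxon labels, a toy
# GO DAG and taxonomy, and time-course PSM tables with spiked functional
# effects. Emulates the structure of a shipboard incubation experiment:
# two treatments sampled at days 0/1/6/10, multinomial spectral sampling,
# a configurable fraction of class-ambiguous and nonbacterial peptides.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: a 6-class bacterial
#' community, 300 metagenome proteins, a 60-term ontology over three
#' aspects, 2,000 observed peptides, 20,000 spectra per run at days
#' 0/1/6/10 under two treatments, spiked functional effects spanning
#' log2 fold changes of 2.2-3.8 realized over the first day, 15% of
#' peptides ambiguous across classes and 2% nonbacterial.
#'
#' @param seed integer seed; the generator is fully deterministic in it.
#' @param n_classes number of bacterial classes.
#' @param n_proteins number of reference proteins.
#' @param n_go_terms total GO terms over the three aspects (>= 3).
#' @param days sampling days.
#' @param n_peptides number of distinct observed peptides.
#' @param total_spectra_per_run spectra drawn per run (multinomial total).
#' @param spike_drifts log2 effects of the spiked GO terms, realized over
#'   day 0 to `spike_saturation_day` in the `spike_treatment` arm and held
#'   thereafter; `numeric(0)` gives a fully null dataset.
#' @param spike_saturation_day day at which spike trajectories plateau.
#' @param spike_share_range baseline spectral-share band from which spiked
#'   terms are drawn.
#' @param spike_treatment treatment receiving the spikes.
#' @param lca_ambiguity_rate fraction of bacterial peptides planted into a
#'   second protein of a different class (LCA resolves above class).
#' @param nonbacterial_rate fraction of peptides drawn from the
#'   non-Bacteria branch.
#' @param otu_reads 16S reads sampled per run for the OTU class tables.
#' @param treatments treatment labels.
#' @param peptide_length min/max peptide length.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_classes = 6L,
                       n_proteins = 300L,
                       n_go_terms = 60L,
                       days = c(0, 1, 6, 10),
                       n_peptides = 2000L,
                       total_spectra_per_run = 20000L,
                       spike_drifts = c(2.2, 3.0, 3.8),
                       spike_saturation_day = 1,
                       spike_share_range = c(0.0005, 0.003),
                       spike_treatment = "OM",
                       lca_ambiguity_rate = 0.15,
                       nonbacterial_rate = 0.02,
                       otu_reads = 10000L,
                       treatments = c("OM", "control"),
                       peptide_length = c(9L, 15L)) {
  stopifnot(n_classes >= 1, n_proteins >= 2, n_go_terms >= 3,
            length(days) >= 2, all(diff(days) > 0),
            n_peptides >= 1, total_spectra_per_run >= 1,
            lca_ambiguity_rate >= 0, lca_ambiguity_rate <= 1,
            nonbacterial_rate >= 0, nonbacterial_rate <= 1,
            spike_treatment %in% treatments,
            peptide_length[1] >= 5, peptide_length[2] >= peptide_length[1])
  structure(list(
    seed = as.integer(seed), n_classes = as.integer(n_classes),
    n_proteins = as.integer(n_proteins), n_go_terms = as.integer(n_go_terms),
    days = as.numeric(days), n_peptides = as.integer(n_peptides),
    total_spectra_per_run = as.integer(total_spectra_per_run),
    spike_drifts = as.numeric(spike_drifts),
    spike_saturation_day = as.numeric(spike_saturation_day),
    spike_share_range = as.numeric(spike_share_range),
    spike_treatment = spike_treatment,
    lca_ambiguity_rate = as.numeric(lca_ambiguity_rate),
    nonbacterial_rate = as.numeric(nonbacterial_rate),
    otu_reads = as.integer(otu_reads),
    treatments = treatments,
    peptide_length = as.integer(peptide_length)
  ), class = "sim_config")
}

sim_aa <- setdiff(AA_ALPHABET, "X")

#' Generate the synthetic reference: GO DAG, taxonomy, proteins
#'
#' Builds one random rooted DAG per GO aspect (each non-root term attached
#' to 1-2 earlier terms of its aspect), a taxonomy
#' root / superkingdom / phylum / class / genus with the configured number
#' of bacterial classes plus one non-Bacteria branch, and random
#' amino-acid proteins with 1-2 GO leaf annotations and a genus-level
#' top-hit taxon. Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `dag`, `tree`, `proteins` (data.frame with
#'   list-column `go_ids`, `top_hit_taxon`, `class_true`, `is_bacterial`),
#'   and `class_abundance` (named, sums to 1).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    # --- GO DAG: one random rooted DAG per aspect -------------------------
    n <- config$n_go_terms
    per_aspect <- diff(floor(seq(0, n, length.out = 4)))
    ids <- sprintf("GO:%07d", seq_len(n))
    aspect <- rep(GO_ASPECTS, per_aspect)
    parents <- stats::setNames(vector("list", n), ids)
    offset <- 0L
    for (a in seq_along(per_aspect)) {
      k <- per_aspect[a]
      local_ids <- ids[offset + seq_len(k)]
      for (j in seq_len(k)) {
        if (j == 1L) { parents[[local_ids[j]]] <- character(0); next }
        n_par <- sample.int(min(2L, j - 1L), 1L)
        parents[[local_ids[j]]] <- sample(local_ids[seq_len(j - 1L)], n_par)
      }
      offset <- offset + k
    }
    dag <- go_dag(data.frame(id = ids,
                             name = paste("synthetic term", seq_len(n)),
                             aspect = aspect, stringsAsFactors = FALSE),
                  parents)

    # --- taxonomy ---------------------------------------------------------
    nc <- config$n_classes
    n_phyla <- max(1L, ceiling(nc / 3))
    class_ids <- sprintf("c%02d", seq_len(nc))
    class_names <- sprintf("class%02d", seq_len(nc))
    phylum_of_class <- sprintf("p%02d", ((seq_len(nc) - 1L) %% n_phyla) + 1L)
    genus_ids <- c(sprintf("g%02d_1", seq_len(nc)),
                   sprintf("g%02d_2", seq_len(nc)))
    genus_parent <- rep(class_ids, 2)
    nodes <- rbind(
      data.frame(id = "root", parent_id = "", rank = "root", name = "root"),
      data.frame(id = "sk_bact", parent_id = "root", rank = "superkingdom",
                 name = "Bacteria"),
      data.frame(id = "sk_euk", parent_id = "root", rank = "superkingdom",
                 name = "Eukaryota"),
      data.frame(id = sprintf("p%02d", seq_len(n_phyla)),
                 parent_id = "sk_bact", rank = "phylum",
                 name = sprintf("phylum%02d", seq_len(n_phyla))),
      data.frame(id = "p_euk", parent_id = "sk_euk", rank = "phylum",
                 name = "EukPhylum"),
      data.frame(id = class_ids, parent_id = phylum_of_class,
                 rank = "class", name = class_names),
      data.frame(id = "c_euk", parent_id = "p_euk", rank = "class",
                 name = "EukClass"),
      data.frame(id = genus_ids, parent_id = genus_parent, rank = "genus",
                 name = paste0("genus_", genus_ids)),
      data.frame(id = "g_euk", parent_id = "c_euk", rank = "genus",
                 name = "genus_euk")
    )
    tree <- tax_tree(nodes)

    # --- community composition (uneven, marine-like) ----------------------
    w <- stats::rgamma(nc, shape = 1.2)
    class_abundance <- stats::setNames(w / sum(w), class_names)

    # --- proteins ---------------------------------------------------------
    np <- config$n_proteins
    n_euk <- max(2L, round(config$nonbacterial_rate * np))
    n_bact <- np - n_euk
    cls <- sample(seq_len(nc), n_bact, replace = TRUE,
                  prob = class_abundance)
    genus <- sprintf("g%02d_%d", cls, sample.int(2L, n_bact, replace = TRUE))
    leaves <- go_leaves(dag)
    if (length(leaves) < 2L) stop("infeasible config: ontology has no leaves")
    lens <- sample(120:240, np, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(sim_aa, L, replace = TRUE), collapse = ""), character(1))
    # heavy-tailed term usage (Zipf-like), so some terminal terms are rare
    leaf_prob <- 1 / seq_along(leaves)^2
    leaf_prob <- sample(leaf_prob / sum(leaf_prob))
    go_ids <- replicate(np,
      sample(leaves, sample.int(2L, 1L), prob = leaf_prob),
      simplify = FALSE)
    proteins <- data.frame(
      id = sprintf("prot%04d", seq_len(np)),
      sequence = seqs,
      top_hit_taxon = c(genus, rep("g_euk", n_euk)),
      class_true = c(class_names[cls], rep(NA_character_, n_euk)),
      is_bacterial = c(rep(TRUE, n_bact), rep(FALSE, n_euk)),
      stringsAsFactors = FALSE
    )
    proteins$go_ids <- go_ids
    list(config = config, dag = dag, tree = tree, proteins = proteins,
         class_abundance = class_abundance)
  })
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Generate the synthetic time course: peptides, PSM tables, OTU tables
#'
#' Peptides are substrings of their source proteins (so the matcher always
#' finds them); a configured fraction is additionally planted verbatim
#' into a protein of a different class, forcing the LCA above class rank.
#' Per-run spectral counts are multinomial over per-peptide weights;
#' weights of peptides carrying a spiked GO term drift by the configured
#' log2 effect up to the saturation day in the spiked treatment. 16S OTU
#' class tables are sampled from the true (source-class) composition.
#' Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @param reference output of [simulate_reference()] (same config).
#' @return list of class `pepgo_sim`; see Details. Key elements:
#'   `reference` (with planted protein sequences), `peptides`, `psm`
#'   (long PSM data.frame over all runs), `otu` (long class-fraction
#'   data.frame), `runs` (run_id/treatment/day), and `truth` (spiked
#'   terms, analytic per-run term proportions and class compositions).
#' @export
simulate_timecourse <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  dag <- reference$dag; tree <- reference$tree
  proteins <- reference$proteins
  withr::with_seed(config$seed + 1L, {
    np <- config$n_peptides
    n_nonb <- round(config$nonbacterial_rate * np)
    n_bact <- np - n_nonb
    bact_idx <- which(proteins$is_bacterial)
    euk_idx <- which(!proteins$is_bacterial)
    class_n <- table(proteins$class_true[bact_idx])
    prot_w <- reference$class_abundance[proteins$class_true[bact_idx]] /
      as.numeric(class_n[proteins$class_true[bact_idx]])
    src <- c(sample(bact_idx, n_bact, replace = TRUE, prob = prot_w),
             if (n_nonb > 0) sample(euk_idx, n_nonb, replace = TRUE))

    draw_peptide <- function(pidx) {
      s <- proteins$sequence[pidx]
      L <- sample(seq(config$peptide_length[1], config$peptide_length[2]), 1L)
      start <- sample.int(nchar(s) - L + 1L, 1L)
      substr(s, start, start + L - 1L)
    }
    peps <- vapply(src, draw_peptide, character(1))
    for (iter in 1:100) {        # enforce distinct peptide sequences
      dup <- which(duplicated(peps))
      if (!length(dup)) break
      peps[dup] <- vapply(src[dup], draw_peptide, character(1))
    }
    if (anyDuplicated(peps)) stop("could not generate distinct peptides")

    is_nonbact <- c(rep(FALSE, n_bact), rep(TRUE, n_nonb))
    is_amb <- stats::runif(np) < config$lca_ambiguity_rate & !is_nonbact
    protein_sets <- as.list(proteins$id[src])
    src_class <- proteins$class_true[src]
    for (i in which(is_amb)) {
      other <- bact_idx[proteins$class_true[bact_idx] != src_class[i]]
      if (!length(other)) { is_amb[i] <- FALSE; next }
      tgt <- if (length(other) == 1L) other else sample(other, 1L)
      proteins$sequence[tgt] <- paste0(proteins$sequence[tgt], peps[i])
      protein_sets[[i]] <- c(protein_sets[[i]], proteins$id[tgt])
    }

    # closed GO sets per peptide (union over its planted protein set)
    prot_go <- stats::setNames(proteins$go_ids, proteins$id)
    pep_go <- lapply(protein_sets, function(pp) {
      raw <- unique(unlist(prot_go[pp], use.names = FALSE))
      if (length(raw)) go_closure(dag, raw) else character(0)
    })

    w <- stats::rlnorm(np, meanlog = 0, sdlog = 1)
    w_bact_total <- sum(w[!is_nonbact])

    # spiked terms: DAG leaves whose baseline bacterial spectral share
    # falls in the configured band
    spikes <- data.frame(go_id = character(0), drift = numeric(0),
                         base_share = numeric(0))
    drift_per_pep <- numeric(np)
    if (length(config$spike_drifts)) {
      leaves <- go_leaves(dag)
      share <- vapply(leaves, function(t) {
        sum(w[!is_nonbact][vapply(pep_go[!is_nonbact],
                                  function(g) t %in% g, logical(1))]) /
          w_bact_total
      }, numeric(1))
      n_spk <- length(config$spike_drifts)
      lo <- config$spike_share_range[1]; hi <- config$spike_share_range[2]
      in_band <- leaves[share >= lo & share <= hi]
      above <- leaves[share >= lo]
      if (length(above) < n_spk)
        stop("infeasible config: only ", length(above),
             " leaf terms with baseline share >= ", lo)
      picked <- if (length(in_band) >= n_spk) sample(in_band, n_spk)
      else {
        # fall back to the smallest shares above the floor, keeping the
        # total spiked mass minimal
        extra <- setdiff(above[order(share[match(above, leaves)])], in_band)
        c(in_band, extra[seq_len(n_spk - length(in_band))])
      }
      # largest effect on the rarest term, so the spiked spectral mass
      # (and hence compositional displacement of null terms) stays small
      picked <- picked[order(share[match(picked, leaves)])]
      config$spike_drifts <- sort(config$spike_drifts, decreasing = TRUE)
      spikes <- data.frame(go_id = picked, drift = config$spike_drifts,
                           base_share = share[picked],
                           stringsAsFactors = FALSE)
      for (k in seq_len(nrow(spikes))) {
        carrier <- vapply(pep_go, function(g) spikes$go_id[k] %in% g,
                          logical(1))
        drift_per_pep[carrier] <- drift_per_pep[carrier] + spikes$drift[k]
      }
    }

    runs <- expand.grid(treatment = config$treatments, day = config$days,
                        stringsAsFactors = FALSE)
    runs <- runs[order(runs$treatment, runs$day), , drop = FALSE]
    runs$run_id <- sprintf("%s_d%g", runs$treatment, runs$day)
    rownames(runs) <- NULL

    run_weights <- sapply(seq_len(nrow(runs)), function(r) {
      if (runs$treatment[r] == config$spike_treatment) {
        w * 2^(drift_per_pep * pmin(runs$day[r], config$spike_saturation_day))
      } else w
    })
    colnames(run_weights) <- runs$run_id

    psm <- do.call(rbind, lapply(seq_len(nrow(runs)), function(r) {
      cnt <- as.integer(stats::rmultinom(1, config$total_spectra_per_run,
                                         run_weights[, r]))
      keep <- cnt > 0L
      data.frame(peptide = peps[keep], run_id = runs$run_id[r],
                 spectral_count = cnt[keep], stringsAsFactors = FALSE)
    }))
    rownames(psm) <- NULL

    # --- analytic truth ---------------------------------------------------
    bact <- !is_nonbact
    q_bact <- apply(run_weights, 2, function(v) v[bact] / sum(v[bact]))
    term_props <- t(vapply(dag$ids, function(t) {
      carrier <- vapply(pep_go[bact], function(g) t %in% g, logical(1))
      colSums(q_bact[carrier, , drop = FALSE])
    }, numeric(nrow(runs))))
    pep_class <- ifelse(is_amb, "Unclassified", src_class)  # peptide view
    cls_levels <- sort(unique(pep_class[bact]))
    class_props <- t(vapply(cls_levels, function(cl)
      colSums(q_bact[pep_class[bact] == cl, , drop = FALSE]),
      numeric(nrow(runs))))
    cls16 <- sort(unique(src_class[bact]))
    class_props_16s <- t(vapply(cls16, function(cl)
      colSums(q_bact[src_class[bact] == cl, , drop = FALSE]),
      numeric(nrow(runs))))

    otu <- do.call(rbind, lapply(seq_len(nrow(runs)), function(r) {
      reads <- stats::rmultinom(1, config$otu_reads, class_props_16s[, r])
      data.frame(run_id = runs$run_id[r], class = rownames(class_props_16s),
                 fraction = as.numeric(reads) / config$otu_reads,
                 stringsAsFactors = FALSE)
    }))
    rownames(otu) <- NULL

    peptides <- data.frame(peptide = peps,
                           source_protein = proteins$id[src],
                           class_true = src_class,
                           is_ambiguous = is_amb,
                           is_nonbacterial = is_nonbact,
                           weight = w, stringsAsFactors = FALSE)
    peptides$protein_ids <- protein_sets
    peptides$go_ids <- pep_go

    reference$proteins <- proteins  # planted sequences included
    structure(list(config = config, reference = reference,
                   peptides = peptides, psm = psm, otu = otu, runs = runs,
                   truth = list(spikes = spikes, term_props = term_props,
                                class_props = class_props,
                                class_props_16s = class_props_16s)),
              class = "pepgo_sim")
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [simulate_reference()] then
#' [simulate_timecourse()].
#' @param config a [sim_config()].
#' @return A `pepgo_sim` object.
#' @export
simulate_dataset <- function(config = sim_config()) {
  simulate_timecourse(config, simulate_reference(config))
}

#' @export
print.pepgo_sim <- function(x, ...) {
  cat("pepgo_sim:", nrow(x$peptides), "peptides,", nrow(x$runs), "runs,",
      nrow(x$truth$spikes), "spiked GO term(s)\n")
  invisible(x)
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Writes `ontology.obo`, `taxonomy.tsv`, `proteins.fasta`,
#' `annotations.tsv`, one `psm_<run>.tsv` and `otu_<run>.tsv` per run,
#' `truth.tsv` (spiked terms), and `manifest.tsv`.
#'
#' @param sim a `pepgo_sim` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame (with file paths).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "pepgo_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- sim$reference$dag; tree <- sim$reference$tree
  proteins <- sim$reference$proteins

  obo <- c("format-version: 1.2", "")
  for (i in dag$ids) {
    p <- dag$parents[[i]]
    obo <- c(obo, "[Term]", paste0("id: ", i),
             paste0("name: ", dag$name[[i]]),
             paste0("namespace: ", dag$aspect[[i]]),
             if (length(p)) paste0("is_a: ", p), "")
  }
  writeLines(obo, file.path(dir, "ontology.obo"))

  tax <- data.frame(id = tree$ids,
                    parent_id = ifelse(is.na(tree$parent), "", tree$parent),
                    rank = unname(tree$rank), name = unname(tree$name),
                    stringsAsFactors = FALSE)
  utils::write.table(tax, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  aa <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                proteins$id))
  Biostrings::writeXStringSet(aa, file.path(dir, "proteins.fasta"))

  ann <- data.frame(protein_id = proteins$id,
                    go_ids = vapply(proteins$go_ids, paste,
                                    character(1), collapse = ";"),
                    top_hit_taxon = proteins$top_hit_taxon,
                    stringsAsFactors = FALSE)
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- sim$runs
  manifest$psm_path <- file.path(dir, paste0("psm_", manifest$run_id, ".tsv"))
  manifest$otu_path <- file.path(dir, paste0("otu_", manifest$run_id, ".tsv"))
  for (r in seq_len(nrow(manifest))) {
    utils::write.table(
      sim$psm[sim$psm$run_id == manifest$run_id[r], , drop = FALSE],
      manifest$psm_path[r], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      sim$otu[sim$otu$run_id == manifest$run_id[r], , drop = FALSE],
      manifest$otu_path[r], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sim$truth$spikes, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Evaluate enrichment calls against the simulation truth
#'
#' Positives are the spiked GO terms. Negatives are tested terminal terms
#' whose analytic (weight-derived) log2 proportion change between the two
#' runs is within `null_band` — compositional renormalisation caused by
#' the spikes is therefore part of the truth, not a false positive.
#'
#' @param sim a `pepgo_sim`.
#' @param enrichment result of [compare_runs()] for `run_a` vs `run_b`.
#' @param run_a,run_b the compared run ids (e.g. `"OM_d0"`, `"OM_d1"`).
#' @param null_band absolute true log2 change below which a term counts
#'   as null (default 0.15).
#' @return list with `sensitivity`, `specificity`, `n_pos`, `n_neg`,
#'   `true_pos`, `false_pos`, and the true per-term log2 changes.
#' @export
truth_eval <- function(sim, enrichment, run_a, run_b, null_band = 0.15) {
  stopifnot(inherits(sim, "pepgo_sim"))
  tp <- sim$truth$term_props
  stopifnot(all(c(run_a, run_b) %in% colnames(tp)))
  true_l2 <- log2(tp[, run_b] / tp[, run_a])
  sig <- enrichment$go_id[enrichment$is_significant]
  spiked <- sim$truth$spikes$go_id
  tested_terminal <- enrichment$go_id[enrichment$is_terminal]
  neg <- setdiff(tested_terminal, spiked)
  neg <- neg[is.finite(true_l2[neg]) & abs(true_l2[neg]) <= null_band]
  n_pos <- length(spiked); n_neg <- length(neg)
  list(
    sensitivity = if (n_pos) mean(spiked %in% sig) else NA_real_,
    specificity = if (n_neg) mean(!neg %in% sig) else NA_real_,
    n_pos = n_pos, n_neg = n_neg,
    true_pos = sum(spiked %in% sig), false_pos = sum(neg %in% sig),
    true_log2_change = true_l2
  )
}

#' Simulate a ratio matrix by clamped random walks
#'
#' Each row starts uniformly inside `start_range` and takes Gaussian steps
#' with standard deviation `step_sd` per day, clamped to [0, 1]. Used for
#' calibrating the rate permutation test: rows with a common `step_sd`
#' are exchangeable (a true null), and `step_sd` scales the expected
#' per-day rate of change. Uses the current RNG state.
#'
#' @param n_rows number of rows.
#' @param days numeric day grid (default `c(0, 1, 6)`).
#' @param step_sd per-day step standard deviation.
#' @param start_range range of the starting ratios.
#' @return A ratio matrix with a `days` attribute.
#' @export
simulate_ratio_matrix <- function(n_rows, days = c(0, 1, 6),
                                  step_sd = 0.02,
                                  start_range = c(0.05, 0.95)) {
  stopifnot(n_rows >= 1, length(days) >= 2, all(diff(days) > 0))
  m <- matrix(0, n_rows, length(days),
              dimnames = list(sprintf("row%03d", seq_len(n_rows)),
                              paste0("day_", days)))
  m[, 1] <- stats::runif(n_rows, start_range[1], start_range[2])
  for (j in seq_along(days)[-1]) {
    m[, j] <- clamp01(m[, j - 1] +
                        stats::rnorm(n_rows, 0,
                                     step_sd * (days[j] - days[j - 1])))
  }
  attr(m, "days") <- as.numeric(days)
  m
}
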