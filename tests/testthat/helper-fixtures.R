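# Shared fixtures and independent brute-force oracles.
# Oracles deliberately use different algorithms from the package
# (fixed-point set expansion, path intersection, sliding-window scans).

write_text <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# --- toy GO DAG: root <- A <- {B, C}; D under both B and C (diamond) ----
toy_dag <- function() {
  go_dag(
    data.frame(id = c("GO:1", "GO:2", "GO:3", "GO:4", "GO:5"),
               name = c("root", "A", "B", "C", "D"),
               aspect = "biological_process"),
    list("GO:1" = character(0), "GO:2" = "GO:1",
         "GO:3" = "GO:2", "GO:4" = "GO:2", "GO:5" = c("GO:3", "GO:4"))
  )
}

# --- toy taxonomy: two bacterial classes + a eukaryote branch ----------
toy_tree <- function() {
  tax_tree(data.frame(
    id = c("root", "Bacteria", "Eukaryota", "Bacteroidetes",
           "Proteobacteria", "Flavobacteriia", "Gammaproteobacteria",
           "Polaribacter", "Tenacibaculum", "Colwellia",
           "Dinophyceae", "Karenia"),
    parent_id = c("", "root", "root", "Bacteria", "Bacteria",
                  "Bacteroidetes", "Proteobacteria", "Flavobacteriia",
                  "Flavobacteriia", "Gammaproteobacteria",
                  "Eukaryota", "Dinophyceae"),
    rank = c("root", "superkingdom", "superkingdom", "phylum", "phylum",
             "class", "class", "genus", "genus", "genus",
             "class", "genus"),
    name = c("root", "Bacteria", "Eukaryota", "Bacteroidetes",
             "Proteobacteria", "Flavobacteriia", "Gammaproteobacteria",
             "Polaribacter", "Tenacibaculum", "Colwellia",
             "Dinophyceae", "Karenia"),
    stringsAsFactors = FALSE))
}

# random single-aspect DAG as a raw parent list (id "t1" is the root)
random_parent_list <- function(n) {
  ids <- paste0("t", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  parents[[ids[1]]] <- character(0)
  for (j in seq_len(n)[-1]) {
    k <- sample.int(min(2L, j - 1L), 1L)
    parents[[ids[j]]] <- sample(ids[seq_len(j - 1L)], k)
  }
  parents
}

random_go_dag <- function(n) {
  parents <- random_parent_list(n)
  go_dag(data.frame(id = names(parents), name = names(parents),
                    aspect = "molecular_function"), parents)
}

# oracle: transitive closure by fixed-point expansion over a parent list
brute_ancestors <- function(parents, id) {
  anc <- character(0)
  frontier <- parents[[id]]
  while (length(frontier)) {
    anc <- union(anc, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), anc)
  }
  anc
}

# oracle: terminal members = observed terms that are nobody's ancestor
brute_terminal <- function(parents, observed) {
  observed[vapply(observed, function(t) {
    !any(vapply(setdiff(observed, t),
                function(s) t %in% brute_ancestors(parents, s),
                logical(1)))
  }, logical(1))]
}

# random rooted tree as a node table with "no rank" internal labels
random_tax_table <- function(n) {
  parent <- c("", paste0("n", vapply(seq_len(n - 1L) + 1L,
                                     function(j) sample.int(j - 1L, 1L),
                                     integer(1))))
  data.frame(id = paste0("n", seq_len(n)), parent_id = parent,
             rank = c("root", rep("no rank", n - 1L)),
             name = paste0("n", seq_len(n)), stringsAsFactors = FALSE)
}

# oracle: LCA as the deepest member of the intersection of root paths
brute_lca <- function(tab, taxa) {
  parent <- stats::setNames(tab$parent_id, tab$id)
  path_set <- function(id) {
    p <- id
    while (nzchar(parent[[p[length(p)]]]))
      p <- c(p, parent[[p[length(p)]]])
    p
  }
  paths <- lapply(taxa, path_set)
  common <- Reduce(intersect, paths)
  depth <- vapply(common, function(x) length(path_set(x)), integer(1))
  common[which.max(depth)]
}

# oracle: naive sliding-window substring scan on I/L-normalized strings
brute_match <- function(proteins, peptide, il = TRUE) {
  norm <- function(x) if (il) chartr("I", "L", x) else x
  pep <- norm(peptide)
  hit <- vapply(proteins$sequence, function(s) {
    s <- norm(s)
    ns <- nchar(s); np <- nchar(pep)
    if (np > ns) return(FALSE)
    any(vapply(seq_len(ns - np + 1L),
               function(i) substr(s, i, i + np - 1L) == pep, logical(1)))
  }, logical(1))
  proteins$id[hit]
}

# oracle: per-spectrum DAG propagation (expand every spectrum singly)
brute_go_counts <- function(annotations, observations, run_id) {
  obs <- observations[observations$run_id == run_id, , drop = FALSE]
  counts <- new.env()
  for (i in seq_len(nrow(obs))) {
    g <- annotations$go_ids[[match(obs$peptide[i], annotations$peptide)]]
    for (s in seq_len(obs$spectral_count[i]))
      for (t in g) assign(t, (counts[[t]] %||% 0) + 1, envir = counts)
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# oracle: mean rate by explicit loops, written independently
brute_mean_rate <- function(m, days) {
  rates <- numeric(nrow(m))
  for (r in seq_len(nrow(m))) {
    acc <- 0
    for (j in seq_len(ncol(m) - 1L))
      acc <- acc + abs(m[r, j + 1L] - m[r, j]) / (days[j + 1L] - days[j])
    rates[r] <- acc / (ncol(m) - 1L)
  }
  mean(rates)
}

# tiny protein table usable with peptide_index()
toy_proteins <- function() {
  df <- data.frame(
    id = c("p1", "p2", "p3"),
    sequence = c("MKSAMPLERX", "AAASAMPLERGGG", "MKTENACWWW"),
    top_hit_taxon = c("Polaribacter", "Tenacibaculum", "Colwellia"),
    stringsAsFactors = FALSE)
  df$go_ids <- list("GO:3", c("GO:4", "GO:5"), "GO:2")
  df
}
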