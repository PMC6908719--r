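# GO DAG and reference taxonomy: parsing, ancestor closure, LCA, rank rollup.

GO_ASPECTS <- c("biological_process", "molecular_function", "cellular_component")

#' Ordered taxonomic ranks used for rollup
#'
#' The canonical eight-rank hierarchy, coarsest first. Intermediate ranks
#' (suborder etc.) are treated as "no rank" and skipped during rollup.
#' @export
TAX_RANKS <- c("root", "superkingdom", "phylum", "class", "order",
               "family", "genus", "species")

#' Construct a GO DAG from a term table and parent lists
#'
#' Low-level constructor shared by [read_obo()] and the synthetic-data
#' generator. Validates acyclicity and that every term reaches exactly one
#' aspect root, then precomputes the full ancestor closure of every term.
#'
#' @param terms data.frame with columns `id`, `name`, `aspect`.
#' @param parents named list mapping each term id to a character vector of
#'   parent term ids (empty for aspect roots).
#' @return An object of class `go_dag`.
#' @export
go_dag <- function(terms, parents) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "aspect") %in% names(terms)))
  ids <- as.character(terms$id)
  if (anyDuplicated(ids))
    stop("duplicate GO term id: ", ids[duplicated(ids)][1])
  bad_aspect <- setdiff(unique(terms$aspect), GO_ASPECTS)
  if (length(bad_aspect))
    stop("unknown GO aspect: ", bad_aspect[1])
  parents <- lapply(ids, function(i) {
    p <- parents[[i]]
    if (is.null(p)) character(0) else unique(as.character(p))
  })
  names(parents) <- ids
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown))
    stop("parent edge points to unknown term: ", unknown[1])

  # Kahn-style pass over child -> parent edges; leftovers indicate a cycle.
  ancestors <- vector("list", length(ids))
  names(ancestors) <- ids
  done <- logical(length(ids))
  names(done) <- ids
  remaining <- ids
  while (length(remaining)) {
    ready <- remaining[vapply(parents[remaining],
                              function(p) all(done[p]), logical(1))]
    if (!length(ready))
      stop("cycle detected in ontology graph (involving ", remaining[1], ")")
    for (i in ready) {
      p <- parents[[i]]
      ancestors[[i]] <- unique(c(p, unlist(ancestors[p], use.names = FALSE)))
    }
    done[ready] <- TRUE
    remaining <- setdiff(remaining, ready)
  }

  roots <- ids[lengths(parents) == 0L]
  if (!length(roots)) stop("ontology has no root term")
  reach <- vapply(ids, function(i) {
    r <- intersect(c(i, ancestors[[i]]), roots)
    length(r)
  }, integer(1))
  if (any(reach != 1L))
    stop("term does not reach exactly one aspect root: ", ids[reach != 1L][1])

  children <- lapply(ids, function(i) character(0))
  names(children) <- ids
  for (i in ids)
    for (p in parents[[i]]) children[[p]] <- c(children[[p]], i)

  structure(list(
    ids = ids,
    name = stats::setNames(as.character(terms$name), ids),
    aspect = stats::setNames(as.character(terms$aspect), ids),
    parents = parents,
    children = children,
    ancestors = ancestors,
    roots = roots
  ), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag with", length(x$ids), "terms,", length(x$roots),
      "aspect root(s):", paste(x$roots, collapse = ", "), "\n")
  invisible(x)
}

#' Parse a Gene Ontology OBO file into a DAG
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas. Obsolete terms are dropped. Parent
#' edges are `is_a` plus, by default, `relationship: part_of`. References
#' to terms absent from the file (or obsolete) are dropped with a warning.
#'
#' @param path path to an OBO file (or connection readable by `readLines`).
#' @param include_part_of logical; treat `part_of` relationships as parent
#'   edges in addition to `is_a` (default `TRUE`).
#' @return A [go_dag()] object.
#' @export
read_obo <- function(path, include_part_of = TRUE) {
  lines <- readLines(path, warn = FALSE)
  stanza_start <- grep("^\\[", lines)
  if (!length(stanza_start)) stop("no stanzas found in OBO input")

  recs <- list()
  for (k in seq_along(stanza_start)) {
    from <- stanza_start[k]
    to <- if (k < length(stanza_start)) stanza_start[k + 1] - 1L else length(lines)
    if (lines[from] != "[Term]") next
    body <- lines[(from + 1L):to]
    body <- body[nzchar(body) & !grepl("^!", body)]
    field <- sub(":.*$", "", body)
    value <- sub("^[^:]+: *", "", body)
    value <- sub(" *!.*$", "", value)  # strip trailing comments
    id <- value[field == "id"]
    if (length(id) != 1L)
      stop("malformed OBO stanza starting at line ", from, ": missing id")
    if (any(field == "is_obsolete" & value == "true")) next
    nm <- value[field == "name"]
    ns <- value[field == "namespace"]
    is_a <- sub(" .*$", "", value[field == "is_a"])
    rel <- value[field == "relationship"]
    part_of <- sub("^part_of +", "", rel[grepl("^part_of ", rel)])
    part_of <- sub(" .*$", "", part_of)
    recs[[id]] <- list(
      id = id,
      name = if (length(nm)) nm[1] else id,
      aspect = if (length(ns)) ns[1] else NA_character_,
      parents = if (include_part_of) c(is_a, part_of) else is_a
    )
  }
  if (!length(recs)) stop("no non-obsolete [Term] stanzas in OBO input")

  ids <- names(recs)
  parents <- lapply(recs, function(r) {
    p <- unique(r$parents)
    missing <- setdiff(p, ids)
    if (length(missing))
      warning("dropping parent reference(s) to unknown/obsolete term(s): ",
              paste(missing, collapse = ", "), call. = FALSE)
    intersect(p, ids)
  })
  terms <- data.frame(
    id = ids,
    name = vapply(recs, `[[`, "", "name"),
    aspect = vapply(recs, `[[`, "", "aspect"),
    stringsAsFactors = FALSE
  )
  # Terms lacking an explicit namespace inherit their root's aspect.
  if (anyNA(terms$aspect)) {
    dag_try <- terms
    dag_try$aspect[is.na(dag_try$aspect)] <- GO_ASPECTS[1]
    tmp <- go_dag(dag_try, parents)
    for (i in which(is.na(terms$aspect))) {
      root <- intersect(c(terms$id[i], tmp$ancestors[[terms$id[i]]]), tmp$roots)
      terms$aspect[i] <- tmp$aspect[[root]]
    }
  }
  go_dag(terms, parents)
}

#' Ancestors of a GO term
#'
#' All terms reachable from `id` by parent (`is_a`/`part_of`) edges,
#' excluding `id` itself.
#'
#' @param dag a [go_dag()].
#' @param id a GO term id present in `dag`.
#' @return Character vector of ancestor ids (empty for an aspect root).
#' @export
go_ancestors <- function(dag, id) {
  stopifnot(inherits(dag, "go_dag"))
  if (!id %in% dag$ids) stop("unknown GO term: ", id)
  dag$ancestors[[id]]
}

#' Ancestor closure of a set of GO terms
#'
#' The union of the given terms and all their ancestors. This is the term
#' set a peptide's spectral count is credited to.
#'
#' @inheritParams go_ancestors
#' @param ids character vector of term ids.
#' @return Character vector (sorted, unique).
#' @export
go_closure <- function(dag, ids) {
  stopifnot(inherits(dag, "go_dag"))
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, dag$ids)
  if (length(unknown)) stop("unknown GO term: ", unknown[1])
  sort(unique(c(ids, unlist(dag$ancestors[ids], use.names = FALSE))))
}

#' Leaf terms of a GO DAG
#'
#' Terms with no children in the full ontology.
#' @inheritParams go_ancestors
#' @return Character vector of term ids.
#' @export
go_leaves <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  dag$ids[lengths(dag$children) == 0L]
}

#' Construct a taxonomy tree from a node table
#'
#' @param nodes data.frame with columns `id`, `parent_id`, `rank`, `name`;
#'   exactly one row (the root) has an empty/NA `parent_id`.
#' @return An object of class `tax_tree`.
#' @export
tax_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "parent_id", "rank", "name") %in% names(nodes)))
  ids <- as.character(nodes$id)
  if (anyDuplicated(ids))
    stop("duplicate taxon id: ", ids[duplicated(ids)][1])
  parent <- as.character(nodes$parent_id)
  parent[!nzchar(parent) | is.na(parent)] <- NA_character_
  root <- ids[is.na(parent)]
  if (length(root) != 1L)
    stop("taxonomy must have exactly one root, found ", length(root))
  orphan <- setdiff(parent[!is.na(parent)], ids)
  if (length(orphan))
    stop("taxon references missing parent: ", orphan[1])

  parent <- stats::setNames(parent, ids)
  rank <- stats::setNames(as.character(nodes$rank), ids)
  name <- stats::setNames(as.character(nodes$name), ids)

  # depth + cycle check by walking every path to the root
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth[root] <- 0L
  for (i in ids) {
    path <- i
    while (is.na(depth[path[length(path)]])) {
      nxt <- parent[[path[length(path)]]]
      if (nxt %in% path) stop("cycle detected in taxonomy at ", nxt)
      path <- c(path, nxt)
    }
    base <- depth[path[length(path)]]
    if (length(path) > 1L)
      depth[path[-length(path)]] <- base + rev(seq_len(length(path) - 1L))
  }

  # no rank inversions along any parent edge (among the canonical ranks)
  ri <- stats::setNames(match(rank, TAX_RANKS), ids)  # NA for "no rank" labels
  for (i in ids) {
    p <- parent[[i]]
    if (is.na(p) || is.na(ri[[i]])) next
    anc <- p
    while (!is.na(anc) && is.na(ri[[anc]])) anc <- parent[[anc]]
    if (!is.na(anc) && ri[[anc]] > ri[[i]])
      stop("rank inversion: ", i, " (", rank[i], ") under ", anc,
           " (", rank[anc], ")")
  }

  structure(list(ids = ids, parent = parent, rank = rank, name = name,
                 depth = depth, root = root),
            class = "tax_tree")
}

#' @export
print.tax_tree <- function(x, ...) {
  cat("tax_tree with", length(x$ids), "nodes, root:", x$root, "\n")
  invisible(x)
}

#' Read a taxonomy table
#'
#' Native format: UTF-8 TSV with a header row and columns
#' `id`, `parent_id`, `rank`, `name`; the single root row has an empty
#' `parent_id`.
#'
#' @param path path to the TSV file.
#' @return A [tax_tree()].
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("id", "parent_id", "rank", "name")
  if (!all(need %in% names(df)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  tax_tree(df)
}

tax_check_ids <- function(tree, ids) {
  unknown <- setdiff(ids, tree$ids)
  if (length(unknown)) stop("unknown taxon: ", unknown[1])
}

# Path from the root down to id (root first, id last).
tax_root_path <- function(tree, id) {
  path <- id
  while (!is.na(tree$parent[[path[1]]]))
    path <- c(tree$parent[[path[1]]], path)
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node lying on the root path of every member;
#' `tax_lca(tree, x)` of a single taxon is `x` itself.
#'
#' @param tree a [tax_tree()].
#' @param taxa nonempty character vector of taxon ids.
#' @return A single taxon id.
#' @export
tax_lca <- function(tree, taxa) {
  stopifnot(inherits(tree, "tax_tree"))
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("tax_lca() requires at least one taxon")
  tax_check_ids(tree, taxa)
  paths <- lapply(taxa, tax_root_path, tree = tree)
  k <- min(lengths(paths))
  common <- 0L
  for (j in seq_len(k)) {
    step <- paths[[1]][j]
    if (all(vapply(paths, function(p) p[j] == step, logical(1))))
      common <- j
    else break
  }
  paths[[1]][common]
}

#' Ancestor-or-self of a taxon at a given rank
#'
#' Walks up the parent chain from `id` and returns the node whose rank
#' equals `rank`, or `NA` if the path to the root contains no node of that
#' rank (e.g. `id` itself sits above it).
#'
#' @inheritParams tax_lca
#' @param id a taxon id.
#' @param rank one of [TAX_RANKS].
#' @return A taxon id or `NA_character_`.
#' @export
tax_rank_at <- function(tree, id, rank = "class") {
  stopifnot(inherits(tree, "tax_tree"))
  rank <- match.arg(rank, TAX_RANKS)
  tax_check_ids(tree, id)
  cur <- id
  repeat {
    if (identical(unname(tree$rank[[cur]]), rank)) return(cur)
    cur <- tree$parent[[cur]]
    if (is.na(cur)) return(NA_character_)
  }
}

#' Is a taxon on or under a given ancestor?
#'
#' @inheritParams tax_rank_at
#' @param ancestor a taxon id (e.g. the Bacteria superkingdom node).
#' @return Logical.
#' @export
tax_is_under <- function(tree, id, ancestor) {
  stopifnot(inherits(tree, "tax_tree"))
  tax_check_ids(tree, c(id, ancestor))
  ancestor %in% tax_root_path(tree, id)
}
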