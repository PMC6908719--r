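# Peptide-to-protein matching, GO/taxon annotation, nonbacterial filtering.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "X", "Y")

normalize_il <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Read a metagenome protein database (FASTA + annotation table)
#'
#' The annotation table is a TSV with header columns
#' `protein_id`, `go_ids` (semicolon-separated GO accessions, may be
#' empty) and `top_hit_taxon` (taxon id of the protein's top BLAST hit,
#' may be empty). Proteins present in the FASTA but absent from the table
#' get an empty GO set and no taxon. GO ids not found in `dag` are dropped
#' with a warning.
#'
#' @param fasta_path path to an amino-acid FASTA file.
#' @param annotation_path path to the annotation TSV.
#' @param dag optional [go_dag()] used to validate GO ids.
#' @return data.frame with columns `id`, `sequence`, list-column `go_ids`,
#'   and `top_hit_taxon` (`NA` when absent).
#' @export
read_protein_db <- function(fasta_path, annotation_path, dag = NULL) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub(" .*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate protein id in FASTA: ", ids[duplicated(ids)][1])
  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  need <- c("protein_id", "go_ids", "top_hit_taxon")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$protein_id))
    stop("duplicate protein id in annotation table: ",
         ann$protein_id[duplicated(ann$protein_id)][1])
  idx <- match(ids, ann$protein_id)
  go_raw <- ifelse(is.na(idx), "", ann$go_ids[idx])
  go_ids <- lapply(strsplit(go_raw, ";", fixed = TRUE),
                   function(g) unique(g[nzchar(g)]))
  if (!is.null(dag)) {
    known <- unique(unlist(go_ids))
    bad <- setdiff(known, dag$ids)
    if (length(bad)) {
      warning("dropping ", length(bad),
              " GO id(s) absent from the ontology (e.g. ", bad[1], ")",
              call. = FALSE)
      go_ids <- lapply(go_ids, intersect, y = dag$ids)
    }
  }
  taxon <- ifelse(is.na(idx), NA_character_, ann$top_hit_taxon[idx])
  taxon[!is.na(taxon) & !nzchar(taxon)] <- NA_character_
  out <- data.frame(id = ids, sequence = as.character(aa),
                    top_hit_taxon = taxon, stringsAsFactors = FALSE)
  out$go_ids <- go_ids
  out[, c("id", "sequence", "go_ids", "top_hit_taxon")]
}

#' Read a peptide spectral-count (PSM) table
#'
#' TSV with header columns `peptide`, `run_id`, `spectral_count`. Rows with
#' peptides shorter than 5 residues or counts below 1 are dropped with a
#' warning.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `peptide`, `run_id`,
#'   `spectral_count` (integer).
#' @export
read_psm_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  need <- c("peptide", "run_id", "spectral_count")
  if (!all(need %in% names(df)))
    stop("PSM table must have columns: ", paste(need, collapse = ", "))
  bad <- nchar(df$peptide) < 5L | is.na(df$spectral_count) |
    df$spectral_count < 1L
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " PSM row(s) with short peptide or count < 1", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Build an exact-substring peptide matcher over a protein database
#'
#' By default isoleucine and leucine are treated as identical (they are
#' isobaric and indistinguishable by mass spectrometry), so matching is
#' performed on I/L-normalized sequences.
#'
#' @param proteins data.frame as returned by [read_protein_db()] (columns
#'   `id`, `sequence` required).
#' @param il_equivalent logical; fold I onto L before matching
#'   (default `TRUE`).
#' @return An object of class `peptide_matcher`.
#' @export
peptide_index <- function(proteins, il_equivalent = TRUE) {
  stopifnot(is.data.frame(proteins),
            all(c("id", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0L) stop("protein list must be nonempty")
  if (anyDuplicated(proteins$id))
    stop("duplicate protein id: ",
         proteins$id[duplicated(proteins$id)][1])
  seqs <- toupper(proteins$sequence)
  if (any(!nzchar(seqs))) stop("empty protein sequence")
  structure(list(
    ids = as.character(proteins$id),
    seq_norm = if (il_equivalent) normalize_il(seqs) else seqs,
    il_equivalent = il_equivalent
  ), class = "peptide_matcher")
}

#' Find all proteins containing a peptide
#'
#' Exact contiguous-substring search under the matcher's I/L convention.
#'
#' @param matcher a [peptide_index()].
#' @param peptide amino-acid string.
#' @return Character vector of protein ids (possibly empty).
#' @export
match_peptide <- function(matcher, peptide) {
  stopifnot(inherits(matcher, "peptide_matcher"))
  peptide <- toupper(peptide)
  if (!nzchar(peptide)) stop("peptide must be nonempty")
  if (!all(strsplit(peptide, "")[[1]] %in% AA_ALPHABET))
    stop("peptide contains non-amino-acid characters: ", peptide)
  if (matcher$il_equivalent) peptide <- normalize_il(peptide)
  matcher$ids[grepl(peptide, matcher$seq_norm, fixed = TRUE)]
}

#' Annotate peptides with GO term closures and LCA taxa
#'
#' For each peptide: matches it against the protein database, takes the
#' union of the matched proteins' GO annotations closed under ancestors,
#' and assigns the lowest common ancestor of the matched proteins'
#' top-hit taxa. A peptide is flagged bacterial when its LCA lies on or
#' under the `bacteria` node; peptides with no resolvable taxon are
#' non-bacterial unless `keep_untaxed = TRUE`.
#'
#' @param peptides character vector of peptide sequences (deduplicated
#'   internally).
#' @param matcher a [peptide_index()] built from `proteins`.
#' @param proteins protein data.frame (see [read_protein_db()]).
#' @param dag a [go_dag()].
#' @param tree a [tax_tree()].
#' @param bacteria id (or name) of the Bacteria node in `tree`.
#' @param keep_untaxed treat peptides with no taxon as bacterial
#'   (default `FALSE`, conservative removal).
#' @return data.frame with columns `peptide`, list-columns `protein_ids`
#'   and `go_ids` (ancestor-closed), `lca_taxon`, `is_bacterial`.
#' @export
annotate_peptides <- function(peptides, matcher, proteins, dag, tree,
                              bacteria = "Bacteria", keep_untaxed = FALSE) {
  stopifnot(inherits(matcher, "peptide_matcher"), inherits(dag, "go_dag"),
            inherits(tree, "tax_tree"))
  peptides <- unique(as.character(peptides))
  if (!bacteria %in% tree$ids) {
    hit <- tree$ids[tree$name == bacteria]
    if (length(hit) != 1L)
      stop("cannot resolve Bacteria node '", bacteria, "' in taxonomy")
    bacteria <- hit
  }
  pidx <- stats::setNames(seq_len(nrow(proteins)), proteins$id)

  n <- length(peptides)
  protein_ids <- vector("list", n)
  go_ids <- vector("list", n)
  lca_taxon <- character(n)
  is_bact <- logical(n)
  for (i in seq_len(n)) {
    hits <- match_peptide(matcher, peptides[i])
    protein_ids[[i]] <- hits
    if (length(hits)) {
      raw_go <- unique(unlist(proteins$go_ids[pidx[hits]], use.names = FALSE))
      go_ids[[i]] <- if (length(raw_go)) go_closure(dag, raw_go) else character(0)
      taxa <- proteins$top_hit_taxon[pidx[hits]]
      taxa <- unique(taxa[!is.na(taxa)])
      lca_taxon[i] <- if (length(taxa)) tax_lca(tree, taxa) else NA_character_
    } else {
      go_ids[[i]] <- character(0)
      lca_taxon[i] <- NA_character_
    }
    is_bact[i] <- if (is.na(lca_taxon[i])) keep_untaxed else
      tax_is_under(tree, lca_taxon[i], bacteria)
  }
  out <- data.frame(peptide = peptides, lca_taxon = lca_taxon,
                    is_bacterial = is_bact, stringsAsFactors = FALSE)
  out$protein_ids <- protein_ids
  out$go_ids <- go_ids
  out[, c("peptide", "protein_ids", "go_ids", "lca_taxon", "is_bacterial")]
}

#' Remove nonbacterial peptide annotations
#'
#' @param annotations data.frame from [annotate_peptides()].
#' @return list with `kept` (the bacterial rows) and `removed_count`.
#' @export
filter_nonbacterial <- function(annotations) {
  stopifnot(is.data.frame(annotations), "is_bacterial" %in% names(annotations))
  kept <- annotations[annotations$is_bacterial, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed_count = nrow(annotations) - nrow(kept))
}
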