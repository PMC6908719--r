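test_that("OBO parsing builds the expected DAG and drops obsolete terms", {
  path <- write_text(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: A", "namespace: biological_process",
    "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:3", "name: B", "namespace: biological_process",
    "is_a: GO:2 ! A", "",
    "[Term]", "id: GO:9", "name: gone", "namespace: biological_process",
    "is_a: GO:1", "is_obsolete: true", ""), ext = ".obo")
  dag <- read_obo(path)
  expect_s3_class(dag, "go_dag")
  expect_setequal(dag$ids, c("GO:1", "GO:2", "GO:3"))
  expect_equal(dag$parents[["GO:3"]], "GO:2")
  expect_equal(dag$roots, "GO:1")
})

test_that("OBO parser honors the part_of flag", {
  path <- write_text(c(
    "[Term]", "id: GO:1", "name: root", "namespace: cellular_component", "",
    "[Term]", "id: GO:2", "name: A", "namespace: cellular_component",
    "is_a: GO:1", "",
    "[Term]", "id: GO:3", "name: B", "namespace: cellular_component",
    "is_a: GO:1", "relationship: part_of GO:2 ! A", ""), ext = ".obo")
  with_po <- read_obo(path, include_part_of = TRUE)
  without <- read_obo(path, include_part_of = FALSE)
  expect_setequal(with_po$parents[["GO:3"]], c("GO:1", "GO:2"))
  expect_equal(without$parents[["GO:3"]], "GO:1")
})

test_that("malformed and cyclic OBO input raise informative errors", {
  no_id <- write_text(c("[Term]", "name: nameless", ""), ext = ".obo")
  expect_error(read_obo(no_id), "line 1")
  cyc <- write_text(c(
    "[Term]", "id: GO:1", "name: a", "namespace: biological_process",
    "is_a: GO:2", "",
    "[Term]", "id: GO:2", "name: b", "namespace: biological_process",
    "is_a: GO:1", ""), ext = ".obo")
  expect_error(read_obo(cyc), "cycle")
})

test_that("ancestors walk every parent path exactly once", {
  dag <- toy_dag()
  expect_setequal(go_ancestors(dag, "GO:3"), c("GO:2", "GO:1"))
  expect_identical(go_ancestors(dag, "GO:1"), character(0))
  # diamond: D reaches A once through two routes
  expect_setequal(go_ancestors(dag, "GO:5"),
                  c("GO:3", "GO:4", "GO:2", "GO:1"))
  expect_error(go_ancestors(dag, "GO:99"), "unknown")
})

test_that("ancestors match brute-force transitive closure on random DAGs", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(3:50, 1)
    parents <- random_parent_list(n)
    dag <- go_dag(data.frame(id = names(parents), name = names(parents),
                             aspect = "molecular_function"), parents)
    id <- sample(names(parents), 1)
    expect_setequal(go_ancestors(dag, id), brute_ancestors(parents, id))
  }
})

test_that("taxonomy table parsing validates structure", {
  ok <- write_text(c("id\tparent_id\trank\tname",
                     "root\t\troot\troot",
                     "b\troot\tsuperkingdom\tBacteria",
                     "f\tb\tclass\tFlavobacteriia",
                     "p\tf\tgenus\tPolaribacter"), ext = ".tsv")
  tree <- read_taxonomy(ok)
  expect_s3_class(tree, "tax_tree")
  expect_equal(unname(tree$depth[["p"]]), 3L)

  orphan <- write_text(c("id\tparent_id\trank\tname",
                         "root\t\troot\troot",
                         "x\tmissing\tclass\tX"), ext = ".tsv")
  expect_error(read_taxonomy(orphan), "missing parent")

  two_roots <- write_text(c("id\tparent_id\trank\tname",
                            "r1\t\troot\tr1", "r2\t\troot\tr2"),
                          ext = ".tsv")
  expect_error(read_taxonomy(two_roots), "exactly one root")

  dup <- write_text(c("id\tparent_id\trank\tname",
                      "root\t\troot\troot",
                      "a\troot\tclass\tA", "a\troot\tclass\tA2"),
                    ext = ".tsv")
  expect_error(read_taxonomy(dup), "duplicate")
})

test_that("LCA handles singletons, siblings, and cross-class sets", {
  tree <- toy_tree()
  expect_equal(tax_lca(tree, "Polaribacter"), "Polaribacter")
  expect_equal(tax_lca(tree, c("Polaribacter", "Tenacibaculum")),
               "Flavobacteriia")
  # cross-phylum set resolves above class rank
  above <- tax_lca(tree, c("Flavobacteriia", "Colwellia"))
  expect_equal(above, "Bacteria")
  expect_true(is.na(tax_rank_at(tree, above, "class")))
  expect_error(tax_lca(tree, character(0)), "at least one")
  expect_error(tax_lca(tree, "NotATaxon"), "unknown")
})

test_that("LCA matches the root-path-intersection oracle on random trees", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(5:200, 1)
    tab <- random_tax_table(n)
    tree <- tax_tree(tab)
    taxa <- sample(tab$id, sample(1:4, 1))
    expect_equal(tax_lca(tree, taxa), unname(brute_lca(tab, taxa)))
  }
})

test_that("LCA is an ancestor-or-self of every member and is deepest", {
  set.seed(303)
  for (rep in 1:25) {
    tab <- random_tax_table(sample(5:100, 1))
    tree <- tax_tree(tab)
    taxa <- sample(tab$id, 2)
    l <- tax_lca(tree, taxa)
    expect_true(all(vapply(taxa, tax_is_under, logical(1),
                           tree = tree, ancestor = l)))
    kids <- tab$id[tab$parent_id == l]
    deeper <- kids[vapply(kids, function(k)
      all(vapply(taxa, tax_is_under, logical(1),
                 tree = tree, ancestor = k)), logical(1))]
    expect_length(deeper, 0)
  }
})

test_that("rank rollup returns ancestor-or-self, or NA above the rank", {
  tree <- toy_tree()
  expect_equal(tax_rank_at(tree, "Polaribacter", "class"), "Flavobacteriia")
  expect_equal(tax_rank_at(tree, "Flavobacteriia", "class"),
               "Flavobacteriia")
  expect_true(is.na(tax_rank_at(tree, "Bacteroidetes", "class")))
  expect_error(tax_rank_at(tree, "NotATaxon", "class"), "unknown")
})
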