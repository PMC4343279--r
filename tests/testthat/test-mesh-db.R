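test_that("transitive closure of a chain and of an empty edge set", {
  db <- chainDb()
  aor <- meshEdges(db, "AOR")
  expect_equal(aor$ancestor, c("DX", "DX", "DY"))
  expect_equal(aor$offspring, c("DY", "DZ", "DZ"))

  flat <- MeshDb(meshTerms(db), edges = NULL)
  expect_equal(nrow(meshEdges(flat, "AOR")), 0L)
})

test_that("closure matches breadth-first reachability on random DAGs", {
  set.seed(42)
  for (rep in 1:5) {
    g <- randomDagEdges(30, pEdge = 0.12)
    db <- MeshDb(g$terms, g$edges)
    oracle <- bfsClosureOracle(g$terms$mesh_id, g$edges$parent,
                               g$edges$child)
    got <- meshEdges(db, "AOR")
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle)
    ## per-node queries agree with the oracle too
    for (n in sample(g$terms$mesh_id, 5)) {
      expect_equal(meshOffspring(db, n),
                   oracle$offspring[oracle$ancestor == n])
      expect_equal(meshAncestors(db, n),
                   sort(oracle$ancestor[oracle$offspring == n]))
    }
  }
})

test_that("cyclic or dangling hierarchies are rejected with the culprit named", {
  terms <- data.frame(mesh_id = c("DA", "DB"), term = c("a", "b"),
                      category = "A")
  cyc <- data.frame(parent = c("DA", "DB"), child = c("DB", "DA"))
  expect_error(MeshDb(terms, cyc), "cycle.*D[AB]")
  expect_error(MeshDb(terms, data.frame(parent = "DA", child = "DA")),
               "self-edge")
  expect_error(MeshDb(terms, data.frame(parent = "DA", child = "DQ")),
               "unknown mesh_id 'DQ'")
  expect_error(
    MeshDb(terms, cyc[0, ],
           links = data.frame(gene_id = 1L, mesh_id = "DQ",
                              source = "gendoo", pubmed_ids = "")),
    "unknown mesh_id 'DQ'")
})

test_that("direct hierarchy queries return PCR neighbours only", {
  db <- chainDb()
  expect_equal(meshParents(db, "DZ"), "DY")
  expect_equal(meshParents(db, "DX"), character(0))
  expect_equal(meshChildren(db, "DX"), "DY")
  expect_equal(meshAncestors(db, "DZ"), c("DX", "DY"))
  expect_equal(meshAncestors(db, "DX"), character(0))
  expect_error(meshParents(db, "nope"), "unknown mesh_id")

  ## a multi-parent node reports both parents: DAGs, not trees
  terms <- data.frame(mesh_id = c("P1", "P2", "C"), term = c("p1", "p2", "c"),
                      category = "G")
  edges <- data.frame(parent = c("P1", "P2"), child = c("C", "C"))
  db2 <- MeshDb(terms, edges)
  expect_equal(meshParents(db2, "C"), c("P1", "P2"))
  expect_equal(meshAncestors(db2, "C"), c("P1", "P2"))
})

test_that("select retrieves by any keytype and is total on missing keys", {
  db <- chainDb()
  one <- meshSelect(db, keys = 101, cols = "MESHID", keytype = "GENEID")
  expect_equal(one, data.frame(MESHID = "DX"))
  expect_equal(nrow(meshSelect(db, keys = integer(0), cols = "MESHID",
                               keytype = "GENEID")), 0L)
  expect_equal(nrow(meshSelect(db, keys = 999, cols = "MESHID",
                               keytype = "GENEID")), 0L)
  byDoc <- meshSelect(db, keys = c(12, 13), cols = c("GENEID", "PUBMEDID"),
                      keytype = "PUBMEDID")
  expect_equal(byDoc$GENEID, c(102L, 102L))
  expect_equal(byDoc$PUBMEDID, c(12L, 13L))
  byCat <- meshSelect(db, keys = "D", cols = c("MESHID", "SOURCEID"),
                      keytype = "MESHCATEGORY")
  expect_equal(byCat$MESHID, c("DX", "DY", "DZ"))
  expect_error(meshSelect(db, 1, cols = "MESHID", keytype = "WAT"),
               "unknown keytype.*GENEID")
  expect_error(meshSelect(db, 1, cols = c("MESHID", "WAT"),
                          keytype = "GENEID"),
               "non-empty subset")
})

test_that("selecting 50 random links gene by gene recovers the link set", {
  set.seed(11)
  terms <- data.frame(mesh_id = sprintf("D%03d", 1:10),
                      term = sprintf("term %d", 1:10), category = "C")
  links <- unique(data.frame(
    gene_id = sample(1:25, 50, replace = TRUE),
    mesh_id = sample(terms$mesh_id, 50, replace = TRUE),
    source = "gendoo", pubmed_ids = "", stringsAsFactors = FALSE))
  db <- MeshDb(terms, edges = NULL, links = links)
  got <- do.call(rbind, lapply(unique(links$gene_id), function(g)
    meshSelect(db, keys = g, cols = c("GENEID", "MESHID"),
               keytype = "GENEID")))
  got <- got[order(got$GENEID, got$MESHID, method = "radix"), ]
  want <- links[order(links$gene_id, links$mesh_id, method = "radix"),
                c("gene_id", "mesh_id")]
  expect_equal(got$GENEID, want$gene_id)
  expect_equal(got$MESHID, want$mesh_id)
})

test_that("keytypes and columns are the fixed schema lists", {
  db <- chainDb()
  expect_length(meshKeytypes(db), 6L)
  expect_length(meshColumns(db), 8L)
  expect_identical(meshKeytypes(db), meshKeytypes(db))
  expect_true(all(meshKeytypes(db) %in%
                    c(meshColumns(db), "MESHID", "MESHTERM")))
})

test_that("a store survives a disk round-trip with identical answers", {
  db <- chainDb()
  dir <- withr::local_tempdir()
  writeMeshDb(db, dir)
  db2 <- readMeshDb(dir)
  for (kt in list(list(101, "GENEID"), list("DY", "MESHID"),
                  list("D", "MESHCATEGORY"))) {
    a <- meshSelect(db, kt[[1]], cols = meshColumns(db), keytype = kt[[2]])
    b <- meshSelect(db2, kt[[1]], cols = meshColumns(db2), keytype = kt[[2]])
    expect_identical(a, b)
  }
  expect_identical(meshEdges(db, "AOR"), meshEdges(db2, "AOR"))
  expect_identical(meshMetadata(db), meshMetadata(db2))
})
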