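test_that("literature join produces one aggregated link per gene-term pair", {
  g2p <- data.frame(gene_id = c(1L, 1L, 2L), pubmed_id = c(11L, 12L, 11L))
  p2m <- data.frame(pubmed_id = c(11L, 12L), mesh_id = c("D1", "D1"))
  out <- joinGenePubmedMesh(g2p, p2m)
  expect_equal(out$gene_id, c(1L, 2L))
  expect_equal(out$mesh_id, c("D1", "D1"))
  expect_equal(out$pubmed_ids, c("11|12", "11"))
  expect_equal(out$source, c("gene2pubmed", "gene2pubmed"))

  expect_equal(nrow(joinGenePubmedMesh(g2p[0, ], p2m)), 0L)
  expect_equal(nrow(joinGenePubmedMesh(g2p, p2m[0, ])), 0L)
})

test_that("over-large papers are dropped before the join, threshold strict", {
  ## paper P9 tags 1001 genes, paper P2 tags 3; only P2 links survive
  g2p <- rbind(data.frame(gene_id = 1:1001, pubmed_id = 9L),
               data.frame(gene_id = 1:3, pubmed_id = 2L))
  p2m <- data.frame(pubmed_id = c(9L, 2L), mesh_id = c("D9", "D2"))
  out <- joinGenePubmedMesh(g2p, p2m)
  expect_false(any(out$mesh_id == "D9"))
  expect_equal(out$gene_id[out$mesh_id == "D2"], 1:3)

  ## exactly 1000 genes: "more than 1000" is strict, the paper is kept
  g2p2 <- data.frame(gene_id = 1:1000, pubmed_id = 7L)
  p2m2 <- data.frame(pubmed_id = 7L, mesh_id = "D7")
  expect_equal(nrow(joinGenePubmedMesh(g2p2, p2m2)), 1000L)

  ## a gene appearing only in over-large papers receives no links at all
  expect_false(any(out$gene_id > 3))
})

test_that("RBBH transfer copies, tags and unions donor links", {
  major <- data.frame(gene_id = c(7L, 7L, 8L),
                      mesh_id = c("D1", "D2", "D2"),
                      source = "gene2pubmed",
                      pubmed_ids = c("100", "200", "201"))
  pairs <- data.frame(gene_id_minor = 501L, gene_id_major = 7L)
  out <- transferByRbbh(major, pairs)
  expect_equal(out$gene_id, c(501L, 501L))
  expect_equal(out$mesh_id, c("D1", "D2"))
  expect_true(all(out$source == "RBBH"))
  expect_equal(out$pubmed_ids, c("100", "200"))

  expect_equal(nrow(transferByRbbh(major, pairs[0, ])), 0L)
  ## donor without links contributes nothing, silently
  expect_equal(nrow(transferByRbbh(major,
    data.frame(gene_id_minor = 502L, gene_id_major = 99L))), 0L)

  ## hits in two donor organisms with overlapping terms: union, no dupes,
  ## documents merged per term
  pairs2 <- data.frame(gene_id_minor = c(501L, 501L),
                       gene_id_major = c(7L, 8L))
  out2 <- transferByRbbh(major, pairs2)
  expect_equal(out2$mesh_id, c("D1", "D2"))
  expect_equal(out2$pubmed_ids[out2$mesh_id == "D2"], "200|201")
  ## never invents terms
  expect_true(all(out2$mesh_id %in% major$mesh_id))
})

test_that("custom store builder validates schemas with file and line", {
  dir <- withr::local_tempdir()
  vocab <- file.path(dir, "vocab.tsv")
  edges <- file.path(dir, "edges.tsv")
  links <- file.path(dir, "links.tsv")
  writeLines(c("mesh_id\tterm\tcategory\tqualifiers\tsynonyms",
               "D1\tAlpha\tD\tgenetics\t",
               "D2\tBeta\tD\t\t"), vocab)
  writeLines(c("parent_id\tchild_id", "D1\tD2"), edges)
  writeLines(c("gene_id\tmesh_id\tsource\tpubmed_ids",
               "101\tD2\tgendoo\t5|6"), links)
  db <- buildCustomStore(links, vocab, edges,
                         metadata = c(organism = "custom"))
  expect_s4_class(db, "MeshDb")
  expect_equal(meshSelect(db, 101, "MESHID", "GENEID")$MESHID, "D2")

  ## link to an unknown term is rejected with the offending line
  writeLines(c("gene_id\tmesh_id\tsource\tpubmed_ids",
               "101\tD2\tgendoo\t",
               "102\tD9\tgendoo\t"), links)
  expect_error(buildCustomStore(links, vocab, edges), "links.tsv:3.*D9")

  ## bad source and bad gene id report their lines too
  writeLines(c("gene_id\tmesh_id\tsource\tpubmed_ids",
               "101\tD1\tguesswork\t"), links)
  expect_error(buildCustomStore(links, vocab, edges),
               "links.tsv:2.*invalid source")
  writeLines(c("gene_id\tmesh_id\tsource\tpubmed_ids",
               "-4\tD1\tgendoo\t"), links)
  expect_error(buildCustomStore(links, vocab, edges), "positive integer")
})

test_that("a dumped store rebuilds into identical query answers", {
  spec <- fixtureSpec(nGenes = 80, nTerms = 15, seed = 5)
  voc <- makeVocabulary(spec)
  links <- makeAnnotations(spec, voc)
  db <- MeshDb(voc$terms, voc$edges, links)
  dir <- withr::local_tempdir()
  writeMeshDb(db, dir)
  db2 <- buildCustomStore(file.path(dir, "links.tsv"),
                          file.path(dir, "terms.tsv"),
                          file.path(dir, "edges_pcr.tsv"))
  genes <- unique(links$gene_id)
  a <- meshSelect(db, genes, cols = c("GENEID", "MESHID", "PUBMEDID"),
                  keytype = "GENEID")
  b <- meshSelect(db2, genes, cols = c("GENEID", "MESHID", "PUBMEDID"),
                  keytype = "GENEID")
  expect_identical(a, b)
})
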