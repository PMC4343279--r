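test_that("hypergeometric point mass: worked example, forced cases, normalization", {
  expect_equal(hypergeomPmf(10, 4, 5, 4), 1 / 42, tolerance = 1e-12)
  expect_equal(hypergeomPmf(50, 10, 0, 0), 1)
  set.seed(77)
  for (i in 1:50) {
    N <- sample(2:60, 1)
    k <- sample(1:N, 1)
    M <- sample(0:N, 1)
    xs <- max(0, k - (N - M)):min(k, M)
    expect_equal(sum(hypergeomPmf(N, k, M, xs)), 1, tolerance = 1e-12)
  }
})

test_that("count invariants are enforced with the violated bound named", {
  expect_error(hypergeomPmf(10, 4, 11, 2), "M <= N")
  expect_error(hypergeomPmf(10, 11, 5, 2), "k <= N")
  expect_error(hypergeomPmf(10, 4, 5, 5), "min\\(k, M\\)")
  expect_error(hypergeomPvalue(10, 8, 4, 1), "k - x <= N - M")
})

test_that("upper tail equals exhaustive draw enumeration and phyper", {
  expect_equal(hypergeomPvalue(10, 4, 5, 4), 1 / 42, tolerance = 1e-12)
  expect_equal(hypergeomPvalue(30, 7, 11, 0), 1)
  for (N in c(6, 9, 11)) {
    for (k in c(1, 3, N %/% 2)) {
      for (M in c(0, 2, N - 1)) {
        xs <- max(0, k - (N - M)):min(k, M)
        for (x in xs) {
          expect_equal(hypergeomPvalue(N, k, M, x),
                       exhaustiveTail(N, k, M, x), tolerance = 1e-12)
        }
      }
    }
  }
  ## independent distribution-function oracle at larger sizes
  set.seed(8)
  for (i in 1:25) {
    N <- sample(50:500, 1); k <- sample(1:N, 1); M <- sample(1:N, 1)
    x <- sample(max(0, k - (N - M)):min(k, M), 1)
    expect_equal(hypergeomPvalue(N, k, M, x),
                 phyper(x - 1, M, N - M, k, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("planted term ranks first and per-term p-values recount", {
  spec <- fixtureSpec(nGenes = 800, nTerms = 60, seed = 13)
  voc <- makeVocabulary(spec)
  links <- makeAnnotations(spec, voc)
  study <- makeStudy(spec, links)
  db <- MeshDb(voc$terms, voc$edges, links)
  catg <- voc$terms$category[voc$terms$mesh_id == study$plantedTerm]
  res <- meshHyperGTest(db, study$universe, study$selected,
                        MeshOraParams(catg, correction = "BH"))
  tab <- oraTable(res)
  expect_equal(tab$mesh_id[1], study$plantedTerm)
  expect_true(tab$significant[1])

  ## recount oracle: recompute every (N, k, M, x) from the raw link table
  slice <- links[voc$terms$category[match(links$mesh_id,
                                          voc$terms$mesh_id)] == catg, ]
  annotated <- unique(slice$gene_id)
  selAnnot <- intersect(study$selected, annotated)
  for (i in seq_len(nrow(tab))) {
    genes <- unique(slice$gene_id[slice$mesh_id == tab$mesh_id[i]])
    expect_equal(tab$N[i], length(annotated))
    expect_equal(tab$k[i], length(selAnnot))
    expect_equal(tab$M[i], length(genes))
    expect_equal(tab$x[i], length(intersect(genes, selAnnot)))
    expect_equal(tab$p_raw[i],
                 hypergeomPvalue(tab$N[i], tab$k[i], tab$M[i], tab$x[i]))
  }
  ## sorted by p then mesh_id
  expect_true(all(diff(tab$p_raw) >= 0))
})

test_that("selected = universe forces x = M and p = 1 everywhere", {
  db <- chainDb()
  res <- meshHyperGTest(db, 101:103, 101:103,
                        MeshOraParams("D", correction = "none"))
  tab <- oraTable(res)
  expect_equal(tab$x, tab$M)
  expect_true(all(tab$p_raw == 1))
  expect_false(any(tab$significant))
})

test_that("no annotated selected gene yields an explicit empty outcome", {
  db <- chainDb()
  res <- meshHyperGTest(db, c(101:103, 900:905), 900:903,
                        MeshOraParams("D"))
  expect_true(nothingTestable(res))
  expect_equal(nrow(oraTable(res)), 0L)
  expect_error(meshHyperGTest(db, 101:103, 104L, MeshOraParams("D")),
               "subset of the universe")
})

test_that("tag-cloud weights are -log10 p", {
  expect_equal(termWeights(c(a = 0.01)), c(a = 2))
  expect_equal(termWeights(c(a = 1)), c(a = 0))
  p <- c(a = 0.2, b = 0.02, c = 0.002)
  expect_true(all(diff(termWeights(p)) > 0))
  expect_error(termWeights(c(a = 0)), "strictly positive")
})

test_that("reports round-trip byte-identically in TSV and losslessly in JSON", {
  spec <- fixtureSpec(nGenes = 300, nTerms = 30, seed = 17)
  voc <- makeVocabulary(spec)
  links <- makeAnnotations(spec, voc)
  study <- makeStudy(spec, links)
  db <- MeshDb(voc$terms, voc$edges, links)
  catg <- voc$terms$category[voc$terms$mesh_id == study$plantedTerm]
  res <- meshHyperGTest(db, study$universe, study$selected,
                        MeshOraParams(catg, correction = "BH"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeOraReport(res, f1, "tsv")
  tab <- readOraReport(f1, "tsv")
  writeOraReport(tab, f2, "tsv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  fj <- withr::local_tempfile(fileext = ".json")
  writeOraReport(res, fj, "json")
  expect_equal(readOraReport(fj, "json"), oraTable(res))

  ## empty result: header-only file with the fixed column order
  empty <- meshHyperGTest(chainDb(), c(101:103, 900L), 900L,
                          MeshOraParams("D"))
  fe <- withr::local_tempfile(fileext = ".tsv")
  writeOraReport(empty, fe, "tsv")
  lines <- readLines(fe)
  expect_length(lines, 1L)
  expect_equal(strsplit(lines, "\t")[[1]][1:3],
               c("mesh_id", "term", "category"))
})
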