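test_that("BH worked example and edge cases", {
  bh <- bhAdjust(c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_equal(adjustedValues(bh), rep(0.05, 5), tolerance = 1e-12)
  ## strict rule: nothing rejected at alpha = 0.05, everything at 0.06
  expect_false(any(rejected(bhAdjust(c(0.01, 0.02, 0.03, 0.04, 0.05),
                                     alpha = 0.05))))
  expect_true(all(rejected(bhAdjust(c(0.01, 0.02, 0.03, 0.04, 0.05),
                                    alpha = 0.06))))
  expect_equal(adjustedValues(bhAdjust(0.031)), 0.031)
  allOne <- bhAdjust(rep(1, 10), alpha = 0.99)
  expect_true(all(adjustedValues(allOne) == 1))
  expect_false(any(rejected(allOne)))
  expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH agrees with the stats::p.adjust reference on random vectors", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(3:400, 1))
    expect_equal(adjustedValues(bhAdjust(p)), p.adjust(p, "BH"),
                 tolerance = 1e-14)
  }
})

test_that("adjustment is permutation-equivariant", {
  set.seed(12)
  p <- runif(200)
  perm <- sample(200)
  expect_equal(adjustedValues(bhAdjust(p))[perm],
               adjustedValues(bhAdjust(p[perm])))
  expect_equal(adjustedValues(qvalueAdjust(p, pi0 = 0.7))[perm],
               adjustedValues(qvalueAdjust(p[perm], pi0 = 0.7)))
})

test_that("pi0 estimation behaves under null, signal and degenerate input", {
  mix <- makePvalueMixture(10000, 1, seed = 101)
  est <- estimatePi0(mix$p)
  expect_gte(est$pi0, 0.9)
  expect_lte(est$pi0, 1)

  strong <- estimatePi0(rbeta(1000, 0.02, 1) * 0.0009 + 1e-7)
  expect_lte(strong$pi0, 0.2)
  expect_gt(strong$pi0, 0)

  expect_equal(estimatePi0(runif(10))$pi0, 1)  # small-m fallback
  expect_warning(est2 <- estimatePi0(rep(0.5, 50)), "degenerate")
  expect_equal(est2$pi0, 1)

  set.seed(3)
  for (pi0 in c(0.5, 0.8)) {
    m <- makePvalueMixture(5000, pi0, seed = 7 + round(100 * pi0))
    expect_lte(estimatePi0(m$p)$pi0, 1)
  }
})

test_that("q-values scale BH by pi0 and never exceed it", {
  set.seed(19)
  for (i in 1:10) {
    p <- runif(sample(30:300, 1))
    expect_equal(adjustedValues(qvalueAdjust(p, pi0 = 1)),
                 adjustedValues(bhAdjust(p)))
    q <- adjustedValues(qvalueAdjust(p))
    expect_true(all(q <= adjustedValues(bhAdjust(p)) + 1e-15))
  }
})

test_that("local FDR approaches 1 under the null and separates mixtures", {
  mix <- makePvalueMixture(5000, 1, seed = 23)
  lf <- localFdr(mix$p)
  expect_true(all(adjustedValues(lf) <= 1))
  expect_gte(median(adjustedValues(lf)), 0.85)

  mixed <- makePvalueMixture(2000, 0.8, altShape = 0.1, seed = 29)
  lf2 <- adjustedValues(localFdr(mixed$p))
  expect_gt(mean(lf2[mixed$is_null]), mean(lf2[!mixed$is_null]))

  expect_error(localFdr(runif(10)), "at least 20")
})

test_that("all methods are no-ops on the all-ones regime", {
  p <- rep(1, 30)
  expect_false(any(rejected(bhAdjust(p, alpha = 0.9))))
  expect_false(any(rejected(qvalueAdjust(p, alpha = 0.9, pi0 = 1))))
  suppressWarnings({
    lf <- localFdr(c(rep(1, 29), 0.999), alpha = 0.9)
  })
  expect_false(any(rejected(lf)))
})

test_that("BH controls the false discovery proportion in simulation", {
  ## 60 replicates at m = 400 keeps the unit run fast; the acceptance
  ## suite runs the full 200 x 1000 condition
  fdps <- vapply(1:60, function(r) {
    mix <- makePvalueMixture(400, 0.8, altShape = 0.1, seed = 1000 + r)
    rej <- rejected(bhAdjust(mix$p, alpha = 0.05))
    if (!any(rej)) 0 else sum(rej & mix$is_null) / sum(rej)
  }, numeric(1))
  se <- sd(fdps) / sqrt(length(fdps))
  expect_lte(mean(fdps), 0.05 + 3 * se)
})

test_that("diagnostics summarise the p-value distribution", {
  mix <- makePvalueMixture(2000, 1, seed = 31)
  d <- pvalueDiagnostics(mix$p)
  expect_length(d$decile_counts, 10L)
  expect_equal(sum(d$decile_counts), 2000L)
  expect_true(d$looks_uniform)
  d2 <- pvalueDiagnostics(rep(0.001, 500))
  expect_gt(d2$ks_distance, 0.99)
  expect_false(d2$looks_uniform)
})

test_that("p-value and adjusted tables travel as TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  mix <- makePvalueMixture(50, 0.9, seed = 37)
  ids <- sprintf("h%03d", 1:50)
  writePvalues(ids, mix$p, f)
  back <- readPvalues(f)
  expect_equal(back$p, mix$p)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeAdjusted(ids, mix$p, bhAdjust(mix$p), f2)
  adj <- read.delim(f2)
  expect_equal(names(adj), c("id", "p", "method", "adjusted", "reject"))
  expect_equal(adj$adjusted, adjustedValues(bhAdjust(mix$p)))
})
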