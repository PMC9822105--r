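test_that("per-protein F1 reproduces all worked-example cells to 3 decimals", {
  tab <- caseStudyCounts()
  for (i in seq_len(nrow(tab))) {
    f1 <- f1FromCounts(tab$tp[i], tab$fp[i], tab$truth[i])
    # agreement to the printed 3-decimal precision (half-ulp at the boundary)
    expect_lte(abs(f1 - tab$f1[i]), 5.0001e-4,
               label = paste(tab$method[i], tab$protein[i], "F1 deviation"))
  }
})

test_that("per-protein F1 handles identity, disjoint and degenerate sets", {
  expect_equal(proteinF1(c("a", "b"), c("a", "b")), 1)
  expect_equal(proteinF1(c("a", "b"), c("c", "d")), 0)
  expect_equal(proteinF1(character(0), c("a")), 0)
  expect_error(proteinF1(c("a"), character(0)), "truth")
})

test_that("functional similarity matches set-arithmetic oracles", {
  cfg <- similarityConfig("f1")
  expect_equal(functionalSimilarity(c("x", "y", "z"), c("y", "z", "u", "v"), cfg),
               4 / 7)
  for (metric in c("f1", "jaccard", "weighted_f1", "weighted_jaccard")) {
    ic <- c(x = 3, y = 1)
    c2 <- similarityConfig(metric, icWeights = ic)
    expect_equal(functionalSimilarity(c("x", "y"), c("x", "y"), c2), 1)
  }
  jc <- similarityConfig("jaccard")
  expect_equal(functionalSimilarity(c("x", "y"), "y", jc), 1 / 2)
  wj <- similarityConfig("weighted_jaccard", icWeights = c(x = 3, y = 1))
  expect_equal(functionalSimilarity(c("x", "y"), "y", wj), 1 / 4)
  expect_equal(functionalSimilarity(character(0), character(0), cfg), 0)
  expect_error(similarityConfig("weighted_f1"), "icWeights")
})

test_that("functional similarity is symmetric and bounded on random sets", {
  set.seed(33)
  universe <- sprintf("t%02d", 1:20)
  ic <- setNames(runif(20, 0.1, 5), universe)
  cfgs <- list(similarityConfig("f1"), similarityConfig("jaccard"),
               similarityConfig("weighted_f1", icWeights = ic),
               similarityConfig("weighted_jaccard", icWeights = ic))
  for (rep in 1:25) {
    a <- sample(universe, sample(1:8, 1))
    b <- sample(universe, sample(1:8, 1))
    for (cfg in cfgs) {
      s <- functionalSimilarity(a, b, cfg)
      expect_equal(s, functionalSimilarity(b, a, cfg))
      expect_gte(s, 0); expect_lte(s, 1)
      if (s == 1) expect_setequal(a, b)
      if (setequal(a, b)) expect_equal(s, 1)
    }
  }
})

test_that("same-function uses a strict cutoff", {
  cfg <- similarityConfig("f1", cutoff = 0.5)
  expect_true(sameFunction(c("x", "y", "z"), c("y", "z", "u", "v"), cfg)) # 4/7
  half <- similarityConfig("f1", cutoff = 0.5)
  expect_false(sameFunction(c("x", "y"), c("y", "z"), half))  # exactly 0.5
  zero <- similarityConfig("f1", cutoff = 0)
  expect_true(sameFunction(c("x"), c("x", "y"), zero))
})

test_that("Fmax sweep finds the optimal cutoff on a hand fixture", {
  s <- GOScoreMatrix(list(P1 = c(a = 0.9, b = 0.4, c = 0.3)), aspect = "BP")
  truth <- GOAnnotationSet(list(P1 = c("a", "b")), aspect = "BP",
                           propagated = TRUE)
  for (mode in c("micro", "cafa")) {
    sw <- fmaxSweep(s, truth, mode = mode, exact = TRUE)
    expect_equal(sw$fmax, 1)
    expect_equal(sw$tmax, 0.4)
  }
  # perfect scores
  perf <- GOScoreMatrix(list(P1 = c(a = 1, b = 1)), aspect = "BP")
  expect_equal(fmaxSweep(perf, truth)$fmax, 1)
  expect_error(fmaxSweep(s, GOAnnotationSet(list(P1 = character(0)),
                                            aspect = "BP", propagated = TRUE)),
               "truth")
})

test_that("micro Fmax equals the brute-force all-thresholds oracle", {
  set.seed(17)
  terms <- sprintf("t%02d", 1:12)
  for (rep in 1:8) {
    scores <- lapply(1:10, function(i) {
      k <- sample(3:8, 1)
      setNames(round(runif(k), 2), sample(terms, k))
    })
    names(scores) <- sprintf("P%02d", 1:10)
    truth <- lapply(1:10, function(i) sample(terms, sample(2:5, 1)))
    names(truth) <- names(scores)
    sw <- fmaxSweep(GOScoreMatrix(scores, aspect = "BP"),
                    GOAnnotationSet(truth, aspect = "BP", propagated = TRUE),
                    mode = "micro", exact = TRUE)
    oracle <- fmaxMicroOracle(scores, truth)
    expect_equal(sw$fmax, oracle$fmax)
  }
})

test_that("Fmax with an exact sweep is invariant to monotone score transforms", {
  set.seed(55)
  terms <- sprintf("t%02d", 1:10)
  scores <- lapply(1:6, function(i) setNames(runif(6), sample(terms, 6)))
  names(scores) <- sprintf("P%d", 1:6)
  truth <- lapply(1:6, function(i) sample(terms, 3))
  names(truth) <- names(scores)
  tr <- GOAnnotationSet(truth, aspect = "BP", propagated = TRUE)
  f1 <- fmaxSweep(GOScoreMatrix(scores, aspect = "BP"), tr, exact = TRUE)$fmax
  squashed <- lapply(scores, function(s) s ^ 3)  # strictly monotone
  f2 <- fmaxSweep(GOScoreMatrix(squashed, aspect = "BP"), tr, exact = TRUE)$fmax
  expect_equal(f1, f2)
})

test_that("micro Fmax on one protein at a threshold equals per-protein F1", {
  set.seed(71)
  terms <- sprintf("t%02d", 1:10)
  s <- setNames(runif(8), sample(terms, 8))
  truth <- sample(terms, 4)
  sw <- fmaxSweep(GOScoreMatrix(list(P1 = s), aspect = "BP"),
                  GOAnnotationSet(list(P1 = truth), aspect = "BP",
                                  propagated = TRUE),
                  mode = "micro", exact = TRUE)
  expect_equal(sw$fmax, proteinF1(names(s)[s >= sw$tmax], truth))
})

test_that("AUPR and AUROC behave on perfect and hand-integrated rankings", {
  truth <- GOAnnotationSet(list(P1 = c("a", "b")), aspect = "BP",
                           propagated = TRUE)
  perf <- GOScoreMatrix(list(P1 = c(a = 1, b = 1, c = 0.2)), aspect = "BP")
  sw <- fmaxSweep(perf, truth, mode = "micro", exact = TRUE)
  expect_equal(aupr(sw$curve), 1)
  expect_equal(auroc(perf, truth), 1)

  # 5-point toy ranking, hand-integrated step function:
  # scores a=.9 b=.7 c=.5 d=.3 e=.1, truth {a, c}
  s <- GOScoreMatrix(list(P1 = c(a = .9, b = .7, c = .5, d = .3, e = .1)),
                     aspect = "BP")
  tr <- GOAnnotationSet(list(P1 = c("a", "c")), aspect = "BP",
                        propagated = TRUE)
  sw <- fmaxSweep(s, tr, mode = "micro", exact = TRUE)
  # steps: rc 0->1/2 at pr 1 (t=.9), rc 1/2->1 at pr 2/3 (t=.5)
  expect_equal(aupr(sw$curve), 0.5 * 1 + 0.5 * (2 / 3))
  # AUROC: positives ranked 1st and 3rd of 5 -> U = 5/6
  expect_equal(auroc(s, tr), 5 / 6)
  expect_error(aupr(sw$curve[1, , drop = FALSE]), "two")
})

test_that("coverage counts proteins with any nonzero score", {
  m <- matrix(c(0.5, 0, 0, 0), 2, 2,
              dimnames = list(c("P1", "P2"), c("a", "b")))
  s <- GOScoreMatrix(m, aspect = "BP")
  expect_equal(coverageScore(s), 0.5)
  expect_equal(coverageScore(s, proteins = c("P1", "P2", "P3", "P4")), 0.25)
  expect_equal(coverageScore(GOScoreMatrix(m * 0 + 0.2, aspect = "BP")), 1)
})

test_that("ICW-Fmax reduces to Fmax under equal IC and matches the IC-sum oracle", {
  set.seed(91)
  terms <- sprintf("t%02d", 1:8)
  scores <- lapply(1:5, function(i) setNames(runif(6), sample(terms, 6)))
  names(scores) <- sprintf("P%d", 1:5)
  truth <- lapply(1:5, function(i) sample(terms, 3))
  names(truth) <- names(scores)
  sm <- GOScoreMatrix(scores, aspect = "BP")
  tr <- GOAnnotationSet(truth, aspect = "BP", propagated = TRUE)
  icEq <- setNames(rep(2, 8), terms)
  attr(icEq, "ceiling") <- 2
  expect_equal(icwFmax(sm, tr, icEq, mode = "micro", exact = TRUE)$fmax,
               fmaxSweep(sm, tr, mode = "micro", exact = TRUE)$fmax)

  # one high-IC term dominates: hand threshold-sweep oracle on a tiny case
  ic <- c(a = 10, b = 1, c = 1)
  attr(ic, "ceiling") <- 10
  s1 <- GOScoreMatrix(list(P1 = c(a = 0.9, b = 0.2)), aspect = "BP")
  t1 <- GOAnnotationSet(list(P1 = c("a", "c")), aspect = "BP",
                        propagated = TRUE)
  got <- icwFmax(s1, t1, ic, mode = "micro", exact = TRUE)
  # at t=0.9: pred {a}: tp=10, fp=0, fn=1 -> pr=1, rc=10/11, F=20/21
  expect_equal(got$fmax, 20 / 21)
  expect_equal(got$tmax, 0.9)

  icZero <- c(a = 0, c = 0)
  attr(icZero, "ceiling") <- 0
  expect_error(suppressWarnings(icwFmax(s1, t1, icZero)), "zero")
})

test_that("Friedman/Nemenyi detect dominance and match the closed form", {
  # no difference among methods: perfectly balanced within-protein ranks
  # (cyclic Latin-square rows) give a zero statistic and p = 1
  m <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
             c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)) / 10
  res0 <- friedmanNemenyi(m)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  expect_true(all(res0$pairwise >= 0.9, na.rm = TRUE))

  # one strictly dominant method over 20 proteins, 3 methods
  set.seed(13)
  base <- matrix(runif(60, 0.2, 0.6), 20, 3)
  base[, 1] <- base[, 1] + 0.5
  res <- friedmanNemenyi(base)
  expect_lt(res$p.value, 0.05)
  expect_lt(res$pairwise[1, 2], 0.05)

  # permutation oracle on the Friedman rank statistic
  permStat <- function(mm) {
    R <- colMeans(t(apply(mm, 1, rank)))
    n <- nrow(mm); k <- ncol(mm)
    12 * n / (k * (k + 1)) * sum((R - (k + 1) / 2) ^ 2)
  }
  obs <- permStat(base)
  set.seed(14)
  perm <- replicate(400, permStat(t(apply(base, 1, sample))))
  expect_lt(mean(perm >= obs), 0.05)

  # tie-free toy matrix vs the textbook chi-square formula
  toy <- matrix(c(1, 2, 3, 2, 3, 1, 3, 1, 2, 1, 3, 2), 4, 3, byrow = TRUE)
  toy <- toy / 10 + matrix(seq(0, 0.011, by = 0.001), 4, 3) * 0
  expect_equal(friedmanNemenyi(toy)$statistic, permStat(toy))

  expect_error(friedmanNemenyi(matrix(1, 5, 3)), "constant|degenerate")
  expect_error(friedmanNemenyi(matrix(runif(4), 2, 2)), "3 methods")
})

test_that("repeated-run comparison against a fixed competitor value works", {
  set.seed(2)
  runs <- rnorm(10, mean = 0.62, sd = 0.005)
  ht <- compareRunsToFixed(runs, 0.55)
  expect_lt(ht$p.value, 1e-6)
})

test_that("evaluation report writer mirrors the benchmark-table layout", {
  s <- GOScoreMatrix(list(P1 = c(a = 0.9, b = 0.4), P2 = c(a = 0.8)),
                     aspect = "BP")
  tr <- GOAnnotationSet(list(P1 = c("a", "b"), P2 = "a"), aspect = "BP",
                        propagated = TRUE)
  ic <- c(a = 1, b = 2); attr(ic, "ceiling") <- 3
  ev <- evaluateScores(s, tr, ic = ic)
  path <- tempfile(fileext = ".tsv")
  df <- writeEvaluationReport(list(model = ev), path)
  expect_true(file.exists(path))
  expect_named(df, c("method", "aspect", "fmax", "t_star", "aupr", "auroc",
                     "coverage", "icw_fmax"))
  expect_equal(df$fmax, 1)
  expect_equal(df$coverage, 1)
})
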