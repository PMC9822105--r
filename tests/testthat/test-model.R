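test_that("mean pooling is the arithmetic column mean", {
  expect_equal(meanPool(matrix(1:4, 1)), c(1, 2, 3, 4))
  expect_equal(meanPool(rbind(rep(0, 3), rep(2, 3))), rep(1, 3))
  set.seed(1)
  m <- matrix(rnorm(40), 5, 8)
  expect_equal(meanPool(m), colSums(m) / 5)
  expect_error(meanPool(matrix(numeric(0), 0, 3)), "empty")
})

test_that("forward pass reduces to known closed forms", {
  # identity-weighted single-view degenerate config: embedding == input
  cfg <- trainingConfig(N1 = 3, N2 = 3, activation = "identity")
  model <- tripletModel(D = 3, terms = c("q1", "q2"), nViews = 1, config = cfg)
  model@weights$Wv[[1]] <- diag(3)
  model@weights$Wa <- diag(3)
  model@weights$Wo <- matrix(0, 3, 2)
  X <- matrix(c(0.3, -1, 2), 1, dimnames = list("P1", NULL))
  out <- fusedEmbedding(model, EmbeddingBundle(list(X)))
  expect_equal(unname(out$embedding[1, ]), c(0.3, -1, 2))

  # fixed small weights on a 2-term toy: hand-computed sigmoid
  model@weights$Wo <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2)
  model@weights$bo <- c(0.5, -0.5)
  out <- fusedEmbedding(model, EmbeddingBundle(list(X)))
  expect_equal(unname(out$ssaf[1, ]),
               1 / (1 + exp(-c(0.3 + 0.5, -1 - 0.5))))

  # sigmoid range holds for random weights/inputs
  rnd <- tripletModel(D = 5, terms = letters[1:4], nViews = 3,
                      config = trainingConfig(N1 = 6, N2 = 6, seed = 3))
  Xs <- lapply(1:3, function(v) {
    m <- matrix(rnorm(10), 2, 5); rownames(m) <- c("A", "B"); m
  })
  s <- fusedEmbedding(rnd, EmbeddingBundle(Xs))$ssaf
  expect_true(all(s > 0 & s < 1))
})

test_that("forward pass rejects dimension mismatches", {
  model <- tripletModel(D = 4, terms = "q", nViews = 2,
                        config = trainingConfig(N1 = 3, N2 = 3))
  X <- matrix(0, 1, 5, dimnames = list("P1", NULL))
  expect_error(fusedEmbedding(model, EmbeddingBundle(list(X, X))), "width")
})

test_that("triplet loss matches its closed forms", {
  # place points on a line to realize exact distances
  anc <- c(0, 0)
  expect_equal(tripletLoss(anc, c(0.5, 0), c(2, 0), margin = 0.5), 0)
  expect_equal(tripletLoss(anc, c(1.2, 0), c(1.5, 0), margin = 0.5), 0.2)
  p <- c(0.7, -0.3)
  expect_equal(tripletLoss(anc, p, p, margin = 0.5), 0.5)
})

test_that("batch-hard loss equals exhaustive triplet enumeration", {
  simcfg <- similarityConfig("f1", cutoff = 0.5)
  # hand-built 4-protein batch: two functional groups
  sets <- list(A = c("x", "y"), B = c("x", "y"), C = c("u", "v"),
               D = c("u", "v"))
  emb <- rbind(A = c(0, 0), B = c(1, 0), C = c(0.5, 0.2), D = c(3, 3))
  got <- batchHardLoss(emb, sets, margin = 1, simcfg = simcfg)
  expect_equal(as.numeric(got), batchHardOracle(emb, sets, 1, simcfg))

  # random batches of <= 8 proteins, random embeddings and term sets
  set.seed(61)
  universe <- sprintf("t%d", 1:6)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    ids <- sprintf("P%d", 1:n)
    sets <- lapply(ids, function(i) sample(universe, sample(2:4, 1)))
    names(sets) <- ids
    emb <- matrix(rnorm(n * 3), n, dimnames = list(ids, NULL))
    oracle <- batchHardOracle(emb, sets, 1, simcfg)
    if (is.na(oracle)) next
    got <- suppressWarnings(batchHardLoss(emb, sets, 1, simcfg))
    expect_equal(as.numeric(got), oracle)
    expect_gte(as.numeric(got), 0)
  }
})

test_that("batch-hard loss is zero when every margin is satisfied and
           invariant under rigid rotation", {
  sets <- list(A = c("x"), B = c("x"), C = c("y"), D = c("y"))
  emb <- rbind(A = c(0, 0), B = c(0.1, 0), C = c(10, 0), D = c(10.1, 0))
  expect_equal(as.numeric(batchHardLoss(emb, sets, margin = 1)), 0)

  set.seed(77)
  ids <- sprintf("P%d", 1:6)
  sets <- setNames(lapply(1:6, function(i) sample(c("x", "y", "z"), 2)), ids)
  emb <- matrix(rnorm(12), 6, dimnames = list(ids, NULL))
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  l1 <- suppressWarnings(batchHardLoss(emb, sets, 1))
  l2 <- suppressWarnings(batchHardLoss(emb %*% R, sets, 1))
  expect_equal(as.numeric(l1), as.numeric(l2))
})

test_that("an anchor is never its own positive", {
  # the same protein appearing twice (duplicate ID) is excluded from its
  # own positive pool; other same-function proteins still count
  emb <- rbind(c(0, 0), c(5, 0), c(1, 0), c(3, 0))
  rownames(emb) <- c("A", "A", "B", "C")
  termSets <- list(A = c("x"), B = c("x"), C = c("y"))
  got <- suppressWarnings(batchHardLoss(emb, termSets, margin = 1))
  # A@0: pos B (d=1, the duplicate A is excluded), neg C (d=3) -> 0
  # A@5: pos B (d=4), neg C (d=2) -> 3;  B@1: pos max over A's (d=4) -> 3
  # C: no positive -> skipped
  expect_equal(as.numeric(got), mean(c(0, 3, 3)))
  # with only the two copies of A there is no valid anchor at all
  expect_error(batchHardLoss(emb[1:2, ], termSets, 1), "anchor")
})

test_that("cross-entropy loss matches closed forms and the elementwise oracle", {
  y <- matrix(c(1, 0, 0, 1), 2)
  expect_lt(crossEntropyLoss(y, y), 1e-5)
  expect_equal(crossEntropyLoss(matrix(0.5, 2, 2), y), log(2))
  set.seed(5)
  s <- matrix(runif(12, 0.05, 0.95), 3, 4)
  y <- matrix(rbinom(12, 1, 0.5), 3, 4)
  expect_equal(crossEntropyLoss(s, y),
               -mean(y * log(s) + (1 - y) * log(1 - s)))
})

test_that("composite loss is triplet + alpha * cross-entropy", {
  cfg <- trainingConfig(N1 = 4, N2 = 4, seed = 2, alpha = 0.5)
  sets <- list(A = c("x", "y"), B = c("x", "y"), C = c("u", "v"),
               D = c("u", "v"))
  model <- tripletModel(D = 3, terms = c("x", "y", "u", "v"), nViews = 2,
                        config = cfg)
  set.seed(6)
  views <- lapply(1:2, function(v) {
    m <- matrix(rnorm(12), 4, 3); rownames(m) <- names(sets); m
  })
  total <- compositeLoss(model, views, sets, cfg)
  fw <- fusedEmbedding(model, EmbeddingBundle(views))
  lt <- batchHardLoss(fw$embedding, sets, cfg$margin)
  Y <- matrix(0, 4, 4, dimnames = list(names(sets), c("x", "y", "u", "v")))
  for (p in names(sets)) Y[p, sets[[p]]] <- 1
  lc <- crossEntropyLoss(fw$ssaf, Y)
  expect_equal(as.numeric(total), as.numeric(lt) + 0.5 * lc)
  expect_equal(attr(total, "triplet"), as.numeric(lt))

  cfg0 <- cfg; cfg0$alpha <- 0
  expect_equal(as.numeric(compositeLoss(model, views, sets, cfg0)),
               as.numeric(lt))
  expect_error(trainingConfig(alpha = -1), "alpha")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- trainingConfig(N1 = 4, N2 = 3, seed = 9, alpha = 0.7, margin = 0.8)
  terms <- c("x", "y", "u")
  sets <- list(A = c("x", "y"), B = c("x", "y"), C = c("u"), D = c("u"))
  model <- tripletModel(D = 3, terms = terms, nViews = 2, config = cfg)
  set.seed(10)
  views <- lapply(1:2, function(v) {
    m <- matrix(rnorm(12, sd = 0.7), 4, 3); rownames(m) <- names(sets); m
  })
  Y <- GOTriplet:::.labelMatrix(sets, terms)
  simM <- sapply(sets, function(a) sapply(sets, function(b)
    functionalSimilarity(a, b)))
  pos <- simM > 0.5; diag(pos) <- FALSE
  bg <- GOTriplet:::.batchGradients(model, views, Y, pos, names(sets), cfg)
  lossAt <- function(m) {
    GOTriplet:::.batchGradients(m, views, Y, pos, names(sets), cfg)$loss
  }
  h <- 1e-5
  for (probe in 1:12) {
    set.seed(probe)
    part <- sample(c("Wa", "Wo", "Wv1", "bv2", "ba"), 1)
    m1 <- m2 <- model
    if (part == "Wv1") {
      i <- sample(length(model@weights$Wv[[1]]), 1)
      m1@weights$Wv[[1]][i] <- m1@weights$Wv[[1]][i] + h
      m2@weights$Wv[[1]][i] <- m2@weights$Wv[[1]][i] - h
      g <- bg$grads$Wv[[1]][i]
    } else if (part == "bv2") {
      i <- sample(length(model@weights$bv[[2]]), 1)
      m1@weights$bv[[2]][i] <- m1@weights$bv[[2]][i] + h
      m2@weights$bv[[2]][i] <- m2@weights$bv[[2]][i] - h
      g <- bg$grads$bv[[2]][i]
    } else {
      i <- sample(length(model@weights[[part]]), 1)
      m1@weights[[part]][i] <- m1@weights[[part]][i] + h
      m2@weights[[part]][i] <- m2@weights[[part]][i] - h
      g <- bg$grads[[part]][i]
    }
    expect_equal(g, (lossAt(m1) - lossAt(m2)) / (2 * h), tolerance = 1e-4)
  }
})

test_that("training is seed-deterministic and reduces the composite loss", {
  w <- tinyWorld(seed = 19, nProteins = 60, nTerms = 25)
  ids <- w$splits$train
  trB <- subsetBundle(w$bundle, ids)
  trA <- subsetAnno(w$anno, ids)
  cfg <- trainingConfig(epochs = 6, N1 = 16, N2 = 16, batchSize = 16,
                        seed = 123)
  fit1 <- trainTripletModel(trB, trA, cfg)
  fit2 <- trainTripletModel(trB, trA, cfg)
  expect_identical(fit1$embeddings, fit2$embeddings)
  expect_identical(scoreMatrix(fit1$ssaf), scoreMatrix(fit2$ssaf))
  expect_lt(fit1$history$loss[nrow(fit1$history)], fit1$history$loss[1])
  expect_true(all(scoreMatrix(fit1$ssaf) > 0 & scoreMatrix(fit1$ssaf) < 1))

  # zero-epoch config returns the seeded initialization, reproducibly
  cfg0 <- trainingConfig(epochs = 0, N1 = 16, N2 = 16, seed = 123)
  f0a <- trainTripletModel(trB, trA, cfg0)
  f0b <- trainTripletModel(trB, trA, cfg0)
  expect_identical(f0a$embeddings, f0b$embeddings)
  expect_null(f0a$history)
})

test_that("training reduces batch-hard loss on clustered data", {
  w <- tinyWorld(seed = 23, nProteins = 80, signal = 1.5)
  ids <- w$splits$train
  trB <- subsetBundle(w$bundle, ids)
  trA <- subsetAnno(w$anno, ids)
  cfg <- trainingConfig(epochs = 15, N1 = 32, N2 = 32, seed = 31)
  init <- tripletModel(D = w$cfg$dim,
                       terms = sort(unique(unlist(annotations(trA)))),
                       nViews = 3, config = cfg)
  e0 <- fusedEmbedding(init, trB)$embedding
  l0 <- batchHardLoss(e0, annotations(trA), cfg$margin)
  fit <- trainTripletModel(trB, trA, cfg)
  l1 <- batchHardLoss(fit$embeddings, annotations(trA), cfg$margin)
  expect_lt(as.numeric(l1), as.numeric(l0))
  expect_lt(attr(l1, "violationRate"), attr(l0, "violationRate"))
})

test_that("ensemble averaging is the elementwise mean with aligned indices", {
  m1 <- GOScoreMatrix(list(P1 = c(a = 0.2)), aspect = "BP")
  m2 <- GOScoreMatrix(list(P1 = c(a = 0.8)), aspect = "BP")
  expect_equal(scoreMatrix(ensembleAverage(list(m1)))["P1", "a"], 0.2)
  expect_equal(scoreMatrix(ensembleAverage(list(m1, m2)))["P1", "a"], 0.5)

  set.seed(41)
  runs <- lapply(1:10, function(i) {
    m <- matrix(runif(6), 2, 3, dimnames = list(c("P1", "P2"), c("a", "b", "c")))
    GOScoreMatrix(m, aspect = "BP")
  })
  avg <- ensembleAverage(runs)
  expect_equal(scoreMatrix(avg),
               Reduce(`+`, lapply(runs, scoreMatrix)) / 10)

  bad <- GOScoreMatrix(list(P9 = c(a = 0.1)), aspect = "BP")
  expect_error(ensembleAverage(list(m1, bad)), "indices")
})

test_that("embedding views round-trip through the TSV layout", {
  w <- tinyWorld(seed = 3, nProteins = 12, dim = 5)
  dir <- tempfile()
  writeEmbeddingViews(w$bundle, dir)
  back <- readEmbeddingViews(sort(list.files(dir, full.names = TRUE)))
  expect_equal(length(embeddingViews(back)), 3)
  for (v in 1:3) {
    expect_equal(embeddingViews(back)[[v]], embeddingViews(w$bundle)[[v]],
                 tolerance = 1e-8)
  }
})
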