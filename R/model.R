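## Multi-view fusion network with a composite objective: batch-hard triplet
## loss on the fused (metric) embedding plus a sigmoid cross-entropy term on
## the output layer. Written in plain matrix code with hand-derived
## gradients and an Adam optimizer; everything is deterministic given the
## seed.

.ACTIVATIONS <- list(
  relu = list(f = function(z) pmax(z, 0), df = function(z) (z > 0) * 1),
  identity = list(f = function(z) z, df = function(z) z * 0 + 1),
  tanh = list(f = tanh, df = function(z) 1 - tanh(z) ^ 2)
)

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Column-mean pooling of a residue-level embedding matrix
#'
#' Collapses an L x D per-residue embedding (L = sequence length) to a
#' single D-vector by averaging each column, the standard pooling for
#' sequence-level downstream tasks.
#'
#' @param m numeric matrix with one row per residue.
#' @return numeric vector of length `ncol(m)`.
#' @export
meanPool <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop("cannot pool an empty embedding matrix", call. = FALSE)
  }
  colMeans(m)
}

#' Training configuration for the triplet fusion model
#'
#' Defaults: `margin = 1`, same-function cutoff `cf = 0.5`, loss balance
#' `alpha = 1`, `K = 10` guilt-by-association templates, 10-run ensembles.
#' These are tunable and are meant to be selected by maximizing Fmax on a
#' validation split.
#'
#' @param margin positive triplet margin.
#' @param cf same-function functional-similarity cutoff `c_f`.
#' @param alpha weight of the cross-entropy term in the composite loss.
#' @param K template count for guilt-by-association scoring.
#' @param seed integer seed controlling initialization and batch order.
#' @param epochs,batchSize,learningRate Adam optimization schedule.
#' @param nRuns ensemble size for repeated training runs.
#' @param N1,N2 widths of the per-view and fused hidden layers.
#' @param activation hidden-layer nonlinearity (`"relu"`, `"identity"`,
#'   `"tanh"`).
#' @param metric functional-similarity flavour for triplet supervision.
#' @return list of class `trainingConfig`.
#' @export
trainingConfig <- function(margin = 1, cf = 0.5, alpha = 1, K = 10,
                           seed = 1L, epochs = 30L, batchSize = 32L,
                           learningRate = 1e-3, nRuns = 10L,
                           N1 = 1024L, N2 = 1024L, activation = "relu",
                           metric = "f1") {
  .assertNumber(margin, "margin", lower = 1e-12)
  .assertNumber(cf, "cf", 0, 1)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (N1 < 1L || N2 < 1L) stop("N1 and N2 must be positive", call. = FALSE)
  if (!activation %in% names(.ACTIVATIONS)) {
    stop("unknown activation '", activation, "'", call. = FALSE)
  }
  structure(list(margin = margin, cf = cf, alpha = alpha, K = as.integer(K),
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, nRuns = as.integer(nRuns),
                 N1 = as.integer(N1), N2 = as.integer(N2),
                 activation = activation, metric = metric),
            class = "trainingConfig")
}

#' Initialize a TripletFusionModel
#'
#' He-style Gaussian initialization, deterministic given `seed`.
#'
#' @param D input embedding width per view.
#' @param terms ordered candidate GO term list Q scored by the output layer.
#' @param nViews number of embedding views (default 3, the last three
#'   language-model layers).
#' @param config a [trainingConfig()] (widths, activation, seed).
#' @param aspect GO aspect tag stored with the model.
#' @return A [TripletFusionModel-class].
#' @export
tripletModel <- function(D, terms, nViews = 3L, config = trainingConfig(),
                         aspect = "BP") {
  set.seed(config$seed)
  init <- function(nin, nout) {
    matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  w <- list(
    Wv = lapply(seq_len(nViews), function(v) init(D, config$N1)),
    bv = lapply(seq_len(nViews), function(v) numeric(config$N1)),
    Wa = init(nViews * config$N1, config$N2),
    ba = numeric(config$N2),
    Wo = init(config$N2, length(terms)),
    bo = numeric(length(terms))
  )
  new("TripletFusionModel", weights = w, terms = terms,
      config = list(D = D, N1 = config$N1, N2 = config$N2,
                    activation = config$activation, aspect = aspect,
                    seed = config$seed, nViews = nViews))
}

# Forward pass; keeps pre-activations for backprop when `cache = TRUE`.
.forwardFusion <- function(model, views, cache = FALSE) {
  w <- model@weights
  act <- .ACTIVATIONS[[model@config$activation]]
  nViews <- length(w$Wv)
  if (length(views) != nViews) {
    stop(sprintf("model expects %d views, got %d", nViews, length(views)),
         call. = FALSE)
  }
  Z <- H <- vector("list", nViews)
  for (v in seq_len(nViews)) {
    X <- as.matrix(views[[v]])
    if (ncol(X) != nrow(w$Wv[[v]])) {
      stop(sprintf("view %d has width %d, model expects %d",
                   v, ncol(X), nrow(w$Wv[[v]])), call. = FALSE)
    }
    Z[[v]] <- sweep(X %*% w$Wv[[v]], 2, w$bv[[v]], "+")
    H[[v]] <- act$f(Z[[v]])
  }
  C <- do.call(cbind, H)
  Za <- sweep(C %*% w$Wa, 2, w$ba, "+")
  A <- act$f(Za)
  Zo <- sweep(A %*% w$Wo, 2, w$bo, "+")
  S <- .sigmoid(Zo)
  rownames(A) <- rownames(S) <- rownames(views[[1]])
  colnames(S) <- model@terms
  out <- list(embedding = A, ssaf = S)
  if (cache) out <- c(out, list(Z = Z, H = H, C = C, Za = Za))
  out
}

#' Forward pass of the fusion network
#'
#' Maps each pooled view through its dense layer, concatenates, applies the
#' fused layer FCLa (whose output is the metric embedding) and the sigmoid
#' output layer FCLo (per-term confidence scores in (0, 1)). Deterministic
#' given the weights.
#'
#' @param model a [TripletFusionModel-class].
#' @param bundle an [EmbeddingBundle-class] (one pooled matrix per view).
#' @return list with `embedding` (proteins x N2) and `ssaf` (proteins x |Q|,
#'   values in (0, 1)).
#' @export
fusedEmbedding <- function(model, bundle) {
  stopifnot(is(model, "TripletFusionModel"), is(bundle, "EmbeddingBundle"))
  .forwardFusion(model, embeddingViews(bundle))
}

#' Triplet loss for a single (anchor, positive, negative) triple
#'
#' `max(d(anc, pos) + margin - d(anc, neg), 0)` with `d` the Euclidean
#' distance: zero exactly when the negative is at least `margin` farther
#' from the anchor than the positive.
#'
#' @param anchor,pos,neg numeric embedding vectors of equal length.
#' @param margin positive margin.
#' @return nonnegative loss.
#' @export
tripletLoss <- function(anchor, pos, neg, margin = 1) {
  d <- function(a, b) sqrt(sum((a - b) ^ 2))
  max(d(anchor, pos) + margin - d(anchor, neg), 0)
}

.pairwiseDist <- function(A) {
  as.matrix(stats::dist(A))
}

# Shared batch-hard machinery: per-anchor hinge terms, hardest positive and
# hardest negative indices. `posMask[i, j]` = same function; self (by ID)
# excluded from both pools.
.batchHardTerms <- function(D, posMask, ids, margin) {
  n <- nrow(D)
  sameId <- outer(ids, ids, "==")
  loss <- rep(NA_real_, n)
  iPos <- iNeg <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pos <- which(posMask[i, ] & !sameId[i, ])
    neg <- which(!posMask[i, ] & !sameId[i, ])
    if (!length(pos) || !length(neg)) next
    p <- pos[which.max(D[i, pos])]
    q <- neg[which.min(D[i, neg])]
    loss[i] <- max(D[i, p] + margin - D[i, q], 0)
    iPos[i] <- p
    iNeg[i] <- q
  }
  list(loss = loss, iPos = iPos, iNeg = iNeg)
}

#' Batch-hard triplet loss over a batch of embeddings
#'
#' For every anchor in the batch, uses its hardest positive (the
#' same-function protein at maximum Euclidean distance) and hardest negative
#' (the different-function protein at minimum distance) and averages the
#' hinge `max(d_pos_max + margin - d_neg_min, 0)` over anchors. Positives
#' and negatives are decided by [sameFunction()] at the cutoff in `simcfg`;
#' an anchor is never its own positive (proteins are compared by ID).
#' Anchors lacking a positive or a negative are skipped with a warning; a
#' batch with no valid anchor is an error.
#'
#' @param embeddings numeric matrix (batch x N2) with protein-ID rownames.
#' @param termSets named list of propagated term sets, one per row.
#' @param margin positive margin.
#' @param simcfg a [similarityConfig()] (metric + cutoff `c_f`).
#' @return mean hinge loss, with attribute `violationRate` (fraction of
#'   valid anchors with a positive hinge).
#' @export
batchHardLoss <- function(embeddings, termSets, margin = 1,
                          simcfg = similarityConfig()) {
  ids <- rownames(embeddings)
  if (is.null(ids)) stop("embeddings need protein-ID rownames", call. = FALSE)
  sets <- termSets[ids]
  n <- length(ids)
  posMask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) posMask[i, j] <- sameFunction(sets[[i]], sets[[j]], simcfg)
    }
  }
  D <- .pairwiseDist(embeddings)
  bh <- .batchHardTerms(D, posMask, ids, margin)
  valid <- !is.na(bh$loss)
  if (!any(valid)) {
    stop("no anchor with both a positive and a negative in the batch",
         call. = FALSE)
  }
  if (any(!valid)) {
    warning(sprintf("skipped %d anchor(s) without a positive or a negative",
                    sum(!valid)), call. = FALSE)
  }
  out <- mean(bh$loss[valid])
  attr(out, "violationRate") <- mean(bh$loss[valid] > 0)
  out
}

#' Fraction of anchors violating the triplet margin
#'
#' @inheritParams batchHardLoss
#' @return proportion of valid anchors whose batch-hard hinge is positive.
#' @export
marginViolationRate <- function(embeddings, termSets, margin = 1,
                                simcfg = similarityConfig()) {
  l <- suppressWarnings(batchHardLoss(embeddings, termSets, margin, simcfg))
  attr(l, "violationRate")
}

#' Binary cross-entropy loss on sigmoid confidence scores
#'
#' Mean over proteins and terms of `-[y log s + (1 - y) log(1 - s)]`
#' (natural log); scores are clamped to `[eps, 1 - eps]`.
#'
#' @param ssaf numeric matrix of scores in (0, 1).
#' @param y 0/1 matrix of propagated truth labels, same shape.
#' @param eps clamp distance from 0 and 1.
#' @return nonnegative loss.
#' @export
crossEntropyLoss <- function(ssaf, y, eps = 1e-7) {
  s <- pmin(pmax(ssaf, eps), 1 - eps)
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

#' Composite training loss: triplet + alpha * cross-entropy
#'
#' Runs the forward pass on a batch and combines [batchHardLoss()] on the
#' fused embedding with [crossEntropyLoss()] on the output scores.
#'
#' @param model a [TripletFusionModel-class].
#' @param views list of view matrices for the batch (rows = proteins).
#' @param termSets named list of propagated truth term sets.
#' @param config a [trainingConfig()].
#' @param simcfg a [similarityConfig()]; defaults to `config`'s metric and
#'   cutoff.
#' @return the composite loss with attributes `triplet` and `crossEntropy`.
#' @export
compositeLoss <- function(model, views, termSets, config = trainingConfig(),
                          simcfg = NULL) {
  if (config$alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (is.null(simcfg)) {
    simcfg <- similarityConfig(config$metric, cutoff = config$cf)
  }
  fw <- .forwardFusion(model, views)
  Y <- .labelMatrix(termSets[rownames(fw$ssaf)], model@terms)
  lt <- suppressWarnings(
    batchHardLoss(fw$embedding, termSets, config$margin, simcfg))
  lc <- crossEntropyLoss(fw$ssaf, Y)
  out <- as.numeric(lt) + config$alpha * lc
  attr(out, "triplet") <- as.numeric(lt)
  attr(out, "crossEntropy") <- lc
  out
}

.labelMatrix <- function(termSets, terms) {
  Y <- matrix(0, length(termSets), length(terms),
              dimnames = list(names(termSets), terms))
  for (p in names(termSets)) {
    hit <- intersect(termSets[[p]], terms)
    Y[p, hit] <- 1
  }
  Y
}

# Gradient of the batch-mean batch-hard loss w.r.t. the embedding matrix.
.batchHardGrad <- function(A, posMask, ids, margin) {
  D <- .pairwiseDist(A)
  bh <- .batchHardTerms(D, posMask, ids, margin)
  valid <- which(!is.na(bh$loss))
  G <- matrix(0, nrow(A), ncol(A))
  if (!length(valid)) return(list(grad = G, loss = 0, nValid = 0L))
  V <- length(valid)
  for (i in valid) {
    if (bh$loss[i] <= 0) next
    p <- bh$iPos[i]; q <- bh$iNeg[i]
    dip <- max(D[i, p], 1e-12); diq <- max(D[i, q], 1e-12)
    up <- (A[i, ] - A[p, ]) / dip
    uq <- (A[i, ] - A[q, ]) / diq
    G[i, ] <- G[i, ] + (up - uq) / V
    G[p, ] <- G[p, ] - up / V
    G[q, ] <- G[q, ] + uq / V
  }
  list(grad = G, loss = mean(bh$loss[valid]), nValid = V)
}

.adamInit <- function(w) {
  flat <- list(m = rapply(w, function(x) x * 0, how = "replace"),
               v = rapply(w, function(x) x * 0, how = "replace"),
               t = 0L)
  flat
}

.adamStep <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(wpart, gpart, mpart, vpart) {
    m <- beta1 * mpart + (1 - beta1) * gpart
    v <- beta2 * vpart + (1 - beta2) * gpart ^ 2
    mhat <- m / (1 - beta1 ^ state$t)
    vhat <- v / (1 - beta2 ^ state$t)
    list(w = wpart - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (nm in c("Wa", "ba", "Wo", "bo")) {
    r <- upd(w[[nm]], g[[nm]], state$m[[nm]], state$v[[nm]])
    w[[nm]] <- r$w; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  for (v in seq_along(w$Wv)) {
    r <- upd(w$Wv[[v]], g$Wv[[v]], state$m$Wv[[v]], state$v$Wv[[v]])
    w$Wv[[v]] <- r$w; state$m$Wv[[v]] <- r$m; state$v$Wv[[v]] <- r$v
    r <- upd(w$bv[[v]], g$bv[[v]], state$m$bv[[v]], state$v$bv[[v]])
    w$bv[[v]] <- r$w; state$m$bv[[v]] <- r$m; state$v$bv[[v]] <- r$v
  }
  list(w = w, state = state)
}

# Full backward pass for one batch; returns gradients and the batch loss.
.batchGradients <- function(model, views, Y, posMask, ids, config) {
  fw <- .forwardFusion(model, views, cache = TRUE)
  w <- model@weights
  act <- .ACTIVATIONS[[model@config$activation]]
  n <- nrow(fw$embedding); nQ <- ncol(fw$ssaf)
  # cross-entropy head
  dZo <- config$alpha * (fw$ssaf - Y) / (n * nQ)
  gWo <- t(fw$embedding) %*% dZo
  gbo <- colSums(dZo)
  dA <- dZo %*% t(w$Wo)
  # triplet on the fused embedding
  bh <- .batchHardGrad(fw$embedding, posMask, ids, config$margin)
  dA <- dA + bh$grad
  dZa <- dA * act$df(fw$Za)
  gWa <- t(fw$C) %*% dZa
  gba <- colSums(dZa)
  dC <- dZa %*% t(w$Wa)
  nViews <- length(w$Wv)
  N1 <- ncol(fw$H[[1]])
  gWv <- gbv <- vector("list", nViews)
  for (v in seq_len(nViews)) {
    idx <- ((v - 1L) * N1 + 1L):(v * N1)
    dZv <- dC[, idx, drop = FALSE] * act$df(fw$Z[[v]])
    gWv[[v]] <- t(as.matrix(views[[v]])) %*% dZv
    gbv[[v]] <- colSums(dZv)
  }
  eps <- 1e-7
  sClamp <- pmin(pmax(fw$ssaf, eps), 1 - eps)
  lce <- -mean(Y * log(sClamp) + (1 - Y) * log(1 - sClamp))
  list(grads = list(Wv = gWv, bv = gbv, Wa = gWa, ba = gba, Wo = gWo,
                    bo = gbo),
       loss = bh$loss + config$alpha * lce,
       triplet = bh$loss, crossEntropy = lce, nValid = bh$nValid)
}

#' Train the triplet fusion model
#'
#' Minimizes the composite loss (batch-hard triplet + alpha * cross-entropy)
#' with Adam over shuffled mini-batches. Positives/negatives are decided
#' once from the pairwise functional-similarity matrix of the training
#' annotations at cutoff `c_f`. Deterministic given `config$seed`.
#'
#' @param bundle training [EmbeddingBundle-class] (pooled views).
#' @param anno propagated training [GOAnnotationSet-class]; the candidate
#'   term set Q defaults to every annotated term.
#' @param config a [trainingConfig()].
#' @param terms optional explicit candidate term list Q.
#' @param validation optional list(bundle=, truth=) whose Fmax (on the
#'   output-layer scores) is recorded per epoch.
#' @return list of class `tripletFit`: `model`, `embeddings` (all training
#'   proteins), `ssaf` ([GOScoreMatrix-class]), `history` (per-epoch loss
#'   components and optional validation Fmax), `config`.
#' @export
trainTripletModel <- function(bundle, anno, config = trainingConfig(),
                              terms = NULL, validation = NULL) {
  stopifnot(is(bundle, "EmbeddingBundle"), is(anno, "GOAnnotationSet"))
  if (!isPropagated(anno)) {
    stop("training annotations must be propagated", call. = FALSE)
  }
  ids <- intersect(proteinIds(bundle), proteinIds(anno))
  if (!length(ids)) stop("no protein shared by bundle and annotations",
                         call. = FALSE)
  views <- lapply(embeddingViews(bundle), function(m) m[ids, , drop = FALSE])
  sets <- annotations(anno)[ids]
  if (is.null(terms)) terms <- sort(unique(unlist(sets, use.names = FALSE)))
  simcfg <- similarityConfig(config$metric, cutoff = config$cf)
  set.seed(config$seed)
  model <- tripletModel(D = ncol(views[[1]]), terms = terms,
                        nViews = length(views), config = config,
                        aspect = goAspect(anno))
  Yall <- .labelMatrix(sets, terms)
  simM <- similarityMatrix(GOAnnotationSet(sets, aspect = goAspect(anno),
                                           propagated = TRUE), simcfg)
  posAll <- simM > simcfg$cutoff
  diag(posAll) <- FALSE
  set.seed(.deriveSeed(config$seed, 7L))
  state <- .adamInit(model@weights)
  n <- length(ids)
  history <- NULL
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    starts <- seq(1L, n, by = config$batchSize)
    eLoss <- eTrip <- eCe <- 0; nb <- 0L
    for (s in starts) {
      sel <- ord[s:min(s + config$batchSize - 1L, n)]
      if (length(sel) < 2L) next
      bViews <- lapply(views, function(m) m[sel, , drop = FALSE])
      bg <- .batchGradients(model, bViews, Yall[sel, , drop = FALSE],
                            posAll[sel, sel, drop = FALSE], ids[sel], config)
      if (!is.finite(bg$loss)) {
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, nb + 1L),
             call. = FALSE)
      }
      stepped <- .adamStep(model@weights, bg$grads, state,
                           config$learningRate)
      model@weights <- stepped$w
      state <- stepped$state
      eLoss <- eLoss + bg$loss; eTrip <- eTrip + bg$triplet
      eCe <- eCe + bg$crossEntropy; nb <- nb + 1L
    }
    valF <- NA_real_
    if (!is.null(validation)) {
      vf <- fusedEmbedding(model, validation$bundle)
      vs <- GOScoreMatrix(vf$ssaf, aspect = goAspect(anno))
      valF <- fmaxSweep(vs, validation$truth)$fmax
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = eLoss / max(nb, 1L),
      triplet = eTrip / max(nb, 1L), crossEntropy = eCe / max(nb, 1L),
      validationFmax = valF))
  }
  fw <- .forwardFusion(model, views)
  structure(list(
    model = model,
    embeddings = fw$embedding,
    ssaf = GOScoreMatrix(fw$ssaf, aspect = goAspect(anno)),
    history = history,
    config = config
  ), class = "tripletFit")
}

#' @export
print.tripletFit <- function(x, ...) {
  cat(sprintf("tripletFit: %d proteins, |Q| = %d, %d epoch(s)\n",
              nrow(x$embeddings), length(x$model@terms),
              if (is.null(x$history)) 0L else nrow(x$history)))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final loss %.4f (triplet %.4f, cross-entropy %.4f)\n",
                last$loss, last$triplet, last$crossEntropy))
  }
  invisible(x)
}

#' Average the score matrices of an ensemble of runs
#'
#' Elementwise arithmetic mean over identically indexed score matrices,
#' the standard way to stabilize repeated stochastic training runs.
#'
#' @param scoreList list of [GOScoreMatrix-class] objects with identical
#'   protein and term indices.
#' @return A [GOScoreMatrix-class] of the means.
#' @export
ensembleAverage <- function(scoreList) {
  if (!length(scoreList)) stop("empty ensemble", call. = FALSE)
  ref <- scoreMatrix(scoreList[[1]])
  for (s in scoreList[-1]) {
    if (!identical(dimnames(scoreMatrix(s)), dimnames(ref))) {
      stop("ensemble members disagree on protein/term indices", call. = FALSE)
    }
  }
  acc <- Reduce(`+`, lapply(scoreList, scoreMatrix))
  GOScoreMatrix(acc / length(scoreList), aspect = goAspect(scoreList[[1]]))
}

#' Read embedding views from per-view TSV matrices
#'
#' Expected layout: one whitespace/tab-separated file per view (layer), with
#' protein IDs in the first column and D numeric columns after it; all
#' files list the same proteins. For ESM-1b-style models the three views
#' are conventionally the mean-pooled outputs of the final three hidden
#' layers (indices 31-33 of 33); whichever convention produced the files,
#' the package treats them as opaque per-protein vectors.
#'
#' @param paths character vector of per-view TSV paths.
#' @return An [EmbeddingBundle-class].
#' @export
readEmbeddingViews <- function(paths) {
  views <- lapply(paths, function(p) {
    tab <- read.delim(p, header = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- as.character(tab[[1]])
    colnames(m) <- NULL
    m
  })
  ids <- rownames(views[[1]])
  views <- lapply(views, function(m) m[ids, , drop = FALSE])
  EmbeddingBundle(views)
}

#' Write embedding views as per-view TSV matrices
#'
#' @param bundle an [EmbeddingBundle-class].
#' @param dir output directory; files are named `view1.tsv`, `view2.tsv`, ...
#' @return character vector of written paths, invisibly.
#' @export
writeEmbeddingViews <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in seq_along(embeddingViews(bundle))) {
    m <- embeddingViews(bundle)[[v]]
    p <- file.path(dir, sprintf("view%d.tsv", v))
    write.table(data.frame(rownames(m), m), p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
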