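## Runnable workflows tying the modules together: simulate -> train ->
## predict -> evaluate, plus the baseline predictors. These are the
## functions the command-line wrapper (inst/scripts/gotriplet) calls; each
## is idempotent given identical inputs and seed.

#' Save a trained model as a JSON checkpoint
#'
#' Stores weights, candidate term list, architecture config and seed as
#' plain JSON, so checkpoints are portable text.
#'
#' @param fit a `tripletFit` from [trainTripletModel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCheckpoint <- function(fit, path) {
  m <- fit$model
  payload <- list(
    terms = m@terms,
    config = m@config,
    trainConfig = unclass(fit$config),
    weights = list(
      Wv = lapply(m@weights$Wv, unclass),
      bv = m@weights$bv,
      Wa = m@weights$Wa, ba = m@weights$ba,
      Wo = m@weights$Wo, bo = m@weights$bo
    )
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [writeCheckpoint()]
#'
#' @param path checkpoint JSON path.
#' @return A [TripletFusionModel-class] with attribute `trainConfig`.
#' @export
readCheckpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  toMat <- function(x) {
    do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
  }
  toVec <- function(x) as.numeric(unlist(x))
  w <- list(
    Wv = lapply(p$weights$Wv, toMat),
    bv = lapply(p$weights$bv, toVec),
    Wa = toMat(p$weights$Wa), ba = toVec(p$weights$ba),
    Wo = toMat(p$weights$Wo), bo = toVec(p$weights$bo)
  )
  model <- new("TripletFusionModel", weights = w,
               terms = as.character(unlist(p$terms)),
               config = lapply(p$config, unlist))
  attr(model, "trainConfig") <- p$trainConfig
  model
}

.loadDataset <- function(dir, aspect = "BP") {
  dag <- readOBO(file.path(dir, "ontology.obo"))
  raw <- readAnnotationsTSV(file.path(dir, "annotations.tsv"), aspect = aspect)
  anno <- propagateAnnotations(raw, dag)
  viewPaths <- sort(list.files(file.path(dir, "embeddings"),
                               pattern = "^view", full.names = TRUE))
  bundle <- readEmbeddingViews(viewPaths)
  splits <- lapply(c(train = "train", valid = "valid", test = "test"),
                   function(s) readLines(file.path(dir, paste0(s, ".txt"))))
  list(dag = dag, anno = anno, bundle = bundle, splits = splits)
}

.subsetBundle <- function(bundle, ids) {
  EmbeddingBundle(lapply(embeddingViews(bundle),
                         function(m) m[ids, , drop = FALSE]))
}

.subsetAnno <- function(anno, ids) {
  GOAnnotationSet(annotations(anno)[intersect(ids, proteinIds(anno))],
                  aspect = goAspect(anno), propagated = isPropagated(anno))
}

#' Workflow: generate a synthetic dataset directory
#'
#' @param outDir output directory.
#' @param cfg a [syntheticConfig()].
#' @param force overwrite a non-empty directory.
#' @return the directory, invisibly (see [simulateDataset()]).
#' @export
runSimulate <- function(outDir, cfg = syntheticConfig(), force = FALSE) {
  simulateDataset(cfg, outDir, force = force)
}

#' Workflow: train an ensemble of models on a dataset directory
#'
#' Trains `config$nRuns` seeded replicas on the training split and writes
#' one JSON checkpoint per run under `outDir`.
#'
#' @param dataDir dataset directory from [runSimulate()] (or identically
#'   laid out real data).
#' @param outDir checkpoint output directory.
#' @param config a [trainingConfig()].
#' @param aspect GO aspect to train on.
#' @return list of `tripletFit` objects, invisibly.
#' @export
runTrain <- function(dataDir, outDir, config = trainingConfig(),
                     aspect = "BP") {
  ds <- .loadDataset(dataDir, aspect)
  trainBundle <- .subsetBundle(ds$bundle, ds$splits$train)
  trainAnno <- .subsetAnno(ds$anno, ds$splits$train)
  validation <- if (length(ds$splits$valid)) {
    list(bundle = .subsetBundle(ds$bundle, ds$splits$valid),
         truth = .subsetAnno(ds$anno, ds$splits$valid))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fits <- vector("list", config$nRuns)
  for (r in seq_len(config$nRuns)) {
    runCfg <- config
    runCfg$seed <- .deriveSeed(config$seed, 100L + r)
    fits[[r]] <- trainTripletModel(trainBundle, trainAnno, runCfg,
                                   validation = validation)
    writeCheckpoint(fits[[r]], file.path(outDir, sprintf("run%02d.json", r)))
  }
  invisible(fits)
}

#' Internal predictor scores for a set of query proteins
#'
#' Computes, for one trained model, the output-layer scores and the
#' guilt-by-association scores of the queries against the training set, and
#' combines them with weight `w`.
#'
#' @param model a [TripletFusionModel-class].
#' @param queryBundle [EmbeddingBundle-class] of the queries.
#' @param trainBundle [EmbeddingBundle-class] of the training proteins.
#' @param trainAnno propagated training [GOAnnotationSet-class].
#' @param K templates for [gbaScores()].
#' @param w combination weight on the GBA component.
#' @return A [GOScoreMatrix-class] (not yet post-processed).
#' @export
predictInternal <- function(model, queryBundle, trainBundle, trainAnno,
                            K = 10, w = 0.5) {
  fq <- fusedEmbedding(model, queryBundle)
  ft <- fusedEmbedding(model, trainBundle)
  sGba <- gbaScores(fq$embedding, ft$embedding, trainAnno, K = K)
  sSaf <- GOScoreMatrix(fq$ssaf, aspect = goAspect(trainAnno))
  combineInternal(sGba, sSaf, w = w)
}

#' Workflow: predict GO terms for the test split
#'
#' Ensemble-averages the internal scores of every checkpoint, optionally
#' combines them with the homology consensus predictor, applies
#' hierarchical post-processing (unless `postprocess = FALSE`), and writes
#' CAFA-style predictions to `outFile`.
#'
#' @param dataDir dataset directory.
#' @param checkpointDir directory of checkpoints from [runTrain()].
#' @param outFile prediction output path.
#' @param aspect GO aspect.
#' @param K,w internal predictor parameters (see [predictInternal()]).
#' @param composite also run [sagpScores()] on the dataset's hit table and
#'   combine via [combineComposite()].
#' @param beta per-aspect composite weight map.
#' @param postprocess apply [postprocessScores()] before writing.
#' @param floor smallest score written.
#' @return the final [GOScoreMatrix-class], invisibly.
#' @export
runPredict <- function(dataDir, checkpointDir, outFile, aspect = "BP",
                       K = 10, w = 0.5, composite = FALSE,
                       beta = defaultCompositeBeta(), postprocess = TRUE,
                       floor = 0.01) {
  ds <- .loadDataset(dataDir, aspect)
  ckpts <- sort(list.files(checkpointDir, pattern = "\\.json$",
                           full.names = TRUE))
  if (!length(ckpts)) {
    stop("no checkpoint found under ", checkpointDir,
         "; run the train step first", call. = FALSE)
  }
  trainBundle <- .subsetBundle(ds$bundle, ds$splits$train)
  trainAnno <- .subsetAnno(ds$anno, ds$splits$train)
  queryBundle <- .subsetBundle(ds$bundle, ds$splits$test)
  perRun <- lapply(ckpts, function(cp) {
    predictInternal(readCheckpoint(cp), queryBundle, trainBundle, trainAnno,
                    K = K, w = w)
  })
  s <- ensembleAverage(perRun)
  if (composite) {
    hits <- readAlignmentHits(file.path(dataDir, "hits.tsv"))
    sagp <- sagpScores(hits, trainAnno, queries = ds$splits$test)
    s <- combineComposite(s, sagp, beta = beta)
  }
  if (postprocess) s <- postprocessScores(s, ds$dag)
  writePredictions(s, outFile, floor = floor)
  invisible(s)
}

#' Workflow: evaluate a prediction file against the dataset truth
#'
#' @param dataDir dataset directory.
#' @param predFile CAFA-style prediction file.
#' @param reportFile optional TSV report path.
#' @param aspect GO aspect.
#' @param method method label used in the report.
#' @param mode Fmax pooling mode.
#' @return a `goEvaluation` list.
#' @export
runEvaluate <- function(dataDir, predFile, reportFile = NULL, aspect = "BP",
                        method = "model", mode = "cafa") {
  ds <- .loadDataset(dataDir, aspect)
  scores <- readPredictions(predFile, aspect = aspect)
  truth <- .subsetAnno(ds$anno, ds$splits$test)
  ic <- informationContent(.subsetAnno(ds$anno, ds$splits$train))
  ev <- suppressWarnings(
    evaluateScores(scores, truth, ic = ic, mode = mode,
                   proteins = ds$splits$test))
  if (!is.null(reportFile)) {
    writeEvaluationReport(setNames(list(ev), method), reportFile)
  }
  ev
}

#' Workflow: run a baseline predictor on a dataset directory
#'
#' @param dataDir dataset directory.
#' @param method one of `"sagp"`, `"blast"`, `"ngp"`, `"ppigp"`.
#' @param outFile prediction output path.
#' @param aspect GO aspect.
#' @param postprocess apply hierarchical post-processing.
#' @param floor smallest score written.
#' @return the [GOScoreMatrix-class], invisibly.
#' @export
runBaseline <- function(dataDir, method = c("sagp", "blast", "ngp", "ppigp"),
                        outFile, aspect = "BP", postprocess = TRUE,
                        floor = 0.01) {
  method <- match.arg(method)
  ds <- .loadDataset(dataDir, aspect)
  trainAnno <- .subsetAnno(ds$anno, ds$splits$train)
  queries <- ds$splits$test
  s <- switch(method,
    sagp = sagpScores(readAlignmentHits(file.path(dataDir, "hits.tsv")),
                      trainAnno, queries = queries),
    blast = blastBaselineScores(
      readAlignmentHits(file.path(dataDir, "hits.tsv")),
      trainAnno, queries = queries),
    ngp = ngpScores(trainAnno, queries),
    ppigp = ppigpScores(readPpiEdges(file.path(dataDir, "ppi.tsv")),
                        trainAnno, queries = queries)
  )
  if (postprocess && nrow(scoreMatrix(s))) s <- postprocessScores(s, ds$dag)
  writePredictions(s, outFile, floor = floor)
  invisible(s)
}
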