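## Evaluation suite: protein-centric threshold sweep (Fmax), AUPR, AUROC,
## coverage, and the information-content-weighted Fmax variant. Conventions
## follow the CAFA assessment: the aspect root is excluded upstream, recall
## is averaged over all evaluated proteins, and precision (in "cafa" mode)
## only over proteins that predict at least one term at the threshold.

# Align a score matrix with a truth set: dense matrices over the union of
# scored and annotated terms, rows = proteins with non-empty truth.
.alignScoresTruth <- function(scores, truth) {
  stopifnot(is(scores, "GOScoreMatrix"), is(truth, "GOAnnotationSet"))
  tr <- annotations(truth)
  keep <- lengths(tr) > 0L
  if (!any(keep)) stop("no protein with a non-empty truth set", call. = FALSE)
  if (any(!keep)) {
    warning(sprintf("excluding %d protein(s) with empty truth sets", sum(!keep)),
            call. = FALSE)
  }
  tr <- tr[keep]
  prots <- names(tr)
  terms <- sort(unique(c(colnames(scoreMatrix(scores)),
                         unlist(tr, use.names = FALSE))))
  S <- matrix(0, length(prots), length(terms), dimnames = list(prots, terms))
  common <- intersect(prots, rownames(scoreMatrix(scores)))
  sm <- scoreMatrix(scores)
  S[common, colnames(sm)] <- sm[common, , drop = FALSE]
  Y <- matrix(FALSE, length(prots), length(terms),
              dimnames = list(prots, terms))
  for (p in prots) Y[p, tr[[p]]] <- TRUE
  list(S = S, Y = Y)
}

.sweepGrid <- function(S, thresholds, exact) {
  if (exact) sort(unique(as.vector(S[S > 0]))) else thresholds
}

# Core sweep shared by fmaxSweep and icwFmax; `w` = per-column weights
# (all ones for the unweighted case).
.weightedSweep <- function(S, Y, w, grid, mode) {
  Wm <- matrix(w, nrow(S), ncol(S), byrow = TRUE)
  truthW <- rowSums(Y * Wm)
  res <- lapply(grid, function(t) {
    P <- S >= t & S > 0  # implicit zeros are never predictions
    predW <- rowSums(P * Wm)
    tpW <- rowSums((P & Y) * Wm)
    if (mode == "micro") {
      tp <- sum(tpW); fp <- sum(predW) - tp; fn <- sum(truthW) - tp
      pr <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      rc <- tp / (tp + fn)
    } else {  # cafa: protein-averaged
      hasPred <- predW > 0
      pr <- if (any(hasPred)) mean(tpW[hasPred] / predW[hasPred]) else NA_real_
      rc <- mean(tpW / truthW)
    }
    f <- if (!is.na(pr) && pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    c(t = t, pr = pr, rc = rc, f = f)
  })
  curve <- as.data.frame(do.call(rbind, res))
  iBest <- which.max(curve$f)
  list(fmax = curve$f[iBest], tmax = curve$t[iBest], curve = curve)
}

#' Threshold sweep for the protein-centric maximum F-measure (Fmax)
#'
#' At each cutoff `t` the predicted set of a protein is every term scored at
#' or above `t` (implicit zeros never predict). In `"micro"` mode true/false
#' positives and false negatives are pooled over all proteins before
#' computing precision and recall; in `"cafa"` mode (default) precision is
#' averaged over proteins with at least one prediction and recall over all
#' evaluated proteins. Proteins with empty truth sets are excluded with a
#' warning; an all-empty truth is an error.
#'
#' @param scores a [GOScoreMatrix-class] (post-processed, root-free).
#' @param truth a propagated, root-free [GOAnnotationSet-class].
#' @param thresholds cutoff grid; default `seq(0, 1, 0.01)` (CAFA
#'   convention).
#' @param mode `"cafa"` or `"micro"` pooling (see above).
#' @param exact ignore `thresholds` and sweep every distinct positive score
#'   instead, which makes Fmax invariant to monotone score transforms.
#' @return list with `fmax`, `tmax` (smallest cutoff attaining it) and the
#'   full precision-recall `curve` data.frame (`t`, `pr`, `rc`, `f`).
#' @export
fmaxSweep <- function(scores, truth, thresholds = seq(0, 1, 0.01),
                      mode = c("cafa", "micro"), exact = FALSE) {
  mode <- match.arg(mode)
  al <- .alignScoresTruth(scores, truth)
  grid <- .sweepGrid(al$S, thresholds, exact)
  if (!length(grid)) grid <- 0
  .weightedSweep(al$S, al$Y, rep(1, ncol(al$S)), grid, mode)
}

#' Area under the precision-recall curve of a threshold sweep
#'
#' Step integration in the average-precision style: the curve is ordered by
#' decreasing threshold and each recall increment contributes its precision,
#' `sum_i (rc_i - rc_{i-1}) * pr_i` starting from recall 0. Points with
#' undefined precision (no predictions) are skipped.
#'
#' @param curve the `curve` data.frame returned by [fmaxSweep()].
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(curve) {
  if (is.list(curve) && !is.data.frame(curve) && !is.null(curve$curve)) {
    curve <- curve$curve
  }
  curve <- curve[!is.na(curve$pr), , drop = FALSE]
  if (nrow(curve) < 2L) {
    stop("AUPR needs a curve with at least two defined points", call. = FALSE)
  }
  o <- order(curve$t, decreasing = TRUE)
  rc <- curve$rc[o]; pr <- curve$pr[o]
  sum(diff(c(0, rc)) * pr)
}

#' Area under the ROC curve over (protein, term) pairs
#'
#' `"micro"` mode pools every (protein, term) pair into one ranking and
#' computes the Mann-Whitney statistic with average ranks for ties;
#' `"macro"` averages per-term AUROCs over terms that have both an
#' annotated and an unannotated protein.
#'
#' @inheritParams fmaxSweep
#' @param mode `"micro"` (default) or `"macro"`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, truth, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  al <- .alignScoresTruth(scores, truth)
  mw <- function(s, y) {
    nPos <- sum(y); nNeg <- sum(!y)
    if (nPos == 0L || nNeg == 0L) return(NA_real_)
    r <- rank(s)
    (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  }
  if (mode == "micro") {
    out <- mw(as.vector(al$S), as.vector(al$Y))
    if (is.na(out)) stop("AUROC undefined: one class only", call. = FALSE)
    return(out)
  }
  perTerm <- vapply(seq_len(ncol(al$S)),
                    function(j) mw(al$S[, j], al$Y[, j]), numeric(1))
  if (all(is.na(perTerm))) stop("AUROC undefined for every term", call. = FALSE)
  mean(perTerm, na.rm = TRUE)
}

#' Coverage: fraction of test proteins with any prediction
#'
#' @param scores a [GOScoreMatrix-class].
#' @param proteins the full test protein set; defaults to the rows of
#'   `scores`. Proteins absent from the matrix count as uncovered.
#' @return coverage in `[0, 1]`.
#' @export
coverageScore <- function(scores, proteins = NULL) {
  m <- scoreMatrix(scores)
  if (is.null(proteins)) proteins <- rownames(m)
  if (!length(proteins)) stop("no test proteins", call. = FALSE)
  covered <- rownames(m)[rowSums(m > 0) > 0]
  length(intersect(proteins, covered)) / length(proteins)
}

#' Information-content-weighted Fmax
#'
#' Identical to [fmaxSweep()] except that each term contributes its
#' information content instead of a unit count to the true/false positive
#' and false negative tallies, down-weighting shallow uninformative terms.
#' Scored terms missing from `ic` fall back to the ceiling IC with a
#' warning. A truth whose terms all carry zero IC leaves recall undefined
#' and is an error.
#'
#' @inheritParams fmaxSweep
#' @param ic named IC vector from [informationContent()].
#' @return list with `fmax`, `tmax`, `curve` (as [fmaxSweep()]).
#' @export
icwFmax <- function(scores, truth, ic, thresholds = seq(0, 1, 0.01),
                    mode = c("cafa", "micro"), exact = FALSE) {
  mode <- match.arg(mode)
  al <- .alignScoresTruth(scores, truth)
  w <- .icLookup(ic, colnames(al$S))
  if (any(rowSums(al$Y * matrix(w, nrow(al$Y), ncol(al$Y), byrow = TRUE)) == 0)) {
    stop("a protein's truth set has zero total IC: weighted recall undefined",
         call. = FALSE)
  }
  grid <- .sweepGrid(al$S, thresholds, exact)
  if (!length(grid)) grid <- 0
  .weightedSweep(al$S, al$Y, w, grid, mode)
}

#' Per-protein F1 at a fixed threshold
#'
#' @inheritParams fmaxSweep
#' @param t confidence cutoff (typically `tmax` from [fmaxSweep()]).
#' @return named numeric vector of per-protein F1 scores.
#' @export
perProteinF1 <- function(scores, truth, t) {
  al <- .alignScoresTruth(scores, truth)
  vapply(rownames(al$S), function(p) {
    pred <- colnames(al$S)[al$S[p, ] >= t & al$S[p, ] > 0]
    proteinF1(pred, colnames(al$Y)[al$Y[p, ]])
  }, numeric(1))
}

#' Full CAFA-style evaluation of one score matrix
#'
#' Convenience wrapper computing Fmax (with its threshold), AUPR, AUROC,
#' coverage, optional ICW-Fmax, and per-protein F1 at the Fmax threshold.
#'
#' @inheritParams fmaxSweep
#' @param ic optional IC vector enabling ICW-Fmax.
#' @param proteins full test protein list for the coverage denominator.
#' @return list of class `goEvaluation`.
#' @export
evaluateScores <- function(scores, truth, ic = NULL,
                           thresholds = seq(0, 1, 0.01),
                           mode = c("cafa", "micro"), proteins = NULL) {
  mode <- match.arg(mode)
  sw <- fmaxSweep(scores, truth, thresholds, mode)
  out <- list(
    fmax = sw$fmax,
    tmax = sw$tmax,
    aupr = aupr(sw$curve),
    auroc = auroc(scores, truth),
    coverage = coverageScore(scores, proteins %||% proteinIds(truth)),
    icwFmax = if (!is.null(ic)) {
      icwFmax(scores, truth, ic, thresholds, mode)$fmax
    } else NA_real_,
    perProteinF1 = perProteinF1(scores, truth, sw$tmax),
    curve = sw$curve,
    mode = mode,
    aspect = goAspect(scores)
  )
  class(out) <- "goEvaluation"
  out
}

#' @export
print.goEvaluation <- function(x, ...) {
  cat(sprintf(
    "GO evaluation (%s, %s pooling)\n  Fmax = %.3f at t = %.2f | AUPR = %.3f | AUROC = %.3f | coverage = %.2f%s\n",
    x$aspect, x$mode, x$fmax, x$tmax, x$aupr, x$auroc, x$coverage,
    if (is.na(x$icwFmax)) "" else sprintf(" | ICW-Fmax = %.3f", x$icwFmax)))
  invisible(x)
}

#' Write a per-method evaluation report as TSV
#'
#' One row per method with Fmax, its threshold, AUPR, AUROC, coverage and
#' ICW-Fmax, mirroring the usual benchmark-table layout.
#'
#' @param results named list of `goEvaluation` objects (one per method).
#' @param path output TSV path.
#' @return the report data.frame, invisibly.
#' @export
writeEvaluationReport <- function(results, path) {
  df <- do.call(rbind, lapply(names(results), function(m) {
    r <- results[[m]]
    data.frame(method = m, aspect = r$aspect, fmax = round(r$fmax, 3),
               t_star = r$tmax, aupr = round(r$aupr, 3),
               auroc = round(r$auroc, 3), coverage = round(r$coverage, 2),
               icw_fmax = round(r$icwFmax, 3))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Friedman test with Nemenyi post-hoc comparisons on per-protein scores
#'
#' Ranks the methods within every protein (ties mid-ranked), applies the
#' Friedman chi-square test for any difference among methods, and then the
#' Nemenyi post-hoc test on mean-rank differences, whose p-values come from
#' the studentized range distribution and are clamped to the reportable
#' range `[1e-3, 0.9]`.
#'
#' @param f1Matrix numeric matrix: rows = proteins, columns = methods
#'   (e.g. per-protein F1 of each method).
#' @return list with `statistic`, `p.value` (Friedman), `meanRanks`, and
#'   `pairwise` (symmetric matrix of Nemenyi p-values).
#' @export
friedmanNemenyi <- function(f1Matrix) {
  f1Matrix <- as.matrix(f1Matrix)
  n <- nrow(f1Matrix); k <- ncol(f1Matrix)
  if (k < 3L) stop("need at least 3 methods", call. = FALSE)
  if (n < 2L) stop("need at least 2 proteins", call. = FALSE)
  ranks <- t(apply(f1Matrix, 1, rank))
  if (all(apply(f1Matrix, 1, function(r) length(unique(r)) == 1L))) {
    stop("all rows constant across methods: Friedman statistic degenerate",
         call. = FALSE)
  }
  ft <- friedman.test(f1Matrix)
  meanRanks <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (12 * n))
  q <- abs(outer(meanRanks, meanRanks, "-")) / se
  p <- 1 - ptukey(q, nmeans = k, df = Inf)
  p <- pmin(pmax(p, 1e-3), 0.9)
  diag(p) <- NA_real_
  dimnames(p) <- list(colnames(f1Matrix), colnames(f1Matrix))
  list(statistic = unname(ft$statistic), p.value = unname(ft$p.value),
       meanRanks = meanRanks, pairwise = p)
}

#' One-sample t-test helper for repeated-run metric comparisons
#'
#' Compares the metric values of several independent training runs against
#' the fixed value reported by a competing method (two-sided one-sample
#' t-test).
#'
#' @param runValues numeric vector, one metric value per run.
#' @param competitorValue single fixed metric value to compare against.
#' @return the `htest` object from [stats::t.test()].
#' @export
compareRunsToFixed <- function(runValues, competitorValue) {
  stats::t.test(runValues, mu = competitorValue)
}
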