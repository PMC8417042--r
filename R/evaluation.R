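## ROC/AUC, PR/AUPR and the leave-one-out cross-validation protocol.

#' ROC curve and AUC for positive versus candidate scores
#'
#' Sweeps a threshold over the union of scores, computes TPR and FPR at
#' each, and integrates by the trapezoidal rule. Ties between a positive
#' and a candidate contribute half credit, so the AUC equals the normalized
#' Mann-Whitney U statistic.
#'
#' @param positiveScores numeric vector of scores of the true (held-out)
#'   associations.
#' @param candidateScores numeric vector of scores of the negative
#'   candidates.
#' @return List with `roc` (data.frame of fpr, tpr) and `auc`.
#' @examples
#' rocAuc(c(0.9, 0.4), c(0.8, 0.3, 0.1))$auc  # 5/6
#' @export
rocAuc <- function(positiveScores, candidateScores) {
  if (!length(positiveScores) || !length(candidateScores)) {
    stop("both score lists must be nonempty")
  }
  thr <- sort(unique(c(positiveScores, candidateScores)), decreasing = TRUE)
  P <- length(positiveScores); N <- length(candidateScores)
  tpr <- vapply(thr, function(t) sum(positiveScores >= t) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(candidateScores >= t) / N, numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Precision-recall curve and AUPR
#'
#' Precision and recall at every threshold of the score union; the area is
#' the step-wise (non-interpolated) sum of precision times the recall
#' increment, i.e. average precision with tied scores handled as one
#' threshold block.
#'
#' @inheritParams rocAuc
#' @return List with `pr` (data.frame of recall, precision) and `aupr`.
#' @export
prAupr <- function(positiveScores, candidateScores) {
  if (!length(positiveScores) || !length(candidateScores)) {
    stop("both score lists must be nonempty")
  }
  thr <- sort(unique(c(positiveScores, candidateScores)), decreasing = TRUE)
  P <- length(positiveScores)
  tp <- vapply(thr, function(t) sum(positiveScores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(candidateScores >= t), numeric(1))
  recall <- tp / P
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(pr = data.frame(recall = recall, precision = precision), aupr = aupr)
}

## Local mode: each fold is reduced to the within-fold rank of its positive
## (half credit for ties). The AUC is the mean per-fold AUC, i.e. the mean
## fraction of own-fold candidates scored below the positive. The reported
## curve sweeps top-k cutoffs over the per-fold candidate lists: TPR(k) is
## the fraction of folds whose positive sits in the top k, FPR(k) the mean
## share of candidates admitted alongside.
.localCurves <- function(posScores, candScores) {
  ranksAbove <- mapply(function(p, cs) sum(cs > p) + 0.5 * sum(cs == p),
                       posScores, candScores)
  sizes <- lengths(candScores)
  auc <- mean((sizes - ranksAbove) / sizes)
  maxK <- max(sizes) + 1L
  tpr <- fpr <- prec <- numeric(maxK)
  for (k in seq_len(maxK)) {
    hit <- ranksAbove < k            # positive within top k of its fold
    tpr[k] <- mean(hit)
    admitted <- pmin(k - hit, sizes)  # candidates admitted alongside
    fpr[k] <- mean(admitted / sizes)
    prec[k] <- sum(hit) / sum(hit + admitted)
  }
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  pr <- data.frame(recall = tpr, precision = prec)
  aupr <- sum(diff(c(0, tpr)) * prec)
  list(roc = roc, auc = auc, pr = pr, aupr = aupr)
}

#' Evaluate recorded LOOCV folds
#'
#' Turns per-fold records (held-out score plus candidate scores) into
#' ROC/AUC and PR/AUPR, pooling globally (all positives against the union
#' of all candidate scores) or locally (each positive ranked only within
#' its own fold's candidates).
#'
#' @param folds data.frame with at least a `positiveScore` column, one row
#'   per held-out association.
#' @param candidateScores list of numeric vectors, one per fold.
#' @param mode `"global"` or `"local"`.
#' @param params list of parameters to carry along in the result.
#' @return An [EvaluationResult-class].
#' @export
evaluateFolds <- function(folds, candidateScores, mode = c("global", "local"),
                          params = list()) {
  mode <- match.arg(mode)
  if (nrow(folds) != length(candidateScores)) {
    stop("one candidate score vector per fold required")
  }
  if (mode == "global") {
    pooled <- unlist(candidateScores, use.names = FALSE)
    r <- rocAuc(folds$positiveScore, pooled)
    p <- prAupr(folds$positiveScore, pooled)
    out <- list(roc = r$roc, auc = r$auc, pr = p$pr, aupr = p$aupr)
  } else {
    out <- .localCurves(folds$positiveScore, candidateScores)
  }
  new("EvaluationResult", mode = mode, folds = folds,
      candidateScores = candidateScores, roc = out$roc, auc = out$auc,
      pr = out$pr, aupr = out$aupr, params = params)
}

#' Leave-one-out cross-validation of the walk
#'
#' Masks each known association (l, d) in turn, optionally recomputes the
#' association-derived similarity layers (both GIP kernels and the
#' functional layer; the ontology semantic layer does not depend on the
#' associations) from the masked matrix, ranks the lncRNAs for disease d,
#' and records the held-out lncRNA's score together with the scores of the
#' candidate lncRNAs (those without a known association to d in the masked
#' matrix).
#'
#' @param LD an [AssociationMatrix-class] with at least 2 associations.
#' @param params an [RWRParams-class].
#' @param dag optional [OntologyDAG-class] for the semantic layer.
#' @param termOf optional disease-to-term mapping.
#' @param mode pooling mode, `"global"` (default) or `"local"`.
#' @param recomputeSimilarity recompute GIP/functional layers per fold
#'   (default TRUE; FALSE reuses the layers built from the full matrix,
#'   which is cheaper but lets the held-out edge leak into the kernels).
#' @param decay,gammaPrime layer parameters, see [buildSimilarityLayers()].
#' @param verbose print fold progress every 50 folds.
#' @param ... layer switches (`useFunctional`, `useLncGip`, `useSemantic`,
#'   `useDisGip`) forwarded to [buildSimilarityLayers()].
#' @return An [EvaluationResult-class].
#' @export
loocv <- function(LD, params = RWRParams(), dag = NULL, termOf = NULL,
                  mode = c("global", "local"), recomputeSimilarity = TRUE,
                  decay = 0.5, gammaPrime = 1, verbose = FALSE, ...) {
  mode <- match.arg(mode)
  B <- assocMatrix(LD)
  pairs <- which(B == 1, arr.ind = TRUE)
  if (nrow(pairs) < 2L) stop("need at least 2 known associations")
  fullLayers <- buildSimilarityLayers(LD, dag, termOf, decay, gammaPrime, ...)
  semantic <- fullLayers$disease$semantic  # reused: association-independent
  posScore <- numeric(nrow(pairs))
  candScores <- vector("list", nrow(pairs))
  for (f in seq_len(nrow(pairs))) {
    i <- pairs[f, 1L]; j <- pairs[f, 2L]
    Bm <- B
    Bm[i, j] <- 0
    LDm <- AssociationMatrix(Bm)
    layers <- if (recomputeSimilarity) {
      ly <- buildSimilarityLayers(LDm, dag, termOf, decay, gammaPrime, ...)
      if (!is.null(semantic)) ly$disease$semantic <- semantic
      ly
    } else fullLayers
    pred <- predictForDisease(LDm, layers, params, colnames(B)[j])
    sc <- stats::setNames(predRanking(pred)$score, predRanking(pred)$candidate)
    held <- rownames(B)[i]
    posScore[f] <- sc[[held]]
    candScores[[f]] <- unname(sc[setdiff(names(sc), held)])
    if (verbose && f %% 50L == 0L) {
      message("fold ", f, " / ", nrow(pairs))
    }
  }
  folds <- data.frame(lncrna = rownames(B)[pairs[, 1L]],
                      disease = colnames(B)[pairs[, 2L]],
                      positiveScore = posScore,
                      nCandidates = lengths(candScores))
  evaluateFolds(folds, candScores, mode,
                params = list(gamma = params@gamma, lambda = params@lambda,
                              eta = params@eta, delta = params@delta,
                              recomputeSimilarity = recomputeSimilarity))
}
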