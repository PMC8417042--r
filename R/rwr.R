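## Random walk with restart: restart vector, power iteration, copy
## aggregation and candidate ranking.

#' Build the restart (seed) probability vector
#'
#' The restart distribution places weight `eta` on the disease side and
#' `1 - eta` on the lncRNA side. The disease mass sits on the query disease,
#' split uniformly over its K layer copies; the lncRNA mass is split
#' uniformly over the seed lncRNAs and then over their L copies. When no
#' seed lncRNA exists the full restart mass goes to the disease side, so
#' the vector is always a probability distribution.
#'
#' @param queryDisease a disease identifier.
#' @param seedLncrnas character vector of seed lncRNA ids (may be empty).
#' @param eta disease-side restart weight in (0, 1).
#' @param lncrnaIds,diseaseIds entity orderings of the transition matrix.
#' @param nLncLayers,nDisLayers layer counts L and K.
#' @return A [ProbabilityVector-class].
#' @examples
#' buildRestartVector("d1", character(), 0.9, c("l1", "l2"), c("d1", "d2"), 2L, 2L)
#' @export
buildRestartVector <- function(queryDisease, seedLncrnas, eta,
                               lncrnaIds, diseaseIds,
                               nLncLayers = 1L, nDisLayers = 1L) {
  if (length(eta) != 1L || eta <= 0 || eta >= 1) stop("eta must lie in (0, 1)")
  j <- match(queryDisease, diseaseIds)
  if (is.na(j)) stop("unknown disease id: ", queryDisease)
  seedLncrnas <- unique(seedLncrnas)
  si <- match(seedLncrnas, lncrnaIds)
  if (anyNA(si)) {
    stop("unknown lncRNA id(s): ",
         paste(seedLncrnas[is.na(si)], collapse = ", "))
  }
  n <- length(lncrnaIds); m <- length(diseaseIds)
  L <- as.integer(nLncLayers); K <- as.integer(nDisLayers)
  r0 <- numeric(n * L)
  d0 <- numeric(m * K)
  etaEff <- if (length(si)) eta else 1
  d0[(seq_len(K) - 1L) * m + j] <- etaEff / K
  if (length(si)) {
    for (a in seq_len(L)) r0[(a - 1L) * n + si] <- (1 - eta) / (length(si) * L)
  }
  new("ProbabilityVector", values = c(r0, d0), lncrnaIds = lncrnaIds,
      diseaseIds = diseaseIds, nLncLayers = L, nDisLayers = K)
}

#' Power iteration for the restart walk
#'
#' Iterates P_{t+1} = (1 - gamma) H' P_t + gamma P_rs from P_0 = P_rs until
#' the L1 change drops below `tol`. Because H is row-stochastic and
#' gamma > 0, the map is an L1 contraction with factor (1 - gamma): the
#' fixed point is unique and the residual shrinks geometrically, so with
#' gamma = 0.9 about a dozen iterations reach 1e-10.
#'
#' @param H a [TransitionMatrix-class] (or row-stochastic matrix).
#' @param pRS a [ProbabilityVector-class] (or numeric vector summing to 1).
#' @param gamma restart probability in (0, 1]; gamma = 1 returns the restart
#'   vector itself.
#' @param tol L1 convergence threshold, default 1e-10.
#' @param maxIter iteration cap, default 10000.
#' @return List with `pInf` (a [ProbabilityVector-class] when `pRS` was one,
#'   else a numeric vector) and `iterations`.
#' @export
rwrIterate <- function(H, pRS, gamma = 0.9, tol = 1e-10, maxIter = 10000L) {
  if (length(gamma) != 1L || gamma <= 0 || gamma > 1) {
    stop("gamma must lie in (0, 1]")
  }
  if (tol <= 0) stop("tol must be positive")
  Hm <- if (is(H, "TransitionMatrix")) H@values else H
  isPV <- is(pRS, "ProbabilityVector")
  p0 <- if (isPV) pRS@values else pRS
  if (abs(sum(p0) - 1) > 1e-9) stop("restart vector must sum to 1")
  tH <- t(Hm)
  p <- p0
  for (it in seq_len(maxIter)) {
    pNew <- as.vector((1 - gamma) * (tH %*% p)) + gamma * p0
    res <- sum(abs(pNew - p))
    p <- pNew
    if (res < tol) {
      pInf <- if (isPV) initialize(pRS, values = p) else p
      return(list(pInf = pInf, iterations = it))
    }
  }
  stop(sprintf("no convergence after %d iterations (residual %.3e)",
               maxIter, res))
}

#' Aggregate copy probabilities into entity scores
#'
#' The walk lives on node copies; entities are scored by summing the
#' stationary probability over their L (or K) layer copies.
#'
#' @param pInf a [ProbabilityVector-class].
#' @param side `"lncrna"` or `"disease"`.
#' @return Named numeric vector of per-entity scores.
#' @export
aggregateScores <- function(pInf, side = c("lncrna", "disease")) {
  side <- match.arg(side)
  n <- length(pInf@lncrnaIds); m <- length(pInf@diseaseIds)
  L <- pInf@nLncLayers; K <- pInf@nDisLayers
  v <- pInf@values
  if (side == "lncrna") {
    block <- matrix(v[seq_len(n * L)], nrow = n, ncol = L)
    stats::setNames(rowSums(block), pInf@lncrnaIds)
  } else {
    block <- matrix(v[n * L + seq_len(m * K)], nrow = m, ncol = K)
    stats::setNames(rowSums(block), pInf@diseaseIds)
  }
}

## shared pipeline: layers list -> transition matrix
.assembleTransition <- function(LD, layers, params) {
  netL <- MultiplexNetwork(unname(layers$lncrna), delta = params@delta)
  netD <- MultiplexNetwork(unname(layers$disease), delta = params@delta)
  buildTransitionMatrix(buildSupraAdjacency(netL), buildSupraAdjacency(netD),
                        LD, lambda = params@lambda)
}

#' Rank candidate lncRNAs for a disease
#'
#' Runs the full pipeline for one query disease: the disease is the
#' disease-side seed, every lncRNA already associated with it is a
#' lncRNA-side seed, the walk is iterated to its stationary distribution,
#' lncRNA copy probabilities are aggregated, the seeds are removed and the
#' remaining lncRNAs are ranked by score (higher = more likely associated).
#'
#' @param LD an [AssociationMatrix-class].
#' @param layers list with elements `lncrna` and `disease`, each a list of
#'   [SimilarityMatrix-class] layers (see [buildSimilarityLayers()]).
#' @param params an [RWRParams-class].
#' @param queryDisease the disease to rank candidates for.
#' @return A [RankedPredictions-class].
#' @export
predictForDisease <- function(LD, layers, params, queryDisease) {
  stopifnot(is(params, "RWRParams"))
  if (!queryDisease %in% diseaseIds(LD)) {
    stop("unknown disease id: ", queryDisease)
  }
  H <- .assembleTransition(LD, layers, params)
  seeds <- lncrnaIds(LD)[assocMatrix(LD)[, queryDisease] == 1]
  pRS <- buildRestartVector(queryDisease, seeds, params@eta,
                            lncrnaIds(LD), diseaseIds(LD),
                            H@nLncLayers, H@nDisLayers)
  fit <- rwrIterate(H, pRS, params@gamma, params@tol, params@maxIter)
  scores <- aggregateScores(fit$pInf, "lncrna")
  scores <- scores[setdiff(names(scores), seeds)]
  ord <- order(-scores)
  ranking <- data.frame(rank = seq_along(ord),
                        candidate = names(scores)[ord],
                        score = unname(scores[ord]))
  new("RankedPredictions", query = queryDisease, side = "lncrna",
      ranking = ranking, excluded = seeds)
}

#' Rank candidate diseases for a lncRNA
#'
#' Mirror image of [predictForDisease()]: the query lncRNA and its known
#' diseases seed the walk on the transposed association structure, and the
#' remaining diseases are ranked by aggregated disease-side score.
#'
#' @inheritParams predictForDisease
#' @param queryLncrna the lncRNA to rank candidate diseases for.
#' @return A [RankedPredictions-class] with `side = "disease"`.
#' @export
predictForLncrna <- function(LD, layers, params, queryLncrna) {
  stopifnot(is(params, "RWRParams"))
  if (!queryLncrna %in% lncrnaIds(LD)) {
    stop("unknown lncRNA id: ", queryLncrna)
  }
  ## transpose the heterogeneous structure: diseases take the lncRNA role
  LDt <- AssociationMatrix(t(assocMatrix(LD)))
  layersT <- list(lncrna = layers$disease, disease = layers$lncrna)
  pred <- predictForDisease(LDt, layersT, params, queryLncrna)
  new("RankedPredictions", query = queryLncrna, side = "disease",
      ranking = predRanking(pred), excluded = pred@excluded)
}
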