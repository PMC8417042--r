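## Assembly of the multiplex supra-adjacency matrices and the global
## transition matrix over all lncRNA and disease node copies.
##
## Copy indexing is layer-major throughout: the copy of node i on layer a
## sits at position (a - 1) * n + i. The layout is internal; every
## user-facing result aggregates over copies.

#' Row-normalize a similarity layer for the walk
#'
#' Removes self-loops (the unit diagonal of a similarity matrix would
#' otherwise dominate the transitions) and divides each row by its sum so
#' that the layer is a within-layer transition matrix. Rows that are all
#' zero after diagonal removal (nodes isolated within the layer) are left
#' at zero and flagged; the supra-adjacency construction gives them a
#' self-loop fallback.
#'
#' @param layer a [SimilarityMatrix-class] or a square nonnegative matrix.
#' @return List with `values` (the row-normalized matrix) and `isolated`
#'   (logical vector flagging all-zero rows).
#' @export
normalizeLayer <- function(layer) {
  v <- if (is(layer, "SimilarityMatrix")) simMatrix(layer) else layer
  if (nrow(v) != ncol(v)) stop("layer must be square")
  if (min(v) < 0) stop("layer must be nonnegative")
  diag(v) <- 0
  rs <- rowSums(v)
  isolated <- rs == 0
  rs[isolated] <- 1
  list(values = v / rs, isolated = isolated)
}

#' Build the supra-adjacency matrix of a multiplex network
#'
#' Stacks the row-normalized layers into the (nL) x (nL) supra-adjacency
#' matrix: with probability (1 - delta) the particle moves within its
#' current layer, with probability delta it jumps to one of the other L - 1
#' copies of its current node (uniformly). A node isolated within a layer
#' keeps the within-layer mass (1 - delta) on its own copy, so every row
#' sums to exactly 1. With a single layer delta is forced to 0 and the
#' supra-adjacency equals the normalized layer.
#'
#' @param net a [MultiplexNetwork-class].
#' @return A [SupraAdjacency-class].
#' @export
buildSupraAdjacency <- function(net) {
  stopifnot(is(net, "MultiplexNetwork"))
  L <- nLayers(net)
  n <- length(net@nodeIds)
  delta <- if (L == 1L) 0 else net@delta
  norm <- lapply(net@layers, normalizeLayer)
  isolated <- vapply(norm, `[[`, logical(n), "isolated")
  isolated <- matrix(isolated, nrow = n, ncol = L)
  supra <- matrix(0, n * L, n * L)
  for (a in seq_len(L)) {
    idx <- (a - 1L) * n + seq_len(n)
    block <- (1 - delta) * norm[[a]]$values
    ## self-loop fallback for isolated-in-layer nodes
    iso <- which(norm[[a]]$isolated)
    if (length(iso)) block[cbind(iso, iso)] <- 1 - delta
    supra[idx, idx] <- block
    if (L > 1L) {
      for (b in seq_len(L)[-a]) {
        jdx <- (b - 1L) * n + seq_len(n)
        supra[cbind(idx, jdx)] <- delta / (L - 1)
      }
    }
  }
  copyIds <- as.vector(outer(net@nodeIds, seq_len(L),
                             function(id, a) paste0(id, "@L", a)))
  dimnames(supra) <- list(copyIds, copyIds)
  new("SupraAdjacency", values = supra, nodeIds = net@nodeIds,
      nLayers = as.integer(L), isolated = isolated)
}

#' Build the global transition matrix
#'
#' Couples the lncRNA supra-adjacency, the disease supra-adjacency and the
#' bipartite association matrix into one row-stochastic transition matrix
#' over all nL + mK node copies. From a lncRNA copy, a particle follows its
#' supra-adjacency row with probability (1 - lambda) and jumps to a disease
#' copy with probability lambda, choosing an associated disease
#' proportionally to the association row and one of its K copies uniformly;
#' a lncRNA with no associations keeps its full supra-adjacency row
#' (lambda does not apply). Disease copies are handled symmetrically via the
#' association columns and the L lncRNA layers.
#'
#' @param supraL [SupraAdjacency-class] over the lncRNAs.
#' @param supraD [SupraAdjacency-class] over the diseases.
#' @param LD an [AssociationMatrix-class] (rows must match `supraL`'s nodes,
#'   columns `supraD`'s nodes).
#' @param lambda bipartite jump probability in [0, 1); 0 turns the coupling
#'   off entirely.
#' @return A [TransitionMatrix-class].
#' @export
buildTransitionMatrix <- function(supraL, supraD, LD, lambda = 0.9) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0 || lambda >= 1) {
    stop("lambda must lie in [0, 1)")
  }
  B <- assocMatrix(LD)
  if (!identical(rownames(B), supraL@nodeIds) ||
      !identical(colnames(B), supraD@nodeIds)) {
    stop("association ids do not match the supra-adjacency node ids")
  }
  n <- nrow(B); m <- ncol(B)
  L <- supraL@nLayers; K <- supraD@nLayers
  nL <- n * L; mK <- m * K
  H <- matrix(0, nL + mK, nL + mK)
  rowDeg <- rowSums(B)
  colDeg <- colSums(B)

  ## lncRNA block rows: scale the whole supra-row by (1 - lambda) when the
  ## lncRNA has bipartite links, and spread lambda over the K copies of each
  ## associated disease
  scaleR <- ifelse(rowDeg > 0, 1 - lambda, 1)
  crossR <- matrix(0, n, m)
  hasR <- rowDeg > 0
  crossR[hasR, ] <- lambda * B[hasR, , drop = FALSE] / rowDeg[hasR] / K
  for (a in seq_len(L)) {
    idx <- (a - 1L) * n + seq_len(n)
    H[idx, seq_len(nL)] <- scaleR * supraL@values[idx, , drop = FALSE]
    for (b in seq_len(K)) {
      jdx <- nL + (b - 1L) * m + seq_len(m)
      H[idx, jdx] <- crossR
    }
  }

  ## disease block rows, mirror construction with columns of B and 1/L
  scaleD <- ifelse(colDeg > 0, 1 - lambda, 1)
  crossD <- matrix(0, m, n)
  hasD <- colDeg > 0
  crossD[hasD, ] <- lambda * t(B)[hasD, , drop = FALSE] / colDeg[hasD] / L
  for (b in seq_len(K)) {
    idx <- nL + (b - 1L) * m + seq_len(m)
    H[idx, nL + seq_len(mK)] <- scaleD * supraD@values[(b - 1L) * m + seq_len(m), ,
                                                       drop = FALSE]
    for (a in seq_len(L)) {
      jdx <- (a - 1L) * n + seq_len(n)
      H[idx, jdx] <- crossD
    }
  }

  copyIds <- c(rownames(supraL@values), rownames(supraD@values))
  dimnames(H) <- list(copyIds, copyIds)
  new("TransitionMatrix", values = H, lncrnaIds = rownames(B),
      diseaseIds = colnames(B), nLncLayers = as.integer(L),
      nDisLayers = as.integer(K), lambda = lambda)
}
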