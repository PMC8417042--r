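#' @import methods
NULL

## ---------------------------------------------------------------------------
## OntologyDAG
## ---------------------------------------------------------------------------

#' Disease-ontology DAG
#'
#' A rooted directed acyclic graph of ontology terms, stored as child-to-parent
#' edges. Only the hierarchy (is_a) structure is kept; this is the input of the
#' semantic-contribution machinery.
#'
#' @slot terms character vector of term identifiers.
#' @slot parentEdges named list; for each non-root term, the character vector
#'   of its parent terms. Terms absent from the list are roots.
#' @slot roots character vector of terms with no parents.
#'
#' @seealso [OntologyDAG()], [semanticContributions()],
#'   [diseaseSemanticSimilarity()]
#' @exportClass OntologyDAG
setClass("OntologyDAG",
  representation(
    terms = "character",
    parentEdges = "list",
    roots = "character"
  )
)

setValidity("OntologyDAG", function(object) {
  msgs <- character()
  trm <- object@terms
  if (anyDuplicated(trm)) msgs <- c(msgs, "duplicated term identifiers")
  pe <- object@parentEdges
  if (length(pe) > 0L) {
    if (is.null(names(pe)) || any(!nzchar(names(pe)))) {
      return("parentEdges must be a named list")
    }
    if (!all(names(pe) %in% trm)) msgs <- c(msgs, "parentEdges child not in terms")
    if (!all(unlist(pe, use.names = FALSE) %in% trm)) {
      msgs <- c(msgs, "parent term outside the term set")
    }
  }
  expectRoots <- setdiff(trm, names(pe)[lengths(pe) > 0L])
  if (!setequal(expectRoots, object@roots)) {
    msgs <- c(msgs, "roots slot inconsistent with parentEdges")
  }
  ## acyclicity: a topological sort must exist
  if (length(pe) > 0L) {
    el <- cbind(
      rep(names(pe), lengths(pe)),
      unlist(pe, use.names = FALSE)
    )
    g <- igraph::graph_from_edgelist(el, directed = TRUE)
    if (!igraph::is_dag(g)) msgs <- c(msgs, "ontology graph contains a cycle")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OntologyDAG
#'
#' @param edges two-column matrix or data.frame of `child, parent` term pairs,
#'   or `NULL` for an edgeless ontology.
#' @param terms optional character vector of term ids; defaults to the ids
#'   appearing in `edges`. Extra ids become isolated roots.
#' @return An [OntologyDAG-class] object.
#' @examples
#' dag <- OntologyDAG(rbind(c("b", "a"), c("c", "b")))
#' ontoRoots(dag)
#' @export
OntologyDAG <- function(edges = NULL, terms = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    child <- parent <- character()
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns: child, parent")
    child <- as.character(edges[, 1L])
    parent <- as.character(edges[, 2L])
  }
  allTerms <- unique(c(child, parent, terms))
  pe <- split(parent, factor(child, levels = unique(child)))
  pe <- lapply(pe, unique)
  roots <- setdiff(allTerms, names(pe)[lengths(pe) > 0L])
  new("OntologyDAG", terms = allTerms, parentEdges = pe, roots = roots)
}

#' @describeIn OntologyDAG Term identifiers of the ontology.
#' @param dag an [OntologyDAG-class] object.
#' @export
ontoTerms <- function(dag) dag@terms

#' @describeIn OntologyDAG Root terms (no parents).
#' @export
ontoRoots <- function(dag) dag@roots

#' @describeIn OntologyDAG Named list of child-to-parent edges.
#' @export
parentEdges <- function(dag) dag@parentEdges

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG with", length(object@terms), "terms,",
      sum(lengths(object@parentEdges)), "is_a edges,",
      length(object@roots), "root(s)\n")
})

## ---------------------------------------------------------------------------
## AssociationMatrix
## ---------------------------------------------------------------------------

#' Binary lncRNA-disease association matrix
#'
#' The bipartite adjacency matrix LD: rows are lncRNAs, columns diseases,
#' LD[i, j] = 1 when lncRNA i is associated with disease j. Row i is the
#' interaction profile of lncRNA i; column j is the interaction profile of
#' disease j. This matrix is both the source of the Gaussian interaction
#' profile kernels and the bipartite coupling of the heterogeneous network.
#'
#' @slot values numeric matrix with 0/1 entries; dimnames carry the ids.
#'
#' @seealso [AssociationMatrix()], [gipSimilarity()], [readAssociations()]
#' @exportClass AssociationMatrix
setClass("AssociationMatrix", representation(values = "matrix"))

setValidity("AssociationMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    return("values must carry lncRNA rownames and disease colnames")
  }
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v))) {
    msgs <- c(msgs, "duplicated ids")
  }
  if (!all(v %in% c(0, 1))) msgs <- c(msgs, "entries must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AssociationMatrix
#'
#' @param values binary matrix with lncRNA rownames and disease colnames.
#' @return An [AssociationMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("l1", "l2"), c("d1", "d2")))
#' AssociationMatrix(m)
#' @export
AssociationMatrix <- function(values) {
  storage.mode(values) <- "double"
  new("AssociationMatrix", values = values)
}

#' @describeIn AssociationMatrix lncRNA identifiers (row order).
#' @param x an [AssociationMatrix-class] object.
#' @export
lncrnaIds <- function(x) rownames(x@values)

#' @describeIn AssociationMatrix Disease identifiers (column order).
#' @export
diseaseIds <- function(x) colnames(x@values)

#' @describeIn AssociationMatrix The underlying 0/1 matrix.
#' @export
assocMatrix <- function(x) x@values

setMethod("show", "AssociationMatrix", function(object) {
  v <- object@values
  cat("AssociationMatrix:", nrow(v), "lncRNAs x", ncol(v), "diseases,",
      sum(v), "associations\n")
})

setMethod("dim", "AssociationMatrix", function(x) dim(x@values))

## ---------------------------------------------------------------------------
## SimilarityMatrix
## ---------------------------------------------------------------------------

#' Square symmetric similarity matrix
#'
#' One network layer: square, symmetric, entries in [0, 1], unit diagonal for
#' nodes with a defined self-profile.
#'
#' @slot values numeric matrix with identical row and column names.
#'
#' @seealso [SimilarityMatrix()], [gipSimilarity()],
#'   [diseaseSemanticSimilarity()], [lncrnaFunctionalSimilarity()]
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    return("ids required as dimnames")
  }
  if (!identical(rownames(v), colnames(v))) {
    msgs <- c(msgs, "row and column ids differ")
  }
  if (max(abs(v - t(v))) > 1e-12) msgs <- c(msgs, "matrix not symmetric (tol 1e-12)")
  if (min(v) < -1e-12 || max(v) > 1 + 1e-12) {
    msgs <- c(msgs, "entries outside [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values square symmetric numeric matrix in [0, 1] with ids as
#'   dimnames (rownames are used if colnames are missing).
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values) {
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  new("SimilarityMatrix", values = values)
}

#' @describeIn SimilarityMatrix Node identifiers.
#' @param x a [SimilarityMatrix-class] object.
#' @export
simIds <- function(x) rownames(x@values)

#' @describeIn SimilarityMatrix The underlying numeric matrix.
#' @export
simMatrix <- function(x) x@values

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  cat("SimilarityMatrix over", nrow(v), "nodes; mean off-diagonal",
      signif(mean(v[row(v) != col(v)]), 4), "\n")
})

setMethod("dim", "SimilarityMatrix", function(x) dim(x@values))

## ---------------------------------------------------------------------------
## MultiplexNetwork / SupraAdjacency / TransitionMatrix
## ---------------------------------------------------------------------------

#' Multiplex network of similarity layers
#'
#' Several similarity layers over the identical ordered node set, plus the
#' inter-layer jump probability delta used when assembling the
#' supra-adjacency matrix.
#'
#' @slot nodeIds ordered node identifiers shared by all layers.
#' @slot layers list of [SimilarityMatrix-class], all over `nodeIds`.
#' @slot delta inter-layer jump probability in [0, 1).
#'
#' @seealso [MultiplexNetwork()], [buildSupraAdjacency()]
#' @exportClass MultiplexNetwork
setClass("MultiplexNetwork",
  representation(nodeIds = "character", layers = "list", delta = "numeric")
)

setValidity("MultiplexNetwork", function(object) {
  msgs <- character()
  if (length(object@layers) < 1L) msgs <- c(msgs, "need at least one layer")
  for (ly in object@layers) {
    if (!is(ly, "SimilarityMatrix")) {
      return("layers must be SimilarityMatrix objects")
    }
    if (!identical(simIds(ly), object@nodeIds)) {
      msgs <- c(msgs, "layer id ordering differs from nodeIds")
    }
  }
  d <- object@delta
  if (length(d) != 1L || d < 0 || d >= 1) msgs <- c(msgs, "delta must lie in [0, 1)")
  if (length(msgs)) unique(msgs) else TRUE
})

#' Construct a MultiplexNetwork
#'
#' @param layers list of [SimilarityMatrix-class] sharing one id ordering.
#' @param delta inter-layer jump probability in [0, 1); forced to 0 when a
#'   single layer is supplied (there is nowhere to jump).
#' @return A [MultiplexNetwork-class] object.
#' @export
MultiplexNetwork <- function(layers, delta = 0.5) {
  if (!length(layers)) stop("need at least one layer")
  if (length(layers) == 1L) delta <- 0
  new("MultiplexNetwork",
      nodeIds = simIds(layers[[1L]]), layers = layers, delta = delta)
}

#' @describeIn MultiplexNetwork Number of layers.
#' @param x a [MultiplexNetwork-class] object.
#' @export
nLayers <- function(x) length(x@layers)

setMethod("show", "MultiplexNetwork", function(object) {
  cat("MultiplexNetwork:", length(object@nodeIds), "nodes x",
      length(object@layers), "layers, delta =", object@delta, "\n")
})

#' Supra-adjacency matrix of a multiplex network
#'
#' The (n*L) x (n*L) row-stochastic matrix over all node copies. Copy
#' indexing is layer-major: copy of node i on layer a sits at row
#' (a-1)*n + i. Diagonal blocks carry (1-delta) times the row-normalized
#' layer; off-diagonal blocks are (delta/(L-1)) times the identity.
#' Nodes isolated within a layer keep their mass on their own copy.
#'
#' @slot values row-stochastic numeric matrix.
#' @slot nodeIds node identifiers (length n).
#' @slot nLayers number of layers L.
#' @slot isolated logical n x L matrix flagging isolated-in-layer nodes.
#'
#' @seealso [buildSupraAdjacency()], [buildTransitionMatrix()]
#' @exportClass SupraAdjacency
setClass("SupraAdjacency",
  representation(values = "matrix", nodeIds = "character",
                 nLayers = "integer", isolated = "matrix")
)

setValidity("SupraAdjacency", function(object) {
  v <- object@values
  n <- length(object@nodeIds)
  L <- object@nLayers
  if (nrow(v) != n * L || ncol(v) != n * L) return("size must be (nL) x (nL)")
  if (min(v) < 0) return("entries must be nonnegative")
  if (max(abs(rowSums(v) - 1)) > 1e-12) return("rows must sum to 1")
  TRUE
})

setMethod("show", "SupraAdjacency", function(object) {
  cat("SupraAdjacency:", length(object@nodeIds), "nodes x",
      object@nLayers, "layers (", nrow(object@values), "copies ),",
      sum(object@isolated), "isolated-in-layer entries\n")
})

#' Global transition matrix of the multiplex-heterogeneous network
#'
#' Row-stochastic matrix of size (nL + mK) x (nL + mK) over all lncRNA and
#' disease node copies, assembled from the two supra-adjacency matrices and
#' the replicated bipartite association matrix. The first nL rows/columns
#' are lncRNA copies (layer-major), the remaining mK are disease copies.
#'
#' @slot values row-stochastic numeric matrix.
#' @slot lncrnaIds,diseaseIds node identifiers.
#' @slot nLncLayers,nDisLayers layer counts L and K.
#' @slot lambda bipartite jump probability.
#'
#' @seealso [buildTransitionMatrix()], [rwrIterate()]
#' @exportClass TransitionMatrix
setClass("TransitionMatrix",
  representation(values = "matrix", lncrnaIds = "character",
                 diseaseIds = "character", nLncLayers = "integer",
                 nDisLayers = "integer", lambda = "numeric")
)

setValidity("TransitionMatrix", function(object) {
  v <- object@values
  sz <- length(object@lncrnaIds) * object@nLncLayers +
    length(object@diseaseIds) * object@nDisLayers
  if (nrow(v) != sz || ncol(v) != sz) return("inconsistent dimensions")
  if (min(v) < 0) return("entries must be nonnegative")
  if (max(abs(rowSums(v) - 1)) > 1e-12) return("rows must sum to 1")
  TRUE
})

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix:", length(object@lncrnaIds), "lncRNAs x",
      object@nLncLayers, "layers +", length(object@diseaseIds), "diseases x",
      object@nDisLayers, "layers =", nrow(object@values),
      "node copies; lambda =", object@lambda, "\n")
})

#' @describeIn TransitionMatrix The underlying row-stochastic matrix.
#' @param x a [TransitionMatrix-class] (or [SupraAdjacency-class]) object.
#' @export
transMatrix <- function(x) x@values

## ---------------------------------------------------------------------------
## RWRParams / ProbabilityVector / RankedPredictions
## ---------------------------------------------------------------------------

#' Random-walk-with-restart parameters
#'
#' @slot gamma restart probability in (0, 1).
#' @slot lambda bipartite (lncRNA <-> disease) jump probability in [0, 1).
#' @slot eta disease-side restart weight in (0, 1); eta < 0.5 shifts restart
#'   mass toward the lncRNA side.
#' @slot delta inter-layer jump probability in [0, 1).
#' @slot tol L1 convergence threshold.
#' @slot maxIter iteration cap.
#'
#' @seealso [RWRParams()], [predictForDisease()]
#' @exportClass RWRParams
setClass("RWRParams",
  representation(gamma = "numeric", lambda = "numeric", eta = "numeric",
                 delta = "numeric", tol = "numeric", maxIter = "integer")
)

setValidity("RWRParams", function(object) {
  msgs <- character()
  inOpen <- function(p) length(p) == 1L && is.finite(p) && p > 0 && p < 1
  if (!inOpen(object@gamma)) msgs <- c(msgs, "gamma must lie in (0, 1)")
  if (!inOpen(object@eta)) msgs <- c(msgs, "eta must lie in (0, 1)")
  if (length(object@lambda) != 1L || object@lambda < 0 || object@lambda >= 1) {
    msgs <- c(msgs, "lambda must lie in [0, 1)")
  }
  if (length(object@delta) != 1L || object@delta < 0 || object@delta >= 1) {
    msgs <- c(msgs, "delta must lie in [0, 1)")
  }
  if (object@tol <= 0) msgs <- c(msgs, "tol must be positive")
  if (object@maxIter < 1L) msgs <- c(msgs, "maxIter must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct RWRParams
#'
#' Defaults gamma = lambda = eta = 0.9 are the setting reported to perform
#' best for this walk; delta = 0.5 balances intra- and inter-layer moves.
#'
#' @param gamma restart probability in (0, 1).
#' @param lambda bipartite jump probability in [0, 1); 0 decouples the two
#'   node classes.
#' @param eta disease-side restart weight in (0, 1).
#' @param delta inter-layer jump probability in [0, 1); 0 decouples layers.
#' @param tol L1 convergence threshold.
#' @param maxIter iteration cap.
#' @return An [RWRParams-class] object.
#' @examples
#' RWRParams(gamma = 0.7)
#' @export
RWRParams <- function(gamma = 0.9, lambda = 0.9, eta = 0.9, delta = 0.5,
                      tol = 1e-10, maxIter = 10000L) {
  new("RWRParams", gamma = gamma, lambda = lambda, eta = eta, delta = delta,
      tol = tol, maxIter = as.integer(maxIter))
}

setMethod("show", "RWRParams", function(object) {
  cat(sprintf(
    "RWRParams: gamma=%g lambda=%g eta=%g delta=%g tol=%g maxIter=%d\n",
    object@gamma, object@lambda, object@eta, object@delta, object@tol,
    object@maxIter))
})

#' Probability vector over all node copies
#'
#' A nonnegative vector of length nL + mK summing to 1: the first nL entries
#' are lncRNA copies (layer-major), the last mK are disease copies.
#'
#' @slot values nonnegative numeric vector.
#' @slot lncrnaIds,diseaseIds entity identifiers.
#' @slot nLncLayers,nDisLayers layer counts.
#'
#' @seealso [buildRestartVector()], [rwrIterate()], [aggregateScores()]
#' @exportClass ProbabilityVector
setClass("ProbabilityVector",
  representation(values = "numeric", lncrnaIds = "character",
                 diseaseIds = "character", nLncLayers = "integer",
                 nDisLayers = "integer")
)

setValidity("ProbabilityVector", function(object) {
  v <- object@values
  sz <- length(object@lncrnaIds) * object@nLncLayers +
    length(object@diseaseIds) * object@nDisLayers
  if (length(v) != sz) return("length must equal nL + mK")
  if (min(v) < 0) return("entries must be nonnegative")
  if (abs(sum(v) - 1) > 1e-9) return("entries must sum to 1 (tol 1e-9)")
  TRUE
})

setMethod("show", "ProbabilityVector", function(object) {
  nL <- length(object@lncrnaIds) * object@nLncLayers
  cat("ProbabilityVector over", length(object@values), "node copies;",
      "lncRNA-side mass", signif(sum(object@values[seq_len(nL)]), 4), "\n")
})

#' @describeIn ProbabilityVector The raw numeric vector.
#' @param x a [ProbabilityVector-class] object.
#' @export
probValues <- function(x) x@values

#' Ranked candidate predictions
#'
#' @slot query the query disease (or lncRNA) identifier.
#' @slot side `"lncrna"` when lncRNAs are ranked for a disease query,
#'   `"disease"` for the mirror direction.
#' @slot ranking data.frame with columns `rank`, `candidate`, `score`,
#'   descending in score.
#' @slot excluded seed identifiers removed before ranking.
#'
#' @seealso [predictForDisease()], [predictForLncrna()], [writePredictions()]
#' @exportClass RankedPredictions
setClass("RankedPredictions",
  representation(query = "character", side = "character",
                 ranking = "data.frame", excluded = "character")
)

setValidity("RankedPredictions", function(object) {
  r <- object@ranking
  if (!all(c("rank", "candidate", "score") %in% names(r))) {
    return("ranking needs columns rank, candidate, score")
  }
  if (nrow(r) > 1L && any(diff(r$score) > 1e-15)) {
    return("scores must be non-increasing")
  }
  if (any(r$candidate %in% object@excluded)) {
    return("excluded ids must not appear in the ranking")
  }
  TRUE
})

setMethod("show", "RankedPredictions", function(object) {
  cat("RankedPredictions for", object@side == "lncrna", "\n")
})

setMethod("show", "RankedPredictions", function(object) {
  what <- if (object@side == "lncrna") "lncRNAs" else "diseases"
  cat("RankedPredictions:", nrow(object@ranking), what, "ranked for query",
      sQuote(object@query), "(", length(object@excluded), "seeds removed )\n")
  print(utils::head(object@ranking, 5L), row.names = FALSE)
})

#' @describeIn RankedPredictions The ranking as a data.frame.
#' @param x a [RankedPredictions-class] object.
#' @export
predRanking <- function(x) x@ranking

## ---------------------------------------------------------------------------
## EvaluationResult
## ---------------------------------------------------------------------------

#' LOOCV evaluation result
#'
#' @slot mode `"global"` or `"local"`.
#' @slot folds data.frame with one row per held-out association: the lncRNA,
#'   the disease, the held-out score and the number/summary of candidates.
#' @slot candidateScores list (per fold) of candidate score vectors.
#' @slot roc data.frame of ROC curve points (fpr, tpr).
#' @slot auc area under the ROC curve.
#' @slot pr data.frame of precision-recall points (recall, precision).
#' @slot aupr area under the PR curve (step rule).
#' @slot params list of the parameters used.
#'
#' @seealso [loocv()], [rocAuc()], [prAupr()]
#' @exportClass EvaluationResult
setClass("EvaluationResult",
  representation(mode = "character", folds = "data.frame",
                 candidateScores = "list", roc = "data.frame",
                 auc = "numeric", pr = "data.frame", aupr = "numeric",
                 params = "list")
)

setValidity("EvaluationResult", function(object) {
  msgs <- character()
  if (!object@mode %in% c("global", "local")) {
    msgs <- c(msgs, "mode must be 'global' or 'local'")
  }
  if (object@auc < 0 || object@auc > 1) msgs <- c(msgs, "auc outside [0, 1]")
  if (object@aupr < 0 || object@aupr > 1) msgs <- c(msgs, "aupr outside [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult (%s LOOCV): %d folds, AUC = %.5f, AUPR = %.5f\n",
              object@mode, nrow(object@folds), object@auc, object@aupr))
})
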