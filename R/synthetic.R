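## Seeded synthetic fixtures: random rooted ontologies, cluster-structured
## bipartite association matrices, and a planted-structure recovery
## benchmark. All generators are pure functions of (spec, seed): the same
## seed reproduces the same objects bit for bit (Mersenne-Twister via R's
## default RNG, restored on exit).

#' Specification of a synthetic benchmark
#'
#' @param nLncrnas,mDiseases bipartite dimensions.
#' @param nTerms number of ontology terms.
#' @param nClusters number of planted co-clusters; lncRNAs and diseases are
#'   partitioned contiguously into matching blocks.
#' @param withinDensity edge probability inside a co-cluster.
#' @param crossDensity edge probability outside; for a planted benchmark it
#'   must be below `withinDensity` (equal densities give the structureless
#'   control).
#' @param rngSeed integer seed making the generators deterministic.
#' @return A list of class `SyntheticSpec`.
#' @examples
#' syntheticSpec(nLncrnas = 10, mDiseases = 8, nClusters = 2, rngSeed = 7)
#' @export
syntheticSpec <- function(nLncrnas = 30L, mDiseases = 30L, nTerms = 40L,
                          nClusters = 3L, withinDensity = 0.6,
                          crossDensity = 0.02, rngSeed = 1L) {
  if (withinDensity <= 0 || withinDensity > 1 || crossDensity < 0 ||
      crossDensity > 1) {
    stop("densities must lie in (0, 1]")
  }
  structure(list(nLncrnas = as.integer(nLncrnas),
                 mDiseases = as.integer(mDiseases),
                 nTerms = as.integer(nTerms),
                 nClusters = as.integer(nClusters),
                 withinDensity = withinDensity,
                 crossDensity = crossDensity,
                 rngSeed = as.integer(rngSeed),
                 rngKind = "Mersenne-Twister"),
            class = "SyntheticSpec")
}

## evaluate `expr` under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Generate a random rooted ontology DAG
#'
#' Terms are added in order t1, t2, ...; each term after the first picks one
#' or two parents uniformly among the earlier terms, so the graph is acyclic
#' by construction and rooted at t1.
#'
#' @param spec a [syntheticSpec()].
#' @return An [OntologyDAG-class].
#' @export
generateDag <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"), spec$nTerms >= 1L)
  nT <- spec$nTerms
  termIds <- paste0("t", seq_len(nT))
  .withSeed(spec$rngSeed + 101L, {
    edges <- NULL
    for (i in seq_len(nT)[-1]) {
      nPar <- sample(1:2, 1L)
      parents <- sample(seq_len(i - 1L), min(nPar, i - 1L))
      edges <- rbind(edges, cbind(termIds[i], termIds[parents]))
    }
    OntologyDAG(edges, terms = termIds)
  })
}

#' Map diseases onto ontology terms
#'
#' Assigns each disease a uniformly random term of the generated ontology.
#'
#' @param spec a [syntheticSpec()].
#' @param dag the [OntologyDAG-class] to map into.
#' @return Named character vector disease id -> term id.
#' @export
generateMapping <- function(spec, dag) {
  dIds <- paste0("d", seq_len(spec$mDiseases))
  .withSeed(spec$rngSeed + 202L, {
    stats::setNames(sample(ontoTerms(dag), spec$mDiseases, replace = TRUE),
                    dIds)
  })
}

#' Generate a cluster-structured association matrix
#'
#' lncRNAs and diseases are partitioned contiguously into `nClusters`
#' matching co-clusters; a pair inside a co-cluster is associated with
#' probability `withinDensity`, outside with `crossDensity`. Every lncRNA
#' and disease is guaranteed at least one association (empty rows/columns
#' are resampled, with a bounded number of attempts), so the GIP kernels
#' are always well defined.
#'
#' @param spec a [syntheticSpec()].
#' @return An [AssociationMatrix-class].
#' @export
generateAssociations <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$nLncrnas; m <- spec$mDiseases; nc <- spec$nClusters
  lClust <- sort(rep(seq_len(nc), length.out = n))
  dClust <- sort(rep(seq_len(nc), length.out = m))
  pMat <- ifelse(outer(lClust, dClust, "=="), spec$withinDensity,
                 spec$crossDensity)
  .withSeed(spec$rngSeed + 303L, {
    B <- matrix(as.numeric(stats::runif(n * m) < pMat), n, m)
    for (attempt in seq_len(200L)) {
      emptyRow <- which(rowSums(B) == 0)
      emptyCol <- which(colSums(B) == 0)
      if (!length(emptyRow) && !length(emptyCol)) break
      for (i in emptyRow) {
        B[i, ] <- as.numeric(stats::runif(m) < pMat[i, ])
      }
      for (j in emptyCol) {
        B[, j] <- as.numeric(stats::runif(n) < pMat[, j])
      }
    }
    if (any(rowSums(B) == 0) || any(colSums(B) == 0)) {
      stop("could not guarantee nonempty profiles: densities too low for ",
           "this matrix size")
    }
    dimnames(B) <- list(paste0("l", seq_len(n)), paste0("d", seq_len(m)))
    AssociationMatrix(B)
  })
}

#' Planted-structure recovery benchmark
#'
#' Generates a cluster-structured association matrix plus an ontology with
#' a random disease mapping, runs global (or local) LOOCV with the full
#' four-layer walk, and returns the evaluation. Serves as a statistical
#' gate: a working walk must recover the planted co-clusters well above
#' chance, while the structureless control (within = cross density)
#' stays near 0.5.
#'
#' @param spec a [syntheticSpec()].
#' @param params an [RWRParams-class].
#' @param mode LOOCV pooling mode.
#' @param recomputeSimilarity per-fold layer refit, default TRUE.
#' @return An [EvaluationResult-class].
#' @export
benchmarkRecovery <- function(spec, params = RWRParams(),
                              mode = c("global", "local"),
                              recomputeSimilarity = TRUE) {
  mode <- match.arg(mode)
  dag <- generateDag(spec)
  termOf <- generateMapping(spec, dag)
  LD <- generateAssociations(spec)
  loocv(LD, params, dag = dag, termOf = termOf, mode = mode,
        recomputeSimilarity = recomputeSimilarity)
}
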