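## Fixture builders and independent brute-force oracles. The oracles follow
## the defining formulas directly (recursion, pair enumeration, dense
## solves) and never call the implementation paths they check.

makeLD <- function(mat, lnc = NULL, dis = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- lnc %||% paste0("l", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- dis %||% paste0("d", seq_len(ncol(mat)))
  AssociationMatrix(mat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## random association matrix with guaranteed nonempty rows and columns
randomLD <- function(n, m, density = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    B <- matrix(rbinom(n * m, 1, density), n, m)
    if (all(rowSums(B) > 0) && all(colSums(B) > 0)) break
  }
  dimnames(B) <- list(paste0("l", seq_len(n)), paste0("d", seq_len(m)))
  AssociationMatrix(B)
}

chainDag <- function() OntologyDAG(rbind(c("c", "b"), c("b", "a")))
diamondDag <- function() OntologyDAG(rbind(c("c", "b1"), c("c", "b2"),
                                           c("b1", "a"), c("b2", "a")))

## random similarity matrix (symmetric, [0,1], unit diagonal)
randomSim <- function(ids, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  v <- matrix(runif(n * n), n)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  dimnames(v) <- list(ids, ids)
  SimilarityMatrix(v)
}

## --- brute-force oracles ---------------------------------------------------

## semantic contributions by literal recursion over the ancestor closure
oracleContrib <- function(dag, term, decay = 0.5) {
  pe <- parentEdges(dag)
  closure <- term
  frontier <- term
  while (length(frontier)) {
    frontier <- unique(unlist(pe[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, closure)
    closure <- c(closure, frontier)
  }
  childrenIn <- function(k) {
    kids <- names(pe)[vapply(pe, function(p) k %in% p, logical(1))]
    intersect(kids, closure)
  }
  memo <- new.env()
  rec <- function(k) {
    if (!is.null(memo[[k]])) return(memo[[k]])
    val <- if (k == term) 1 else decay * max(vapply(childrenIn(k), rec, numeric(1)))
    memo[[k]] <- val
    val
  }
  setNames(vapply(closure, rec, numeric(1)), closure)
}

oracleDSS <- function(dag, termOf, decay = 0.5) {
  ids <- names(termOf)
  maps <- lapply(termOf, function(t) oracleContrib(dag, t, decay))
  m <- diag(1, length(ids)); dimnames(m) <- list(ids, ids)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    mi <- maps[[i]]; mj <- maps[[j]]
    sh <- intersect(names(mi), names(mj))
    m[i, j] <- if (length(sh)) (sum(mi[sh]) + sum(mj[sh])) / (sum(mi) + sum(mj)) else 0
  }
  m
}

oracleGIP <- function(B, side, gammaPrime = 1) {
  prof <- if (side == "lncrna") B else t(B)
  gamma <- gammaPrime / mean(rowSums(prof^2))
  n <- nrow(prof)
  k <- matrix(NA_real_, n, n, dimnames = list(rownames(prof), rownames(prof)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k[i, j] <- exp(-gamma * sum((prof[i, ] - prof[j, ])^2))
  }
  k
}

oracleNFS <- function(B, DSS) {
  n <- nrow(B)
  out <- diag(1, n); dimnames(out) <- list(rownames(B), rownames(B))
  SS <- function(d, D) if (length(D)) max(DSS[d, D]) else 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    Di <- colnames(B)[B[i, ] == 1]; Dj <- colnames(B)[B[j, ] == 1]
    out[i, j] <- if (!length(Di) || !length(Dj)) 0 else
      (sum(vapply(Di, SS, numeric(1), D = Dj)) +
       sum(vapply(Dj, SS, numeric(1), D = Di))) / (length(Di) + length(Dj))
  }
  out
}

## AUC by exhaustive positive-candidate pair enumeration (half-credit ties)
oracleAucPairs <- function(pos, cand) {
  wins <- 0
  for (p in pos) for (c in cand) {
    wins <- wins + (p > c) + 0.5 * (p == c)
  }
  wins / (length(pos) * length(cand))
}

## stationary distribution by direct dense linear solve of the restart walk
oracleStationary <- function(H, pRS, gamma) {
  Hm <- if (is(H, "TransitionMatrix")) transMatrix(H) else H
  p0 <- if (is(pRS, "ProbabilityVector")) probValues(pRS) else pRS
  n <- nrow(Hm)
  as.vector(gamma * solve(diag(n) - (1 - gamma) * t(Hm), p0))
}

## small end-to-end fixture shared by several tests
smallFixture <- function(seed = 3, n = 8, m = 6) {
  spec <- syntheticSpec(nLncrnas = n, mDiseases = m, nTerms = 12,
                        nClusters = 2, withinDensity = 0.7,
                        crossDensity = 0.1, rngSeed = seed)
  dag <- generateDag(spec)
  termOf <- generateMapping(spec, dag)
  LD <- generateAssociations(spec)
  list(spec = spec, dag = dag, termOf = termOf, LD = LD,
       layers = buildSimilarityLayers(LD, dag, termOf))
}

## directly assembled classic two-network heterogeneous RWR transition
## matrix (single similarity layer per side), written independently of the
## multiplex construction
classicHetTransition <- function(Wl, Wd, B, lambda) {
  rowNorm <- function(W) {
    diag(W) <- 0
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, ] / rs[rs > 0]
    iso <- which(rs == 0)
    W[cbind(iso, iso)] <- 1
    W
  }
  Sl <- rowNorm(Wl); Sd <- rowNorm(Wd)
  n <- nrow(B); m <- ncol(B)
  H <- matrix(0, n + m, n + m)
  for (i in seq_len(n)) {
    deg <- sum(B[i, ])
    if (deg == 0) {
      H[i, seq_len(n)] <- Sl[i, ]
    } else {
      H[i, seq_len(n)] <- (1 - lambda) * Sl[i, ]
      H[i, n + seq_len(m)] <- lambda * B[i, ] / deg
    }
  }
  for (j in seq_len(m)) {
    deg <- sum(B[, j])
    if (deg == 0) {
      H[n + j, n + seq_len(m)] <- Sd[j, ]
    } else {
      H[n + j, n + seq_len(m)] <- (1 - lambda) * Sd[j, ]
      H[n + j, seq_len(n)] <- lambda * B[, j] / deg
    }
  }
  H
}
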