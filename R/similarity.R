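## Similarity layers: ontology semantic similarity for diseases, Gaussian
## interaction profile (GIP) kernels for both sides, and lncRNA functional
## similarity from shared disease annotations.

## child edges (parent -> children) derived from the stored parent edges
.childEdges <- function(dag) {
  pe <- parentEdges(dag)
  if (!length(pe)) return(list())
  child <- rep(names(pe), lengths(pe))
  parent <- unlist(pe, use.names = FALSE)
  split(child, factor(parent, levels = unique(parent)))
}

## ancestor closure of a term (excluding the term itself)
.ancestors <- function(dag, term) {
  pe <- parentEdges(dag)
  seen <- character()
  frontier <- pe[[term]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(pe[frontier], use.names = FALSE))
  }
  seen
}

#' Semantic contributions of a term's ancestors
#'
#' For an ontology term, every ancestor contributes to the term's semantic
#' value: the term itself contributes 1, and each ancestor contributes
#' `decay` times the largest contribution among its children inside the
#' term's ancestor closure. Contributions therefore decay geometrically with
#' distance from the term and are combined by max under multiple inheritance.
#'
#' @param dag an [OntologyDAG-class].
#' @param term a term identifier present in `dag`.
#' @param decay decay factor per generation, in (0, 1); default 0.5.
#' @return Named numeric vector of contributions over the term and its
#'   ancestors; the entry for `term` is 1.
#' @examples
#' dag <- OntologyDAG(rbind(c("c", "b"), c("b", "a")))
#' semanticContributions(dag, "c")  # c = 1, b = 0.5, a = 0.25
#' @export
semanticContributions <- function(dag, term, decay = 0.5) {
  if (!term %in% ontoTerms(dag)) stop("term not in ontology: ", term)
  if (length(decay) != 1L || !is.finite(decay) || decay <= 0 || decay >= 1) {
    stop("decay must lie in (0, 1)")
  }
  closure <- c(term, .ancestors(dag, term))
  ce <- .childEdges(dag)
  contrib <- c(1)
  names(contrib) <- term
  ## process ancestors in order of increasing distance from the term:
  ## repeatedly relax until fixed (closure is small; DAG guarantees halt)
  pending <- setdiff(closure, term)
  while (length(pending)) {
    progressed <- FALSE
    for (k in pending) {
      kids <- intersect(ce[[k]], closure)
      if (all(kids %in% names(contrib))) {
        contrib[k] <- decay * max(contrib[kids])
        pending <- setdiff(pending, k)
        progressed <- TRUE
      }
    }
    if (!progressed) stop("ontology graph contains a cycle near term ", term)
  }
  contrib[closure]
}

#' Disease semantic similarity from an ontology
#'
#' Pairwise similarity of diseases from the semantic contributions of their
#' mapped ontology terms: the contributions of shared ancestors, summed for
#' both diseases, divided by the two total semantic values. Diseases mapped
#' to the same term get similarity 1; diseases without an ontology mapping
#' get similarity 0 to every other disease and 1 to themselves (the GIP
#' layer still covers them).
#'
#' @param dag an [OntologyDAG-class].
#' @param termOf named character vector mapping disease ids to term ids;
#'   diseases absent from it (or mapped to `NA`) are treated as unmapped.
#' @param diseaseIds ordered disease identifiers for the output matrix;
#'   defaults to `names(termOf)`.
#' @param decay semantic decay factor, default 0.5.
#' @return A [SimilarityMatrix-class] over `diseaseIds`.
#' @export
diseaseSemanticSimilarity <- function(dag, termOf, diseaseIds = names(termOf),
                                      decay = 0.5) {
  if (!length(diseaseIds)) stop("empty disease list")
  termOf <- termOf[!is.na(termOf)]
  unknown <- setdiff(termOf, ontoTerms(dag))
  if (length(unknown)) {
    stop("mapped term(s) not in ontology: ", paste(unknown, collapse = ", "))
  }
  mapped <- intersect(diseaseIds, names(termOf))
  ## contribution maps memoized by term (several diseases may share a term)
  uniqTerms <- unique(unname(termOf[mapped]))
  maps <- lapply(uniqTerms, function(t) semanticContributions(dag, t, decay))
  names(maps) <- uniqTerms
  m <- length(diseaseIds)
  dss <- diag(1, m)
  dimnames(dss) <- list(diseaseIds, diseaseIds)
  if (length(mapped) >= 2L) {
    tot <- vapply(maps, sum, numeric(1))
    for (ii in seq_along(mapped)[-length(mapped)]) {
      for (jj in seq((ii + 1L), length(mapped))) {
        di <- mapped[ii]; dj <- mapped[jj]
        mi <- maps[[termOf[[di]]]]; mj <- maps[[termOf[[dj]]]]
        shared <- intersect(names(mi), names(mj))
        val <- if (length(shared)) {
          (sum(mi[shared]) + sum(mj[shared])) /
            (tot[[termOf[[di]]]] + tot[[termOf[[dj]]]])
        } else 0
        dss[di, dj] <- dss[dj, di] <- val
      }
    }
  }
  SimilarityMatrix(dss)
}

#' Gaussian interaction profile kernel bandwidth
#'
#' The kernel bandwidth gamma is the reference bandwidth gamma' divided by
#' the mean squared Euclidean norm of the interaction profiles, making gamma
#' dimensionless and the kernel scale-free in the profile density.
#'
#' @param profiles numeric matrix, one profile per row (or a list of equal
#'   length vectors).
#' @param gammaPrime positive reference bandwidth, default 1.
#' @return The bandwidth gamma (positive scalar).
#' @examples
#' gipBandwidth(diag(2))  # unit-norm profiles: gamma = 1
#' @export
gipBandwidth <- function(profiles, gammaPrime = 1) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (!is.matrix(profiles) || nrow(profiles) < 1L) stop("need at least one profile")
  if (length(gammaPrime) != 1L || gammaPrime <= 0) {
    stop("gammaPrime must be positive")
  }
  meanSq <- mean(rowSums(profiles^2))
  if (meanSq == 0) stop("degenerate profiles: bandwidth undefined")
  gammaPrime / meanSq
}

#' Gaussian interaction profile kernel similarity
#'
#' Kernel similarity exp(-gamma * ||IP_i - IP_j||^2) between the binary
#' interaction profiles of lncRNAs (rows of the association matrix) or
#' diseases (columns), with the bandwidth from [gipBandwidth()].
#'
#' @param LD an [AssociationMatrix-class].
#' @param side `"lncrna"` (profiles are rows) or `"disease"` (columns).
#' @param gammaPrime reference bandwidth, default 1.
#' @return A [SimilarityMatrix-class] over the chosen side's ids.
#' @examples
#' m <- diag(2); dimnames(m) <- list(c("l1", "l2"), c("d1", "d2"))
#' simMatrix(gipSimilarity(AssociationMatrix(m), "disease"))
#' @export
gipSimilarity <- function(LD, side = c("lncrna", "disease"), gammaPrime = 1) {
  side <- match.arg(side)
  prof <- if (side == "lncrna") assocMatrix(LD) else t(assocMatrix(LD))
  gamma <- gipBandwidth(prof, gammaPrime)
  sq <- rowSums(prof^2)
  ## ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(prof)
  d2[d2 < 0] <- 0
  k <- exp(-gamma * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  SimilarityMatrix(k)
}

#' Similarity between a disease and a disease set
#'
#' The best semantic match of disease `d` within the set `D`: the maximum of
#' the pairwise semantic similarities. An empty set has no evidence to offer
#' and scores 0.
#'
#' @param d a disease identifier indexed in `DSS`.
#' @param D character vector of disease identifiers (may be empty).
#' @param DSS a [SimilarityMatrix-class] of disease semantic similarities.
#' @return A number in [0, 1].
#' @export
lncrnaSetSimilarity <- function(d, D, DSS) {
  ids <- simIds(DSS)
  if (!d %in% ids) stop("disease not indexed in DSS: ", d)
  if (!length(D)) return(0)
  bad <- setdiff(D, ids)
  if (length(bad)) stop("disease not indexed in DSS: ", paste(bad, collapse = ", "))
  max(simMatrix(DSS)[d, D])
}

#' lncRNA functional similarity from shared disease annotations
#'
#' Two lncRNAs are functionally similar when the disease sets they are
#' associated with are semantically similar: each disease of either set is
#' matched to its best counterpart in the other set, and the matches are
#' averaged over both sets. lncRNAs with no associated disease score 0
#' against every other lncRNA (and 1 to themselves).
#'
#' @param LD an [AssociationMatrix-class].
#' @param DSS a [SimilarityMatrix-class] indexed by (at least) the diseases
#'   of `LD`.
#' @return A [SimilarityMatrix-class] over the lncRNA ids.
#' @export
lncrnaFunctionalSimilarity <- function(LD, DSS) {
  B <- assocMatrix(LD)
  dIds <- diseaseIds(LD)
  missing <- setdiff(dIds, simIds(DSS))
  if (length(missing)) {
    stop("disease(s) absent from DSS: ", paste(missing, collapse = ", "))
  }
  S <- simMatrix(DSS)[dIds, dIds, drop = FALSE]
  n <- nrow(B)
  deg <- rowSums(B)
  ## bestMatch[a, j] = max_{b in D_j} DSS(a, b); 0 when D_j is empty
  bestMatch <- matrix(0, nrow = length(dIds), ncol = n,
                      dimnames = list(dIds, rownames(B)))
  for (j in seq_len(n)) {
    Dj <- dIds[B[j, ] == 1]
    if (length(Dj)) bestMatch[, j] <- do.call(pmax, as.data.frame(S[, Dj, drop = FALSE]))
  }
  ## numerator(i, j) = sum_{a in D_i} best(a, D_j) + sum_{b in D_j} best(b, D_i)
  half <- B %*% bestMatch
  num <- half + t(half)
  den <- outer(deg, deg, "+")
  nfs <- matrix(0, n, n, dimnames = list(rownames(B), rownames(B)))
  ok <- deg > 0
  pos <- outer(ok, ok, "&")
  nfs[pos] <- num[pos] / den[pos]
  nfs[nfs > 1] <- 1
  nfs <- (nfs + t(nfs)) / 2
  diag(nfs) <- 1
  SimilarityMatrix(nfs)
}

#' Build the default similarity layers for the walk
#'
#' Convenience wrapper assembling the lncRNA layers (functional similarity,
#' GIP kernel) and disease layers (ontology semantic similarity, GIP kernel)
#' from an association matrix and optional ontology inputs. Individual
#' layers can be switched off; at least one layer per side must remain.
#'
#' @param LD an [AssociationMatrix-class].
#' @param dag optional [OntologyDAG-class]; without it the semantic and
#'   functional layers fall back to GIP-only configurations.
#' @param termOf named disease-to-term mapping (see
#'   [diseaseSemanticSimilarity()]).
#' @param decay semantic decay factor.
#' @param gammaPrime GIP reference bandwidth.
#' @param useFunctional,useLncGip,useSemantic,useDisGip logical layer
#'   switches.
#' @return List with elements `lncrna` and `disease`, each a named list of
#'   [SimilarityMatrix-class] layers.
#' @export
buildSimilarityLayers <- function(LD, dag = NULL, termOf = NULL, decay = 0.5,
                                  gammaPrime = 1, useFunctional = TRUE,
                                  useLncGip = TRUE, useSemantic = TRUE,
                                  useDisGip = TRUE) {
  haveOnto <- !is.null(dag) && !is.null(termOf)
  dis <- list()
  if (useSemantic && haveOnto) {
    dis$semantic <- diseaseSemanticSimilarity(dag, termOf,
                                              diseaseIds = diseaseIds(LD),
                                              decay = decay)
  }
  if (useDisGip) dis$gip <- gipSimilarity(LD, "disease", gammaPrime)
  lnc <- list()
  if (useFunctional) {
    DSS <- if (useSemantic && haveOnto) dis$semantic else gipSimilarity(LD, "disease", gammaPrime)
    lnc$functional <- lncrnaFunctionalSimilarity(LD, DSS)
  }
  if (useLncGip) lnc$gip <- gipSimilarity(LD, "lncrna", gammaPrime)
  if (!length(lnc) || !length(dis)) {
    stop("at least one lncRNA layer and one disease layer must be enabled")
  }
  list(lncrna = lnc, disease = dis)
}
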