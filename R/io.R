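## Readers and writers for the plain-text interchange formats: association
## edge lists, ontologies (2-column TSV or a minimal is_a-only OBO subset),
## disease-to-term mappings, square similarity matrices and prediction
## tables. Identifier matching everywhere is exact-string and
## case-sensitive.

#' Read a lncRNA-disease association list
#'
#' Two tab-separated columns, `lncRNA_id<TAB>disease_id`, one association
#' per line, optional header. Duplicate edges are kept once (with a
#' message); identifiers are ordered by first appearance.
#'
#' @param path TSV file path.
#' @param header logical; skip a header line (default FALSE).
#' @return An [AssociationMatrix-class].
#' @export
readAssociations <- function(path, header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no associations in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed association line ", bad[1L] + header, " in ", path)
  }
  l <- vapply(parts, `[[`, character(1), 1L)
  d <- vapply(parts, `[[`, character(1), 2L)
  dup <- duplicated(paste0(l, "\r", d))
  if (any(dup)) {
    message(sum(dup), " duplicate association(s) in ", path, "; kept once")
    l <- l[!dup]; d <- d[!dup]
  }
  lIds <- unique(l); dIds <- unique(d)
  B <- matrix(0, length(lIds), length(dIds), dimnames = list(lIds, dIds))
  B[cbind(match(l, lIds), match(d, dIds))] <- 1
  AssociationMatrix(B)
}

#' Write an association matrix as an edge list
#'
#' @param LD an [AssociationMatrix-class].
#' @param path output TSV path.
#' @export
writeAssociations <- function(LD, path) {
  B <- assocMatrix(LD)
  idx <- which(B == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  writeLines(paste(rownames(B)[idx[, 1L]], colnames(B)[idx[, 2L]],
                   sep = "\t"), path)
  invisible(path)
}

## minimal OBO stanza reader: [Term] blocks, id: and is_a: tags only.
## Other relationship types are ignored with a single warning.
.readObo <- function(path) {
  lines <- trimws(readLines(path))
  inTerm <- FALSE
  id <- NULL
  child <- parent <- character()
  otherRel <- 0L
  terms <- character()
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      inTerm <- identical(ln, "[Term]")
      id <- NULL
    } else if (inTerm && startsWith(ln, "id:")) {
      id <- trimws(sub("^id:", "", ln))
      terms <- c(terms, id)
    } else if (inTerm && startsWith(ln, "is_a:")) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      if (!is.null(id)) {
        child <- c(child, id)
        parent <- c(parent, p)
      }
    } else if (inTerm && startsWith(ln, "relationship:")) {
      otherRel <- otherRel + 1L
    }
  }
  if (otherRel > 0L) {
    warning(otherRel, " non-is_a relationship line(s) ignored in ", path)
  }
  list(edges = cbind(child, parent), terms = unique(terms))
}

#' Read a disease ontology
#'
#' Either a 2-column TSV of `child<TAB>parent` term pairs or an OBO file
#' restricted to its `is_a` hierarchy (other relationship types are ignored
#' with a warning). Cyclic inputs are rejected.
#'
#' @param path file path.
#' @param format `"tsv"` or `"obo"`; `"auto"` (default) decides by file
#'   extension.
#' @return An [OntologyDAG-class].
#' @export
readOntology <- function(path, format = c("auto", "tsv", "obo")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.obo$", path, ignore.case = TRUE)) "obo" else "tsv"
  }
  if (format == "obo") {
    parsed <- .readObo(path)
    edges <- parsed$edges
    extraTerms <- parsed$terms
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) stop("malformed ontology line ", bad[1L], " in ", path)
    edges <- cbind(vapply(parts, `[[`, character(1), 1L),
                   vapply(parts, `[[`, character(1), 2L))
    extraTerms <- NULL
  }
  if (NROW(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(which(comp$membership == which(comp$csize > 1L)[1L]))[1L]
      stop("ontology contains a cycle (involving term ", cyc, ")")
    }
  }
  OntologyDAG(edges, terms = extraTerms)
}

#' Read a disease-to-term mapping
#'
#' Two tab-separated columns `disease_id<TAB>term_id`, optional header.
#'
#' @param path TSV file path.
#' @param header logical; skip a header line.
#' @return Named character vector disease id -> term id.
#' @export
readMapping <- function(path, header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed mapping line ", bad[1L] + header, " in ", path)
  stats::setNames(vapply(parts, `[[`, character(1), 2L),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Write a similarity matrix as TSV
#'
#' Square matrix with an id header row and id first column; values at full
#' double precision.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param path output path.
#' @export
writeSimilarity <- function(sim, path) {
  v <- simMatrix(sim)
  df <- data.frame(id = rownames(v),
                   format(v, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix from TSV
#'
#' @param path file written by [writeSimilarity()] (id header row and
#'   column).
#' @return A [SimilarityMatrix-class].
#' @export
readSimilarity <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA)
  ids <- as.character(df[[1L]])
  v <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  dimnames(v) <- list(ids, ids)
  SimilarityMatrix(v)
}

#' Write ranked predictions as TSV
#'
#' Columns `rank`, `candidate`, `score` (full precision); an empty ranking
#' produces a header-only file.
#'
#' @param pred a [RankedPredictions-class].
#' @param path output path.
#' @export
writePredictions <- function(pred, path) {
  r <- predRanking(pred)
  lines <- c("rank\tcandidate\tscore",
             if (nrow(r)) sprintf("%d\t%s\t%.17g", r$rank, r$candidate, r$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read a predictions TSV back
#'
#' @param path file written by [writePredictions()].
#' @return data.frame with columns rank, candidate, score.
#' @export
readPredictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("integer", "character", "numeric"))
}
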