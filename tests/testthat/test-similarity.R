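test_that("semantic contributions decay along the ancestor hierarchy", {
  dag <- chainDag()
  expect_identical(semanticContributions(dag, "c"),
                   c(c = 1, b = 0.5, a = 0.25))
  ## the queried term always contributes 1, for any decay
  expect_equal(semanticContributions(dag, "a", decay = 0.3), c(a = 1))
  ## diamond: two equal 0.5-children both propose 0.25 for the shared root
  contribs <- semanticContributions(diamondDag(), "c")
  expect_equal(unname(contribs["a"]), 0.25)
  ## a pure chain gives exactly decay^depth
  deep <- OntologyDAG(cbind(paste0("t", 2:6), paste0("t", 1:5)))
  expect_equal(unname(semanticContributions(deep, "t6", 0.4)),
               0.4^(0:5))
})

test_that("semantic contribution inputs are validated", {
  dag <- chainDag()
  expect_error(semanticContributions(dag, "zz"), "not in ontology")
  expect_error(semanticContributions(dag, "c", decay = 1), "decay")
  expect_error(semanticContributions(dag, "c", decay = 0), "decay")
})

test_that("disease semantic similarity matches hand-evaluated cases", {
  ## shared root with two children: maps {a:1, r:0.5} and {b:1, r:0.5}
  dag <- OntologyDAG(rbind(c("a", "r"), c("b", "r")))
  dss <- diseaseSemanticSimilarity(dag, c(d1 = "a", d2 = "b"))
  expect_equal(simMatrix(dss)["d1", "d2"], 1 / 3)
  ## identical terms are maximally similar
  dss2 <- diseaseSemanticSimilarity(dag, c(d1 = "a", d2 = "a"))
  expect_equal(simMatrix(dss2)["d1", "d2"], 1)
  ## disjoint components share no ancestor
  dag3 <- OntologyDAG(rbind(c("a1", "r1"), c("a2", "r2")))
  dss3 <- diseaseSemanticSimilarity(dag3, c(d1 = "r1", d2 = "r2"))
  expect_equal(simMatrix(dss3)["d1", "d2"], 0)
})

test_that("unmapped diseases fall back to zero off-diagonal, one on-diagonal", {
  dag <- chainDag()
  dss <- diseaseSemanticSimilarity(dag, c(d1 = "c", d2 = "b"),
                                   diseaseIds = c("d1", "d2", "d3"))
  v <- simMatrix(dss)
  expect_equal(v["d3", "d3"], 1)
  expect_equal(unname(v["d3", c("d1", "d2")]), c(0, 0))
  expect_error(diseaseSemanticSimilarity(dag, c(d1 = "c"), character()),
               "empty")
  expect_error(diseaseSemanticSimilarity(dag, c(d1 = "nope")), "not in ontology")
})

test_that("GIP bandwidth is gammaPrime over the mean squared profile norm", {
  expect_equal(gipBandwidth(diag(2)), 1)
  expect_equal(gipBandwidth(matrix(1, 2, 2)), 1 / 2)
  expect_equal(gipBandwidth(rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, 1))), 0.5)
  expect_error(gipBandwidth(matrix(0, 2, 3)), "degenerate")
  expect_error(gipBandwidth(diag(2), gammaPrime = -1), "positive")
})

test_that("GIP similarity matches the kernel formula", {
  LD <- makeLD(diag(2))
  k <- simMatrix(gipSimilarity(LD, "disease"))
  expect_equal(k["d1", "d2"], exp(-2))
  expect_equal(diag(k), c(d1 = 1, d2 = 1))
  ## identical profiles are maximally similar
  B <- makeLD(cbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0)))
  k2 <- simMatrix(gipSimilarity(B, "disease"))
  expect_equal(k2["d1", "d2"], 1)
  ## strictly decreasing in squared profile distance at fixed bandwidth
  expect_lt(k2["d1", "d3"], k2["d1", "d2"])
})

test_that("disease-set similarity takes the best match, empty set scores 0", {
  ids <- c("d", "x", "y")
  v <- diag(1, 3); dimnames(v) <- list(ids, ids)
  v["d", "x"] <- v["x", "d"] <- 0.2
  v["d", "y"] <- v["y", "d"] <- 0.7
  DSS <- SimilarityMatrix(v)
  expect_equal(lncrnaSetSimilarity("d", c("x", "y"), DSS), 0.7)
  expect_equal(lncrnaSetSimilarity("d", character(), DSS), 0)
  expect_equal(lncrnaSetSimilarity("d", c("d", "x"), DSS), 1)
  expect_error(lncrnaSetSimilarity("zz", "x", DSS), "not indexed")
  expect_error(lncrnaSetSimilarity("d", "zz", DSS), "not indexed")
})

test_that("functional similarity averages best matches over both disease sets", {
  ## singleton sets with DSS(a, b) = 1/3 give NFS = 1/3
  dag <- OntologyDAG(rbind(c("a", "r"), c("b", "r")))
  DSS <- diseaseSemanticSimilarity(dag, c(da = "a", db = "b"))
  LD <- makeLD(rbind(c(1, 0), c(0, 1)), dis = c("da", "db"))
  nfs <- simMatrix(lncrnaFunctionalSimilarity(LD, DSS))
  expect_equal(nfs["l1", "l2"], 1 / 3)
  ## identical nonempty sets are maximally similar
  LD2 <- makeLD(rbind(c(1, 1), c(1, 1)), dis = c("da", "db"))
  expect_equal(simMatrix(lncrnaFunctionalSimilarity(LD2, DSS))["l1", "l2"], 1)
  ## a lncRNA with no annotations scores 0 against everything else
  LD3 <- makeLD(rbind(c(1, 1), c(0, 0)), dis = c("da", "db"))
  nfs3 <- simMatrix(lncrnaFunctionalSimilarity(LD3, DSS))
  expect_equal(nfs3["l2", "l1"], 0)
  expect_equal(nfs3["l2", "l2"], 1)
})

test_that("similarity layers match brute-force oracles on random fixtures", {
  for (seed in 1:4) {
    LD <- randomLD(5, 6, 0.4, seed = seed)
    B <- assocMatrix(LD)
    expect_equal(simMatrix(gipSimilarity(LD, "lncrna")),
                 oracleGIP(B, "lncrna"), tolerance = 1e-12)
    expect_equal(simMatrix(gipSimilarity(LD, "disease")),
                 oracleGIP(B, "disease"), tolerance = 1e-12)
    dag <- generateDag(syntheticSpec(nTerms = 6, rngSeed = seed))
    termOf <- setNames(sample(ontoTerms(dag), 6, replace = TRUE),
                       colnames(B))
    expect_equal(simMatrix(diseaseSemanticSimilarity(dag, termOf)),
                 oracleDSS(dag, termOf), tolerance = 1e-12)
    DSS <- diseaseSemanticSimilarity(dag, termOf)
    expect_equal(simMatrix(lncrnaFunctionalSimilarity(LD, DSS)),
                 oracleNFS(B, simMatrix(DSS)), tolerance = 1e-12)
  }
})

test_that("every similarity layer is symmetric, unit-diagonal and in [0,1]", {
  fx <- smallFixture(seed = 11)
  for (side in names(fx$layers)) {
    for (ly in fx$layers[[side]]) {
      v <- simMatrix(ly)
      expect_lte(max(abs(v - t(v))), 1e-12)
      expect_true(all(v >= 0 & v <= 1))
      expect_equal(unname(diag(v)), rep(1, nrow(v)))
    }
  }
})

test_that("functional similarity is invariant under disease relabeling", {
  LD <- randomLD(5, 6, 0.4, seed = 9)
  dag <- generateDag(syntheticSpec(nTerms = 8, rngSeed = 9))
  set.seed(9)
  termOf <- setNames(sample(ontoTerms(dag), 6, replace = TRUE), diseaseIds(LD))
  DSS <- diseaseSemanticSimilarity(dag, termOf)
  nfs <- simMatrix(lncrnaFunctionalSimilarity(LD, DSS))
  perm <- sample(6)
  LDp <- AssociationMatrix(assocMatrix(LD)[, perm])
  DSSp <- SimilarityMatrix(simMatrix(DSS)[perm, perm])
  nfsP <- simMatrix(lncrnaFunctionalSimilarity(LDp, DSSp))
  expect_equal(nfsP, nfs, tolerance = 1e-12)
})
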