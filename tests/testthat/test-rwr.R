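test_that("restart vector splits mass eta/(1-eta) across sides and copies", {
  lIds <- c("l1", "l2"); dIds <- c("d1", "d2")
  ## no lncRNA seeds: full mass renormalized onto the disease side
  p <- buildRestartVector("d1", character(), 0.9, lIds, dIds, 2L, 2L)
  v <- probValues(p)
  expect_equal(sum(v), 1)
  expect_equal(unname(v[1:4]), rep(0, 4))
  expect_equal(unname(v[c(5, 7)]), c(0.5, 0.5))  # d1's two copies
  ## two seed lncRNAs, L = K = 2
  p2 <- buildRestartVector("d1", c("l1", "l2"), 0.9, lIds, dIds, 2L, 2L)
  v2 <- probValues(p2)
  expect_equal(unname(v2[1:4]), rep(0.025, 4))
  expect_equal(unname(v2[c(5, 7)]), c(0.45, 0.45))
  expect_equal(sum(v2), 1)
  ## eta below 0.5 shifts restart mass toward the lncRNA side
  p3 <- buildRestartVector("d1", "l1", 0.3, lIds, dIds, 2L, 2L)
  v3 <- probValues(p3)
  expect_gt(sum(v3[1:4]), sum(v3[5:8]))
  expect_error(buildRestartVector("zz", character(), 0.9, lIds, dIds, 2L, 2L),
               "unknown disease")
  expect_error(buildRestartVector("d1", "zz", 0.9, lIds, dIds, 2L, 2L),
               "unknown lncRNA")
})

test_that("power iteration reaches the restart fixed point", {
  fx <- smallFixture(seed = 5)
  params <- RWRParams()
  H <- mhrwr:::.assembleTransition(fx$LD, fx$layers, params)
  pRS <- buildRestartVector("d1", c("l1"), 0.9, lncrnaIds(fx$LD),
                            diseaseIds(fx$LD), H@nLncLayers, H@nDisLayers)
  ## gamma = 1: restart dominates after a single iteration
  one <- rwrIterate(H, pRS, gamma = 1)
  expect_equal(probValues(one$pInf), probValues(pRS))
  expect_equal(one$iterations, 1L)
  ## fixed-point property at the returned solution
  fit <- rwrIterate(H, pRS, gamma = 0.7, tol = 1e-12)
  p <- probValues(fit$pInf)
  step <- 0.3 * as.vector(t(transMatrix(H)) %*% p) + 0.7 * probValues(pRS)
  expect_lt(sum(abs(step - p)), 1e-12)
  ## total probability is conserved
  expect_equal(sum(p), 1, tolerance = 1e-9)
  ## dense linear-solve oracle
  expect_lt(sum(abs(p - oracleStationary(H, pRS, 0.7))), 1e-8)
  expect_error(rwrIterate(H, pRS, gamma = 0.9, maxIter = 2L),
               "no convergence")
})

test_that("convergence is geometric in the restart probability", {
  fx <- smallFixture(seed = 6)
  H <- mhrwr:::.assembleTransition(fx$LD, fx$layers, RWRParams())
  pRS <- buildRestartVector("d2", character(), 0.9, lncrnaIds(fx$LD),
                            diseaseIds(fx$LD), H@nLncLayers, H@nDisLayers)
  fit <- rwrIterate(H, pRS, gamma = 0.9, tol = 1e-10)
  expect_lte(fit$iterations, ceiling(log(1e-10) / log(0.1)) + 2)
})

test_that("copy aggregation conserves probability", {
  fx <- smallFixture(seed = 7)
  H <- mhrwr:::.assembleTransition(fx$LD, fx$layers, RWRParams())
  pRS <- buildRestartVector("d1", "l1", 0.9, lncrnaIds(fx$LD),
                            diseaseIds(fx$LD), H@nLncLayers, H@nDisLayers)
  fit <- rwrIterate(H, pRS, 0.9)
  sl <- aggregateScores(fit$pInf, "lncrna")
  sd <- aggregateScores(fit$pInf, "disease")
  expect_named(sl, lncrnaIds(fx$LD))
  expect_equal(sum(sl) + sum(sd), 1, tolerance = 1e-9)
  ## single-layer aggregation is the identity
  p1 <- buildRestartVector("d1", character(), 0.9, "l1", c("d1", "d2"), 1L, 1L)
  expect_equal(unname(aggregateScores(p1, "disease")), probValues(p1)[2:3])
})

test_that("disease queries rank the non-seed lncRNAs", {
  fx <- smallFixture(seed = 8)
  params <- RWRParams()
  B <- assocMatrix(fx$LD)
  d <- diseaseIds(fx$LD)[1]
  k <- sum(B[, d])
  pred <- predictForDisease(fx$LD, fx$layers, params, d)
  r <- predRanking(pred)
  expect_equal(nrow(r), nrow(B) - k)
  expect_setequal(pred@excluded, rownames(B)[B[, d] == 1])
  expect_true(all(diff(r$score) <= 1e-15))
  ## a disease with no known lncRNA ranks the full set
  B2 <- B; B2[, 2] <- 0
  LD2 <- AssociationMatrix(B2)
  layers2 <- buildSimilarityLayers(LD2, fx$dag, fx$termOf)
  pred2 <- predictForDisease(LD2, layers2, params, diseaseIds(LD2)[2])
  expect_equal(nrow(predRanking(pred2)), nrow(B))
  expect_error(predictForDisease(fx$LD, fx$layers, params, "zz"),
               "unknown disease")
})

test_that("lncRNA queries mirror disease queries under transposition", {
  fx <- smallFixture(seed = 9)
  params <- RWRParams()
  pred <- predictForLncrna(fx$LD, fx$layers, params, "l1")
  ## same computation run on the transposed association structure
  LDt <- AssociationMatrix(t(assocMatrix(fx$LD)))
  layersT <- list(lncrna = fx$layers$disease, disease = fx$layers$lncrna)
  ref <- predictForDisease(LDt, layersT, params, "l1")
  expect_equal(predRanking(pred), predRanking(ref))
  expect_identical(pred@side, "disease")
  ## a lncRNA with every disease known yields an empty ranking
  B <- assocMatrix(fx$LD); B[1, ] <- 1
  LDfull <- AssociationMatrix(B)
  layersF <- buildSimilarityLayers(LDfull, fx$dag, fx$termOf)
  predF <- predictForLncrna(LDfull, layersF, params, "l1")
  expect_equal(nrow(predRanking(predF)), 0L)
})

test_that("raising eta raises the query disease's stationary score", {
  fx <- smallFixture(seed = 10)
  score <- function(eta) {
    params <- RWRParams(eta = eta)
    H <- mhrwr:::.assembleTransition(fx$LD, fx$layers, params)
    seeds <- lncrnaIds(fx$LD)[assocMatrix(fx$LD)[, "d1"] == 1]
    pRS <- buildRestartVector("d1", seeds, eta, lncrnaIds(fx$LD),
                              diseaseIds(fx$LD), H@nLncLayers, H@nDisLayers)
    fit <- rwrIterate(H, pRS, params@gamma)
    aggregateScores(fit$pInf, "disease")[["d1"]]
  }
  s <- vapply(c(0.2, 0.5, 0.8), score, numeric(1))
  expect_true(all(diff(s) > 0))
})
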