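test_that("identity breed correlations make path coefficients equal correlations", {
  rYX <- c(A = 0.6, B = 0.3)
  RXX <- diag(2); dimnames(RXX) <- list(c("A", "B"), c("A", "B"))
  sol <- solvePathCoefficients(list(rYX = rYX, RXX = RXX))
  expect_equal(pathCoefficients(sol), rYX)
  expect_equal(unname(sol@directDet), c(0.36, 0.09))
  expect_equal(sol@residualDet, 1 - 0.45, tolerance = 1e-12)
})

test_that("K=2 solve matches the closed-form semi-partial correlations", {
  expect_equal(solveBivariate(0.6, 0.5, 0.4),
               c(0.4761905, 0.3095238), tolerance = 1e-6)
  expect_equal(solveBivariate(0.6, 0.5, 0), c(0.6, 0.5))
  expect_error(solveBivariate(0.5, 0.5, 1.0), "singular")
  set.seed(8)
  for (i in 1:10) {
    r12 <- runif(1, -0.8, 0.8)
    ry <- runif(2, -0.7, 0.7)
    RXX <- matrix(c(1, r12, r12, 1), 2, 2)
    sol <- suppressWarnings(
      solvePathCoefficients(list(rYX = ry, RXX = RXX)))
    ## independent 2x2 matrix-solve oracle
    oracle <- solve(RXX) %*% ry
    expect_equal(unname(pathCoefficients(sol)), as.vector(oracle),
                 tolerance = 1e-12)
    expect_equal(unname(pathCoefficients(sol)),
                 solveBivariate(ry[1], ry[2], r12), tolerance = 1e-12)
  }
})

test_that("correlation solve and standardized regression agree (dual route)", {
  set.seed(13)
  for (i in 1:10) {
    K <- sample(2:8, 1)
    M <- sample(100:2000, 1)
    X <- matrix(runif(M * K, 0.05, 0.95), M, K)
    y <- X %*% runif(K, 0, 1) + rnorm(M, sd = 0.2)
    y <- as.vector(y)
    solReg <- pathFromRegression(y, X)
    cs <- correlationStructure(y, ftab(pmin(pmax(X, 0), 1)))
    solCor <- solvePathCoefficients(cs)
    expect_equal(unname(pathCoefficients(solReg)),
                 unname(pathCoefficients(solCor)), tolerance = 1e-8)
    expect_equal(solReg@residualDet, solCor@residualDet,
                 tolerance = 1e-8)
  }
})

test_that("standardized regression path solution has the exact no-residual limits", {
  set.seed(14)
  X <- matrix(rnorm(600), 200, 3)
  X <- scale(X) %*% diag(3)            # columns standardized
  y <- as.vector(X %*% c(0.5, 0.3, 0.2))
  sol <- pathFromRegression(y, X)
  expect_equal(sol@residualDet, 0, tolerance = 1e-10)
  expect_equal(sol@pYE, 0, tolerance = 1e-5)
  expect_equal(sol@reliability, 1, tolerance = 1e-10)

  ## y equal to x1, x's orthogonalized
  X2 <- qr.Q(qr(matrix(rnorm(100), 50, 2))) * sqrt(49)
  sol2 <- pathFromRegression(X2[, 1], X2)
  expect_equal(unname(pathCoefficients(sol2)), c(1, 0), tolerance = 1e-10)
})

test_that("combined determination has the paper-system values and quadratic-form sum", {
  p <- c(0.707107, 0.5, 0.5)
  R <- beefmasterR()
  d <- combinedDetermination(p, R)
  expect_equal(unname(d), c(0.553033, 0.385355, 0.367678),
               tolerance = 1e-5)
  expect_equal(sum(d), as.vector(t(p) %*% R %*% p), tolerance = 1e-12)
  expect_equal(unname(combinedDetermination(p, diag(3))), p^2)
  set.seed(15)
  for (i in 1:10) {
    K <- sample(2:6, 1)
    p <- rnorm(K)
    A <- matrix(rnorm(K * K), K)
    R <- cov2cor(crossprod(A) + diag(K))
    expect_equal(sum(combinedDetermination(p, R)),
                 as.vector(t(p) %*% R %*% p), tolerance = 1e-12)
  }
})

test_that("D-GBC is the normalised squared path coefficients", {
  expect_equal(round(unname(composition(dGBC(c(0.668, 0.418)))), 3),
               c(0.719, 0.281))
  expect_equal(unname(composition(dGBC(0.4))), 1)
  expect_equal(unname(composition(dGBC(c(0.6, 0.8)))), c(0.36, 0.64))
  expect_error(dGBC(c(0, 0)), "zero")
})

test_that("C-GBC reproduces the worked composite system and collapses to D-GBC", {
  p <- c(sqrt(2) * 0.5, 0.5, 0.5)
  est <- cGBC(p, beefmasterR())
  expect_equal(round(unname(composition(est)), 3), c(0.423, 0.295, 0.282))
  ## zero correlations: C-GBC == D-GBC == 2:1:1 ratios
  est0 <- cGBC(p, diag(3))
  expect_equal(unname(composition(est0)), c(0.5, 0.25, 0.25))
  expect_equal(composition(est0), composition(dGBC(p)),
               ignore_attr = TRUE)
  expect_false(est0@clamped)
  ## negative components are clamped and flagged
  estn <- cGBC(c(1, -0.05), matrix(c(1, 0.6, 0.6, 1), 2))
  expect_true(estn@clamped)
  expect_true(all(composition(estn) >= 0))
  expect_equal(sum(composition(estn)), 1, tolerance = 1e-12)
})

test_that("residual determination completes the decomposition identity", {
  ## exact linear combination: R = 0, reliability 1
  set.seed(16)
  X <- matrix(runif(300), 100, 3)
  y <- as.vector(X %*% c(0.2, 0.3, 0.5))
  sol <- suppressWarnings(pathFromRegression(y, X))  # R ~ -1e-16 possible
  rd <- suppressWarnings(
    residualDetermination(pathCoefficients(sol), sol@RXX))
  expect_equal(rd$R, 0, tolerance = 1e-10)
  expect_equal(rd$reliability, 1, tolerance = 1e-10)

  ## the worked composite system overshoots: R < 0, pYE clamped
  p <- c(sqrt(2) * 0.5, 0.5, 0.5)
  expect_warning(rd2 <- residualDetermination(p, beefmasterR()),
                 "clamped")
  expect_equal(rd2$R, 1 - 1.306066, tolerance = 1e-6)
  expect_equal(rd2$pYE, 0)

  ## noisy simulations keep 0 <= R <= 1
  set.seed(17)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    X <- matrix(runif(60 * K), 60, K)
    y <- as.vector(X %*% runif(K)) + rnorm(60, sd = 0.5)
    sol <- suppressWarnings(pathFromRegression(y, X))
    expect_gte(sol@residualDet, 0)
    expect_lte(sol@residualDet, 1)
  }
})

test_that("decomposition and reconstruction identities hold on solved instances", {
  set.seed(18)
  for (i in 1:20) {
    K <- sample(2:8, 1)
    A <- matrix(rnorm(K * K), K)
    RXX <- cov2cor(crossprod(A) + diag(K))
    rYX <- as.vector(RXX %*% runif(K, -0.4, 0.6))  # consistent system
    sol <- suppressWarnings(
      solvePathCoefficients(list(rYX = rYX, RXX = RXX)))
    ## Sum of combined determinations + residual = 1
    expect_equal(sum(sol@combinedDet) + sol@residualDet, 1,
                 tolerance = 1e-10)
    ## RXX p reproduces rYX
    expect_equal(as.vector(sol@RXX %*% pathCoefficients(sol)),
                 unname(sol@rYX), tolerance = 1e-10)
    ## D-GBC simplex without clamping
    dg <- composition(dGBC(sol))
    expect_true(all(dg >= 0))
    expect_equal(sum(dg), 1, tolerance = 1e-12)
  }
})

test_that("ill-conditioned correlation matrices are refused with diagnostics", {
  RXX <- matrix(c(1, 1 - 1e-12, 1 - 1e-12, 1), 2, 2,
                dimnames = list(c("H", "S"), c("H", "S")))
  expect_error(solvePathCoefficients(list(rYX = c(0.5, 0.5), RXX = RXX)),
               "ill-conditioned.*[HS] - [HS]")
})

test_that("full path pipeline recovers a pure breed and mirrors the D/C contrast", {
  F <- simulateBreedFrequencies(2000, 2, sharedAncestor = FALSE,
                                seed = 91)
  est <- estimatePathGBC(freq(F)[, 1], F, mode = "direct")
  expect_gt(unname(composition(est)[1]), 0.999)

  sc <- makeScenarios(seed = 5, M = 4000, n = 60)
  yb <- colMeans(dosage(sc$brangus_like$genotypes)) / 2
  bD <- estimatePathGBC(yb, sc$brangus_like$freq, mode = "direct")
  bC <- estimatePathGBC(yb, sc$brangus_like$freq, mode = "combined")
  gapB <- abs(composition(bD)[1] - composition(bC)[1])
  expect_lt(gapB, 0.02)  # distant breeds: D-GBC ~ C-GBC

  ym <- colMeans(dosage(sc$beefmaster_like$genotypes)) / 2
  mD <- estimatePathGBC(ym, sc$beefmaster_like$freq, mode = "direct")
  mC <- estimatePathGBC(ym, sc$beefmaster_like$freq, mode = "combined")
  gapM <- abs(composition(mD)[1] - composition(mC)[1])
  expect_gt(gapM, gapB)  # correlated pair widens the D/C gap
  expect_false(is.na(reliability(mC)))
})
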