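test_that("tube ground truth matches the closed forms", {
  s <- makeTube("straight", length = 100, r = 15, nAxial = 10, nCirc = 12)
  expect_equal(s$truth[c("D", "L", "T", "DCR", "EILR")],
               list(D = 30, L = 100, T = 1, DCR = 0.3, EILR = 1),
               tolerance = 1e-9)
  t <- makeTube("torus", R = 40, r = 15, theta = pi, nAxial = 10, nCirc = 12)
  expect_equal(t$truth$D, 30)
  expect_equal(t$truth$L, 40 * pi)
  expect_equal(t$truth$T, pi / 2, tolerance = 1e-12)
  expect_equal(t$truth$DCR, 30 / (40 * pi), tolerance = 1e-12)
  expect_equal(t$truth$EILR, 55 / 25, tolerance = 1e-12)
  b <- makeTube("torus", R = 40, r = 15, theta = pi,
                bulge = list(A = 11, sigma = 8), nAxial = 10, nCirc = 12)
  expect_equal(b$truth$D, 52, tolerance = 1e-6)
  # bulged EILR against an independently coded profile-curve quadrature
  phi <- seq(0, pi, length.out = 2e4)
  rProf <- 15 + 11 * exp(-(40 * phi - 20 * pi)^2 / (2 * 8^2))
  curveLen <- function(rho) {
    x <- rho * cos(phi); y <- rho * sin(phi)
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }
  oracle <- curveLen(40 + rProf) / curveLen(40 - rProf)
  expect_equal(b$truth$EILR, oracle, tolerance = 1e-4)
})

test_that("tube vertices lie exactly on the parametric surface", {
  tor <- makeTube("torus", R = 40, r = 15, theta = pi, nAxial = 30,
                  nCirc = 16)
  V <- meshVertices(tor$mesh)
  # torus implicit equation: (sqrt(x^2+y^2) - R)^2 + z^2 = r^2
  resid <- abs((sqrt(V[, 1]^2 + V[, 2]^2) - 40)^2 + V[, 3]^2 - 15^2)
  expect_lt(max(resid), 1e-9)
  s <- makeTube("straight", length = 50, r = 8, nAxial = 10, nCirc = 12)
  Vs <- meshVertices(s$mesh)
  expect_lt(max(abs(sqrt(Vs[, 1]^2 + Vs[, 2]^2) - 8)), 1e-9)
})

test_that("tubes are open, manifold, two-loop surfaces with outward normals", {
  for (tube in list(makeTube("straight", nAxial = 10, nCirc = 12),
                    makeTube("torus", nAxial = 10, nCirc = 12),
                    makeTube("helical", nAxial = 10, nCirc = 12))) {
    expect_length(boundaryLoops(tube$mesh), 2L)
    expect_true(aortamorph:::.outwardOriented(tube$mesh))
  }
})

test_that("invalid tube specifications are rejected", {
  expect_error(makeTube("torus", R = 10, r = 15), "self-intersecting")
  expect_error(makeTube("straight", r = -1), "radius must be")
  expect_error(makeTube("straight", bulge = list(A = -20, sigma = 5)),
               "stay > 0")
})

test_that("helical tortuosity ground truth comes from quadrature", {
  h <- makeTube("helical", R = 40, theta = pi, pitch = 15, r = 10,
                nAxial = 10, nCirc = 12)
  # helix: L = theta * sqrt(R^2 + p^2); chord from endpoint coordinates
  L <- pi * sqrt(40^2 + 15^2)
  w <- sqrt(40^2 + 15^2)
  endpt <- c(40 * cos(pi), 40 * sin(pi), 15 * pi)
  chord <- sqrt(sum((endpt - c(40, 0, 0))^2))
  expect_equal(h$truth$T, L / chord, tolerance = 1e-6)
})

test_that("simulated cohorts honor fixed counts, seeds and Eq-8 consistency", {
  coh <- simulateCohort(n = 50, nFast = 9, seed = 1)
  expect_equal(nrow(coh), 50L)
  expect_equal(sum(coh$risk_class == "fast"), 9L)
  expect_true(all(coh$dt_months >= 6))
  expect_equal(coh$GR, (coh$D2 - coh$D) / coh$dt_months, tolerance = 1e-12)
  expect_identical(as.character(coh$risk_class),
                   as.character(assignClass(coh$GR)))
  # determinism
  coh2 <- simulateCohort(n = 50, nFast = 9, seed = 1)
  expect_identical(coh, coh2)
  coh3 <- simulateCohort(n = 50, nFast = 9, seed = 2)
  expect_false(identical(coh$D, coh3$D))
})

test_that("zero-noise linear growth model yields constant GR", {
  coh <- simulateCohort(n = 20, beta = c(D = 0, DCR = 0, EILR = 0, T = 0),
                        beta0 = 0.1, noiseSd = 0, seed = 4)
  expect_equal(coh$GR, rep(0.1, 20), tolerance = 1e-12)
  expect_true(all(coh$risk_class == "low"))
})

test_that("full pipeline recovers ground truth on randomized tubes", {
  set.seed(20260923)
  nSpecs <- 6
  for (i in seq_len(nSpecs)) {
    kind <- sample(c("straight", "torus"), 1)
    r <- runif(1, 10, 16)
    spec <- if (kind == "straight")
      list(kind = "straight", length = runif(1, 70, 120), r = r)
    else
      list(kind = "torus", R = runif(1, max(3 * r, 35), 60),
           theta = runif(1, pi / 2, pi), r = r)
    tube <- do.call(makeTube, c(spec, nAxial = 70, nCirc = 32))
    cl <- extractCenterline(tube$mesh)
    dom <- isolateAscending(tube$mesh, cl, ostiumArc = centerlineLength(cl))
    feats <- quietly(computeShapeFeatures(
      dom, id = paste0("spec", i), config = pipelineConfig(n_sections = 50)))
    expect_equal(feats$D, tube$truth$D, tolerance = 0.02)
    expect_equal(feats$DCR, tube$truth$DCR, tolerance = 0.02)
    expect_equal(feats$T, tube$truth$T, tolerance = 0.02)
    expect_equal(feats$EILR, tube$truth$EILR, tolerance = 0.05)
  }
})

test_that("four features beat the diameter alone when the classes differ in DCR/EILR", {
  # classes overlapping in D, separated in (DCR, EILR)
  deltas <- replicate(10, {
    seed <- sample.int(1e6, 1)
    coh <- simulateCohort(
      n = 40, nFast = 12, seed = seed,
      meansLow = c(D = 48.4, DCR = 0.47, EILR = 2.2, T = 1.20),
      meansFast = c(D = 48.8, DCR = 0.58, EILR = 2.75, T = 1.22))
    d <- loocvClassify(coh, coh$risk_class, "ld", "D", seed = seed)
    all4 <- loocvClassify(coh, coh$risk_class, "ld", seed = seed)
    all4@auroc - d@auroc
  })
  expect_gt(mean(deltas), 0)
})
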