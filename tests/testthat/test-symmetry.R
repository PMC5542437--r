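test_that("polar resampling of a constant image is constant", {
  img <- new("ParticleImage", pixels = matrix(2.5, 96, 96), pixelSizeA = 2,
             particleId = "const")
  pol <- toPolar(img, c(cx = 47.5, cy = 47.5), 10, 40)
  expect_lt(max(abs(polarValues(pol) - 2.5)), 1e-12)
})

test_that("polar resampling recovers a pure angular harmonic", {
  box <- 96L; c0 <- (box - 1) / 2
  idx <- seq_len(box) - 1
  X <- matrix(idx, box, box); Y <- matrix(idx, box, box, byrow = TRUE)
  img <- new("ParticleImage", pixels = cos(6 * atan2(Y - c0, X - c0)),
             pixelSizeA = 2, particleId = "cos6")
  pol <- toPolar(img, c(cx = c0, cy = c0), 15, 35, nRings = 16L,
                 nAngles = 360L)
  theta <- 2 * pi * (0:359) / 360
  expected <- matrix(cos(6 * theta), 16, 360, byrow = TRUE)
  expect_lt(max(abs(polarValues(pol) - expected)), 0.02)
})

test_that("polar sample mean matches the direct annulus average", {
  # bilinear sampling is exact for a linear image, and the symmetric grids
  # make both averages equal the value at the center
  box <- 96L; idx <- 0:95
  X <- matrix(idx, box, box); Y <- matrix(idx, box, box, byrow = TRUE)
  lin <- new("ParticleImage", pixels = 0.3 + 0.01 * X + 0.02 * Y,
             pixelSizeA = 2, particleId = "linear")
  polLin <- toPolar(lin, c(cx = 47.5, cy = 47.5), 15, 35)
  r <- sqrt((X - 47.5)^2 + (Y - 47.5)^2)
  sel <- r >= 15 & r <= 35
  expect_lt(abs(mean(polarValues(polLin)) - mean(pixels(lin)[sel])), 1e-9)

  # smooth annulus: the polar grid is uniform in r, so the matching direct
  # average weights cartesian pixels by 1/r; radial endpoints get trapezoid
  # weights
  img <- uniformAnnulusImage()
  pol <- toPolar(img, c(cx = 47.5, cy = 47.5), 15, 35)
  rowm <- rowMeans(polarValues(pol))
  w <- c(0.5, rep(1, 30), 0.5) / 31
  m <- pixels(img)
  oracle <- sum(m[sel] / r[sel]) / sum(1 / r[sel])
  expect_lt(abs(sum(rowm * w) - oracle) / oracle, 0.01)
})

test_that("an annulus outside the image is rejected", {
  img <- generateRingParticle(flipRingModel(), seed = 1L)
  expect_error(toPolar(img, c(cx = 47.5, cy = 47.5), 10, 60), "outside")
  expect_error(toPolar(img, c(cx = 47.5, cy = 47.5), 0.5, 20), "rMinPx")
  expect_error(toPolar(img, c(cx = 90, cy = 47.5), 10, 20), "outside")
})

test_that("angular profile collapses rings, is zero-sum, and supports weights", {
  pol <- new("PolarImage",
             values = matrix(cos(6 * 2 * pi * (0:359) / 360), 16, 360,
                             byrow = TRUE), rMinPx = 15, rMaxPx = 35)
  f <- angularProfile(pol)
  expect_lt(max(abs(f - cos(6 * 2 * pi * (0:359) / 360))), 1e-9)
  expect_lt(abs(sum(f)), 1e-9)
  # constant polar image -> zero profile
  cpol <- new("PolarImage", values = matrix(4, 8, 64), rMinPx = 5,
              rMaxPx = 20)
  expect_true(all(angularProfile(cpol) == 0))
  # weights: profile of a two-row polar image with one informative row
  v <- rbind(cos(2 * pi * (0:359) / 360 * 5), rep(0, 360))
  wpol <- new("PolarImage", values = v, rMinPx = 5, rMaxPx = 20)
  fw <- angularProfile(wpol, weights = c(1, 0))
  expect_lt(max(abs(fw - v[1, ])), 1e-9)
})

test_that("circular autocorrelation of a cosine is the closed-form cosine", {
  N <- 360
  f <- cos(6 * 2 * pi * (0:(N - 1)) / N)
  acf <- circularAutocorrelation(f)
  expect_lt(max(abs(acf - cos(6 * 2 * pi * (0:(N - 1)) / N))), 1e-9)
  expect_equal(acf[1], 1, tolerance = 1e-12)
  # real circular ACFs are symmetric: c(m) = c(N - m)
  expect_lt(max(abs(acf[-1] - rev(acf[-1]))), 1e-9)
  expect_error(circularAutocorrelation(rep(0, N)), "degenerate")
})

test_that("spectrum of ACF equals the normalized squared profile DFT", {
  set.seed(101)
  for (rep in 1:10) {
    f <- rnorm(360); f <- f - mean(f)
    p <- spectrumPower(symmetrySpectrum(circularAutocorrelation(f)))
    oracle <- naiveProfilePower(f, 16L)
    # relative to the order's own power, floored so that exact zeros (the
    # DC term of a zero-mean profile) compare on the spectrum scale
    rel <- abs(p - oracle) / pmax(oracle, 1e-6 * max(oracle))
    expect_lt(max(rel), 1e-8)
  }
})

test_that("a pure cos(6 theta) profile concentrates power at k = 6", {
  f <- cos(6 * 2 * pi * (0:359) / 360)
  p <- spectrumPower(symmetrySpectrum(circularAutocorrelation(f)))
  expect_gt(p["6"] / sum(p[-1]), 0.999)
})

test_that("assignment takes the in-band argmax with small-k tie-break", {
  flat <- new("SymmetrySpectrum",
              power = setNames(rep(1, 17), as.character(0:16)),
              nAngles = 360L)
  a <- assignSymmetry(flat)
  expect_identical(kBest(a), 3L)
  expect_true(isLowConfidence(a))
  expect_error(assignSymmetry(flat, kMin = 5L, kMax = 3L), "candidate range")
  expect_error(assignSymmetry(flat, kMax = 40L), "orders up to")
})

test_that("the full chain assigns the true order to noiseless rings", {
  for (n in 3:8) {
    res <- analyzeParticle(generateRingParticle(
      flipRingModel(nFold = as.integer(n), rotationRad = 0.2), seed = 1L))
    expect_identical(kBest(res$assignment), as.integer(n))
    expect_false(isLowConfidence(res$assignment))
  }
})

test_that("harmonics are present but never outrank the fundamental", {
  for (n in 3:8) {
    res <- analyzeParticle(generateRingParticle(
      flipRingModel(nFold = as.integer(n)), seed = 1L))
    p <- spectrumPower(res$spectrum)
    if (2 * n <= 16) {
      expect_gt(p[as.character(n)], p[as.character(2 * n)])
      expect_gt(p[as.character(2 * n)], 0)
    }
    expect_identical(kBest(res$assignment), as.integer(n))
  }
})

test_that("in-plane rotation changes neither the call nor the spectrum", {
  base <- analyzeParticle(generateRingParticle(flipRingModel(), seed = 1L))
  p0 <- spectrumPower(base$spectrum)
  peak <- max(p0[-1])
  for (rot in c(0.3, 1.1, 2.7)) {
    res <- analyzeParticle(generateRingParticle(
      flipRingModel(rotationRad = rot), seed = 1L))
    expect_identical(kBest(res$assignment), 6L)
    expect_lt(max(abs(spectrumPower(res$spectrum) - p0)), 0.02 * peak)
  }
})

test_that("collapse-first and per-radius ACF modes agree on noiseless rings", {
  for (n in c(3L, 6L, 8L)) {
    img <- generateRingParticle(flipRingModel(nFold = n), seed = 1L)
    a1 <- analyzeParticle(img, analysisConfig(acfMode = "collapse"))
    a2 <- analyzeParticle(img, analysisConfig(acfMode = "per_radius"))
    expect_identical(kBest(a1$assignment), kBest(a2$assignment))
  }
})

test_that("ring radius is recovered and converted to nm", {
  # noiseless: sub-pixel accuracy against generator truth
  img <- normalizeImage(generateRingParticle(flipRingModel(), seed = 1L))
  est <- estimateRingRadius(img, estimateCenter(img))
  expect_lt(abs(est$radiusPx - 25) / 25, 0.05)
  expect_lt(abs(est$diameterNm - 10) / 10, 0.05)
  # SNR 2: median over a fixed stack within 5%
  radii <- vapply(1:20, function(s) {
    im <- normalizeImage(generateRingParticle(
      flipRingModel(noiseSigma = 0.5), seed = s))
    estimateRingRadius(im, estimateCenter(im))$radiusPx
  }, numeric(1))
  expect_lt(abs(median(radii) - 25) / 25, 0.05)
})

test_that("radius estimation fails when there is no positive radial peak", {
  neg <- new("ParticleImage", pixels = matrix(-1, 96, 96) -
               pixels(generateRingParticle(flipRingModel(), seed = 1L)),
             pixelSizeA = 2, particleId = "neg")
  expect_error(estimateRingRadius(neg, c(cx = 47.5, cy = 47.5)),
               "no positive radial peak")
})

test_that("a uniform annulus never yields a confident symmetry call", {
  res <- analyzeParticle(uniformAnnulusImage())
  expect_true(isLowConfidence(res$assignment))
  # the angular signal is numerically empty relative to the annulus content
  pol <- toPolar(normalizeImage(uniformAnnulusImage()),
                 c(cx = 47.5, cy = 47.5), 15, 35)
  expect_lt(var(angularProfile(pol)) / var(as.vector(polarValues(pol))),
            1e-6)
})

test_that("assignment accuracy degrades monotonically with noise", {
  acc <- vapply(c(0.25, 0.5, 1.0), function(ns) {
    ds <- generateDataset(mixtureSpec(20L, masterSeed = 11L,
                                      noiseSigma = ns))
    res <- analyzeStack(ds$images)
    ev <- evaluateAgainstTruth(res$assignments, ds$truth)
    mean(ev$perClass$accuracy)
  }, numeric(1))
  expect_true(all(diff(acc) <= 1e-9))
})
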