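test_that("the tabulated kernel is a truncated Gaussian with sigma = alpha*w", {
  k <- readKernel(0.2, 146)
  sigma <- 0.2 * 146
  expect_equal(k$sigma, sigma)
  # mode at offset 0 equals the Gaussian density peak
  expect_equal(k$values[k$offsets == 0], 1 / (sigma * sqrt(2 * pi)))
  # symmetric about the centre
  expect_equal(k$values, rev(k$values))
  # mass inside a 6-sigma cutoff matches the analytic Gaussian mass
  expect_gte(sum(k$values), 0.999)
  expect_lte(sum(k$values), 1.001)
  expect_equal(sum(k$values), pnorm(6) - pnorm(-6), tolerance = 1e-6)
})

test_that("half-integer midpoints get a phase-shifted kernel", {
  k <- readKernel(0.2, 147, frac = 0.5)
  # evaluation points sit half a base off the midpoint's enclosing base
  expect_equal(k$values[k$offsets == 0], dnorm(-0.5, sd = 0.2 * 147))
  expect_equal(k$values[k$offsets == 1], dnorm(0.5, sd = 0.2 * 147))
  expect_equal(sum(k$values), 1, tolerance = 1e-6)
})

test_that("fragment weights penalise short fragments", {
  expect_equal(fragmentWeights(146, 10), 0.1)
  expect_equal(fragmentWeights(200, 10), 0.1)
  expect_equal(fragmentWeights(73, 1), 0.5)   # linear ramp below 146
  expect_true(all(fragmentWeights(c(40, 100, 146, 500), 7) <= 1 / 7))
  expect_error(fragmentWeights(146, 0), "empty fragment set")
})

test_that("a single fragment yields a unimodal profile peaked at its midpoint", {
  fr <- makeFragments(100, 246)  # midpoint 173
  reg <- GRanges("chr1", IRanges(1, 400))
  p <- computeProfile(fr, alpha = 0.2, region = reg)
  v <- curveValues(p)
  expect_equal(which.max(v) + curveStart(p) - 1, 173)
  expect_true(all(v >= 0))
  expect_true(all(diff(v[1:173]) >= 0))        # rises to the mode
  expect_true(all(diff(v[175:400]) <= 0))      # and falls after
})

test_that("profile mass equals the summed weights up to truncation loss", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    # keep every kernel support inside the region: the largest sigma is
    # 0.63 * 300 = 189 bp, so 6 sigma stays within ~1140 bp of a midpoint
    mids <- sample(1300:4600, n, replace = TRUE)
    lens <- sample(seq(40, 300, 2), n, replace = TRUE)
    fr <- makeFragments(mids - lens / 2, mids + lens / 2)
    cfg <- testConfig()
    w8 <- fragmentWeights(width(fr), n, cfg)
    reg <- GRanges("chr1", IRanges(1, 6000))
    for (a in c(0.05, 0.3, 0.63)) {
      p <- computeProfile(fr, a, reg, cfg, weights = w8)
      bound <- sum(w8) * 2 * (1 - pnorm(cfg@truncation)) + 1e-10
      expect_lte(abs(sum(curveValues(p)) - sum(w8)), bound)
    }
  }
})

test_that("profiles are linear in their fragment sets", {
  frA <- fragmentsAt(c(300, 500))
  frB <- fragmentsAt(c(700, 900, 950))
  reg <- GRanges("chr1", IRanges(1, 1500))
  cfg <- testConfig()
  n <- length(frA) + length(frB)
  wA <- fragmentWeights(width(frA), n, cfg)
  wB <- fragmentWeights(width(frB), n, cfg)
  pU <- computeProfile(c(frA, frB), 0.2, reg, cfg,
                       weights = fragmentWeights(width(c(frA, frB)), n, cfg))
  pA <- computeProfile(frA, 0.2, reg, cfg, weights = wA)
  pB <- computeProfile(frB, 0.2, reg, cfg, weights = wB)
  expect_equal(curveValues(pU), curveValues(pA) + curveValues(pB))
  # two identical fragments match one fragment carrying twice the weight
  fr2 <- fragmentsAt(c(400, 400))
  p2 <- computeProfile(fr2, 0.2, reg, cfg, weights = c(0.05, 0.05))
  p1 <- computeProfile(fr2[1], 0.2, reg, cfg, weights = 0.1)
  expect_equal(curveValues(p2), curveValues(p1))
})

test_that("as alpha approaches zero the profile collapses onto read midpoints", {
  mids <- c(300, 500, 800)
  fr <- fragmentsAt(mids)
  p <- computeProfile(fr, 1e-3, GRanges("chr1", IRanges(1, 1000)),
                      testConfig())
  nz <- which(curveValues(p) > 0) + curveStart(p) - 1
  expect_true(all(vapply(nz, function(x) min(abs(x - mids)), numeric(1)) <= 1))
})

test_that("an empty fragment set yields an all-zero profile with a warning", {
  reg <- GRanges("chr1", IRanges(1, 200))
  expect_warning(p <- computeProfile(GRanges(), 0.2, reg), "empty")
  expect_true(all(curveValues(p) == 0))
})

test_that("landscapes are log-ratios with exact zeros where profiles agree", {
  fr <- fragmentsAt(300)
  reg <- GRanges("chr1", IRanges(1, 600))
  cfg <- testConfig()
  p <- computeProfile(fr, 0.2, reg, cfg)
  pA <- computeProfile(fr, 1.5, reg, cfg)
  ls <- computeLandscape(p, pA, epsilon = 1e-6)
  v <- curveValues(ls)
  expect_true(all(is.finite(v)))
  # identical profiles give the exactly-zero landscape (epsilon cancels)
  ls0 <- computeLandscape(p, p, epsilon = 1e-6)
  expect_true(all(curveValues(ls0) == 0))
  # S > S_A implies N > 0 and vice versa
  expect_true(all((v > 0) == (curveValues(p) > curveValues(pA))))
  # mismatched regions are rejected
  pShort <- computeProfile(fr, 0.2, GRanges("chr1", IRanges(1, 500)), cfg)
  expect_error(computeLandscape(pShort, pA), "different regions")
})

test_that("the landscape family has one entry per scale, shared reference", {
  fr <- fragmentsAt(c(300, 600))
  cfg <- ProfileConfig(m = 40)
  fam <- buildLandscapeFamily(fr, config = cfg)
  expect_length(fam$landscapes, 40L)
  alphas <- vapply(fam$landscapes, scaleFactor, numeric(1))
  expect_equal(alphas, seq(0.05, 0.63, length.out = 40))
  expect_equal(scaleFactor(fam$reference), 1.5)
  # a single fragment gives a unimodal landscape at every scale
  fam1 <- buildLandscapeFamily(fragmentsAt(400), config = testConfig())
  for (ls in fam1$landscapes) {
    pk <- peaks(detectPeaks(ls))
    expect_equal(nrow(pk), 1L)
    expect_lte(abs(pk$qRaw - 400), 1)
  }
})

test_that("profile roughness is non-increasing in alpha", {
  set.seed(77)
  for (rep in 1:6) {
    n <- sample(20:60, 1)
    cen <- sort(runif(sample(2:4, 1), 300, 1800))
    mids <- round(rnorm(n, sample(cen, n, replace = TRUE), 25))
    lens <- sample(seq(80, 240, 2), n, replace = TRUE)
    fr <- makeFragments(mids - lens / 2, mids + lens / 2)
    cfg <- testConfig(m = 8)
    reg <- GRanges("chr1", IRanges(1, 2500))
    # profiles are defined up to the kernel truncation error, so maxima are
    # only counted above that numerical floor (staggered kernel supports can
    # leave ~1e-11-scale staircase bumps in far-tail regions)
    floorV <- 1e-8
    nMax <- vapply(profileAlphas(cfg), function(a) {
      v <- curveValues(computeProfile(fr, a, reg, cfg))
      e <- findExtrema(v)
      sum(v[e$maxima + 1L] > floorV)
    }, integer(1))
    expect_true(all(diff(nMax) <= 0))
  }
})
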