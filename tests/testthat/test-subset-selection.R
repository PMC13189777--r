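test_that("noiseless outcomes are recovered exactly", {
  set.seed(2)
  x <- cbind(a = rnorm(30), b = rnorm(30))
  y <- 1.5 - 2 * x[, "a"] + 0.25 * x[, "b"]
  fit <- ols_fit(x, y)
  expect_equal(fit$coefficients$estimate, c(1.5, -2, 0.25), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-10)
})

test_that("univariate fit matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4)
  y <- c(2.0, 2.9, 4.2, 4.9)
  fit <- ols_fit(cbind(x = x), y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  expect_equal(fit$coefficients$estimate, c(intercept, slope),
               tolerance = 1e-12)
  # standard errors from the unbiased variance estimate
  s2 <- fit$rss / (4 - 1 - 1)
  expect_equal(fit$coefficients$std_error[2], sqrt(s2 / sxx),
               tolerance = 1e-12)
})

test_that("fits are invariant to row permutation", {
  set.seed(8)
  x <- cbind(a = rnorm(40), b = rnorm(40))
  y <- 0.5 * x[, 1] + rnorm(40)
  ord <- sample(40)
  f1 <- ols_fit(x, y)
  f2 <- ols_fit(x[ord, ], y[ord])
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-10)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-10)
})

test_that("rank deficiency raises a singularity error naming the column", {
  x <- cbind(a = 1:20, twice_a = 2 * (1:20))
  expect_error(ols_fit(x, rnorm(20)), "rank deficient.*twice_a")
})

test_that("Gaussian AIC has the published arithmetic", {
  expect_equal(aic_gaussian(10, 100, 3), 63.52919734153, tolerance = 1e-9)
  expect_equal(aic_gaussian(10, 100, 4) - aic_gaussian(10, 100, 3), 2)
  expect_lt(aic_gaussian(5, 100, 3), aic_gaussian(10, 100, 3))
  expect_warning(val <- aic_gaussian(0, 50, 2), "perfect fit")
  expect_identical(val, -Inf)
  expect_error(aic_gaussian(-1, 50, 2), "non-negative")
})

test_that("branch-and-bound equals the exhaustive oracle on random instances", {
  for (seed in 1:20) {
    p <- sample(3:8, 1)
    d <- random_instance(n = 40, p = p, seed = seed)
    cands <- sprintf("v%02d", seq_len(p))
    bb <- best_subset(d, "y", cands, forced = "f1")
    ex <- best_subset(d, "y", cands, forced = "f1", method = "exhaustive")
    oracle <- oracle_best_subset(d, "y", cands, forced = "f1")
    expect_identical(bb$selected, oracle$selected,
                     info = paste("seed", seed))
    expect_identical(ex$selected, oracle$selected,
                     info = paste("seed", seed))
    expect_equal(bb$aic, oracle$aic, tolerance = 1e-6)
    expect_equal(ex$search_stats$subsets_evaluated, 2^p)
  }
})

test_that("forced predictors appear in every returned model", {
  set.seed(31)
  d <- tibble::tibble(delta_age = rnorm(200, 4.9, 1.5),
                      junk1 = rnorm(200), junk2 = rnorm(200))
  d$y <- rnorm(200)  # outcome unrelated to everything
  m <- best_subset(d, "y", c("junk1", "junk2"), forced = "delta_age")
  expect_true("delta_age" %in% m$fit$coefficients$term)
  expect_identical(m$forced, "delta_age")
})

test_that("a strong true predictor is always selected; spurious pickups stay modest", {
  reps <- 60
  hits <- logical(reps)
  spurious <- integer(reps)
  set.seed(17)
  for (i in seq_len(reps)) {
    n <- 2000
    x <- matrix(rnorm(n * 10), n, 10)
    colnames(x) <- c("true", paste0("noise", 1:9))
    y <- 0.5 * x[, "true"] + rnorm(n) + 0.8 * rnorm(n)
    d <- tibble::as_tibble(as.data.frame(x))
    d$fu_gap <- rnorm(n)
    d$y <- y
    m <- best_subset(d, "y", colnames(x), forced = "fu_gap")
    hits[i] <- "true" %in% m$selected
    spurious[i] <- length(setdiff(m$selected, "true"))
  }
  expect_true(all(hits))
  # AIC admits a null predictor when t^2 > 2 (rate ~0.157 each); with nine
  # null candidates the expected pickup is ~1.4 per fit
  expect_lt(mean(spurious), 3)
})

test_that("selection is invariant to affine rescaling of candidates", {
  d <- random_instance(n = 60, p = 5, seed = 101)
  cands <- sprintf("v%02d", 1:5)
  base <- best_subset(d, "y", cands, forced = "f1")
  d2 <- d
  d2$v02 <- 100 * d2$v02 + 7
  d2$v04 <- -0.001 * d2$v04
  rescaled <- best_subset(d2, "y", cands, forced = "f1")
  expect_identical(base$selected, rescaled$selected)
})

test_that("more than 30 candidates are refused with guidance", {
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(40 * 31), 40, 31)))
  names(d) <- paste0("c", 1:31)
  d$y <- rnorm(40)
  expect_error(best_subset(d, "y", paste0("c", 1:31)),
               "exact-search limit of 30")
})

test_that("VIFs are one for an orthogonal design and exact for r = 0.6", {
  ortho <- cbind(a = c(1, -1, 1, -1, 0, 0), b = c(1, 1, -1, -1, 0, 0))
  v <- vif(ortho)
  expect_equal(v$vif, c(1, 1), tolerance = 1e-12)
  # exact sample correlation 0.6 via orthonormal construction
  z1 <- c(1, -1, 0, 0) / sqrt(2)
  z2 <- c(0, 0, 1, -1) / sqrt(2)
  x <- cbind(p = z1, q = 0.6 * z1 + 0.8 * z2)
  expect_equal(cor(x)[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(vif(x)$vif, c(1.5625, 1.5625), tolerance = 1e-10)
})

test_that("VIFs are scale invariant, >= 1, and flag perfect collinearity", {
  set.seed(13)
  x <- cbind(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  x[, "b"] <- x[, "b"] + 0.7 * x[, "a"]
  v1 <- vif(x)
  x2 <- x
  x2[, "a"] <- x2[, "a"] * 1000
  expect_equal(vif(x2)$vif, v1$vif, tolerance = 1e-8)
  expect_true(all(v1$vif >= 1))
  collinear <- cbind(a = x[, "a"], dup = 3 * x[, "a"], c = x[, "c"])
  vc <- vif(collinear)
  expect_identical(vc$vif[1], Inf)
  expect_identical(vc$vif[2], Inf)
})

test_that("our VIFs agree with the standard regression-diagnostics oracle", {
  skip_if_not_installed("car")
  set.seed(77)
  d <- tibble::tibble(a = rnorm(80), b = rnorm(80), c = rnorm(80))
  d$b <- d$b + 0.6 * d$a
  d$y <- d$a + rnorm(80)
  want <- car::vif(lm(y ~ a + b + c, data = d))
  got <- vif(as.matrix(d[c("a", "b", "c")]))
  expect_equal(got$vif, unname(want[got$term]), tolerance = 1e-10)
})

test_that("effect contrasts multiply the coefficient by the unit span", {
  fit <- tibble::tibble(term = c("diet5", "diet16"),
                        estimate = c(0.0921, 0.0941))
  expect_equal(effect_contrast(fit, "diet5", 4), 0.3684)
  expect_equal(effect_contrast(fit, "diet16", 4), 0.3764)
  expect_identical(effect_contrast(fit, "diet5", 0), 0)
  expect_error(effect_contrast(fit, "absent", 4), "not in the fitted model")
})
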