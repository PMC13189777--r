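test_that("residualize matches explicit normal equations on a fixed dataset", {
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 12.3)
  z <- cbind(z1 = c(1, 2, 3, 4, 5, 6), z2 = c(0.5, 0.1, 0.9, 0.4, 0.2, 0.8))
  expect_equal(residualize(y, z), oracle_residualize(y, z), tolerance = 1e-10)
})

test_that("residualize with no covariates mean-centers", {
  y <- c(1, 2, 4, 9)
  expect_equal(residualize(y, NULL), y - mean(y))
  expect_equal(mean(residualize(y, NULL)), 0, tolerance = 1e-12)
})

test_that("an exact linear combination residualizes to zero", {
  z <- cbind(a = rnorm(20), b = rnorm(20))
  y <- 2 + 3 * z[, "a"] - 0.5 * z[, "b"]
  expect_lt(max(abs(residualize(y, z))), 1e-10)
})

test_that("rank-deficient covariates raise a singularity error naming the column", {
  z <- cbind(a = 1:10, dup = 2 * (1:10))
  expect_error(residualize(rnorm(10), z), "rank deficient.*dup")
})

test_that("partial correlation matches the two-step oracle on a fixed dataset", {
  set.seed(42)
  z <- cbind(z1 = rnorm(8), z2 = rnorm(8))
  x <- 0.5 * z[, 1] + rnorm(8)
  y <- -0.3 * z[, 2] + 0.6 * x + rnorm(8)
  got <- partial_correlation(x, y, z)
  want <- oracle_partial_corr(x, y, z)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$n, 8L)
  expect_equal(got$k, 2L)
  expect_true(got$ci_low <= got$r && got$r <= got$ci_high)
})

test_that("with no covariates the partial correlation is plain Pearson", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    got <- partial_correlation(x, y)
    ct <- cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("partial correlation agrees with the inverse-correlation-matrix form", {
  set.seed(11)
  for (i in 1:25) {
    n <- 50
    z1 <- rnorm(n); z2 <- rnorm(n)
    x <- 0.4 * z1 + rnorm(n); y <- 0.4 * z2 + 0.3 * x + rnorm(n)
    p_inv <- solve(cor(cbind(x, y, z1, z2)))
    want <- -p_inv[1, 2] / sqrt(p_inv[1, 1] * p_inv[2, 2])
    got <- partial_correlation(x, y, cbind(z1, z2))$r
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("partial correlation is invariant to positive affine maps", {
  set.seed(3)
  z <- cbind(rnorm(30))
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  base <- partial_correlation(x, y, z)$r
  expect_equal(partial_correlation(3.2 * x + 7, y, z)$r, base,
               tolerance = 1e-12)
  expect_equal(partial_correlation(x, 0.1 * y - 2, z)$r, base,
               tolerance = 1e-12)
})

test_that("self-correlation yields r = 1 with a degenerate-free interval", {
  x <- rnorm(25)
  z <- cbind(rnorm(25))
  got <- partial_correlation(x, x, z)
  expect_equal(got$r, 1)
  expect_equal(got$ci_high, 1)
  expect_equal(got$p, 0)
})

test_that("degenerate residuals raise an explicit error", {
  z <- cbind(a = 1:20)
  expect_error(partial_correlation(2 * (1:20), rnorm(20), z),
               class = "phenodelta_degenerate_error")
})

test_that("Fisher-z intervals cover a known partial correlation at ~95%", {
  set.seed(123)
  rho <- 0.3
  n <- 200
  reps <- 1000
  covered <- vapply(seq_len(reps), function(i) {
    z <- rnorm(n)
    u <- rnorm(n); v <- rnorm(n)
    x <- z + u
    y <- z + rho * u + sqrt(1 - rho^2) * v
    res <- partial_correlation(x, y, cbind(z))
    res$ci_low <= rho && rho <= res$ci_high
  }, logical(1))
  half <- 1.96 * sqrt(0.95 * 0.05 / reps)
  expect_gt(mean(covered), 0.95 - half)
  expect_lt(mean(covered), 0.95 + half)
})

test_that("the screen selects a planted factor and reports sorted results", {
  set.seed(99)
  n <- 5000
  sex <- rbinom(n, 1, 0.4)
  delta_age <- rnorm(n, 4.9, 1.5)
  planted <- rnorm(n)
  noise <- rnorm(n)
  outcome <- 1.2 * delta_age + 0.3 * planted + 0.954 * rnorm(n)
  d <- tibble::tibble(sex = sex, delta_age = delta_age,
                      planted = planted, noise = noise, outcome = outcome)
  sc <- screen_factors(d, "outcome", c("planted", "noise"),
                       covariates = c("sex", "delta_age"))
  expect_s3_class(sc, "pheno_screen")
  expect_true(sc$selected[sc$factor_name == "planted"])
  expect_false(is.unsorted(sc$r))
  sel <- selected_factors(sc)
  expect_true("planted" %in% sel$positive)
})

test_that("a factor equal to the outcome is selected with r = 1", {
  set.seed(5)
  d <- tibble::tibble(y = rnorm(40), z = rnorm(40))
  d$copy <- d$y
  sc <- screen_factors(d, "y", "copy", covariates = "z")
  expect_equal(sc$r, 1)
  expect_true(sc$selected)
})

test_that("constant factors are excluded with a warning; empty list is vacuous", {
  d <- tibble::tibble(y = rnorm(30), z = rnorm(30), flat = 1,
                      ok = rnorm(30))
  expect_warning(sc <- screen_factors(d, "y", c("flat", "ok"),
                                      covariates = "z"),
                 "constant factor")
  expect_equal(nrow(sc), 1)
  expect_identical(attr(sc, "excluded_constant"), "flat")
  empty <- screen_factors(d, "y", character(), covariates = "z")
  expect_equal(nrow(empty), 0)
})

test_that("incomplete rows are dropped once, globally, with a logged count", {
  d <- tibble::tibble(y = c(rnorm(9), NA), z = rnorm(10),
                      f1 = c(NA, rnorm(9)), f2 = rnorm(10))
  expect_message(sc <- screen_factors(d, "y", c("f1", "f2"),
                                      covariates = "z"),
                 "dropped 2 incomplete")
  expect_true(all(sc$n == 8))
})

test_that("an optional multiplicity correction can be switched on", {
  set.seed(21)
  d <- tibble::tibble(y = rnorm(100), z = rnorm(100))
  for (j in 1:10) d[[paste0("f", j)]] <- rnorm(100)
  raw <- screen_factors(d, "y", paste0("f", 1:10), covariates = "z")
  bonf <- screen_factors(d, "y", paste0("f", 1:10), covariates = "z",
                         p_adjust = "bonferroni")
  expect_true(all(bonf$p_adjusted >= raw$p_adjusted - 1e-15))
  expect_equal(bonf$p_adjusted,
               pmin(1, raw$p[match(bonf$factor_name, raw$factor_name)] * 10))
})
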