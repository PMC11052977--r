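linear_fn <- function(w) {
  function(m) as.numeric(m %*% w)
}

test_that("exact_shapley satisfies the axioms on small models", {
  withr::with_seed(1, {
    bg <- matrix(rnorm(20 * 3), 20, 3)
  })
  x <- c(1, 2, 3)

  # null player: constant model attributes nothing
  phi0 <- exact_shapley(function(m) rep(4, nrow(m)), bg, x)
  expect_equal(unname(phi0[, 1]), c(0, 0, 0))

  # linear closed form: phi_j = w_j (x_j - mean background_j)
  w <- c(2, 3, 0)
  phi <- exact_shapley(linear_fn(w), bg, x)
  expect_equal(unname(phi[, 1]), w * (x - colMeans(bg)), tolerance = 1e-12)

  # symmetry: exchangeable features of f(x) = x1 + x2 get equal credit
  bg_sym <- cbind(rep(c(0, 1), 8), rep(c(0, 1), each = 8))
  phi_sym <- exact_shapley(function(m) m[, 1] + m[, 2], bg_sym, c(1, 1))
  expect_equal(phi_sym[1, 1], phi_sym[2, 1], tolerance = 1e-12)

  # efficiency: attributions sum to f(x) - mean f(background)
  f_int <- function(m) m[, 1] * m[, 2] + m[, 3]^2
  phi_int <- exact_shapley(f_int, bg, x)
  expect_equal(sum(phi_int[, 1]),
               f_int(matrix(x, 1)) - mean(f_int(bg)), tolerance = 1e-12)

  expect_error(exact_shapley(linear_fn(rep(1, 11)),
                             matrix(0, 2, 11), rep(0, 11)), "<= 10")
})

test_that("Monte-Carlo attribution agrees with exact enumeration", {
  withr::with_seed(2, {
    bg <- matrix(rnorm(15 * 4), 15, 4)
    inst <- matrix(rnorm(2 * 4), 2, 4)
  })
  f <- function(m) m[, 1] * 2 + m[, 2] * m[, 3] - 0.5 * m[, 4]^2
  rep_mc <- shapley_attribution(f, bg, inst, n_samples = 400, seed = 3)

  for (i in 1:2) {
    phi_exact <- exact_shapley(f, bg, inst[i, ])
    vals <- rep_mc$values[rep_mc$values$instance == i, ]
    eff <- rep_mc$efficiency[rep_mc$efficiency$instance == i, ]
    # every per-feature estimate within 3 Monte-Carlo standard errors
    expect_true(all(abs(vals$attribution - phi_exact[, 1]) <=
                      3 * vals$se + 1e-8))
    # efficiency within 3 standard errors of the background-mean noise
    expect_lt(abs(eff$attribution_sum - eff$prediction_gap),
              3 * eff$mc_se + 1e-8)
  }
})

test_that("Monte-Carlo estimates are seed-reproducible and zero for constants", {
  withr::with_seed(4, {
    bg <- matrix(runif(10 * 3), 10, 3)
    inst <- matrix(runif(3), 1, 3)
  })
  a <- shapley_attribution(linear_fn(c(1, 1, 1)), bg, inst,
                           n_samples = 50, seed = 11)
  b <- shapley_attribution(linear_fn(c(1, 1, 1)), bg, inst,
                           n_samples = 50, seed = 11)
  expect_identical(a$values$attribution, b$values$attribution)

  z <- shapley_attribution(function(m) rep(0.3, nrow(m)), bg, inst,
                           n_samples = 30, seed = 1)
  expect_true(all(z$values$attribution == 0))
  expect_error(shapley_attribution(linear_fn(c(1, 1, 1)),
                                   matrix(numeric(0), 0, 3), inst), "empty")
})

test_that("two-class predictors get per-class attributions", {
  withr::with_seed(5, {
    bg <- matrix(runif(12 * 3), 12, 3)
    inst <- matrix(runif(6), 2, 3)
  })
  f2 <- function(m) {
    p <- plogis(m %*% c(2, -1, 0.5))
    cbind(class_0 = 1 - p, class_1 = p)
  }
  rep2 <- shapley_attribution(f2, bg, inst, n_samples = 60, seed = 2)
  expect_setequal(unique(rep2$values$class), c("class_0", "class_1"))
  # complementary classes mirror each other's attributions
  v0 <- rep2$values$attribution[rep2$values$class == "class_0"]
  v1 <- rep2$values$attribution[rep2$values$class == "class_1"]
  expect_equal(v0, -v1, tolerance = 1e-12)
})

test_that("uniformity index and report comparison behave as designed", {
  withr::with_seed(6, {
    bg <- matrix(runif(10 * 4), 10, 4)
    inst <- matrix(runif(8), 2, 4)
  })
  # perfectly symmetric model: all features identical -> index 1
  f_sym <- function(m) rowSums(m)
  rep_sym <- shapley_attribution(f_sym, bg, inst, n_samples = 80, seed = 3)
  # one-feature model: maximally concentrated -> index well below 1
  f_one <- function(m) 5 * m[, 1]
  rep_one <- shapley_attribution(f_one, bg, inst, n_samples = 80, seed = 3)
  u_sym <- rep_sym$uniformity$uniformity_index[1]
  u_one <- rep_one$uniformity$uniformity_index[1]
  expect_gt(u_sym, u_one)
  expect_equal(u_one, 1 - gsfair:::gini_coefficient(c(1, 0, 0, 0)),
               tolerance = 0.05)

  cmp_same <- compare_attributions(rep_sym, rep_sym)
  expect_equal(cmp_same$by_class$uniformity_delta, 0)
  expect_equal(cmp_same$by_class$kendall_tau, 1)

  cmp <- compare_attributions(rep_one, rep_sym)
  expect_true(all(cmp$by_class$more_equalized))
  expect_equal(cmp$by_class$zero_features_benchmark,
               rep(3L, nrow(cmp$by_class)))
})
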