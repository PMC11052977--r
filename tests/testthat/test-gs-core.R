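test_that("dft2 matches the double-sum definition", {
  # frozen value computed with dft2_bruteforce
  expect_equal(dft2(matrix(c(1, 3, 2, 4), 2, 2)),
               matrix(c(10, -4, -2, 0) + 0i, 2, 2))
  expect_equal(dft2(matrix(0, 2, 2)), matrix(0 + 0i, 2, 2))
  expect_equal(dft2(matrix(3.7)), matrix(3.7 + 0i))

  withr::with_seed(5, {
    for (dims in list(c(3, 4), c(5, 2), c(1, 6))) {
      x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
      expect_equal(dft2(x), dft2_bruteforce(x), tolerance = 1e-10)
    }
  })
  expect_error(dft2(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("idft2 inverts dft2 and Parseval's relation holds", {
  expect_equal(idft2(matrix(c(10, -4, -2, 0) + 0i, 2, 2)),
               matrix(c(1, 3, 2, 4) + 0i, 2, 2), tolerance = 1e-12)
  expect_equal(idft2(matrix(2.5)), matrix(2.5 + 0i))

  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(1:64, 1)
      m <- sample(1:64, 1)
      x <- matrix(rnorm(n * m), n, m)
      fx <- dft2(x)
      expect_lt(max(Mod(idft2(fx) - x)), 1e-10)
      expect_equal(sum(Mod(fx)^2), n * m * sum(x^2),
                   tolerance = 1e-9)
    }
  })
})

test_that("init_phase draws seeded uniform angles in [0, 2*pi)", {
  ph <- init_phase(2, 3, seed = 7)
  expect_identical(dim(ph), c(2L, 3L))
  expect_true(all(ph >= 0 & ph < 2 * pi))
  expect_identical(ph, init_phase(2, 3, seed = 7))
  expect_false(identical(init_phase(4, 4, 1), init_phase(4, 4, 2)))
  expect_error(init_phase(0, 3, 1), "positive")

  # angles cover the range roughly uniformly
  big <- init_phase(100, 100, seed = 3)
  expect_gt(max(big), 2 * pi * 0.999)
  expect_lt(min(big), 2 * pi * 0.001)
})

test_that("gs_iterate reduces the magnitude mismatch monotonically", {
  withr::with_seed(2, {
    src <- matrix(abs(rnorm(64)), 8, 8)
  })
  st <- gs_iterate(src, matrix(1, 8, 8), cycles = 50, seed = 9)
  expect_s3_class(st, "gs_state")
  expect_identical(st$k, 50L)
  expect_length(st$error_trace, 50L)
  expect_true(all(st$error_trace >= 0))
  expect_true(all(diff(st$error_trace) <= 1e-9))
  expect_true(all(st$phase_hologram >= 0 & st$phase_hologram < 2 * pi))
})

test_that("1x1 iteration is a fixed point with a constant error trace", {
  st <- gs_iterate(matrix(5), matrix(1), cycles = 10, seed = 4)
  # field 5*e^{i*theta}: spectrum magnitude always 5, error (5-1)^2
  expect_equal(st$error_trace, rep(16, 10))
  # the initial angle is preserved by every cycle
  theta0 <- init_phase(1, 1, seed = 4)[1, 1]
  expect_equal(st$phase_hologram[1, 1], theta0, tolerance = 1e-12)
  expect_equal(st$phase_target[1, 1], theta0, tolerance = 1e-12)
})

test_that("gs_iterate validates shapes, signs and cycle counts", {
  expect_error(gs_iterate(matrix(1, 2, 2), matrix(1, 3, 2)), "shape")
  expect_error(gs_iterate(matrix(-1, 2, 2), matrix(1, 2, 2)),
               "non-negative")
  expect_error(gs_iterate(matrix(1, 2, 2), matrix(1, 2, 2), cycles = 0),
               "positive")
  expect_identical(formals(gs_iterate)$cycles, 50L)
})

test_that("gs_transform yields a unit-magnitude spectrum field", {
  withr::with_seed(3, {
    x <- matrix(runif(16 * 8, 0, 22), 16, 8)
  })
  out <- gs_transform(x, gs_config(seed = 5))
  expect_lt(max(abs(Mod(dft2(out$field)) - 1)), 1e-9)
  expect_true(all(out$values >= 0 & out$values <= 1))
  expect_identical(dim(out$values), dim(x))

  # determinism: identical config -> bitwise identical output
  out2 <- gs_transform(x, gs_config(seed = 5))
  expect_identical(out$values, out2$values)
  # different phase seed -> different output
  out3 <- gs_transform(x, gs_config(seed = 6))
  expect_false(identical(out$values, out3$values))
})

test_that("gs_transform handles the 1x1 closed form and bad input", {
  out <- gs_transform(matrix(5), gs_config(rescale = "none"))
  expect_equal(out$values, matrix(1), tolerance = 1e-12)
  expect_error(gs_transform(matrix(c(1, NA), 1, 2)), "complete-case")
  expect_error(gs_transform(matrix(c(1, Inf), 1, 2)), "complete-case")
})

test_that("real-part output mode and no-rescale mode are honored", {
  withr::with_seed(8, x <- matrix(runif(40, 0, 22), 8, 5))
  out <- gs_transform(x, gs_config(seed = 2, output_mode = "real_part",
                                   rescale = "none"))
  expect_equal(out$values, Re(out$field))
  outm <- gs_transform(x, gs_config(seed = 2, rescale = "none"))
  expect_equal(outm$values, Mod(outm$field))
})

test_that("the output preserves the location of a smooth maximum", {
  bump <- 22 * gaussian_bump()
  out <- gs_transform(bump, gs_config(seed = 1))
  pos_in <- which(bump == max(bump), arr.ind = TRUE)[1, ]
  pos_out <- which(out$values == max(out$values), arr.ind = TRUE)[1, ]
  expect_true(all(abs(pos_in - pos_out) <= 1L))
})

test_that("stratified batches partition rows with proportional groups", {
  cohort <- tibble::tibble(group = rep(c("a", "b"), c(70, 30)))
  b <- stratified_batches(cohort, batch_size = 50, seed = 1)
  expect_length(b, 2L)
  expect_equal(sort(unlist(b)), 1:100)
  for (batch in b) {
    expect_equal(sum(cohort$group[batch] == "a"), 35L)
    expect_equal(sum(cohort$group[batch] == "b"), 15L)
  }

  expect_identical(stratified_batches(cohort, "all"), list(1:100))
  expect_error(stratified_batches(cohort, batch_size = 1), "smaller")

  # partition contract on awkward sizes
  cohort2 <- tibble::tibble(group = sample(c("x", "y", "z"), 83,
                                           replace = TRUE))
  b2 <- stratified_batches(cohort2, batch_size = 20, seed = 3)
  expect_equal(sort(unlist(b2)), 1:83)
  expect_equal(sum(vapply(b2, length, 1L)), 83L)
  shares <- table(cohort2$group) / nrow(cohort2)
  for (batch in b2) {
    tab <- table(factor(cohort2$group[batch], levels = names(shares)))
    expect_true(all(abs(tab - shares * length(batch)) <= 1 + 1e-9))
  }
})

test_that("cohort-level transform equals the matrix transform when unbatched", {
  spec <- small_cohort_spec(seed = 3)
  coh <- generate_cohort(spec)
  feats <- grep("^feature_", names(coh), value = TRUE)
  tr <- gs_transform_cohort(coh, gs_config(seed = 4))
  direct <- gs_transform(as.matrix(coh[feats]), gs_config(seed = 4))
  expect_equal(unname(as.matrix(tr[feats])), unname(direct$values))
  expect_identical(tr$outcome, coh$outcome)
  expect_identical(tr$group, coh$group)
  expect_length(attr(tr, "gs_states"), 1L)

  # batched transform still returns values on [0,1] with states per batch
  trb <- gs_transform_cohort(coh, gs_config(seed = 4, batch_size = 150))
  expect_length(attr(trb, "gs_states"), ceiling(nrow(coh) / 150))
  vals <- as.matrix(trb[feats])
  expect_true(all(vals >= 0 & vals <= 1))
})
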