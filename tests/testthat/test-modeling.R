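# MLR fitting, fit statistics, LOO Q2, and the repeated-split protocol

test_that("fit_mlr recovers exact coefficients on noiseless data", {
  x <- matrix(seq_len(12), ncol = 1, dimnames = list(NULL, "x"))
  m <- fit_mlr(x, 2 * x[, 1] + 1)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(m$coefficients["x"]), 2, tolerance = 1e-10)

  # constant response: zero slope, intercept = mean
  m0 <- fit_mlr(x, rep(4.2, 12))
  expect_equal(m0$intercept, 4.2, tolerance = 1e-10)
  expect_equal(unname(m0$coefficients["x"]), 0, tolerance = 1e-10)
})

test_that("fit_mlr matches an independent pseudoinverse solve", {
  fx <- make_regression_fixture(n = 8, p = 2, seed = 9)
  m <- fit_mlr(fx$X, fx$y)
  A <- cbind(1, fx$X)
  cf <- solve(t(A) %*% A, t(A) %*% fx$y)  # normal equations oracle
  expect_equal(m$intercept, unname(cf[1, 1]), tolerance = 1e-10)
  expect_equal(unname(m$coefficients), unname(cf[-1, 1]), tolerance = 1e-10)
})

test_that("fit_mlr names collinear columns and refuses bad shapes", {
  X <- cbind(a = rnorm(10), b = rnorm(10))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_mlr(X, rnorm(10)), "collinear")
  expect_error(fit_mlr(X[1:3, ], rnorm(3)), "n > k")
})

test_that("prediction reproduces stored fitted values and training R2", {
  fx <- make_regression_fixture(seed = 4)
  m <- fit_mlr(fx$X, fx$y)
  expect_equal(predict(m, fx$X), m$fitted, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r_squared(fx$y, predict(m, fx$X)), m$training_r2, tolerance = 1e-12)
  expect_error(predict(m, fx$X[, -1]), "missing")
})

test_that("r_squared endpoints and oracle", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  y_hat <- c(1.2, 2.5, 2.4, 4.4, 4.1)
  expect_equal(r_squared(y, y_hat),
               1 - sum((y - y_hat)^2) / sum((y - mean(y))^2), tolerance = 1e-14)
  expect_error(r_squared(rep(1, 5), y_hat), "zero-variance")
})

test_that("hat-matrix Q2 equals the literal refit-per-row oracle", {
  for (seed in 1:20) {
    fx <- make_regression_fixture(n = 10 + seed %% 7, p = 3, seed = seed)
    expect_equal(q2_loo(fx$X, fx$y), loo_q2_bruteforce(fx$X, fx$y),
                 tolerance = 1e-10, info = paste("seed", seed))
  }
})

test_that("Q2 is 1 on exact linear data and below R2 under noise", {
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(q2_loo(X, 2 + X[, 1] - 3 * X[, 2]), 1, tolerance = 1e-10)
  for (seed in 1:20) {
    set.seed(seed + 100)
    Xn <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
    yn <- rnorm(40)  # pure noise
    m <- fit_mlr(Xn, yn)
    expect_lt(q2_loo(Xn, yn), m$training_r2)
  }
})

test_that("run_protocol is perfect on noiseless planted data and deterministic", {
  fx <- generate_matrix(synthetic_spec(n_molecules = 60, n_descriptors = 8,
                                       support_size = 3, noise_sd = 0,
                                       seed = 11))
  plan <- make_split_plan(rownames(fx$matrix$values), seed = 2, n_repeats = 10)
  st <- run_protocol(fx$matrix, fx$y, fx$true_support, plan)
  expect_equal(st$pct_meeting_criteria, 100)
  expect_true(all(st$per_split$validation_r2 > 0.999))
  expect_true(st$stable)
  st2 <- run_protocol(fx$matrix, fx$y, fx$true_support, plan)
  expect_equal(st$per_split, st2$per_split)
  expect_equal(st$testing_r2, st2$testing_r2)
})

test_that("y-scrambling collapses validation performance", {
  fx <- generate_matrix(synthetic_spec(n_molecules = 80, n_descriptors = 10,
                                       support_size = 3, target_r2 = 0.7,
                                       seed = 21))
  plan <- make_split_plan(rownames(fx$matrix$values), seed = 3, n_repeats = 10)
  means <- vapply(1:10, function(s) {
    set.seed(s)
    ys <- setNames(sample(fx$y), names(fx$y))
    mean(run_protocol(fx$matrix, ys, fx$true_support, plan)$per_split$validation_r2)
  }, numeric(1))
  expect_lt(mean(means), 0.2)
  # while the unscrambled protocol performs well
  real <- run_protocol(fx$matrix, fx$y, fx$true_support, plan)
  expect_gt(mean(real$per_split$validation_r2), 0.5)
})

test_that("protocol supports select-once and per-split selector functions", {
  fx <- generate_matrix(synthetic_spec(n_molecules = 60, n_descriptors = 8,
                                       support_size = 2, target_r2 = 0.8,
                                       seed = 31))
  plan <- make_split_plan(rownames(fx$matrix$values), seed = 5, n_repeats = 5)
  selector <- function(X, y) forward_stepwise(X, y, selection_config(k = 2))
  per_split <- run_protocol(fx$matrix, fx$y, selector, plan)
  once <- run_protocol(fx$matrix, fx$y, selector, plan, selection = "once")
  expect_length(once$final_descriptors, 2)
  expect_length(unique(once$split_descriptors), 1)  # reused subset
  expect_s3_class(per_split$final_model, "qsar_model")
})

test_that("the frozen published model evaluates exactly", {
  m <- published_model()
  zero <- data.frame(balabanJ = 0, b_max1len = 0, Q_VSA_PNEG = 0,
                     vsa_acc = 0, SlogP_VSA1 = 0)
  expect_equal(unname(predict(m, zero)), 11.29, tolerance = 1e-12)
  ones <- zero + 1
  expect_equal(unname(predict(m, ones)),
               11.29 - 3.77 + 0.23 - 0.029 + 0.043 - 0.026, tolerance = 1e-12)
  bj <- zero; bj$balabanJ <- 1
  expect_equal(unname(predict(m, bj)), 7.52, tolerance = 1e-12)
})

test_that("models round-trip through JSON", {
  fx <- make_regression_fixture(seed = 6)
  m <- fit_mlr(fx$X, fx$y)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-12)
})
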