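# descriptor-subset selection: combinatorics, stepwise, lasso path, GA,
# GreedGene

test_that("binomial counts are exact", {
  expect_equal(count_combinations(160, 5), 820384032)
  expect_equal(count_combinations(158, 3), 158 * 157 * 156 / 6)
  expect_equal(count_combinations(5, 5), 1)
  expect_equal(count_combinations(7, 0), 1)
  expect_error(count_combinations(3, 5), "exceed")
  expect_error(count_combinations(2.5, 1), "integer")
  # consistency with R's choose over a grid
  for (n in c(10, 25, 60)) for (k in 0:5) {
    expect_equal(count_combinations(n, k), choose(n, k))
  }
})

test_that("stepwise starts from the best single descriptor", {
  set.seed(1)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, LETTERS[1:5]))
  y <- X[, "C"]
  r <- forward_stepwise(X, y, selection_config(k = 1))
  expect_equal(r$descriptor_names, "C")
  r_all <- forward_stepwise(X, y, selection_config(k = 5))
  expect_setequal(r_all$descriptor_names, LETTERS[1:5])
})

test_that("stepwise finds a planted pair confirmed by exhaustive search", {
  fx <- generate_matrix(synthetic_spec(n_molecules = 50, n_descriptors = 10,
                                       support_size = 2, coefficients = c(2, 3),
                                       noise_sd = 0.3, seed = 13))
  r <- forward_stepwise(fx$matrix, fx$y, selection_config(k = 2))
  ex <- exhaustive_select(fx$matrix, fx$y, 2)
  expect_setequal(r$descriptor_names, fx$true_support)
  expect_setequal(ex$descriptor_names, fx$true_support)
  expect_equal(r$fitness_value, ex$fitness_value, tolerance = 1e-12)
  # classic correlation-driven entry also lands on the strong support here
  rc <- forward_stepwise(fx$matrix, fx$y, selection_config(k = 2), classic = TRUE)
  expect_setequal(rc$descriptor_names, fx$true_support)
})

test_that("lasso entry order tracks |correlation| on an orthonormal design", {
  set.seed(11)
  Q <- qr.Q(qr(scale(matrix(rnorm(240), 40, 6), center = TRUE, scale = FALSE)))
  colnames(Q) <- paste0("V", 1:6)
  y <- drop(Q %*% c(3, -2, 1.2, 0.6, 0.3, 0.1))
  r <- lasso_path_select(Q, y, selection_config(k = 4))
  expect_equal(r$trace[1:4], colnames(Q)[order(-abs(cor(Q, y)))][1:4])
  expect_equal(sort(r$descriptor_names), c("V1", "V2", "V3", "V4"))
})

test_that("lasso selects an exactly-matching single column and planted pairs", {
  set.seed(12)
  X <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("d", 1:6)))
  r1 <- lasso_path_select(X, X[, "d4"], selection_config(k = 1))
  expect_equal(r1$descriptor_names, "d4")

  fx <- generate_matrix(synthetic_spec(n_molecules = 60, n_descriptors = 8,
                                       support_size = 2, coefficients = c(3, -2),
                                       noise_sd = 0.3, seed = 17))
  r2 <- lasso_path_select(fx$matrix, fx$y, selection_config(k = 2))
  ex <- exhaustive_select(fx$matrix, fx$y, 2)
  expect_setequal(r2$descriptor_names, ex$descriptor_names)
})

test_that("lasso reports when too few variables activate", {
  set.seed(5)
  # a zero-variance column can never enter the active set
  X <- cbind(a = rnorm(30), flat = rep(1, 30))
  y <- 2 * X[, "a"] + rnorm(30, sd = 0.1)
  expect_error(lasso_path_select(X, y, selection_config(k = 2)), "entered")
})

test_that("GA finds the global optimum on an easy planted instance", {
  fx <- generate_matrix(synthetic_spec(n_molecules = 70, n_descriptors = 15,
                                       support_size = 3,
                                       coefficients = c(2, -2, 1.5),
                                       target_r2 = 0.95, seed = 23))
  ex <- exhaustive_select(fx$matrix, fx$y, 3)  # full C(15,3) oracle
  g1 <- ga_select(fx$matrix, fx$y, selection_config(k = 3, seed = 1))
  g2 <- ga_select(fx$matrix, fx$y, selection_config(k = 3, seed = 999))
  expect_equal(g1$descriptor_names, ex$descriptor_names)
  expect_equal(g2$descriptor_names, ex$descriptor_names)  # seed-independent optimum
  expect_equal(g1$fitness_value, ex$fitness_value, tolerance = 1e-12)
  # trace is monotone non-decreasing (best-ever)
  expect_true(all(diff(g1$trace) >= 0))
})

test_that("GA degenerate cases behave", {
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, letters[1:4]))
  y <- rnorm(20)
  r <- ga_select(X, y, selection_config(k = 4, seed = 1))
  expect_setequal(r$descriptor_names, letters[1:4])
  expect_error(selection_config(ga_population = 1), "population")
})

test_that("GA is deterministic given a seed", {
  fx <- generate_matrix(synthetic_spec(n_molecules = 50, n_descriptors = 12,
                                       support_size = 3, seed = 29))
  a <- ga_select(fx$matrix, fx$y, selection_config(k = 3, seed = 42,
                                                   ga_generations = 10))
  b <- ga_select(fx$matrix, fx$y, selection_config(k = 3, seed = 42,
                                                   ga_generations = 10))
  expect_identical(a$descriptor_names, b$descriptor_names)
  expect_identical(a$trace, b$trace)
})

test_that("GreedGene matches the exhaustive optimum and its accounting", {
  fx <- generate_matrix(synthetic_spec(n_molecules = 80, n_descriptors = 20,
                                       support_size = 3, target_r2 = 0.95,
                                       seed = 37))
  ex <- exhaustive_select(fx$matrix, fx$y, 3)
  gg <- greedgene(fx$matrix, fx$y, selection_config(k = 3, seed = 5,
                                                    ga_generations = 25))
  expect_equal(gg$descriptor_names, ex$descriptor_names)
  expect_equal(gg$fitness_value, ex$fitness_value, tolerance = 1e-12)
  # accounting: completions evaluated = C(p - |core|, k - |core|)
  expect_equal(gg$exhaustive_evaluations,
               count_combinations(20 - length(gg$core_names),
                                  3 - length(gg$core_names)))
  # hybrid is never worse than any of its own GA repeats
  for (run in attr(gg, "ga_repeats")) {
    expect_gte(gg$fitness_value, run$fitness_value - 1e-12)
  }
})

test_that("GreedGene refuses exhaustive runs over budget, reporting the count", {
  set.seed(7)
  X <- matrix(rnorm(40 * 160), 40, 160, dimnames = list(NULL, sprintf("D%03d", 1:160)))
  y <- rnorm(40)
  cfg <- selection_config(k = 5, seed = 1, ga_population = 6,
                          ga_generations = 1, ga_repeats = 2,
                          core_consensus_fraction = 1, exhaustive_budget = 1000)
  expect_error(greedgene(X, y, cfg), "budget")
})

test_that("swap refinement recovers a better correlated twin", {
  # plant the response on column A; prune sees only its noisy twin A_dup
  set.seed(41)
  n <- 60
  A <- rnorm(n)
  A_dup <- A + rnorm(n, sd = 0.3)
  B <- rnorm(n); C <- rnorm(n)
  y <- 2 * A + 0.5 * B + rnorm(n, sd = 0.2)
  X_full <- cbind(A = A, A_dup = A_dup, B = B, C = C)
  rownames(X_full) <- sprintf("m%02d", 1:n)
  groups <- list(A_dup = c("A", "A_dup"), B = "B", C = "C")
  X_pruned <- X_full[, c("A_dup", "B", "C")]
  gg <- greedgene(X_pruned, y, selection_config(k = 2, seed = 3, ga_repeats = 3,
                                                ga_generations = 10),
                  correlation_groups = groups, X_full = X_full)
  expect_setequal(gg$descriptor_names, c("A", "B"))
  # the swap strictly improved on the pruned-matrix optimum
  no_swap <- exhaustive_select(X_pruned, y, 2)
  expect_gt(gg$fitness_value, no_swap$fitness_value)
})

test_that("all four algorithms return exactly k distinct pruned names", {
  fx <- generate_matrix(synthetic_spec(n_molecules = 70, n_descriptors = 12,
                                       support_size = 3, target_r2 = 0.8,
                                       seed = 43))
  cfg <- selection_config(k = 3, seed = 2, ga_generations = 15)
  results <- list(
    forward_stepwise(fx$matrix, fx$y, cfg),
    lasso_path_select(fx$matrix, fx$y, cfg),
    ga_select(fx$matrix, fx$y, cfg),
    greedgene(fx$matrix, fx$y, cfg)
  )
  for (r in results) {
    expect_length(r$descriptor_names, 3)
    expect_equal(anyDuplicated(r$descriptor_names), 0L)
    expect_true(all(r$descriptor_names %in% colnames(fx$matrix$values)))
  }
})
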