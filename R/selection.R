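# Descriptor-subset selection: forward stepwise, lasso-path entry order, a
# fixed-size genetic algorithm, and GreedGene - the hybrid that completes a
# consensus core from repeated GA runs by exhaustive search, then refines by
# correlated-descriptor swaps.

#' Exact binomial coefficient
#'
#' Exact integer C(n, k), used to pre-plan exhaustive completions and to
#' refuse runs whose regression count exceeds the configured budget. The
#' full search over 160 descriptors for a 5-descriptor model would already
#' cost C(160, 5) = 820,384,032 model fits, which is what the hybrid
#' selector is designed to avoid.
#'
#' @param n Pool size (non-negative integer).
#' @param k Subset size, `0 <= k <= n`.
#' @return The exact count as a double (exact while below 2^53).
#' @examples
#' count_combinations(160, 5)  # 820384032
#' @export
count_combinations <- function(n, k) {
  n <- as.numeric(n); k <- as.numeric(k)
  if (length(n) != 1L || length(k) != 1L || n < 0 || k < 0 ||
      n != floor(n) || k != floor(k)) {
    stop_gg("n and k must be single non-negative integers")
  }
  if (k > n) stop_gg("k must not exceed n")
  k <- min(k, n - k)
  if (k == 0) return(1)
  out <- 1
  for (i in seq_len(k)) out <- out * (n - k + i) / i
  round(out)
}

#' Selection configuration
#'
#' @param k Target subset size (the models are built with exactly `k`
#'   descriptors; default 5, matching the 1:25 descriptor:compound guidance
#'   for a ~127-compound modeling set).
#' @param fitness Objective: `"q2_loo"` (leave-one-out Q2 of the
#'   k-descriptor MLR; default, penalizes overfit) or `"r2_train"`.
#' @param ga_population GA population size.
#' @param ga_generations GA generations.
#' @param ga_mutation_rate Per-gene replacement probability (default `1/p`,
#'   resolved at run time).
#' @param ga_crossover_rate Probability a child is produced by crossover.
#' @param ga_repeats Number of independent GA runs pooled by [greedgene()].
#' @param core_consensus_fraction Fraction of GA repeats a descriptor must
#'   appear in to join the GreedGene core.
#' @param exhaustive_budget Maximum number of exhaustive completions
#'   [greedgene()] may evaluate before refusing.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `selection_config` list.
#' @export
selection_config <- function(k = 5L, fitness = c("q2_loo", "r2_train"),
                             ga_population = 100L, ga_generations = 50L,
                             ga_mutation_rate = NULL, ga_crossover_rate = 0.8,
                             ga_repeats = 5L, core_consensus_fraction = 0.8,
                             exhaustive_budget = 2e6, seed = 1L) {
  fitness <- match.arg(fitness)
  if (k < 1L) stop_gg("k must be >= 1")
  if (core_consensus_fraction <= 0 || core_consensus_fraction > 1) {
    stop_gg("core_consensus_fraction must be in (0, 1]")
  }
  if (ga_population < 2L) stop_gg("ga_population must be >= 2")
  structure(list(
    k = as.integer(k), fitness = fitness,
    ga_population = as.integer(ga_population),
    ga_generations = as.integer(ga_generations),
    ga_mutation_rate = ga_mutation_rate,
    ga_crossover_rate = ga_crossover_rate,
    ga_repeats = as.integer(ga_repeats),
    core_consensus_fraction = core_consensus_fraction,
    exhaustive_budget = exhaustive_budget,
    seed = as.integer(seed)
  ), class = "selection_config")
}

selection_result <- function(algorithm, names, fitness_value,
                             core_names = NULL, exhaustive_evaluations = NA,
                             trace = NULL) {
  structure(list(
    algorithm = algorithm, descriptor_names = names,
    fitness_value = fitness_value, core_names = core_names,
    exhaustive_evaluations = exhaustive_evaluations, trace = trace
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection: {%s}\n  fitness = %.4f\n", x$algorithm,
              paste(x$descriptor_names, collapse = ", "), x$fitness_value))
  if (!is.null(x$core_names)) {
    cat("  consensus core: {", paste(x$core_names, collapse = ", "), "}\n", sep = "")
  }
  if (!is.na(x$exhaustive_evaluations %||% NA)) {
    cat("  exhaustive completions evaluated:", format(x$exhaustive_evaluations, big.mark = ","), "\n")
  }
  invisible(x)
}

# prepares the shared evaluation closure; subsets are integer column index
# vectors into X
make_evaluator <- function(X, y, fitness) {
  X <- as_descriptor_values(X)
  ss_tot <- sum((y - mean(y))^2)
  fn <- if (fitness == "q2_loo") fitness_q2 else fitness_r2
  ones <- rep(1, nrow(X))
  function(cols) fn(cbind(ones, X[, cols, drop = FALSE]), y, ss_tot)
}

subset_names <- function(X, cols) sort(colnames(as_descriptor_values(X))[cols])

#' Forward stepwise descriptor selection
#'
#' Starts from the single best descriptor and greedily adds, at each step,
#' the descriptor whose refit model maximizes the configured fitness, until
#' `k` descriptors are selected. Ties are broken lexicographically by name.
#' With `classic = TRUE` candidates are instead ranked by absolute partial
#' correlation with the current residual (the traditional
#' correlation-driven entry), and the fitness of the final refit is
#' reported.
#'
#' @param X Descriptor matrix (pruned).
#' @param y Response (pKi).
#' @param config A [selection_config()].
#' @param classic Use correlation-driven entry instead of fitness-driven.
#' @return A `selection_result`.
#' @export
forward_stepwise <- function(X, y, config = selection_config(), classic = FALSE) {
  Xv <- as_descriptor_values(X)
  p <- ncol(Xv)
  if (config$k > p) stop_gg("k exceeds the number of descriptors")
  if (nrow(Xv) <= config$k + 1L) stop_gg("need n > k + 1 rows")
  evaluate <- make_evaluator(Xv, y, config$fitness)
  ord <- order(colnames(Xv))  # lexicographic candidate order => ties break by name
  chosen <- integer(0)
  for (step in seq_len(config$k)) {
    cand <- setdiff(ord, chosen)
    if (classic) {
      res <- if (length(chosen)) {
        stats::lm.fit(cbind(1, Xv[, chosen, drop = FALSE]), y)$residuals
      } else {
        y - mean(y)
      }
      sds <- apply(Xv[, cand, drop = FALSE], 2, stats::sd)
      sc <- abs(suppressWarnings(stats::cor(Xv[, cand, drop = FALSE], res)))
      sc[sds == 0] <- -Inf
      best <- cand[which.max(sc)]
    } else {
      scores <- vapply(cand, function(j) evaluate(c(chosen, j)), numeric(1))
      if (all(!is.finite(scores))) {
        warning(sprintf("all candidates singular at step %d", step))
        break
      }
      best <- cand[which.max(scores)]
    }
    chosen <- c(chosen, best)
  }
  selection_result("stepwise", subset_names(Xv, chosen), evaluate(chosen))
}

#' Lasso-path descriptor selection
#'
#' Columns are standardized internally and the lasso path is traversed from
#' large to small penalty; the first `k` distinct descriptors to enter the
#' active set are selected (ties within one path step are ordered by
#' absolute correlation with the response, then name). The reported fitness
#' is that of the unpenalized MLR refit on the selected `k`.
#'
#' @param X Descriptor matrix.
#' @param y Response.
#' @param config A [selection_config()].
#' @param lambda_path Optional descending positive lambda sequence;
#'   by default a fine 200-step path is used.
#' @return A `selection_result` (with `trace` recording the entry order).
#' @export
lasso_path_select <- function(X, y, config = selection_config(),
                              lambda_path = NULL) {
  Xv <- as_descriptor_values(X)
  if (config$k > ncol(Xv)) stop_gg("k exceeds the number of descriptors")
  fit <- glmnet::glmnet(
    Xv, y, alpha = 1, standardize = TRUE,
    lambda = lambda_path, nlambda = 200L, lambda.min.ratio = 1e-4,
    intercept = TRUE
  )
  beta <- fit$beta  # p x nlambda sparse matrix, lambda descending
  first_idx <- apply(as.matrix(beta) != 0, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else Inf
  })
  activated <- names(first_idx)[is.finite(first_idx)]
  if (length(activated) < config$k) {
    stop_gg(sprintf("only %d descriptor(s) entered the lasso path; need k = %d",
                    length(activated), config$k))
  }
  ry <- abs(drop(stats::cor(Xv, y)))
  ord <- order(first_idx[activated], -ry[activated], activated)
  entry <- activated[ord]
  chosen <- entry[seq_len(config$k)]
  evaluate <- make_evaluator(Xv, y, config$fitness)
  selection_result("lasso", sort(chosen),
                   evaluate(match(chosen, colnames(Xv))),
                   trace = entry)
}

#' Genetic-algorithm descriptor selection
#'
#' Individuals are exactly-k descriptor subsets (a fixed-size bitstring with
#' a repair operator). Each generation applies tournament selection (size
#' 2), uniform subset crossover, per-gene swap mutation (default rate 1/p),
#' and elitism (the best individual survives unchanged). Returns the best
#' subset ever evaluated. Deterministic given `config$seed`.
#'
#' @param X Descriptor matrix (pruned so no pair of columns is correlated
#'   above the pruning threshold).
#' @param y Response.
#' @param config A [selection_config()].
#' @return A `selection_result` with a per-generation best-fitness `trace`.
#' @export
ga_select <- function(X, y, config = selection_config()) {
  Xv <- as_descriptor_values(X)
  p <- ncol(Xv)
  k <- config$k
  if (k > p) stop_gg("k exceeds the number of descriptors")
  if (config$ga_population < 2L) stop_gg("population must be >= 2")
  if (k == p) {
    evaluate <- make_evaluator(Xv, y, config$fitness)
    return(selection_result("ga", subset_names(Xv, seq_len(p)),
                            evaluate(seq_len(p)), trace = numeric(0)))
  }
  mut_rate <- config$ga_mutation_rate %||% (1 / p)
  evaluate <- make_evaluator(Xv, y, config$fitness)

  with_seed(config$seed, {
    pop_n <- config$ga_population
    pop <- lapply(seq_len(pop_n), function(i) sort(sample.int(p, k)))
    fit <- vapply(pop, evaluate, numeric(1))
    best_i <- which.max(fit)
    best <- pop[[best_i]]
    best_fit <- fit[best_i]
    trace <- numeric(config$ga_generations)

    for (gen in seq_len(config$ga_generations)) {
      tournament <- function() {
        c2 <- sample.int(pop_n, 2L)
        if (fit[c2[1L]] >= fit[c2[2L]]) pop[[c2[1L]]] else pop[[c2[2L]]]
      }
      newpop <- vector("list", pop_n)
      newpop[[1L]] <- best  # elitism
      for (i in seq(2L, pop_n)) {
        child <- if (stats::runif(1) < config$ga_crossover_rate) {
          a <- tournament(); b <- tournament()
          common <- intersect(a, b)
          pool <- setdiff(union(a, b), common)
          need <- k - length(common)
          sort(c(common, pool[sample.int(length(pool))][seq_len(need)]))
        } else {
          tournament()
        }
        # per-gene swap mutation preserving |subset| = k
        flip <- which(stats::runif(k) < mut_rate)
        if (length(flip)) {
          outside <- setdiff(seq_len(p), child)
          n_flip <- min(length(flip), length(outside))
          flip <- flip[seq_len(n_flip)]
          repl <- outside[sample.int(length(outside), n_flip)]
          child <- sort(c(child[-flip], repl))
        }
        newpop[[i]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, evaluate, numeric(1))
      gi <- which.max(fit)
      if (fit[gi] > best_fit) {
        best_fit <- fit[gi]
        best <- pop[[gi]]
      }
      trace[gen] <- best_fit
    }
    selection_result("ga", subset_names(Xv, best), best_fit, trace = trace)
  })
}

#' GreedGene: hybrid GA + exhaustive descriptor selection
#'
#' Runs the genetic algorithm `ga_repeats` times with derived seeds; the
#' descriptors present in at least `core_consensus_fraction` of the repeat
#' results form the consensus core (truncated to the `k` most frequent if
#' larger). Every completion of the core to size `k` over the remaining
#' descriptors is then evaluated exhaustively - C(p - |core|, k - |core|)
#' model fits, checked against `exhaustive_budget` before starting. Finally,
#' because correlation pruning kept a single representative per correlated
#' group, each selected descriptor is tentatively swapped with every member
#' of its group and any strict fitness improvement is kept, repeating until
#' a fixed point.
#'
#' @param X Descriptor matrix (pruned).
#' @param y Response.
#' @param config A [selection_config()].
#' @param correlation_groups Optional `groups` mapping from
#'   [prune_correlated()] (representative -> correlated members) used by the
#'   swap-refinement stage. Swapped-in members are looked up in `X_full`.
#' @param X_full Optional unpruned matrix containing the correlated group
#'   members (defaults to `X`).
#' @return A `selection_result` with `core_names`,
#'   `exhaustive_evaluations`, and the GA repeats' results in
#'   `attr(, "ga_repeats")`.
#' @export
greedgene <- function(X, y, config = selection_config(),
                      correlation_groups = NULL, X_full = NULL) {
  Xv <- as_descriptor_values(X)
  p <- ncol(Xv)
  k <- config$k
  if (k > p) stop_gg("k exceeds the number of descriptors")

  runs <- lapply(seq_len(config$ga_repeats), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    ga_select(Xv, y, cfg)
  })
  freq <- sort(table(unlist(lapply(runs, `[[`, "descriptor_names"))), decreasing = TRUE)
  need <- config$core_consensus_fraction * config$ga_repeats
  core <- names(freq)[freq >= need]
  if (length(core) > k) {
    # k most frequent, ties lexicographic
    ord <- order(-as.numeric(freq[core]), core)
    core <- core[ord][seq_len(k)]
  }
  core <- sort(core)

  n_eval <- count_combinations(p - length(core), k - length(core))
  if (n_eval > config$exhaustive_budget) {
    stop_gg(sprintf(
      "exhaustive completion needs %s model fits (C(%d, %d)), over the budget of %s",
      format(n_eval, big.mark = ","), p - length(core), k - length(core),
      format(config$exhaustive_budget, big.mark = ",")))
  }

  evaluate <- make_evaluator(Xv, y, config$fitness)
  core_idx <- match(core, colnames(Xv))
  pool <- setdiff(seq_len(p), core_idx)
  need_k <- k - length(core)
  if (need_k == 0L) {
    best_idx <- core_idx
    best_fit <- evaluate(core_idx)
  } else {
    combos <- utils::combn(pool, need_k)
    best_fit <- -Inf
    best_idx <- NULL
    for (cc in seq_len(ncol(combos))) {
      idx <- c(core_idx, combos[, cc])
      f <- evaluate(idx)
      if (f > best_fit ||
          (f == best_fit && !is.null(best_idx) &&
           paste(subset_names(Xv, idx), collapse = "\r") <
             paste(subset_names(Xv, best_idx), collapse = "\r"))) {
        best_fit <- f
        best_idx <- idx
      }
    }
  }
  # the hybrid must be at least as good as every GA repeat it pooled: a
  # repeat's best subset need not contain the full consensus core, so it is
  # compared against the exhaustive completion explicitly
  for (run in runs) {
    idx <- match(run$descriptor_names, colnames(Xv))
    if (run$fitness_value > best_fit) {
      best_fit <- run$fitness_value
      best_idx <- idx
    }
  }
  names_sel <- subset_names(Xv, best_idx)

  # swap refinement over correlated groups
  if (!is.null(correlation_groups)) {
    Xf <- as_descriptor_values(X_full %||% Xv)
    current <- names_sel
    current_fit <- best_fit
    repeat {
      improved <- FALSE
      for (nm in current) {
        members <- setdiff(correlation_groups[[nm]] %||% character(0), current)
        for (m in members) {
          if (!m %in% colnames(Xf)) next
          trial <- sort(c(setdiff(current, nm), m))
          Xt <- cbind(Xf[, intersect(trial, colnames(Xf)), drop = FALSE])
          if (ncol(Xt) < length(trial)) next
          f <- make_evaluator(Xt, y, config$fitness)(seq_len(ncol(Xt)))
          if (f > current_fit) {
            # carry the group mapping to the swapped-in member
            correlation_groups[[m]] <- correlation_groups[[nm]]
            current <- trial
            current_fit <- f
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) break
    }
    names_sel <- current
    best_fit <- current_fit
  }

  out <- selection_result("greedgene", names_sel, best_fit,
                          core_names = core, exhaustive_evaluations = n_eval,
                          trace = vapply(runs, `[[`, numeric(1), "fitness_value"))
  attr(out, "ga_repeats") <- runs
  out
}

#' Exhaustive best subset (reference oracle)
#'
#' Evaluates every C(p, k) subset and returns the optimum. Intended for
#' small p as an independent check of the heuristic selectors; refuses runs
#' over `budget`.
#'
#' @param X Descriptor matrix.
#' @param y Response.
#' @param k Subset size.
#' @param fitness `"q2_loo"` or `"r2_train"`.
#' @param budget Maximum number of evaluations.
#' @return A `selection_result`.
#' @export
exhaustive_select <- function(X, y, k, fitness = "q2_loo", budget = 2e6) {
  Xv <- as_descriptor_values(X)
  p <- ncol(Xv)
  n_eval <- count_combinations(p, k)
  if (n_eval > budget) stop_gg("exhaustive search needs ", n_eval, " evaluations")
  evaluate <- make_evaluator(Xv, y, fitness)
  combos <- utils::combn(p, k)
  best_fit <- -Inf
  best_idx <- NULL
  for (cc in seq_len(ncol(combos))) {
    f <- evaluate(combos[, cc])
    if (f > best_fit) {
      best_fit <- f
      best_idx <- combos[, cc]
    }
  }
  selection_result("exhaustive", subset_names(Xv, best_idx), best_fit,
                   exhaustive_evaluations = n_eval)
}
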