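# Multivariate linear regression QSAR models: fitting, R2 / LOO-Q2
# statistics, the repeated-split validation protocol, and the frozen
# published five-descriptor S2R model.

#' Fit a multivariate linear regression QSAR model
#'
#' Ordinary least-squares fit of `y` (typically pKi) on the selected
#' descriptor columns, solved exactly via QR.
#'
#' @param X Numeric matrix (molecules x descriptors) with column names, or a
#'   data.frame coercible to one. Only the columns named in `names` are used
#'   when `names` is given.
#' @param y Numeric response vector (pKi), length `nrow(X)`.
#' @param names Optional character vector restricting `X` to a descriptor
#'   subset.
#' @return A `qsar_model` object: list with `intercept`, named `coefficients`,
#'   `fitted`, `residuals`, `training_r2` and `provider_label`.
#' @examples
#' X <- cbind(a = rnorm(20), b = rnorm(20))
#' fit_mlr(X, 1 + 2 * X[, "a"] - X[, "b"])
#' @export
fit_mlr <- function(X, y, names = NULL) {
  X <- as_descriptor_values(X)
  if (!is.null(names)) {
    missing <- setdiff(names, colnames(X))
    if (length(missing)) {
      stop_gg("descriptor columns missing from X: ", paste(missing, collapse = ", "))
    }
    X <- X[, names, drop = FALSE]
  }
  if (length(y) != nrow(X)) stop_gg("length(y) must equal nrow(X)")
  if (nrow(X) <= ncol(X) + 1L) stop_gg("need n > k + 1 observations to fit")
  A <- cbind(`(Intercept)` = 1, X)
  dec <- qr(A)
  if (dec$rank < ncol(A)) {
    bad <- colnames(A)[dec$pivot[seq(dec$rank + 1L, ncol(A))]]
    stop_gg("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  cf <- qr.coef(dec, y)
  fitted <- drop(A %*% cf)
  res <- y - fitted
  r2 <- if (stats::var(y) > 0) 1 - sum(res^2) / sum((y - mean(y))^2) else NA_real_
  qsar_model(
    intercept = unname(cf[1L]),
    coefficients = cf[-1L],
    provider_label = "fit_mlr",
    fitted = fitted, residuals = res, training_r2 = r2
  )
}

#' Construct a linear QSAR model object
#'
#' @param intercept Numeric scalar.
#' @param coefficients Named numeric vector of descriptor coefficients.
#' @param provider_label Label for the descriptor provider the model was fit
#'   against (predictions are only meaningful on descriptors from the same
#'   provider).
#' @param ... Extra fields stored on the object (e.g. fit diagnostics).
#' @return A `qsar_model` object.
#' @export
qsar_model <- function(intercept, coefficients, provider_label = "user", ...) {
  assert_scalar_number(intercept, "intercept")
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients)) ||
      any(!nzchar(names(coefficients)))) {
    stop_gg("`coefficients` must have unique non-empty names")
  }
  structure(
    list(intercept = intercept, coefficients = coefficients,
         provider_label = provider_label, ...),
    class = "qsar_model"
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("Linear QSAR model (", x$provider_label, ")\n", sep = "")
  cat(sprintf("  pKi = %.4g", x$intercept))
  for (nm in names(x$coefficients)) {
    b <- x$coefficients[[nm]]
    cat(sprintf(" %s %.4g * %s", if (b < 0) "-" else "+", abs(b), nm))
  }
  cat("\n")
  if (!is.null(x$training_r2)) cat(sprintf("  training R2 = %.4f\n", x$training_r2))
  invisible(x)
}

#' Predict pKi for new molecules
#'
#' @param object A `qsar_model`.
#' @param newdata Descriptor matrix or data.frame containing every descriptor
#'   named in the model's coefficients.
#' @param ... Unused.
#' @return Numeric vector of predicted pKi, named by row when `newdata` has
#'   row names.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  X <- as_descriptor_values(newdata)
  missing <- setdiff(names(object$coefficients), colnames(X))
  if (length(missing)) {
    stop_gg("descriptor columns missing from newdata: ", paste(missing, collapse = ", "))
  }
  drop(object$intercept +
         X[, names(object$coefficients), drop = FALSE] %*% object$coefficients)
}

#' Coefficient of determination
#'
#' `r_squared()` is the squared-correlation-style fit statistic
#' 1 - SS_res/SS_tot; with `pearson2 = TRUE` it is the squared Pearson
#' correlation between observed and predicted values instead. The two agree
#' on training data but differ out of sample.
#'
#' @param y Observed values.
#' @param y_hat Predicted values.
#' @param pearson2 Use squared Pearson correlation instead of
#'   1 - SS_res/SS_tot.
#' @return Numeric scalar (at most 1 for the default definition).
#' @export
r_squared <- function(y, y_hat, pearson2 = FALSE) {
  if (length(y) != length(y_hat) || length(y) < 2L) {
    stop_gg("y and y_hat must have equal length >= 2")
  }
  if (stats::var(y) == 0) stop_gg("r_squared undefined: zero-variance y")
  if (pearson2) return(stats::cor(y, y_hat)^2)
  1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)
}

# fast LOO Q2 for the selection inner loop: Cholesky of the normal equations
# plus the PRESS identity e_i / (1 - h_ii). Returns -Inf on a singular or
# leverage-one design so selection can simply skip the candidate.
fitness_q2 <- function(A, y, ss_tot = sum((y - mean(y))^2)) {
  AtA <- crossprod(A)
  R <- tryCatch(chol(AtA), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  cf <- backsolve(R, forwardsolve(R, crossprod(A, y), upper.tri = TRUE, transpose = TRUE))
  res <- y - drop(A %*% cf)
  B <- forwardsolve(R, t(A), upper.tri = TRUE, transpose = TRUE)
  h <- colSums(B^2)
  if (any(h > 1 - 1e-10)) return(-Inf)
  1 - sum((res / (1 - h))^2) / ss_tot
}

fitness_r2 <- function(A, y, ss_tot = sum((y - mean(y))^2)) {
  AtA <- crossprod(A)
  R <- tryCatch(chol(AtA), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  cf <- backsolve(R, forwardsolve(R, crossprod(A, y), upper.tri = TRUE, transpose = TRUE))
  1 - sum((y - drop(A %*% cf))^2) / ss_tot
}

#' Leave-one-out cross-validated Q2
#'
#' Q2 = 1 - PRESS/SS_tot, where PRESS is the sum of squared prediction errors
#' when each compound in turn is left out and predicted from a model refit on
#' the remainder. Computed by the exact hat-matrix identity
#' e_(i) = e_i / (1 - h_ii), which equals the literal refit-per-row
#' computation for full-rank least squares.
#'
#' @param X Descriptor matrix.
#' @param y Response (pKi).
#' @param names Optional descriptor subset.
#' @return Numeric scalar Q2 (can be negative; at most 1).
#' @export
q2_loo <- function(X, y, names = NULL) {
  X <- as_descriptor_values(X)
  if (!is.null(names)) X <- X[, names, drop = FALSE]
  if (length(y) != nrow(X)) stop_gg("length(y) must equal nrow(X)")
  if (nrow(X) <= ncol(X) + 2L) stop_gg("need n > k + 2 observations for LOO")
  if (stats::var(y) == 0) stop_gg("q2_loo undefined: zero-variance y")
  A <- cbind(1, X)
  out <- fitness_q2(A, y)
  if (!is.finite(out)) stop_gg("a leave-one-out refit is rank-deficient")
  out
}

#' The published five-descriptor S2R binding-affinity model
#'
#' Frozen coefficients of the reported Sigma-2 receptor 2D-QSAR model:
#' pKi = 11.29 - 3.77 balabanJ + 0.23 b_max1len - 0.029 Q_VSA_PNEG
#' + 0.043 vsa_acc - 0.026 SlogP_VSA1. The model was fit on MOE descriptor
#' values; descriptor analogs computed by [compute_descriptors()] carry the
#' same names but are not numerically identical to MOE's, so for faithful
#' scoring supply externally computed descriptor CSVs.
#'
#' @return A `qsar_model` with the frozen intercept and coefficients.
#' @examples
#' m <- published_model()
#' predict(m, data.frame(balabanJ = 0, b_max1len = 0, Q_VSA_PNEG = 0,
#'                       vsa_acc = 0, SlogP_VSA1 = 0))  # 11.29
#' @export
published_model <- function() {
  qsar_model(
    intercept = 11.29,
    coefficients = c(
      balabanJ   = -3.77,
      b_max1len  = +0.23,
      Q_VSA_PNEG = -0.029,
      vsa_acc    = +0.043,
      SlogP_VSA1 = -0.026
    ),
    provider_label = "published-moe"
  )
}

#' Model acceptance criteria for the repeated-split protocol
#'
#' @param train_r2 Strict lower bound on training R2 (split passes when
#'   training R2 exceeds it).
#' @param q2 Non-strict lower bound on training LOO Q2.
#' @param val_r2 Non-strict lower bound on validation R2.
#' @param stability Percentage of splits that must meet the validation
#'   criterion for the model to count as stable.
#' @return A list of thresholds used by [run_protocol()].
#' @export
model_criteria <- function(train_r2 = 0.6, q2 = 0.5, val_r2 = 0.5,
                           stability = 95) {
  list(train_r2 = train_r2, q2 = q2, val_r2 = val_r2, stability = stability)
}

#' Run the repeated-split model building and validation protocol
#'
#' For each train/validation repeat of a [make_split_plan()] plan: select a
#' descriptor subset (or reuse a fixed one), fit the MLR on the training
#' rows, record training R2 and LOO Q2, and score the held-out validation
#' rows. Afterwards the model is refit on the full modeling set with the
#' modeling-set selection and scored on the external testing set.
#'
#' @param X Descriptor matrix over the full curated set (row names = ids).
#' @param y Named pKi vector aligned with `X` (or unnamed, same order).
#' @param selector Either a character vector of fixed descriptor names, or a
#'   function `f(X, y)` returning a `selection_result` or character vector.
#' @param plan A `split_plan`.
#' @param criteria Output of [model_criteria()].
#' @param selection How often to run the selector: `"per_split"` reselects on
#'   every training split (the honest protocol whose per-split ranges are
#'   reported); `"once"` selects on the full modeling set and reuses the
#'   subset.
#' @param pearson2 Passed to [r_squared()] for validation/testing R2.
#' @return A `model_stats` object: per-split table, min/max ranges,
#'   `pct_meeting_criteria`, final model and testing R2.
#' @export
run_protocol <- function(X, y, selector, plan,
                         criteria = model_criteria(),
                         selection = c("per_split", "once"),
                         pearson2 = FALSE) {
  selection <- match.arg(selection)
  X <- as_descriptor_values(X)
  if (is.null(rownames(X))) stop_gg("X must have row names (molecule ids)")
  if (is.null(names(y))) {
    if (length(y) != nrow(X)) stop_gg("unnamed y must align with X rows")
    names(y) <- rownames(X)
  }
  need <- unique(c(plan$modeling_ids, plan$testing_ids))
  missing <- setdiff(need, rownames(X))
  if (length(missing)) stop_gg("split plan ids absent from X: ", paste(utils::head(missing, 5), collapse = ", "))

  pick <- function(Xs, ys) {
    if (is.character(selector)) return(selector)
    out <- selector(Xs, ys)
    if (inherits(out, "selection_result")) out$descriptor_names else out
  }

  fixed_names <- NULL
  if (selection == "once" || is.character(selector)) {
    Xm <- X[plan$modeling_ids, , drop = FALSE]
    fixed_names <- pick(Xm, y[plan$modeling_ids])
  }

  n_rep <- length(plan$repeats)
  per_split <- data.frame(
    repeat_index = seq_len(n_rep), train_r2 = NA_real_,
    train_q2 = NA_real_, validation_r2 = NA_real_, meets = NA
  )
  split_names <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    tr <- plan$repeats[[r]]$train_ids
    va <- plan$repeats[[r]]$validation_ids
    nms <- fixed_names %||% tryCatch(
      pick(X[tr, , drop = FALSE], y[tr]),
      error = function(e) stop_gg(sprintf("selector failed on split %d: %s", r, conditionMessage(e)))
    )
    split_names[[r]] <- nms
    fit <- fit_mlr(X[tr, , drop = FALSE], y[tr], names = nms)
    per_split$train_r2[r] <- fit$training_r2
    per_split$train_q2[r] <- q2_loo(X[tr, , drop = FALSE], y[tr], names = nms)
    pred <- predict(fit, X[va, , drop = FALSE])
    per_split$validation_r2[r] <- r_squared(y[va], pred, pearson2 = pearson2)
    per_split$meets[r] <- per_split$train_r2[r] > criteria$train_r2 &&
      per_split$train_q2[r] >= criteria$q2 &&
      per_split$validation_r2[r] >= criteria$val_r2
  }
  pct <- 100 * mean(per_split$validation_r2 >= criteria$val_r2)

  final_names <- fixed_names %||% pick(X[plan$modeling_ids, , drop = FALSE], y[plan$modeling_ids])
  final <- fit_mlr(X[plan$modeling_ids, , drop = FALSE], y[plan$modeling_ids],
                   names = final_names)
  modeling_q2 <- q2_loo(X[plan$modeling_ids, , drop = FALSE], y[plan$modeling_ids],
                        names = final_names)
  testing_r2 <- if (length(plan$testing_ids) >= 2L) {
    r_squared(y[plan$testing_ids],
              predict(final, X[plan$testing_ids, , drop = FALSE]),
              pearson2 = pearson2)
  } else {
    NA_real_
  }

  structure(list(
    per_split = per_split,
    split_descriptors = split_names,
    ranges = list(
      train_r2 = range(per_split$train_r2),
      train_q2 = range(per_split$train_q2),
      validation_r2 = range(per_split$validation_r2)
    ),
    pct_meeting_criteria = pct,
    stable = pct >= criteria$stability,
    final_model = final,
    final_descriptors = final_names,
    modeling_r2 = final$training_r2,
    modeling_q2 = modeling_q2,
    testing_r2 = testing_r2,
    criteria = criteria
  ), class = "model_stats")
}

#' @export
print.model_stats <- function(x, ...) {
  fmt <- function(r) sprintf("%.2f-%.2f", r[1], r[2])
  cat("Repeated-split QSAR validation (", nrow(x$per_split), " splits)\n", sep = "")
  cat("  training R2:   ", fmt(x$ranges$train_r2), "\n")
  cat("  training Q2:   ", fmt(x$ranges$train_q2), "\n")
  cat("  validation R2: ", fmt(x$ranges$validation_r2), "\n")
  cat(sprintf("  %% splits meeting validation criterion: %.0f%% (stable: %s)\n",
              x$pct_meeting_criteria, x$stable))
  cat(sprintf("  modeling R2 = %.2f, modeling Q2 = %.2f, testing R2 = %.2f\n",
              x$modeling_r2, x$modeling_q2, x$testing_r2))
  invisible(x)
}

# coerce user input (matrix, data.frame, descriptor_matrix) to a plain
# numeric matrix with ids as rownames
as_descriptor_values <- function(X) {
  if (inherits(X, "descriptor_matrix")) return(X$values)
  if (is.data.frame(X)) {
    idcol <- which(vapply(X, is.character, logical(1)))
    if (length(idcol) && identical(names(X)[1], "id")) {
      rn <- X[[1]]
      X <- X[, -1, drop = FALSE]
      X <- as.matrix(X)
      rownames(X) <- rn
      return(X)
    }
    return(as.matrix(X))
  }
  if (!is.matrix(X) || !is.numeric(X)) stop_gg("X must be a numeric matrix or data.frame")
  X
}
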