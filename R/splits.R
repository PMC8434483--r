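# Reproducible modeling/testing and train/validation split plans.

#' Build a reproducible split plan for the repeated 4:1 protocol
#'
#' The curated compound set is first split into a modeling set and an
#' external testing set at `ratio` (default 4:1). The modeling set is then
#' randomly re-split into a training and a validation set at the same ratio,
#' `n_repeats` times (default 50), each repeat seeded with `seed + r` so any
#' individual split is independently reproducible. All set sizes use
#' round-half-up of the modeled fraction: 159 compounds give a 127/32
#' modeling/testing split and a 127-compound modeling set gives 102/25
#' training/validation repeats.
#'
#' Ids are sorted canonically before sampling, so the plan depends only on
#' the id set and the seed, not on input ordering.
#'
#' @param ids Character vector of compound ids (at least 10, unique).
#' @param seed Integer seed.
#' @param ratio Length-2 positive integer vector, modeling:testing
#'   proportions (default `c(4, 1)`).
#' @param n_repeats Number of train/validation repeats (default 50).
#' @return A `split_plan`: list with `modeling_ids`, `testing_ids`,
#'   `repeats` (list of `train_ids`/`validation_ids` pairs), `seed`, `ratio`,
#'   `n_repeats`.
#' @examples
#' plan <- make_split_plan(sprintf("m%03d", 1:159), seed = 1)
#' length(plan$modeling_ids)  # 127
#' @export
make_split_plan <- function(ids, seed, ratio = c(4L, 1L), n_repeats = 50L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_gg("ids must be unique")
  if (length(ids) < 10L) stop_gg("too few compounds to split (need >= 10)")
  if (length(ratio) != 2L || any(ratio <= 0)) stop_gg("ratio must be two positive numbers")
  seed <- as.integer(seed)
  ids <- sort(ids)

  frac <- ratio[1] / sum(ratio)
  n <- length(ids)
  n_model <- round_half_up(n * frac)
  modeling <- with_seed(seed, sort(sample(ids, n_model)))
  testing <- setdiff(ids, modeling)

  n_train <- round_half_up(n_model * frac)
  repeats <- lapply(seq_len(n_repeats), function(r) {
    tr <- with_seed(seed + r, sort(sample(modeling, n_train)))
    list(train_ids = tr, validation_ids = setdiff(modeling, tr))
  })

  structure(list(
    modeling_ids = modeling, testing_ids = testing, repeats = repeats,
    seed = seed, ratio = as.integer(ratio), n_repeats = as.integer(n_repeats)
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "Split plan (seed %d): %d modeling / %d testing; %d repeats of %d train / %d validation\n",
    x$seed, length(x$modeling_ids), length(x$testing_ids), x$n_repeats,
    length(x$repeats[[1]]$train_ids), length(x$repeats[[1]]$validation_ids)
  ))
  invisible(x)
}

#' Write / read a split plan as JSON
#'
#' @param plan A `split_plan`.
#' @param path File path.
#' @return `read_split_plan` returns the `split_plan`; `write_split_plan`
#'   returns `path` invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$repeats <- lapply(seq_len(nrow_or_len(x$repeats)), function(r) {
    if (is.data.frame(x$repeats)) {
      list(train_ids = x$repeats$train_ids[[r]], validation_ids = x$repeats$validation_ids[[r]])
    } else {
      x$repeats[[r]]
    }
  })
  structure(x, class = "split_plan")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
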