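# Plain-text interchange: descriptor matrix CSV, model JSON, report JSON.

#' Read / write a descriptor matrix CSV
#'
#' The CSV has an `id` first column and one named numeric column per
#' descriptor - the interchange format for externally computed descriptors
#' (e.g. a proprietary provider's values for scoring with the published
#' model).
#'
#' @param matrix A `descriptor_matrix`.
#' @param path CSV path.
#' @param provider Provider label attached on read.
#' @return `read_descriptor_csv` returns a `descriptor_matrix`;
#'   `write_descriptor_csv` returns `path` invisibly.
#' @export
write_descriptor_csv <- function(matrix, path) {
  X <- as_descriptor_values(matrix)
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(path, provider = "csv") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop_gg("descriptor CSV must have an `id` first column")
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X)) stop_gg("descriptor columns must be numeric")
  rownames(X) <- df$id
  descriptor_matrix(X, provider = provider)
}

#' Write / read a linear model as JSON
#'
#' @param model A `qsar_model`.
#' @param path JSON path.
#' @return `read_model_json` returns a `qsar_model`; the writer returns
#'   `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    provider_label = model$provider_label
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  qsar_model(x$intercept, unlist(x$coefficients), provider_label = x$provider_label %||% "user")
}
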