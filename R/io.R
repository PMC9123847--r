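check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  df
}

#' Read and write the pipeline's CSV tables
#'
#' Thin, schema-checked CSV round-trips for visit tables
#' (`subject_id, age, delta` plus optional `group`, `week`), pair tables
#' (`subject_id, delta_initial, delta_subsequent, age_initial, ivi`), mouse
#' visit tables (`mouse_id, group, week, age, delta`) and expression tables
#' (`mouse_id, mrna_relative` plus optional `group`). Writers emit plain
#' comma-separated text without row names; each reader validates the schema
#' and returns a data frame that its paired writer reproduces exactly.
#'
#' @param path CSV file path.
#' @param df data frame to write.
#' @name io_csv
NULL

#' @rdname io_csv
#' @export
read_visits <- function(path) {
  check_columns(utils::read.csv(path), c("subject_id", "age", "delta"),
                "visits table")
}

#' @rdname io_csv
#' @export
write_visits <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_pairs <- function(path) {
  validate_pairs(utils::read.csv(path))
}

#' @rdname io_csv
#' @export
write_pairs <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_mouse_visits <- function(path) {
  check_columns(utils::read.csv(path),
                c("mouse_id", "group", "week", "age", "delta"),
                "mouse visits table")
}

#' @rdname io_csv
#' @export
read_expression <- function(path) {
  check_columns(utils::read.csv(path), c("mouse_id", "mrna_relative"),
                "expression table")
}

#' Serialize a natural-history fit as JSON
#'
#' @param fit an `nh_fit`.
#' @param path output path; when `NULL` the JSON string is returned.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "nh_fit"))
  obj <- list(coefficients = fit$coefficients, sigma_b = fit$sigma_b,
              sigma_e = fit$sigma_e, rmse = fit$rmse, aic = fit$aic,
              method = fit$method, units = fit$units,
              n_pairs = fit$n_pairs, n_subjects = fit$n_subjects)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
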