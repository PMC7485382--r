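#' Read a production record from CSV or JSON
#'
#' CSV input needs a header with columns `word` and `onset_seconds`;
#' JSON input is an object `{"word": [...], "onset_seconds": [...]}` (or
#' an array of row objects, as written by [write_production_record()]).
#' The record is validated: unique words, positive strictly increasing
#' onsets.
#'
#' @param path file path; format chosen by extension (`.json` for JSON,
#'   otherwise CSV).
#' @return a [production_record()].
#' @export
read_production_record <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(x)) {
      df <- x
    } else {
      if (!all(c("word", "onset_seconds") %in% names(x)))
        stop(path, ": JSON must provide 'word' and 'onset_seconds'")
      df <- data.frame(word = unlist(x$word),
                       onset_seconds = unlist(x$onset_seconds),
                       stringsAsFactors = FALSE)
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("word", "onset_seconds") %in% names(df)))
    stop(path, ": missing column(s) 'word'/'onset_seconds'")
  production_record(df$word, df$onset_seconds)
}

#' Write a production record
#'
#' @param record a [production_record()].
#' @param path output path; `.json` writes a JSON array of row objects,
#'   anything else a CSV with header `word,onset_seconds`.
#' @return invisibly, `path`.
#' @export
write_production_record <- function(record, path) {
  df <- as.data.frame(record)[, c("word", "onset_seconds")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a state vector from JSON or CSV
#'
#' JSON form: `{"items": [...], "coefficients": [...]}`. CSV form: one
#' coefficient per row with columns `tuple_label`, `bitstring`,
#' `decimal`, `coefficient` (as written by [write_state()]); items are
#' recovered from the single-member tuples.
#'
#' @param path file path; format chosen by extension.
#' @return a [state_vector()].
#' @export
read_state <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!all(c("items", "coefficients") %in% names(x)))
      stop(path, ": JSON must provide 'items' and 'coefficients'")
    basis <- tuple_basis(as.character(x$items))
    return(state_vector(basis, as.numeric(x$coefficients)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("decimal", "coefficient") %in% names(df)))
    stop(path, ": missing column(s) 'decimal'/'coefficient'")
  i <- round(log2(nrow(df)))
  if (2^i != nrow(df))
    stop(path, ": row count is not a power of two")
  # recover item labels from the singleton tuples {x}
  singles <- df$tuple_label[df$decimal %in% 2^(0:(i - 1))]
  items <- sub("^\\{(.*)\\}$", "\\1", singles)
  basis <- tuple_basis(items)
  df <- df[order(df$decimal), ]
  state_vector(basis, df$coefficient)
}

#' Write a state vector
#'
#' @param state a [state_vector()].
#' @param path output path; `.json` writes
#'   `{"items": [...], "coefficients": [...]}`, anything else the
#'   CSV of [basis_table()] plus a `coefficient` column.
#' @return invisibly, `path`.
#' @export
write_state <- function(state, path) {
  stopifnot(inherits(state, "state_vector"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(items = state$basis$items, coefficients = state$coefficients),
      path, digits = NA)
  } else {
    tab <- basis_table(state$basis)
    tab$coefficient <- state$coefficients
    # tuple labels contain commas, so character fields stay quoted
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a fit result as JSON
#'
#' @param fit a `vf_fit` from [fit_production()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "vf_fit"))
  out <- list(
    model = fit$model,
    params = fit$params[names(fit$params) %in% c("c", "r", "alpha", "k")],
    sse = fit$sse,
    aicc = fit$aicc,
    candidates = lapply(fit$candidates, function(x)
      list(pars = as.list(x$pars), sse = x$sse, aicc = x$aicc,
           at_bound = x$at_bound, error = x$error))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
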