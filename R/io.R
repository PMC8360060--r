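# Reading and validating delimited count-regression datasets, plus
# writers that pair simulated datasets with a sidecar of generating
# parameters and seeds.

#' Read a count-regression dataset from delimited text
#'
#' Reads a CSV (or other delimited) file holding one row per observation
#' with named columns for the success count, the trial count and the
#' covariates, and validates it: the named columns must exist, counts
#' must be integers, and `0 <= y <= n` row-wise — each violation is a
#' distinct error naming the offending rows. Columns listed in `factors`
#' are converted to factors with lexicographically sorted levels, the
#' first being the baseline (overridable through `baseline`); they
#' expand to treatment dummies when the dataset is passed to
#' [fbb_fit()]. Columns listed in `standardize` are centered and scaled.
#'
#' @param path path to the delimited file.
#' @param response name of the success-count column (default `"y"`).
#' @param trials name of the trial-count column (default `"n"`).
#' @param factors character vector of covariate columns to treat as
#'   factors.
#' @param baseline named character vector mapping factor columns to
#'   their baseline level.
#' @param standardize character vector of numeric covariate columns to
#'   standardize to mean 0, sd 1.
#' @param sep field separator (default `","`).
#' @return a validated tibble.
#' @export
read_count_data <- function(path, response = "y", trials = "n",
                            factors = character(), baseline = character(),
                            standardize = character(), sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c(response, trials, factors, standardize), names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  y <- df[[response]]; n <- df[[trials]]
  if (!is.numeric(y) || !is.numeric(n) || any(y != floor(y)) || any(n != floor(n))) {
    stop(sprintf("columns '%s' and '%s' must hold integer counts", response, trials),
         call. = FALSE)
  }
  bad <- which(y < 0 | y > n)
  if (length(bad)) {
    stop(sprintf("count exceeds trials (y > n) or is negative in row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  for (f in factors) {
    lev <- sort(unique(as.character(df[[f]])))
    if (f %in% names(baseline)) {
      if (!baseline[[f]] %in% lev) {
        stop(sprintf("baseline '%s' is not a level of column '%s'", baseline[[f]], f),
             call. = FALSE)
      }
      lev <- c(baseline[[f]], setdiff(lev, baseline[[f]]))
    }
    df[[f]] <- factor(as.character(df[[f]]), levels = lev)
  }
  for (s in standardize) df[[s]] <- as.numeric(scale(df[[s]]))
  tibble::as_tibble(df)
}

#' Write a simulated dataset with its generating record
#'
#' Writes the dataset as CSV and, when the tibble carries a `truth`
#' attribute (as the `simulate_*` generators produce), a sidecar JSON
#' file `<path>.truth.json` with the generating parameters, seeds and
#' contaminated indices.
#'
#' @param data a tibble, typically from [simulate_fit_scenario()],
#'   [simulate_zero_excess()] or [simulate_outliers()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenario_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      warning("jsonlite not available; truth sidecar not written", call. = FALSE)
    } else {
      jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                           digits = NA)
    }
  }
  invisible(path)
}
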