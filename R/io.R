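#' Read subject-level data from CSV
#'
#' Reads a subject-level CSV, applies exclusion rules and optional
#' dichotomization, standardizes column names via [as_subject_data()], and
#' records every step (rows read, rows excluded, thresholds and their
#' direction, rows dropped listwise) in a log attached to the result.
#'
#' Dichotomization specs are lists `list(threshold =, direction =)` with
#' `direction` `"above"` (abnormal, coded 1, strictly above the threshold)
#' or `"below"`; the direction must always be stated explicitly — it is
#' never inferred from the data. Drop rules are lists
#' `list(col =, equals =)`: rows whose `col` equals `equals` are excluded
#' before anything else, mirroring exclusions such as removing subjects on
#' a particular medication.
#'
#' @param path CSV file path.
#' @param d_col,s_col,e_col column names for disease, susceptibility and
#'   exposure.
#' @param covariate_cols character vector of covariate column names.
#' @param stratum_col optional stratum column name.
#' @param drop_rules list of drop-rule specs (see Details).
#' @param dichotomize_s,dichotomize_e optional dichotomization specs.
#' @return A standardized subject data frame (see [as_subject_data()]) with
#'   a `log` attribute of step records.
#' @export
read_subjects <- function(path, d_col = "D", s_col = "S", e_col = "E",
                          covariate_cols = character(), stratum_col = NULL,
                          drop_rules = NULL, dichotomize_s = NULL,
                          dichotomize_e = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  steps <- sprintf("read %d rows from %s", nrow(raw), basename(path))
  for (rule in drop_rules %||% list()) {
    if (!rule$col %in% names(raw))
      stop("drop rule names a missing column: ", rule$col, call. = FALSE)
    hit <- !is.na(raw[[rule$col]]) & raw[[rule$col]] == rule$equals
    raw <- raw[!hit, , drop = FALSE]
    steps <- c(steps, sprintf("dropped %d rows with %s == %s",
                              sum(hit), rule$col, rule$equals))
  }
  cut01 <- function(x, spec, nm) {
    if (!spec$direction %in% c("above", "below"))
      stop("dichotomization direction must be 'above' or 'below'",
           call. = FALSE)
    coded <- if (spec$direction == "above") as.integer(x > spec$threshold)
             else as.integer(x < spec$threshold)
    steps <<- c(steps, sprintf("dichotomized %s: abnormal = %s %g", nm,
                               if (spec$direction == "above") ">" else "<",
                               spec$threshold))
    coded
  }
  if (!is.null(dichotomize_s)) raw[[s_col]] <- cut01(raw[[s_col]],
                                                     dichotomize_s, s_col)
  if (!is.null(dichotomize_e)) raw[[e_col]] <- cut01(raw[[e_col]],
                                                     dichotomize_e, e_col)
  out <- as_subject_data(raw, d = d_col, s = s_col, e = e_col,
                         covariates = covariate_cols, stratum = stratum_col)
  steps <- c(steps, sprintf("dropped %d rows with missing used values; n = %d",
                            attr(out, "n_dropped"), nrow(out)))
  attr(out, "log") <- steps
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write aggregated count tables
#'
#' Aggregated 2x4 tables are serialized as a JSON object with keys
#' `a, B, c, D, e, F, g, H`, or as a single-row CSV with those headers;
#' the format is chosen from the file extension. Round-trips preserve the
#' counts exactly.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @return `read_table_counts()` returns a [two_by_four_table()];
#'   `write_table_counts()` returns `path` invisibly.
#' @export
read_table_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  keys <- c("a", "B", "c", "D", "e", "F", "g", "H")
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.list(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    if (nrow(df) != 1L)
      stop("table CSV must contain exactly one row", call. = FALSE)
    as.list(df)
  }
  miss <- setdiff(keys, names(x))
  if (length(miss))
    stop("table file missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  do.call(two_by_four_table, x[keys])
}

#' @rdname read_table_counts
#' @param t a [two_by_four_table()].
#' @export
write_table_counts <- function(t, path) {
  stopifnot(inherits(t, "two_by_four"))
  keys <- c("a", "B", "c", "D", "e", "F", "g", "H")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(t[keys], path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(t[keys], check.names = FALSE), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

as_record <- function(e) {
  list(estimand = e$estimand, point = e$point, ci_low = e$ci_low,
       ci_high = e$ci_high, level = e$level, method = e$method)
}

#' Serialize a case-only analysis as JSON
#'
#' Writes a [caseonly()] result as a JSON report: every estimate as a
#' record `{estimand, point, ci_low, ci_high, level, method}`, the
#' independence decision, the headline choice, the narrative rows and the
#' run log. Wall-clock timestamps are excluded by default so that two runs
#' on identical inputs produce byte-identical files; set
#' `include_times = TRUE` to keep them.
#'
#' @param x a `caseonly` fit.
#' @param path output file path.
#' @param include_times include log timestamps (breaks byte-identical
#'   reproducibility)?
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, include_times = FALSE) {
  stopifnot(inherits(x, "caseonly"))
  logs <- lapply(x$log, function(e) {
    rec <- list(step = e$step, detail = e$detail)
    if (include_times) rec$time <- attr(e, "time")
    rec
  })
  rep <- list(
    estimates = lapply(caseonly_estimates(x), as_record),
    decision = x$decision,
    headline = x$headline,
    narrative = lapply(x$narrative, as.list),
    n_used = x$n_used, n_cases = x$n_cases,
    variables = x$variables, config = x$config, log = logs)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a workflow configuration file
#'
#' Reads a YAML configuration for the command-line workflow: column
#' mapping (`d_col`, `s_col`, `e_col`, `covariate_cols`, `stratum_col`),
#' optional `dichotomize_s` / `dichotomize_e` (`threshold`, `direction`),
#' `drop_rules`, and analysis settings (`level`, `independence_rule`,
#' `epsilon`, `ci_method`, `continuous_s`). Missing settings take the
#' [caseonly()] defaults.
#'
#' @param path YAML file path.
#' @return A named list of settings.
#' @export
read_workflow_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(d_col = "D", s_col = "S", e_col = "E",
                   covariate_cols = character(), stratum_col = NULL,
                   drop_rules = NULL, dichotomize_s = NULL,
                   dichotomize_e = NULL, level = 0.95,
                   independence_rule = "ci_contains_one", epsilon = NULL,
                   ci_method = "bound_product", continuous_s = "error")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, cfg)
}
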