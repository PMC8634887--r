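#' Read a two-group indicator panel from CSV
#'
#' Expects a comma-separated file (UTF-8, header row, decimal point) with one
#' group-label column and the indicator columns. Rows with missing values in
#' the used columns are dropped with a warning stating the count.
#'
#' @param path CSV file path.
#' @param group_col name of the group column.
#' @param indicator_cols character vector of indicator column names; `NULL`
#'   (default) uses every numeric column except the group column.
#' @param reference optional reference group label (becomes group 1).
#' @return an [indicator_panel()].
#' @export
read_panel_csv <- function(path, group_col, indicator_cols = NULL,
                           reference = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!group_col %in% names(df))
    lw_stop(sprintf("group column '%s' not found in %s", group_col, path),
            "lw_bad_input")
  if (is.null(indicator_cols)) {
    indicator_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                              group_col)
    if (length(indicator_cols) == 0L)
      lw_stop("no numeric indicator columns found", "lw_bad_input")
  } else {
    missing_cols <- setdiff(indicator_cols, names(df))
    if (length(missing_cols) > 0L)
      lw_stop(paste0("indicator column(s) not found: ",
                     paste(missing_cols, collapse = ", ")), "lw_bad_input")
  }
  used <- df[, c(group_col, indicator_cols)]
  keep <- stats::complete.cases(used)
  if (any(!keep))
    warning(sprintf("dropped %d row(s) with missing values", sum(!keep)))
  used <- used[keep, , drop = FALSE]
  indicator_panel(as.matrix(used[, indicator_cols, drop = FALSE]),
                  group = used[[group_col]], reference = reference)
}

#' Write a test result or grid table to disk
#'
#' Serializes a [latent_wmw_test()] result, a [run_scenario()] result or a
#' [run_grid()] table. JSON output (`format = "json"`, or a `.json` path)
#' stores numbers at 6 significant digits together with the package version;
#' grid tables can also be written as TSV.
#'
#' @param result a `latent_wmw`, `scenario_result` or data.frame object.
#' @param path output path.
#' @param format `"json"` or `"tsv"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "json")
  version <- as.character(utils::packageVersion("latentWMW"))
  if (format == "tsv") {
    if (!is.data.frame(result))
      lw_stop("TSV output is only defined for grid tables (data frames)",
              "lw_bad_input")
    utils::write.table(result, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  payload <-
    if (inherits(result, "latent_wmw")) {
      r <- unclass(result)
      r$composite <- list(strategy = r$strategy,
                          weights = signif(result$composite$weights$weights, 6),
                          est_reliability =
                            signif(result$composite$weights$est_reliability, 6))
      num <- vapply(r, is.numeric, logical(1)) &
        !names(r) %in% "composite"
      r[num] <- lapply(r[num], signif, digits = 6)
      r
    } else if (inherits(result, "scenario_result")) {
      list(scenario = unclass(result$scenario),
           rejection_rate = signif(result$rejection_rate, 6),
           mc_se = signif(result$mc_se, 6),
           n_reps = result$n_reps, seed = result$seed,
           failures = result$failures)
    } else if (is.data.frame(result)) {
      result
    } else lw_stop("unsupported result type", "lw_bad_input")
  out <- list(package = "latentWMW", version = version, result = payload)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a simulation grid configuration
#'
#' Parses a YAML or JSON description of a scenario grid. Recognized keys
#' (all optional, vectors allowed): `latent_dist`, `linearity`,
#' `reliability`, `group_size`, `setting`, `hypothesis`, `delta`, `n_reps`,
#' `seed`, `methods`.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON config file.
#' @return list with `scenarios` (list of [wmw_scenario()]) plus `n_reps`,
#'   `seed` and `methods`.
#' @export
read_grid_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  scen <- scenario_grid(
    latent_dist = cfg$latent_dist %||% c("normal", "t5", "laplace",
                                         "exponential"),
    linearity = cfg$linearity %||% c("linear", "nonlinear"),
    reliability = cfg$reliability %||% c(0.80, 0.60),
    group_size = cfg$group_size %||% c(15L, 50L, 100L),
    setting = cfg$setting %||% 1:4,
    hypothesis = cfg$hypothesis %||% "alternative",
    delta = cfg$delta %||% 0.65)
  list(scenarios = scen,
       n_reps = cfg$n_reps %||% 1000L,
       seed = cfg$seed %||% 1L,
       methods = cfg$methods %||% sim_methods)
}

#' Write a synthetic example dataset
#'
#' Generates a seeded CSV for examples and pipeline checks. Two kinds:
#'
#' * `"case_like"` — a synthetic stand-in shaped like a questionnaire study:
#'   three positively correlated, right-skewed indicator scores driven by a
#'   centered-exponential latent variable, the third indicator flattened
#'   near the low end (a floor-effect-like nonlinearity), and a binary
#'   employment-like group factor. Defaults: 455 subjects (273 vs 182),
#'   probabilistic index about 0.57. Entirely simulated; it mimics the shape
#'   of such data, not any real study.
#' * `"scenario"` — one draw from a [wmw_scenario()] given via `params`.
#'
#' @param kind `"case_like"` or `"scenario"`.
#' @param params named list overriding defaults; for `"case_like"`: `m`, `n`,
#'   `delta`, `reliability`; for `"scenario"`: arguments of
#'   [wmw_scenario()].
#' @param seed integer seed (same seed, byte-identical file).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
make_fixture <- function(kind = c("case_like", "scenario"), params = list(),
                         seed = 1L, path) {
  kind <- match.arg(kind)
  if (kind == "scenario") {
    sc <- do.call(wmw_scenario, params)
    panel <- simulate_panel(sc, seed = seed)
    df <- data.frame(group = as.character(panel$group), panel$values)
  } else {
    m <- params$m %||% 273L
    n <- params$n %||% 182L
    delta <- params$delta %||% 0.57
    rel <- params$reliability %||% 0.8
    sc <- wmw_scenario("exponential", "linear", reliability = rel,
                       m = m, n = n, hypothesis = "alternative",
                       delta = delta)
    cal <- scenario_calibration(sc)
    # replace indicator 3's link by the flattening sigmoid to echo a floor
    # effect; re-calibrate its error sd against the transformed signal
    cal$h_specs[[3]] <- list(type = "t_cdf_probit", df = 3)
    cal$sd1[3] <- cal$sd2[3] <-
      calibrate_error_sd("exponential", cal$h_specs[[3]], rel)
    panel <- simulate_panel(sc, seed = seed, calibration = cal)
    sc1 <- 3 * panel$values[, 1] + 8     # questionnaire-like score scales
    sc2 <- 3.5 * panel$values[, 2] + 9
    sc3 <- 8 * panel$values[, 3] + 52
    df <- data.frame(
      employment = ifelse(panel$group == "group1", "employed", "unemployed"),
      phq_like = round(pmax(sc1, 0), 1),
      cesd_like = round(pmax(sc2, 0), 1),
      promis_like = round(sc3, 1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
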