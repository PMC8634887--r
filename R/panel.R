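#' Two-group indicator panel
#'
#' Container for the raw input of every analysis in the package: a matrix of
#' indicator scores (subjects in rows, indicators in columns) together with a
#' two-level group label per subject. Group levels are ordered
#' lexicographically unless a reference level is given; the first level plays
#' the role of "group 1" in every downstream probabilistic-index computation.
#'
#' @param values numeric matrix or data frame of indicator scores, one column
#'   per indicator. Column names are kept; unnamed columns are called
#'   `ind1, ind2, ...`.
#' @param group vector of group labels, one per row of `values`; must contain
#'   exactly two distinct values, each at least twice.
#' @param reference optional group label to use as group 1. Defaults to the
#'   lexicographically smaller level.
#'
#' @return An object of class `indicator_panel`: a list with elements
#'   `values` (numeric matrix), `group` (factor with two levels),
#'   `indicator_names`, and group sizes `m` (group 1) and `n` (group 2).
#' @examples
#' pan <- indicator_panel(cbind(a = rnorm(10), b = rnorm(10)),
#'                        group = rep(c("ctrl", "trt"), each = 5))
#' pan$m
#' @export
indicator_panel <- function(values, group, reference = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
  storage.mode(values) <- "double"
  if (anyNA(values) || anyNA(group))
    lw_stop("indicator panel must not contain missing values",
            "lw_missing_values")
  if (nrow(values) != length(group))
    lw_stop("`group` must have one label per row of `values`",
            "lw_bad_input")
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2L)
    lw_stop(sprintf("exactly two group levels required, found %d (%s)",
                    length(lev), paste(utils::head(lev, 5), collapse = ", ")),
            "lw_bad_group")
  if (!is.null(reference)) {
    reference <- as.character(reference)
    if (!reference %in% lev)
      lw_stop(sprintf("reference group '%s' not among levels %s/%s",
                      reference, lev[1], lev[2]), "lw_bad_group")
    lev <- c(reference, setdiff(lev, reference))
  }
  grp <- factor(as.character(group), levels = lev)
  m <- sum(grp == lev[1])
  n <- sum(grp == lev[2])
  if (m < 2L || n < 2L)
    lw_stop("each group needs at least two subjects", "lw_bad_group")
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("ind", seq_len(ncol(values)))
  colnames(values) <- nm
  structure(list(values = values, group = grp, indicator_names = nm,
                 m = m, n = n),
            class = "indicator_panel")
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat("Two-group indicator panel\n")
  cat(sprintf("  indicators: %s\n", paste(x$indicator_names, collapse = ", ")))
  cat(sprintf("  groups: %s (m = %d) vs %s (n = %d)\n",
              levels(x$group)[1], x$m, levels(x$group)[2], x$n))
  invisible(x)
}

#' @export
dim.indicator_panel <- function(x) dim(x$values)

# split a numeric vector of per-subject scores by the panel's groups
split_by_group <- function(panel, scores) {
  list(x = scores[panel$group == levels(panel$group)[1]],
       y = scores[panel$group == levels(panel$group)[2]])
}
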