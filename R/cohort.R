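#' Validate a patient table against declared category levels
#'
#' Checks every analysis column against its declared level set, applies
#' complete-case deletion over the analysis columns, and converts them to
#' factors with fixed levels. Columns of `x` not named in `levels` are kept
#' untouched (e.g. raw numeric columns awaiting [discretize_cohort()]).
#'
#' @param x a data frame, one row per patient.
#' @param levels named list of character level vectors, one per categorical
#'   analysis column; defaults to the eight study variables ([gi_levels()])
#'   restricted to the columns present in `x`.
#' @return a `bn_cohort`: the validated data frame with factor columns, and
#'   attributes `n_dropped` (rows removed for missing values) and `dropped`
#'   (their original row indices).
#' @export
as_cohort <- function(x, levels = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(levels)) levels <- gi_levels()
  levels <- levels[names(levels) %in% names(x)]
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    if (length(lv) < 2L) stop("variable ", nm, " needs at least 2 levels")
    if (anyDuplicated(lv)) stop("duplicate level labels for ", nm)
    col <- x[[nm]]
    col_chr <- as.character(col)
    blank <- !is.na(col_chr) & !nzchar(trimws(col_chr))
    col_chr[blank] <- NA_character_
    bad <- which(!is.na(col_chr) & !col_chr %in% lv)
    if (length(bad))
      stop("unknown category label in column '", nm, "', row ", bad[1],
           ": \"", col_chr[bad[1]], "\"")
    x[[nm]] <- factor(col_chr, levels = lv)
  }
  keep <- stats::complete.cases(x[names(levels)])
  dropped <- which(!keep)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_dropped = length(dropped), dropped = dropped,
            class = c("bn_cohort", "data.frame"))
}

#' Read a patient table from CSV
#'
#' @param path CSV file path (header row; UTF-8; one row per patient).
#' @param levels as in [as_cohort()].
#' @param quiet if `FALSE`, message the number of rows dropped as incomplete.
#' @return a `bn_cohort` (see [as_cohort()]).
#' @export
read_cohort <- function(path, levels = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""))
  out <- as_cohort(df, levels = levels)
  nd <- attr(out, "n_dropped")
  if (!quiet && nd > 0)
    message(nd, " row(s) dropped for incomplete analysis data (complete-case rule)")
  out
}

#' @rdname read_cohort
#' @param x a cohort data frame.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE,
                   na = "")
  invisible(path)
}

#' Define a clinical discretization rule
#'
#' Maps one numeric column to an interval-labelled categorical variable. With
#' `right = TRUE` intervals are right-closed (a cut point belongs to the lower
#' class, as in albumin \eqn{\le} 3.5); with `right = FALSE` they are
#' left-closed (the cut point belongs to the upper class, as in BMI
#' \eqn{\ge} 25).
#'
#' @param source name of the numeric source column.
#' @param output name of the categorical variable produced.
#' @param cuts strictly increasing numeric cut points.
#' @param labels interval labels, `length(cuts) + 1` of them.
#' @param right boundary-inclusion side (see above).
#' @return an object of class `discretization_rule`.
#' @export
discretization_rule <- function(source, output, cuts, labels, right = TRUE) {
  cuts <- as.numeric(cuts)
  if (length(cuts) < 1L || is.unsorted(cuts, strictly = TRUE))
    stop("'cuts' must be strictly increasing")
  if (length(labels) != length(cuts) + 1L)
    stop("need length(cuts) + 1 labels")
  if (anyDuplicated(labels)) stop("duplicate interval labels")
  structure(list(source = source, output = output, cuts = cuts,
                 labels = as.character(labels), right = right),
            class = "discretization_rule")
}

#' Discretize raw numeric columns of a cohort
#'
#' Applies each rule's cut points to its source column and replaces it with
#' the labelled categorical variable; all other columns pass through. A rule
#' whose source column is already categorical is rejected (discretization is
#' never silently re-applied).
#'
#' @param x a data frame or `bn_cohort` containing the rules' source columns.
#' @param rules a list of [discretization_rule()] objects; defaults to the
#'   study's clinical rules ([gi_discretization_rules()]) restricted to the
#'   columns present.
#' @return the cohort with categorical columns in place of the numeric
#'   sources, validated via [as_cohort()].
#' @export
discretize_cohort <- function(x, rules = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(rules)) {
    rules <- gi_discretization_rules()
    rules <- rules[vapply(rules, function(r) r$source %in% names(x), logical(1))]
  }
  lv <- gi_levels()
  for (r in rules) {
    if (!inherits(r, "discretization_rule")) stop("each rule must be a discretization_rule")
    if (!r$source %in% names(x)) stop("source column not found: ", r$source)
    col <- x[[r$source]]
    if (is.factor(col) || is.character(col))
      stop("column '", r$source, "' is already categorical; refusing to re-bin")
    if (!is.numeric(col)) stop("column '", r$source, "' is not numeric")
    binned <- cut(col, breaks = c(-Inf, r$cuts, Inf), labels = r$labels,
                  right = r$right)
    x[[r$source]] <- NULL
    x[[r$output]] <- as.character(binned)
    lv[[r$output]] <- r$labels
  }
  as_cohort(x, levels = lv[names(lv) %in% names(x)])
}

#' Per-variable level counts and proportions
#'
#' The cohort-description summary: for every categorical variable, the count
#' and proportion of patients at each level.
#'
#' @param x a `bn_cohort` or data frame of factors.
#' @param vars variables to summarize; default all factor columns.
#' @return a data frame with columns `variable`, `level`, `count`,
#'   `proportion`, of class `bn_marginals`.
#' @export
marginal_summary <- function(x, vars = NULL) {
  x <- as.data.frame(x)
  if (is.null(vars)) vars <- names(x)[vapply(x, is.factor, logical(1))]
  n <- nrow(x)
  if (n == 0L) {
    warning("empty cohort: no observations to summarize")
    out <- data.frame(variable = character(0), level = character(0),
                      count = integer(0), proportion = numeric(0))
    return(structure(out, n = 0L, class = c("bn_marginals", "data.frame")))
  }
  pieces <- lapply(vars, function(v) {
    tab <- table(x[[v]])
    data.frame(variable = v, level = names(tab),
               count = as.integer(tab),
               proportion = as.numeric(tab) / n)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, n = n, class = c("bn_marginals", "data.frame"))
}

#' @export
print.bn_marginals <- function(x, digits = 3, ...) {
  cat("Cohort summary (n = ", attr(x, "n"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$proportion <- round(df$proportion, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.bn_cohort <- function(x, ...) {
  cat("Cohort: ", nrow(x), " patients, ", ncol(x), " variables",
      if (attr(x, "n_dropped") > 0)
        paste0(" (", attr(x, "n_dropped"), " incomplete row(s) dropped)"),
      "\n", sep = "")
  NextMethod()
}
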