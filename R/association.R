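#' Pearson chi-square test of independence between two cohort variables
#'
#' Builds the r x s contingency table of the two categorical columns and
#' applies Pearson's chi-square test without continuity correction, so that
#' 2 x 2 tables are treated identically to larger ones. Levels with zero
#' marginal count are dropped from the table with a warning; if fewer than
#' two levels remain on either margin the test is undefined and an error is
#' raised. When any expected cell count falls below 5 a small-sample warning
#' is emitted but the statistic is still computed (small clinical cohorts
#' necessarily violate the classic rule).
#'
#' @param x a data frame of factors (e.g. a `bn_cohort`).
#' @param a,b names of two distinct categorical columns.
#' @return a list of class `bn_chisq`: `statistic`, `df`, `p.value`,
#'   `observed`, `expected`, and the variable `pair`.
#' @examples
#' d <- data.frame(u = factor(rep(c("a", "b"), c(40, 40))),
#'                 v = factor(rep(c("x", "y", "x", "y"), c(30, 10, 10, 30))))
#' chi_square_test(d, "u", "v")
#' @export
chi_square_test <- function(x, a, b) {
  x <- as.data.frame(x)
  if (a == b) stop("'a' and 'b' must be distinct variables")
  for (v in c(a, b)) {
    if (!v %in% names(x)) stop("unknown variable: ", v)
    if (!is.factor(x[[v]]) && !is.character(x[[v]]))
      stop("variable ", v, " is not categorical")
  }
  tab <- table(x[[a]], x[[b]], dnn = c(a, b))
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-count level(s): ",
            paste(c(rownames(tab)[zr], colnames(tab)[zc]), collapse = ", "))
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate contingency table for ", a, " vs ", b,
         " (fewer than 2 levels on a margin)")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected count below 5 in ", a, " vs ", b,
            " table; chi-square approximation may be coarse")
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p.value = unname(ht$p.value), observed = tab,
                 expected = ht$expected, pair = c(a, b)),
            class = "bn_chisq")
}

#' @export
print.bn_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square, %s vs %s: X2 = %.4g, df = %d, p = %.4g\n",
              x$pair[1], x$pair[2], x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Pairwise association screening matrix
#'
#' Runs the Pearson chi-square test on every unordered pair of variables and
#' flags the significant ones. Two tiers are recorded: the primary decision
#' at level `alpha` (flag 1 iff p <= alpha, so a p-value exactly at the
#' threshold counts as associated) and a secondary suggestive tier at
#' `secondary`. No multiple-testing correction is applied: the matrix
#' reports unadjusted per-pair decisions.
#'
#' @param x a data frame of factors.
#' @param alpha primary significance level (default 0.05).
#' @param secondary suggestive-tier level (default 0.10).
#' @param vars variables to screen; default all factor columns.
#' @return an object of class `bn_assoc`: list with the 0/1 `flag` matrix,
#'   the `tier` character matrix (`"**"`, `"*"`, or `"."`), and the `p`,
#'   `statistic`, `df` matrices, plus `alpha`, `secondary`, `n`.
#' @export
association_matrix <- function(x, alpha = 0.05, secondary = 0.10, vars = NULL) {
  x <- as.data.frame(x)
  if (is.null(vars)) vars <- names(x)[vapply(x, is.factor, logical(1))]
  if (length(vars) < 2L) stop("need at least 2 variables to screen")
  m <- length(vars)
  empty <- matrix(NA_real_, m, m, dimnames = list(vars, vars))
  p <- stat <- df <- empty
  for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
    ht <- chi_square_test(x, vars[i], vars[j])
    p[i, j] <- p[j, i] <- ht$p.value
    stat[i, j] <- stat[j, i] <- ht$statistic
    df[i, j] <- df[j, i] <- ht$df
  }
  flag <- ifelse(p <= alpha, 1L, 0L)
  tier <- ifelse(p <= alpha, "**", ifelse(p <= secondary, "*", "."))
  structure(list(vars = vars, flag = flag, tier = tier, p = p,
                 statistic = stat, df = df, alpha = alpha,
                 secondary = secondary, n = nrow(x)),
            class = "bn_assoc")
}

#' @export
print.bn_assoc <- function(x, ...) {
  cat("Pairwise chi-square association screen (n = ", x$n,
      ", alpha = ", x$alpha, ")\n", sep = "")
  m <- assoc_lower_triangle(x)
  print(as.data.frame(m), right = TRUE)
  cat("1 = p <= ", x$alpha, "; 0 = not significant\n", sep = "")
  invisible(x)
}

assoc_lower_triangle <- function(x) {
  m <- matrix("-", length(x$vars), length(x$vars),
              dimnames = list(x$vars, x$vars))
  low <- lower.tri(m)
  m[low] <- as.character(x$flag[low])
  m
}

#' Export the association matrix as CSV
#'
#' Writes the lower-triangular 0/1 layout (upper triangle and diagonal as
#' `"-"`), one row per variable.
#'
#' @param x a `bn_assoc` object.
#' @param path file path.
#' @export
write_assoc_csv <- function(x, path) {
  stopifnot(inherits(x, "bn_assoc"))
  m <- assoc_lower_triangle(x)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Significance tiers for the arcs of a DAG
#'
#' Looks up each arc's endpoint pair in an association screen and returns the
#' tier symbol used to annotate graph exports (`"**"` p <= alpha, `"*"`
#' p <= secondary, `"."` otherwise).
#'
#' @param g a [bn_dag].
#' @param assoc a `bn_assoc` from [association_matrix()].
#' @return a data frame with columns `from`, `to`, `p`, `tier`.
#' @export
arc_significance <- function(g, assoc) {
  stopifnot(inherits(g, "bn_dag"), inherits(assoc, "bn_assoc"))
  a <- arcs(g)
  missing <- setdiff(unique(as.vector(a)), assoc$vars)
  if (length(missing)) stop("arc endpoint(s) not in the screen: ",
                            paste(missing, collapse = ", "))
  pv <- mapply(function(f, t) assoc$p[f, t], a[, 1], a[, 2])
  data.frame(from = a[, 1], to = a[, 2], p = as.numeric(pv),
             tier = ifelse(pv <= assoc$alpha, "**",
                           ifelse(pv <= assoc$secondary, "*", ".")),
             row.names = NULL)
}
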