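# -- discrete factor algebra -------------------------------------------------
# A factor is list(vars = character, tab = array) with one dimension per
# variable (dimnames named by variable); a factor with no variables is a
# scalar. All inference below is exact table arithmetic.

factor_from_cpt <- function(cpt) list(vars = names(dimnames(cpt)), tab = cpt)

reduce_factor <- function(f, ev) {
  common <- intersect(f$vars, names(ev))
  if (!length(common)) return(f)
  dn <- dimnames(f$tab)
  idx <- lapply(seq_along(f$vars), function(i) {
    v <- f$vars[i]
    if (v %in% common) match(ev[[v]], dn[[i]]) else seq_len(dim(f$tab)[i])
  })
  tab <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
  keep <- !(f$vars %in% common)
  if (!any(keep)) return(list(vars = character(0), tab = as.numeric(tab)))
  out <- array(tab, dim = dim(f$tab)[keep], dimnames = dn[keep])
  list(vars = f$vars[keep], tab = out)
}

expand_factor <- function(f, u, lv) {
  vars <- f$vars
  tab <- f$tab
  for (m in setdiff(u, vars)) {
    k <- length(lv[[m]])
    newdim <- c(if (length(vars)) dim(tab) else NULL, k)
    newdn <- c(if (length(vars)) dimnames(tab) else NULL,
               stats::setNames(list(lv[[m]]), m))
    tab <- array(rep(as.numeric(tab), times = k), dim = newdim, dimnames = newdn)
    vars <- c(vars, m)
  }
  if (length(u) > 1L) tab <- aperm(tab, match(u, vars))
  list(vars = u, tab = tab)
}

multiply_factors <- function(f, g, lv) {
  u <- union(f$vars, g$vars)
  if (!length(u)) return(list(vars = character(0),
                              tab = as.numeric(f$tab) * as.numeric(g$tab)))
  fe <- expand_factor(f, u, lv)
  ge <- expand_factor(g, u, lv)
  list(vars = u, tab = fe$tab * ge$tab)
}

sum_out <- function(f, v) {
  i <- match(v, f$vars)
  if (is.na(i)) return(f)
  if (length(f$vars) == 1L)
    return(list(vars = character(0), tab = sum(f$tab)))
  keep <- seq_along(f$vars)[-i]
  tab <- apply(f$tab, keep, sum)
  if (length(keep) == 1L)
    tab <- array(tab, dim = length(tab),
                 dimnames = stats::setNames(list(names(tab)), f$vars[keep]))
  list(vars = f$vars[keep], tab = tab)
}

# min-degree elimination order over the factor hypergraph, ties lexicographic
elimination_order <- function(scopes, elim) {
  order <- character(0)
  remaining <- elim
  while (length(remaining)) {
    deg <- vapply(remaining, function(v) {
      nb <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s, logical(1))]))
      length(setdiff(nb, v))
    }, numeric(1))
    pick <- sort(remaining[deg == min(deg)])[1]
    order <- c(order, pick)
    touched <- vapply(scopes, function(s) pick %in% s, logical(1))
    merged <- setdiff(unique(unlist(scopes[touched])), pick)
    scopes <- c(scopes[!touched], list(merged))
    remaining <- setdiff(remaining, pick)
  }
  order
}

eliminate_to_target <- function(cpts, lv, target, ev) {
  factors <- lapply(cpts, factor_from_cpt)
  if (length(ev)) factors <- lapply(factors, reduce_factor, ev = ev)
  elim <- setdiff(names(cpts), c(target, names(ev)))
  ord <- elimination_order(lapply(factors, `[[`, "vars"), elim)
  for (v in ord) {
    touched <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod <- Reduce(function(a, b) multiply_factors(a, b, lv), factors[touched])
    factors <- c(factors[!touched], list(sum_out(prod, v)))
  }
  out <- Reduce(function(a, b) multiply_factors(a, b, lv), factors)
  if (!identical(out$vars, target)) out <- expand_factor(out, target, lv)
  p <- as.numeric(out$tab)
  names(p) <- lv[[target]]
  p
}

check_evidence <- function(bn, ev) {
  if (is.null(ev) || !length(ev)) return(stats::setNames(list(), character(0)))
  ev <- as.list(ev)
  if (is.null(names(ev)) || any(names(ev) == ""))
    stop("evidence must be a named set of variable = level assignments")
  for (v in names(ev)) {
    if (!v %in% names(bn$levels)) stop("unknown evidence variable: ", v)
    if (!ev[[v]] %in% bn$levels[[v]])
      stop("\"", ev[[v]], "\" is not a level of ", v)
  }
  ev
}

#' Exact posterior query by variable elimination
#'
#' Computes the exact posterior distribution of one variable given evidence,
#' by sum-product variable elimination with a min-degree elimination order,
#' together with the no-evidence marginal of the same variable and the
#' per-level shift in percentage points.
#'
#' @param bn a fitted network ([catbn()] or [gi_reference_network()]).
#' @param target name of the query variable (must not appear in `evidence`).
#' @param evidence named character vector or list of `variable = level`
#'   assignments (may be empty).
#' @return an object of class `bn_query`: a data frame with columns `level`,
#'   `marginal`, `posterior`, `shift_pp`, and attributes `target`,
#'   `evidence`, `alpha` (the smoothing under which the CPTs were fitted).
#' @examples
#' bn <- gi_reference_network()
#' eliminate_query(bn, "HRA", c(NUTR = "Yes", RADIO = "No"))
#' @export
eliminate_query <- function(bn, target, evidence = NULL) {
  stopifnot(inherits(bn, "catbn"))
  if (!target %in% names(bn$levels)) stop("unknown target variable: ", target)
  ev <- check_evidence(bn, evidence)
  if (target %in% names(ev)) stop("target must not appear in the evidence")
  lv <- bn$levels
  unnorm <- eliminate_to_target(bn$cpts, lv, target, ev)
  z <- sum(unnorm)
  if (z <= 0)
    stop("evidence has probability zero under the network: ",
         paste(names(ev), unlist(ev), sep = " = ", collapse = ", "))
  posterior <- unnorm / z
  marg <- eliminate_to_target(bn$cpts, lv, target, list())
  marginal <- marg / sum(marg)
  out <- data.frame(level = lv[[target]], marginal = as.numeric(marginal),
                    posterior = as.numeric(posterior),
                    shift_pp = 100 * (as.numeric(posterior) - as.numeric(marginal)))
  structure(out, target = target, evidence = ev, alpha = bn$alpha,
            class = c("bn_query", "data.frame"))
}

#' @export
print.bn_query <- function(x, digits = 4, ...) {
  ev <- attr(x, "evidence")
  cat("Posterior of ", attr(x, "target"),
      if (length(ev)) paste0(" | ", paste(names(ev), unlist(ev), sep = " = ",
                                          collapse = ", "))
      else " (no evidence)",
      "\n", sep = "")
  df <- as.data.frame(x)
  df$marginal <- round(df$marginal, digits)
  df$posterior <- round(df$posterior, digits)
  df$shift_pp <- round(df$shift_pp, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Full joint distribution by enumeration (oracle)
#'
#' Materializes the product of the CPTs over every configuration of the
#' variables. Intended as the independent oracle against which variable
#' elimination is validated; refuses state spaces above one million
#' configurations.
#'
#' @param bn a fitted network.
#' @return a data frame with one factor column per variable and a `prob`
#'   column summing to 1.
#' @export
enumerate_joint <- function(bn) {
  stopifnot(inherits(bn, "catbn"))
  sizes <- vapply(bn$levels, length, numeric(1))
  if (prod(sizes) > 1e6)
    stop("state space too large to enumerate (", format(prod(sizes)), " states)")
  grid <- expand.grid(bn$levels, stringsAsFactors = TRUE, KEEP.OUT.ATTRS = FALSE)
  for (v in names(bn$levels)) grid[[v]] <- factor(grid[[v]], levels = bn$levels[[v]])
  grid$prob <- exp(record_loglik(bn, grid))
  grid
}

#' Posterior shift between two evidence scenarios
#'
#' Per-level difference, in percentage points, between the posterior of
#' `target` under `e1` and under `e2`.
#'
#' @inheritParams eliminate_query
#' @param e1,e2 evidence sets as in [eliminate_query()].
#' @return named numeric vector of percentage-point differences (one per
#'   level of `target`); the entries sum to zero.
#' @export
posterior_shift <- function(bn, target, e1, e2) {
  q1 <- eliminate_query(bn, target, e1)
  q2 <- eliminate_query(bn, target, e2)
  stats::setNames(100 * (q1$posterior - q2$posterior), q1$level)
}
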