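#' Estimate conditional probability tables
#'
#' For every node of the structure, the distribution of its levels within
#' each configuration of its parents is estimated from counts with optional
#' Dirichlet (pseudo-count) smoothing:
#' `P(level | config) = (count + alpha) / (total + alpha * levels)`.
#' With `alpha = 0` this is the maximum-likelihood estimate; a parent
#' configuration never observed then gets the uniform distribution.
#'
#' @param x a data frame of factors covering all nodes of `dag`.
#' @param dag a [bn_dag].
#' @param alpha smoothing pseudo-count, `>= 0` (0 = MLE, 1 = Laplace).
#' @return a named list of CPT arrays, one per node; the first dimension of
#'   each array is the node itself, remaining dimensions its parents.
#' @export
fit_cpts <- function(x, dag, alpha = 0) {
  x <- as.data.frame(x)
  stopifnot(inherits(dag, "bn_dag"), alpha >= 0)
  absent <- setdiff(dag$nodes, names(x))
  if (length(absent)) stop("node(s) absent from cohort: ",
                           paste(absent, collapse = ", "))
  for (v in dag$nodes) if (!is.factor(x[[v]]))
    stop("column ", v, " must be a factor with declared levels")
  cpts <- list()
  for (v in dag$nodes) {
    counts <- table(x[c(v, dag$parents[[v]])])
    cpts[[v]] <- cpt_from_counts(counts, alpha)
  }
  cpts
}

cpt_from_counts <- function(counts, alpha = 0) {
  k <- as.array(counts) + alpha
  nd <- length(dim(k))
  if (nd == 1L) {
    tot <- sum(k)
    p <- if (tot > 0) k / tot else rep(1 / length(k), length(k))
  } else {
    tot <- apply(k, 2:nd, sum)
    p <- sweep(k, 2:nd, tot, "/")
    p[is.nan(p)] <- 1 / dim(k)[1]  # unseen parent configuration -> uniform
  }
  array(as.numeric(p), dim = dim(k), dimnames = dimnames(counts))
}

cpt_levels <- function(cpts) {
  lv <- list()
  for (v in names(cpts)) lv[[v]] <- dimnames(cpts[[v]])[[1]]
  lv
}

#' Number of free parameters of a structure
#'
#' Each node with `L` levels and parent-level product `Q` contributes
#' `(L - 1) * Q` free probabilities, so `k = sum over nodes`.
#'
#' @param dag a [bn_dag].
#' @param nlevels named integer vector (or named list of level vectors)
#'   giving each node's number of levels.
#' @return integer `k`.
#' @export
parameter_count <- function(dag, nlevels) {
  stopifnot(inherits(dag, "bn_dag"))
  if (is.list(nlevels)) nlevels <- vapply(nlevels, length, integer(1))
  absent <- setdiff(dag$nodes, names(nlevels))
  if (length(absent)) stop("no level count for: ", paste(absent, collapse = ", "))
  sum(vapply(dag$nodes, function(v) {
    (nlevels[[v]] - 1) * prod(nlevels[dag$parents[[v]]])
  }, numeric(1)))
}

#' Log-likelihood of a cohort under a fitted network
#'
#' Sum over records of the log joint probability, itself the sum over nodes
#' of `log P(level | parent levels)` under the network's CPTs. A record with
#' zero probability makes the total `-Inf` and triggers a warning naming the
#' first such record.
#'
#' @param bn a fitted network ([catbn]) or a bare named CPT list.
#' @param x a data frame of factors covering the network's nodes.
#' @return the scalar log-likelihood (0 for an empty cohort).
#' @export
log_likelihood <- function(bn, x) {
  ll <- record_loglik(bn, x)
  if (!length(ll)) return(0)
  if (any(is.infinite(ll)))
    warning("record ", which(is.infinite(ll))[1],
            " has probability zero under the network")
  sum(ll)
}

record_loglik <- function(bn, x) {
  cpts <- if (inherits(bn, "catbn")) bn$cpts else bn
  x <- as.data.frame(x)
  n <- nrow(x)
  if (n == 0L) return(numeric(0))
  ll <- numeric(n)
  for (v in names(cpts)) {
    cpt <- cpts[[v]]
    dims <- names(dimnames(cpt))
    miss <- setdiff(dims, names(x))
    if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
    idx <- vapply(dims, function(d) match(as.character(x[[d]]), dimnames(cpt)[[d]]),
                  integer(n))
    idx <- matrix(idx, nrow = n)
    if (anyNA(idx)) stop("value outside declared levels in ",
                         dims[which(colSums(is.na(idx)) > 0)[1]])
    ll <- ll + as.numeric(log(cpt[idx]))
  }
  ll
}

# Maximized per-family log-likelihood sum_config sum_level n log(n/total),
# computed straight from the contingency counts.
family_loglik <- function(x, v, pars) {
  counts <- as.array(table(x[c(v, pars)]))
  nd <- length(dim(counts))
  tot <- if (nd == 1L) array(sum(counts), dim = dim(counts)) else {
    t <- apply(counts, 2:nd, sum)
    array(rep(t, each = dim(counts)[1]), dim = dim(counts))
  }
  nz <- counts > 0
  sum(counts[nz] * (log(counts[nz]) - log(tot[nz])))
}

#' Score a structure against a cohort
#'
#' Fits maximum-likelihood CPTs family by family and reports both
#' information-criterion conventions: the minimization form
#' `bic = k * ln(n) - 2 * lnL` and the decomposable maximization form
#' `score = lnL - (ln(n)/2) * k`, related by `bic = -2 * score`. The
#' per-parameter penalization coefficient is `ln(n)/2` for BIC and 1 for
#' AIC (`aic = lnL - k`). The score decomposes additively over node
#' families, which is what makes local structure search incremental.
#'
#' @param x a data frame of factors (complete categorical cohort).
#' @param dag a [bn_dag].
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return an object of class `bn_score`: list with `loglik`, `k`, `n`,
#'   `penalty`, `bic`, `score`, `aic`, `criterion`, and the per-family
#'   breakdown `families` (node, k, loglik).
#' @export
network_score <- function(x, dag, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  x <- as.data.frame(x)
  stopifnot(inherits(dag, "bn_dag"))
  n <- nrow(x)
  if (n == 0L) stop("cannot score an empty cohort")
  nlev <- vapply(dag$nodes, function(v) nlevels(x[[v]]), integer(1))
  fam <- data.frame(node = dag$nodes,
                    k = vapply(dag$nodes, function(v)
                      (nlev[[v]] - 1) * prod(nlev[dag$parents[[v]]]), numeric(1)),
                    loglik = vapply(dag$nodes, function(v)
                      family_loglik(x, v, dag$parents[[v]]), numeric(1)),
                    row.names = NULL)
  loglik <- sum(fam$loglik)
  k <- sum(fam$k)
  penalty <- if (criterion == "bic") log(n) / 2 else 1
  structure(list(loglik = loglik, k = k, n = n, penalty = penalty,
                 bic = k * log(n) - 2 * loglik,
                 score = loglik - (log(n) / 2) * k,
                 aic = loglik - k,
                 criterion = criterion, families = fam),
            class = "bn_score")
}

#' @export
print.bn_score <- function(x, ...) {
  cat(sprintf("Network score (n = %d, k = %d, criterion = %s)\n",
              x$n, as.integer(x$k), toupper(x$criterion)))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  cat(sprintf("  BIC (minimization form): %.4f;  score (maximization form): %.4f\n",
              x$bic, x$score))
  cat(sprintf("  AIC score: %.4f;  per-parameter penalization: %.4f\n",
              x$aic, x$penalty))
  invisible(x)
}

# criterion value in maximization form for search (higher is better)
criterion_value <- function(sc, criterion) {
  if (criterion == "bic") sc$score else sc$aic
}
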