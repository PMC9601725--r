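#' Fit a multinomial Bayesian network to a categorical cohort
#'
#' The central modelling function. Given a cohort of categorical variables it
#' either takes a fixed structure (`dag`) or learns one by
#' whitelist/blacklist-constrained BIC hill climbing ([hill_climb()]), then
#' estimates the conditional probability tables. Scoring always uses the
#' maximum-likelihood tables (the convention under which BIC is defined);
#' the tables stored for inference are smoothed with pseudo-count `alpha`,
#' which defaults to 1 (Laplace) so that no posterior query dies on a zero
#' cell in a small cohort. Set `alpha = 0` for pure MLE inference.
#'
#' @param data a data frame of factors (e.g. a validated `bn_cohort`).
#' @param dag a fixed [bn_dag], or `NULL` to learn the structure from the
#'   data under `constraints`.
#' @param constraints a [bn_constraints]; with a fixed `dag` it is only
#'   validated against the structure, with `dag = NULL` it constrains the
#'   search.
#' @param criterion `"bic"` (default) or `"aic"` for structure scoring.
#' @param alpha smoothing pseudo-count for the stored inference tables.
#' @param restarts,seed,max_iter passed to [hill_climb()] when learning.
#' @return an object of class `catbn`: list with `dag`, `cpts` (smoothed,
#'   for inference), `levels`, `alpha`, `score` (the MLE [network_score()]
#'   report), `search` (the [hill_climb()] trace, or `NULL`), `n`, `data`,
#'   `call`. Supported methods: `print`, `summary`, `coef`, `logLik`
#'   (hence `AIC`/`BIC`), `simulate`, `predict`, `plot`.
#' @examples
#' bn0 <- gi_reference_network()
#' d <- sample_cohort(bn0, n = 500, seed = 7)
#' fit <- catbn(d, constraints = gi_constraints(), seed = 7)
#' summary(fit)
#' @export
catbn <- function(data, dag = NULL, constraints = NULL,
                  criterion = c("bic", "aic"), alpha = 1,
                  restarts = 0, seed = NULL, max_iter = 500L) {
  criterion <- match.arg(criterion)
  cl <- match.call()
  data <- as.data.frame(data)
  vars <- names(data)[vapply(data, is.factor, logical(1))]
  data <- data[vars]
  search <- NULL
  if (is.null(dag)) {
    search <- hill_climb(data, constraints = constraints, criterion = criterion,
                         restarts = restarts, seed = seed, max_iter = max_iter)
    dag <- search$dag
  } else {
    stopifnot(inherits(dag, "bn_dag"))
    if (!is.null(constraints)) {
      chk <- validate_constraints(dag, constraints)
      if (!chk$ok) {
        print(chk)
        stop("supplied structure violates the constraints")
      }
    }
  }
  cpts <- fit_cpts(data, dag, alpha = alpha)
  sc <- network_score(data, dag, criterion = criterion)
  structure(list(dag = dag, cpts = cpts, levels = cpt_levels(cpts),
                 alpha = alpha, score = sc, search = search,
                 n = nrow(data), data = data, call = cl),
            class = "catbn")
}

#' Assemble a network from a structure and explicit tables
#'
#' Builds a `catbn` object directly from known conditional probability
#' tables (e.g. a simulation ground truth) rather than from data.
#'
#' @param dag a [bn_dag].
#' @param cpts named list of CPT arrays: for node `v` with parents `p1, ...`,
#'   an array whose first dimension (levels of `v`) sums to 1 for every
#'   parent configuration, with `dimnames` named `c(v, p1, ...)`.
#' @return an (unfitted) object of class `catbn`.
#' @export
make_bn <- function(dag, cpts) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!setequal(names(cpts), dag$nodes)) stop("need exactly one CPT per node")
  for (v in dag$nodes) {
    cpt <- cpts[[v]]
    dn <- names(dimnames(cpt))
    if (is.null(dn) || dn[1] != v)
      stop("CPT for ", v, " must have ", v, " as its first dimension")
    if (!setequal(dn[-1], dag$parents[[v]]))
      stop("CPT parent dimensions for ", v, " do not match the structure")
    sums <- if (length(dim(cpt)) == 1L) sum(cpt) else
      apply(cpt, seq_along(dim(cpt))[-1], sum)
    if (any(abs(sums - 1) > 1e-12))
      stop("CPT rows for ", v, " do not sum to 1")
    if (any(cpt < 0) || any(cpt > 1)) stop("CPT entries for ", v, " outside [0, 1]")
  }
  cpts <- cpts[dag$nodes]
  structure(list(dag = dag, cpts = cpts, levels = cpt_levels(cpts),
                 alpha = NA_real_, score = NULL, search = NULL,
                 n = NULL, data = NULL, call = sys.call()),
            class = "catbn")
}

#' @export
print.catbn <- function(x, ...) {
  cat("Multinomial Bayesian network: ", length(x$dag$nodes), " nodes, ",
      narcs(x$dag), " arcs\n", sep = "")
  cat("  structure: ", format(x$dag), "\n", sep = "")
  if (!is.null(x$score))
    cat(sprintf("  fitted on n = %d (inference smoothing alpha = %g); BIC = %.2f\n",
                x$n, x$alpha, x$score$bic))
  else cat("  tables supplied directly (not fitted to data)\n")
  invisible(x)
}

#' @export
summary.catbn <- function(object, ...) {
  marg <- lapply(names(object$levels), function(v) {
    p <- eliminate_to_target(object$cpts, object$levels, v, list())
    p / sum(p)
  })
  names(marg) <- names(object$levels)
  structure(list(object = object, indicators = graph_indicators(object$dag),
                 marginals = marg), class = "summary.catbn")
}

#' @export
print.summary.catbn <- function(x, ...) {
  print(x$object)
  cat("\nStructural indicators:\n")
  print(x$indicators)
  cat("\nImplied marginal distributions:\n")
  for (v in names(x$marginals)) {
    p <- round(x$marginals[[v]], 3)
    cat("  ", v, ": ", paste(names(p), p, sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$object$score)) {
    cat("\n")
    print(x$object$score)
  }
  invisible(x)
}

#' @export
coef.catbn <- function(object, ...) object$cpts

#' @export
logLik.catbn <- function(object, ...) {
  if (is.null(object$score)) stop("network was not fitted to data")
  structure(object$score$loglik, df = object$score$k, nobs = object$score$n,
            class = "logLik")
}

#' Sample a synthetic cohort from a network
#'
#' Ancestral sampling: each node is drawn in topological order from its CPT
#' given the already-sampled parent values. The same seed always yields the
#' identical cohort.
#'
#' @param bn a `catbn` network.
#' @param n number of patients to draw.
#' @param seed RNG seed (required, so that every draw is reproducible).
#' @return a validated `bn_cohort` data frame with `n` rows.
#' @export
sample_cohort <- function(bn, n, seed) {
  stopifnot(inherits(bn, "catbn"), n >= 0)
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  with_seed(seed, {
    out <- list()
    for (v in topo_sort(bn$dag)) {
      cpt <- bn$cpts[[v]]
      lv <- bn$levels[[v]]
      pars <- names(dimnames(cpt))[-1]
      if (!length(pars)) {
        out[[v]] <- sample(lv, n, replace = TRUE, prob = as.numeric(cpt))
      } else {
        dims <- dim(cpt)
        cfg <- rep(1L, n)
        mult <- 1L
        for (j in seq_along(pars)) {
          pi <- match(out[[pars[j]]], dimnames(cpt)[[j + 1L]])
          cfg <- cfg + (pi - 1L) * mult
          mult <- mult * dims[j + 1L]
        }
        m <- matrix(cpt, nrow = dims[1])
        res <- character(n)
        for (u in unique(cfg))
          res[cfg == u] <- sample(lv, sum(cfg == u), replace = TRUE,
                                  prob = m[, u])
        out[[v]] <- res
      }
    }
    df <- as.data.frame(lapply(out, identity), stringsAsFactors = FALSE,
                        check.names = FALSE)
    if (n == 0L) df <- as.data.frame(stats::setNames(
      lapply(names(bn$levels), function(v) character(0)), names(bn$levels)),
      check.names = FALSE)
    as_cohort(df[names(bn$levels)], levels = bn$levels)
  })
}

#' @export
simulate.catbn <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (is.null(n)) n <- object$n %||% 96L
  if (is.null(seed)) stop("'seed' is required")
  sims <- lapply(seq_len(nsim), function(i) sample_cohort(object, n, seed + i - 1L))
  if (nsim == 1L) sims[[1]] else sims
}

#' Posterior prediction for new records
#'
#' For each row of `newdata`, the observed values of the non-target columns
#' are used as evidence and the exact posterior of `target` is computed by
#' variable elimination. `NA` cells are treated as unobserved.
#'
#' @param object a fitted `catbn`.
#' @param target name of the variable to predict.
#' @param newdata data frame with any subset of the network's variables;
#'   defaults to the training data.
#' @param type `"prob"` for the posterior matrix (rows = records, columns =
#'   levels), `"class"` for the maximum-posterior level.
#' @param ... unused.
#' @return a numeric matrix or a factor, according to `type`.
#' @export
predict.catbn <- function(object, target, newdata = NULL,
                          type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  if (is.null(newdata)) stop("no 'newdata' and no stored training data")
  newdata <- as.data.frame(newdata)
  evvars <- intersect(setdiff(names(object$levels), target), names(newdata))
  probs <- t(vapply(seq_len(nrow(newdata)), function(i) {
    ev <- lapply(newdata[i, evvars, drop = FALSE], as.character)
    ev <- ev[!vapply(ev, is.na, logical(1))]
    eliminate_query(object, target, ev)$posterior
  }, numeric(length(object$levels[[target]]))))
  colnames(probs) <- object$levels[[target]]
  if (type == "prob") probs
  else factor(object$levels[[target]][max.col(probs, ties.method = "first")],
              levels = object$levels[[target]])
}

#' Plot a network structure
#'
#' Base-graphics rendering: nodes on a circle, directed arcs as arrows,
#' optional per-arc labels (e.g. significance tiers).
#'
#' @param x a [bn_dag] or `catbn`.
#' @param labels optional arc labels: data frame with columns `from`, `to`,
#'   `tier` (as produced by [arc_significance()]).
#' @param ... passed to [plot()].
#' @export
plot.bn_dag <- function(x, labels = NULL, ...) {
  g <- x
  n <- length(g$nodes)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  xy <- cbind(cos(th), sin(th))
  rownames(xy) <- g$nodes
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1, ...)
  a <- arcs(g)
  lab <- character(0)
  if (!is.null(labels))
    lab <- stats::setNames(as.character(labels$tier),
                           paste(labels$from, labels$to, sep = "->"))
  for (i in seq_len(nrow(a))) {
    p0 <- xy[a[i, 1], ]; p1 <- xy[a[i, 2], ]
    d <- p1 - p0
    len <- sqrt(sum(d^2))
    sh <- 0.14 / len
    q0 <- p0 + d * sh; q1 <- p1 - d * sh
    graphics::arrows(q0[1], q0[2], q1[1], q1[2], length = 0.1, col = "grey30")
    k <- paste(a[i, 1], a[i, 2], sep = "->")
    if (k %in% names(lab))
      graphics::text((q0[1] + q1[1]) / 2, (q0[2] + q1[2]) / 2, lab[[k]],
                     col = "red3", cex = 0.9)
  }
  graphics::text(xy[, 1] * 1.15, xy[, 2] * 1.15, g$nodes, cex = 0.9)
  invisible(x)
}

#' @rdname plot.bn_dag
#' @export
plot.catbn <- function(x, labels = NULL, ...) plot.bn_dag(x$dag, labels = labels, ...)
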