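#' Constrained greedy structure search
#'
#' Hill climbing over DAGs in the decomposable maximization form of the
#' chosen criterion (for BIC, `lnL - (ln n / 2) k`; maximizing it is the same
#' as minimizing `k ln n - 2 lnL`). The search starts from the graph
#' containing exactly the whitelisted arcs; at every step the single-arc
#' moves (add, delete, reverse) are scored incrementally through cached
#' family scores and the best strictly improving move is taken. Whitelisted
#' arcs are never deleted or reversed, blacklisted arcs never added, and
#' cyclic moves are rejected. Ties between equally improving moves are broken
#' lexicographically by (move type, parent, child), so a run with
#' `restarts = 0` is fully deterministic. Random restarts perturb the start
#' graph with seeded random valid moves and keep the best-scoring optimum.
#'
#' @param x a data frame of factors (complete categorical cohort).
#' @param constraints a [bn_constraints] or `NULL` for an unconstrained
#'   search.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param restarts number of random restarts (0 = single deterministic run).
#' @param seed RNG seed for the restarts; required when `restarts > 0`.
#' @param max_iter cap on accepted moves per run.
#' @return an object of class `bn_search`: list with the final `dag`, its
#'   [network_score()] report `score`, the move `trace` (a data frame with
#'   step, move, from, to, delta, score), `steps`, `restarts`, `seed`.
#' @export
hill_climb <- function(x, constraints = NULL, criterion = c("bic", "aic"),
                       restarts = 0, seed = NULL, max_iter = 500L) {
  criterion <- match.arg(criterion)
  x <- as.data.frame(x)
  nodes <- names(x)[vapply(x, is.factor, logical(1))]
  if (length(nodes) < 2L) stop("need at least 2 categorical variables")
  x <- x[nodes]
  if (nrow(x) == 0L) stop("cannot search on an empty cohort")
  k <- constraints %||% bn_constraints()
  stopifnot(inherits(k, "bn_constraints"))
  outside <- setdiff(unique(c(as.vector(k$whitelist), as.vector(k$blacklist))), nodes)
  if (length(outside)) stop("constraint on unknown variable(s): ",
                            paste(outside, collapse = ", "))
  if (restarts > 0 && is.null(seed)) stop("'seed' is required when restarts > 0")
  ctx <- search_context(x, nodes, k, criterion)
  start <- bn_dag(arcs_to_parents(k$whitelist, nodes = nodes), nodes = nodes)
  best <- local_search(start, ctx, max_iter)
  if (restarts > 0) {
    best <- with_seed(seed, {
      b <- best
      for (r in seq_len(restarts)) {
        res <- local_search(perturb_dag(start, ctx), ctx, max_iter)
        if (res$value > b$value + 1e-12) b <- res
      }
      b
    })
  }
  sc <- network_score(x, best$dag, criterion = criterion)
  structure(list(dag = best$dag, score = sc, trace = best$trace,
                 steps = nrow(best$trace), restarts = restarts, seed = seed,
                 criterion = criterion, method = "hill_climb"),
            class = "bn_search")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

search_context <- function(x, nodes, k, criterion) {
  n <- nrow(x)
  pen <- if (criterion == "bic") log(n) / 2 else 1
  nlev <- vapply(nodes, function(v) nlevels(x[[v]]), numeric(1))
  cache <- new.env(parent = emptyenv())
  fam_score <- function(v, pars) {
    key <- paste(v, paste(sort(pars), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- family_loglik(x, v, pars) - pen * (nlev[[v]] - 1) * prod(nlev[pars])
    cache[[key]] <- val
    val
  }
  list(nodes = nodes, fam_score = fam_score,
       wl = arc_keys(k$whitelist), bl = arc_keys(k$blacklist))
}

# enumerate valid single-arc moves in lexicographic (move, from, to) order
valid_moves <- function(g, ctx) {
  nodes <- sort(ctx$nodes)
  out <- list()
  for (type in c("add", "delete", "reverse")) {
    for (from in nodes) for (to in nodes) {
      if (from == to) next
      key <- paste(from, to, sep = "->")
      rkey <- paste(to, from, sep = "->")
      present <- has_arc(g, from, to)
      ok <- switch(type,
        add = !present && !has_arc(g, to, from) && !key %in% ctx$bl &&
          !from %in% descendants(g, to),
        delete = present && !key %in% ctx$wl,
        reverse = present && !key %in% ctx$wl && !rkey %in% ctx$bl &&
          !to %in% descendants(drop_arc(g, from, to), from))
      if (ok) out[[length(out) + 1L]] <- c(type, from, to)
    }
  }
  out
}

descendants <- function(g, v) {
  seen <- character(0)
  frontier <- bn_children(g, v)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, bn_children, g = g))), seen)
  }
  seen
}

move_delta <- function(g, mv, ctx) {
  type <- mv[1]; from <- mv[2]; to <- mv[3]
  fs <- ctx$fam_score
  if (type == "add")
    fs(to, c(g$parents[[to]], from)) - fs(to, g$parents[[to]])
  else if (type == "delete")
    fs(to, setdiff(g$parents[[to]], from)) - fs(to, g$parents[[to]])
  else
    (fs(to, setdiff(g$parents[[to]], from)) - fs(to, g$parents[[to]])) +
      (fs(from, c(g$parents[[from]], to)) - fs(from, g$parents[[from]]))
}

apply_move <- function(g, mv) {
  switch(mv[1],
         add = add_arc(g, mv[2], mv[3]),
         delete = drop_arc(g, mv[2], mv[3]),
         reverse = reverse_arc(g, mv[2], mv[3]))
}

local_search <- function(g, ctx, max_iter) {
  value <- sum(vapply(ctx$nodes, function(v) ctx$fam_score(v, g$parents[[v]]),
                      numeric(1)))
  trace <- data.frame(step = integer(0), move = character(0),
                      from = character(0), to = character(0),
                      delta = numeric(0), score = numeric(0))
  for (it in seq_len(max_iter)) {
    moves <- valid_moves(g, ctx)
    if (!length(moves)) break
    best_delta <- 1e-12
    best_mv <- NULL
    for (mv in moves) {   # lexicographic order: first strictly-best wins ties
      d <- move_delta(g, mv, ctx)
      if (d > best_delta + 1e-12) {
        best_delta <- d
        best_mv <- mv
      }
    }
    if (is.null(best_mv)) break
    g <- apply_move(g, best_mv)
    value <- value + best_delta
    trace <- rbind(trace, data.frame(step = it, move = best_mv[1],
                                     from = best_mv[2], to = best_mv[3],
                                     delta = best_delta, score = value))
  }
  list(dag = g, value = value, trace = trace)
}

perturb_dag <- function(g, ctx, n_moves = length(ctx$nodes)) {
  for (i in seq_len(n_moves)) {
    moves <- valid_moves(g, ctx)
    if (!length(moves)) break
    g <- apply_move(g, moves[[sample.int(length(moves), 1L)]])
  }
  g
}

#' @export
print.bn_search <- function(x, ...) {
  cat("Structure search (", x$method, ", criterion = ", toupper(x$criterion),
      ")\n", sep = "")
  if (!is.null(x$steps)) cat("  accepted moves:", x$steps,
                             " restarts:", x$restarts, "\n")
  if (!is.null(x$n_dags)) cat("  DAGs enumerated:", x$n_dags, "\n")
  cat("  final structure: ", format(x$dag), "\n", sep = "")
  cat(sprintf("  score (maximization form): %.4f\n",
              criterion_value(x$score, x$criterion)))
  invisible(x)
}

#' Exhaustive structure search (oracle for small instances)
#'
#' Enumerates every constraint-compliant DAG over at most five variables
#' (29,281 DAGs at five nodes) and returns the one with the best criterion
#' value; among exact ties the DAG with the lexicographically least arc list
#' is returned, so the result is unique and deterministic. Used as the
#' independent optimum against which [hill_climb()] is validated.
#'
#' @inheritParams hill_climb
#' @return a `bn_search` object with `method = "exhaustive"` and the number
#'   of structures enumerated in `n_dags`.
#' @export
exhaustive_search <- function(x, constraints = NULL, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  x <- as.data.frame(x)
  nodes <- names(x)[vapply(x, is.factor, logical(1))]
  x <- x[nodes]
  if (length(nodes) > 5L)
    stop("exhaustive enumeration is limited to 5 variables (got ",
         length(nodes), ")")
  if (length(nodes) < 2L) stop("need at least 2 categorical variables")
  k <- constraints %||% bn_constraints()
  ctx <- search_context(x, nodes, k, criterion)
  wl_par <- arcs_to_parents(k$whitelist, nodes = nodes)
  bl_par <- arcs_to_parents(k$blacklist, nodes = nodes)
  # admissible parent sets per node, with their family scores
  cand <- lapply(nodes, function(v) {
    others <- setdiff(nodes, v)
    req <- wl_par[[v]]
    forb <- bl_par[[v]]
    free <- setdiff(others, c(req, forb))
    sets <- list(req)
    for (f in free) sets <- c(sets, lapply(sets, c, f))
    lapply(sets, function(p) list(parents = sort(p),
                                  score = ctx$fam_score(v, p)))
  })
  names(cand) <- nodes
  best <- new.env(parent = emptyenv())
  best$value <- -Inf
  best$key <- NULL
  best$parents <- NULL
  best$count <- 0L
  parents <- stats::setNames(lapply(nodes, function(v) character(0)), nodes)
  recurse <- function(i, parents, value) {
    if (i > length(nodes)) {
      best$count <- best$count + 1L
      key <- dag_key(parents)
      if (value > best$value + 1e-12 ||
          (abs(value - best$value) <= 1e-12 &&
           (is.null(best$key) || key < best$key))) {
        best$value <- value
        best$key <- key
        best$parents <- parents
      }
      return(invisible())
    }
    v <- nodes[i]
    for (opt in cand[[v]]) {
      parents[[v]] <- opt$parents
      if (!is_acyclic(parents)) next
      recurse(i + 1L, parents, value + opt$score)
    }
    invisible()
  }
  recurse(1L, parents, 0)
  g <- bn_dag(best$parents, nodes = nodes)
  structure(list(dag = g, score = network_score(x, g, criterion = criterion),
                 trace = NULL, n_dags = best$count, restarts = 0L,
                 seed = NULL, criterion = criterion, method = "exhaustive"),
            class = "bn_search")
}

dag_key <- function(parents) {
  ks <- unlist(lapply(names(parents), function(v)
    if (length(parents[[v]])) paste(parents[[v]], v, sep = "->") else character(0)))
  paste(sort(ks), collapse = ";")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  glob <- globalenv()
  had <- exists(".Random.seed", envir = glob, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = glob)
  on.exit(if (had) assign(".Random.seed", old, envir = glob)
          else if (exists(".Random.seed", envir = glob, inherits = FALSE))
            rm(".Random.seed", envir = glob))
  set.seed(seed)
  force(code)
}
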