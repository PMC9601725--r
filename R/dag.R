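#' Directed acyclic graphs over named categorical variables
#'
#' A `bn_dag` stores the structure of a discrete Bayesian network: a set of
#' node names and, for every node, its parent set. The joint distribution of
#' the network factorizes as the product over nodes of
#' P(node | parents(node)), so a `bn_dag` can be written down directly from a
#' printed factorization formula.
#'
#' @param x either a named list mapping each variable to the character vector
#'   of its parents (roots map to `character(0)`), or a single model string in
#'   the bracket notation `"[A][B|A][C|A:B]"` where parents are separated by
#'   colons.
#' @param nodes optional character vector fixing the node set and its order;
#'   defaults to the variables named in `x`. Must contain every variable and
#'   parent that appears in `x`.
#' @return an object of class `bn_dag`.
#' @examples
#' g <- bn_dag("[A][B|A][C|A:B]")
#' bn_parents(g, "C")
#' narcs(g)
#' @export
bn_dag <- function(x = list(), nodes = NULL) {
  if (is.character(x) && length(x) == 1L) x <- parse_model_string(x)
  if (!is.list(x)) stop("'x' must be a named list of parent sets or a model string")
  vars <- names(x)
  if (length(x) && (is.null(vars) || anyNA(vars) || any(vars == "")))
    stop("every element of 'x' must be named by its variable")
  if (anyDuplicated(vars)) stop("variable listed more than once: ",
                                paste(unique(vars[duplicated(vars)]), collapse = ", "))
  pars <- lapply(x, function(p) as.character(if (is.null(p)) character(0) else p))
  all_mentioned <- unique(c(vars, unlist(pars, use.names = FALSE)))
  if (is.null(nodes)) nodes <- all_mentioned
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  unknown <- setdiff(all_mentioned, nodes)
  if (length(unknown)) stop("unknown parent variable(s): ", paste(unknown, collapse = ", "))
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) parents[[v]] <- character(0)
  for (v in vars) {
    p <- pars[[v]]
    if (anyDuplicated(p)) stop("duplicate parent of ", v)
    if (v %in% p) stop("self-arc at ", v)
    parents[[v]] <- p
  }
  g <- structure(list(nodes = nodes, parents = parents), class = "bn_dag")
  ts <- topo_sort(g, quiet = TRUE)
  if (is.null(ts)) stop("parent specification is cyclic")
  g
}

parse_model_string <- function(s) {
  s <- gsub("\\s", "", s)
  if (!grepl("^(\\[[^]\\[]+\\])+$", s)) stop("malformed model string: ", s)
  blocks <- regmatches(s, gregexpr("\\[[^]]+\\]", s))[[1]]
  blocks <- substr(blocks, 2L, nchar(blocks) - 1L)
  out <- list()
  for (b in blocks) {
    parts <- strsplit(b, "|", fixed = TRUE)[[1]]
    v <- parts[1]
    out[[v]] <- if (length(parts) > 1L) strsplit(parts[2], ":", fixed = TRUE)[[1]] else character(0)
  }
  out
}

#' @export
format.bn_dag <- function(x, ...) {
  blocks <- vapply(x$nodes, function(v) {
    p <- x$parents[[v]]
    if (length(p)) paste0("[", v, "|", paste(p, collapse = ":"), "]") else paste0("[", v, "]")
  }, character(1))
  paste(blocks, collapse = "")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("Directed acyclic graph:", length(x$nodes), "nodes,", narcs(x), "arcs\n")
  cat(" ", format(x), "\n")
  invisible(x)
}

#' Arcs of a DAG
#'
#' @param g a [bn_dag].
#' @return a two-column character matrix with columns `from` and `to`, one row
#'   per directed arc, in canonical (lexicographic) order.
#' @export
arcs <- function(g) {
  stopifnot(inherits(g, "bn_dag"))
  from <- unlist(g$parents, use.names = FALSE)
  to <- rep(names(g$parents), lengths(g$parents))
  m <- cbind(from = from, to = to)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' @rdname arcs
#' @export
narcs <- function(g) sum(lengths(g$parents))

#' Parents and children of a node
#'
#' @param g a [bn_dag].
#' @param v a node name.
#' @return a character vector of node names.
#' @export
bn_parents <- function(g, v) {
  check_node(g, v)
  g$parents[[v]]
}

#' @rdname bn_parents
#' @export
bn_children <- function(g, v) {
  check_node(g, v)
  g$nodes[vapply(g$nodes, function(u) v %in% g$parents[[u]], logical(1))]
}

check_node <- function(g, v) {
  stopifnot(inherits(g, "bn_dag"))
  if (length(v) != 1L || !v %in% g$nodes) stop("unknown node: ", paste(v, collapse = ", "))
  invisible(v)
}

has_arc <- function(g, from, to) from %in% g$parents[[to]]

add_arc <- function(g, from, to) {
  g$parents[[to]] <- c(g$parents[[to]], from)
  g
}

drop_arc <- function(g, from, to) {
  g$parents[[to]] <- setdiff(g$parents[[to]], from)
  g
}

reverse_arc <- function(g, from, to) add_arc(drop_arc(g, from, to), to, from)

#' Topological order of a DAG
#'
#' Kahn's algorithm; among the nodes available at each step the one that comes
#' first in `g$nodes` is emitted, so the order is deterministic.
#'
#' @param g a [bn_dag] (or the `parents` list of one).
#' @param quiet if `TRUE`, return `NULL` on a cyclic graph instead of erroring.
#' @return character vector of node names, parents before children.
#' @export
topo_sort <- function(g, quiet = FALSE) {
  parents <- if (inherits(g, "bn_dag")) g$parents else g
  nodes <- names(parents)
  remaining <- parents
  out <- character(0)
  while (length(remaining)) {
    free <- names(remaining)[vapply(remaining, function(p) !any(p %in% names(remaining)), logical(1))]
    if (!length(free)) {
      if (quiet) return(NULL)
      stop("graph is cyclic")
    }
    nxt <- free[1]
    out <- c(out, nxt)
    remaining[[nxt]] <- NULL
  }
  out
}

is_acyclic <- function(parents) !is.null(topo_sort(parents, quiet = TRUE))

#' Adjacency matrix of a DAG
#'
#' @param g a [bn_dag].
#' @return a 0/1 integer matrix with `a[i, j] = 1` iff there is an arc
#'   `i -> j`; rows and columns named by node.
#' @export
amat <- function(g) {
  stopifnot(inherits(g, "bn_dag"))
  n <- length(g$nodes)
  a <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  for (v in g$nodes) a[g$parents[[v]], v] <- 1L
  a
}

#' Markov blanket of a node
#'
#' The Markov blanket of `v` is the union of its parents, its children, and
#' the other parents of its children ("spouses"). Conditioning on the blanket
#' renders `v` independent of every other variable in the network.
#'
#' @param g a [bn_dag].
#' @param v a node name.
#' @return character vector of node names (excluding `v` itself).
#' @export
markov_blanket <- function(g, v) {
  check_node(g, v)
  ch <- bn_children(g, v)
  spouses <- unlist(lapply(ch, function(c) g$parents[[c]]), use.names = FALSE)
  setdiff(unique(c(g$parents[[v]], ch, spouses)), v)
}

#' Structural indicators of a network
#'
#' Summaries used to compare network structures: the number of directed arcs,
#' the average Markov-blanket size, the average neighborhood size (parents
#' plus children, i.e. `2 * arcs / nodes`), and the average branching factor
#' (children per node, i.e. `arcs / nodes`).
#'
#' @param g a [bn_dag].
#' @return an object of class `bn_indicators`: a list with elements `nodes`,
#'   `arcs`, `avg_markov_blanket`, `avg_neighborhood`, `avg_branching`
#'   (exact values; the print method rounds half-up to two decimals).
#' @export
graph_indicators <- function(g) {
  stopifnot(inherits(g, "bn_dag"))
  if (!length(g$nodes)) stop("empty node set")
  mb <- vapply(g$nodes, function(v) length(markov_blanket(g, v)), numeric(1))
  nb <- vapply(g$nodes, function(v)
    length(unique(c(g$parents[[v]], bn_children(g, v)))), numeric(1))
  a <- narcs(g)
  structure(list(nodes = length(g$nodes), arcs = a,
                 avg_markov_blanket = mean(mb),
                 avg_neighborhood = mean(nb),
                 avg_branching = a / length(g$nodes)),
            class = "bn_indicators")
}

#' @export
print.bn_indicators <- function(x, ...) {
  cat("Directed arcs:            ", x$arcs, "\n")
  cat("Average Markov blanket:   ", format(round_half_up(x$avg_markov_blanket, 2), nsmall = 2), "\n")
  cat("Average neighborhood:     ", format(round_half_up(x$avg_neighborhood, 2), nsmall = 2), "\n")
  cat("Average branching factor: ", format(round_half_up(x$avg_branching, 2), nsmall = 2), "\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding for structural indicators: `0.875` rounds to `0.88`
#' (base R's [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Test d-separation
#'
#' `x` and `y` are d-separated by the conditioning set `z` when every path
#' between them is blocked: a chain or fork is blocked by conditioning on its
#' middle node, while a collider blocks unless it (or a descendant) is
#' conditioned on. Implemented by moralizing the ancestral subgraph of
#' `{x, y} `\eqn{\cup}` z`, deleting `z`, and testing connectivity.
#'
#' @param g a [bn_dag].
#' @param x,y node names, distinct and not in `z`.
#' @param z character vector of conditioning nodes (may be empty).
#' @return `TRUE` iff `x` and `y` are d-separated given `z`.
#' @export
d_separated <- function(g, x, y, z = character(0)) {
  check_node(g, x); check_node(g, y)
  z <- as.character(z)
  for (v in z) check_node(g, v)
  if (x == y) stop("'x' and 'y' must differ")
  if (x %in% z || y %in% z) stop("'x' and 'y' must not be in 'z'")
  keep <- ancestors_of(g, c(x, y, z))
  # moral graph on the ancestral set: undirected adjacency + married co-parents
  adj <- stats::setNames(lapply(keep, function(v) character(0)), keep)
  link <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  for (v in keep) {
    ps <- intersect(g$parents[[v]], keep)
    for (p in ps) link(p, v)
    if (length(ps) > 1L) {
      cmb <- utils::combn(ps, 2L)
      for (i in seq_len(ncol(cmb))) link(cmb[1, i], cmb[2, i])
    }
  }
  # remove z and flood-fill from x
  live <- setdiff(keep, z)
  frontier <- x
  seen <- x
  while (length(frontier)) {
    nxt <- setdiff(intersect(unique(unlist(adj[frontier], use.names = FALSE)), live), seen)
    if (y %in% nxt) return(FALSE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  TRUE
}

ancestors_of <- function(g, vs) {
  seen <- unique(vs)
  frontier <- seen
  while (length(frontier)) {
    ps <- unique(unlist(g$parents[frontier], use.names = FALSE))
    frontier <- setdiff(ps, seen)
    seen <- c(seen, frontier)
  }
  seen
}
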