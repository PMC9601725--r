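#' Whitelist/blacklist arc constraints
#'
#' Structure search over clinical variables is rarely unconstrained: prior
#' knowledge forces some causal arcs to be present (whitelist) and forbids
#' others (blacklist). A whitelisted arc can never be deleted or reversed
#' during search and a blacklisted arc can never be added.
#'
#' @param whitelist,blacklist arcs as a two-column matrix or data frame
#'   (`from`, `to`), or `NULL` for no constraint of that kind.
#' @return an object of class `bn_constraints` with canonical-ordered
#'   `whitelist` and `blacklist` arc matrices.
#' @examples
#' k <- bn_constraints(whitelist = rbind(c("ALB", "NUTR")),
#'                     blacklist = rbind(c("NUTR", "ALB")))
#' @export
bn_constraints <- function(whitelist = NULL, blacklist = NULL) {
  wl <- as_arc_matrix(whitelist)
  bl <- as_arc_matrix(blacklist)
  both <- intersect(arc_keys(wl), arc_keys(bl))
  if (length(both)) stop("arc(s) both whitelisted and blacklisted: ",
                         paste(both, collapse = ", "))
  if (any(wl[, 1] == wl[, 2]) || any(bl[, 1] == bl[, 2]))
    stop("self-arcs are not valid constraints")
  if (nrow(wl)) {
    p <- arcs_to_parents(wl)
    if (!is_acyclic(p)) stop("whitelist is cyclic")
  }
  structure(list(whitelist = wl, blacklist = bl), class = "bn_constraints")
}

as_arc_matrix <- function(x) {
  if (is.null(x)) return(matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to"))))
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("arc sets need two columns (from, to)")
  m <- cbind(from = as.character(x[, 1]), to = as.character(x[, 2]))
  m <- unique(m)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

arc_keys <- function(m) if (nrow(m)) paste(m[, 1], m[, 2], sep = "->") else character(0)

arcs_to_parents <- function(m, nodes = NULL) {
  nodes <- unique(c(nodes, as.vector(m)))
  p <- stats::setNames(lapply(nodes, function(v) character(0)), nodes)
  for (i in seq_len(nrow(m))) p[[m[i, 2]]] <- union(p[[m[i, 2]]], m[i, 1])
  p
}

#' @export
print.bn_constraints <- function(x, ...) {
  cat("Arc constraints:", nrow(x$whitelist), "whitelisted,",
      nrow(x$blacklist), "blacklisted\n")
  if (nrow(x$whitelist)) cat("  must hold: ", paste(arc_keys(x$whitelist), collapse = ", "), "\n")
  if (nrow(x$blacklist)) cat("  forbidden: ", paste(arc_keys(x$blacklist), collapse = ", "), "\n")
  invisible(x)
}

#' Check a DAG against arc constraints
#'
#' @param g a [bn_dag].
#' @param k a [bn_constraints] object.
#' @return an object of class `bn_constraint_check`: list with `ok` (logical),
#'   `missing_whitelist` and `forbidden_present` arc matrices.
#' @export
validate_constraints <- function(g, k) {
  stopifnot(inherits(g, "bn_dag"), inherits(k, "bn_constraints"))
  present <- arc_keys(arcs(g))
  miss <- k$whitelist[!arc_keys(k$whitelist) %in% present, , drop = FALSE]
  forb <- k$blacklist[arc_keys(k$blacklist) %in% present, , drop = FALSE]
  structure(list(ok = nrow(miss) == 0L && nrow(forb) == 0L,
                 missing_whitelist = miss, forbidden_present = forb),
            class = "bn_constraint_check")
}

#' @export
print.bn_constraint_check <- function(x, ...) {
  if (x$ok) cat("Constraints satisfied.\n")
  else {
    cat("Constraint violations:\n")
    if (nrow(x$missing_whitelist))
      cat("  missing whitelist arc(s): ", paste(arc_keys(x$missing_whitelist), collapse = ", "), "\n")
    if (nrow(x$forbidden_present))
      cat("  blacklisted arc(s) present: ", paste(arc_keys(x$forbidden_present), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read/write arc constraint sets as CSV
#'
#' The file has columns `from,to,list` with `list` either `"whitelist"` or
#' `"blacklist"`.
#'
#' @param path file path.
#' @param k a [bn_constraints] object (for writing).
#' @return `read_constraints` returns a [bn_constraints] object.
#' @export
read_constraints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("from", "to", "list")
  if (!all(need %in% names(df))) stop("constraint file needs columns from,to,list")
  bad <- setdiff(unique(df$list), c("whitelist", "blacklist"))
  if (length(bad)) stop("unknown constraint list: ", paste(bad, collapse = ", "))
  bn_constraints(whitelist = df[df$list == "whitelist", c("from", "to")],
                 blacklist = df[df$list == "blacklist", c("from", "to")])
}

#' @rdname read_constraints
#' @export
write_constraints <- function(k, path) {
  stopifnot(inherits(k, "bn_constraints"))
  df <- rbind(
    data.frame(from = k$whitelist[, 1], to = k$whitelist[, 2],
               list = rep("whitelist", nrow(k$whitelist))),
    data.frame(from = k$blacklist[, 1], to = k$blacklist[, 2],
               list = rep("blacklist", nrow(k$blacklist))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
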