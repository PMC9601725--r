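#' Export a DAG to DOT format
#'
#' Writes Graphviz DOT text, one node statement per variable and one edge
#' statement per arc. Arcs can be annotated with a significance tier symbol
#' (e.g. `"**"` for p < 0.05, `"*"` for p < 0.10, `"."` for not significant),
#' rendered as an edge label.
#'
#' @param g a [bn_dag].
#' @param path file path, or `""` to return the DOT text invisibly only.
#' @param tiers optional annotation: a data frame or matrix with columns
#'   `from`, `to`, `tier`. Every annotated arc must exist in `g`.
#' @param name graph name used in the `digraph` header.
#' @return the DOT text, invisibly (visibly if `path = ""`).
#' @export
write_dot <- function(g, path = "", tiers = NULL, name = "bn") {
  stopifnot(inherits(g, "bn_dag"))
  lab <- character(0)
  if (!is.null(tiers)) {
    tiers <- as.data.frame(tiers, stringsAsFactors = FALSE)
    if (!all(c("from", "to", "tier") %in% names(tiers)))
      stop("'tiers' needs columns from, to, tier")
    key <- paste(tiers$from, tiers$to, sep = "->")
    missing <- setdiff(key, arc_keys(arcs(g)))
    if (length(missing)) stop("annotation for arc(s) not in graph: ",
                              paste(missing, collapse = ", "))
    lab <- stats::setNames(as.character(tiers$tier), key)
  }
  q <- function(s) paste0("\"", gsub("\"", "\\\\\"", s), "\"")
  lines <- c(paste0("digraph ", name, " {"),
             paste0("  ", q(g$nodes), ";"))
  a <- arcs(g)
  for (i in seq_len(nrow(a))) {
    k <- paste(a[i, 1], a[i, 2], sep = "->")
    suffix <- if (k %in% names(lab)) paste0(" [label=", q(lab[[k]]), "]") else ""
    lines <- c(lines, paste0("  ", q(a[i, 1]), " -> ", q(a[i, 2]), suffix, ";"))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (nzchar(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Import a DAG from DOT format
#'
#' Parses the subset of DOT that [write_dot()] emits (quoted or bare node
#' identifiers, `a -> b` edges, optional attribute brackets), sufficient for
#' round-tripping structures.
#'
#' @param path file path or character vector of DOT lines.
#' @return a [bn_dag].
#' @export
read_dot <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  body <- paste(lines, collapse = "\n")
  body <- gsub("digraph[^{]*\\{", "", body)
  body <- gsub("\\}", "", body)
  stmts <- strsplit(body, ";", fixed = TRUE)[[1]]
  stmts <- trimws(gsub("\\[[^]]*\\]", "", stmts))
  stmts <- stmts[nzchar(stmts)]
  unq <- function(s) {
    s <- trimws(s)
    gsub("^\"|\"$", "", s)
  }
  nodes <- character(0)
  edges <- matrix(character(0), 0, 2)
  for (s in stmts) {
    if (grepl("->", s, fixed = TRUE)) {
      ends <- unq(strsplit(s, "->", fixed = TRUE)[[1]])
      if (length(ends) != 2L) stop("cannot parse edge statement: ", s)
      nodes <- union(nodes, ends)
      edges <- rbind(edges, ends)
    } else {
      nodes <- union(nodes, unq(s))
    }
  }
  bn_dag(arcs_to_parents(edges, nodes = nodes), nodes = nodes)
}
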