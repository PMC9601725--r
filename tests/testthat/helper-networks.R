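# toy networks and generators shared across the test files

# A -> B with P(A=1) = 0.3, P(B=1 | A=1) = 0.9, P(B=1 | A=0) = 0.2
toy_ab <- function() {
  dag <- bn_dag(list(A = character(0), B = "A"))
  cpts <- list(
    A = array(c(0.7, 0.3), dim = 2, dimnames = list(A = c("0", "1"))),
    B = array(c(0.8, 0.2, 0.1, 0.9), dim = c(2, 2),
              dimnames = list(B = c("0", "1"), A = c("0", "1")))
  )
  make_bn(dag, cpts)
}

# chain A -> B -> C with strong links
toy_chain <- function(p_keep = 0.9) {
  dag <- bn_dag("[A][B|A][C|B]")
  flip <- function(p) array(c(p, 1 - p, 1 - p, p), dim = c(2, 2))
  ab <- flip(p_keep); dimnames(ab) <- list(B = c("0", "1"), A = c("0", "1"))
  bc <- flip(p_keep); dimnames(bc) <- list(C = c("0", "1"), B = c("0", "1"))
  make_bn(dag, list(
    A = array(c(0.5, 0.5), dim = 2, dimnames = list(A = c("0", "1"))),
    B = ab, C = bc))
}

rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

# random CPTs on a given structure, binary levels unless specified
random_bn <- function(dag, nlev = NULL) {
  nodes <- dag$nodes
  if (is.null(nlev)) nlev <- stats::setNames(rep(2L, length(nodes)), nodes)
  lv <- lapply(nlev, function(k) paste0("l", seq_len(k)))
  cpts <- lapply(nodes, function(v) {
    pars <- bn_parents(dag, v)
    q <- prod(nlev[pars])
    tab <- vapply(seq_len(q), function(i) rdirichlet1(nlev[[v]]),
                  numeric(nlev[[v]]))
    array(tab, dim = c(nlev[[v]], nlev[pars]),
          dimnames = stats::setNames(lv[c(v, pars)], c(v, pars)))
  })
  names(cpts) <- nodes
  make_bn(dag, cpts)
}

# random DAG over the given nodes: random order, each upper pair an arc w.p. p
random_dag <- function(nodes, p = 0.4) {
  ord <- sample(nodes)
  parents <- stats::setNames(lapply(nodes, function(v) character(0)), nodes)
  for (i in seq_along(ord)) for (j in seq_len(i - 1L)) {
    if (stats::runif(1) < p)
      parents[[ord[i]]] <- c(parents[[ord[i]]], ord[j])
  }
  bn_dag(parents, nodes = nodes)
}

# data frame of independent uniform binary factors
independent_binaries <- function(n, m, labels = c("a", "b")) {
  d <- as.data.frame(lapply(seq_len(m), function(j)
    factor(sample(labels, n, replace = TRUE), levels = labels)))
  names(d) <- LETTERS[seq_len(m)]
  d
}

# expand a contingency table of counts into a two-column factor data frame
counts_to_df <- function(counts, a = "u", b = "v") {
  rn <- rownames(counts) %||% paste0("r", seq_len(nrow(counts)))
  cn <- colnames(counts) %||% paste0("c", seq_len(ncol(counts)))
  rows <- rep(rep(rn, ncol(counts)), as.vector(counts))
  cols <- rep(rep(cn, each = nrow(counts)), as.vector(counts))
  out <- data.frame(factor(rows, levels = rn), factor(cols, levels = cn))
  names(out) <- c(a, b)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
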