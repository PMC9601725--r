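arc_keys_test <- function(g) {
  a <- arcs(g)
  paste(a[, 1], a[, 2], sep = "->")
}

test_that("a DAG can be read off a factorization and is validated", {
  g <- gi_bic_dag()
  expect_equal(narcs(g), 7L)
  expect_setequal(arc_keys_test(g),
                  c("CANCER->MTX", "ALB->NUTR", "MTX->BTcP", "BMI->BTcP",
                    "MTX->RADIO", "NUTR->HRA", "RADIO->HRA"))
  expect_equal(narcs(bn_dag(list(A = character(0), B = character(0)))), 0L)
  expect_error(bn_dag(list(A = "B", B = "A")), "cyclic")
  expect_error(bn_dag(list(A = "Z"), nodes = c("A", "B")), "unknown parent")
  expect_error(bn_dag(list(A = "A")), "self-arc")
  expect_equal(format(bn_dag("[A][B|A][C|A:B]")), "[A][B|A][C|A:B]")
})

test_that("Markov blankets collect parents, children and spouses", {
  g <- gi_bic_dag()
  expect_setequal(markov_blanket(g, "MTX"), c("CANCER", "BTcP", "RADIO", "BMI"))
  expect_setequal(markov_blanket(g, "ALB"), "NUTR")
  iso <- bn_dag(list(A = character(0), B = "C", C = character(0)))
  expect_length(markov_blanket(iso, "A"), 0L)
  expect_error(markov_blanket(g, "XYZ"), "unknown node")
})

test_that("Markov blanket membership is symmetric", {
  set.seed(41)
  for (i in 1:20) {
    g <- random_dag(LETTERS[1:6], p = 0.4)
    for (x in g$nodes) for (y in setdiff(g$nodes, x)) {
      expect_equal(y %in% markov_blanket(g, x), x %in% markov_blanket(g, y))
    }
  }
})

test_that("indicator identities hold exactly on random graphs", {
  set.seed(42)
  for (i in 1:20) {
    g <- random_dag(LETTERS[1:7], p = 0.35)
    ind <- graph_indicators(g)
    expect_equal(ind$avg_neighborhood, 2 * narcs(g) / 7, tolerance = 1e-12)
    expect_equal(ind$avg_branching, narcs(g) / 7, tolerance = 1e-12)
    expect_gte(ind$avg_markov_blanket, ind$avg_neighborhood)
  }
  empty <- bn_dag(stats::setNames(lapply(1:8, function(i) character(0)),
                                  LETTERS[1:8]))
  ind0 <- graph_indicators(empty)
  expect_equal(ind0$avg_markov_blanket, 0)
  expect_equal(ind0$avg_branching, 0)
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(0.875, 2), 0.88)
  expect_equal(round_half_up(1.375, 2), 1.38)
  expect_equal(round_half_up(-0.875, 2), -0.88)
})

test_that("d-separation matches the textbook cases", {
  chain <- bn_dag("[A][B|A][C|B]")
  expect_true(d_separated(chain, "A", "C", "B"))
  expect_false(d_separated(chain, "A", "C"))
  g <- gi_bic_dag()
  # conditioning on the readmission parents blocks every path to metastasis
  expect_true(d_separated(g, "HRA", "MTX", c("RADIO", "NUTR")))
  # collider at BTcP: marginally independent, dependent given the collider
  expect_true(d_separated(g, "MTX", "BMI"))
  expect_false(d_separated(g, "MTX", "BMI", "BTcP"))
  expect_error(d_separated(g, "MTX", "MTX"), "must differ")
  expect_error(d_separated(g, "MTX", "BMI", "MTX"), "must not be in")
})

test_that("d-separation implies numeric conditional independence", {
  # P(x | y, z) == P(x | z) under any parameterization of the structure
  set.seed(43)
  for (i in 1:10) {
    g <- random_dag(LETTERS[1:5], p = 0.4)
    bn <- random_bn(g)
    pairs <- utils::combn(g$nodes, 2)
    for (j in seq_len(ncol(pairs))) {
      x <- pairs[1, j]; y <- pairs[2, j]
      rest <- setdiff(g$nodes, c(x, y))
      z <- if (length(rest)) sample(rest, sample(0:length(rest), 1)) else character(0)
      if (!d_separated(g, x, y, z)) next
      ev_z <- stats::setNames(lapply(z, function(v) bn$levels[[v]][1]), z)
      ev_yz <- c(ev_z, stats::setNames(list(bn$levels[[y]][1]), y))
      p_z <- try(eliminate_query(bn, x, ev_z)$posterior, silent = TRUE)
      p_yz <- try(eliminate_query(bn, x, ev_yz)$posterior, silent = TRUE)
      if (inherits(p_z, "try-error") || inherits(p_yz, "try-error")) next
      expect_equal(p_yz, p_z, tolerance = 1e-10)
    }
  }
})

test_that("constraint sets are validated and checked against structures", {
  g <- gi_bic_dag()
  k <- gi_constraints()
  expect_true(validate_constraints(g, k)$ok)
  empty <- bn_dag(stats::setNames(lapply(g$nodes, function(v) character(0)),
                                  g$nodes))
  chk <- validate_constraints(empty, bn_constraints(whitelist = rbind(c("ALB", "NUTR"))))
  expect_false(chk$ok)
  expect_equal(nrow(chk$missing_whitelist), 1L)
  bad <- bn_dag(list(MTX = "NUTR"), nodes = g$nodes)
  expect_false(validate_constraints(bad, k)$ok)
  expect_error(bn_constraints(whitelist = rbind(c("A", "B")),
                              blacklist = rbind(c("A", "B"))), "both")
  expect_error(bn_constraints(whitelist = rbind(c("A", "B"), c("B", "A"))),
               "cyclic")
})

test_that("constraint CSV and DOT files round-trip", {
  k <- gi_constraints()
  path <- withr::local_tempfile(fileext = ".csv")
  write_constraints(k, path)
  k2 <- read_constraints(path)
  expect_identical(k$whitelist, k2$whitelist)
  expect_identical(k$blacklist, k2$blacklist)

  g <- gi_bic_dag()
  dotf <- withr::local_tempfile(fileext = ".dot")
  write_dot(g, dotf, tiers = data.frame(from = "NUTR", to = "HRA", tier = "**"))
  txt <- readLines(dotf)
  expect_true(any(grepl("\"NUTR\" -> \"HRA\" \\[label=\"\\*\\*\"\\]", txt)))
  g2 <- read_dot(dotf)
  expect_setequal(arc_keys_test(g2), arc_keys_test(g))
  expect_setequal(g2$nodes, g$nodes)
  # an empty graph still lists all isolated nodes
  empty <- bn_dag(stats::setNames(lapply(g$nodes, function(v) character(0)),
                                  g$nodes))
  txt2 <- write_dot(empty)
  expect_setequal(read_dot(strsplit(txt2, "\n")[[1]])$nodes, g$nodes)
  expect_error(write_dot(g, tiers = data.frame(from = "HRA", to = "NUTR",
                                               tier = "*")), "not in graph")
})
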