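test_that("independent variables yield the empty graph", {
  set.seed(61)
  d <- independent_binaries(2000, 2)
  hc <- hill_climb(d)
  expect_equal(narcs(hc$dag), 0L)
  # direct score comparison of the three possible 2-node graphs agrees
  g0 <- bn_dag(list(A = character(0), B = character(0)))
  gab <- bn_dag(list(A = character(0), B = "A"))
  gba <- bn_dag(list(B = character(0), A = "B"), nodes = c("A", "B"))
  scores <- vapply(list(g0, gab, gba),
                   function(g) network_score(d, g)$score, numeric(1))
  expect_equal(which.max(scores), 1L)
})

test_that("perfect correlation yields one arc oriented by the tie-break", {
  x <- factor(rep(c("p", "q"), 50))
  d <- data.frame(A = x, B = x)
  hc <- hill_climb(d)
  expect_equal(unname(arcs(hc$dag)[1, ]), c("A", "B"))
  expect_equal(narcs(hc$dag), 1L)
  # both orientations score identically; lexicographic order decided
  expect_equal(network_score(d, bn_dag(list(A = character(0), B = "A")))$score,
               network_score(d, bn_dag(list(B = character(0), A = "B"),
                                       nodes = c("A", "B")))$score,
               tolerance = 1e-9)
})

test_that("whitelist arcs are forced even on independent data", {
  set.seed(62)
  d <- independent_binaries(500, 3)
  names(d) <- c("ALB", "NUTR", "HRA")
  k <- bn_constraints(whitelist = rbind(c("ALB", "NUTR")))
  hc <- hill_climb(d, constraints = k)
  expect_true("ALB" %in% bn_parents(hc$dag, "NUTR"))
  expect_true(validate_constraints(hc$dag, k)$ok)
})

test_that("the search trace is score-monotone and constraint-compliant", {
  d <- sample_cohort(gi_reference_network(), 3000, seed = 63)
  k <- gi_constraints()
  hc <- hill_climb(d, constraints = k)
  expect_true(validate_constraints(hc$dag, k)$ok)
  expect_true(all(hc$trace$delta > 0))
  expect_true(all(diff(hc$trace$score) > 0))
  expect_equal(hc$steps, nrow(hc$trace))
  # the reported final score matches an independent rescoring
  expect_equal(hc$trace$score[hc$steps],
               network_score(d, hc$dag)$score, tolerance = 1e-9)
})

test_that("restarts require a seed and constraint errors precede search", {
  d <- independent_binaries(50, 3)
  expect_error(hill_climb(d, restarts = 2), "seed")
  k <- bn_constraints(whitelist = rbind(c("A", "Z")))
  expect_error(hill_climb(d, constraints = k), "unknown variable")
})

test_that("exhaustive search enumerates and honors constraints", {
  set.seed(64)
  d <- independent_binaries(100, 3)
  all_arcs <- expand.grid(from = names(d), to = names(d),
                          stringsAsFactors = FALSE)
  all_arcs <- all_arcs[all_arcs$from != all_arcs$to, ]
  ex <- exhaustive_search(d, bn_constraints(blacklist = all_arcs))
  expect_equal(narcs(ex$dag), 0L)
  expect_equal(exhaustive_search(d)$n_dags, 25L)  # 25 DAGs on 3 nodes
  expect_error(exhaustive_search(independent_binaries(20, 6)), "5 variables")
})

test_that("exhaustive optimum on chain data is Markov-equivalent to the chain", {
  bn <- toy_chain(0.9)
  d <- sample_cohort(bn, 5000, seed = 65)
  ex <- exhaustive_search(d)
  # the chain's equivalence class: A-B and B-C adjacent, A-C not, no v-structure at B
  a <- amat(ex$dag)
  und <- a + t(a)
  expect_equal(und["A", "B"], 1L)
  expect_equal(und["B", "C"], 1L)
  expect_equal(und["A", "C"], 0L)
  expect_false(all(c(a["A", "B"], a["C", "B"]) == 1L))  # no collider at B
})

test_that("hill climbing with restarts attains the exhaustive optimum", {
  set.seed(66)
  for (i in 1:10) {
    d <- independent_binaries(150, 4)
    d$B <- factor(ifelse(stats::runif(150) < 0.75, as.character(d$A),
                         as.character(d$B)), levels = c("a", "b"))
    d$D <- factor(ifelse(stats::runif(150) < 0.6, as.character(d$C),
                         as.character(d$D)), levels = c("a", "b"))
    ex <- exhaustive_search(d)
    hc <- hill_climb(d, restarts = 20, seed = i)
    expect_equal(hc$score$score, ex$score$score, tolerance = 1e-9)
  }
})

test_that("structure recovery from simulation at scale", {
  d <- sample_cohort(gi_reference_network(), 10000, seed = 67)
  hc <- hill_climb(d, constraints = gi_constraints())
  got <- arcs(hc$dag)
  want <- arcs(gi_bic_dag())
  expect_identical(got, want)
})
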