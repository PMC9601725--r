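test_that("posteriors match hand-computed values on the two-node network", {
  bn <- toy_ab()
  q <- eliminate_query(bn, "B")
  # P(B=1) = 0.3 * 0.9 + 0.7 * 0.2 = 0.41
  expect_equal(q$posterior[q$level == "1"], 0.41, tolerance = 1e-12)
  qa <- eliminate_query(bn, "A", c(B = "1"))
  expect_equal(qa$posterior[qa$level == "1"], 0.27 / 0.41, tolerance = 1e-12)
  # fixing every non-target variable reproduces the CPT row
  qb <- eliminate_query(bn, "B", c(A = "1"))
  expect_equal(qb$posterior, as.numeric(coef(bn)$B[, "1"]), tolerance = 1e-12)
})

test_that("query results normalize and report shifts against the marginal", {
  bn <- gi_reference_network()
  q <- eliminate_query(bn, "HRA", c(NUTR = "Yes", RADIO = "No"))
  expect_equal(sum(q$posterior), 1, tolerance = 1e-10)
  expect_equal(sum(q$marginal), 1, tolerance = 1e-10)
  expect_equal(sum(q$shift_pp), 0, tolerance = 1e-8)
  expect_equal(q$shift_pp, 100 * (q$posterior - q$marginal), tolerance = 1e-10)
})

test_that("impossible or malformed evidence is rejected", {
  bn <- toy_ab()
  bn0 <- make_bn(bn$dag, list(
    A = array(c(1, 0), 2, dimnames = list(A = c("0", "1"))),
    B = coef(bn)$B))
  expect_error(eliminate_query(bn0, "B", c(A = "1")), "probability zero")
  expect_error(eliminate_query(bn, "B", c(B = "1")), "target")
  expect_error(eliminate_query(bn, "B", c(Z = "1")), "unknown evidence")
  expect_error(eliminate_query(bn, "B", c(A = "9")), "not a level")
  expect_error(eliminate_query(bn, "Z"), "unknown target")
})

test_that("the enumerated joint is a distribution and factorizes when independent", {
  bn <- gi_reference_network()
  j <- enumerate_joint(bn)
  expect_equal(nrow(j), 576L)
  expect_equal(sum(j$prob), 1, tolerance = 1e-12)
  ind <- make_bn(bn_dag(list(A = character(0), B = character(0))), list(
    A = array(c(0.3, 0.7), 2, dimnames = list(A = c("0", "1"))),
    B = array(c(0.6, 0.4), 2, dimnames = list(B = c("0", "1")))))
  ji <- enumerate_joint(ind)
  expect_equal(ji$prob, c(0.18, 0.42, 0.12, 0.28), tolerance = 1e-12)
})

test_that("variable elimination equals the renormalized enumeration slice", {
  set.seed(71)
  bn <- gi_reference_network()
  j <- enumerate_joint(bn)
  vars <- names(bn$levels)
  for (i in 1:25) {
    target <- sample(vars, 1)
    nev <- sample(0:3, 1)
    evv <- sample(setdiff(vars, target), nev)
    ev <- stats::setNames(lapply(evv, function(v) sample(bn$levels[[v]], 1)), evv)
    q <- eliminate_query(bn, target, ev)
    sel <- rep(TRUE, nrow(j))
    for (v in names(ev)) sel <- sel & j[[v]] == ev[[v]]
    oracle <- tapply(j$prob[sel], j[[target]][sel], sum)
    oracle <- as.numeric(oracle / sum(oracle))
    expect_equal(q$posterior, oracle, tolerance = 1e-10)
  }
})

test_that("chain rule holds through the joint: P(a|e) P(e) = P(a, e)", {
  set.seed(72)
  bn <- random_bn(random_dag(LETTERS[1:5], p = 0.5))
  j <- enumerate_joint(bn)
  for (i in 1:10) {
    target <- sample(names(bn$levels), 1)
    evv <- sample(setdiff(names(bn$levels), target), 2)
    ev <- stats::setNames(lapply(evv, function(v) sample(bn$levels[[v]], 1)), evv)
    a <- sample(bn$levels[[target]], 1)
    sel_e <- rep(TRUE, nrow(j))
    for (v in names(ev)) sel_e <- sel_e & j[[v]] == ev[[v]]
    p_e <- sum(j$prob[sel_e])
    p_ae <- sum(j$prob[sel_e & j[[target]] == a])
    q <- eliminate_query(bn, target, ev)
    expect_equal(q$posterior[q$level == a] * p_e, p_ae, tolerance = 1e-10)
  }
})

test_that("posterior shifts behave like differences of posteriors", {
  bn <- toy_ab()
  s <- posterior_shift(bn, "B", c(A = "1"), c(A = "0"))
  expect_equal(unname(s["1"]), 70, tolerance = 1e-10)  # 0.9 - 0.2
  expect_equal(sum(s), 0, tolerance = 1e-10)
  same <- posterior_shift(bn, "B", c(A = "1"), c(A = "1"))
  expect_equal(unname(same), c(0, 0), tolerance = 1e-12)
})
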