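test_that("CPT estimation follows the smoothing formula", {
  d <- data.frame(V = factor(rep(c("yes", "no"), c(7, 3)), levels = c("yes", "no")))
  g <- bn_dag(list(V = character(0)))
  expect_equal(as.numeric(fit_cpts(d, g, alpha = 0)$V["yes"]), 0.7)
  expect_equal(as.numeric(fit_cpts(d, g, alpha = 1)$V["yes"]), 8 / 12)
  # unseen parent configuration falls back to uniform under MLE
  d2 <- data.frame(P = factor(rep("a", 6), levels = c("a", "b")),
                   C = factor(rep(c("x", "y"), 3), levels = c("x", "y")))
  cpt <- fit_cpts(d2, bn_dag(list(P = character(0), C = "P")), alpha = 0)$C
  expect_equal(as.numeric(cpt[, "b"]), c(0.5, 0.5))
  expect_error(fit_cpts(d2, bn_dag(list(Z = character(0))), alpha = 0), "absent")
})

test_that("fitted CPT rows are simplexes", {
  d <- sample_cohort(gi_reference_network(), 400, seed = 17)
  for (alpha in c(0, 1)) {
    cpts <- fit_cpts(d, gi_bic_dag(), alpha = alpha)
    for (v in names(cpts)) {
      cpt <- cpts[[v]]
      sums <- if (length(dim(cpt)) == 1) sum(cpt) else
        apply(cpt, seq_along(dim(cpt))[-1], sum)
      expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
      expect_true(all(cpt >= 0 & cpt <= 1))
    }
  }
})

test_that("free-parameter counting follows (levels-1) x parent configurations", {
  nlev <- vapply(gi_levels(), length, integer(1))
  g <- gi_bic_dag()
  # the readmission family alone contributes (3 - 1) * 2 * 2 = 8
  hra_family <- bn_dag(list(NUTR = character(0), RADIO = character(0),
                            HRA = c("NUTR", "RADIO")))
  roots_only <- bn_dag(list(NUTR = character(0), RADIO = character(0)))
  expect_equal(parameter_count(hra_family, nlev[c("NUTR", "RADIO", "HRA")]) -
                 parameter_count(roots_only, nlev[c("NUTR", "RADIO")]), 8)
  expect_equal(parameter_count(g, nlev), 23)
  expect_equal(parameter_count(bn_dag(list(A = character(0))), c(A = 2)), 1)
})

test_that("log-likelihood sums per-record log probabilities", {
  bn <- make_bn(bn_dag(list(A = character(0))),
                list(A = array(c(0.5, 0.5), 2, dimnames = list(A = c("h", "t")))))
  d <- data.frame(A = factor(rep(c("h", "t"), 5), levels = c("h", "t")))
  expect_equal(log_likelihood(bn, d), 10 * log(0.5), tolerance = 1e-12)
  expect_equal(log_likelihood(bn, d[0, , drop = FALSE]), 0)
  bn0 <- make_bn(bn_dag(list(A = character(0))),
                 list(A = array(c(1, 0), 2, dimnames = list(A = c("h", "t")))))
  expect_warning(ll <- log_likelihood(bn0, d), "record 2")
  expect_equal(ll, -Inf)
})

test_that("the MLE parameterization dominates perturbed ones", {
  set.seed(51)
  d <- sample_cohort(gi_reference_network(), 300, seed = 19)
  g <- gi_bic_dag()
  cpts <- fit_cpts(d, g, alpha = 0)
  ll_mle <- log_likelihood(cpts, d)
  for (i in 1:10) {
    pert <- lapply(cpts, function(cpt) {
      noise <- array(stats::rgamma(length(cpt), 5), dim = dim(cpt))
      k <- cpt * noise + 1e-9
      nd <- length(dim(k))
      tot <- if (nd == 1) sum(k) else apply(k, 2:nd, sum)
      out <- if (nd == 1) k / tot else sweep(k, 2:nd, tot, "/")
      array(out, dim = dim(cpt), dimnames = dimnames(cpt))
    })
    expect_lte(suppressWarnings(log_likelihood(pert, d)), ll_mle + 1e-9)
  }
})

test_that("score report carries both conventions consistently", {
  d <- sample_cohort(gi_reference_network(), 250, seed = 23)
  sc <- network_score(d, gi_bic_dag())
  expect_equal(sc$bic, -2 * sc$score, tolerance = 1e-9)
  expect_equal(sc$penalty, log(nrow(d)) / 2, tolerance = 1e-12)
  expect_equal(sc$aic, sc$loglik - sc$k, tolerance = 1e-12)
  expect_equal(sc$loglik, sum(sc$families$loglik), tolerance = 1e-9)
  expect_equal(sc$k, sum(sc$families$k))
  # matches an independent full-likelihood computation at the MLE
  cpts <- fit_cpts(d, gi_bic_dag(), alpha = 0)
  expect_equal(sc$loglik, log_likelihood(cpts, d), tolerance = 1e-8)
  expect_equal(network_score(d, gi_bic_dag(), criterion = "aic")$penalty, 1)
})

test_that("incremental move deltas equal full rescoring", {
  set.seed(53)
  d <- sample_cohort(gi_reference_network(), 500, seed = 29)
  g <- gi_bic_dag()
  sc_g <- network_score(d, g)
  cases <- list(c("add", "BMI", "HRA"), c("delete", "ALB", "NUTR"),
                c("reverse", "CANCER", "MTX"))
  for (mv in cases) {
    g2 <- switch(mv[1],
                 add = bn_dag(modifyList(g$parents,
                        list(HRA = c(g$parents$HRA, "BMI"))), nodes = g$nodes),
                 delete = bn_dag(modifyList(g$parents, list(NUTR = character(0))),
                                 nodes = g$nodes),
                 reverse = bn_dag(modifyList(g$parents,
                        list(MTX = character(0), CANCER = "MTX")), nodes = g$nodes))
    full_delta <- network_score(d, g2)$score - sc_g$score
    ctx <- readmitbn:::search_context(as.data.frame(d)[g$nodes], g$nodes,
                                      bn_constraints(), "bic")
    inc_delta <- readmitbn:::move_delta(g, mv, ctx)
    expect_equal(inc_delta, full_delta, tolerance = 1e-9)
  }
})

test_that("adding an arc never decreases fit or parameter count", {
  set.seed(57)
  for (i in 1:5) {
    d <- independent_binaries(120, 4)
    g0 <- random_dag(names(d), p = 0.3)
    # pick an addable arc
    added <- FALSE
    for (from in names(d)) for (to in setdiff(names(d), from)) {
      if (added) next
      if (from %in% bn_parents(g0, to) || to %in% bn_parents(g0, from)) next
      p2 <- g0$parents
      p2[[to]] <- c(p2[[to]], from)
      g1 <- tryCatch(bn_dag(p2, nodes = g0$nodes), error = function(e) NULL)
      if (is.null(g1)) next
      added <- TRUE
      s0 <- network_score(d, g0); s1 <- network_score(d, g1)
      expect_gte(s1$loglik, s0$loglik - 1e-9)
      expect_gte(s1$k, s0$k)
    }
  }
})
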