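test_that("Mk likelihood of trivial configurations is exact", {
  tr <- parse_newick("(A:1,B:1);")
  states <- setNames(factor(c("a", "a"), c("a", "b")), c("A", "B"))
  Q0 <- matrix(0, 2, 2)
  expect_equal(
    mk_loglik(tr, states, Q0, root_prior = "uniform", states = c("a", "b")),
    log(0.5)
  )
})

test_that("two-state cherry likelihood matches the closed-form exponential", {
  # P(same state after time t) = 1/2 + 1/2 exp(-2qt) for symmetric q
  q <- 0.3
  t1 <- 1.2
  t2 <- 0.7
  Q <- matrix(c(-q, q, q, -q), 2, 2)
  tr <- parse_newick(sprintf("(A:%g,B:%g);", t1, t2))
  p_same <- function(t) 0.5 + 0.5 * exp(-2 * q * t)
  p_diff <- function(t) 0.5 - 0.5 * exp(-2 * q * t)
  # both tips in state a: sum over the root state
  lik <- 0.5 * p_same(t1) * p_same(t2) + 0.5 * p_diff(t1) * p_diff(t2)
  states <- setNames(factor(c("a", "a"), c("a", "b")), c("A", "B"))
  expect_equal(
    mk_loglik(tr, states, Q, root_prior = "uniform", states = c("a", "b")),
    log(lik),
    tolerance = 1e-12
  )
})

test_that("likelihood and marginals match brute-force enumeration (small trees)", {
  set.seed(101)
  for (i in 1:25) {
    ntip <- sample(3:6, 1)
    k <- sample(2:3, 1)
    tree <- ape::rtree(ntip)
    Q <- random_Q(k)
    st_int <- sample(seq_len(k), ntip, replace = TRUE)
    states <- setNames(factor(letters[st_int], letters[seq_len(k)]), tree$tip.label)
    bf <- brute_force_mk(tree, st_int, Q, rep(1 / k, k))
    ll <- mk_loglik(tree, states, Q, root_prior = "uniform", states = letters[seq_len(k)])
    asr <- marginal_asr(tree, states, Q, root_prior = "uniform", states = letters[seq_len(k)])
    expect_equal(ll, bf$loglik, tolerance = 1e-8)
    expect_lt(max(abs(asr$prob - bf$marginal)), 1e-8)
    expect_equal(rowSums(asr$prob), rep(1, nrow(asr$prob)), tolerance = 1e-9)
  }
})

test_that("FitzJohn-weighted marginals also match enumeration with its prior", {
  set.seed(55)
  for (i in 1:5) {
    tree <- ape::rtree(5)
    k <- 3
    Q <- random_Q(k)
    st_int <- sample(seq_len(k), 5, replace = TRUE)
    states <- setNames(factor(letters[st_int], letters[1:k]), tree$tip.label)
    asr <- marginal_asr(tree, states, Q, root_prior = "fitzjohn", states = letters[1:k])
    # oracle: root-state weights proportional to the root partial likelihoods,
    # found by running the uniform-prior enumeration and reusing its root row
    bf_u <- brute_force_mk(tree, st_int, Q, rep(1, k))
    pi_fj <- bf_u$marginal[ape::Ntip(tree) + 1, ] # proportional to D_root
    bf <- brute_force_mk(tree, st_int, Q, pi_fj)
    expect_lt(max(abs(asr$prob - bf$marginal)), 1e-8)
  }
})

test_that("likelihood is invariant to child order and state relabeling", {
  set.seed(5)
  tree <- ape::rtree(8)
  k <- 3
  Q <- random_Q(k)
  st_int <- sample(1:k, 8, replace = TRUE)
  states <- setNames(factor(letters[st_int], letters[1:k]), tree$tip.label)
  ll <- mk_loglik(tree, states, Q, root_prior = "uniform", states = letters[1:k])
  rot <- ape::rotate(tree, node = ape::Ntip(tree) + 1)
  expect_equal(
    mk_loglik(rot, states, Q, root_prior = "uniform", states = letters[1:k]),
    ll,
    tolerance = 1e-9
  )
  perm <- c(3, 1, 2)
  Qp <- Q[perm, perm]
  states_p <- setNames(
    factor(letters[match(st_int, perm)], letters[1:k]), tree$tip.label
  )
  expect_equal(
    mk_loglik(tree, states_p, Qp, root_prior = "uniform", states = letters[1:k]),
    ll,
    tolerance = 1e-9
  )
})

test_that("no-change limit concentrates marginals on the observed state", {
  tree <- ape::rtree(6)
  states <- setNames(factor(rep("a", 6), c("a", "b")), tree$tip.label)
  Qtiny <- matrix(c(-1e-10, 1e-10, 1e-10, -1e-10), 2, 2)
  asr <- marginal_asr(tree, states, Qtiny, root_prior = "uniform", states = c("a", "b"))
  expect_true(all(asr$prob[, "a"] > 1 - 1e-6))
})

test_that("polytomies are handled natively by the pruning pass", {
  tr <- parse_newick("(A:1,B:1,C:1,D:1);")
  k <- 2
  Q <- matrix(c(-0.4, 0.4, 0.2, -0.2), 2, 2, byrow = TRUE)
  st_int <- c(1, 1, 2, 2)
  states <- setNames(factor(letters[st_int], letters[1:2]), tr$tip.label)
  bf <- brute_force_mk(tr, st_int, Q, c(0.5, 0.5))
  expect_equal(
    mk_loglik(tr, states, Q, root_prior = "uniform", states = c("a", "b")),
    bf$loglik,
    tolerance = 1e-9
  )
})

test_that("ML rate recovery lands near the generating rate", {
  set.seed(9)
  tree <- phytools::pbtree(n = 200, scale = 10, quiet = TRUE)
  Q <- matrix(c(-0.1, 0.1, 0.1, -0.1), 2, 2)
  dimnames(Q) <- list(c("1", "2"), c("1", "2"))
  x <- phytools::sim.Mk(tree, Q)
  states <- setNames(factor(as.character(x), c("1", "2")), tree$tip.label)
  fit <- fit_mk(tree, states, scheme = "SYM", states = c("1", "2"))
  expect_true(fit$converged)
  expect_gt(fit$rates[1], 0.05)
  expect_lt(fit$rates[1], 0.2)
  # AIC bookkeeping identity
  expect_equal(fit$AIC, 2 * fit$n_free - 2 * fit$loglik, tolerance = 1e-9)
  # independent implementation agrees on the ML log-likelihood
  ref <- phytools::fitMk(tree, x, model = "SYM", pi = "fitzjohn")
  expect_equal(fit$loglik, ref$logLik, tolerance = 0.01)
})

test_that("degenerate single-state data drives rates to the lower bound", {
  tree <- ape::rcoal(10)
  states <- setNames(factor(rep("a", 10), c("a", "b")), tree$tip.label)
  expect_warning(
    fit <- fit_mk(tree, states, scheme = "SYM", states = c("a", "b")),
    "one observed state"
  )
  expect_lt(fit$rates[1], 1e-6)
})

test_that("ARD never fits worse than nested SYM", {
  set.seed(21)
  tree <- phytools::pbtree(n = 80, scale = 10, quiet = TRUE)
  Q <- matrix(c(-0.15, 0.15, 0.05, -0.05), 2, 2, byrow = TRUE)
  dimnames(Q) <- list(c("1", "2"), c("1", "2"))
  x <- phytools::sim.Mk(tree, Q)
  states <- setNames(factor(as.character(x), c("1", "2")), tree$tip.label)
  sel <- fit_models_and_select(tree, states,
    schemes = c("SYM", "ARD"),
    states = c("1", "2")
  )
  tab <- sel$aic_table
  expect_gte(
    tab$loglik[tab$scheme == "ARD"],
    tab$loglik[tab$scheme == "SYM"] - 1e-6
  )
  expect_equal(tab$AIC, sort(tab$AIC))
  # single scheme: returned trivially as best
  one <- fit_models_and_select(tree, states, schemes = "SYM", states = c("1", "2"))
  expect_equal(one$best$scheme, "SYM")
})

test_that("AIC selection prefers the generating scheme on SYM data", {
  set.seed(31)
  wins <- 0
  for (i in 1:8) {
    tree <- phytools::pbtree(n = 120, scale = 10, quiet = TRUE)
    Q <- matrix(c(-0.12, 0.12, 0.12, -0.12), 2, 2)
    dimnames(Q) <- list(c("1", "2"), c("1", "2"))
  x <- phytools::sim.Mk(tree, Q)
    states <- setNames(factor(as.character(x), c("1", "2")), tree$tip.label)
    sel <- suppressWarnings(fit_models_and_select(
      tree, states,
      schemes = c("SYM", "ARD"), states = c("1", "2")
    ))
    if (sel$best$scheme == "SYM") wins <- wins + 1
  }
  expect_gte(wins, 5) # SYM should win in most replicates
})

test_that("rate recovery error shrinks with tip count", {
  set.seed(77)
  rel_err <- function(n, reps) {
    sapply(seq_len(reps), function(i) {
      tree <- phytools::pbtree(n = n, scale = 10, quiet = TRUE)
      Q <- matrix(c(-0.15, 0.15, 0.15, -0.15), 2, 2)
      dimnames(Q) <- list(c("1", "2"), c("1", "2"))
  x <- phytools::sim.Mk(tree, Q)
      states <- setNames(factor(as.character(x), c("1", "2")), tree$tip.label)
      fit <- suppressWarnings(
        fit_mk(tree, states, scheme = "SYM", states = c("1", "2"), n_starts = 1)
      )
      abs(fit$rates[1] - 0.15) / 0.15
    })
  }
  expect_lt(median(rel_err(200, 8)), median(rel_err(50, 8)) + 0.05)
})

test_that("constrained schemes force masked rates to zero", {
  sch <- make_rate_scheme(3, "CONSTRAINED",
    mask = rbind(c(1, 3), c(3, 1)),
    states = letters[1:3]
  )
  expect_equal(sch$n_free, 4)
  Q <- build_rate_matrix(c(0.1, 0.2, 0.3, 0.4), sch)
  expect_equal(Q["a", "c"], 0)
  expect_equal(Q["c", "a"], 0)
  expect_equal(rowSums(Q), rep(0, 3), ignore_attr = TRUE)
  # SYM/ARD free-parameter counts
  expect_equal(make_rate_scheme(4, "SYM")$n_free, 6)
  expect_equal(make_rate_scheme(4, "ARD")$n_free, 12)
})
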