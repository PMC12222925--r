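test_that("birth-death trees have the requested size and are reproducible", {
  tr <- simulate_bd_tree(50, lambda = 0.3, mu = 0.1, seed = 4)
  expect_equal(ape::Ntip(tr), 50)
  d <- ape::node.depth.edgelength(tr)[1:50]
  expect_lt(max(d) - min(d), 1e-8) # ultrametric to numerical precision
  tr2 <- simulate_bd_tree(50, lambda = 0.3, mu = 0.1, seed = 4)
  expect_identical(write_newick(tr), write_newick(tr2))
  expect_error(simulate_bd_tree(2, 1, 0), "n >= 3")
})

test_that("pure-birth root height matches the Yule expectation", {
  n <- 15
  lam <- 1
  h <- sapply(1:200, function(s) {
    max(ape::node.depth.edgelength(simulate_bd_tree(n, lam, 0, seed = s)))
  })
  expected <- sum(1 / (lam * (2:n)))
  expect_lt(abs(mean(h) - expected) / expected, 0.2)
})

test_that("coupled histories honor their structural constraints", {
  tree <- simulate_bd_tree(80, 0.2, 0.05, seed = 6)
  tree$edge.length <- tree$edge.length * 25 / max(ape::node.depth.edgelength(tree))

  # ENV_FIRST with no baseline shift rate: a pollinator shift implies an
  # earlier environment shift on the same root path, in every lineage
  spec <- scenario_spec("ENV_FIRST", q_base = 0, seed = 6)
  h <- simulate_joint_history(tree, spec, seed = 8)
  tr_ord <- true_shift_ordering(tree, h)
  both <- tr_ord[!is.na(tr_ord$t_poll_shift), ]
  expect_gt(nrow(both), 0)
  expect_true(all(both$ordering == "env_first"))
  expect_true(all(both$t_env_shift < both$t_poll_shift))

  # all rates zero: everything stays at the (lowland, bee) root state
  null_spec <- scenario_spec("ENV_FIRST",
    q_env_up = 0, q_env_down = 0,
    q_base = 0, q_boost = 0, seed = 1
  )
  h0 <- simulate_joint_history(tree, null_spec, seed = 1)
  expect_true(all(h0$env_states == "lowland"))
  expect_true(all(h0$poll_states == "bee"))
  expect_equal(nrow(h0$events), 0)
})

test_that("event counts follow the Poisson expectation for a state-free rate", {
  # with equal up/down rates the environment flips as a Poisson process with
  # rate q over the whole tree length, regardless of state
  tree <- simulate_bd_tree(30, 0.4, 0, seed = 9)
  q <- 0.08
  L <- sum(tree$edge.length)
  spec <- scenario_spec("INDEPENDENT",
    q_env_up = q, q_env_down = q, q_base = 0,
    seed = 1
  )
  counts <- sapply(1:500, function(s) {
    nrow(simulate_joint_history(tree, spec, seed = s)$events)
  })
  expected <- q * L
  se <- sqrt(expected / 500)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("four-state expansion is consistent and invertible at 1000 m", {
  set.seed(3)
  n <- 1000
  env <- setNames(
    factor(sample(c("lowland", "montane"), n, TRUE), c("lowland", "montane")),
    paste0("t", 1:n)
  )
  poll <- setNames(
    factor(sample(c("bee", "shifted"), n, TRUE, prob = c(0.3, 0.7)), c("bee", "shifted")),
    paste0("t", 1:n)
  )
  e4 <- expand_to_four_states(env, poll, weights = c(0.5, 0.3, 0.2), seed = 2)
  # binarizing at the 1000 m boundary recovers the inputs exactly
  expect_equal(
    as.character(env),
    ifelse(e4$elev_bin %in% c("E3", "E4"), "montane", "lowland"),
    ignore_attr = TRUE
  )
  expect_equal(
    as.character(poll),
    ifelse(e4$syndrome == "bee", "bee", "shifted"),
    ignore_attr = TRUE
  )
  # degenerate weights pin the shifted syndrome
  e1 <- expand_to_four_states(env, poll, weights = c(0, 1, 0), seed = 2)
  expect_true(all(e1$syndrome[poll == "shifted"] == "nectar_vertebrate"))
  # syndrome frequencies within 3 SE of the weights
  shifted_syn <- e4$syndrome[poll == "shifted"]
  p_hat <- mean(shifted_syn == "generalist")
  n_sh <- length(shifted_syn)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.5 * 0.5 / n_sh))
})

test_that("occurrence clouds center on the species optima", {
  optima <- tibble::tibble(
    species = c("lo", "hi"), elevation_m = c(300, 1800), bio12_mm = c(2500, 1500),
    longitude = c(-70, -71), latitude = c(0, 1)
  )
  # zero noise: every record sits exactly at the optimum
  occ0 <- simulate_occurrences(optima,
    n_per_species = 5,
    sigma = c(elev = 0, temp = 0, precip = 0, coord = 0), seed = 1
  )
  expect_true(all(occ0$elevation_m[occ0$species == "lo"] == 300))
  expect_equal(
    unique(occ0$bio1_degC[occ0$species == "hi"]), 27 - 5.5 * 1.8,
    tolerance = 1e-12
  )
  # sample medians approach the optima (SE of a normal median)
  occ <- simulate_occurrences(optima, n_per_species = 200, seed = 2)
  med <- median(occ$elevation_m[occ$species == "hi"])
  se_med <- 1.2533 * 150 / sqrt(200)
  expect_lt(abs(med - 1800), 3 * se_med)
  # lapse coupling induces the strong negative elevation-temperature
  # correlation seen in real climate layers
  occ_wide <- simulate_occurrences(optima,
    n_per_species = 400,
    sigma = c(elev = 400, temp = 0.5, precip = 200, coord = 0.5), seed = 3
  )
  expect_lt(cor(occ_wide$elevation_m, occ_wide$bio1_degC), -0.8)
})

test_that("scenario datasets are conditioned on carrying an ordering signal", {
  ds <- simulate_scenario_dataset(scenario_spec("ENV_FIRST", n = 80, seed = 2),
    n_per_species = 3
  )
  nsh <- sum(ds$history$poll_states == "shifted")
  expect_gte(nsh, 3)
  expect_lte(nsh, 48)
  expect_equal(max(ape::node.depth.edgelength(ds$tree)), 25, tolerance = 1e-9)
  expect_equal(nrow(ds$occurrences), 3 * 80)
  expect_s3_class(ds$truth, "tbl_df")
})
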