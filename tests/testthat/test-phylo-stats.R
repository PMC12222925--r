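# species-level fixture on an arbitrary tree
stats_data <- function(tree, seed = 1) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  tibble::tibble(
    species = tree$tip.label,
    elevation_m = runif(n, 0, 2500),
    latitude = runif(n, 0, 30),
    bio12_mm = runif(n, 500, 3500)
  )
}

test_that("phylogenetic covariance has the shared-height structure", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tr)
  expect_equal(diag(C), c(A = 1, B = 1, C = 1))
  expect_equal(C["A", "B"], 0.5) # shared path fraction
  expect_equal(C["A", "C"], 0)
})

test_that("GLS on a star tree reproduces ordinary least squares exactly", {
  tr <- star_tree(40)
  d <- stats_data(tr)
  d$y <- 2 + 0.001 * d$elevation_m + 0.05 * d$latitude + rnorm(40)
  fit <- phylo_lm_fit(d, y ~ elevation_m + latitude, tr)
  ref <- summary(lm(y ~ elevation_m + latitude, d))$coefficients
  expect_equal(fit$coefficients$estimate, unname(ref[, 1]), tolerance = 1e-8)
  expect_equal(fit$coefficients$std_error, unname(ref[, 2]), tolerance = 1e-8)
  expect_equal(fit$coefficients$p_value, unname(ref[, 4]), tolerance = 1e-8)
})

test_that("GLS handles degenerate and scaled responses predictably", {
  tr <- ape::rcoal(25)
  d <- stats_data(tr)
  d$y <- 7
  fit <- suppressWarnings(phylo_lm_fit(d, y ~ elevation_m, tr))
  expect_equal(fit$coefficients$estimate[2], 0, tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate[1], 7, tolerance = 1e-10)
  # scaling y scales the coefficients exactly
  d$y <- rnorm(25)
  f1 <- phylo_lm_fit(d, y ~ elevation_m, tr)
  d$y <- 10 * d$y
  f2 <- phylo_lm_fit(d, y ~ elevation_m, tr)
  expect_equal(f2$coefficients$estimate, 10 * f1$coefficients$estimate)
  expect_error(
    phylo_lm_fit(dplyr::mutate(d, e2 = elevation_m), y ~ elevation_m + e2, tr),
    "collinear"
  )
  expect_error(
    phylo_lm_fit(dplyr::mutate(d, bio1_degC = 1:25), y ~ elevation_m + bio1_degC, tr),
    "collinear"
  )
})

test_that("GLS recovers a known slope under Brownian residuals", {
  set.seed(17)
  slopes <- sapply(1:10, function(i) {
    tr <- phytools::pbtree(n = 150, scale = 1, quiet = TRUE)
    d <- tibble::tibble(
      species = tr$tip.label,
      x = phytools::fastBM(tr)
    )
    d$y <- 1.5 * d$x + phytools::fastBM(tr, sig2 = 0.5)
    phylo_lm_fit(d, y ~ x, tr)$coefficients$estimate[2]
  })
  expect_gt(median(slopes), 1.2)
  expect_lt(median(slopes), 1.8)
})

test_that("the two-sample comparison matches the classic t-test on a star tree", {
  tr <- star_tree(30)
  set.seed(2)
  d <- tibble::tibble(
    species = tr$tip.label,
    y = c(rnorm(15, 0), rnorm(15, 1)),
    grp = rep(c("a", "b"), each = 15)
  )
  res <- phylo_two_sample(d, "y", "grp", tr)
  ref <- t.test(y ~ grp, d, var.equal = TRUE)
  expect_equal(res$mean_difference, unname(diff(ref$estimate)), tolerance = 1e-6)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
  # label swap negates the difference, p unchanged
  d2 <- dplyr::mutate(d, grp = ifelse(grp == "a", "z", "a"))
  res2 <- phylo_two_sample(d2, "y", "grp", tr)
  expect_equal(res2$mean_difference, -res$mean_difference, tolerance = 1e-10)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-10)
  expect_error(
    phylo_two_sample(dplyr::mutate(d, grp = "a"), "y", "grp", tr),
    "2 non-empty"
  )
})

test_that("simulation-based phylogenetic ANOVA reduces to classic ANOVA on a star tree", {
  tr <- star_tree(45)
  set.seed(8)
  d <- tibble::tibble(
    species = tr$tip.label,
    y = rnorm(45) + rep(c(0, 0.9, 0.2), each = 15),
    g = rep(c("a", "b", "c"), each = 15)
  )
  res <- phylo_anova(d, "y", "g", tr, nsim = 2000, seed = 3)
  classic <- anova(lm(y ~ g, d))
  expect_equal(res$F_statistic, classic$`F value`[1], tolerance = 1e-8)
  expect_lt(abs(res$p_phylo - classic$`Pr(>F)`[1]), 0.03)
  # deterministic under the seed
  res2 <- phylo_anova(d, "y", "g", tr, nsim = 2000, seed = 3)
  expect_equal(res$p_phylo, res2$p_phylo)
  expect_error(phylo_anova(dplyr::mutate(d, g = "a"), "y", "g", tr), ">= 2 groups")
})

test_that("phylogenetic logistic regression reduces to glm when s2 is pinned at zero", {
  tr <- ape::rcoal(40)
  d <- stats_data(tr, seed = 5)
  set.seed(105)
  d$y <- rbinom(40, 1, plogis(scale(d$elevation_m) * 1.5))
  fit0 <- phylo_logistic_fit(d, y ~ elevation_m, tr, s2_fixed = 0)
  ref <- summary(glm(y ~ elevation_m, binomial(), d))$coefficients
  expect_equal(fit0$coefficients$estimate, unname(ref[, 1]), tolerance = 1e-6)
  expect_equal(fit0$coefficients$p_value, unname(ref[, 4]), tolerance = 1e-6)
  expect_equal(fit0$s2, 0)
})

test_that("phylogenetic logistic regression approaches glm on a star tree", {
  tr <- star_tree(60)
  d <- stats_data(tr, seed = 6)
  set.seed(106)
  d$y <- rbinom(60, 1, plogis(as.numeric(scale(d$elevation_m)) * 1.2))
  fit <- phylo_logistic_fit(d, y ~ elevation_m, tr)
  ref <- glm(y ~ elevation_m, binomial(), d)
  expect_lt(
    abs(fit$coefficients$estimate[2] - coef(ref)[2]) /
      max(abs(coef(ref)[2]), 1), 0.05
  )
  expect_true(all(fit$mu > 0 & fit$mu < 1))
  # z-based p-values are consistent with the reported z scores
  expect_equal(
    fit$coefficients$p_value,
    2 * pnorm(-abs(fit$coefficients$statistic)),
    tolerance = 1e-9
  )
})

test_that("perfect separation is refused with the predictor named", {
  tr <- ape::rcoal(20)
  d <- stats_data(tr, seed = 7)
  d$y <- as.numeric(d$elevation_m > median(d$elevation_m))
  expect_error(
    phylo_logistic_fit(d, y ~ elevation_m, tr),
    "separation.*elevation_m"
  )
})

test_that("logistic effect recovery brackets the generating coefficient", {
  set.seed(19)
  betas <- sapply(1:8, function(i) {
    tr <- phytools::pbtree(n = 100, scale = 1, quiet = TRUE)
    z <- rnorm(100)
    d <- tibble::tibble(species = tr$tip.label, x = z)
    d$y <- rbinom(100, 1, plogis(2 * z))
    fit <- tryCatch(
      phylo_logistic_fit(d, y ~ x, tr),
      error = function(e) NULL
    )
    if (is.null(fit)) NA else fit$coefficients$estimate[2]
  })
  expect_gte(median(betas, na.rm = TRUE), 1)
  expect_lte(median(betas, na.rm = TRUE), 3)
})

test_that("backward stepwise reduction respects significance and hierarchy", {
  tr <- star_tree(80)
  set.seed(23)
  d <- tibble::tibble(
    species = tr$tip.label,
    x1 = rnorm(80), x2 = rnorm(80)
  )
  d$y <- 2 * d$x1 + 2 * d$x2 + rnorm(80, 0, 0.5)
  # all terms significant: model unchanged
  sw <- stepwise_reduce(d, y ~ x1 + x2, tr, model = "linear")
  expect_equal(nrow(sw$log), 0)
  expect_setequal(sw$fit$term_labels, c("x1", "x2"))

  # interaction signal only: main effects are retained by hierarchy
  d$y2 <- 3 * d$x1 * d$x2 + rnorm(80, 0, 0.5)
  sw2 <- stepwise_reduce(d, y2 ~ x1 + x2 + x1:x2, tr, model = "linear")
  expect_true("x1:x2" %in% sw2$fit$term_labels)
  expect_true(all(c("x1", "x2") %in% sw2$fit$term_labels))

  # pure noise terms are eliminated most of the time
  dropped <- sapply(1:10, function(i) {
    set.seed(100 + i)
    dd <- tibble::tibble(
      species = tr$tip.label,
      signal = rnorm(80), noise = rnorm(80)
    )
    dd$y <- 2 * dd$signal + rnorm(80, 0, 0.5)
    sw <- stepwise_reduce(dd, y ~ signal + noise, tr, model = "linear")
    !"noise" %in% sw$fit$term_labels
  })
  expect_gte(sum(dropped), 8)
})

test_that("occurrence resampling is seeded and tallies failures", {
  set.seed(31)
  tr <- phytools::pbtree(n = 40, scale = 1, quiet = TRUE)
  optima <- tibble::tibble(
    species = tr$tip.label,
    elevation_m = runif(40, 0, 2500), bio12_mm = 2000,
    longitude = runif(40, -75, -70), latitude = runif(40, -10, 10)
  )
  occ <- simulate_occurrences(optima, n_per_species = 8, seed = 1)
  y <- setNames(rbinom(40, 1, plogis(1.5 * as.numeric(scale(optima$elevation_m)))), tr$tip.label)
  r1 <- occurrence_resampling(occ, y, shifted ~ elevation_m, tr, n_iter = 5, seed = 9)
  r2 <- occurrence_resampling(occ, y, shifted ~ elevation_m, tr, n_iter = 5, seed = 9)
  expect_equal(r1$percent_significant, r2$percent_significant)
  expect_equal(nrow(r1$iterations), 5)
  expect_equal(r1$n_failed, sum(r1$iterations$failed))
  expect_error(
    occurrence_resampling(occ[occ$species != tr$tip.label[1], ], y,
      shifted ~ elevation_m, tr,
      n_iter = 2
    ),
    "without records"
  )
})
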