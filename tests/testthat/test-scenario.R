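syn4 <- function(x) factor(x, levels = c("bee", "generalist", "nectar_vertebrate", "foodbody_vertebrate"))

test_that("shifted clades are the maximal all-shifted monophyletic groups", {
  tr <- parse_newick("(A:1,B:1);")
  cl <- identify_shifted_clades(tr, setNames(syn4(c("bee", "generalist")), c("A", "B")))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_tips, 1)
  expect_equal(cl$tips[[1]], "B")

  tr2 <- parse_newick("((B1:1,B2:1):1,A:2);")
  cl2 <- identify_shifted_clades(
    tr2, setNames(syn4(c("nectar_vertebrate", "nectar_vertebrate", "bee")), c("B1", "B2", "A"))
  )
  expect_equal(nrow(cl2), 1)
  expect_equal(sort(cl2$tips[[1]]), c("B1", "B2"))
  expect_equal(cl2$mrca, ape::getMRCA(tr2, c("B1", "B2")))

  tr3 <- parse_newick("((B1:1,A:1):1,B2:2);")
  cl3 <- identify_shifted_clades(
    tr3, setNames(syn4(c("generalist", "bee", "generalist")), c("B1", "A", "B2"))
  )
  expect_equal(nrow(cl3), 2)
  expect_true(all(cl3$n_tips == 1))

  expect_warning(
    cl0 <- identify_shifted_clades(tr, setNames(syn4(c("bee", "bee")), c("A", "B"))),
    "no shifted"
  )
  expect_equal(nrow(cl0), 0)
})

test_that("shift paths walk rootward between the stated probability plateaus", {
  # chain: tip 1 -> node 6 (parent) -> node 5 (grandparent) -> root 4... use
  # a 3-tip caterpillar so node ids are explicit
  tr <- parse_newick("((S:1,A:1):1,B:2);")
  # nodes: tips S=1, A=2, B=3; root=4; (S,A) ancestor=5
  prob_poll <- rbind(
    c(0, 1), # S shifted
    c(1, 0), # A bee
    c(1, 0), # B bee
    c(1, 0), # root fully bee
    c(0.4, 0.6) # cherry node: shifted with p = 0.6
  )
  prob_env <- rbind(
    c(0, 1), c(0, 1), c(1, 0),
    c(0, 1), # root montane
    c(0, 1)
  )
  ages <- c(0, 0, 0, 2, 1)
  ap <- manual_asr(prob_poll, ages, c("bee", "shifted"))
  ae <- manual_asr(prob_env, ages, c("lowland", "montane"))
  syn <- setNames(syn4(c("generalist", "bee", "bee")), c("S", "A", "B"))
  cl <- identify_shifted_clades(tr, syn)
  path <- extract_shift_path(tr, cl[1, ], ap, ae, cutoff = 1000, tau_shift = 0.95)
  # tip (x=1), cherry node (x=0.6, y=1), root (x=0, y=1): 3 points, ends at root
  expect_equal(path$node, c(1, 5, 4))
  expect_equal(path$x, c(1, 0.6, 0))
  expect_equal(path$y, c(1, 1, 1))
  expect_false(attr(path, "flagged_root"))

  # a clade whose MRCA (and nothing above) is on the high plateau starts there
  prob_poll2 <- prob_poll
  prob_poll2[5, ] <- c(0.02, 0.98)
  ap2 <- manual_asr(prob_poll2, ages, c("bee", "shifted"))
  syn2 <- setNames(syn4(c("generalist", "generalist", "bee")), c("S", "A", "B"))
  cl2 <- identify_shifted_clades(tr, syn2)
  path2 <- extract_shift_path(tr, cl2[1, ], ap2, ae, cutoff = 1000)
  expect_equal(path2$node[1], 5) # the shared node, not the tips

  # tau = 1 with strictly interior probabilities runs to the root, flagged
  prob_poll3 <- prob_poll
  prob_poll3[4, ] <- c(0.97, 0.03)
  ap3 <- manual_asr(prob_poll3, ages, c("bee", "shifted"))
  path3 <- extract_shift_path(tr, cl[1, ], ap3, ae, cutoff = 1000, tau_shift = 1)
  expect_true(attr(path3, "flagged_root"))
  expect_equal(path3$node[length(path3$node)], 4)
})

test_that("archetype paths classify as in the three-scenario schematic", {
  env_first <- tibble::tibble(node = 1:2, x = c(1, 0), y = c(1, 1), age_myr = 0:1)
  cls <- classify_lineage(env_first)
  expect_equal(cls$axis_category, "ON_Y_AXIS")
  expect_equal(cls$line_position, "ABOVE_1_1")

  poll_first <- tibble::tibble(node = 1:2, x = c(1, 1), y = c(0, 0), age_myr = 0:1)
  cls2 <- classify_lineage(poll_first)
  expect_equal(cls2$axis_category, "ON_X_AXIS")
  expect_equal(cls2$line_position, "BELOW_1_1")

  simul <- tibble::tibble(node = 1:3, x = c(1, 0.5, 0), y = c(1, 0.5, 0), age_myr = 0:2)
  expect_equal(classify_lineage(simul)$line_position, "NEAR_1_1")

  # duplicating intermediate nodes does not change the classification
  dup <- simul[c(1, 2, 2, 2, 3), ]
  expect_equal(classify_lineage(dup), classify_lineage(simul))
})

test_that("environment-shift probability is monotone non-increasing in cutoff", {
  set.seed(61)
  p4 <- matrix(runif(40), 10, 4)
  p4 <- p4 / rowSums(p4)
  ae <- manual_asr(p4, rep(0, 10), c("E1", "E2", "E3", "E4"))
  y500 <- pollshift:::.env_shift_prob(ae, 500)
  y1000 <- pollshift:::.env_shift_prob(ae, 1000)
  y1500 <- pollshift:::.env_shift_prob(ae, 1500)
  expect_true(all(y1000 <= y500 + 1e-12))
  expect_true(all(y1500 <= y1000 + 1e-12))
})

test_that("a hand-built three-lineage toy yields one lineage per category", {
  tr <- parse_newick("((s1:1,b1:1):2,((s2:1,b2:1):1,(s3:1,b3:1):1):1);")
  n <- 6
  lab <- tr$tip.label
  # nodes: 7 root, 8 = (s1,b1), 9 = inner, 10 = (s2,b2), 11 = (s3,b3)
  px <- matrix(0, 11, 2) # P(bee), P(shifted)
  px[, 1] <- 1
  for (tip in c(1, 3, 5)) px[tip, ] <- c(0, 1)
  py <- matrix(0, 11, 2)
  py[, 1] <- 1
  # lineage 1 (s1): env-first -> parent node 8 montane while still bee
  py[c(1, 8), ] <- rep(c(0, 1), each = 2)
  # lineage 2 (s3, node 11): poll-first -> everything lowland
  # lineage 3 (s2, node 10): simultaneous-ish -> tip montane, ancestors low
  py[5, ] <- c(1, 0)
  py[3, ] <- c(0, 1)
  px[10, ] <- c(0.5, 0.5)
  py[10, ] <- c(0.5, 0.5)
  ages <- c(rep(0, 6), 3, 1, 2, 1, 1)
  ap <- manual_asr(px, ages, c("bee", "shifted"))
  ae <- manual_asr(py, ages, c("lowland", "montane"))
  syn <- setNames(
    syn4(c("generalist", "bee", "nectar_vertebrate", "bee", "foodbody_vertebrate", "bee")),
    lab
  )
  rep <- scenario_report(tr, syn, ap, ae, cutoffs = 1000)
  expect_equal(nrow(rep$lineages), 3)
  expect_setequal(
    rep$lineages$line_position,
    c("ABOVE_1_1", "BELOW_1_1", "NEAR_1_1")
  )
  expect_equal(rep$verdicts$verdict, "SIMULTANEOUS") # no strict majority
  # path count equals clade count for every cutoff
  expect_equal(nrow(rep$lineages), nrow(rep$clades))
})

test_that("empty scenario reports carry an UNDEFINED verdict", {
  tr <- parse_newick("(A:1,B:1);")
  ap <- manual_asr(matrix(c(1, 0, 1, 0, 1, 0), 3, 2, byrow = TRUE), c(0, 0, 1), c("bee", "shifted"))
  ae <- manual_asr(matrix(c(1, 0, 1, 0, 1, 0), 3, 2, byrow = TRUE), c(0, 0, 1), c("lowland", "montane"))
  syn <- setNames(syn4(c("bee", "bee")), c("A", "B"))
  expect_warning(rep <- scenario_report(tr, syn, ap, ae, cutoffs = 1000))
  expect_equal(rep$verdicts$verdict, "UNDEFINED")
})

test_that("generating scenarios separate in the y-axis occupancy statistic", {
  frac_on_y <- function(scn, seeds) {
    sapply(seeds, function(s) {
      r <- suppressWarnings(
        recover_scenario(scenario_spec(scn, n = 100, seed = s))
      )
      mean(r$report$lineages$axis_category == "ON_Y_AXIS")
    })
  }
  env <- frac_on_y("ENV_FIRST", 1:6)
  pol <- frac_on_y("POLL_FIRST", 1:6)
  expect_gt(mean(env), mean(pol))
})
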