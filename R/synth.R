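#' Specify a synthetic shift-ordering scenario
#'
#' Defines the coupled two-character process used by
#' [simulate_joint_history()]. Under `ENV_FIRST` the environment flips at its
#' base rates and the pollinator shifts at `q_base + q_boost` while montane;
#' `POLL_FIRST` mirrors the dependency (the pollinator takes the leading rate
#' `q_env_up` and the environment's uphill rate becomes
#' `q_base + q_boost` once shifted); `SIMULTANEOUS` uses a single coupled
#' jump channel moving both characters at once; `INDEPENDENT` sets the
#' coupling to zero. Pollinator shifts are not reversible, matching the
#' near-absence of reversals in buzz-pollinated lineages.
#'
#' @param scenario One of `"ENV_FIRST"`, `"POLL_FIRST"`, `"SIMULTANEOUS"`,
#'   `"INDEPENDENT"`.
#' @param n Number of extant tips for the companion tree.
#' @param lambda,mu Birth and death rates (per Myr) for the tree.
#' @param q_env_up,q_env_down Lowland->montane and montane->lowland rates
#'   (per Myr).
#' @param q_base Baseline pollinator shift rate (per Myr).
#' @param q_boost Added shift rate while in the conducive state (per Myr).
#' @param seed RNG seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("ENV_FIRST", "POLL_FIRST", "SIMULTANEOUS", "INDEPENDENT"),
                          n = 150, lambda = 0.2, mu = 0.05, height_myr = 25,
                          q_env_up = 0.05, q_env_down = 0.02,
                          q_base = 0.001, q_boost = 0.05, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(
    n >= 3, lambda > mu, mu >= 0,
    q_env_up >= 0, q_env_down >= 0, q_base >= 0, q_boost >= 0
  )
  if (scenario == "INDEPENDENT") q_boost <- 0
  structure(
    list(
      scenario = scenario, n = n, lambda = lambda, mu = mu,
      height_myr = height_myr,
      q_env_up = q_env_up, q_env_down = q_env_down,
      q_base = q_base, q_boost = q_boost, seed = seed
    ),
    class = "scenario_spec"
  )
}

#' Simulate a dated birth-death tree
#'
#' Constant-rate birth-death tree conditioned on `n` extant tips (extinct
#' lineages pruned), via [phytools::pbtree()]; resimulated up to a retry cap
#' if every lineage goes extinct.
#'
#' @param n Number of extant tips (>= 3).
#' @param lambda Speciation rate (> mu).
#' @param mu Extinction rate (>= 0).
#' @param seed RNG seed (same seed, same tree).
#' @param max_tries Retry cap for full extinction.
#' @return An ultrametric `phylo` with `n` tips.
#' @export
simulate_bd_tree <- function(n, lambda = 0.1, mu = 0, seed = 1L, max_tries = 50) {
  stopifnot(n >= 3, lambda > mu, mu >= 0)
  withr_seed(seed, {
    for (i in seq_len(max_tries)) {
      tr <- tryCatch(
        suppressWarnings(
          phytools::pbtree(
            b = lambda, d = mu, n = n, extant.only = TRUE, quiet = TRUE
          )
        ),
        error = function(e) NULL
      )
      if (!is.null(tr) && ape::Ntip(tr) == n) {
        return(tr)
      }
    }
    abort("birth-death simulation failed after retry cap (all lineages extinct)")
  })
}

# channel table for the coupled process: given (env, poll) return a list of
# (rate, new_env, new_poll)
.channels <- function(env, poll, spec) {
  ch <- list()
  add <- function(rate, e, p) {
    if (rate > 0) ch[[length(ch) + 1]] <<- list(rate = rate, env = e, poll = p)
  }
  sc <- spec$scenario
  if (sc == "SIMULTANEOUS") {
    # the coupled jump is the dominant channel; residual env wobble at the
    # baseline rates only
    if (env == "lowland") add(spec$q_base, "montane", poll)
    if (env == "montane") add(spec$q_env_down, "lowland", poll)
    if (poll == "bee") add(spec$q_env_up, "montane", "shifted") # coupled jump
    return(ch)
  }
  if (sc == "POLL_FIRST") {
    if (poll == "bee") add(spec$q_env_up, env, "shifted")
    up <- spec$q_base + if (poll == "shifted") spec$q_boost else 0
    if (env == "lowland") add(up, "montane", poll)
    if (env == "montane") add(spec$q_env_down, "lowland", poll)
    return(ch)
  }
  # ENV_FIRST and INDEPENDENT (q_boost = 0)
  if (env == "lowland") add(spec$q_env_up, "montane", poll)
  if (env == "montane") add(spec$q_env_down, "lowland", poll)
  shift_rate <- spec$q_base + if (env == "montane") spec$q_boost else 0
  if (poll == "bee") add(shift_rate, env, "shifted")
  ch
}

#' Simulate a coupled environment/pollinator history on a tree
#'
#' Exact event-driven (Gillespie) simulation of the coupled two-character
#' Markov process along every branch, from a root fixed at
#' (lowland, bee). Every event's absolute time is recorded, so true shift
#' orderings are available per lineage.
#'
#' @param tree A dated `phylo`.
#' @param spec A [scenario_spec()].
#' @param seed RNG seed (defaults to the spec's).
#' @return A list: `env_states`, `poll_states` (named tip vectors),
#'   `node_env`, `node_poll` (states at all tips+nodes), `events` (tibble:
#'   `edge_child`, `time_abs`, `character`, `from`, `to`), `spec`.
#' @export
simulate_joint_history <- function(tree, spec, seed = spec$seed) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  tr <- reorder(tree, "postorder")
  depth <- ape::node.depth.edgelength(tree)
  root <- tr$edge[nrow(tr$edge), 1]
  node_env <- rep(NA_character_, N)
  node_poll <- rep(NA_character_, N)
  node_env[root] <- "lowland"
  node_poll[root] <- "bee"
  ev <- list()
  withr_seed(seed, {
    for (e in rev(seq_len(nrow(tr$edge)))) { # preorder
      p <- tr$edge[e, 1]
      c_ <- tr$edge[e, 2]
      env <- node_env[p]
      poll <- node_poll[p]
      t <- 0
      len <- tr$edge.length[e]
      repeat {
        ch <- .channels(env, poll, spec)
        if (length(ch) == 0) break
        rates <- vapply(ch, function(x) x$rate, 1)
        R <- sum(rates)
        dt <- rexp(1, R)
        if (t + dt > len) break
        t <- t + dt
        pick <- ch[[sample.int(length(ch), 1, prob = rates)]]
        if (pick$env != env) {
          ev[[length(ev) + 1]] <- list(
            edge_child = c_, time_abs = depth[p] + t,
            character = "env", from = env, to = pick$env
          )
        }
        if (pick$poll != poll) {
          ev[[length(ev) + 1]] <- list(
            edge_child = c_, time_abs = depth[p] + t,
            character = "poll", from = poll, to = pick$poll
          )
        }
        env <- pick$env
        poll <- pick$poll
      }
      node_env[c_] <- env
      node_poll[c_] <- poll
    }
  })
  events <- if (length(ev)) {
    dplyr::bind_rows(lapply(ev, tibble::as_tibble))
  } else {
    tibble::tibble(
      edge_child = integer(), time_abs = double(),
      character = character(), from = character(), to = character()
    )
  }
  env_states <- setNames(factor(node_env[seq_len(n)], c("lowland", "montane")), tree$tip.label)
  poll_states <- setNames(factor(node_poll[seq_len(n)], c("bee", "shifted")), tree$tip.label)
  list(
    env_states = env_states, poll_states = poll_states,
    node_env = node_env, node_poll = node_poll, events = events, spec = spec
  )
}

#' Expand binary histories to four elevation bins and four syndromes
#'
#' Lowland tips draw E1 or E2 with equal probability, montane tips E3 or E4;
#' shifted tips draw one of the three shifted syndromes by the given weights.
#' Binarizing the output at the 1000 m boundary recovers the binary inputs
#' exactly.
#'
#' @param env_states,poll_states Named binary factors
#'   (lowland/montane, bee/shifted).
#' @param weights Syndrome weights (generalist, nectar_vertebrate,
#'   foodbody_vertebrate).
#' @param seed RNG seed.
#' @return List: `elev_bin` (factor E1..E4), `syndrome` (4-level factor),
#'   `mapping` (tibble recording each tip's draw).
#' @export
expand_to_four_states <- function(env_states, poll_states,
                                  weights = c(1, 1, 1) / 3, seed = 1L) {
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  sp <- names(env_states)
  withr_seed(seed, {
    bins <- ifelse(
      env_states == "montane",
      sample(c("E3", "E4"), length(sp), replace = TRUE),
      sample(c("E1", "E2"), length(sp), replace = TRUE)
    )
    shifted_syn <- sample(SYNDROME_LEVELS[-1], length(sp), replace = TRUE, prob = weights)
    syn <- ifelse(poll_states == "shifted", shifted_syn, "bee")
    list(
      elev_bin = setNames(factor(bins, ELEV_BINS), sp),
      syndrome = setNames(factor(syn, SYNDROME_LEVELS), sp),
      mapping = tibble::tibble(
        species = sp, env = as.character(env_states),
        poll = as.character(poll_states), elev_bin = bins, syndrome = syn
      )
    )
  })
}

#' Simulate per-species occurrence clouds
#'
#' Records are drawn Normal(optimum, sigma) per variable; temperature is
#' coupled to each record's elevation through an atmospheric lapse rate
#' (default -5.5 degC per 1000 m from a 27 degC sea-level baseline) so that
#' the elevation-temperature correlation matches the strong negative
#' correlation of real climate layers (|r| > 0.8).
#'
#' @param optima Tibble with `species`, `elevation_m`, optionally
#'   `bio12_mm`, `longitude`, `latitude` (species optima).
#' @param n_per_species Records per species.
#' @param sigma Named vector of record-level standard deviations:
#'   `elev` (m), `temp` (degC), `precip` (mm), `coord` (deg).
#' @param lapse Lapse rate (degC per m).
#' @param sea_level_temp Sea-level temperature baseline (degC).
#' @param seed RNG seed.
#' @return Occurrence tibble with the standard columns.
#' @export
simulate_occurrences <- function(optima, n_per_species = 20,
                                 sigma = c(elev = 150, temp = 0.5, precip = 200, coord = 0.5),
                                 lapse = -5.5 / 1000, sea_level_temp = 27,
                                 seed = 1L) {
  stopifnot(all(sigma >= 0), n_per_species >= 1)
  withr_seed(seed, {
    purrr::map_dfr(seq_len(nrow(optima)), function(i) {
      o <- optima[i, ]
      elev <- rnorm(n_per_species, o$elevation_m, sigma[["elev"]])
      opt_temp <- sea_level_temp + lapse * o$elevation_m
      temp <- opt_temp + lapse * (elev - o$elevation_m) +
        rnorm(n_per_species, 0, sigma[["temp"]])
      precip0 <- if ("bio12_mm" %in% names(o)) o$bio12_mm else 2000
      precip <- pmax(0, rnorm(n_per_species, precip0, sigma[["precip"]]))
      lon0 <- if ("longitude" %in% names(o)) o$longitude else runif(1, -80, -40)
      lat0 <- if ("latitude" %in% names(o)) o$latitude else runif(1, -20, 20)
      tibble::tibble(
        species = o$species,
        longitude = rnorm(n_per_species, lon0, sigma[["coord"]]),
        latitude = rnorm(n_per_species, lat0, sigma[["coord"]]),
        elevation_m = elev, bio1_degC = temp, bio12_mm = precip
      )
    })
  })
}

#' Simulate a full synthetic dataset for one scenario
#'
#' Tree, coupled binary histories, four-state expansions, species elevation
#' optima consistent with the binary environment (lowland optima 100-700 m,
#' montane 1300-2200 m), and an occurrence cloud per species.
#'
#' The tree is rescaled to the spec's fixed height (`height_myr`) so that the
#' per-Myr trait rates always act on the same timescale, and the draw is
#' conditioned on a non-degenerate dataset (between 2% and 60% of tips
#' shifted, 5-75% montane): a draw in which (almost) every lineage has
#' shifted carries no ordering signal and is resimulated under a shifted
#' seed, exactly as birth-death trees are conditioned on survival.
#'
#' @param spec A [scenario_spec()].
#' @param n_per_species Occurrence records per species (0 skips the
#'   occurrence stage).
#' @param max_tries Retry cap for the validity conditioning.
#' @return List: `tree`, `history`, `expanded`, `optima`, `occurrences`,
#'   `truth` (ordering table from [true_shift_ordering()]).
#' @export
simulate_scenario_dataset <- function(spec, n_per_species = 20, max_tries = 30) {
  n <- spec$n
  tree <- NULL
  for (try in seq_len(max_tries) - 1L) {
    seed_t <- spec$seed + 10000L * try
    tr <- simulate_bd_tree(n, spec$lambda, spec$mu, seed = seed_t)
    tr$edge.length <- tr$edge.length *
      spec$height_myr / max(ape::node.depth.edgelength(tr))
    hs <- simulate_joint_history(tr, spec, seed = seed_t + 1000L)
    nsh <- sum(hs$poll_states == "shifted")
    nmo <- sum(hs$env_states == "montane")
    if (nsh >= max(3, 0.02 * n) && nsh <= 0.6 * n &&
      nmo >= 0.05 * n && nmo <= 0.75 * n) {
      tree <- tr
      hist <- hs
      break
    }
  }
  if (is.null(tree)) {
    abort("no non-degenerate dataset within the retry cap; adjust the spec rates")
  }
  exp4 <- expand_to_four_states(hist$env_states, hist$poll_states, seed = spec$seed + 2000L)
  optima <- withr_seed(spec$seed + 3000L, tibble::tibble(
    species = tree$tip.label,
    elevation_m = ifelse(
      exp4$elev_bin == "E1", runif(spec$n, 100, 450),
      ifelse(exp4$elev_bin == "E2", runif(spec$n, 550, 950),
        ifelse(exp4$elev_bin == "E3", runif(spec$n, 1050, 1450),
          runif(spec$n, 1550, 2200)
        )
      )
    ),
    bio12_mm = runif(spec$n, 1200, 3200),
    longitude = runif(spec$n, -80, -40),
    latitude = runif(spec$n, -25, 25)
  ))
  occ <- if (n_per_species > 0) {
    simulate_occurrences(optima,
      n_per_species = n_per_species,
      seed = spec$seed + 4000L
    )
  }
  list(
    tree = tree, history = hist, expanded = exp4, optima = optima,
    occurrences = occ, truth = true_shift_ordering(tree, hist)
  )
}

#' True shift ordering per tip lineage
#'
#' For every tip, walks the recorded event history on its root path and
#' reports the first environment-shift and first pollinator-shift times
#' (absolute, from the root), and which came first.
#'
#' @param tree The simulated `phylo`.
#' @param history Output of [simulate_joint_history()].
#' @return Tibble: `species`, `t_env_shift`, `t_poll_shift`, `ordering`
#'   (`env_first`, `poll_first`, `env_only`, `poll_only`, `none`).
#' @export
true_shift_ordering <- function(tree, history) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  parent <- rep(NA_integer_, N)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  ev <- history$events
  purrr::map_dfr(seq_len(n), function(tip) {
    path <- tip
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    sub <- ev[ev$edge_child %in% path, ]
    te <- suppressWarnings(min(sub$time_abs[sub$character == "env" & sub$to == "montane"]))
    tp <- suppressWarnings(min(sub$time_abs[sub$character == "poll"]))
    ordering <- if (is.finite(te) && is.finite(tp)) {
      if (te < tp) "env_first" else if (tp < te) "poll_first" else "tie"
    } else if (is.finite(te)) {
      "env_only"
    } else if (is.finite(tp)) {
      "poll_only"
    } else {
      "none"
    }
    tibble::tibble(
      species = tree$tip.label[tip],
      t_env_shift = ifelse(is.finite(te), te, NA_real_),
      t_poll_shift = ifelse(is.finite(tp), tp, NA_real_),
      ordering = ordering
    )
  })
}
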