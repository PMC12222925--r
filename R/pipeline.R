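#' Build a run configuration
#'
#' Validates and fills defaults for the end-to-end analysis. `tree`, `traits`
#' and `occurrences` may be file paths (Newick / CSV) or in-memory objects.
#'
#' @param tree Path to a Newick file, or a `phylo`.
#' @param traits Path to a trait CSV, or a data frame
#'   (`species, syndrome, ...`).
#' @param occurrences Path to an occurrence CSV, or a data frame.
#' @param cell_size_deg Grid cell for occurrence thinning (deg).
#' @param cutoffs Elevation cutoffs (m) for the scenario binarizations.
#' @param tau_shift High-probability plateau for shift-path extraction.
#' @param delta Classification margin.
#' @param engine Likelihood engine for the character models
#'   (`"mk"` or `"sse"`).
#' @param schemes Rate schemes compared per character.
#' @param root_prior Root prior for the character models.
#' @param split_elevation Elevation threshold (m) for the montane-subset
#'   comparisons.
#' @param n_iter Resampling iterations.
#' @param seed Seed recorded in every output and used for all randomness.
#' @param out_dir Optional output directory for the results bundle (CSV/JSON
#'   + manifest); stage results are cached there keyed by config hash.
#' @return An object of class `run_config`.
#' @export
run_config <- function(tree, traits, occurrences,
                       cell_size_deg = 1 / 120,
                       cutoffs = c(500, 1000, 1500),
                       tau_shift = 0.95, delta = 0.10,
                       engine = c("mk", "sse"),
                       schemes = c("SYM", "ARD"),
                       root_prior = "fitzjohn",
                       split_elevation = 1000,
                       n_iter = 100, seed = 1L, out_dir = NULL) {
  engine <- match.arg(engine)
  for (f in list(tree, traits, occurrences)) {
    if (is.character(f) && !file.exists(f)) {
      abort(paste0("input file does not exist: ", f))
    }
  }
  structure(
    list(
      tree = tree, traits = traits, occurrences = occurrences,
      cell_size_deg = cell_size_deg, cutoffs = cutoffs,
      tau_shift = tau_shift, delta = delta, engine = engine,
      schemes = schemes, root_prior = root_prior,
      split_elevation = split_elevation, n_iter = n_iter,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  rlang::hash(cfg)
}

# content-addressed stage cache under out_dir/cache
.stage_cached <- function(config, stage, fn) {
  if (is.null(config$out_dir)) {
    return(fn())
  }
  dir.create(file.path(config$out_dir, "cache"), recursive = TRUE, showWarnings = FALSE)
  key <- file.path(
    config$out_dir, "cache",
    paste0(stage, "-", .config_hash(config), ".rds")
  )
  if (file.exists(key)) {
    return(readRDS(key))
  }
  out <- fn()
  saveRDS(out, key)
  out
}

#' Run the full shift-ordering analysis
#'
#' Orchestrates niche preparation, character coding, model fitting and AIC
#' selection for both characters, marginal ancestral reconstruction, the
#' scenario report, the correlated-evolution test, the phylogenetic
#' statistics battery, and the single-occurrence resampling procedure, from
#' one configuration. Deterministic given inputs and seed. A stage failure
#' marks the bundle partial (with the failing stage named) and skips the
#' stages that depend on it.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return An object of class `shift_order_results`: list of stage outputs
#'   plus a `manifest` (config hash, seed, timings, stage log).
#' @export
run_shift_order <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log <- list()
  failed <- NULL
  res <- list(config = config)
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- sprintf("%s: %s", stage, msg)
  }
  run_stage <- function(stage, fn) {
    if (!is.null(failed)) {
      return(NULL)
    }
    out <- tryCatch(.stage_cached(config, stage, fn), error = function(e) {
      failed <<- stage
      note(stage, paste0("FAILED: ", conditionMessage(e)))
      NULL
    })
    out
  }

  # --- inputs
  inputs <- run_stage("inputs", function() {
    tree <- if (is.character(config$tree))

      parse_newick(paste(readLines(config$tree), collapse = "")) else config$tree
    traits <- if (is.character(config$traits)) {
      read_trait_table(config$traits)
    } else {
      validate_trait_table(config$traits)
    }
    occ <- if (is.character(config$occurrences)) {
      read_occurrences(config$occurrences)
    } else {
      validate_occurrences(config$occurrences)
    }
    list(tree = tree, traits = traits, occ = occ)
  })
  if (!is.null(inputs)) note("inputs", sprintf(
    "%d tips, %d trait rows, %d occurrence records",
    ape::Ntip(inputs$tree), nrow(inputs$traits), nrow(inputs$occ)
  ))

  # --- niche preparation
  niche <- run_stage("niche", function() {
    occ <- dedup_occurrences(inputs$occ, quiet = TRUE)
    occ <- grid_subsample(occ, config$cell_size_deg, quiet = TRUE)
    summarize_species(occ)
  })
  if (!is.null(niche)) note("niche", sprintf("%d species summarized", nrow(niche)))
  res$niche_summaries <- niche

  # --- alignment and character coding
  chars <- run_stage("characters", function() {
    al <- align_tree_and_traits(inputs$tree, inputs$traits, quiet = TRUE)
    keep <- intersect(al$tree$tip.label, niche$species)
    tree <- prune_to_taxa(al$tree, keep)
    traits <- al$traits[match(tree$tip.label, al$traits$species), ]
    summ <- niche[match(tree$tip.label, niche$species), ]
    syndrome <- setNames(factor(traits$syndrome, SYNDROME_LEVELS), tree$tip.label)
    elev_bin <- setNames(
      factor(as.character(summ$elev_bin), ELEV_BINS), tree$tip.label
    )
    shifted <- setNames(as.integer(syndrome != "bee"), tree$tip.label)
    montane <- setNames(
      as.integer(summ$elevation_m > config$split_elevation), tree$tip.label
    )
    list(
      tree = tree, traits = traits, summaries = summ, syndrome = syndrome,
      elev_bin = elev_bin, shifted = shifted, montane = montane
    )
  })
  if (!is.null(chars)) note("characters", sprintf(
    "%d aligned species, %d shifted", ape::Ntip(chars$tree), sum(chars$shifted)
  ))
  res$characters <- chars

  # --- model fitting + selection per character
  models <- run_stage("models", function() {
    # drop unused syndrome levels so the model matches the observed states
    syn <- droplevels(chars$syndrome)
    bin <- droplevels(chars$elev_bin)
    sel_poll <- fit_models_and_select(
      chars$tree, syn,
      schemes = config$schemes, engine = config$engine,
      root_prior = config$root_prior, states = levels(syn)
    )
    sel_env <- fit_models_and_select(
      chars$tree, bin,
      schemes = config$schemes, engine = config$engine,
      root_prior = config$root_prior, states = levels(bin)
    )
    list(poll = sel_poll, env = sel_env)
  })
  res$aic_tables <- if (!is.null(models)) {
    list(pollination = models$poll$aic_table, elevation = models$env$aic_table)
  }
  if (!is.null(models)) note("models", sprintf(
    "pollination best %s, elevation best %s",
    models$poll$best$scheme, models$env$best$scheme
  ))

  # --- ancestral reconstruction
  asr <- run_stage("asr", function() {
    syn <- droplevels(chars$syndrome)
    bin <- droplevels(chars$elev_bin)
    list(
      poll = marginal_asr(chars$tree, syn, models$poll$best$Q,
        root_prior = config$root_prior, states = levels(syn)
      ),
      env = marginal_asr(chars$tree, bin, models$env$best$Q,
        root_prior = config$root_prior, states = levels(bin)
      ),
      env_continuous = bm_asr_continuous(
        chars$tree, setNames(chars$summaries$elevation_m, chars$tree$tip.label)
      )
    )
  })
  res$asr <- asr

  # --- scenario report
  scen <- run_stage("scenario", function() {
    scenario_report(
      chars$tree, chars$syndrome, asr$poll, asr$env,
      cutoffs = config$cutoffs, delta = config$delta,
      tau_shift = config$tau_shift
    )
  })
  res$scenario <- scen
  if (!is.null(scen)) note("scenario", paste(
    sprintf("%dm:%s", scen$verdicts$cutoff, scen$verdicts$verdict),
    collapse = " "
  ))

  # --- correlated evolution (binarized characters)
  corr <- run_stage("correlation", function() {
    env_bin <- setNames(
      factor(ifelse(chars$montane == 1, "montane", "lowland"), c("lowland", "montane")),
      chars$tree$tip.label
    )
    poll_bin <- setNames(
      factor(ifelse(chars$shifted == 1, "shifted", "bee"), c("bee", "shifted")),
      chars$tree$tip.label
    )
    correlation_test(chars$tree, poll_bin, env_bin,
      scheme = "ARD", root_prior = config$root_prior
    )
  })
  res$correlation <- corr
  if (!is.null(corr)) note("correlation", corr$verdict)

  # --- phylogenetic statistics battery
  stats_battery <- run_stage("stats", function() {
    d <- tibble::tibble(
      species = chars$tree$tip.label,
      shifted = as.numeric(chars$shifted),
      syndrome = as.character(chars$syndrome),
      elevation_m = chars$summaries$elevation_m,
      bio1_degC = chars$summaries$bio1_degC,
      bio12_mm = chars$summaries$bio12_mm,
      latitude = chars$summaries$latitude
    )
    out <- list()
    out$anova_elevation <- phylo_anova(
      d, "elevation_m", "syndrome", chars$tree,
      nsim = 500, seed = config$seed
    )
    out$logistic_stepwise <- stepwise_reduce(
      d, shifted ~ elevation_m + latitude + bio12_mm, chars$tree,
      model = "logistic"
    )
    out$two_sample_elevation <- phylo_two_sample(
      dplyr::mutate(d, grp = ifelse(.data$shifted == 1, "shifted", "bee")),
      "elevation_m", "grp", chars$tree
    )
    mont <- d[chars$summaries$elevation_m > config$split_elevation, ]
    if (sum(mont$shifted) >= 3 && sum(1 - mont$shifted) >= 3) {
      mt <- prune_to_taxa(chars$tree, mont$species)
      out$montane_logistic <- tryCatch(
        phylo_logistic_fit(mont, shifted ~ bio1_degC + bio12_mm, mt),
        error = function(e) NULL
      )
    }
    if ("biome_id" %in% names(chars$summaries)) {
      grp <- setNames(
        ifelse(chars$shifted == 1, "shifted", "bee"), chars$tree$tip.label
      )
      out$biome_chisq <- tryCatch(
        biome_chisq(grp, chars$summaries),
        error = function(e) NULL
      )
    }
    # flower-size models when floral traits are available
    tr <- chars$traits
    if (all(c("petal_length_mm", "pore_height_mm", "pore_width_mm") %in% names(tr))) {
      dd <- dplyr::mutate(d,
        log_petal = log(tr$petal_length_mm),
        log_pore = log(pore_area(tr$pore_height_mm, tr$pore_width_mm))
      )
      bee_only <- dd[dd$shifted == 0 & is.finite(dd$log_petal) & is.finite(dd$log_pore), ]
      if (nrow(bee_only) >= 10) {
        bt <- prune_to_taxa(chars$tree, bee_only$species)
        out$petal_model <- stepwise_reduce(
          bee_only, log_petal ~ elevation_m + bio12_mm + latitude + elevation_m:latitude,
          bt,
          model = "linear"
        )
        out$pore_model <- stepwise_reduce(
          bee_only, log_pore ~ elevation_m + bio12_mm + latitude + elevation_m:latitude,
          bt,
          model = "linear"
        )
      }
    }
    out
  })
  res$stats <- stats_battery

  # --- occurrence resampling
  resamp <- run_stage("resampling", function() {
    occ <- dedup_occurrences(inputs$occ, quiet = TRUE)
    occ <- occ[occ$species %in% chars$tree$tip.label, ]
    occurrence_resampling(
      occ, setNames(chars$shifted, chars$tree$tip.label),
      shifted ~ elevation_m, chars$tree,
      n_iter = config$n_iter, seed = config$seed
    )
  })
  res$resampling <- resamp
  if (!is.null(resamp)) note("resampling", sprintf(
    "%.1f%% significant", resamp$percent_significant
  ))

  res$manifest <- list(
    config_hash = .config_hash(config),
    seed = config$seed,
    partial = !is.null(failed),
    failed_stage = failed,
    log = unlist(log),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    r_version = as.character(getRversion())
  )
  out <- structure(res, class = "shift_order_results")
  if (!is.null(config$out_dir)) write_results_bundle(out, config$out_dir)
  out
}

#' @export
print.shift_order_results <- function(x, ...) {
  cat("Shift-order analysis results\n")
  for (l in x$manifest$log) cat(" -", l, "\n")
  if (x$manifest$partial) {
    cat("PARTIAL bundle; failed stage:", x$manifest$failed_stage, "\n")
  }
  invisible(x)
}

#' Write a results bundle to disk (CSV/JSON + manifest)
#' @param results A `shift_order_results`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results_bundle <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      write.csv(df, file.path(dir, name), row.names = FALSE)
    }
  }
  w(results$niche_summaries, "niche_summaries.csv")
  if (!is.null(results$aic_tables)) {
    w(results$aic_tables$pollination, "aic_pollination.csv")
    w(results$aic_tables$elevation, "aic_elevation.csv")
  }
  if (!is.null(results$asr)) {
    w(tidy(results$asr$poll), "asr_pollination.csv")
    w(tidy(results$asr$env), "asr_elevation.csv")
    w(results$asr$env_continuous, "asr_elevation_continuous.csv")
  }
  if (!is.null(results$scenario)) {
    w(results$scenario$lineages, "scenario_lineages.csv")
    w(results$scenario$verdicts, "scenario_verdicts.csv")
    jsonlite::write_json(
      list(
        verdicts = results$scenario$verdicts,
        sensitivity = results$scenario$sensitivity
      ),
      file.path(dir, "scenario_report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(results$correlation)) {
    jsonlite::write_json(
      results$correlation[c(
        "loglik_indep", "AIC_indep", "loglik_dep", "AIC_dep", "verdict"
      )],
      file.path(dir, "correlation_test.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(results$resampling)) {
    w(results$resampling$iterations, "resampling_iterations.csv")
  }
  jsonlite::write_json(
    results$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
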