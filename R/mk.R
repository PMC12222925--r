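#' Build a rate scheme for a k-state Mk model
#'
#' `SYM` ties each pair of opposing rates (k(k-1)/2 free rates), `ARD` frees
#' every off-diagonal cell (k(k-1)), and `CONSTRAINED` is ARD with a
#' user-supplied zero mask fixing forbidden transitions at 0.
#'
#' @param k Number of states.
#' @param scheme One of `"SYM"`, `"ARD"`, `"CONSTRAINED"`.
#' @param mask For `CONSTRAINED`: a two-column matrix/data frame of (from, to)
#'   state indices (or state names if `states` given) whose rates are fixed
#'   at zero.
#' @param states Optional state names of length `k`.
#' @return An object of class `rate_scheme`: list with `k`, `scheme`,
#'   `par_index` (k x k matrix of parameter ids, 0 = structural zero), and
#'   `n_free`.
#' @export
make_rate_scheme <- function(k, scheme = c("ARD", "SYM", "CONSTRAINED"),
                             mask = NULL, states = NULL) {
  scheme <- match.arg(scheme)
  idx <- matrix(0L, k, k)
  if (scheme == "SYM") {
    p <- 0L
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        p <- p + 1L
        idx[i, j] <- p
        idx[j, i] <- p
      }
    }
  } else {
    p <- 0L
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i != j) {
          p <- p + 1L
          idx[i, j] <- p
        }
      }
    }
    if (scheme == "CONSTRAINED") {
      if (is.null(mask)) abort("CONSTRAINED scheme requires a zero mask")
      mask <- as.matrix(mask)
      for (r in seq_len(nrow(mask))) {
        i <- mask[r, 1]
        j <- mask[r, 2]
        if (!is.null(states) && is.character(i)) {
          i <- match(i, states)
          j <- match(j, states)
        }
        i <- as.integer(i)
        j <- as.integer(j)
        if (i == j) abort("mask cannot target diagonal cells")
        idx[i, j] <- 0L
      }
      # re-number surviving parameters compactly
      free <- sort(unique(idx[idx > 0]))
      idx[idx > 0] <- match(idx[idx > 0], free)
    }
  }
  structure(
    list(k = k, scheme = scheme, par_index = idx, n_free = max(idx), states = states),
    class = "rate_scheme"
  )
}

#' Assemble a rate matrix from free rates under a scheme
#' @param rates Vector of free rates (length `scheme$n_free`).
#' @param scheme A `rate_scheme`.
#' @return k x k instantaneous rate matrix with rows summing to zero.
#' @export
build_rate_matrix <- function(rates, scheme) {
  stopifnot(length(rates) == scheme$n_free, all(rates >= 0))
  Q <- matrix(0, scheme$k, scheme$k)
  pos <- scheme$par_index > 0
  Q[pos] <- rates[scheme$par_index[pos]]
  diag(Q) <- -rowSums(Q)
  if (!is.null(scheme$states)) dimnames(Q) <- list(scheme$states, scheme$states)
  Q
}

# tip states (factor/character/integer, NA = missing) -> ntip x k partial
# likelihood matrix in tree tip order
tip_state_matrix <- function(tree, tip_states, states = NULL) {
  x <- tip_states[tree$tip.label]
  if (any(is.na(names(tip_states))) || is.null(names(tip_states))) {
    abort("tip_states must be a named vector (species -> state)")
  }
  if (!all(tree$tip.label %in% names(tip_states))) {
    abort(paste0(
      "tips without states: ",
      paste(setdiff(tree$tip.label, names(tip_states)), collapse = ", ")
    ))
  }
  if (is.null(states)) {
    states <- if (is.factor(x)) levels(x) else sort(unique(na.omit(as.character(x))))
  }
  k <- length(states)
  L <- matrix(0, ape::Ntip(tree), k)
  idx <- match(as.character(x), states)
  for (i in seq_along(idx)) {
    if (is.na(idx[i])) L[i, ] <- 1 else L[i, idx[i]] <- 1 # missing = uniform
  }
  attr(L, "states") <- states
  L
}

resolve_root_prior <- function(root_prior, Q) {
  k <- nrow(Q)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k, all(root_prior >= 0))
    return(list(pi = root_prior / sum(root_prior), fitzjohn = FALSE))
  }
  switch(match.arg(root_prior, c("fitzjohn", "uniform", "stationary")),
    fitzjohn = list(pi = rep(1 / k, k), fitzjohn = TRUE),
    uniform = list(pi = rep(1 / k, k), fitzjohn = FALSE),
    stationary = {
      # left null vector of Q
      ev <- eigen(t(Q))
      i <- which.min(abs(ev$values))
      pi <- Re(ev$vectors[, i])
      pi <- abs(pi) / sum(abs(pi))
      list(pi = pi, fitzjohn = FALSE)
    }
  )
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a discrete character on a rooted dated tree
#' under a continuous-time Markov model, using per-branch transition matrices
#' `P(t) = exp(Qt)` and a pruning pass that handles polytomies natively.
#' Missing tip states enter as uniform partial likelihoods.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named vector (species -> state); factor, character or
#'   integer. `NA` = missing.
#' @param Q k x k instantaneous rate matrix (rows sum to 0).
#' @param root_prior `"fitzjohn"` (default), `"uniform"`, `"stationary"`, or a
#'   numeric prior vector of length k.
#' @param states Optional explicit state ordering.
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "fitzjohn", states = NULL) {
  L <- tip_state_matrix(tree, tip_states, states)
  if (ncol(L) != nrow(Q)) abort("state count mismatch between data and Q")
  tr <- reorder(tree, "postorder")
  rp <- resolve_root_prior(root_prior, Q)
  res <- mk_pruning_cpp(
    tr$edge, tr$edge.length, ape::Ntip(tr), L, unname(as.matrix(Q)),
    rp$pi, rp$fitzjohn, FALSE
  )
  res$loglik
}

#' Marginal ancestral state reconstruction under an Mk model
#'
#' Marginal state probabilities at every node by the two-pass
#' (conditioning/rerooting) method: the pruning pass supplies below-node
#' partial likelihoods, a preorder pass supplies above-node likelihoods, and
#' their normalized product is the marginal. Tip rows are degenerate on the
#' observed state (posterior for missing tips).
#'
#' @inheritParams mk_loglik
#' @return An object of class `marginal_asr`: list with `prob` (node x state
#'   matrix over all tips+internal nodes, rows normalized), `age_myr` (node
#'   ages before present), `states`, `loglik`, `ntip`.
#' @export
marginal_asr <- function(tree, tip_states, Q, root_prior = "fitzjohn", states = NULL) {
  L <- tip_state_matrix(tree, tip_states, states)
  states <- attr(L, "states")
  if (ncol(L) != nrow(Q)) abort("state count mismatch between data and Q")
  tr <- reorder(tree, "postorder")
  rp <- resolve_root_prior(root_prior, Q)
  res <- mk_pruning_cpp(
    tr$edge, tr$edge.length, ape::Ntip(tr), L, unname(as.matrix(Q)),
    rp$pi, rp$fitzjohn, TRUE
  )
  prob <- res$marginal
  # degenerate tip rows for observed tips (keep posterior for missing tips)
  obs <- rowSums(L) == 1
  prob[seq_len(nrow(L)), ][obs, ] <- L[obs, ]
  colnames(prob) <- states
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  structure(
    list(
      prob = prob, age_myr = ages, states = states,
      loglik = res$loglik, ntip = ape::Ntip(tree)
    ),
    class = "marginal_asr"
  )
}

#' @export
print.marginal_asr <- function(x, ...) {
  cat(sprintf(
    "Marginal ASR: %d tips, %d nodes, states: %s (logL = %.4f)\n",
    x$ntip, nrow(x$prob) - x$ntip, paste(x$states, collapse = ", "), x$loglik
  ))
  invisible(x)
}

#' Maximum-likelihood Mk fit
#'
#' Fits the free rates of a scheme by bounded multi-start optimization on log
#' rates (bounds 1e-9 to 100 per Myr). Zero-length branches are nudged before
#' fitting for numerical stability.
#'
#' @inheritParams mk_loglik
#' @param scheme `"SYM"`, `"ARD"`, `"CONSTRAINED"`, or a prebuilt
#'   `rate_scheme`.
#' @param mask Zero mask for `CONSTRAINED` (see [make_rate_scheme()]).
#' @param n_starts Number of optimization starts; the first uses a
#'   height-scaled heuristic, the rest deterministic multipliers and seeded
#'   random perturbations.
#' @param lower,upper Rate bounds (per Myr).
#' @param seed Seed for the random restarts.
#' @return An object of class `mk_fit`: `Q`, `rates`, `loglik`, `AIC`,
#'   `n_free`, `scheme`, `states`, `converged`, `root_prior`, `trace`.
#' @export
fit_mk <- function(tree, tip_states, scheme = "ARD", mask = NULL,
                   root_prior = "fitzjohn", states = NULL, n_starts = 3,
                   lower = 1e-9, upper = 100, seed = 1L) {
  tree <- ensure_positive_branches(tree)
  L <- tip_state_matrix(tree, tip_states, states)
  states <- attr(L, "states")
  k <- length(states)
  if (k < 2) abort("need at least 2 states in the model")
  n_obs_states <- sum(colSums(L[rowSums(L) == 1, , drop = FALSE]) > 0)
  if (is.character(scheme)) {
    scheme <- make_rate_scheme(k, scheme, mask = mask, states = states)
  }
  tr <- reorder(tree, "postorder")
  rp_is_num <- is.numeric(root_prior)
  nll <- function(logq) {
    Q <- build_rate_matrix(exp(logq), scheme)
    rp <- resolve_root_prior(root_prior, Q)
    res <- tryCatch(
      mk_pruning_cpp(
        tr$edge, tr$edge.length, ape::Ntip(tr), L, Q, rp$pi, rp$fitzjohn, FALSE
      ),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$loglik)) {
      return(1e10)
    }
    -res$loglik
  }
  h <- max(ape::node.depth.edgelength(tree))
  q0 <- 0.5 / h
  starts <- list(rep(log(q0), scheme$n_free))
  mults <- c(0.1, 10, 0.01, 100)
  i <- 1
  while (length(starts) < n_starts && i <= length(mults)) {
    starts[[length(starts) + 1]] <- rep(log(q0 * mults[i]), scheme$n_free)
    i <- i + 1
  }
  if (length(starts) < n_starts) {
    extra <- withr_seed(seed, {
      lapply(seq_len(n_starts - length(starts)), function(i) {
        log(q0) + runif(scheme$n_free, -3, 3)
      })
    })
    starts <- c(starts, extra)
  }
  best <- NULL
  for (s in starts[seq_len(n_starts)]) {
    fit <- tryCatch(
      optim(s, nll,
        method = "L-BFGS-B",
        lower = log(lower), upper = log(upper),
        control = list(maxit = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("all Mk optimization starts failed")
  converged <- best$convergence == 0 && best$value < 1e9
  if (!converged) warn("Mk fit did not converge; inspect trace")
  rates <- exp(best$par)
  if (n_obs_states < 2) {
    warn("only one observed state: rates driven to the lower bound")
  }
  Q <- build_rate_matrix(rates, scheme)
  ll <- -best$value
  structure(
    list(
      Q = Q, rates = rates, loglik = ll,
      AIC = 2 * scheme$n_free - 2 * ll, n_free = scheme$n_free,
      scheme = scheme$scheme, rate_scheme = scheme, states = states,
      converged = converged, root_prior = root_prior,
      trace = list(counts = best$counts, message = best$message, n_starts = n_starts)
    ),
    class = "mk_fit"
  )
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf(
    "Mk fit (%s, %d free rates): logL = %.4f, AIC = %.4f%s\n",
    x$scheme, x$n_free, x$loglik, x$AIC,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  print(round(x$Q, 5))
  invisible(x)
}

# evaluate a block with a temporary seed without disturbing the global RNG
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Fit several rate schemes and select by AIC
#'
#' Fits each requested scheme with the chosen likelihood engine and returns
#' the AIC table (sorted ascending) together with the best fit; ties are
#' broken toward fewer parameters.
#'
#' @inheritParams fit_mk
#' @param schemes Character vector of schemes to fit.
#' @param engine `"mk"` (default) or `"sse"` (MuSSE-style state-dependent
#'   diversification likelihood).
#' @param ... Passed to [fit_mk()] or [fit_sse()].
#' @return List with `aic_table` (tibble: scheme, loglik, n_free, AIC,
#'   delta_AIC, converged) and `best` (the winning fit object).
#' @export
fit_models_and_select <- function(tree, tip_states, schemes = c("SYM", "ARD"),
                                  engine = c("mk", "sse"), mask = NULL, ...) {
  engine <- match.arg(engine)
  stopifnot(length(schemes) >= 1)
  fits <- list()
  for (sch in schemes) {
    f <- tryCatch(
      if (engine == "mk") {
        fit_mk(tree, tip_states, scheme = sch, mask = mask, ...)
      } else {
        fit_sse(tree, tip_states, scheme = sch, mask = mask, ...)
      },
      error = function(e) NULL
    )
    if (!is.null(f)) fits[[sch]] <- f
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (length(fits) == 0 || !any(conv)) abort("no scheme converged")
  tab <- tibble::tibble(
    scheme = names(fits),
    loglik = vapply(fits, function(f) f$loglik, 1),
    n_free = vapply(fits, function(f) f$n_free, 1),
    AIC = vapply(fits, function(f) f$AIC, 1),
    converged = conv
  )
  tab <- dplyr::arrange(tab, .data$AIC, .data$n_free)
  tab$delta_AIC <- tab$AIC - min(tab$AIC[tab$converged])
  ok <- tab[tab$converged, ]
  best_scheme <- ok$scheme[order(ok$AIC, ok$n_free)][1]
  list(aic_table = tab, best = fits[[best_scheme]])
}
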