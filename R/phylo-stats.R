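#' Phylogenetic covariance matrix under Brownian motion
#'
#' Shared-branch-length covariance, optionally scaled so the largest diagonal
#' element (tree height) is 1; on an ultrametric tree the scaled diagonal is
#' identically 1 and off-diagonals are shared-height fractions.
#'
#' @param tree A `phylo` object.
#' @param scale Scale to unit height (default TRUE).
#' @return n x n covariance matrix, rows/cols named by tip label.
#' @export
phylo_vcv <- function(tree, scale = TRUE) {
  C <- ape::vcv(tree)
  if (scale) C <- C / max(diag(C))
  C
}

# order a species-keyed data frame along the tree tips
.align_data <- function(data, tree) {
  stopifnot("species" %in% names(data))
  miss <- setdiff(tree$tip.label, data$species)
  if (length(miss)) abort(paste0("species missing from data: ", paste(head(miss, 10), collapse = ", ")))
  data[match(tree$tip.label, data$species), , drop = FALSE]
}

# model matrix + response from a formula; guard the elevation/temperature
# collinearity the analysis refuses by default
.build_design <- function(formula, data, allow_collinear = FALSE) {
  vars <- all.vars(formula[[3]])
  if (!allow_collinear && all(c("elevation_m", "bio1_degC") %in% vars)) {
    abort(paste0(
      "elevation_m and bio1_degC are strongly collinear (|r| > 0.8); ",
      "include only one, or set allow_collinear = TRUE"
    ))
  }
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("singular design; collinear column(s): ", paste(bad, collapse = ", ")))
  }
  list(X = X, y = y, assign = attr(X, "assign"),
       term_labels = attr(terms(formula), "term.labels"))
}

#' Phylogenetic logistic regression (binary GLMM)
#'
#' Logistic regression of a binary species trait with a phylogenetic random
#' effect `b ~ N(0, s2 C)` estimated by penalized iterative reweighted least
#' squares (the Ives-Garland formulation, via [ape::binaryPGLMM()]).
#' Numeric predictors are standardized internally and coefficients
#' back-transformed to the input scale; p-values use the normal (z)
#' reference.
#'
#' @param data Data frame with a `species` column, the binary response and
#'   the predictors.
#' @param formula Model formula, e.g. `shifted ~ elevation_m + latitude`.
#' @param tree A `phylo` object whose tips are the species.
#' @param standardize Standardize predictor columns before fitting.
#' @param s2_fixed Fix the phylogenetic variance (0 = ordinary logistic
#'   regression); `NULL` (default) estimates it.
#' @param allow_collinear Permit elevation and temperature in one model.
#' @return Object of class `phylo_glm_fit`: `coefficients` tibble (term,
#'   estimate, std_error, statistic, p_value), `s2`, `mu` (fitted
#'   probabilities named by species), `converged`, `formula`, `n`.
#' @export
phylo_logistic_fit <- function(data, formula, tree, standardize = TRUE,
                               s2_fixed = NULL, allow_collinear = FALSE) {
  data <- .align_data(data, tree)
  d <- .build_design(formula, data, allow_collinear)
  y <- as.numeric(d$y)
  if (!all(y %in% c(0, 1))) abort("response must be binary 0/1")
  X <- d$X
  # perfect-separation guard, per numeric column
  for (j in seq_len(ncol(X))[-1]) {
    x0 <- X[y == 0, j]
    x1 <- X[y == 1, j]
    if (length(x0) && length(x1) &&
      (max(x0) < min(x1) || max(x1) < min(x0))) {
      abort(paste0("perfect separation on predictor: ", colnames(X)[j]))
    }
  }
  has_int <- colnames(X)[1] == "(Intercept)"
  ctr <- rep(0, ncol(X))
  scl <- rep(1, ncol(X))
  if (standardize && ncol(X) > has_int) {
    for (j in seq_len(ncol(X))[if (has_int) -1 else TRUE]) {
      s <- sd(X[, j])
      if (s > 0) {
        ctr[j] <- mean(X[, j])
        scl[j] <- s
        X[, j] <- (X[, j] - ctr[j]) / s
      }
    }
  }
  fit_df <- data.frame(.y = y, X[, -1, drop = FALSE], check.names = FALSE)
  safe <- if (ncol(X) > 1) paste0(".x", seq_len(ncol(X) - 1)) else character(0)
  names(fit_df) <- c(".y", safe)
  rownames(fit_df) <- tree$tip.label # binaryPGLMM matches rows to tips by name
  rhs <- if (length(safe)) paste(safe, collapse = " + ") else "1"
  fml <- as.formula(paste(".y ~", rhs))
  if (!is.null(s2_fixed) && s2_fixed == 0) {
    g <- glm(fml, data = fit_df, family = binomial())
    B <- unname(coef(g))
    V <- unname(stats::vcov(g))
    s2 <- 0
    mu <- g$fitted.values
    converged <- g$converged
  } else {
    res <- ape::binaryPGLMM(fml, data = fit_df, phy = tree)
    B <- res$B[, 1]
    V <- res$B.cov
    s2 <- res$s2
    mu <- res$mu[, 1]
    converged <- !isTRUE(res$convergeflag != "converged") ||
      is.null(res$convergeflag)
  }
  # back-transform to the input scale (exact linear reparameterization)
  p <- ncol(X)
  A <- diag(1 / scl, p)
  if (has_int && p > 1) A[1, 2:p] <- -ctr[2:p] / scl[2:p]
  est <- as.vector(A %*% B)
  se <- sqrt(diag(A %*% V %*% t(A)))
  Z <- est / se
  P <- 2 * pnorm(-abs(Z))
  coefs <- tibble::tibble(
    term = colnames(d$X), estimate = est, std_error = se,
    statistic = Z, p_value = P
  )
  names(mu) <- tree$tip.label
  structure(
    list(
      coefficients = coefs, s2 = s2, mu = mu, converged = converged,
      formula = formula, n = length(y), assign = d$assign,
      term_labels = d$term_labels, model = "logistic"
    ),
    class = "phylo_glm_fit"
  )
}

#' @export
print.phylo_glm_fit <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic logistic regression (n = %d, s2 = %.4g)%s\n",
    x$n, x$s2, if (x$converged) "" else " [NOT CONVERGED]"
  ))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' Phylogenetic linear model (GLS under Brownian motion)
#'
#' Generalized least squares with residual covariance `sigma2 * C`, where C
#' is the Brownian-motion phylogenetic covariance scaled to unit height.
#' Log-transforms of the response are applied by the caller. On a star tree
#' this reduces exactly to ordinary least squares.
#'
#' @inheritParams phylo_logistic_fit
#' @return Object of class `phylo_lm_fit`: `coefficients` tibble (t statistic,
#'   p-value on n-p df), `sigma2` (ML), `residual_variance` (unbiased),
#'   `df_residual`, `loglik`, `formula`, `n`.
#' @export
phylo_lm_fit <- function(data, formula, tree, allow_collinear = FALSE) {
  data <- .align_data(data, tree)
  d <- .build_design(formula, data, allow_collinear)
  y <- as.numeric(d$y)
  X <- d$X
  n <- length(y)
  p <- ncol(X)
  C <- phylo_vcv(tree)
  Cinv_chol <- chol(solve(C))
  Xs <- Cinv_chol %*% X
  ys <- Cinv_chol %*% y
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))[, 1]
  r <- ys - Xs %*% beta
  rss <- sum(r^2)
  s2_ml <- rss / n
  s2_hat <- rss / (n - p)
  se <- sqrt(diag(solve(XtX)) * s2_hat)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  ll <- -0.5 * (n * log(2 * pi * s2_ml) + as.numeric(determinant(C)$modulus) + n)
  coefs <- tibble::tibble(
    term = colnames(X), estimate = unname(beta), std_error = unname(se),
    statistic = unname(tval), p_value = unname(pval)
  )
  structure(
    list(
      coefficients = coefs, sigma2 = s2_ml, residual_variance = s2_hat,
      df_residual = n - p, loglik = ll, formula = formula, n = n,
      assign = d$assign, term_labels = d$term_labels, model = "linear",
      converged = TRUE
    ),
    class = "phylo_lm_fit"
  )
}

#' @export
print.phylo_lm_fit <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic linear model (n = %d, residual variance = %.4g)\n",
    x$n, x$residual_variance
  ))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' Phylogenetic two-sample comparison
#'
#' Phylogenetic analogue of the two-sample t-test: a [phylo_lm_fit()] with a
#' group indicator; the phylogenetic mean difference is the indicator
#' coefficient. On a star tree this matches the classic equal-variance
#' two-sample t-test.
#'
#' @param data Data frame with `species`, the response and the group column.
#' @param response,group Column names (strings).
#' @param tree A `phylo` object.
#' @return A one-row tibble: `mean_difference`, `std_error`, `statistic`,
#'   `p_value`, plus the group labels compared.
#' @export
phylo_two_sample <- function(data, response, group, tree) {
  g <- data[[group]]
  lv <- sort(unique(as.character(g)))
  if (length(lv) != 2 || any(table(g) == 0)) abort("group must have exactly 2 non-empty levels")
  d2 <- data.frame(
    species = data$species, .y = data[[response]],
    .g = as.integer(as.character(g) == lv[2])
  )
  fit <- phylo_lm_fit(d2, .y ~ .g, tree)
  row <- fit$coefficients[fit$coefficients$term == ".g", ]
  tibble::tibble(
    mean_difference = row$estimate, std_error = row$std_error,
    statistic = row$statistic, p_value = row$p_value,
    group_low = lv[1], group_high = lv[2]
  )
}

# vectorized one-way ANOVA F statistics for columns of Y
.anova_F <- function(Y, g) {
  g <- as.factor(g)
  n <- nrow(Y)
  k <- nlevels(g)
  G <- stats::model.matrix(~ g - 1)
  ng <- colSums(G)
  gm <- (t(G) %*% Y) / ng
  grand <- colMeans(Y)
  ssb <- colSums(ng * (sweep(gm, 2, grand))^2)
  tot <- colSums(sweep(Y, 2, grand)^2)
  ssw <- tot - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Simulation-based phylogenetic ANOVA
#'
#' Observed F from a standard one-way ANOVA on the tips; the null
#' distribution comes from `nsim` Brownian-motion simulations on the tree
#' with a single rate estimated by ML from the residuals of the group-means
#' GLS model. `p = (1 + #(F_sim >= F_obs)) / (nsim + 1)`.
#'
#' @inheritParams phylo_two_sample
#' @param nsim Number of null simulations (>= 100).
#' @param seed RNG seed (results are deterministic given the seed).
#' @return A one-row tibble: `F_statistic`, `p_phylo`, `sigma2`, `nsim`.
#' @export
phylo_anova <- function(data, response, group, tree, nsim = 1000, seed = 1L) {
  stopifnot(nsim >= 100)
  data <- .align_data(data, tree)
  y <- data[[response]]
  g <- as.factor(data[[group]])
  if (nlevels(g) < 2) abort("need >= 2 groups")
  Fobs <- .anova_F(matrix(y, ncol = 1), g)
  # ML BM rate from GLS residuals of the group model, unscaled C (per Myr)
  C <- ape::vcv(tree)
  X <- stats::model.matrix(~g)
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  sig2 <- as.numeric(t(r) %*% Ci %*% r) / length(y)
  sims <- withr_seed(seed, phytools::fastBM(tree, sig2 = sig2, nsim = nsim))
  Fsim <- .anova_F(sims, g)
  p <- (1 + sum(Fsim >= Fobs)) / (nsim + 1)
  tibble::tibble(F_statistic = Fobs, p_phylo = p, sigma2 = sig2, nsim = nsim)
}

# per-term p-values from a fit's coefficient table (min over a term's columns)
.term_pvalues <- function(fit) {
  tl <- fit$term_labels
  if (length(tl) == 0) {
    return(numeric(0))
  }
  p <- vapply(seq_along(tl), function(i) {
    min(fit$coefficients$p_value[fit$assign == i])
  }, 1)
  names(p) <- tl
  p
}

#' Backward stepwise reduction of a phylogenetic model
#'
#' Repeatedly drops the least-significant droppable term with `p > alpha`;
#' a main effect is never dropped while an interaction containing it remains
#' (hierarchy rule). Ties break toward the larger term index. An
#' intercept-only final model is allowed and flagged.
#'
#' @inheritParams phylo_logistic_fit
#' @param model `"linear"` or `"logistic"`.
#' @param alpha Retention threshold (default 0.05).
#' @param ... Passed to the underlying fit function.
#' @return List with `fit` (the final fit), `formula`, `log` (tibble of
#'   elimination steps), `intercept_only`.
#' @export
stepwise_reduce <- function(data, formula, tree, model = c("linear", "logistic"),
                            alpha = 0.05, ...) {
  model <- match.arg(model)
  stopifnot(alpha > 0, alpha < 1)
  fit_fun <- if (model == "linear") phylo_lm_fit else phylo_logistic_fit
  fml <- formula
  log <- tibble::tibble(step = integer(), dropped = character(), p_value = double())
  step <- 0L
  repeat {
    fit <- fit_fun(data, fml, tree, ...)
    tl <- fit$term_labels
    if (length(tl) == 0) break
    tt <- terms(fml)
    fac <- attr(tt, "factors")
    ord <- attr(tt, "order")
    # a term is droppable if no retained higher-order term contains it
    droppable <- vapply(seq_along(tl), function(i) {
      if (ord[i] == max(ord)) {
        return(TRUE)
      }
      vars_i <- rownames(fac)[fac[, i] > 0]
      !any(vapply(seq_along(tl), function(j) {
        j != i && ord[j] > ord[i] && all(vars_i %in% rownames(fac)[fac[, j] > 0])
      }, TRUE))
    }, TRUE)
    pvals <- .term_pvalues(fit)
    cand <- which(droppable & pvals > alpha)
    if (length(cand) == 0) break
    # drop highest p; ties toward larger index
    worst <- cand[order(-pvals[cand], -cand)][1]
    step <- step + 1L
    log <- dplyr::bind_rows(log, tibble::tibble(
      step = step, dropped = tl[worst], p_value = unname(pvals[worst])
    ))
    remaining <- tl[-worst]
    rhs <- if (length(remaining) == 0) "1" else paste(remaining, collapse = " + ")
    fml <- as.formula(paste(deparse(fml[[2]]), "~", rhs))
  }
  intercept_only <- length(fit$term_labels) == 0
  if (intercept_only) warn("stepwise reduction removed all terms (intercept-only model)")
  list(fit = fit, formula = fml, log = log, intercept_only = intercept_only)
}

#' Single-occurrence resampling of a phylogenetic logistic model
#'
#' Repeatedly samples one occurrence record per species, rebuilds the
#' species-level predictors from that single record, refits the phylogenetic
#' logistic regression, and records the focal term's p-value; reports the
#' percentage of iterations with `p < 0.05`. Failed iterations are tallied,
#' never silently dropped.
#'
#' @param records Occurrence tibble (one row per record, `species` column).
#' @param response Named binary vector (species -> 0/1).
#' @param formula Model formula on record columns, e.g.
#'   `shifted ~ elevation_m`.
#' @param tree A `phylo` object.
#' @param term Focal term whose p-value is tracked (default the first).
#' @param n_iter Number of resampling iterations (>= 1).
#' @param seed RNG seed.
#' @param ... Passed to [phylo_logistic_fit()].
#' @return Object of class `resampling_result`: `percent_significant`,
#'   `n_failed`, `iterations` tibble (iter, estimate, p_value, significant).
#' @export
occurrence_resampling <- function(records, response, formula, tree,
                                  term = NULL, n_iter = 100, seed = 1L, ...) {
  stopifnot(n_iter >= 1)
  sp <- tree$tip.label
  miss <- setdiff(sp, unique(records$species))
  if (length(miss)) abort(paste0("species without records: ", paste(head(miss, 10), collapse = ", ")))
  recs <- split(records, records$species)
  if (is.null(term)) term <- all.vars(formula[[3]])[1]
  resp_col <- deparse(formula[[2]])
  rows <- withr_seed(seed, {
    purrr::map_dfr(seq_len(n_iter), function(it) {
      one <- purrr::map_dfr(sp, function(s) {
        ri <- recs[[s]]
        ri[sample.int(nrow(ri), 1), , drop = FALSE]
      })
      one[[resp_col]] <- as.numeric(response[one$species])
      fit <- tryCatch(
        phylo_logistic_fit(one, formula, tree, ...),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(tibble::tibble(
          iter = it, estimate = NA_real_, p_value = NA_real_,
          significant = NA, failed = TRUE
        ))
      }
      i <- match(term, fit$term_labels)
      pv <- min(fit$coefficients$p_value[fit$assign == i])
      est <- fit$coefficients$estimate[fit$assign == i][1]
      tibble::tibble(
        iter = it, estimate = est, p_value = pv,
        significant = pv < 0.05, failed = FALSE
      )
    })
  })
  ok <- !rows$failed
  structure(
    list(
      percent_significant = 100 * sum(rows$significant[ok]) / sum(ok),
      n_failed = sum(rows$failed),
      n_iter = n_iter,
      term = term,
      iterations = rows
    ),
    class = "resampling_result"
  )
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "Occurrence resampling: %.1f%% of %d iterations significant for '%s' (%d failed)\n",
    x$percent_significant, x$n_iter, x$term, x$n_failed
  ))
  invisible(x)
}
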