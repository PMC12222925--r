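#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.marginal_asr <- function(x, ...) {
  probs <- tibble::as_tibble(x$prob)
  names(probs) <- paste0("p_", x$states)
  dplyr::bind_cols(
    tibble::tibble(
      node = seq_len(nrow(x$prob)),
      is_tip = seq_len(nrow(x$prob)) <= x$ntip,
      age_myr = x$age_myr
    ),
    probs
  )
}

#' @exportS3Method generics::glance
glance.marginal_asr <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, n_states = length(x$states), n_tips = x$ntip
  )
}

#' @exportS3Method generics::tidy
tidy.mk_fit <- function(x, ...) {
  k <- nrow(x$Q)
  idx <- which(x$rate_scheme$par_index > 0, arr.ind = TRUE)
  tibble::tibble(
    from = x$states[idx[, 1]], to = x$states[idx[, 2]],
    rate = x$Q[idx]
  )
}

#' @exportS3Method generics::glance
glance.mk_fit <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, loglik = x$loglik, AIC = x$AIC,
    n_free = x$n_free, converged = x$converged
  )
}

#' @exportS3Method generics::tidy
tidy.phylo_glm_fit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.phylo_glm_fit <- function(x, ...) {
  tibble::tibble(s2 = x$s2, n = x$n, converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.phylo_lm_fit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.phylo_lm_fit <- function(x, ...) {
  tibble::tibble(
    sigma2 = x$sigma2, residual_variance = x$residual_variance,
    df_residual = x$df_residual, loglik = x$loglik, n = x$n
  )
}

#' @exportS3Method generics::tidy
tidy.correlation_test <- function(x, ...) {
  tibble::tibble(
    model = c("independent", "dependent"),
    loglik = c(x$loglik_indep, x$loglik_dep),
    n_free = c(x$n_free_indep, x$n_free_dep),
    AIC = c(x$AIC_indep, x$AIC_dep)
  )
}

#' @exportS3Method generics::glance
glance.correlation_test <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict, delta_AIC = x$AIC_dep - x$AIC_indep
  )
}

#' @exportS3Method generics::tidy
tidy.scenario_report <- function(x, ...) x$lineages

#' @exportS3Method generics::glance
glance.scenario_report <- function(x, ...) x$verdicts

#' @exportS3Method generics::tidy
tidy.biome_chisq <- function(x, ...) {
  res <- as.data.frame(as.table(x$stdres))
  names(res) <- c("group", "biome", "stdres")
  obs <- as.data.frame(as.table(x$table))
  res$count <- obs$Freq
  res$flagged <- abs(res$stdres) > 2
  tibble::as_tibble(res)
}

#' @exportS3Method generics::glance
glance.biome_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}
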