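#' Combine two discrete characters into a product-space character
#' @param states_A,states_B Named state vectors on the same species.
#' @param levels_A,levels_B Optional explicit state orderings.
#' @return Named factor of joint states `"a.b"`, levels crossing A (slow)
#'   by B (fast).
#' @export
combine_characters <- function(states_A, states_B, levels_A = NULL, levels_B = NULL) {
  sp <- intersect(names(states_A), names(states_B))
  if (length(sp) == 0) abort("characters share no species")
  a <- as.character(states_A[sp])
  b <- as.character(states_B[sp])
  if (is.null(levels_A)) levels_A <- if (is.factor(states_A)) levels(states_A) else sort(unique(a))
  if (is.null(levels_B)) levels_B <- if (is.factor(states_B)) levels(states_B) else sort(unique(b))
  lv <- as.vector(t(outer(levels_A, levels_B, paste, sep = ".")))
  out <- factor(paste(a, b, sep = "."), levels = lv)
  names(out) <- sp
  out
}

# mask of product-space transitions that change both characters at once
dual_change_mask <- function(kA, kB) {
  idx <- expand.grid(a = seq_len(kA), b = seq_len(kB))
  s <- function(a, b) (a - 1) * kB + b
  out <- NULL
  for (i in seq_len(nrow(idx))) {
    for (j in seq_len(nrow(idx))) {
      if (i == j) next
      if (idx$a[i] != idx$a[j] && idx$b[i] != idx$b[j]) {
        out <- rbind(out, c(s(idx$a[i], idx$b[i]), s(idx$a[j], idx$b[j])))
      }
    }
  }
  out
}

#' Embed two independent rate matrices in the product state space
#'
#' `Q = QA (x) I + I (x) QB` (Kronecker sums), the product-space generator of
#' two independently evolving characters.
#'
#' @param QA,QB Component rate matrices.
#' @return The (kA*kB) x (kA*kB) product generator.
#' @export
embed_independent_Q <- function(QA, QB) {
  kA <- nrow(QA)
  kB <- nrow(QB)
  kronecker(QA, diag(kB)) + kronecker(diag(kA), QB)
}

#' Test for correlated evolution of two discrete characters
#'
#' Compares an independent model (two separate Mk fits; log-likelihoods and
#' parameter counts add) against a dependent model: an Mk fit on the product
#' state space with all-rates-different transitions except structural zeros
#' forbidding simultaneous change of both characters. The verdict is the
#' model with the lower AIC.
#'
#' @param tree A `phylo` object.
#' @param states_A,states_B Named state vectors (>= 2 states each).
#' @param scheme Scheme for the component fits (`"ARD"` or `"SYM"`).
#' @param root_prior Root prior for all fits.
#' @param ... Passed to [fit_mk()].
#' @return An object of class `correlation_test`: list with `loglik_indep`,
#'   `AIC_indep`, `loglik_dep`, `AIC_dep`, `verdict` (`"independent"` or
#'   `"dependent"`), `fit_A`, `fit_B`, `fit_dep`.
#' @export
correlation_test <- function(tree, states_A, states_B, scheme = "ARD",
                             root_prior = "fitzjohn", ...) {
  lvA <- if (is.factor(states_A)) levels(states_A) else sort(unique(as.character(na.omit(states_A))))
  lvB <- if (is.factor(states_B)) levels(states_B) else sort(unique(as.character(na.omit(states_B))))
  kA <- length(lvA)
  kB <- length(lvB)
  if (kA < 2 || kB < 2) abort("both characters need >= 2 states")
  if (kA * kB > 16) {
    abort("product state space exceeds 16 states; binarize the characters first")
  }
  fit_A <- fit_mk(tree, states_A, scheme = scheme, root_prior = root_prior, states = lvA, ...)
  fit_B <- fit_mk(tree, states_B, scheme = scheme, root_prior = root_prior, states = lvB, ...)
  joint <- combine_characters(states_A, states_B, lvA, lvB)
  mask <- dual_change_mask(kA, kB)
  dep_scheme <- make_rate_scheme(kA * kB, "CONSTRAINED", mask = mask, states = levels(joint))
  fit_dep <- fit_mk(tree, joint,
    scheme = dep_scheme, root_prior = root_prior,
    states = levels(joint), ...
  )
  ll_i <- fit_A$loglik + fit_B$loglik
  aic_i <- 2 * (fit_A$n_free + fit_B$n_free) - 2 * ll_i
  structure(
    list(
      loglik_indep = ll_i, AIC_indep = aic_i,
      loglik_dep = fit_dep$loglik, AIC_dep = fit_dep$AIC,
      n_free_indep = fit_A$n_free + fit_B$n_free, n_free_dep = fit_dep$n_free,
      verdict = if (aic_i <= fit_dep$AIC) "independent" else "dependent",
      fit_A = fit_A, fit_B = fit_B, fit_dep = fit_dep
    ),
    class = "correlation_test"
  )
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf(
    "Correlated evolution test\n  independent: logL = %.4f, AIC = %.4f (%d par)\n  dependent:   logL = %.4f, AIC = %.4f (%d par)\n  verdict: %s\n",
    x$loglik_indep, x$AIC_indep, x$n_free_indep,
    x$loglik_dep, x$AIC_dep, x$n_free_dep, x$verdict
  ))
  invisible(x)
}
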