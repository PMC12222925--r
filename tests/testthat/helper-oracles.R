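# Independent oracles and fixture builders shared across the suite.

# Brute-force Mk likelihood and marginal ancestral probabilities by summing
# over every joint assignment of internal states (tiny trees only).
# Independent of the package's pruning code: transition matrices come from
# Matrix::expm and the sum is explicit.
brute_force_mk <- function(tree, tip_states_int, Q, prior) {
  k <- nrow(Q)
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  internals <- (n + 1):N
  combs <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  marg <- matrix(0, N, k)
  tot <- 0
  st <- rep(NA_integer_, N)
  st[seq_len(n)] <- tip_states_int
  root <- n + 1
  for (r in seq_len(nrow(combs))) {
    st[internals] <- combs[r, ]
    pr <- prior[st[root]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    tot <- tot + pr
    for (v in seq_len(N)) marg[v, st[v]] <- marg[v, st[v]] + pr
  }
  list(marginal = marg / tot, loglik = log(tot))
}

# random k-state rate matrix with all transitions allowed
random_Q <- function(k, lo = 0.05, hi = 1) {
  Q <- matrix(runif(k * k, lo, hi), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# named factor of random tip states
random_states <- function(tree, k) {
  s <- sample(letters[seq_len(k)], ape::Ntip(tree), replace = TRUE)
  setNames(factor(s, letters[seq_len(k)]), tree$tip.label)
}

# Closed-form constant-rate birth-death log-likelihood on a dated tree
# (sampling fraction 1, no survival conditioning, uniform/no root prior):
# along a branch D(t2) = D(t1) e^{-r dt} ((1-E(t2))/(1-E(t1)))^2 with
# E(t) = mu (e^{rt}-1) / (lambda e^{rt} - mu), plus log(lambda) per
# internal branching event.
bd_loglik_closed_form <- function(tree, lambda, mu) {
  r <- lambda - mu
  Et <- function(t) mu * (exp(r * t) - 1) / (lambda * exp(r * t) - mu)
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  ll <- 0
  for (e in seq_len(nrow(tree$edge))) {
    t1 <- age[tree$edge[e, 2]]
    t2 <- age[tree$edge[e, 1]]
    ll <- ll - r * (t2 - t1) + 2 * (log(1 - Et(t2)) - log(1 - Et(t1)))
  }
  ll + (ape::Ntip(tree) - 1) * log(lambda)
}

# star tree with unit branch lengths (C = I after scaling)
star_tree <- function(n) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("s", seq_len(n))
  tr
}

# hand-built marginal_asr object (for scenario toys)
manual_asr <- function(prob, ages, states) {
  colnames(prob) <- states
  structure(
    list(
      prob = prob, age_myr = ages, states = states,
      loglik = NA_real_, ntip = NA_integer_
    ),
    class = "marginal_asr"
  )
}
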