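#' Ancestral reconstruction of a continuous trait under Brownian motion
#'
#' Maximum-likelihood (GLS) ancestral values computed by Gaussian message
#' passing on the tree: a pruning pass combines tip values into
#' precision-weighted means, and a preorder pass supplies the
#' rest-of-tree message, so each node's estimate equals the rerooted weighted
#' average. Handles polytomies natively. On a two-tip cherry with values
#' v1, v2 and branch lengths t1, t2 the root estimate is
#' `(v1/t1 + v2/t2) / (1/t1 + 1/t2)`.
#'
#' @param tree A `phylo` object.
#' @param tip_values Named numeric vector (species -> value), finite at all
#'   tips.
#' @return A tibble with columns `node`, `age_myr`, `estimate`; tips first
#'   (their observed values), then internal nodes. The root estimate is the
#'   row with `node == ape::Ntip(tree) + 1`.
#' @export
bm_asr_continuous <- function(tree, tip_values) {
  n <- ape::Ntip(tree)
  if (n < 2) abort("need at least 2 tips")
  x <- tip_values[tree$tip.label]
  if (any(!is.finite(x))) abort("tip values must be finite for all tips")
  tr <- reorder(tree, "postorder")
  N <- n + tr$Nnode
  m_down <- rep(NA_real_, N)
  v_down <- rep(NA_real_, N)
  m_down[seq_len(n)] <- x
  v_down[seq_len(n)] <- 0
  prec <- rep(0, N) # accumulated precision at internal nodes
  wsum <- rep(0, N) # accumulated precision-weighted mean
  edges <- tr$edge
  elen <- tr$edge.length
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]
    c_ <- edges[e, 2]
    if (is.na(m_down[c_])) { # internal child: all its edges already seen
      m_down[c_] <- wsum[c_] / prec[c_]
      v_down[c_] <- 1 / prec[c_]
    }
    w <- 1 / (v_down[c_] + elen[e])
    prec[p] <- prec[p] + w
    wsum[p] <- wsum[p] + w * m_down[c_]
  }
  internal <- setdiff(seq_len(N), seq_len(n))
  root0 <- edges[nrow(edges), 1]
  m_down[root0] <- wsum[root0] / prec[root0]
  v_down[root0] <- 1 / prec[root0]

  # up messages, preorder = reverse postorder
  m_up <- rep(NA_real_, N)
  v_up <- rep(NA_real_, N)
  root <- edges[nrow(edges), 1]
  m_up[root] <- NA
  v_up[root] <- Inf # flat: no information from above the root
  for (e in rev(seq_len(nrow(edges)))) {
    p <- edges[e, 1]
    c_ <- edges[e, 2]
    # combine at p: everything except the message from c_
    w_c <- 1 / (v_down[c_] + elen[e])
    pr <- prec[p] - w_c + (if (is.finite(v_up[p])) 1 / v_up[p] else 0)
    ws <- wsum[p] - w_c * m_down[c_] +
      (if (is.finite(v_up[p])) m_up[p] / v_up[p] else 0)
    if (pr <= 0) {
      m_up[c_] <- NA
      v_up[c_] <- Inf
    } else {
      m_up[c_] <- ws / pr
      v_up[c_] <- 1 / pr + elen[e]
    }
  }

  est <- rep(NA_real_, N)
  est[seq_len(n)] <- x
  for (v in internal) {
    if (is.finite(v_up[v])) {
      w1 <- if (v_down[v] > 0) 1 / v_down[v] else Inf
      w2 <- 1 / v_up[v]
      est[v] <- if (is.infinite(w1)) m_down[v] else (w1 * m_down[v] + w2 * m_up[v]) / (w1 + w2)
    } else {
      est[v] <- m_down[v]
    }
  }
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth[seq_len(n)]) - depth
  tibble::tibble(node = seq_len(N), age_myr = ages, estimate = est)
}
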