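#' Marginal ancestral state reconstruction
#'
#' For each internal node and state `i`, the subtree likelihood at the node
#' is restricted to state `i` and propagated to the root along the node's
#' path, re-using the stored branch-top vectors of the off-path subtrees.
#' The resulting per-state root likelihoods, normalized, are the marginal
#' posterior state probabilities of the node under the supplied rates.
#'
#' @inheritParams sse_loglik
#' @return Matrix of `tree$Nnode` rows (internal nodes in ape numbering,
#'   root in the first row) by `n_states` columns; rows sum to 1.
#' @export
asr_marginal <- function(tree, states, rates, sampling_f = 1,
                         root = c("fixed", "weights"), root_state = 0,
                         root_weights = NULL, rtol = 1e-8, atol = 1e-10) {
  root <- match.arg(root)
  fit <- sse_loglik(tree, states, rates, sampling_f, root, root_state,
                    root_weights, condition_surv = FALSE, rtol = rtol,
                    atol = atol, details = TRUE)
  if (!is.finite(fit$loglik))
    stop("log-likelihood is not finite; cannot reconstruct states")
  n <- rates$n_states
  edge <- fit$edge
  len <- fit$edge.length
  n_tip <- length(tree$tip.label)
  root_id <- fit$root
  parent_edge <- integer(max(edge))
  parent_edge[edge[, 2]] <- seq_len(nrow(edge))

  internal <- root_id:(n_tip + tree$Nnode)
  labs <- if (!is.null(rates$state_space)) rates$state_space$labels else NULL
  out <- matrix(0, length(internal), n, dimnames = list(internal, labs))

  for (m in internal) {
    loglik_i <- rep(-Inf, n)
    for (i in which(fit$nodeD[m, ] > 0)) {
      loglik_i[i] <- clamped_loglik(fit, rates, m, i, root_id, parent_edge,
                                    edge, len, rtol, atol)
    }
    top <- max(loglik_i)
    if (!is.finite(top)) stop("zero marginal likelihood at node ", m)
    w <- exp(loglik_i - top)
    out[as.character(m), ] <- w / sum(w)
  }
  out
}

# log-likelihood (up to a constant common to all states of node m) of the
# tree with node m's subtree vector clamped to state i
clamped_loglik <- function(fit, rates, m, i, root_id, parent_edge, edge,
                           len, rtol, atol) {
  n <- rates$n_states
  v <- numeric(n)
  v[i] <- fit$nodeD[m, i]
  logc <- 0
  cur <- m
  while (cur != root_id) {
    e <- parent_edge[cur]
    top <- sse_branch_cpp(v, fit$nodeE[cur, ], rates$lambda, rates$mu,
                          rates$Q, len[e], rtol, atol)
    if (!top$ok) stop("branch integration failed during reconstruction")
    p <- edge[e, 1]
    sib <- setdiff(which(edge[, 1] == p), e)
    v <- node_lambda(rates) * top$D * fit$branchTopD[sib, ]
    s <- sum(v)
    if (s <= 0) return(-Inf)
    v <- v / s
    logc <- logc + log(s)
    cur <- p
  }
  val <- sum(fit$root_weights * v)
  if (val <= 0) return(-Inf)
  log(val) + logc
}
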