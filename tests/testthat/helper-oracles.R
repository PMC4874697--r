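# Independent oracles used across the suite.  None of these share code with
# the package's pruning path: the Mk oracle uses dense matrix exponentials
# (ape::matexpo), the brute-force SSE oracle integrates the coupled D/E
# system with deSolve::lsoda, and the Yule and two-state stationary values
# are closed forms.

# Mk (pure character change) pruning log-likelihood via matrix exponentials,
# fixed root state, complete sampling.  Optionally clamps one internal node
# to a given state (for checking marginal reconstructions).
mk_loglik_expm <- function(tree, states, Q, root_state, clamp_node = NULL,
                           clamp_state = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- nrow(Q)
  ntip <- length(tree$tip.label)
  L <- matrix(0, ntip + tree$Nnode, n)
  for (i in seq_len(ntip)) L[i, states[tree$tip.label[i]] + 1L] <- 1
  seen <- integer(ntip + tree$Nnode)
  logcomp <- 0
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    if (!is.null(clamp_node) && ch == clamp_node) {
      keep <- L[ch, clamp_state + 1L]
      L[ch, ] <- 0
      L[ch, clamp_state + 1L] <- keep
    }
    P <- ape::matexpo(Q * tree$edge.length[e])
    up <- as.vector(P %*% L[ch, ])
    if (seen[p] == 0L) L[p, ] <- up else L[p, ] <- L[p, ] * up
    seen[p] <- seen[p] + 1L
    s <- sum(L[p, ])
    if (s <= 0) return(-Inf)
    L[p, ] <- L[p, ] / s
    logcomp <- logcomp + log(s)
  }
  root <- ntip + 1L
  if (!is.null(clamp_node) && root == clamp_node) {
    keep <- L[root, clamp_state + 1L]
    L[root, ] <- 0
    L[root, clamp_state + 1L] <- keep
  }
  val <- L[root, root_state + 1L]
  if (val <= 0) return(-Inf)
  log(val) + logcomp
}

# Mk marginal ancestral reconstruction by clamping each internal node in
# turn (expm oracle, brute force).
mk_asr_expm <- function(tree, states, Q, root_state) {
  ntip <- length(tree$tip.label)
  n <- nrow(Q)
  nodes <- ntip + seq_len(tree$Nnode)
  out <- matrix(0, length(nodes), n)
  for (k in seq_along(nodes)) {
    ll <- vapply(seq_len(n) - 1L, function(s)
      mk_loglik_expm(tree, states, Q, root_state, clamp_node = nodes[k],
                     clamp_state = s), numeric(1L))
    w <- exp(ll - max(ll[is.finite(ll)]))
    w[!is.finite(w)] <- 0
    out[k, ] <- w / sum(w)
  }
  out
}

# Brute-force SSE log-likelihood: pruning with per-branch lsoda integration
# of the coupled D/E equations at tight tolerance, no rescaling.
sse_loglik_desolve <- function(tree, states, rs, f, root_state) {
  n <- rs$n_states
  deriv <- function(t, y, p) {
    E <- y[1:n]
    D <- y[(n + 1):(2 * n)]
    dE <- rs$mu - (rs$lambda + rs$mu) * E + rs$lambda * E^2 +
      as.vector(rs$Q %*% E)
    dD <- -(rs$lambda + rs$mu) * D + 2 * rs$lambda * D * E +
      as.vector(rs$Q %*% D)
    list(c(dE, dD))
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  vals <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    D <- numeric(n)
    D[states[tree$tip.label[i]] + 1L] <- f
    vals[[i]] <- list(D = D, E = rep(1 - f, n))
  }
  seen <- integer(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    y0 <- c(vals[[ch]]$E, vals[[ch]]$D)
    sol <- deSolve::lsoda(y0, c(0, tree$edge.length[e]), deriv, NULL,
                          rtol = 1e-11, atol = 1e-13)
    yy <- sol[2L, -1L]
    up <- list(E = yy[1:n], D = yy[(n + 1):(2 * n)])
    if (seen[p] == 0L) vals[[p]] <- up
    else vals[[p]] <- list(D = rs$lambda * vals[[p]]$D * up$D, E = up$E)
    seen[p] <- seen[p] + 1L
  }
  unname(log(vals[[ntip + 1L]]$D[root_state + 1L]))
}

# Yule (pure birth, single state) log-likelihood for a labeled history with
# the root state fixed: one lambda factor per internal node, exponential
# survival along every branch.
yule_loglik <- function(tree, lambda) {
  (length(tree$tip.label) - 1L) * log(lambda) -
    lambda * sum(tree$edge.length)
}

# Dominant eigenpair of the two-set mean-growth matrix solved from the
# characteristic polynomial (independent of base::eigen).
two_state_equilibrium <- function(r_F, r_N, q_FN, q_NF) {
  # A acts on (n_N, n_F) with A11 = r_N - q_NF, A22 = r_F - q_FN
  a11 <- r_N - q_NF
  a22 <- r_F - q_FN
  a12 <- q_FN
  a21 <- q_NF
  tr <- a11 + a22
  det <- a11 * a22 - a12 * a21
  ev <- (tr + sqrt(tr^2 - 4 * det)) / 2
  v_N <- a12
  v_F <- ev - a11
  list(eigenvalue = ev, focal_freq = v_F / (v_F + v_N))
}

# random ultrametric test tree with depth scaled to `depth`
random_tree <- function(n_tip, depth) {
  tr <- ape::rcoal(n_tip)
  tr$edge.length <- tr$edge.length * depth /
    max(ape::node.depth.edgelength(tr))
  tr
}
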