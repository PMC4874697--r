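#' Tip initial conditions under state-specific sampling
#'
#' An extant species in state `i` is included in the tree with probability
#' `f[i]`.  A scored tip therefore starts with `D[i] = f[i]` at its observed
#' state and 0 elsewhere, and `E[i] = 1 - f[i]` for every state; a tip with
#' missing state starts with `D[i] = f[i]` for all states.
#'
#' @param state Observed state index (0-based) or `NA` for missing.
#' @param sampling_f Per-state sampling fractions in (0, 1]; recycled to
#'   `n_states` if scalar.
#' @param n_states Number of states.
#' @return List with numeric vectors `D` and `E` of length `n_states`.
#' @export
tip_init <- function(state, sampling_f, n_states) {
  f <- rep_len(sampling_f, n_states)
  if (any(f <= 0) || any(f > 1))
    stop("sampling fractions must be in (0, 1]")
  D <- if (is.na(state)) f else {
    if (state < 0 || state >= n_states) stop("state index out of range")
    d <- numeric(n_states)
    d[state + 1L] <- f[state + 1L]
    d
  }
  list(D = D, E = 1 - f)
}

#' Propagate D and E along a branch
#'
#' Integrates the coupled SSE ordinary differential equations
#' `dE_i/dt = mu_i - (lambda_i + mu_i) E_i + lambda_i E_i^2 + sum_j Q_ij E_j`
#' and
#' `dD_i/dt = -(lambda_i + mu_i) D_i + 2 lambda_i D_i E_i + sum_j Q_ij D_j`
#' from the tipward end of a branch to its rootward end.
#'
#' @param D,E Numeric vectors at the tipward end.
#' @param rates A [rateset()].
#' @param duration Branch length (Myr), `>= 0`.
#' @param rtol,atol Integrator tolerances.
#' @return List with `D` and `E` at the rootward end.
#' @export
integrate_branch <- function(D, E, rates, duration, rtol = 1e-8,
                             atol = 1e-10) {
  stopifnot(length(D) == rates$n_states, length(E) == rates$n_states)
  if (duration < 0) stop("duration must be >= 0")
  if (duration == 0) return(list(D = D, E = E))
  out <- sse_branch_cpp(D, E, rates$lambda, rates$mu, rates$Q, duration,
                        rtol, atol)
  if (!out$ok) stop("branch integration failed to reach tolerance")
  list(D = out$D, E = out$E)
}

#' Combine daughter likelihoods at a node
#'
#' Speciation at an internal node contributes `lambda_i * D_left_i *
#' D_right_i`.  When every speciation rate is zero the process degenerates
#' to a pure character model, and the vanishing speciation factors are
#' omitted so the likelihood reduces to the Mk pruning likelihood.
#'
#' @param D_left,D_right Branch-top D vectors of the two daughters.
#' @param rates A [rateset()].
#' @return Combined D vector at the node.
#' @export
combine_node <- function(D_left, D_right, rates) {
  node_lambda(rates) * D_left * D_right
}

node_lambda <- function(rates) {
  if (all(rates$lambda == 0)) rep(1, rates$n_states) else rates$lambda
}

prepare_tip_states <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  if (!is.null(names(states))) {
    miss <- setdiff(tree$tip.label, names(states))
    if (length(miss) > 0)
      stop("tips without a state entry: ", paste(head(miss, 5),
                                                 collapse = ", "))
    states <- states[tree$tip.label]
  } else if (length(states) != n_tip) {
    stop("`states` must be named by tip label or match the tip count")
  }
  as.integer(states)
}

#' MuSSE-type log-likelihood on a time-calibrated tree
#'
#' Felsenstein pruning with the SSE branch equations: tips are initialized
#' from their observed combination state and the per-state sampling
#' fractions, D/E are integrated along each branch, daughters are combined
#' with the per-state speciation rates, and D is renormalized at every node
#' with log-compensation.  The root is handled either by fixing the root
#' state (the all-ancestral combination in the study design) or by a given
#' weight vector.  Grouping states into sets never alters the underlying
#' data, so log-likelihoods are comparable across all bipartitions and
#' models fitted to the same tree and character matrix.
#'
#' @param tree An `ape::phylo`, rooted and bifurcating.
#' @param states Integer vector of 0-based state indices, named by tip label
#'   (or in `tree$tip.label` order); `NA` = missing.
#' @param rates A [rateset()].
#' @param sampling_f Per-state sampling fractions in (0, 1]; scalar or
#'   length `n_states`.
#' @param root `"fixed"` (default) or `"weights"`.
#' @param root_state 0-based root state when `root = "fixed"`.
#' @param root_weights Probability vector over states when
#'   `root = "weights"`.
#' @param condition_surv Condition the likelihood on survival of the two
#'   root lineages (off by default).
#' @param rtol,atol Integrator tolerances.
#' @param details Also return root vectors and per-node quantities.
#' @return The log-likelihood, or (with `details = TRUE`) a list with
#'   `loglik`, `rootD`, `rootE` and the internal pruning tables.
#' @export
sse_loglik <- function(tree, states, rates, sampling_f = 1,
                       root = c("fixed", "weights"), root_state = 0,
                       root_weights = NULL, condition_surv = FALSE,
                       rtol = 1e-8, atol = 1e-10, details = FALSE) {
  root <- match.arg(root)
  n <- rates$n_states
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape phylo object")
  if (!ape::is.binary(tree)) stop("`tree` must be fully bifurcating")
  states <- prepare_tip_states(tree, states)
  if (any(states < 0 | states >= n, na.rm = TRUE))
    stop("tip state index out of range")

  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  f <- rep_len(sampling_f, n)
  if (any(f <= 0) || any(f > 1))
    stop("sampling fractions must be in (0, 1]")

  tipD <- matrix(0, n_tip, n)
  for (i in seq_len(n_tip)) {
    tipD[i, ] <- tip_init(states[i], f, n)$D
  }

  w <- root_weight_vector(root, root_state, root_weights, n)

  pr <- sse_prune_cpp(tree$edge, tree$edge.length, n_tip, tipD, 1 - f,
                      rates$lambda, rates$mu, rates$Q,
                      node_lambda(rates), rtol, atol)
  if (!is.null(pr$loglik) && identical(pr$loglik, -Inf)) {
    warning("likelihood underflowed to zero; returning -Inf")
    return(if (details) list(loglik = -Inf) else -Inf)
  }
  lik_root <- sum(w * pr$rootD)
  ll <- if (lik_root > 0) log(lik_root) + pr$logcomp else -Inf
  if (ll == -Inf)
    warning("root state has zero likelihood mass")
  if (condition_surv && is.finite(ll)) {
    cond <- sum(w * rates$lambda * (1 - pr$rootE)^2)
    ll <- ll - log(cond)
  }
  if (!details) return(ll)
  list(loglik = ll, rootD = pr$rootD, rootE = pr$rootE,
       logcomp = pr$logcomp, root = pr$root, nodeD = pr$nodeD,
       nodeE = pr$nodeE, branchTopD = pr$branchTopD,
       edge = tree$edge, edge.length = tree$edge.length,
       root_weights = w)
}

root_weight_vector <- function(root, root_state, root_weights, n) {
  if (root == "fixed") {
    if (root_state < 0 || root_state >= n) stop("root state out of range")
    w <- numeric(n)
    w[root_state + 1L] <- 1
    w
  } else {
    if (is.null(root_weights) || length(root_weights) != n)
      stop("`root_weights` must have one entry per state")
    if (abs(sum(root_weights) - 1) > 1e-8)
      stop("root weights must sum to 1")
    as.numeric(root_weights)
  }
}
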