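#' Simulate a state-dependent birth-death tree
#'
#' Exact (Gillespie) simulation: at every instant each lineage may speciate,
#' go extinct, or change state along a hypercube edge, with exponential
#' waiting times and event probabilities proportional to the per-state
#' rates.  The process starts from a single lineage in `root_state` and
#' runs for `duration` Myr.  Randomness comes from R's RNG, so a fixed
#' `set.seed()` gives bit-identical trees.
#'
#' @param rates A [rateset()].
#' @param root_state 0-based state of the founding lineage.
#' @param duration Simulation horizon (Myr).
#' @param max_lineages Cap on simultaneously living lineages; exceeding it
#'   stops the simulation with `truncated = TRUE`.
#' @return An object of class `sse_sim`: list with `tree` (an `ape::phylo`
#'   with a stem `root.edge`, or `NULL` when the founding lineage never
#'   speciated), `tip_states` (0-based, named by tip label), `alive`
#'   (named logical), `n_extant`, `extinct`, `truncated`, `duration` and
#'   `lineages` (a data frame of all lineage segments).
#' @export
simulate_tree <- function(rates, root_state = 0, duration,
                          max_lineages = 5e5) {
  if (duration <= 0) stop("duration must be > 0")
  if (root_state < 0 || root_state >= rates$n_states)
    stop("root state out of range")
  raw <- sim_tree_cpp(rates$lambda, rates$mu, rates$Q, as.integer(root_state),
                      duration, as.integer(max_lineages))
  lineages <- data.frame(
    id = seq_along(raw$parent), parent = raw$parent, t_start = raw$t_start,
    t_end = raw$t_end, n_children = raw$n_children, state = raw$state,
    alive = raw$alive)
  if (raw$truncated)
    warning("lineage cap reached at t = ", signif(raw$t_stop, 4),
            "; tree truncated")

  tip_rows <- which(lineages$n_children == 0L)
  out <- list(tree = NULL, tip_states = NULL, alive = NULL,
              n_extant = raw$n_extant, extinct = raw$extinct,
              truncated = raw$truncated, duration = duration,
              lineages = lineages)
  if (length(tip_rows) >= 2L) {
    out[c("tree", "tip_states", "alive")] <-
      lineages_to_phylo(lineages, tip_rows)
  } else {
    out$tip_states <- setNames(lineages$state[tip_rows],
                               paste0("t", tip_rows))
    out$alive <- setNames(lineages$alive[tip_rows], paste0("t", tip_rows))
  }
  structure(out, class = "sse_sim")
}

#' @export
print.sse_sim <- function(x, ...) {
  cat(sprintf(
    "SSE simulation: %d lineage segments, %d extant tips over %.4g Myr%s\n",
    nrow(x$lineages), x$n_extant, x$duration,
    if (x$truncated) " (truncated)" else if (x$extinct) " (extinct)" else ""))
  invisible(x)
}

# Each lineage segment is one edge; a segment ending in speciation is an
# internal node, any other ending is a tip.
lineages_to_phylo <- function(lineages, tip_rows) {
  int_rows <- which(lineages$n_children == 2L)
  n_tip <- length(tip_rows)
  node_num <- integer(nrow(lineages))
  node_num[tip_rows] <- seq_len(n_tip)
  root_row <- which(lineages$parent == 0L)
  stopifnot(length(root_row) == 1L, root_row %in% int_rows)
  node_num[root_row] <- n_tip + 1L
  rest <- setdiff(int_rows, root_row)
  node_num[rest] <- n_tip + 1L + seq_along(rest)

  child_rows <- which(lineages$parent != 0L)
  edge <- cbind(node_num[lineages$parent[child_rows]], node_num[child_rows])
  edge_length <- lineages$t_end[child_rows] -
    lineages$t_end[lineages$parent[child_rows]]
  tip_labels <- paste0("t", tip_rows)

  tree <- structure(list(
    edge = edge, edge.length = edge_length, Nnode = length(int_rows),
    tip.label = tip_labels,
    root.edge = lineages$t_end[root_row] - lineages$t_start[root_row]),
    class = "phylo", order = "cladewise")
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(tree = tree,
       tip_states = setNames(lineages$state[tip_rows], tip_labels),
       alive = setNames(lineages$alive[tip_rows], tip_labels))
}

#' Drop extinct lineages and subsample extant tips
#'
#' Removes lineages that did not survive to the simulation horizon and
#' retains `n` extant tips chosen uniformly at random, preserving branch
#' lengths along the retained paths (the result is ultrametric).
#'
#' @param sim An `sse_sim` from [simulate_tree()].
#' @param n Number of extant tips to retain.
#' @return List with `tree` (extant-only, `n` tips) and `tip_states`.
#' @export
prune_subsample <- function(sim, n) {
  if (is.null(sim$tree)) stop("simulation has no tree to prune")
  extant <- names(sim$alive)[sim$alive]
  if (length(extant) < n)
    stop(sprintf("only %d extant tips, cannot subsample %d",
                 length(extant), n))
  keep <- if (length(extant) == n) extant else sample(extant, n)
  tree <- ape::keep.tip(sim$tree, keep)
  list(tree = tree, tip_states = sim$tip_states[tree$tip.label])
}

#' Counts-only simulation of trait-combination frequencies
#'
#' The same jump process as [simulate_tree()] but tracking only the vector
#' of per-state lineage counts, which makes long or species-rich runs far
#' cheaper.  Counts are recorded on a fixed time grid.
#'
#' @inheritParams simulate_tree
#' @param record_interval Grid spacing (Myr); must divide `duration`.
#' @param max_total Cap on the total lineage count.
#' @param thin_at_cap Instead of stopping at the cap, binomially thin every
#'   state count by 1/2 and continue, recording the cumulative log
#'   correction in `log_scale`.  Thinning preserves the expected per-state
#'   frequencies, so long-horizon frequency dynamics can be followed with a
#'   bounded population; `exp(log_scale)` rescales recorded counts back to
#'   the unthinned population size.
#' @return Object of class `sse_trajectory`: list with `times`, `counts`
#'   (time x state matrix; rows after a truncation stop are `NA`),
#'   `log_scale` (per-record log of the thinning correction), `first_origin`
#'   (per-state first appearance time; `NA` if never), `final_counts`,
#'   `final_time`, `extinct`, `truncated`, `n_thins`.
#' @export
simulate_counts <- function(rates, root_state = 0, duration,
                            record_interval = 1, max_total = 5e5,
                            thin_at_cap = FALSE) {
  if (duration <= 0) stop("duration must be > 0")
  if (record_interval <= 0 ||
      abs(duration / record_interval -
          round(duration / record_interval)) > 1e-9)
    stop("record interval must divide the duration")
  if (root_state < 0 || root_state >= rates$n_states)
    stop("root state out of range")
  raw <- sim_counts_cpp(rates$lambda, rates$mu, rates$Q,
                        as.integer(root_state), duration, record_interval,
                        max_total, thin_at_cap)
  labs <- if (!is.null(rates$state_space)) rates$state_space$labels else NULL
  colnames(raw$counts) <- labs
  structure(list(times = raw$times, counts = raw$counts,
                 log_scale = raw$log_scale,
                 first_origin = setNames(as.numeric(raw$first_origin), labs),
                 final_counts = setNames(as.numeric(raw$final_counts), labs),
                 final_time = raw$final_time, extinct = raw$extinct,
                 truncated = raw$truncated, n_thins = raw$n_thins),
            class = "sse_trajectory")
}

#' @export
print.sse_trajectory <- function(x, ...) {
  cat(sprintf(
    "SSE trajectory: %d records to t = %.4g, final total %d lineages%s\n",
    length(x$times), x$final_time, sum(x$final_counts),
    if (x$truncated) " (truncated)" else if (x$extinct) " (extinct)" else ""))
  invisible(x)
}

#' Stationary (equilibrium) trait-combination frequencies
#'
#' The expected per-state lineage counts follow the linear dynamics
#' `dn/dt = A n` with `A[i,i] = r_i - sum_j q_ij` and `A[i,j] = q_ji`
#' (r = `lambda - mu`).  The long-run expected state frequencies are the
#' dominant right eigenvector of `A`, normalized to sum to 1; they are
#' invariant to a uniform rescaling of the time unit.
#'
#' @param rates A [rateset()].
#' @return Named frequency vector (entries `>= 0`, summing to 1).
#' @export
stationary_frequencies <- function(rates) {
  r <- rates$lambda - rates$mu
  A <- diag(r, rates$n_states) + t(rates$Q)
  e <- eigen(A)
  i <- which.max(Re(e$values))
  scale <- max(abs(e$values))
  if (abs(Im(e$values[i])) > 1e-8 * max(scale, 1))
    stop("dominant eigenvalue is complex; no stationary frequency vector")
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8 * max(abs(v))))
    stop("dominant eigenvector has mixed signs; no stationary frequencies")
  v[v < 0] <- 0
  labs <- if (!is.null(rates$state_space)) rates$state_space$labels else NULL
  setNames(v / sum(v), labs)
}

#' First-origin times of a set of states across replicate trajectories
#'
#' For each replicate, the first time any state in `states` reaches a
#' positive count; replicates in which the set never appears are reported
#' as censored and excluded from the quantiles.
#'
#' @param trajectories List of `sse_trajectory` objects.
#' @param states Integer vector of 0-based state indices to query.
#' @param probs Quantile probabilities for the interval (default 95%).
#' @return List with `median`, `interval` (named quantiles), `times`
#'   (per-replicate first origins, `NA` = censored), `n_censored`, `n`.
#' @export
origin_time_summary <- function(trajectories, states,
                                probs = c(0.025, 0.975)) {
  if (length(states) == 0L) stop("query state set is empty")
  times <- vapply(trajectories, function(tr) {
    fo <- tr$first_origin[states + 1L]
    if (all(is.na(fo))) NA_real_ else min(fo, na.rm = TRUE)
  }, numeric(1L))
  obs <- times[!is.na(times)]
  list(median = if (length(obs)) median(obs) else NA_real_,
       interval = if (length(obs)) quantile(obs, probs)
                  else setNames(rep(NA_real_, length(probs)),
                                paste0(100 * probs, "%")),
       times = times, n_censored = sum(is.na(times)), n = length(times))
}
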