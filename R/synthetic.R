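#' Study-shaped generating rate set
#'
#' The default synthetic-data conditions: six binary characters, the focal
#' set `"0*11**"` (corolla present, bilateral symmetry, few stamens)
#' diversifying at roughly twice the net rate of the rest
#' (`r_F = 0.064`, `r_N = 0.038` per lineage per Myr), and small, equal
#' transition rates (0.001/Myr) on every hypercube edge.
#'
#' @param state_space A [state_space()]; default: the 6-character space.
#' @param mask Focal mask.
#' @param lambda_F,mu_F,lambda_N,mu_N Set-level speciation and extinction
#'   rates.
#' @param q Transition rate applied to all four set-level classes.
#' @return A [rateset()].
#' @export
default_generating_rates <- function(state_space = NULL,
                                     mask = "0*11**",
                                     lambda_F = 0.07, mu_F = 0.006,
                                     lambda_N = 0.042, mu_N = 0.004,
                                     q = 0.001) {
  ss <- if (is.null(state_space)) hypersse::state_space(6) else state_space
  expand_rates(mask, ss,
               q = c(q_FF = q, q_NN = q, q_FN = q, q_NF = q),
               div = c(lambda_F = lambda_F, lambda_N = lambda_N,
                       mu_F = mu_F, mu_N = mu_N))
}

#' Generate a synthetic tree and character matrix
#'
#' Emulates the shape of the study dataset: a birth-death-with-transitions
#' simulation from the all-ancestral combination over `crown_age` Myr,
#' pruned to `n_tips` randomly chosen extant species, with tip combinations
#' decoded into binary character columns.  Runs that go extinct or end with
#' fewer than `n_tips` extant species are retried (fresh randomness,
#' bounded attempts).
#'
#' @param n_tips Number of extant tips to retain (default 464).
#' @param crown_age Simulation horizon in Myr (default 136).
#' @param rates Generating [rateset()]; default
#'   [default_generating_rates()].
#' @param root_state 0-based founding state (default 0, all-ancestral).
#' @param max_attempts Retry bound.
#' @param max_lineages Lineage cap passed to [simulate_tree()].
#' @param dir Optional output directory; writes `tree.nwk` and
#'   `characters.csv`.
#' @return List with `tree`, `tip_states`, `matrix` (data frame
#'   `taxon,c1..cK`), `rates`, `attempts`.
#' @export
generate_dataset <- function(n_tips = 464, crown_age = 136, rates = NULL,
                             root_state = 0, max_attempts = 50,
                             max_lineages = 5e5, dir = NULL) {
  if (n_tips < 4) stop("n_tips must be at least 4")
  if (is.null(rates)) rates <- default_generating_rates()
  for (attempt in seq_len(max_attempts)) {
    sim <- suppressWarnings(
      simulate_tree(rates, root_state, crown_age, max_lineages))
    if (sim$n_extant >= n_tips && !is.null(sim$tree)) {
      pruned <- prune_subsample(sim, n_tips)
      ss <- rates$state_space
      mat <- matrix_from_states(pruned$tip_states, ss)
      out <- list(tree = pruned$tree, tip_states = pruned$tip_states,
                  matrix = mat, rates = rates, attempts = attempt)
      if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        write_tree(out$tree, file.path(dir, "tree.nwk"))
        write_character_matrix(mat, file.path(dir, "characters.csv"))
      }
      return(out)
    }
  }
  stop(sprintf(
    "no run reached %d extant tips in %d attempts; generating rates may be too low",
    n_tips, max_attempts))
}

#' Stratified per-family sample counts with dynamic rounding
#'
#' Each family's expected sample count is `total_n * richness / sum(richness)`.
#' The integer part is taken deterministically; the fractional remainder is
#' rounded stochastically to 1 with probability equal to the fraction
#' (dynamic rounding), so the expectation of the returned counts equals the
#' exact fractional expectation.
#'
#' @param richness Named numeric vector of per-family species richness.
#' @param total_n Total number of species to sample.
#' @return Named integer vector of per-family counts.
#' @export
stratified_sample <- function(richness, total_n) {
  if (any(richness < 1)) stop("family richness must be >= 1")
  if (total_n < 1) stop("total_n must be >= 1")
  if (total_n > sum(richness))
    stop("cannot sample more species than the clade holds")
  expected <- total_n * richness / sum(richness)
  base <- floor(expected)
  frac <- expected - base
  extra <- as.integer(runif(length(frac)) < frac)
  setNames(as.integer(base + extra), names(richness))
}

#' Synthetic family richness table
#'
#' A log-series-flavoured richness distribution (many small families, few
#' large ones) scaled so the total equals `total_richness`, for exercising
#' the stratified sampler without external data.
#'
#' @param n_families Number of families.
#' @param total_richness Total species count across families.
#' @return Named numeric vector of per-family richness (each `>= 1`).
#' @export
synth_family_table <- function(n_families = 134, total_richness = 250000) {
  # log-series: P(k) ~ x^k / k; sample via inverse-cdf on a truncated support
  x <- 0.9999
  ks <- 1:20000
  p <- x^ks / ks
  rich <- sample(ks, n_families, replace = TRUE, prob = p)
  rich <- pmax(1, round(rich * total_richness / sum(rich)))
  # fix the total exactly by adjusting the largest family
  i <- which.max(rich)
  rich[i] <- rich[i] + total_richness - sum(rich)
  setNames(as.numeric(rich), paste0("fam", seq_len(n_families)))
}
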