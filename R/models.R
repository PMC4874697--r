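#' Tied transition-rate model family
#'
#' Five ways of constraining the four set-level transition rates
#' (within-focal `q_FF`, within-non-focal `q_NN`, focal-to-non-focal
#' `q_FN`, non-focal-to-focal `q_NF`):
#'
#' * `onerate` — a single rate for every edge (1 parameter);
#' * `within.between` — one rate within sets, one between (2);
#' * `equal` — free within-set rates, equal rates between sets (3);
#' * `outflow` — one within-set rate, free directional between-set rates (3);
#' * `free` — all four rates free (4).
#'
#' Each entry expands its parameter vector to `c(q_FF, q_NN, q_FN, q_NF)`.
#' The registry is an ordinary named list, so alternative tie schemes can be
#' supplied to the fitting functions in the same format.
#'
#' @return Named list; each element has `id`, `n_par`, `par_names` and
#'   `expand(par)`.
#' @export
transition_models <- function() {
  list(
    onerate = list(
      id = "onerate", n_par = 1L, par_names = "q",
      expand = function(p) c(q_FF = p[1], q_NN = p[1], q_FN = p[1],
                             q_NF = p[1])),
    within.between = list(
      id = "within.between", n_par = 2L, par_names = c("q_within", "q_between"),
      expand = function(p) c(q_FF = p[1], q_NN = p[1], q_FN = p[2],
                             q_NF = p[2])),
    equal = list(
      id = "equal", n_par = 3L, par_names = c("q_FF", "q_NN", "q_between"),
      expand = function(p) c(q_FF = p[1], q_NN = p[2], q_FN = p[3],
                             q_NF = p[3])),
    outflow = list(
      id = "outflow", n_par = 3L, par_names = c("q_within", "q_FN", "q_NF"),
      expand = function(p) c(q_FF = p[1], q_NN = p[1], q_FN = p[2],
                             q_NF = p[3])),
    free = list(
      id = "free", n_par = 4L, par_names = c("q_FF", "q_NN", "q_FN", "q_NF"),
      expand = function(p) c(q_FF = p[1], q_NN = p[2], q_FN = p[3],
                             q_NF = p[4]))
  )
}

#' Tied diversification model family
#'
#' Six ways of constraining the set-level speciation (`lambda`) and
#' extinction (`mu`) rates; net diversification is r = `lambda - mu`:
#'
#' * `equal` — one `lambda` and one `mu` shared by both sets (2 parameters);
#' * `free.lambda` — free `lambda`, shared `mu` (3);
#' * `free.mu` — shared `lambda`, free `mu` (3);
#' * `free` — free `lambda` and `mu` (4);
#' * `two.one` — focal speciation fixed at twice the non-focal rate,
#'   shared `mu` (2);
#' * `equal.r` — equal net diversification with free per-set turnover,
#'   parameterized as `(r, mu_F, mu_N)` with `lambda = r + mu` (3).
#'
#' Each entry expands its parameter vector to
#' `c(lambda_F, lambda_N, mu_F, mu_N)`.
#'
#' @return Named list; same element structure as [transition_models()].
#' @export
diversification_models <- function() {
  list(
    equal = list(
      id = "equal", n_par = 2L, par_names = c("lambda", "mu"),
      expand = function(p) c(lambda_F = p[1], lambda_N = p[1], mu_F = p[2],
                             mu_N = p[2])),
    free.lambda = list(
      id = "free.lambda", n_par = 3L,
      par_names = c("lambda_F", "lambda_N", "mu"),
      expand = function(p) c(lambda_F = p[1], lambda_N = p[2], mu_F = p[3],
                             mu_N = p[3])),
    free.mu = list(
      id = "free.mu", n_par = 3L, par_names = c("lambda", "mu_F", "mu_N"),
      expand = function(p) c(lambda_F = p[1], lambda_N = p[1], mu_F = p[2],
                             mu_N = p[3])),
    free = list(
      id = "free", n_par = 4L,
      par_names = c("lambda_F", "lambda_N", "mu_F", "mu_N"),
      expand = function(p) c(lambda_F = p[1], lambda_N = p[2], mu_F = p[3],
                             mu_N = p[4])),
    two.one = list(
      id = "two.one", n_par = 2L, par_names = c("lambda_N", "mu"),
      expand = function(p) c(lambda_F = 2 * p[1], lambda_N = p[1],
                             mu_F = p[2], mu_N = p[2])),
    equal.r = list(
      id = "equal.r", n_par = 3L, par_names = c("r", "mu_F", "mu_N"),
      expand = function(p) c(lambda_F = p[1] + p[2], lambda_N = p[1] + p[3],
                             mu_F = p[2], mu_N = p[3]))
  )
}

#' The transition x diversification model grid
#'
#' The cross product of the five transition and six diversification tie
#' schemes: 30 models per bipartition.
#'
#' @param transition,diversification Character vectors of registry names
#'   (defaults: all).
#' @return Data frame with columns `transition`, `diversification`, `k`
#'   (free parameter count).
#' @export
model_grid <- function(transition = names(transition_models()),
                       diversification = names(diversification_models())) {
  tms <- transition_models()[transition]
  dms <- diversification_models()[diversification]
  if (anyNA(names(tms)) || anyNA(names(dms)))
    stop("unknown model identifier")
  g <- expand.grid(transition = names(tms), diversification = names(dms),
                   stringsAsFactors = FALSE)
  g$k <- vapply(seq_len(nrow(g)), function(i)
    tms[[g$transition[i]]]$n_par + dms[[g$diversification[i]]]$n_par,
    integer(1L))
  g
}

#' Expand set-level rates to a full per-state rate set
#'
#' Places the four set-level transition rates on the hypercube edges
#' according to the focal/non-focal membership of each endpoint, and assigns
#' per-state speciation and extinction rates by set.  Transitions are
#' allowed only between combinations differing in one character.
#'
#' @param mask Bipartition mask string.
#' @param state_space A [state_space()].
#' @param q Named vector `c(q_FF, q_NN, q_FN, q_NF)`.
#' @param div Named vector `c(lambda_F, lambda_N, mu_F, mu_N)`.
#' @return An object of class `rateset`: list with per-state `lambda`, `mu`,
#'   the `n_states` x `n_states` transition matrix `Q` (rows sum to zero)
#'   and the `state_space`.
#' @export
expand_rates <- function(mask, state_space, q, div) {
  if (any(q < 0) || any(div[c("mu_F", "mu_N")] < 0) ||
      any(div[c("lambda_F", "lambda_N")] < 0))
    stop("rates must be non-negative")
  n <- state_space$n_states
  focal <- rep(FALSE, n)
  focal[focal_members(mask, state_space) + 1L] <- TRUE
  lambda <- ifelse(focal, div[["lambda_F"]], div[["lambda_N"]])
  mu <- ifelse(focal, div[["mu_F"]], div[["mu_N"]])
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in combo_neighbors(i - 1L, state_space) + 1L) {
      Q[i, j] <- if (focal[i] && focal[j]) q[["q_FF"]]
      else if (!focal[i] && !focal[j]) q[["q_NN"]]
      else if (focal[i]) q[["q_FN"]]
      else q[["q_NF"]]
    }
  }
  diag(Q) <- -rowSums(Q)
  rateset(lambda, mu, Q, state_space)
}

#' Construct a rate set
#'
#' @param lambda,mu Per-state speciation and extinction rates
#'   (events/lineage/Myr).
#' @param Q Transition-rate matrix with zero row sums and off-diagonal
#'   support restricted to hypercube edges.
#' @param state_space A [state_space()] (optional; checked if given).
#' @return Object of class `rateset`.
#' @export
rateset <- function(lambda, mu, Q, state_space = NULL) {
  n <- length(lambda)
  stopifnot(length(mu) == n, nrow(Q) == n, ncol(Q) == n)
  if (any(lambda < 0) || any(mu < 0)) stop("lambda and mu must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-10)) stop("rows of Q must sum to 0")
  off <- Q - diag(diag(Q))
  if (any(off < -1e-12)) stop("off-diagonal transition rates must be >= 0")
  if (!is.null(state_space)) {
    stopifnot(state_space$n_states == n)
    for (i in seq_len(n)) {
      allowed <- combo_neighbors(i - 1L, state_space) + 1L
      bad <- setdiff(which(off[i, ] > 0), allowed)
      if (length(bad) > 0)
        stop("transitions allowed only between single-character neighbors")
    }
  }
  structure(list(lambda = as.numeric(lambda), mu = as.numeric(mu),
                 Q = unname(Q), n_states = n, state_space = state_space),
            class = "rateset")
}

#' @export
print.rateset <- function(x, ...) {
  cat(sprintf("Rate set over %d states\n", x$n_states))
  cat(sprintf("  lambda: [%.4g, %.4g]  mu: [%.4g, %.4g]  max q: %.4g\n",
              min(x$lambda), max(x$lambda), min(x$mu), max(x$mu),
              max(x$Q - diag(diag(x$Q)))))
  invisible(x)
}

#' Build a rate set from a tied model specification
#'
#' @param mask Bipartition mask string.
#' @param transition,diversification Registry model names.
#' @param params Numeric parameter vector, transition parameters first, in
#'   registry order; length must equal the model's parameter count.
#' @param state_space A [state_space()].
#' @return A [rateset()].
#' @export
build_rateset <- function(mask, transition, diversification, params,
                          state_space) {
  tm <- transition_models()[[transition]]
  dm <- diversification_models()[[diversification]]
  if (is.null(tm) || is.null(dm)) stop("unknown model identifier")
  if (length(params) != tm$n_par + dm$n_par)
    stop(sprintf("expected %d parameters, got %d", tm$n_par + dm$n_par,
                 length(params)))
  if (any(params < 0)) stop("rates must be non-negative")
  params <- unname(params)
  q <- tm$expand(params[seq_len(tm$n_par)])
  div <- dm$expand(params[tm$n_par + seq_len(dm$n_par)])
  expand_rates(mask, state_space, q, div)
}
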