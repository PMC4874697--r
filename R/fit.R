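#' Maximum-likelihood fit of one tied model on one bipartition
#'
#' Optimizes the set-level rates of a `transition x diversification` tie
#' scheme by maximizing the SSE log-likelihood.  Optimization is bounded
#' quasi-Newton on log-transformed rates, run from several starting points
#' (a birth-death/Mk heuristic, a transition-inflated variant, and a
#' jittered variant); the best optimum is kept.
#'
#' @inheritParams sse_loglik
#' @param mask Bipartition mask string.
#' @param transition,diversification Registry model names (see
#'   [transition_models()], [diversification_models()]).
#' @param state_space A [state_space()].
#' @param starts Optional list of extra starting parameter vectors (natural
#'   scale).
#' @param n_starts Number of automatic starting points (1-3).
#' @param lower,upper Rate bounds (events/lineage/Myr).
#' @param maxit Iteration cap per start.
#' @return An object of class `sse_fit`: the bipartition and model ids, MLE
#'   parameters, `lnL`, parameter count `k`, `AIC`, set-level transition and
#'   diversification rates (including net rates `r_F`, `r_N`), the expanded
#'   per-state [rateset()], and optimizer diagnostics.
#' @export
fit_sse <- function(tree, states, mask, transition, diversification,
                    state_space, sampling_f = 1, root_state = 0,
                    condition_surv = FALSE, starts = NULL, n_starts = 3,
                    lower = 1e-9, upper = 10, maxit = 500,
                    rtol = 1e-8, atol = 1e-10) {
  tm <- transition_models()[[transition]]
  dm <- diversification_models()[[diversification]]
  if (is.null(tm) || is.null(dm)) stop("unknown model identifier")
  k <- tm$n_par + dm$n_par
  tree <- ape::reorder.phylo(tree, "postorder")
  states <- stats::setNames(prepare_tip_states(tree, states),
                            tree$tip.label)

  negll <- function(logpar) {
    par <- exp(logpar)
    rs <- build_rateset(mask, transition, diversification, par, state_space)
    ll <- suppressWarnings(
      sse_loglik(tree, states, rs, sampling_f, root = "fixed",
                 root_state = root_state, condition_surv = condition_surv,
                 rtol = rtol, atol = atol))
    if (!is.finite(ll)) 1e10 else -ll
  }

  start_list <- default_starts(tree, states, tm, dm, sampling_f, n_starts,
                               lower, upper)
  if (!is.null(starts)) start_list <- c(start_list, starts)

  best <- NULL
  convergence <- 1L
  for (st in start_list) {
    st <- pmin(pmax(st, lower * 1.01), upper * 0.99)
    opt <- tryCatch(
      optim(log(st), negll, method = "L-BFGS-B", lower = log(lower),
            upper = log(upper),
            control = list(maxit = maxit, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      convergence <- opt$convergence
    }
  }
  if (is.null(best))
    stop("optimization failed from every starting point")

  par <- exp(unname(best$par))
  q <- tm$expand(par[seq_len(tm$n_par)])
  div <- dm$expand(par[tm$n_par + seq_len(dm$n_par)])
  names(par) <- c(tm$par_names, dm$par_names)
  lnL <- -best$value
  structure(list(
    mask = mask, transition = transition, diversification = diversification,
    par = par, lnL = lnL, k = k, AIC = 2 * k - 2 * lnL,
    q = q, div = div,
    r_F = unname(div[["lambda_F"]] - div[["mu_F"]]),
    r_N = unname(div[["lambda_N"]] - div[["mu_N"]]),
    rates = expand_rates(mask, state_space, q, div),
    convergence = convergence, n_starts = length(start_list)),
    class = "sse_fit")
}

#' @export
print.sse_fit <- function(x, ...) {
  cat(sprintf("SSE fit: focal %s | trans %s | div %s\n", x$mask,
              x$transition, x$diversification))
  cat(sprintf("  lnL = %.4f  k = %d  AIC = %.4f\n", x$lnL, x$k, x$AIC))
  cat(sprintf("  r_F = %.4g  r_N = %.4g\n", x$r_F, x$r_N))
  invisible(x)
}

# heuristic starting points: a crown birth-death guess for diversification
# and a parsimony-flavoured guess for the transition rates
default_starts <- function(tree, states, tm, dm, sampling_f, n_starts,
                           lower, upper) {
  n_tip <- length(tree$tip.label)
  depth <- max(ape::node.depth.edgelength(tree))
  f_bar <- mean(sampling_f)
  r0 <- max(log(max(n_tip / f_bar, 4) / 2) / max(depth, 1e-6), 1e-4)
  lam0 <- 2 * r0
  mu0 <- r0
  total_len <- sum(tree$edge.length)
  n_obs <- length(unique(states[!is.na(states)]))
  q0 <- max(n_obs - 1, 1) / max(total_len, 1e-6)

  make <- function(lam, mu, r, q) {
    val <- function(nm) {
      if (startsWith(nm, "q")) q
      else if (startsWith(nm, "lambda")) lam
      else if (startsWith(nm, "mu")) mu
      else r  # "r" of the equal-net-rate model
    }
    vapply(c(tm$par_names, dm$par_names), val, numeric(1L))
  }
  starts <- list(make(lam0, mu0, r0, q0))
  if (n_starts >= 2) starts <- c(starts, list(make(lam0, mu0, r0, 10 * q0)))
  if (n_starts >= 3)
    starts <- c(starts, list(starts[[1L]] *
                               exp(runif(tm$n_par + dm$n_par, -1, 1))))
  starts
}

#' Fit the model grid over a set of bipartitions
#'
#' Runs [fit_sse()] for every (bipartition, model) combination.  By default
#' the bipartitions are all `3^n_chars - 1` masks reduced to the viable ones
#' (both sides represented among observed tip states).  Fits are independent
#' jobs run in a deterministic order, so results do not depend on scheduling.
#'
#' @inheritParams fit_sse
#' @param masks Bipartition masks to fit; default: all viable masks.
#' @param grid Model grid data frame from [model_grid()].
#' @param verbose Print progress.
#' @return An object of class `sse_fits`: list with `fits` (list of
#'   `sse_fit`), `failed` (character log of failed fits) and the inputs
#'   needed for averaging.
#' @export
fit_grid <- function(tree, states, state_space, masks = NULL,
                     grid = model_grid(), sampling_f = 1, root_state = 0,
                     condition_surv = FALSE, n_starts = 3, lower = 1e-9,
                     upper = 10, maxit = 500, rtol = 1e-8, atol = 1e-10,
                     verbose = FALSE) {
  states_v <- prepare_tip_states(tree, states)
  if (is.null(masks)) {
    masks <- filter_viable(enumerate_bipartitions(state_space),
                           unique(states_v[!is.na(states_v)]), state_space)
  }
  fits <- list()
  failed <- character()
  for (mk in masks) {
    for (i in seq_len(nrow(grid))) {
      id <- sprintf("%s|%s|%s", mk, grid$transition[i],
                    grid$diversification[i])
      if (verbose) message("fitting ", id)
      ft <- tryCatch(
        fit_sse(tree, states, mk, grid$transition[i],
                grid$diversification[i], state_space, sampling_f,
                root_state, condition_surv, n_starts = n_starts,
                lower = lower, upper = upper, maxit = maxit,
                rtol = rtol, atol = atol),
        error = function(e) conditionMessage(e))
      if (inherits(ft, "sse_fit")) fits[[id]] <- ft
      else failed[id] <- ft
    }
  }
  if (length(fits) == 0L) stop("every fit failed")
  structure(list(fits = fits, failed = failed, masks = masks, grid = grid,
                 state_space = state_space),
            class = "sse_fits")
}

#' @export
print.sse_fits <- function(x, ...) {
  cat(sprintf("%d SSE fits over %d bipartitions (%d failed)\n",
              length(x$fits), length(x$masks), length(x$failed)))
  invisible(x)
}

#' Akaike weights
#'
#' `w_m = exp(-(AIC_m - min AIC)/2)`, normalized to sum to 1.  Models with
#' non-finite AIC receive weight 0.
#'
#' @param aic Numeric vector of AIC scores.
#' @return Numeric weight vector summing to 1.
#' @export
akaike_weights <- function(aic) {
  if (length(aic) == 0L || !any(is.finite(aic)))
    stop("at least one finite AIC score is required")
  delta <- aic - min(aic[is.finite(aic)])
  w <- ifelse(is.finite(delta), exp(-delta / 2), 0)
  w / sum(w)
}

#' Model-averaged rate set
#'
#' Expands every fitted model to full per-state speciation, extinction and
#' per-edge transition rates and averages them elementwise with the Akaike
#' weights of all fitted models (no truncation to a top set).
#'
#' @param fits An `sse_fits` object from [fit_grid()], or a list of
#'   `sse_fit`.
#' @param weights Optional weights (default: Akaike weights from the fits'
#'   AIC scores).
#' @return A [rateset()] of the averaged rates.
#' @export
model_average <- function(fits, weights = NULL) {
  fl <- if (inherits(fits, "sse_fits")) fits$fits else fits
  ss <- fl[[1L]]$rates$state_space
  if (is.null(weights))
    weights <- akaike_weights(vapply(fl, `[[`, numeric(1L), "AIC"))
  if (length(weights) != length(fl))
    stop("one weight per fit is required")
  n <- fl[[1L]]$rates$n_states
  lambda <- numeric(n)
  mu <- numeric(n)
  Q <- matrix(0, n, n)
  for (i in seq_along(fl)) {
    lambda <- lambda + weights[i] * fl[[i]]$rates$lambda
    mu <- mu + weights[i] * fl[[i]]$rates$mu
    Q <- Q + weights[i] * fl[[i]]$rates$Q
  }
  rateset(lambda, mu, Q, ss)
}

#' Ranked model table
#'
#' The fitted models sorted by Akaike weight (ties broken by mask, then
#' transition and diversification ids), with cumulative weights and the
#' set-level rates, in the layout of the study's summary table.
#'
#' @param fits An `sse_fits` object or list of `sse_fit`.
#' @param top_n Number of rows to keep (default 10; `Inf` for all).
#' @return Data frame with columns `weight`, `cum_weight`, `focal`,
#'   `diversification`, `r_F`, `r_N`, `transition`, `q_FN`, `q_NF`, `q_NN`,
#'   `q_FF`.  Cumulative weights refer to all fitted models, so they are
#'   meaningful even for a truncated table.
#' @export
rank_table <- function(fits, top_n = 10) {
  fl <- if (inherits(fits, "sse_fits")) fits$fits else fits
  if (length(fl) == 0L) stop("no fits to rank")
  w <- akaike_weights(vapply(fl, `[[`, numeric(1L), "AIC"))
  tab <- data.frame(
    weight = w,
    focal = vapply(fl, `[[`, character(1L), "mask"),
    diversification = vapply(fl, `[[`, character(1L), "diversification"),
    r_F = vapply(fl, `[[`, numeric(1L), "r_F"),
    r_N = vapply(fl, `[[`, numeric(1L), "r_N"),
    transition = vapply(fl, `[[`, character(1L), "transition"),
    q_FN = vapply(fl, function(f) unname(f$q[["q_FN"]]), numeric(1L)),
    q_NF = vapply(fl, function(f) unname(f$q[["q_NF"]]), numeric(1L)),
    q_NN = vapply(fl, function(f) unname(f$q[["q_NN"]]), numeric(1L)),
    q_FF = vapply(fl, function(f) unname(f$q[["q_FF"]]), numeric(1L)),
    row.names = NULL)
  ord <- order(-tab$weight, tab$focal, tab$transition, tab$diversification)
  tab <- tab[ord, ]
  tab <- cbind(tab[, "weight", drop = FALSE],
               cum_weight = cumsum(tab$weight),
               tab[, setdiff(names(tab), "weight")])
  rownames(tab) <- NULL
  head(tab, n = if (is.finite(top_n)) top_n else nrow(tab))
}
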