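#' Marginalize combination frequencies onto a character subset
#'
#' Sums per-combination values over the characters not in `characters`,
#' giving values for the `2^length(characters)` combinations of the chosen
#' characters (e.g. the eight combinations of corolla presence, symmetry
#' and stamen number).
#'
#' @param values Numeric vector over all states (counts or frequencies), in
#'   state order.
#' @param characters Integer positions of the characters to keep (1-based,
#'   leftmost character = 1).
#' @param state_space A [state_space()].
#' @return Named vector over the marginal combinations, labelled by their
#'   bit strings.
#' @export
marginalize_states <- function(values, characters, state_space) {
  stopifnot(length(values) == state_space$n_states,
            all(characters %in% seq_len(state_space$n_chars)))
  sub <- state_space$bits[, characters, drop = FALSE]
  key <- apply(sub, 1L, paste, collapse = "")
  out <- tapply(values, key, sum)
  kk <- length(characters)
  want <- apply(state_space(kk)$bits, 1L, paste, collapse = "")
  setNames(as.numeric(out[want]), want)
}

#' Aggregate frequency of a focal mask
#'
#' @param freq Per-state frequency/count vector.
#' @param mask Bipartition mask.
#' @param state_space A [state_space()].
#' @return Sum of `freq` over the focal members of `mask`.
#' @export
mask_frequency <- function(freq, mask, state_space) {
  sum(freq[focal_members(mask, state_space) + 1L])
}

#' Fit stage: grid search, ranking, averaging
#'
#' Fits the model grid over the viable bipartitions, ranks fits by Akaike
#' weight, model-averages the rates, and (optionally) writes the ranked
#' table as TSV and the per-fit records as JSON.
#'
#' @inheritParams fit_grid
#' @param out_dir Optional output directory (`model_table.tsv`,
#'   `fits.json`).
#' @param top_n Rows of the ranked table to keep.
#' @param ... Passed on to [fit_grid()].
#' @return List with `fits` (`sse_fits`), `table` (ranked data frame),
#'   `averaged` ([rateset()] of model-averaged rates), `n_viable`.
#' @export
run_fit <- function(tree, states, state_space, masks = NULL,
                    grid = model_grid(), sampling_f = 1, root_state = 0,
                    top_n = 10, out_dir = NULL, ...) {
  fits <- fit_grid(tree, states, state_space, masks = masks, grid = grid,
                   sampling_f = sampling_f, root_state = root_state, ...)
  tab <- rank_table(fits, top_n = top_n)
  avg <- model_average(fits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(tab, file.path(out_dir, "model_table.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    recs <- lapply(fits$fits, function(f)
      list(mask = f$mask, transition = f$transition,
           diversification = f$diversification, par = as.list(f$par),
           lnL = f$lnL, k = f$k, AIC = f$AIC, r_F = f$r_F, r_N = f$r_N,
           convergence = f$convergence))
    jsonlite::write_json(recs, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(fits = fits, table = tab, averaged = avg,
       n_viable = length(fits$fits) + length(fits$failed))
}

#' Equilibrium stage: stationary frequencies of the averaged rates
#'
#' @param rates A [rateset()] (e.g. model-averaged rates).
#' @param focal_mask Optional mask whose aggregate equilibrium frequency is
#'   reported.
#' @param out_dir Optional output directory (`equilibrium.tsv`).
#' @return List with `freq` (per-state stationary frequencies) and
#'   `focal_freq` (or `NA`).
#' @export
run_equilibrium <- function(rates, focal_mask = NULL, out_dir = NULL) {
  freq <- stationary_frequencies(rates)
  focal <- if (is.null(focal_mask)) NA_real_
  else mask_frequency(freq, focal_mask, rates$state_space)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    df <- data.frame(state = seq_along(freq) - 1L,
                     combination = names(freq), frequency = unname(freq))
    write.table(df, file.path(out_dir, "equilibrium.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  list(freq = freq, focal_freq = focal)
}

#' Simulation stage: frequency trajectories, future extrapolation, origins
#'
#' Runs replicate counts-only simulations from the ancestral combination to
#' the present (`duration`) and `future` Myr beyond, and summarizes the
#' proportions of the marginal combinations of the chosen characters at the
#' present, in the future, and at equilibrium, together with first-origin
#' times.  Replicates that go extinct are reported but excluded from the
#' proportion summaries.
#'
#' @param rates A [rateset()].
#' @param duration Past horizon in Myr (default 136).
#' @param future Additional future horizon (default 15).
#' @param record_interval Recording grid (Myr).
#' @param n_rep Number of replicates.
#' @param characters Character subset for the marginal summary (default
#'   1, 3, 4: corolla, symmetry, stamens).
#' @param observed Optional named observed frequency vector over the
#'   marginal combinations, added to the summary for comparison.
#' @param root_state Founding state.
#' @param max_total Lineage cap per replicate.
#' @param out_dir Optional output directory (`trajectories.tsv`,
#'   `summary.tsv`).
#' @return List with `summary` (data frame: combination, mean/CI of
#'   present-day and future proportions, equilibrium, optional observed),
#'   `origin` (first-origin summaries per marginal combination),
#'   `trajectories`, `n_surviving`.
#' @export
run_simulate <- function(rates, duration = 136, future = 15,
                         record_interval = 1, n_rep = 50,
                         characters = c(1, 3, 4), observed = NULL,
                         root_state = 0, max_total = 5e5, out_dir = NULL) {
  ss <- rates$state_space
  if (is.null(ss)) stop("rate set must carry its state space")
  horizon <- duration + future
  trajs <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    trajs[[i]] <- suppressWarnings(
      simulate_counts(rates, root_state, horizon, record_interval,
                      max_total))
  }
  surviving <- !vapply(trajs, `[[`, logical(1L), "extinct")

  prop_at <- function(tr, t) {
    idx <- which(abs(tr$times - t) < 1e-9)
    cnt <- tr$counts[idx, ]
    if (anyNA(cnt)) cnt <- tr$final_counts  # truncated before t
    tot <- sum(cnt)
    if (tot <= 0) return(rep(NA_real_, 2^length(characters)))
    marginalize_states(cnt / tot, characters, ss)
  }
  pres <- do.call(rbind, lapply(trajs[surviving], prop_at, t = duration))
  futu <- do.call(rbind, lapply(trajs[surviving], prop_at, t = horizon))
  eq <- marginalize_states(stationary_frequencies(rates), characters, ss)

  ci <- function(m) apply(m, 2L, quantile, probs = c(0.025, 0.975),
                          na.rm = TRUE)
  pres_ci <- ci(pres)
  futu_ci <- ci(futu)
  summary_df <- data.frame(
    combination = names(eq),
    present_mean = colMeans(pres, na.rm = TRUE),
    present_lo = pres_ci[1L, ], present_hi = pres_ci[2L, ],
    future_mean = colMeans(futu, na.rm = TRUE),
    future_lo = futu_ci[1L, ], future_hi = futu_ci[2L, ],
    equilibrium = unname(eq), row.names = NULL)
  if (!is.null(observed))
    summary_df$observed <- as.numeric(observed[summary_df$combination])

  # first-origin summaries per marginal combination of the chosen characters
  kk <- length(characters)
  msub <- state_space(kk)
  origin <- lapply(seq_len(2^kk) - 1L, function(cmb) {
    bits <- combo_decode(cmb, kk)
    members <- which(apply(
      ss$bits[, characters, drop = FALSE], 1L,
      function(row) all(row == bits))) - 1L
    origin_time_summary(trajs, members)
  })
  names(origin) <- msub$labels

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    long <- do.call(rbind, lapply(seq_along(trajs), function(i) {
      tr <- trajs[[i]]
      data.frame(replicate = i,
                 time_Myr = rep(tr$times, each = ncol(tr$counts)),
                 state = rep(seq_len(ncol(tr$counts)) - 1L,
                             times = length(tr$times)),
                 count = as.vector(t(tr$counts)))
    }))
    write.table(long, file.path(out_dir, "trajectories.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(summary_df, file.path(out_dir, "summary.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  list(summary = summary_df, origin = origin, trajectories = trajs,
       n_surviving = sum(surviving))
}
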