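test_that("Akaike weights follow the exponential-difference formula", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(10, 12))
  expect_equal(w, c(exp(0), exp(-1)) / (exp(0) + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_identical(akaike_weights(42), 1)
  expect_equal(sum(akaike_weights(c(3, 9, 1, Inf))), 1)
  expect_identical(akaike_weights(c(5, Inf))[2], 0)
  expect_error(akaike_weights(c(Inf, Inf)), "finite")
})

test_that("ranked tables sort by weight with correct cumulative sums", {
  mkfit <- function(mask, trans, div, aic, rF = 0.06, rN = 0.04) {
    structure(list(mask = mask, transition = trans, diversification = div,
                   lnL = -aic / 2, k = 4, AIC = aic,
                   q = c(q_FF = 1e-3, q_NN = 1e-3, q_FN = 1e-3, q_NF = 1e-3),
                   div = c(lambda_F = rF, lambda_N = rN, mu_F = 0, mu_N = 0),
                   r_F = rF, r_N = rN), class = "sse_fit")
  }
  # weights approximately 0.274 / 0.245 / 0.202 / rest, as in a published
  # top-model table: cumulative sums accumulate in sort order
  w <- c(0.274, 0.245, 0.202, 0.279)
  aic <- -2 * log(w)
  fits <- list(mkfit("0*", "equal", "free", aic[1]),
               mkfit("1*", "free", "free", aic[2]),
               mkfit("*0", "onerate", "free", aic[3]),
               mkfit("*1", "outflow", "equal", aic[4]))
  tab <- rank_table(fits, top_n = 3)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$weight[1:3], c(0.279, 0.274, 0.245), tolerance = 1e-6)
  expect_equal(tab$cum_weight, cumsum(tab$weight), tolerance = 1e-12)
  expect_true(all(diff(tab$cum_weight) >= 0))
  # top_n larger than the fit count returns everything
  expect_identical(nrow(rank_table(fits, top_n = 99)), 4L)
  # exact ties are ordered deterministically by mask then model ids
  fits2 <- list(mkfit("1*", "free", "free", 10),
                mkfit("0*", "equal", "free", 10))
  tab2 <- rank_table(fits2)
  expect_identical(tab2$focal, c("0*", "1*"))
})

test_that("model averaging is an elementwise Akaike-weighted mean", {
  ss <- state_space(2)
  mk <- function(lam, aic) {
    rs <- expand_rates("0*", ss,
                       c(q_FF = 1e-3, q_NN = 1e-3, q_FN = 1e-3, q_NF = 1e-3),
                       c(lambda_F = lam, lambda_N = lam, mu_F = 0.01,
                         mu_N = 0.01))
    structure(list(mask = "0*", transition = "onerate",
                   diversification = "equal", AIC = aic, rates = rs),
              class = "sse_fit")
  }
  one <- model_average(list(mk(0.06, 100)))
  expect_equal(one$lambda, rep(0.06, 4))
  two <- model_average(list(mk(0.06, 100), mk(0.04, 100)))
  expect_equal(two$lambda, rep(0.05, 4))
  # averaged rates lie in the convex hull of the component rates
  set.seed(301)
  fits <- lapply(1:6, function(i) mk(runif(1, 0.02, 0.1), runif(1, 50, 60)))
  avg <- model_average(fits)
  lams <- vapply(fits, function(f) f$rates$lambda[1], numeric(1))
  expect_true(all(avg$lambda >= min(lams) - 1e-12 &
                  avg$lambda <= max(lams) + 1e-12))
  expect_true(all(abs(rowSums(avg$Q)) < 1e-12))
  expect_error(model_average(fits, weights = c(0.5, 0.5)), "one weight")
})

test_that("degenerate single-state data drives transition MLEs to the lower bound", {
  set.seed(302)
  ss <- state_space(2)
  gen <- expand_rates("0*", ss, c(q_FF = 0, q_NN = 0, q_FN = 0, q_NF = 0),
                      c(lambda_F = 0.08, lambda_N = 0.08, mu_F = 0.01,
                        mu_N = 0.01))
  sim <- simulate_tree(gen, 0, 80)
  pr <- prune_subsample(sim, min(40, sim$n_extant))
  ft <- fit_sse(pr$tree, pr$tip_states, "0*", "onerate", "equal", ss,
                sampling_f = 1, root_state = 0, n_starts = 2)
  expect_lt(ft$par[["q"]], 1e-6)
  expect_identical(ft$k, 3L)
  expect_equal(ft$AIC, 2 * 3 - 2 * ft$lnL)
})

test_that("the saturated-tie model yields the same rates on every bipartition", {
  # one-rate transitions + all-equal diversification ignore the bipartition,
  # so likelihoods are identical wherever the model is hosted
  ss <- state_space(2)
  p <- c(0.003, 0.06, 0.01)
  rsA <- build_rateset("0*", "onerate", "equal", p, ss)
  rsB <- build_rateset("11", "onerate", "equal", p, ss)
  expect_identical(rsA$Q, rsB$Q)
  expect_identical(rsA$lambda, rsB$lambda)
  expect_identical(rsA$mu, rsB$mu)
})

test_that("freeing constraints never lowers the optimal likelihood", {
  set.seed(303)
  ss <- state_space(2)
  gen <- expand_rates("1*", ss,
                      c(q_FF = 0.004, q_NN = 0.004, q_FN = 0.004,
                        q_NF = 0.004),
                      c(lambda_F = 0.09, lambda_N = 0.045, mu_F = 0.005,
                        mu_N = 0.005))
  dat <- generate_dataset(n_tips = 80, crown_age = 80, rates = gen)
  null <- fit_sse(dat$tree, dat$tip_states, "1*", "onerate", "equal", ss,
                  sampling_f = 0.5, root_state = 0, n_starts = 2)
  free <- fit_sse(dat$tree, dat$tip_states, "1*", "onerate", "free.lambda",
                  ss, sampling_f = 0.5, root_state = 0, n_starts = 2)
  expect_gte(free$lnL, null$lnL - 1e-4)
})
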