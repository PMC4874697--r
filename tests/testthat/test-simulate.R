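two_state_rates <- function(lam_F = 0.064, lam_N = 0.038, mu_F = 0,
                            mu_N = 0, q = 0.001) {
  # state 1 ("derived") is the focal set of mask "1" on one character
  expand_rates("1", state_space(1),
               c(q_FF = q, q_NN = q, q_FN = q, q_NF = q),
               c(lambda_F = lam_F, lambda_N = lam_N, mu_F = mu_F,
                 mu_N = mu_N))
}

test_that("a rate-free process leaves a single unbranched lineage", {
  rs0 <- build_rateset("1", "free", "free", rep(0, 8), state_space(1))
  sim <- simulate_tree(rs0, 0, 30)
  expect_identical(nrow(sim$lineages), 1L)
  expect_identical(sim$lineages$t_end, 30)
  expect_identical(sim$n_extant, 1L)
  expect_null(sim$tree)
})

test_that("pure-birth tip counts match the Yule expectation", {
  set.seed(401)
  rs <- two_state_rates(lam_F = 0.05, lam_N = 0.05, q = 0)
  nt <- replicate(500, simulate_tree(rs, 0, 50)$n_extant)
  expected <- exp(0.05 * 50)
  se <- sd(nt) / sqrt(length(nt))
  expect_lt(abs(mean(nt) - expected), 3 * se)
})

test_that("identical seeds reproduce trees and trajectories bit for bit", {
  rs <- two_state_rates()
  set.seed(402)
  a <- simulate_tree(rs, 0, 100)
  set.seed(402)
  b <- simulate_tree(rs, 0, 100)
  expect_identical(a$lineages, b$lineages)
  set.seed(403)
  ta <- simulate_counts(rs, 0, 50, 1)
  set.seed(403)
  tb <- simulate_counts(rs, 0, 50, 1)
  expect_identical(ta$counts, tb$counts)
})

test_that("subsampling preserves ultrametry and state frequencies", {
  set.seed(404)
  rs <- two_state_rates(lam_F = 0.09, lam_N = 0.07, mu_F = 0.01,
                        mu_N = 0.01, q = 0.01)
  sim <- simulate_tree(rs, 0, 90)
  expect_gt(sim$n_extant, 100)
  pr <- prune_subsample(sim, 100)
  expect_identical(length(pr$tree$tip.label), 100L)
  depths <- ape::node.depth.edgelength(pr$tree)[1:100]
  expect_lt(diff(range(depths)), 1e-8)
  # all retained tips are extant, so the tree depth is the horizon minus
  # the root lineage's stem
  expect_error(prune_subsample(sim, sim$n_extant + 1), "cannot subsample")
  # identity subsample: extant count unchanged
  pr_all <- prune_subsample(sim, sim$n_extant)
  expect_identical(length(pr_all$tree$tip.label), sim$n_extant)
  # frequency preservation within binomial error
  full_freq <- mean(sim$tip_states[names(sim$alive)[sim$alive]] == 1)
  sub_freq <- mean(pr$tip_states == 1)
  expect_lt(abs(sub_freq - full_freq),
            4 * sqrt(full_freq * (1 - full_freq) / 100))
})

test_that("counts-only runs record the grid, origins and degenerate cases", {
  rs0 <- build_rateset("1", "free", "free", rep(0, 8), state_space(1))
  tr <- simulate_counts(rs0, 0, 136, 1)
  expect_identical(length(tr$times), 137L)
  expect_true(all(tr$counts[, 1] == 1))
  expect_true(all(tr$counts[, 2] == 0))
  expect_identical(unname(tr$first_origin), c(0, NA_real_))
  # no transitions: the derived state never appears; summaries censor it
  set.seed(405)
  rs <- two_state_rates(q = 0)
  trs <- lapply(1:5, function(i) simulate_counts(rs, 0, 30, 1))
  os <- origin_time_summary(trs, 1L)
  expect_identical(os$n_censored, 5L)
  expect_true(is.na(os$median))
  expect_identical(origin_time_summary(trs, 0L)$median, 0)
  expect_error(origin_time_summary(trs, integer(0)), "empty")
})

test_that("tree and counts simulators agree on the tip-count distribution", {
  set.seed(406)
  rs <- two_state_rates(lam_F = 0.1, lam_N = 0.1, q = 0)
  n_tree <- replicate(200, simulate_tree(rs, 0, 25)$n_extant)
  n_cnt <- replicate(200, sum(simulate_counts(rs, 0, 25, 25)$final_counts))
  ks <- suppressWarnings(stats::ks.test(n_tree, n_cnt))
  expect_gt(ks$p.value, 0.01)
})

test_that("stationary frequencies solve the two-set eigenproblem", {
  # uniform rates: every combination equally frequent
  ss <- state_space(2)
  unif <- expand_rates("0*", ss,
                       c(q_FF = 0.01, q_NN = 0.01, q_FN = 0.01,
                         q_NF = 0.01),
                       c(lambda_F = 0.05, lambda_N = 0.05, mu_F = 0.01,
                         mu_N = 0.01))
  expect_equal(unname(stationary_frequencies(unif)), rep(0.25, 4))
  # two-state system against the hand-solved characteristic polynomial
  rs <- two_state_rates()
  eq <- stationary_frequencies(rs)
  oracle <- two_state_equilibrium(0.064, 0.038, 0.001, 0.001)
  expect_equal(unname(eq[2]), oracle$focal_freq, tolerance = 1e-10)
  expect_equal(unname(eq[2]), 0.963, tolerance = 1e-3)
  # invariance to a uniform time-unit rescaling
  rs2 <- rateset(rs$lambda * 3.7, rs$mu * 3.7, rs$Q * 3.7, rs$state_space)
  expect_equal(stationary_frequencies(rs2), eq, tolerance = 1e-10)
})

test_that("long-run simulated frequencies converge to the stationary vector", {
  set.seed(407)
  rs <- two_state_rates()
  eq <- stationary_frequencies(rs)
  props <- vapply(1:4, function(i) {
    tr <- simulate_counts(rs, 0, 450, 1, max_total = 1e5, thin_at_cap = TRUE)
    unname(tr$final_counts[2] / sum(tr$final_counts))
  }, numeric(1))
  expect_lt(abs(mean(props) - eq[2]), 0.01)
})

test_that("mean count dynamics track the linear growth equation", {
  set.seed(408)
  rs <- two_state_rates(lam_F = 0.08, lam_N = 0.05, mu_F = 0.01,
                        mu_N = 0.01, q = 0.02)
  A <- diag(rs$lambda - rs$mu) + t(rs$Q)
  horizon <- 40
  finals <- vapply(1:400, function(i)
    simulate_counts(rs, 0, horizon, horizon)$final_counts, numeric(2))
  expected <- as.vector(Matrix::expm(A * horizon) %*% c(1, 0))
  got <- rowMeans(finals)
  se <- apply(finals, 1, sd) / sqrt(ncol(finals))
  expect_true(all(abs(got - expected) < 4 * se))
})
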