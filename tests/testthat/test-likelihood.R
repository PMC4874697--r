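test_that("tip initial conditions encode state-specific sampling", {
  f <- 464 / 250000
  ti <- tip_init(5, f, 64)
  expect_equal(ti$D[6], 0.001856)
  expect_equal(sum(ti$D), 0.001856)
  expect_equal(ti$E, rep(0.998144, 64))
  ti1 <- tip_init(3, 1, 8)
  expect_equal(ti1$D[4], 1)
  expect_equal(ti1$E, rep(0, 8))
  tim <- tip_init(NA, 1, 8)
  expect_equal(tim$D, rep(1, 8))
  expect_error(tip_init(2, 1.2, 8), "\\(0, 1\\]")
  expect_error(tip_init(9, 1, 8), "range")
})

test_that("branch propagation: identity at zero duration, Mk and Yule closed forms", {
  ss <- state_space(2)
  rs <- expand_rates("0*", ss, c(q_FF = .08, q_NN = .12, q_FN = .05,
                                 q_NF = .03),
                     c(lambda_F = 0, lambda_N = 0, mu_F = 0, mu_N = 0))
  D0 <- c(0.2, 0.3, 0.4, 0.1)
  E0 <- rep(0, 4)
  out0 <- integrate_branch(D0, E0, rs, 0)
  expect_identical(out0$D, D0)
  # with lambda = mu = 0 the D update is the matrix-exponential action
  out <- integrate_branch(D0, E0, rs, 2.5)
  expect_equal(out$D, as.vector(ape::matexpo(rs$Q * 2.5) %*% D0),
               tolerance = 1e-8)
  expect_equal(out$E, rep(0, 4))
  # single-state pure birth: D(t) = d exp(-lambda t), E stays 0
  s1 <- state_space(1)
  rsy <- expand_rates("1", s1, c(q_FF = 0, q_NN = 0, q_FN = 0, q_NF = 0),
                      c(lambda_F = 0.3, lambda_N = 0.3, mu_F = 0, mu_N = 0))
  outy <- integrate_branch(c(0.7, 0.7), c(0, 0), rsy, 4)
  expect_equal(outy$D, rep(0.7 * exp(-0.3 * 4), 2), tolerance = 1e-7)
  expect_error(integrate_branch(D0, E0, rs, -1), ">= 0")
})

test_that("node combination multiplies daughters and the speciation rate", {
  ss <- state_space(1)
  rs <- expand_rates("1", ss, c(q_FF = 0, q_NN = 0, q_FN = 0, q_NF = 0),
                     c(lambda_F = 1, lambda_N = 1, mu_F = 0, mu_N = 0))
  expect_equal(combine_node(c(1, 1), c(1, 1), rs), c(1, 1))
  expect_equal(combine_node(c(0, 2), c(3, 0.5), rs), c(0, 1))
})

test_that("zero-rate likelihood of invariant data is exactly 1", {
  ss <- state_space(2)
  rs0 <- build_rateset("0*", "free", "free", rep(0, 8), ss)
  tr <- random_tree(4, 10)
  st <- setNames(rep(0L, 4), tr$tip.label)
  expect_identical(sse_loglik(tr, st, rs0, root_state = 0), 0)
})

test_that("pure character case matches the matrix-exponential Mk oracle", {
  set.seed(101)
  ss <- state_space(2)
  rs <- expand_rates("0*", ss, c(q_FF = .08, q_NN = .12, q_FN = .05,
                                 q_NF = .03),
                     c(lambda_F = 0, lambda_N = 0, mu_F = 0, mu_N = 0))
  for (i in 1:10) {
    tr <- random_tree(8, 5)
    st <- setNames(sample(0:3, 8, replace = TRUE), tr$tip.label)
    expect_equal(sse_loglik(tr, st, rs, root_state = 0),
                 mk_loglik_expm(tr, st, rs$Q, 0), tolerance = 1e-6)
  }
})

test_that("single-state pure birth matches the closed-form Yule likelihood", {
  set.seed(102)
  s1 <- state_space(1)
  rs <- expand_rates("1", s1, c(q_FF = 0, q_NN = 0, q_FN = 0, q_NF = 0),
                     c(lambda_F = 0.3, lambda_N = 0.3, mu_F = 0, mu_N = 0))
  tr <- random_tree(5, 8)
  st <- setNames(rep(0L, 5), tr$tip.label)
  expect_equal(sse_loglik(tr, st, rs, root_state = 0),
               yule_loglik(tr, 0.3), tolerance = 1e-8)
})

test_that("full SSE likelihood matches brute-force integration on 4-tip trees", {
  set.seed(103)
  ss <- state_space(2)
  rs <- expand_rates("0*", ss, c(q_FF = .02, q_NN = .03, q_FN = .01,
                                 q_NF = .015),
                     c(lambda_F = 0.2, lambda_N = 0.1, mu_F = 0.05,
                       mu_N = 0.03))
  for (i in 1:5) {
    tr <- random_tree(4, 8)
    st <- setNames(sample(0:3, 4, replace = TRUE), tr$tip.label)
    expect_equal(sse_loglik(tr, st, rs, sampling_f = 0.6, root_state = 0),
                 sse_loglik_desolve(tr, st, rs, 0.6, 0), tolerance = 1e-5)
  }
})

test_that("likelihood is invariant to tip ordering and child rotation", {
  set.seed(104)
  ss <- state_space(2)
  rs <- expand_rates("0*", ss, c(q_FF = .02, q_NN = .03, q_FN = .01,
                                 q_NF = .015),
                     c(lambda_F = 0.15, lambda_N = 0.08, mu_F = 0.04,
                       mu_N = 0.02))
  tr <- random_tree(12, 20)
  st <- setNames(sample(0:3, 12, replace = TRUE), tr$tip.label)
  ll <- sse_loglik(tr, st, rs, sampling_f = 0.5, root_state = 0)
  # permuted state vector (matched by name)
  expect_equal(sse_loglik(tr, st[sample(names(st))], rs, sampling_f = 0.5,
                          root_state = 0), ll, tolerance = 1e-10)
  # rotated children / re-ordered edges
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(sse_loglik(tr2, st, rs, sampling_f = 0.5, root_state = 0),
               ll, tolerance = 1e-8)
})

test_that("extinction probability grows monotonically from zero and stays below one", {
  ss <- state_space(2)
  rs <- expand_rates("0*", ss, c(q_FF = .02, q_NN = .03, q_FN = .01,
                                 q_NF = .015),
                     c(lambda_F = 0.2, lambda_N = 0.1, mu_F = 0.08,
                       mu_N = 0.05))
  E <- rep(0, 4)
  D <- rep(1, 4)
  prev <- E
  for (t in seq(0, 40, by = 5)[-1]) {
    out <- integrate_branch(D, rep(0, 4), rs, t)
    expect_true(all(out$E >= prev - 1e-10))
    expect_true(all(out$E <= 1 + 1e-10))
    prev <- out$E
  }
})

test_that("an unreachable fixed root state yields -Inf with a warning", {
  ss <- state_space(2)
  # no transitions possible, tips in a state other than the root state
  rs <- build_rateset("0*", "free", "free",
                      c(0, 0, 0, 0, 0.1, 0.1, 0, 0), ss)
  tr <- random_tree(4, 10)
  st <- setNames(rep(3L, 4), tr$tip.label)
  expect_warning(ll <- sse_loglik(tr, st, rs, root_state = 0), "zero")
  expect_identical(ll, -Inf)
})

test_that("missing tip states integrate over all combinations", {
  set.seed(105)
  ss <- state_space(2)
  rs <- expand_rates("0*", ss, c(q_FF = .05, q_NN = .05, q_FN = .05,
                                 q_NF = .05),
                     c(lambda_F = 0.1, lambda_N = 0.1, mu_F = 0.02,
                       mu_N = 0.02))
  tr <- random_tree(6, 15)
  st <- setNames(c(0L, 1L, 2L, 3L, 0L, NA), tr$tip.label)
  ll <- sse_loglik(tr, st, rs, root_state = 0)
  expect_true(is.finite(ll))
  # marginalization: likelihood with NA equals the sum over that tip's states
  tips <- names(st)
  parts <- vapply(0:3, function(s) {
    st2 <- st
    st2[6] <- s
    exp(sse_loglik(tr, st2, rs, root_state = 0))
  }, numeric(1))
  expect_equal(ll, log(sum(parts)), tolerance = 1e-6)
})
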