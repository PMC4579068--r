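test_that("the single-epoch pure-birth likelihood matches the symbolic form", {
  set.seed(17)
  for (i in 1:50) {
    tr <- simulate_yule(sample(4:60, 1), runif(1, 0.1, 0.6), seed = 700 + i)
    x <- branching_times(tr)$times
    lam <- runif(1, 0.02, 1.5)
    expect_equal(bd_shift_loglik(branching_times(tr), shift_model(lam)),
                 yule_loglik_oracle(x, lam), tolerance = 1e-8)
  }
})

test_that("a two-epoch model with identical rates equals the one-epoch value", {
  tr <- simulate_yule(25, 0.3, seed = 3)
  bt <- branching_times(tr)
  for (pars in list(c(0.3, 0), c(0.25, 0.1))) {
    for (rho in c(1, 0.45)) {
      one <- bd_shift_loglik(bt, shift_model(pars[1], pars[2], rho = rho))
      two <- bd_shift_loglik(bt, shift_model(rep(pars[1], 2), rep(pars[2], 2),
                                             shift_times = 4.2, rho = rho))
      expect_equal(two, one, tolerance = 1e-9)
    }
  }
})

test_that("constant-rate birth-death likelihood matches the textbook form", {
  set.seed(23)
  for (i in 1:20) {
    tr <- simulate_bd(sample(4:30, 1), 0.4, 0.15, seed = 40 + i)
    x <- branching_times(tr)$times
    lam <- runif(1, 0.1, 0.8); mu <- runif(1, 0, 0.9) * lam
    expect_equal(bd_shift_loglik(branching_times(tr), shift_model(lam, mu)),
                 bd_loglik_oracle_rho1(x, lam, mu), tolerance = 1e-8)
  }
})

test_that("the 3-tip birth-death density matches the RK4 ODE oracle", {
  tr <- parse_newick("((a:2.5,b:2.5):3.5,c:6);")
  bt <- branching_times(tr)
  ## one epoch, mu > 0, rho = 1
  ll <- bd_shift_loglik(bt, shift_model(0.35, 0.2))
  expect_equal(ll, bd_loglik_rk4_oracle(bt$times, 0.35, 0.2,
                                        numeric(0), 1),
               tolerance = 5e-4)
  ## and a genuinely piecewise model with incomplete sampling
  m <- shift_model(c(0.3, 0.12), c(0.1, 0.05), shift_times = 3, rho = 0.45)
  ll2 <- bd_shift_loglik(bt, m)
  expect_equal(ll2, bd_loglik_rk4_oracle(bt$times, c(0.3, 0.12),
                                         c(0.1, 0.05), 3, 0.45),
               tolerance = 5e-4)
})

test_that("extinction probability p matches a Monte-Carlo forward simulation", {
  ## first principles: fraction of single-lineage forward simulations with
  ## no survivors at time t
  lam <- 0.25; mu <- 0.18; t_max <- 6
  set.seed(99)
  extinct <- vapply(1:4000, function(i) {
    k <- 1L; t <- 0
    while (k > 0L && t < t_max) {
      t <- t + rexp(1, k * (lam + mu))
      if (t >= t_max) break
      k <- k + (if (runif(1) < lam / (lam + mu)) 1L else -1L)
    }
    k == 0L
  }, logical(1))
  p_pkg <- aridiv:::pq_eval(shift_model(lam, mu), t_max)$p
  se <- sqrt(mean(extinct) * (1 - mean(extinct)) / length(extinct))
  expect_lt(abs(mean(extinct) - p_pkg), 4 * se)
})

test_that("invalid parameter regions yield -Inf, invalid models error", {
  bt <- branching_times(simulate_yule(10, 0.3, seed = 1))
  expect_error(shift_model(c(0.2, 0.3), shift_times = -1), "positive")
  expect_error(shift_model(0), "> 0")
  expect_error(shift_model(0.2, rho = 0), "rho")
})

test_that("fit_constant recovers the generating rate and is invariant", {
  lams <- vapply(1:200, function(r) {
    tr <- simulate_yule(200, 0.2, seed = substream_seed(9000, r))
    fit_constant(branching_times(tr), rho = 1, process = "yule")$model$lambdas
  }, numeric(1))
  expect_gt(median(lams), 0.18)
  expect_lt(median(lams), 0.22)

  tr <- simulate_yule(30, 0.3, seed = 2)
  relab <- tr; relab$tip.label <- sample(tr$tip.label)
  f1 <- fit_constant(branching_times(tr), 1, "yule")
  f2 <- fit_constant(branching_times(as_chronogram(relab)), 1, "yule")
  expect_equal(f1$loglik, f2$loglik)
  expect_equal(f1$n_free_params, 1L)
  expect_equal(fit_constant(branching_times(tr), 1,
                            "birthdeath")$n_free_params, 2L)
})

test_that("the closed-form pure-birth MLE matches the generic optimiser", {
  for (seed in 1:5) {
    tr <- simulate_yule(40, 0.25, seed = seed)
    x <- branching_times(tr)$times
    f <- fit_constant(branching_times(tr), 1, "yule")
    expect_equal(f$model$lambdas, (length(x) - 1) / (2 * x[1] + sum(x[-1])),
                 tolerance = 1e-6)
    ## profile fast path at a fixed shift equals the generic objective
    pf <- aridiv:::yule_profile_fit(x, 5)
    expect_equal(pf$ll, bd_shift_loglik(branching_times(tr),
                                        shift_model(pf$lambdas,
                                                    shift_times = 5)),
                 tolerance = 1e-9)
  }
})

test_that("fit_k_shifts never falls below the nested fit", {
  for (seed in 1:12) {
    tr <- simulate_yule(sample(15:40, 1), 0.3, seed = 300 + seed)
    bt <- branching_times(tr)
    f0 <- fit_constant(bt, 1, "yule")
    f1 <- fit_k_shifts(bt, 1, 1, grid_step = 0.2, process = "yule")
    expect_gte(f1$loglik, f0$loglik - 1e-9)
    expect_equal(f1$n_free_params, 3L)
  }
  ## and on the slower incomplete-sampling path
  for (seed in 1:3) {
    tr <- simulate_yule(20, 0.3, seed = 500 + seed)
    bt <- branching_times(tr)
    f0 <- fit_constant(bt, 0.45, "yule")
    f1 <- fit_k_shifts(bt, 0.45, 1, grid_step = 0.5, process = "yule")
    expect_gte(f1$loglik, f0$loglik - 1e-6)
  }
})

test_that("two shifts nest one shift, greedily placed", {
  tr <- simulate_yule(60, 0.3, seed = 77)
  bt <- branching_times(tr)
  f1 <- fit_k_shifts(bt, 1, 1, grid_step = 0.2, process = "yule")
  f2 <- fit_k_shifts(bt, 1, 2, grid_step = 0.2, process = "yule")
  expect_gte(f2$loglik, f1$loglik - 1e-9)
  expect_true(f1$model$shift_times %in% f2$model$shift_times)
  expect_equal(f2$n_free_params, 5L)
})

test_that("the shift grid respects the 2-branching-event margins", {
  x <- c(12, 9, 7, 5, 3, 1)
  g <- aridiv:::shift_grid(x, 0.5)
  expect_true(all(vapply(g, function(a)
    sum(x > a) >= 2 && sum(x < a) >= 2, logical(1))))
  expect_lt(max(g), 9)
  expect_gt(min(g), 1)
  expect_error(fit_k_shifts(as_branching_times(c(5, 4)), 1, 1, 0.1, "yule"),
               "no admissible")
})

test_that("lrt computes the chi-square test and checks nesting", {
  f0 <- structure(list(model = shift_model(0.2), loglik = -100,
                       n_free_params = 1L, converged = TRUE),
                  class = "fit_result")
  f1 <- structure(list(model = shift_model(c(0.2, 0.3), shift_times = 5),
                       loglik = -97.3, n_free_params = 3L, converged = TRUE),
                  class = "fit_result")
  res <- lrt(f0, f1)
  expect_equal(res$chi2, 5.4, tolerance = 1e-9)
  expect_equal(res$df, 2L)
  expect_equal(res$p, exp(-2.7), tolerance = 1e-12)
  expect_equal(round(res$p, 3), 0.067)

  same <- lrt(f0, structure(list(model = f1$model, loglik = -100,
                                 n_free_params = 3L, converged = TRUE),
                            class = "fit_result"))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_error(lrt(f1, f0), "not nested")
  ## p strictly decreasing in chi2 at fixed df
  ps <- pchisq(seq(0.1, 10, by = 0.5), df = 2, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("incomplete sampling never lowers the pure-birth rate estimate", {
  for (i in 1:15) {
    tr <- simulate_yule(10, 0.3, seed = 100 + i)
    bt <- branching_times(tr)
    l1 <- fit_constant(bt, rho = 1, "yule")$model$lambdas
    l5 <- fit_constant(bt, rho = 0.5, "yule")$model$lambdas
    expect_gte(l5, l1 - 1e-6)
  }
})
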