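test_that("simulate_yule obeys the Exp(k lambda) waiting-time law", {
  ## n = 2: crown age ~ Exp(2 lambda), mean 1/(2 * 0.5) = 1
  set.seed(101)
  crowns <- vapply(1:8000, function(r)
    crown_age(simulate_yule(2, 0.5, seed = substream_seed(101, r))),
    numeric(1))
  se <- sd(crowns) / sqrt(length(crowns))
  expect_lt(abs(mean(crowns) - 1), 3 * se)

  ## n = 51 at lambda = 0.166: mean crown = (1/lam) sum_{k=2}^{51} 1/k
  crowns51 <- vapply(1:2000, function(r)
    crown_age(simulate_yule(51, 0.166, seed = substream_seed(77, r))),
    numeric(1))
  expected <- sum(1 / (2:51)) / 0.166
  se51 <- sd(crowns51) / sqrt(length(crowns51))
  expect_lt(abs(mean(crowns51) - expected), 3 * se51)
})

test_that("simulators are seed-reproducible and validate their contracts", {
  expect_identical(write_newick(simulate_yule(20, 0.3, seed = 5)),
                   write_newick(simulate_yule(20, 0.3, seed = 5)))
  expect_error(simulate_yule(1, 0.3), ">= 2")
  expect_error(simulate_yule(5, -1), "> 0")
  expect_error(simulate_bd(5, 0.2, 0.3), "supercritical")
  for (seed in 1:10) {
    tr <- simulate_bd(50, 0.3, 0.15, seed = seed)
    expect_equal(n_tips(tr), 50L)
    expect_s3_class(tr, "chronogram")   # construction re-validates
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  }
})

test_that("simulate_bd with mu = 0 matches simulate_yule in distribution", {
  ## different code paths: event loop vs vectorised waits; KS on crown ages
  n <- 10; lam <- 0.4; reps <- 1500
  a <- vapply(1:reps, function(r)
    crown_age(simulate_yule(n, lam, seed = substream_seed(11, r))), numeric(1))
  b <- vapply(1:reps, function(r)
    crown_age(simulate_bd(n, lam, 0, seed = substream_seed(22, r))), numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("crown-age response to extinction matches the small-step oracle", {
  ## Under the stop-at-nth conditioning the independent small-step
  ## simulator establishes that the mean reconstructed crown age
  ## DECREASES as mu grows at fixed lam - mu (the overall event rate
  ## lam + mu rises and crown-lineage deaths shorten reconstructed
  ## crowns). The package must agree with the oracle pointwise and
  ## reproduce that direction.
  reps <- 1200
  crown_mu <- function(lam, mu, base) mean(vapply(1:reps, function(r)
    crown_age(simulate_bd(8, lam, mu, seed = substream_seed(base, r))),
    numeric(1)))
  m0 <- crown_mu(0.3, 0, 500)
  m1 <- crown_mu(0.45, 0.15, 600)
  set.seed(42)
  ss_mean <- function(lam, mu, reps = 400) {
    out <- c()
    while (length(out) < reps) {
      v <- smallstep_bd_crown(8, lam, mu, dt = 0.004)
      if (!is.null(v)) out <- c(out, v)
    }
    mean(out)
  }
  s0 <- ss_mean(0.3, 0)
  s1 <- ss_mean(0.45, 0.15)
  expect_lt(abs(s0 - m0) / m0, 0.12)
  expect_lt(abs(s1 - m1) / m1, 0.12)
  expect_lt(m1, m0)
  expect_lt(s1, s0)
})

test_that("simulate_piecewise delegates single-epoch specs to simulate_bd", {
  sp <- simulation_spec(15, 0.3, 0.1, seed = 9)
  expect_identical(write_newick(simulate_piecewise(sp)),
                   write_newick(simulate_bd(15, 0.3, 0.1, seed = 9)))
})

test_that("a piecewise rate increase steepens the LTT after the shift", {
  ## lambda 0.03 -> 0.32 at 10 Ma: branching density per Myr higher after
  reps <- 120
  ratio <- vapply(1:reps, function(r) {
    sp <- simulation_spec(51, c(0.03, 0.32), c(0, 0), shift_times = 10,
                          seed = substream_seed(300, r))
    x <- branching_times(simulate_piecewise(sp))$times
    young <- sum(x < 10) / 10
    old <- (sum(x >= 10) - 1) / (x[1] - 10)   # exclude the crown
    young / max(old, 1e-6)
  }, numeric(1))
  expect_gt(mean(ratio > 1), 0.9)
})

test_that("piecewise simulation is anchored and exact in tip count", {
  sp <- simulation_spec(30, c(0.05, 0.4), c(0, 0.05), shift_times = 8,
                        seed = 13, crown_age = 12)
  tr <- simulate_piecewise(sp)
  expect_equal(n_tips(tr), 30L)
  expect_lte(crown_age(tr), 12 + 1e-9)
  expect_equal(attr(tr, "sim_anchor_age"), 12)
  expect_error(simulate_piecewise(
    simulation_spec(10, c(0.1, 0.2), c(0, 0), shift_times = 8, seed = 1,
                    crown_age = 5)), "exceed")
})

test_that("prune_random_tips removes k tips and preserves divergence ages", {
  full <- simulate_yule(51, 0.166, seed = 4)
  pruned <- prune_random_tips(full, 28, seed = 1)
  expect_equal(n_tips(pruned), 23L)
  expect_identical(write_newick(prune_random_tips(full, 0)),
                   write_newick(full))
  expect_error(prune_random_tips(full, 50), "between 0 and")

  ## exhaustive MRCA-age check on random 10-tip trees
  for (seed in 1:6) {
    tr <- simulate_yule(10, 0.3, seed = seed)
    pr <- prune_random_tips(tr, 4, seed = seed + 50)
    tips <- pr$tip.label
    for (i in seq_len(length(tips) - 1)) for (j in (i + 1):length(tips)) {
      m_full <- ape::getMRCA(tr, c(tips[i], tips[j]))
      m_pr <- ape::getMRCA(pr, c(tips[i], tips[j]))
      expect_equal(pr$node_age[m_pr], tr$node_age[m_full], tolerance = 1e-9)
    }
    expect_lte(crown_age(pr), crown_age(tr) + 1e-12)
  }
})

test_that("pruning commutes with tip relabeling", {
  tr <- simulate_yule(12, 0.3, seed = 8)
  perm <- setNames(paste0("z", 1:12), tr$tip.label)
  relab <- tr
  relab$tip.label <- unname(perm[tr$tip.label])
  p1 <- prune_random_tips(tr, 5, seed = 17)
  p2 <- prune_random_tips(as_chronogram(relab), 5, seed = 17)
  p1$tip.label <- unname(perm[p1$tip.label])
  expect_setequal(unname(clade_key_strings(as_chronogram(p1))),
                  unname(clade_key_strings(p2)))
})

test_that("simulation_spec validates its invariants", {
  expect_error(simulation_spec(10, c(0.1, 0.2), c(0, 0), shift_times = numeric(0)),
               "one fewer")
  expect_error(simulation_spec(10, c(0.1, 0.2, 0.3), c(0, 0, 0),
                               shift_times = c(2, 5)),
               "descending")
  expect_error(simulation_spec(10, c(0.1, -0.2), c(0, 0), shift_times = 5),
               "> 0")
})
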