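test_that("identical seeds give bit-identical trajectories", {
  p <- binding_params(100, 10, k_off = 1, K_d = 50)
  a <- simulate_binding(p, t_end = 20, seed = 99)
  b <- simulate_binding(p, t_end = 20, seed = 99)
  expect_identical(a$states, b$states)
  cfg <- signalling_config(t_stop = 20)
  sa <- simulate_signalling(p, cfg, seed = 99, record = TRUE)
  sb <- simulate_signalling(p, cfg, seed = 99, record = TRUE)
  expect_identical(sa$states, sb$states)
  sc <- simulate_signalling(p, cfg, seed = 100, record = TRUE)
  expect_false(identical(sa$states, sc$states))
})

test_that("signalling trajectories respect conservation and stoichiometry", {
  p <- binding_params(50, 10, k_off = 1, K_d = 20)
  tr <- simulate_signalling(p, signalling_config(t_stop = 50), seed = 3,
                            record = TRUE)
  st <- tr$states
  expect_gt(nrow(st), 10)
  expect_true(all(diff(st$time_s) > 0))
  # first state is the declared initial condition
  expect_equal(unlist(st[1, -1]), c(L = 50, R_I = 10, R_A = 0, B = 0, S = 0))
  # ligand and receptor conservation at every snapshot
  expect_true(all(st$L + st$B == p$L_max))
  expect_true(all(st$R_I + st$R_A + st$B == p$R_max))
  expect_true(all(st[-1] >= 0))
  expect_true(all(diff(st$S) >= 0))
  # successive states differ by exactly one reaction's stoichiometry
  steps <- apply(st[, c("L", "R_I", "R_A", "B", "S")], 2, diff)
  known <- rbind(r1 = c(-1, -1, 0, 1, 0),
                 r2 = c(1, 0, 1, -1, 0),
                 r3 = c(-1, 0, -1, 1, 0),
                 r4 = c(0, 1, -1, 0, 0),
                 r5 = c(0, 0, 0, 0, 1))
  match_one <- apply(steps, 1, function(s) {
    any(apply(known, 1, function(k) all(k == s)))
  })
  expect_true(all(match_one))
})

test_that("pure unbinding decays as the analytic linear death process", {
  # k_on/nu = 0 with B(0) = B0: B(t) ~ Binomial(B0, exp(-k_off t))
  B0 <- 20
  t_obs <- 1
  p <- binding_params(20, 20, k_off = 1, k_on_over_nu = 0)
  n_rep <- 10000
  set.seed(314)
  finals <- vapply(seq_len(n_rep), function(i) {
    simulate_binding(p, t_end = t_obs, B0 = B0, record = FALSE)$B_final
  }, numeric(1))
  q <- exp(-t_obs)
  expect_equal(mean(finals), B0 * q,
               tolerance = 4 * sqrt(B0 * q * (1 - q) / n_rep) / (B0 * q))
  emp <- tabulate(finals + 1, nbins = B0 + 1) / n_rep
  expect_lt(tv_dist(emp, dbinom(0:B0, B0, q)), 0.03)
})

test_that("degenerate inputs give constant trajectories", {
  # no ligand: nothing can ever fire
  p0 <- binding_params(0, 10, k_off = 1, K_d = 10)
  tr <- simulate_binding(p0, t_end = 100, seed = 1)
  expect_equal(tr$n_events, 0)
  expect_equal(nrow(tr$states), 1L)
  sg <- simulate_signalling(p0, signalling_config(t_stop = 100), seed = 1,
                            record = TRUE)
  expect_equal(sg$S_final, 0)
  expect_equal(sg$n_events, 0)
  # non-integer copy numbers are rejected at the parameter boundary
  expect_error(binding_params(10.3, 10, k_off = 1, K_d = 10), "integer")
})

test_that("long-run occupancy matches the analytic stationary law", {
  # single-pair system: occupancy of {0,1} complexes is [Kd, 1]/(1+Kd)
  p1 <- binding_params(1, 1, k_off = 1, k_on_over_nu = 1)
  tr1 <- simulate_binding(p1, t_end = 5000, seed = 5, burn_in = 50,
                          record = FALSE)
  expect_equal(tr1$occupancy, c(0.5, 0.5), tolerance = 0.05)

  # many-state system against the exact distribution (TV distance)
  p <- binding_params(1000, 10, k_off = 1, K_d = 100)
  tr <- simulate_binding(p, t_end = 5000, seed = 6, burn_in = 100,
                         record = FALSE)
  expect_lt(tv_dist(tr$occupancy, stationary_distribution(p)$p), 0.02)
})

test_that("complex-number marginal of the signalling model matches plain binding", {
  p <- binding_params(1000, 10, k_off = 1, K_d = 100)
  cfg <- signalling_config(S_stop = Inf, t_stop = 5000)
  sg <- simulate_signalling(p, cfg, seed = 7, burn_in = 100)
  bd <- simulate_binding(p, t_end = 5000, seed = 8, burn_in = 100,
                         record = FALSE)
  expect_lt(tv_dist(sg$occupancy, bd$occupancy), 0.02)
  # and both match the analytic law
  expect_lt(tv_dist(sg$occupancy, stationary_distribution(p)$p), 0.02)
})

test_that("simulator reproduces the exact master-equation stationary moments", {
  # small enough to solve the CME exactly, including the corner where
  # <R_A> and Var(B) genuinely part company
  oracle <- cme_signalling_moments(10, 10, kon_over_nu = 0.1, k_off = 1)
  p <- binding_params(10, 10, k_off = 1, K_d = 10)
  est <- estimate_signalling_rate(
    p, signalling_config(S_stop = Inf, t_stop = 2000, n_reps = 5, seed = 12),
    burn_in = 20)
  expect_equal(est$mean_R_A, oracle$mean_RA, tolerance = 0.03)
  expect_equal(est$mean_rate, oracle$signalling_rate, tolerance = 0.05)
})

test_that("mean active-TCR count tracks Var(B) in ligand excess", {
  # the aggregation-signalling identity <R_A> ~ Var(B) holds when
  # ligand far outnumbers receptor; checked against the exact CME
  for (K in c(10, 100, 1000)) {
    oracle <- cme_signalling_moments(1000, 10, kon_over_nu = 1 / K,
                                     k_off = 1)
    expect_equal(oracle$mean_RA, oracle$var_B, tolerance = 0.01)
    # and half the variance rate approximates the signalling rate
    expect_equal(oracle$signalling_rate,
                 oracle$mean_B * oracle$var_B, tolerance = 0.15)
  }
})

test_that("signalling rate estimation follows the replicated protocol", {
  p <- binding_params(100, 10, k_off = 1, K_d = 100)
  cfg <- signalling_config(S_stop = 200, t_stop = 100, n_reps = 4, seed = 21)
  est <- estimate_signalling_rate(p, cfg)
  expect_length(est$per_rep_rates, 4)
  expect_equal(est$mean_rate, mean(est$per_rep_rates))
  # replicate i is seeded with seed + i - 1
  tr2 <- simulate_signalling(p, cfg, seed = 22)
  expect_equal(est$per_rep_rates[2],
               if (tr2$t_final > 0) tr2$S_final / tr2$t_final else 0)
  expect_error(estimate_signalling_rate(p, signalling_config()),
               "seed")
})
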