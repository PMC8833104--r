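test_that("small stationary distributions match hand-derivable values", {
  d <- stationary_distribution(binding_params(1, 1, k_off = 1, K_d = 1))
  expect_equal(d$p, c(0.5, 0.5))
  expect_equal(moments(d), c(mean_B = 0.5, var_B = 0.25))
  expect_equal(shannon_entropy(d), 1.0)
  expect_equal(entropy_rate(d, 1), 1.0)
  expect_equal(variance_rate(d, 1), 0.25)
  expect_equal(adhesion_probability(d), 0.5)

  d21 <- stationary_distribution(binding_params(2, 1, k_off = 1, K_d = 1))
  expect_equal(d21$p, c(1 / 3, 2 / 3))
  expect_equal(moments(d21), c(mean_B = 2 / 3, var_B = 2 / 9))
  expect_equal(shannon_entropy(d21), -sum(c(1, 2) / 3 * log2(c(1, 2) / 3)))
  expect_equal(variance_rate(d21, 1), 8 / 27)

  # weak-binding limit concentrates at zero complexes
  dw <- stationary_distribution(binding_params(1, 1, k_off = 1, K_d = 1e12))
  expect_equal(dw$p, c(1, 1e-12), tolerance = 1e-9)
  expect_equal(adhesion_probability(dw), 1e-12, tolerance = 1e-6)

  # zero binding rate gives the degenerate empty-contact distribution
  d0 <- stationary_distribution(binding_params(50, 20, k_off = 1,
                                               k_on_over_nu = 0))
  expect_equal(d0$p, c(1, rep(0, 20)))
  expect_equal(shannon_entropy(d0), 0)
  expect_equal(adhesion_probability(d0), 0)

  # no ligand: B_max = 0, a single certain state
  dnil <- stationary_distribution(binding_params(0, 7, k_off = 1, K_d = 1))
  expect_equal(dnil$p, 1)
  expect_equal(moments(dnil), c(mean_B = 0, var_B = 0))
  expect_equal(adhesion_probability(dnil), 0)
})

test_that("log-space distribution matches direct evaluation and detailed balance", {
  set.seed(11)
  cases <- expand.grid(B_max = c(0, 1, 2, 5, 12), big = c(FALSE, TRUE),
                       K_d = c(0.1, 1, 10, 100))
  for (i in seq_len(nrow(cases))) {
    Bm <- cases$B_max[i]
    Um <- if (cases$big[i]) Bm + sample(1:988, 1) else Bm
    L <- if (i %% 2 == 0) Bm else Um
    R <- if (i %% 2 == 0) Um else Bm
    d <- stationary_distribution(binding_params(L, R, k_off = 1,
                                                K_d = cases$K_d[i]))
    o <- direct_stationary(L, R, cases$K_d[i])
    expect_equal(d$p, o$p, tolerance = 1e-10)
    expect_equal(sum(d$p), 1, tolerance = 1e-12)
    expect_true(all(d$p >= 0))
    expect_equal(d$p, exp(d$log_a - d$log_Z), tolerance = 1e-12)
    # detailed balance: p(B)/p(B-1) = (L-B+1)(R-B+1) / (B K_d)
    if (Bm >= 1) {
      B <- 1:Bm
      expect_equal(d$p[B + 1] / d$p[B],
                   (L - B + 1) * (R - B + 1) / (B * cases$K_d[i]),
                   tolerance = 1e-10)
    }
  }
})

test_that("log-space weights survive regimes where raw weights overflow", {
  # raw a(B) overflows double precision here; log-space must not
  d <- stationary_distribution(binding_params(5000, 400, k_off = 1,
                                              K_d = 0.1))
  expect_true(all(is.finite(d$log_Z)))
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
  expect_true(all(d$p >= 0))
  mv <- moments(d)
  expect_gt(mv[["mean_B"]], 390)  # strong binding saturates the TCRs
})

test_that("entropy is biphasic in the binding rate at fixed copy numbers", {
  kon <- 10^seq(-4, 0, length.out = 33)
  H <- vapply(kon, function(k) {
    shannon_entropy(stationary_distribution(
      binding_params(1000, 10, k_off = 1, k_on_over_nu = k)))
  }, numeric(1))
  i <- which.max(H)
  expect_gt(i, 1)
  expect_lt(i, length(kon))  # interior maximum: rises then falls
  expect_gt(H[i], H[1])
  expect_gt(H[i], H[length(kon)])
})

test_that("distribution depends on rates only through K_d; rates enter via k_off", {
  slow <- binding_params(1000, 10, k_off = 1, k_on_over_nu = 0.01)
  fast <- binding_params(1000, 10, k_off = 10, k_on_over_nu = 0.1)
  ds <- stationary_distribution(slow)
  df <- stationary_distribution(fast)
  expect_equal(ds$p, df$p)  # same K_d = 100 -> identical law
  expect_equal(shannon_entropy(ds), shannon_entropy(df))
  # but the entropy and variance rates scale linearly with k_off
  expect_equal(entropy_rate(df, fast$k_off),
               10 * entropy_rate(ds, slow$k_off))
  expect_equal(variance_rate(df, fast$k_off),
               10 * variance_rate(ds, slow$k_off))
})

test_that("summary_measures composes the exact sub-results", {
  p <- binding_params(1000, 10, k_off = 1, K_d = 100)
  s <- summary_measures(p)
  d <- stationary_distribution(p)
  mv <- moments(d)
  expect_equal(s$mean_B, mv[["mean_B"]])
  expect_equal(s$entropy_rate,
               2 * p$k_off * mv[["mean_B"]] * shannon_entropy(d))
  expect_equal(s$variance_rate,
               2 * p$k_off * mv[["mean_B"]] * mv[["var_B"]])
  expect_equal(s$adhesion_probability, 1 - d$p[1], tolerance = 1e-12)
  expect_true(s$shannon_entropy <= log2(d$B_max + 1))
  df <- as.data.frame(s)
  expect_named(df, c("mean_B", "var_B", "shannon_entropy_bits",
                     "entropy_rate_bits_per_s", "variance_rate_per_s",
                     "adhesion_probability"))
})
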