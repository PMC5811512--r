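test_that("spectral existence test matches hand-worked cases", {
  expect_true(peak_exists_spectral(rate_set(3, 0, 1, 1)))
  expect_false(peak_exists_spectral(rate_set(1, 0, 1, 2)))
  # association rate does not matter
  expect_true(peak_exists_spectral(rate_set(2, 1, 0.1, 1)))
  expect_true(peak_exists_spectral(rate_set(2, 1, 10, 1)))
  expect_message(out <- peak_exists_spectral(rate_set(1, 0, 0, 0.5)),
                 "unreachable")
  expect_false(out)
})

test_that("one-closed-state criterion is alpha > delta, boundary excluded", {
  expect_true(peak_exists_3state(rate_set(2, 5, 1, 1)))
  expect_false(peak_exists_3state(rate_set(1, 0, 1, 1)))
  expect_error(peak_exists_3state(rate_set(1, 0, 1, 1, m = 2)), "m = 1")
  set.seed(808)
  for (i in 1:300) {
    r <- random_rate_set(m = 1)
    if (abs(r$alpha - r$delta) > 1e-6) {
      expect_identical(peak_exists_3state(r), peak_exists_spectral(r))
    }
  }
})

test_that("two-closed-state criterion matches the spectral decision", {
  # beta = 0 reduces to alpha > delta
  expect_true(peak_exists_4state(rate_set(1, 0, 1, 0.99, m = 2)))
  expect_false(peak_exists_4state(rate_set(1, 0, 1, 1.01, m = 2)))
  # alpha = beta = 1: boundary at 2 - sqrt(2)
  dstar <- 2 - sqrt(2)
  expect_true(peak_exists_4state(rate_set(1, 1, 1, dstar - 1e-4, m = 2)))
  expect_false(peak_exists_4state(rate_set(1, 1, 1, dstar + 1e-4, m = 2)))
  bis <- peak_boundary_delta(1, 1, 1, m = 2, bracket = c(0.01, 10), tol = 1e-8)
  expect_equal(bis, dstar, tolerance = 1e-6)
  expect_error(peak_exists_4state(rate_set(1, 0, 1, 1)), "m = 2")
  set.seed(909)
  for (i in 1:300) {
    r <- random_rate_set(m = 2)
    boundary <- r$delta * (3 + r$beta / r$alpha +
                             sqrt(1 + 6 * r$beta / r$alpha +
                                    (r$beta / r$alpha)^2)) / 4
    if (abs(r$alpha - boundary) > 1e-6) {
      expect_identical(peak_exists_4state(r), peak_exists_spectral(r))
    }
  }
})

test_that("peak existence is independent of the association rate", {
  set.seed(111)
  gammas <- 10^seq(-3, 3, by = 1)
  for (i in 1:25) {
    m <- sample(1:4, 1)
    v <- 10^runif(3, -1, 1)
    decisions <- vapply(
      gammas,
      function(g) peak_exists_spectral(rate_set(v[1], v[2], g, v[3], m = m)),
      logical(1)
    )
    expect_true(all(decisions) || !any(decisions))
  }
})

test_that("closed-form peak time and height match the worked example", {
  r <- rate_set(3, 0, 1, 1)
  expect_equal(peak_time_3state(r), log(2), tolerance = 1e-12)
  expect_equal(relative_peak_height(r), 0.25, tolerance = 1e-10)
  expect_error(peak_time_3state(rate_set(1, 0, 1, 2)), "no peak")
  expect_error(relative_peak_height(rate_set(1, 0, 1, 2)), "no peak")
})

test_that("closed forms agree with the numeric argmax on random peaked sets", {
  set.seed(222)
  n_done <- 0
  while (n_done < 120) {
    r <- random_rate_set(m = 1)
    if (!peak_exists_3state(r) ||
        abs(r$alpha - r$delta) < 1e-3 * max(r$alpha, r$delta)) next
    n_done <- n_done + 1
    pk <- find_peak_numeric(build_generator(r))
    expect_true(pk$exists)
    tp <- peak_time_3state(r)
    expect_equal(pk$t_p, tp, tolerance = 1e-6)
    o_ss <- steady_state_open(r)
    expect_equal(relative_peak_height(r), pk$o_p / o_ss - 1,
                 tolerance = 1e-6)
  }
})

test_that("peak time diverges toward the existence boundary", {
  tps <- vapply(c(1.5, 1.1, 1.01, 1.001),
                function(a) peak_time_3state(rate_set(a, 0.5, 1, 1)),
                numeric(1))
  expect_true(all(diff(tps) > 0))
  # logarithmic divergence: roughly constant step per decade of alpha - delta
  expect_gt(tps[4] - tps[1], 3)
})

test_that("Kd-concentration height formula matches the full closed form", {
  expect_equal(relative_peak_height_kd(3, 1), 0.25, tolerance = 1e-12)
  expect_equal(relative_peak_height_kd(4, 1), 1 / 3, tolerance = 1e-12)
  expect_error(relative_peak_height_kd(2, 1), "alpha > 2")
  set.seed(333)
  for (i in 1:100) {
    d <- 10^runif(1, -1, 0.5)
    a <- d * (2 + 10^runif(1, -1, 1))
    full <- relative_peak_height(rate_set(a, 0, d, d))
    expect_equal(relative_peak_height_kd(a, d), full,
                 tolerance = 1e-10)
  }
})

test_that("tabulated limits of the relative peak height are approached", {
  base <- rate_set(3, 1, 1.5, 1)
  expect_equal(relative_peak_height_limit("alpha", "infinity", base), 1.5)
  expect_equal(relative_peak_height_limit("alpha", "zero", base), 0)
  expect_equal(relative_peak_height_limit("beta", "infinity", base), 0)
  expect_equal(relative_peak_height_limit("gamma", "infinity", base), 2)
  expect_equal(relative_peak_height_limit("gamma", "zero", base), 0)
  expect_equal(relative_peak_height_limit("delta", "infinity", base), 0)
  expect_identical(relative_peak_height_limit("delta", "zero", base), Inf)

  psi_at <- function(alpha = 3, beta = 1, gamma = 1.5, delta = 1) {
    r <- rate_set(alpha, beta, gamma, delta)
    if (peak_exists_3state(r)) relative_peak_height(r) else 0
  }
  # monotone approach over six decades of the swept rate
  sweep_up <- 10^(1:6)
  expect_equal(psi_at(alpha = 1e7), 1.5, tolerance = 1e-3)
  a_vals <- vapply(sweep_up, function(s) psi_at(alpha = s), numeric(1))
  expect_true(all(diff(abs(a_vals - 1.5)) < 0))
  g_vals <- vapply(sweep_up, function(s) psi_at(gamma = s), numeric(1))
  expect_true(all(diff(abs(g_vals - 2)) < 0))
  b_vals <- vapply(sweep_up, function(s) psi_at(beta = s), numeric(1))
  expect_true(all(diff(b_vals) < 0))
  d_vals <- vapply(10^(-(1:6)), function(s) psi_at(delta = s), numeric(1))
  expect_true(all(diff(d_vals) > 0))
  expect_gt(d_vals[6], 1e4)
})

test_that("beta -> 0 limit is exposed numerically, not as a closed form", {
  # note alpha = gamma + delta makes beta = 0 exactly degenerate (the
  # piecewise split of the tabulated limit); stay off that line
  base <- rate_set(3, 1, 1.5, 1)
  lim <- relative_peak_height_limit("beta", "zero", base)
  direct <- relative_peak_height(rate_set(3, 0, 1.5, 1))
  expect_equal(lim, direct, tolerance = 1e-12)
  betas <- 10^seq(-1, -6, by = -1)
  vals <- vapply(betas,
                 function(b) relative_peak_height(rate_set(3, b, 1.5, 1)),
                 numeric(1))
  expect_lt(abs(vals[6] - lim), 1e-4)
  no_peak_base <- rate_set(1, 1, 2, 3)
  expect_equal(relative_peak_height_limit("beta", "zero", no_peak_base), 0)
})

test_that("analyze_peak aggregates a consistent report", {
  rep1 <- analyze_peak(rate_set(3, 0, 1, 1))
  expect_true(rep1$exists)
  expect_equal(rep1$t_p, log(2), tolerance = 1e-10)
  expect_equal(rep1$o_p, 0.625, tolerance = 1e-10)
  expect_equal(rep1$rel_height, 0.25, tolerance = 1e-10)
  expect_equal(rep1$o_ss, 0.5, tolerance = 1e-10)

  rep2 <- analyze_peak(rate_set(1, 0, 1, 2))
  expect_false(rep2$exists)
  expect_true(is.na(rep2$t_p))

  set.seed(444)
  for (i in 1:60) {
    rp <- analyze_peak(random_rate_set(m = sample(1:3, 1)))
    if (rp$exists) {
      expect_gt(rp$t_p, 0)
      expect_gt(rp$o_p, rp$o_ss)
      expect_equal(rp$o_p, (1 + rp$rel_height) * rp$o_ss, tolerance = 1e-9)
      expect_gte(rp$rel_height, 0)
    }
    expect_identical(rp$exists,
                     rp$rates$delta + rp$r_slow <
                       -1e-9 * max(unlist(rp$rates[1:4])))
  }
})

test_that("tidy and glance return one-row summaries", {
  rp <- analyze_peak(rate_set(3, 0, 1, 1))
  td <- tidy(rp)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_named(td, c("alpha", "beta", "gamma", "delta", "m", "exists",
                     "t_p", "o_p", "rel_height", "o_ss", "r_slow"))
  gl <- glance(rp)
  expect_equal(gl$n_states, 3L)
  expect_equal(gl$method, "closed-form")
})

test_that("numeric peak finder is stable and detects monotone waveforms", {
  A <- build_generator(rate_set(3, 0, 1, 1))
  pk <- find_peak_numeric(A)
  expect_true(pk$exists)
  expect_equal(pk$t_p, log(2), tolerance = 1e-8)
  expect_equal(pk$o_p, 0.625, tolerance = 1e-10)
  pk2 <- find_peak_numeric(A, n_grid = 1200L)
  expect_equal(pk$t_p, pk2$t_p, tolerance = 1e-8)
  mono <- find_peak_numeric(build_generator(rate_set(1, 0, 1, 2)))
  expect_false(mono$exists)
})

test_that("more closed states shrink the existence boundary when beta > 0", {
  boundaries <- vapply(1:4, function(m) {
    peak_boundary_delta(1, 1, 1, m = m, bracket = c(0.01, 10), tol = 1e-8)
  }, numeric(1))
  expect_equal(boundaries[1], 1, tolerance = 1e-6)
  expect_equal(boundaries[2], 2 - sqrt(2), tolerance = 1e-6)
  expect_true(all(diff(boundaries) < 0))
})
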