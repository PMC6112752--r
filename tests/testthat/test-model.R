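test_that("survival weights follow the geometric LQ decay", {
  s <- schedule_uniform(3, 8)
  expect_equal(survival_weights(s, ref_params),
               c(1, exp(-3.6), exp(-7.2)), tolerance = 1e-12)
  expect_equal(survival_weights(schedule(0, 5), ref_params), 1)
  # unequal doses: cumulative product of per-dose survivals
  u <- schedule(c(0, 1, 2), c(8, 6, 2))
  k <- kill_fraction(c(8, 6), ref_params)
  expect_equal(survival_weights(u, ref_params),
               c(1, 1 - k[1], (1 - k[1]) * (1 - k[2])), tolerance = 1e-12)
})

test_that("theta entries match closed forms and the trapezoid oracle", {
  s <- schedule_uniform(3, 8)
  expect_identical(theta_entry(2, 1, s, ref_kinetics), 0)
  expect_equal(theta_entry(3, 3, s, ref_kinetics), 1)
  # last column: closed-form residual release mass 2^(-((T_N-T_i)/T_D)^2)
  expect_equal(theta_entry(1, 3, s, ref_kinetics), 2^(-4 / 9),
               tolerance = 1e-12)
  expect_error(theta_entry(0, 1, s), "1..3")
  expect_error(theta_entry(1, 4, s), "1..3")
  # fine-grid oracle agreement on the quadrature entries
  expect_equal(theta_entry(1, 1, s, ref_kinetics),
               trap_theta(0:2, 1, 1, 3, 7), tolerance = 1e-8)
  expect_equal(theta_entry(1, 2, s, ref_kinetics),
               trap_theta(0:2, 1, 2, 3, 7), tolerance = 1e-8)
  expect_equal(sum(theta_matrix(s, ref_kinetics)[1, ]), 0.7358408,
               tolerance = 1e-6)
})

test_that("theta matrix is upper-triangular, bounded, and translation invariant", {
  set.seed(7)
  for (rep in 1:10) {
    s <- random_schedule()
    th <- theta_matrix(s, ref_kinetics)
    expect_true(all(th[lower.tri(th)] == 0))
    expect_true(all(th >= 0 & th <= 1))
    expect_true(all(rowSums(th) <= 1 + 1e-9))
    shifted <- schedule(s$time_days + 13.5, s$dose_gy)
    expect_lt(max(abs(theta_matrix(shifted, ref_kinetics) - th)), 1e-12)
  }
  expect_equal(theta_matrix(schedule(0, 8)), matrix(1, 1, 1))
})

test_that("single instantaneous doses obey the closed-form identities", {
  for (d in c(1, 2, 6, 8, 10)) {
    s <- schedule(0, d)
    expect_equal(ied_efficacy(s, ref_params, ref_kinetics),
                 kill_fraction(d, ref_params), tolerance = 1e-12)
    expect_equal(ied(s, ref_params, ref_kinetics),
                 d + (ref_params$beta / ref_params$alpha) * d^2,
                 tolerance = 1e-9)
  }
  expect_equal(ied_efficacy(schedule(0, 2), ref_params), 1 - exp(-0.45),
               tolerance = 1e-12)
})

test_that("slow death and well-separated fractions both recover the total kill", {
  set.seed(11)
  slow_death <- immune_kinetics(t_d = 1e6, t_ir = 7)
  for (rep in 1:5) {
    s <- random_schedule(n_max = 6, gap_range = c(0.5, 12))  # span <= 60 d
    expect_equal(ied_efficacy(s, ref_params, slow_death),
                 total_kill(s, ref_params), tolerance = 1e-3)
  }
  for (rep in 1:5) {
    s <- random_schedule(n_max = 5, gap_range = c(300, 600))
    expect_equal(ied_efficacy(s, ref_params, ref_kinetics),
                 total_kill(s, ref_params), tolerance = 1e-3)
  }
})

test_that("the result bundle is internally consistent and early doses dominate", {
  res <- ied_evaluate(schedule_uniform(3, 8), ref_params, ref_kinetics)
  expect_equal(sum(res$contributions), res$efficacy, tolerance = 1e-12)
  expect_true(all(res$contributions >= 0))
  expect_lt(res$efficacy, 1)
  expect_equal(res$ied_gy, -log(1 - res$efficacy) / ref_params$alpha,
               tolerance = 1e-9)
  expect_true(all(diff(res$contributions) < 0))  # geometric decrease of S
  expect_equal(res$bed_gy, 72)
  expect_equal(res$eqd2_gy, 48)
  # near-zero single dose: every metric collapses to zero
  tiny <- ied_evaluate(schedule(0, 1e-9), ref_params, ref_kinetics)
  expect_lt(tiny$efficacy, 1e-8)
  expect_lt(tiny$ied_gy, 1e-8)
  expect_lt(tiny$bed_gy, 1e-8)
})

test_that("BED and EQD2 match the classic time-free formulas", {
  expect_equal(bed(schedule_uniform(3, 8), ref_params), 72)
  expect_equal(bed(schedule_uniform(5, 6), ref_params), 75)
  expect_equal(bed(schedule(0, 2), ref_params), 3)
  expect_equal(eqd2(schedule_uniform(3, 8), ref_params), 48)
  expect_equal(eqd2(schedule_uniform(5, 6), ref_params), 50)
  # fixed point: a course already in 2 Gy fractions
  s2 <- schedule_uniform(10, 2)
  expect_equal(eqd2(s2, ref_params), sum(s2$dose_gy))
})

test_that("the high-dose transform hook rescales the kill pathway only", {
  s <- schedule_uniform(3, 12)
  halved <- ied_evaluate(s, ref_params, ref_kinetics,
                         dose_transform = function(d) d / 2)
  plain6 <- ied_evaluate(schedule_uniform(3, 6), ref_params, ref_kinetics)
  expect_equal(halved$efficacy, plain6$efficacy, tolerance = 1e-12)
  expect_equal(halved$bed_gy, bed(s, ref_params))  # physical metrics untouched
})
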