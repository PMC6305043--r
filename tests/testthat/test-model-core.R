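# Gas-exchange model core: worked examples frozen from independent hand
# evaluation, limits, and structural properties of the closed forms.

test_that("mean blood flow matches hand evaluation and its limits", {
  expect_equal(mean_blood_flow(patient_params(1000), rescuer_params(x = 30)),
               1000 * 30 / 43.3, tolerance = 1e-12)
  # no compressions, no flow
  expect_identical(mean_blood_flow(patient_params(800), rescuer_params(x = 0)), 0)
  # large-ratio asymptote approaches q_max from below
  q_inf <- mean_blood_flow(patient_params(1000), rescuer_params(x = 1e6))
  expect_lt(q_inf, 1000)
  expect_gt(q_inf, 1000 * (1 - 1e-4))
  expect_error(rescuer_params(t = 0), class = "cproptim_domain_error")
})

test_that("mean blood flow is strictly increasing in x and bounded by q_max", {
  xs <- seq(0.5, 400, length.out = 100)
  q <- vapply(xs, function(x) mean_blood_flow(900, rescuer_params(x = x)), numeric(1))
  expect_true(all(diff(q) > 0))
  expect_true(all(q < 900))
})

test_that("ventilation rate is one breath per full cycle", {
  expect_equal(ventilation_rate(rescuer_params(x = 30, t = 0.01, T = 0.133)),
               1 / 0.433, tolerance = 1e-12)
  expect_equal(ventilation_rate(rescuer_params(x = 0, T = 0.133)),
               1 / 0.133, tolerance = 1e-12)
  expect_equal(ventilation_rate(rescuer_params(x = 15, t = 0.012, T = 0.133)),
               1 / 0.313, tolerance = 1e-12)
  expect_error(ventilation_rate(list(T = 0, t = 0.01, x = 0, v_t = 800,
                                     f_I_O2 = 0.16, f_I_CO2 = 4e-4)),
               class = "cproptim_domain_error")
})

test_that("alveolar fractions match the mass balance and bracket inspired", {
  fr <- alveolar_fractions(rescuer_params(v_t = 800), Q_bar = 692.84, R = 2.309)
  va <- 650 * 2.309
  expect_equal(fr$f_A_O2, va * 0.16 / (va + 692.84 * 1.5), tolerance = 1e-12)
  expect_equal(fr$f_A_CO2, va * 4e-4 / (va - 692.84 * 0.8), tolerance = 1e-12)
  expect_lt(fr$f_A_O2, 0.16)
  expect_gt(fr$f_A_CO2, 4e-4)
  # no perfusion: alveolar equals inspired
  fr0 <- alveolar_fractions(rescuer_params(), Q_bar = 0, R = 2.309)
  expect_equal(fr0$f_A_O2, 0.16)
  expect_equal(fr0$f_A_CO2, 4e-4)
  # near-dead-space tidal volume: perfusion outruns ventilation
  expect_error(alveolar_fractions(rescuer_params(v_t = 160), Q_bar = 692.84, R = 2.309),
               class = "cproptim_singularity_error")
  expect_error(alveolar_fractions(rescuer_params(v_t = 100), Q_bar = 100, R = 2),
               class = "cproptim_domain_error")
})

test_that("concentration changes are linear in alveolar fractions", {
  dc <- delta_concentrations(0.0945, 6.34e-4)
  expect_equal(dc$delta_C_O2, 1.5 * 0.0945, tolerance = 1e-12)
  expect_equal(dc$delta_C_CO2, 0.8 * 6.34e-4, tolerance = 1e-12)
  expect_equal(delta_concentrations(0, 0), list(delta_C_O2 = 0, delta_C_CO2 = 0))
})

test_that("delivery snapshot reproduces the frozen worked example", {
  snap <- fixture_snapshot()
  expect_equal(snap$Q_bar, fixture_expected$Q_bar, tolerance = 1e-12)
  expect_equal(snap$D_O2, fixture_expected$D_O2, tolerance = 1e-12)
  expect_equal(snap$D_CO2, fixture_expected$D_CO2, tolerance = 1e-12)
  expect_equal(snap$D_total, fixture_expected$D_total, tolerance = 1e-12)
  expect_equal(snap$D_total, snap$D_O2 + snap$D_CO2, tolerance = 1e-15)

  corr <- fixture_snapshot("corrected_co2")
  expect_equal(corr$D_O2, fixture_expected$D_O2, tolerance = 1e-12)
  expect_equal(corr$D_CO2, fixture_expected$D_CO2_corrected, tolerance = 1e-12)
})

test_that("explicit-R variant composes the sub-operations exactly", {
  snap <- fixture_snapshot("explicit_R")
  r <- do.call(rescuer_params, fixture_inputs[RESCUER_PARAMS_TEST])
  Qb <- mean_blood_flow(fixture_inputs$q_max, r)
  R <- ventilation_rate(r)
  fr <- alveolar_fractions(r, Q_bar = Qb, R = R)
  dc <- delta_concentrations(fr$f_A_O2, fr$f_A_CO2)
  expect_equal(snap$R, R, tolerance = 1e-12)
  expect_equal(snap$f_A_O2, fr$f_A_O2, tolerance = 1e-12)
  expect_equal(snap$D_O2, Qb * dc$delta_C_O2, tolerance = 1e-12)
  expect_equal(snap$D_CO2, Qb * dc$delta_C_CO2, tolerance = 1e-12)
})

test_that("zero compressions give zero delivery in every variant", {
  for (v in c("as_printed", "corrected_co2", "explicit_R")) {
    snap <- blood_gas_delivery(900, rescuer_params(x = 0), variant = v)
    expect_equal(snap$Q_bar, 0)
    expect_equal(snap$D_O2, 0)
    expect_equal(snap$D_CO2, 0)
    expect_equal(snap$D_total, 0)
  }
})

test_that("oxygen delivery vanishes as tidal volume approaches dead space", {
  # D_O2 <= (v_t - v_d) * f_I_O2 / t: the denominator's perfusion term
  # bounds the ratio, so the delivery is squeezed to zero with v_t - v_d.
  # (The CO2 delivery instead diverges at its singular pole, which is why
  # near-dead-space tidal volumes become infeasible rather than harmless.)
  r <- list(T = 0.133, t = 0.008, x = 0.1, f_I_O2 = 0.16, f_I_CO2 = 4e-4)
  vts <- c(250, 180, 155, 150.5)
  d <- vapply(vts, function(vt) {
    blood_gas_delivery(500, c(r, v_t = vt), variant = "as_printed")$D_O2
  }, numeric(1))
  expect_true(all(diff(d) < 0))
  expect_true(all(d <= (vts - 150) * r$f_I_O2 / r$t))
  for (pt in interior_points(10, seed = 31)) {
    snap <- blood_gas_delivery(900, pt)
    expect_lte(snap$D_O2, (pt$v_t - 150) * pt$f_I_O2 / pt$t)
  }
})

test_that("as-printed and corrected variants agree on oxygen delivery", {
  for (pt in interior_points(10)) {
    a <- blood_gas_delivery(950, pt, variant = "as_printed")
    b <- blood_gas_delivery(950, pt, variant = "corrected_co2")
    expect_equal(a$D_O2, b$D_O2, tolerance = 1e-14)
  }
})

test_that("partial-derivative signs hold at 50 random interior points", {
  pts <- interior_points(50, seed = 77)
  fd <- function(pt, nm, h) {
    up <- pt; up[[nm]] <- pt[[nm]] + h
    dn <- pt; dn[[nm]] <- pt[[nm]] - h
    s_up <- blood_gas_delivery(900, up)
    s_dn <- blood_gas_delivery(900, dn)
    c(dD_O2 = (s_up$D_O2 - s_dn$D_O2) / (2 * h),
      dD_CO2 = (s_up$D_CO2 - s_dn$D_CO2) / (2 * h))
  }
  for (pt in pts) {
    expect_gt(fd(pt, "x", 1e-4)[["dD_O2"]], 0)
    expect_gt(fd(pt, "f_I_O2", 1e-6)[["dD_O2"]], 0)
    expect_gt(fd(pt, "v_t", 1e-3)[["dD_O2"]], 0)
    expect_lt(fd(pt, "v_t", 1e-3)[["dD_CO2"]], 0)
    expect_lt(fd(pt, "T", 1e-6)[["dD_O2"]], 0)
  }
})

test_that("alveolar fractions bracket inspired fractions at every valid point", {
  pts <- dplyr::bind_rows(purrr::map(interior_points(40, seed = 5), tibble::as_tibble))
  pts$q_max <- 1000
  for (v in c("as_printed", "explicit_R")) {
    # the cycle-based ventilation rate makes high-ratio/low-volume points
    # singular; bracketing is asserted on the feasible evaluations
    out <- bgd_evaluate(pts, variant = v)
    out <- out[out$feasible, ]
    expect_gt(nrow(out), 0)
    expect_true(all(out$f_A_O2 <= out$f_I_O2))
    expect_true(all(out$f_A_CO2 >= out$f_I_CO2))
  }
})

test_that("weighted total delivery combines and projects", {
  snap <- fixture_snapshot()
  expect_equal(weighted_total_delivery(snap, 1, 1), snap$D_total, tolerance = 1e-15)
  expect_equal(weighted_total_delivery(snap, 0, 0), 0)
  expect_equal(weighted_total_delivery(snap, 1, 0), snap$D_O2)
  expect_error(weighted_total_delivery(snap, -1, 1), class = "cproptim_domain_error")
})

test_that("vectorized evaluation agrees with scalar evaluation and flags infeasible rows", {
  pts <- dplyr::bind_rows(purrr::map(interior_points(8), tibble::as_tibble))
  pts$q_max <- seq(700, 1100, length.out = 8)
  out <- bgd_evaluate(pts)
  for (i in seq_len(nrow(pts))) {
    snap <- blood_gas_delivery(pts$q_max[i], as.list(pts[i, ]))
    expect_equal(out$D_total[i], snap$D_total, tolerance = 1e-12)
  }
  bad <- pts
  bad$v_t[1] <- 100  # below dead space
  out2 <- bgd_evaluate(bad)
  expect_false(out2$feasible[1])
  expect_true(is.na(out2$D_total[1]))
  expect_true(all(out2$feasible[-1]))
})

test_that("domain validation reports instead of raising", {
  ok <- validate_domain(patient_params(900), rescuer_params())
  expect_s3_class(ok, "tbl_df")
  expect_identical(nrow(ok), 0L)

  v1 <- validate_domain(900, list(T = 0.133, t = 0.01, x = 30, v_t = 100,
                                  f_I_O2 = 0.16, f_I_CO2 = 4e-4))
  expect_identical(nrow(v1), 1L)
  expect_identical(v1$parameter, "v_t")
  expect_identical(v1$condition, "dead_space")

  v2 <- validate_domain(900, list(T = 0.133, t = 0, x = 30, v_t = 800,
                                  f_I_O2 = 0.16, f_I_CO2 = 4e-4))
  expect_true("t" %in% v2$parameter)

  # CO2 singularity: tiny effective ventilation against full perfusion
  v3 <- validate_domain(5000, list(T = 0.0001, t = 0.012, x = 100, v_t = 155,
                                   f_I_O2 = 0.16, f_I_CO2 = 4e-4))
  expect_true("co2_singularity" %in% v3$condition)

  v4 <- validate_domain(900, rescuer_params(x = 300), bounds = default_bounds())
  expect_true("bound" %in% v4$condition)
})

test_that("singular configurations raise a typed error from the snapshot path", {
  expect_error(blood_gas_delivery(5000, list(T = 0.0001, t = 0.012, x = 100, v_t = 155,
                                             f_I_O2 = 0.16, f_I_CO2 = 4e-4)),
               class = "cproptim_singularity_error")
  expect_error(blood_gas_delivery(900, rescuer_params(v_t = 100)),
               class = "cproptim_domain_error")
})
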