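# Time-activity curves, TIAC integration, human projection, RBE-weighted
# dose coefficients, dose tables, activity limits and safety margins.

HL <- 10.6
LAM <- log(2) / HL

test_that("time-activity curves apply physical decay to %ID/g means", {
  summ <- data.frame(organ = "kidneys", timepoint_h = c(1, 4, 24),
                     mean_pct_id_g = c(5, 3, 1))
  tacs <- build_time_activity_curves(summ, c(kidneys = 1), half_life = HL)
  k <- tacs[tacs$organ == "kidneys", ]
  expect_equal(k$time_h, c(0, 1, 4, 24))
  expect_equal(k$frac[1], 0)                       # t=0 anchor
  expect_equal(k$frac[2], 0.05 * 2^(-1 / HL), tolerance = 1e-12)
  expect_equal(round(k$frac[2], 4), 0.0468)
  # constant 100 %ID in a 1 g organ decays as exp(-lambda t)
  summ2 <- data.frame(organ = "o", timepoint_h = c(1, 4, 24),
                      mean_pct_id_g = 100 * 2^(c(1, 4, 24) / HL) *
                        exp(-LAM * c(1, 4, 24)) / exp(-LAM * c(1, 4, 24)))
  summ2$mean_pct_id_g <- 100  # decay-corrected convention: flat at 100
  tacs2 <- build_time_activity_curves(summ2, c(o = 1), half_life = HL,
                                      include_t0 = FALSE)
  expect_equal(tacs2$frac, exp(-LAM * c(1, 4, 24)), tolerance = 1e-12)
  # zero-uptake organ is identically zero
  summ3 <- data.frame(organ = "o", timepoint_h = c(1, 4), mean_pct_id_g = 0)
  expect_equal(build_time_activity_curves(summ3, c(o = 1), HL)$frac,
               c(0, 0, 0))
  expect_error(build_time_activity_curves(summ, c(liver = 1), HL), "mass")
})

test_that("TIAC is trapezoid plus physical-decay tail", {
  # dense sampling of a purely physical curve recovers 1/lambda
  tt <- seq(0, 72, length.out = 1000)
  expect_equal(compute_tiac(tt, exp(-LAM * tt), HL), 1 / LAM, tolerance = 1e-4)
  expect_equal(1 / LAM, 15.29, tolerance = 1e-3)
  # sparse sampling overestimates a convex decaying curve; frozen hand value
  tt5 <- c(0, 1, 4, 24)
  a5 <- exp(-LAM * tt5)
  got <- compute_tiac(tt5, a5, HL)
  hand <- 0.5 * (a5[1] + a5[2]) + 1.5 * (a5[2] + a5[3]) + 10 * (a5[3] + a5[4]) +
    a5[4] / LAM
  expect_equal(got, hand, tolerance = 1e-12)
  expect_equal(got, 16.49, tolerance = 1e-3)
  expect_gt(got, 1 / LAM)
  # identically-zero curve
  expect_equal(compute_tiac(c(0, 24), c(0, 0), HL), 0)
  expect_error(compute_tiac(1, 1, HL), "at least 2")
})

test_that("TIAC respects its bounds: at least the tail, at most max-frac/lambda under dense sampling", {
  set.seed(31)
  for (i in 1:20) {
    tb <- runif(1, 0.5, 50)
    tt <- seq(0, 72, length.out = 800)
    frac <- runif(1, 0.01, 1) * 2^(-tt / tb) * exp(-LAM * tt)
    v <- compute_tiac(tt, frac, HL)
    expect_gte(v, tail(frac, 1) / LAM)
    expect_lte(v, max(frac) / LAM * (1 + 1e-3))
  }
})

test_that("human projection preserves relative concentrations exactly", {
  mouse <- load_phantom("mouse")
  human <- load_phantom("human_female")
  tt <- c(0, 1, 4, 24)
  tacs <- structure(rbind(
    data.frame(organ = "kidneys", time_h = tt,
               frac = 0.06 * 2^(-tt / 3) * exp(-LAM * tt)),
    data.frame(organ = "liver", time_h = tt,
               frac = 0.04 * 2^(-tt / 10) * exp(-LAM * tt)),
    data.frame(organ = "carcass", time_h = tt,
               frac = 0.80 * 2^(-tt / 8) * exp(-LAM * tt))),
    class = c("tac_set", "data.frame"), half_life = HL)
  h <- extrapolate_to_human(tacs, mouse, human)
  wb_m <- whole_body_curve(tacs)
  wb_h <- wb_m  # by construction the human whole-body fraction equals mouse's
  for (o in c("kidneys", "liver")) {
    dm <- tacs[tacs$organ == o, ]; dh <- h[h$organ == o, ]
    r_mouse <- (dm$frac / (mouse$organ_masses[[o]] * 1000)) /
      (wb_m$frac / (mouse$body_mass * 1000))
    r_human <- (dh$frac / (human$organ_masses[[o]] * 1000)) /
      (wb_h$frac / (human$body_mass * 1000))
    expect_equal(r_human[-1], r_mouse[-1], tolerance = 1e-9)
  }
  # organ at whole-body concentration maps to its human mass share
  tacs_eq <- structure(
    data.frame(organ = "kidneys", time_h = tt,
               frac = (mouse$organ_masses[["kidneys"]] / mouse$body_mass) *
                 exp(-LAM * tt)),
    class = c("tac_set", "data.frame"), half_life = HL)
  wb_eq <- data.frame(time_h = tt, frac = exp(-LAM * tt))
  h_eq <- extrapolate_to_human(tacs_eq, mouse, human, whole_body = wb_eq)
  expect_equal(h_eq$frac,
               human$organ_masses[["kidneys"]] / human$body_mass *
                 exp(-LAM * tt), tolerance = 1e-12)
  # common rescaling leaves R(t) unchanged; the projection scales only
  # through the whole-body curve (whole-body renormalization)
  tacs2 <- tacs; tacs2$frac <- tacs2$frac * 0.5
  h2 <- extrapolate_to_human(tacs2, mouse, human)
  expect_equal(h2$frac, 0.5 * h$frac, tolerance = 1e-12)
  expect_error(extrapolate_to_human(
    structure(data.frame(organ = "nonesuch", time_h = tt, frac = 0),
              class = c("tac_set", "data.frame"), half_life = HL),
    mouse, human), "missing")
})

test_that("dose coefficients follow the energy-mass arithmetic", {
  em <- chain_emission_summary(test_chain())
  ph <- structure(list(organ_masses = c(kidneys = 0.31), body_mass = 73,
                       dose_limits = c(kidneys = 23), species = "test"),
                  class = "phantom")
  co <- absorbed_dose_coefficients(c(kidneys = 1), ph, em, rbe = 5)
  expect_equal(unname(co["kidneys"]), 74.2, tolerance = 1e-2)
  # rbe -> 1 with only alphas reduces to the unweighted alpha dose
  em1 <- structure(list(e_alpha = 6, e_electron = 0, e_photon = 0),
                   class = "emission_summary")
  c1 <- absorbed_dose_coefficients(c(kidneys = 1), ph, em1, rbe = 1)
  expect_equal(unname(c1["kidneys"]),
               3600 * 6 * 1.602176634e-13 / 0.31 * 1e9)
  expect_equal(unname(attr(c1, "alpha_fraction")), 1)
  # doubling mass halves the coefficient
  ph2 <- ph; ph2$organ_masses["kidneys"] <- 0.62
  c2 <- absorbed_dose_coefficients(c(kidneys = 1), ph2, em, rbe = 5)
  expect_equal(as.numeric(c2) / as.numeric(co), 0.5)
  expect_error(absorbed_dose_coefficients(c(kidneys = 1), ph, em, rbe = -1),
               "positive")
})

test_that("dose is linear in administered activity and TIAC", {
  em <- chain_emission_summary(test_chain())
  ph <- load_phantom("human_female")
  set.seed(33)
  for (i in 1:10) {
    tiac <- c(kidneys = runif(1, 0.1, 10), liver = runif(1, 0.1, 10))
    co <- absorbed_dose_coefficients(tiac, ph, em, rbe = 5)
    k <- runif(1, 0.5, 4)
    co_k <- absorbed_dose_coefficients(tiac * k, ph, em, rbe = 5)
    expect_equal(unname(as.numeric(co_k)), unname(as.numeric(co)) * k,
                 tolerance = 1e-12)
    a <- runif(2, 0.05, 5)
    dt <- dose_table(co, a, limits = c(kidneys = 23, liver = 30))
    expect_equal(dt$doses[, 2] / dt$doses[, 1], rep(a[2] / a[1], 2),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("activity limit picks the binding organ and round-trips", {
  co <- structure(c(a = 1, b = 2), class = "dose_coefficients", rbe = 5,
                  photon_absorbed_fraction = 0)
  al <- activity_limit(co, c(a = 10, b = 10))
  expect_equal(al$limiting_organ, "b")
  expect_equal(al$activity_GBq, 5)
  # round-trip identity: limit activity x coefficient = limit
  expect_equal(al$activity_GBq * 2, 10)
  # zero coefficient with a finite limit is an unbounded allowance
  co0 <- structure(c(a = 0, b = 2), class = "dose_coefficients", rbe = 5,
                   photon_absorbed_fraction = 0)
  al0 <- activity_limit(co0, c(a = 10, b = 10))
  expect_equal(unname(al0$allowances_GBq["a"]), Inf)
  expect_error(activity_limit(co, c(a = NA, b = NA)), "finite")
  # margin at the activity limit is exactly 1
  expect_equal(safety_margin(co, "b", al$activity_GBq, 10), 1)
  expect_equal(safety_margin(co0, "a", 1, 10), Inf)
})

test_that("phantom loader validates masses", {
  ph <- load_phantom("human_female")
  expect_equal(unname(ph$organ_masses["kidneys"]), 0.275)
  expect_lt(sum(ph$organ_masses), ph$body_mass + 1e-9)
  expect_equal(unname(ph$dose_limits["kidneys"]), 23)
  tf <- tempfile(fileext = ".csv")
  writeLines(c("organ,mass_kg,dose_limit_Gy", "kidneys,0.3,23"), tf)
  expect_error(load_phantom(tf), "body")
})
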