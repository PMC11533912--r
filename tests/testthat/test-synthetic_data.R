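# Generators: calibration to the study's summary kinetics, determinism,
# dose conservation, and pipeline round trips.

test_that("default biodistribution scenario reproduces the headline kinetics", {
  tb <- gen_biodist(biodist_scenario(cv = 0), seed = 1)
  s <- summarize_biodist(tb)
  at1 <- s[s$timepoint_h == 1, ]
  expect_gt(at1$mean_pct_id_g[at1$organ == "pancreas"], 30)
  expect_equal(at1$mean_pct_id_g[at1$organ == "tumor"], 5, tolerance = 0.05)
  # tumor plateau: stays near 5 %ID/g out to 24 h
  at24 <- s[s$timepoint_h == 24, ]
  expect_gt(at24$mean_pct_id_g[at24$organ == "tumor"], 4)
  # pancreas washes out by 24 h
  expect_lt(at24$mean_pct_id_g[at24$organ == "pancreas"],
            0.1 * at1$mean_pct_id_g[at1$organ == "pancreas"])
})

test_that("peptide-mass self-blocking reduces pancreas uptake ~30%", {
  s28 <- summarize_biodist(gen_biodist(biodist_scenario(cv = 0), seed = 1))
  s280 <- summarize_biodist(gen_biodist(
    biodist_scenario(cv = 0, peptide_mass_ng = 280), seed = 1))
  ratio <- s280$mean_pct_id_g[s280$organ == "pancreas" & s280$timepoint_h == 1] /
    s28$mean_pct_id_g[s28$organ == "pancreas" & s28$timepoint_h == 1]
  expect_equal(ratio, 0.70, tolerance = 1e-9)
  # tumor uptake is independent of peptide mass
  rt <- s280$mean_pct_id_g[s280$organ == "tumor" & s280$timepoint_h == 1] /
    s28$mean_pct_id_g[s28$organ == "tumor" & s28$timepoint_h == 1]
  expect_equal(rt, 1, tolerance = 1e-9)
  # and the blocking comparison is statistically visible under noise
  p28 <- percent_id_per_gram(gen_biodist(biodist_scenario(cv = 0.1), seed = 5))
  p280 <- percent_id_per_gram(gen_biodist(
    biodist_scenario(cv = 0.1, peptide_mass_ng = 280), seed = 6, group = "280ng"))
  cmp <- compare_uptake_groups(rbind(p28, p280), "28ng", "280ng",
                               "pancreas", 1)
  expect_lt(cmp$percent_change, -10)
})

test_that("generators are deterministic by seed", {
  expect_identical(gen_biodist(biodist_scenario(), seed = 7),
                   gen_biodist(biodist_scenario(), seed = 7))
  expect_false(identical(gen_biodist(biodist_scenario(), seed = 7),
                         gen_biodist(biodist_scenario(), seed = 8)))
  expect_identical(gen_binding_plate(seed = 3), gen_binding_plate(seed = 3))
  expect_identical(gen_survival(seed = 3), gen_survival(seed = 3))
  expect_identical(gen_chromatogram(seed = 3), gen_chromatogram(seed = 3))
  expect_false(identical(gen_chromatogram(seed = 3), gen_chromatogram(seed = 4)))
})

test_that("the generator conserves the injected dose", {
  tb <- gen_biodist(biodist_scenario(cv = 0), seed = 2)
  pct <- percent_id_per_gram(tb)
  # mass-weighted sum of %ID/g over all organs = total %ID <= 100 per animal
  tot <- tapply(pct$pct_id, pct$animal_id, sum)
  expect_true(all(tot <= 100 + 1e-9))
  # at t = 0+ the organs plus carcass account for the full dose
  sc <- biodist_scenario(cv = 0)
  f0 <- sum(sc$organs$f_eff)
  expect_equal(f0, 1, tolerance = 1e-12)
  # organ + excreted = 100 %ID at each sampled time (excreted = shortfall,
  # non-negative and non-decreasing)
  excreted <- 100 - vapply(split(pct, pct$timepoint_h), function(d) {
    sum(d$pct_id) / length(unique(d$animal_id))
  }, numeric(1))
  expect_true(all(excreted >= -1e-9))
  expect_true(all(diff(excreted[order(as.numeric(names(excreted)))]) >= -1e-9))
})

test_that("binding-plate generator matches the assay design and truth", {
  pl <- gen_binding_plate(cv = 0, seed = 1)
  expect_equal(sort(unique(pl$data$concentration_nM)),
               c(0.5, 1, 2, 4, 8, 16, 32, 64))
  expect_equal(sum(pl$data$well_type == "total"), 24)  # triplicates
  sb <- specific_binding(pl)
  expect_equal(sb$specific, 5000 * sb$concentration_nM / (3.93 + sb$concentration_nM),
               tolerance = 1e-9)
})

test_that("survival generator censors at study end and hits its medians", {
  rec <- gen_survival(survival_scenario(), seed = 1)
  expect_equal(nrow(rec), 65)
  expect_true(all(rec$time_weeks <= 22))
  expect_true(all(rec$event[rec$time_weeks < 22] == 1))
  # degenerate shape: every event lands at the group median
  deg <- gen_survival(survival_scenario(shape = Inf), seed = 1)
  expect_equal(deg$time_weeks[deg$group == "buffer"], rep(9.4, 10))
  # Monte Carlo calibration: mean control median near the configured 9.4 wk
  meds <- vapply(1:300, function(i) {
    r <- gen_survival(survival_scenario(), seed = 4000 + i)
    km_curve(r$time_weeks[r$group == "buffer"],
             r$event[r$group == "buffer"])$median
  }, numeric(1))
  expect_gt(mean(meds), 8.4)
  expect_lt(mean(meds), 10.4)
})

test_that("chromatogram generator hits its area fraction", {
  expect_equal(chromatogram_purity(gen_chromatogram(1, noise = FALSE)), 100)
  expect_equal(chromatogram_purity(gen_chromatogram(0.96, noise = FALSE)), 96,
               tolerance = 1e-6)
  # Poisson noise at 1e5 counts keeps purity within ~1% (binomial SD bound)
  p <- chromatogram_purity(gen_chromatogram(0.96, total_counts = 1e5, seed = 2))
  expect_lt(abs(p - 96), 1)
})

test_that("pipeline TIACs recover the scenario's analytic integrals", {
  lam <- log(2) / pb212_half_life_h()
  analytic_tiac <- function(row) {
    w2 <- 1 - row$w1
    v <- row$w1 / (lam + log(2) / row$tb1_h)
    if (w2 > 0) v <- v + w2 / (lam + log(2) / row$tb2_h)
    row$f_eff * v
  }
  # dense sampling from injection: < 0.5% error
  sc_dense <- biodist_scenario(cv = 0, n_per_timepoint = 1,
                               timepoints_h = seq(0, 72, by = 0.1))
  tb <- gen_biodist(sc_dense, seed = 1)
  summ <- summarize_biodist(tb)
  masses <- setNames(sc_dense$organs$mass_g, sc_dense$organs$organ)
  tiacs <- tiac_set(build_time_activity_curves(summ, masses))
  for (i in seq_len(nrow(sc_dense$organs))) {
    row <- sc_dense$organs[i, ]
    expect_equal(unname(tiacs[row$organ]), analytic_tiac(row),
                 tolerance = 5e-3)
  }
  # study-like 5-timepoint design (log-spaced over ~2 half-lives): < 10% error
  sc5 <- biodist_scenario(cv = 0, n_per_timepoint = 1,
                          timepoints_h = c(1, 4, 8, 16, 24))
  tb5 <- gen_biodist(sc5, seed = 1)
  tiacs5 <- tiac_set(build_time_activity_curves(summarize_biodist(tb5), masses))
  for (i in seq_len(nrow(sc5$organs))) {
    row <- sc5$organs[i, ]
    truth <- analytic_tiac(row)
    expect_lt(abs(unname(tiacs5[row$organ]) - truth) / truth, 0.10)
  }
})

test_that("tumor-size cohort shows the necrotic-core signature", {
  pct <- percent_id_per_gram(gen_tumor_size_cohort(seed = 1))
  res <- uptake_vs_tumor_size(pct)
  expect_lt(res$corr_idg, 0)
  expect_lt(res$p_idg, 0.05)
  expect_lt(abs(res$corr_id), abs(res$corr_idg))
})

test_that("infeasible scenarios are rejected", {
  org <- default_organ_kinetics()
  org$f0[org$organ == "pancreas"] <- 1.2
  expect_error(biodist_scenario(organs = org), "infeasible")
})
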