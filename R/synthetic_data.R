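# Seeded synthetic-data generators emulating the preclinical study designs:
# biodistribution cohorts (5 animals/timepoint, tumor plateau ~5 %ID/g, high
# early pancreas uptake with peptide-mass self-blocking), triplicate
# saturation-binding plates over 0.5-64 nM, treatment-group survival cohorts,
# and two-peak radio-chromatograms.

# lognormal noise multipliers with mean 1 and the requested CV
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Default organ kinetics for the biodistribution generator
#'
#' Each organ carries a mass (g), an initial uptake fraction of the injected
#' dose \code{f0}, and a bi-exponential biological retention
#' \code{w1 * 2^(-t/tb1) + (1-w1) * 2^(-t/tb2)}. The carcass/remainder row
#' absorbs whatever fraction the named organs do not take at \code{t = 0},
#' so the injected dose is conserved (unretained activity counts as
#' excreted). Defaults are calibrated to the study's summary kinetics:
#' tumor plateau near 5 \%ID/g, pancreas above 30 \%ID/g at 1 h with fast
#' washout, predominantly renal excretion.
#'
#' @return Data frame of per-organ kinetic parameters.
#' @export
default_organ_kinetics <- function() {
  data.frame(
    organ = c("tumor", "pancreas", "kidneys", "liver", "spleen", "lungs",
              "heart_wall", "stomach_wall", "blood", "carcass"),
    mass_g = c(0.3, 0.2, 0.4, 1.3, 0.1, 0.15, 0.15, 0.3, 1.5, 20),
    f0 = c(0.015, 0.105, 0.06, 0.04, 0.002, 0.004, 0.002, 0.003, 0.05, NA),
    w1 = c(1, 0.9, 0.75, 1, 1, 1, 1, 1, 0.9, 1),
    tb1_h = c(200, 1.5, 1.5, 10, 10, 4, 4, 8, 0.5, 8),
    tb2_h = c(NA, 20, 40, NA, NA, NA, NA, NA, 30, NA),
    stringsAsFactors = FALSE
  )
}

#' Biodistribution scenario
#'
#' @param organs Kinetics table as in \code{\link{default_organ_kinetics}};
#'   the \code{carcass} row's \code{f0} is filled with the remainder.
#' @param peptide_mass_ng Injected peptide mass (28, 140 or 280 ng in the
#'   specific-activity arm; 28 ng default).
#' @param k_block_ng Saturable self-blocking constant: uptake of blocked
#'   organs scales by \code{1 / (1 + peptide_mass_ng / k_block_ng)}. The
#'   default 560 ng makes 280 vs 28 ng reduce pancreas uptake by exactly
#'   30\%.
#' @param blocked_organs Organs subject to receptor self-blocking.
#' @param cv Lognormal noise CV on counts.
#' @param n_per_timepoint Animals per timepoint (study design: 5).
#' @param timepoints_h Collection times, hours (study design: 1, 4, 24).
#' @param tumor_volume_mm3 Mean tumor volume.
#' @return List of class \code{biodist_scenario}.
#' @export
biodist_scenario <- function(organs = default_organ_kinetics(),
                             peptide_mass_ng = 28, k_block_ng = 560,
                             blocked_organs = "pancreas", cv = 0.10,
                             n_per_timepoint = 5, timepoints_h = c(1, 4, 24),
                             tumor_volume_mm3 = 300) {
  if (cv < 0) stop("`cv` must be non-negative", call. = FALSE)
  block <- 1 / (1 + peptide_mass_ng / k_block_ng)
  f_eff <- organs$f0
  f_eff[organs$organ %in% blocked_organs] <-
    f_eff[organs$organ %in% blocked_organs] * block
  carcass <- which(organs$organ == "carcass")
  f_eff[carcass] <- 1 - sum(f_eff[-carcass])
  if (any(f_eff < 0) || sum(f_eff) > 1 + 1e-9) {
    stop("infeasible uptake fractions: organs exceed the injected dose",
         call. = FALSE)
  }
  organs$f_eff <- f_eff
  structure(list(organs = organs, peptide_mass_ng = peptide_mass_ng,
                 k_block_ng = k_block_ng, blocked_organs = blocked_organs,
                 cv = cv, n_per_timepoint = n_per_timepoint,
                 timepoints_h = timepoints_h,
                 tumor_volume_mm3 = tumor_volume_mm3),
            class = "biodist_scenario")
}

# true biological retention (fraction of ID) of one organ row at time t
organ_retention <- function(row, t) {
  w2 <- 1 - row$w1
  r <- row$w1 * 2^(-t / row$tb1_h)
  if (w2 > 0) r <- r + w2 * 2^(-t / row$tb2_h)
  row$f_eff * r
}

#' Generate a synthetic biodistribution table
#'
#' Per-animal organ counts with lognormal noise, a full-dose-equivalent
#' counting standard, physical decay applied at the collection time, and
#' dose conservation via the carcass/remainder compartment.
#'
#' @param scenario A \code{biodist_scenario}.
#' @param seed Integer seed; same seed, same table.
#' @param group Group label (default derived from the peptide mass).
#' @param standard_counts Counts equivalent to the full injected dose at the
#'   reference time.
#' @return A \code{\link{biodist_table}}.
#' @export
gen_biodist <- function(scenario, seed, group = NULL, standard_counts = 2e6) {
  stopifnot(inherits(scenario, "biodist_scenario"))
  set.seed(seed)
  if (is.null(group)) group <- paste0(scenario$peptide_mass_ng, "ng")
  half_life <- pb212_half_life_h()
  org <- scenario$organs
  animals <- data.frame(
    timepoint_h = rep(scenario$timepoints_h, each = scenario$n_per_timepoint))
  animals$animal_id <- sprintf("%s_a%02d", group, seq_len(nrow(animals)))
  animals$tumor_volume_mm3 <- scenario$tumor_volume_mm3 *
    lognormal_noise(nrow(animals), if (scenario$cv > 0) 0.2 else 0)
  grid <- merge(animals, org, by = NULL, sort = FALSE)
  w2 <- 1 - grid$w1
  frac <- grid$f_eff * (grid$w1 * 2^(-grid$timepoint_h / grid$tb1_h) +
                          ifelse(w2 > 0,
                                 w2 * 2^(-grid$timepoint_h / grid$tb2_h), 0))
  samples <- data.frame(
    animal_id = grid$animal_id, group = group,
    timepoint_h = grid$timepoint_h, organ = grid$organ, mass_g = grid$mass_g,
    counts = frac * standard_counts *
      decay_factor(half_life, grid$timepoint_h) *
      lognormal_noise(nrow(grid), scenario$cv),
    count_time_h = grid$timepoint_h,
    tumor_volume_mm3 = ifelse(grid$organ == "tumor",
                              grid$tumor_volume_mm3, NA_real_),
    stringsAsFactors = FALSE)
  samples <- samples[order(match(samples$animal_id, animals$animal_id),
                           match(samples$organ, org$organ)), ]
  rownames(samples) <- NULL
  biodist_table(samples, standard_counts = standard_counts,
                standard_fraction = 1, standard_time_h = 0)
}

#' Generate a varying-tumor-size cohort
#'
#' Emulates the tumor-size arm: cohorts at roughly 150, 300, 600 and 900
#' mm^3 collected at 4 h. Larger tumors develop necrotic cores, so
#' whole-tumor uptake (\%ID) falls only mildly with volume while uptake per
#' gram (\%ID/g) falls steeply through the mass denominator.
#'
#' @param volumes_mm3 Tumor volumes; default matches the study's group sizes
#'   (n = 5, 6, 4, 3 at 150/300/600/900 mm^3).
#' @param base_pct_id Whole-tumor \%ID of a fully viable tumor.
#' @param necrotic_loss Maximal fractional uptake loss to necrosis at the
#'   largest volumes.
#' @param density_g_mm3 Tissue density (g per mm^3).
#' @param cv Lognormal noise CV.
#' @param timepoint_h Collection time.
#' @param seed Integer seed.
#' @return A \code{\link{biodist_table}} of tumor samples.
#' @export
gen_tumor_size_cohort <- function(volumes_mm3 = rep(c(150, 300, 600, 900),
                                                    times = c(5, 6, 4, 3)),
                                  base_pct_id = 1.5, necrotic_loss = 0.12,
                                  density_g_mm3 = 1.05e-3, cv = 0.15,
                                  timepoint_h = 4, seed = 1) {
  set.seed(seed)
  half_life <- pb212_half_life_h()
  standard_counts <- 2e6
  viable <- 1 - necrotic_loss * pmax(0, volumes_mm3 - min(volumes_mm3)) /
    (max(volumes_mm3) - min(volumes_mm3))
  pct_id <- base_pct_id * viable
  rows <- data.frame(
    animal_id = sprintf("ts_a%02d", seq_along(volumes_mm3)),
    group = "tumor_size", timepoint_h = timepoint_h, organ = "tumor",
    mass_g = volumes_mm3 * density_g_mm3,
    counts = pct_id / 100 * standard_counts *
      decay_factor(half_life, timepoint_h) *
      lognormal_noise(length(volumes_mm3), cv),
    count_time_h = timepoint_h, tumor_volume_mm3 = volumes_mm3,
    stringsAsFactors = FALSE)
  biodist_table(rows, standard_counts = standard_counts,
                standard_fraction = 1, standard_time_h = 0)
}

#' Generate a synthetic saturation-binding plate
#'
#' Triplicate total and cold-block wells over the assay's concentration
#' range. Total wells carry one-site specific binding plus a linear
#' nonspecific component; cold-block wells carry only the nonspecific
#' component. Noise is lognormal with constant CV.
#'
#' @param kd True dissociation constant, nM.
#' @param bmax True maximal specific binding, counts.
#' @param ns_fraction Nonspecific counts at the top concentration as a
#'   fraction of \code{bmax}.
#' @param cv Noise CV.
#' @param concentrations Assay concentrations, nM.
#' @param replicates Wells per concentration and type.
#' @param seed Integer seed.
#' @return A \code{\link{binding_plate}}.
#' @export
gen_binding_plate <- function(kd = 3.93, bmax = 5000, ns_fraction = 0.05,
                              cv = 0.05,
                              concentrations = c(0.5, 1, 2, 4, 8, 16, 32, 64),
                              replicates = 3, seed = 1) {
  if (kd <= 0) stop("`kd` must be positive", call. = FALSE)
  set.seed(seed)
  ns <- ns_fraction * bmax * concentrations / max(concentrations)
  spec <- bmax * concentrations / (kd + concentrations)
  mk <- function(mu, type) {
    do.call(rbind, lapply(seq_along(concentrations), function(i) {
      data.frame(concentration_nM = concentrations[i],
                 replicate = seq_len(replicates), well_type = type,
                 counts = mu[i] * lognormal_noise(replicates, cv))
    }))
  }
  binding_plate(rbind(mk(spec + ns, "total"), mk(ns, "nonspecific")),
                cells_per_well = 35000)
}

#' Default survival-cohort presets
#'
#' Weibull scenarios per treatment group, with medians calibrated to the
#' study's reported group medians and group sizes matching the study design.
#'
#' @param shape Common Weibull shape (steepness of the survival drop).
#' @param study_end_wk Administrative censoring time.
#' @return List of class \code{survival_scenario}.
#' @export
survival_scenario <- function(shape = 2.5, study_end_wk = 22) {
  groups <- data.frame(
    group = c("buffer", "irrelevant_3x555", "grpr_4x370", "grpr_3x555",
              "grpr_1x1665"),
    n = c(10, 10, 15, 15, 15),
    median_wk = c(9.4, 10.5, 18.9, 16, 14.7),
    stringsAsFactors = FALSE)
  if (shape <= 0) stop("`shape` must be positive", call. = FALSE)
  structure(list(groups = groups, shape = shape, study_end_wk = study_end_wk),
            class = "survival_scenario")
}

#' Generate synthetic survival cohorts
#'
#' Weibull event times per group, censored at study end.
#'
#' @param scenario A \code{survival_scenario}.
#' @param seed Integer seed.
#' @return Data frame: \code{animal_id, group, time_weeks, event}.
#' @export
gen_survival <- function(scenario = survival_scenario(), seed = 1) {
  stopifnot(inherits(scenario, "survival_scenario"))
  set.seed(seed)
  shape <- scenario$shape
  rows <- do.call(rbind, lapply(seq_len(nrow(scenario$groups)), function(i) {
    g <- scenario$groups[i, ]
    scale <- g$median_wk / log(2)^(1 / shape)
    t_event <- if (is.infinite(shape)) rep(g$median_wk, g$n) else {
      stats::rweibull(g$n, shape = shape, scale = scale)
    }
    t_event <- pmax(t_event, 0.1)
    data.frame(animal_id = sprintf("%s_a%02d", g$group, seq_len(g$n)),
               group = g$group,
               time_weeks = pmin(t_event, scenario$study_end_wk),
               event = as.integer(t_event <= scenario$study_end_wk),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Generate a synthetic radio-chromatogram
#'
#' Gaussian main (intact-compound) peak plus an earlier-eluting oxidation
#' satellite on a 6-second fraction grid, with optional Poisson count noise.
#' The emitted \code{main_peak_window} cleanly separates the two peaks, so
#' with no noise the purity equals \code{main_area_fraction} exactly.
#'
#' @param main_area_fraction Fraction of total area in the main peak.
#' @param total_counts Expected total counts over the run.
#' @param noise Apply Poisson noise to fraction counts?
#' @param seed Integer seed (used only when \code{noise = TRUE}).
#' @return A \code{\link{chromatogram}}.
#' @export
gen_chromatogram <- function(main_area_fraction = 0.96, total_counts = 1e5,
                             noise = TRUE, seed = 1) {
  if (main_area_fraction < 0 || main_area_fraction > 1) {
    stop("`main_area_fraction` must lie in [0, 1]", call. = FALSE)
  }
  times <- seq(0, 600, by = 6)
  bin_mass <- function(mean, sd) {
    lo <- stats::pnorm(times - 3, mean, sd)
    hi <- stats::pnorm(times + 3, mean, sd)
    p <- hi - lo
    p / sum(p)
  }
  mu <- total_counts * (main_area_fraction * bin_mass(360, 15) +
                          (1 - main_area_fraction) * bin_mass(180, 10))
  counts <- if (noise) {
    set.seed(seed)
    stats::rpois(length(mu), mu)
  } else mu
  chromatogram(times, counts, main_peak_window = c(270, 600))
}
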