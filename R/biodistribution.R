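# Biodistribution analytics: %ID/g from counter data, group summaries,
# specific-activity (peptide mass) comparisons, tumor-size relationships,
# formulation metrics and radiochemical purity from chromatogram fractions.

#' Assemble a biodistribution table
#'
#' @param samples Data frame with columns \code{animal_id}, \code{group},
#'   \code{timepoint_h}, \code{organ}, \code{mass_g}, \code{counts},
#'   \code{count_time_h} (hours after the injection reference at which the
#'   sample was counted) and optionally \code{tumor_volume_mm3}.
#' @param standard_counts Net counts of the injected-dose standard.
#' @param standard_fraction Fraction of the injected dose the standard
#'   represents (1 for a full-dose-equivalent standard; 0.01 for a 1\%
#'   dilution).
#' @param standard_time_h Hours after reference at which the standard was
#'   counted (0 if counted at the reference time).
#' @return An object of class \code{biodist_table}.
#' @export
biodist_table <- function(samples, standard_counts, standard_fraction = 1,
                          standard_time_h = 0) {
  need <- c("animal_id", "group", "timepoint_h", "organ", "mass_g",
            "counts", "count_time_h")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    stop("samples lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(samples$mass_g <= 0)) stop("organ masses must be positive", call. = FALSE)
  if (any(samples$counts < 0)) stop("net counts must be non-negative", call. = FALSE)
  if (any(samples$timepoint_h < 0)) stop("timepoints must be non-negative", call. = FALSE)
  if (!is.numeric(standard_counts) || standard_counts <= 0) {
    stop("a positive `standard_counts` is required", call. = FALSE)
  }
  if (standard_fraction <= 0 || standard_fraction > 1) {
    stop("`standard_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(samples = as.data.frame(samples),
                 standard_counts = standard_counts,
                 standard_fraction = standard_fraction,
                 standard_time_h = standard_time_h),
            class = "biodist_table")
}

#' Read a biodistribution CSV
#'
#' Expected columns: \code{animal_id, group, timepoint_h, organ, mass_g,
#' counts, count_time_h} (or \code{count_time_iso}, converted relative to the
#' standard row's time) and optionally \code{tumor_volume_mm3}. Standards are
#' rows with \code{organ == "__standard__"}; their \code{mass_g} column is
#' ignored and the \code{timepoint_h} column may carry the represented dose
#' fraction via an optional \code{standard_fraction} column (default 1).
#'
#' @param path CSV file path.
#' @return A \code{biodist_table}.
#' @export
read_biodist <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("count_time_iso" %in% names(df) && !("count_time_h" %in% names(df))) {
    tt <- as.POSIXct(df$count_time_iso, tz = "UTC")
    std_i <- which(df$organ == "__standard__")
    if (!length(std_i)) stop("no `__standard__` row in ", path, call. = FALSE)
    ref <- min(tt)
    df$count_time_h <- as.numeric(difftime(tt, ref, units = "hours"))
  }
  std <- df[df$organ == "__standard__", , drop = FALSE]
  if (!nrow(std)) stop("no `__standard__` row in ", path, call. = FALSE)
  frac <- if ("standard_fraction" %in% names(std)) std$standard_fraction[1] else 1
  biodist_table(df[df$organ != "__standard__", , drop = FALSE],
                standard_counts = std$counts[1],
                standard_fraction = if (is.na(frac)) 1 else frac,
                standard_time_h = std$count_time_h[1])
}

#' Percent injected dose per gram of tissue
#'
#' Decay-corrects each sample's counts and the standard's counts to the
#' common reference time, scales by the fraction of the injected dose the
#' standard represents, and divides by organ mass. Values are therefore
#' decay-corrected to injection time (the counting-standard convention);
#' physical decay is re-applied downstream by the dosimetry layer.
#'
#' @param table A \code{biodist_table}.
#' @param half_life Half-life in hours used for decay correction
#'   (default: bundled Pb-212 value).
#' @return The sample data frame with added columns \code{pct_id} (\%ID in
#'   the whole organ) and \code{pct_id_g} (\%ID per gram).
#' @export
percent_id_per_gram <- function(table, half_life = pb212_half_life_h()) {
  stopifnot(inherits(table, "biodist_table"))
  s <- table$samples
  corr <- decay_correct_counts(s$counts, s$count_time_h, 0, half_life)
  std <- decay_correct_counts(table$standard_counts, table$standard_time_h, 0,
                              half_life)
  dose_counts <- std / table$standard_fraction
  s$pct_id <- 100 * corr / dose_counts
  s$pct_id_g <- s$pct_id / s$mass_g
  s
}

#' Half-life of Pb-212 from the bundled constants, in hours
#' @export
pb212_half_life_h <- function() {
  ch <- decay_chain()
  ch$nuclides$half_life_h[ch$nuclides$nuclide == "Pb-212"]
}

#' Summarize a biodistribution by organ, timepoint and group
#'
#' @param table A \code{biodist_table}, or a data frame already carrying
#'   \code{pct_id}/\code{pct_id_g} columns.
#' @param half_life Half-life (hours) forwarded to \code{percent_id_per_gram}.
#' @return Data frame with per-cell \code{n}, mean and sample SD (n-1
#'   denominator; \code{NA} for single-sample cells) of \%ID/g and \%ID.
#' @export
summarize_biodist <- function(table, half_life = pb212_half_life_h()) {
  s <- if (inherits(table, "biodist_table")) {
    percent_id_per_gram(table, half_life)
  } else {
    stopifnot(all(c("pct_id", "pct_id_g") %in% names(table)))
    table
  }
  key <- interaction(s$group, s$organ, s$timepoint_h, drop = TRUE)
  agg <- do.call(rbind, lapply(split(s, key), function(d) {
    data.frame(group = d$group[1], organ = d$organ[1],
               timepoint_h = d$timepoint_h[1], n = nrow(d),
               mean_pct_id_g = mean(d$pct_id_g),
               sd_pct_id_g = if (nrow(d) > 1) stats::sd(d$pct_id_g) else NA_real_,
               mean_pct_id = mean(d$pct_id),
               sd_pct_id = if (nrow(d) > 1) stats::sd(d$pct_id) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$group, agg$organ, agg$timepoint_h), ]
}

# standard atomic weights (IUPAC 2021, conventional)
ATOMIC_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904,
                    Na = 22.990, K = 39.098, Ca = 40.078, Pb = 207.2)

parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse molecular formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(ifelse(grepl("[0-9]+$", parts), sub("^[A-Za-z]+", "", parts), "1"))
  unknown <- setdiff(el, names(ATOMIC_WEIGHTS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  setNames(n, el)
}

#' Formulation metrics for a radiolabeled peptide dose
#'
#' @param activity_kBq Administered activity per injection, kBq.
#' @param peptide_mass_ng Peptide mass per injection, ng.
#' @param formula Molecular formula (default: the 212Pb-chelator peptide
#'   C77H119N23O17).
#' @return List: \code{molar_mass} (g/mol), \code{amount_nmol},
#'   \code{specific_activity_kBq_ng}, \code{molar_activity_GBq_umol}.
#' @examples
#' formulation_metrics(370, 280)
#' @export
formulation_metrics <- function(activity_kBq, peptide_mass_ng,
                                formula = "C77H119N23O17") {
  if (activity_kBq <= 0 || peptide_mass_ng <= 0) {
    stop("activity and peptide mass must be positive", call. = FALSE)
  }
  counts <- parse_formula(formula)
  mm <- sum(counts * ATOMIC_WEIGHTS[names(counts)])
  amount_nmol <- peptide_mass_ng / mm  # ng / (g/mol) = nmol
  list(molar_mass = mm,
       amount_nmol = amount_nmol,
       specific_activity_kBq_ng = activity_kBq / peptide_mass_ng,
       molar_activity_GBq_umol = (activity_kBq * 1e-6) / (amount_nmol * 1e-3))
}

#' Compare organ uptake between two groups at one timepoint
#'
#' Percent change of group b relative to group a plus a two-sided t test
#' (Welch by default; Student's pooled test available).
#'
#' @param pct Data frame from \code{percent_id_per_gram}.
#' @param group_a,group_b Group identifiers (a is the reference).
#' @param organ Organ name.
#' @param timepoint_h Timepoint in hours.
#' @param var_equal \code{FALSE} (default) for Welch; \code{TRUE} for
#'   Student's pooled-variance test.
#' @return List: \code{percent_change}, \code{p_value}, \code{mean_a},
#'   \code{mean_b}, \code{n_a}, \code{n_b}.
#' @export
compare_uptake_groups <- function(pct, group_a, group_b, organ, timepoint_h,
                                  var_equal = FALSE) {
  pick <- function(g) {
    v <- pct$pct_id_g[pct$group == g & pct$organ == organ &
                        pct$timepoint_h == timepoint_h]
    if (length(v) < 2) {
      stop("group '", g, "' has fewer than 2 samples for ", organ, " at ",
           timepoint_h, " h", call. = FALSE)
    }
    v
  }
  a <- pick(group_a); b <- pick(group_b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    p <- stats::t.test(a, b, var.equal = var_equal)$p.value
  }
  list(percent_change = 100 * (mean(b) - mean(a)) / mean(a),
       p_value = p, mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Correlation of tumor uptake with tumor volume
#'
#' Pearson correlation of tumor volume against uptake expressed as \%ID/g
#' and as whole-tumor \%ID. Necrotic cores make large tumors carry less
#' activity per gram, so a negative \%ID/g correlation with a flat \%ID
#' correlation is the expected signature.
#'
#' @param pct Data frame from \code{percent_id_per_gram} restricted to tumor
#'   samples, with a \code{tumor_volume_mm3} column.
#' @return List with \code{corr_idg}, \code{p_idg}, \code{corr_id},
#'   \code{p_id}, \code{n}.
#' @export
uptake_vs_tumor_size <- function(pct) {
  if (!("tumor_volume_mm3" %in% names(pct))) {
    stop("`tumor_volume_mm3` column required", call. = FALSE)
  }
  d <- pct[!is.na(pct$tumor_volume_mm3), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 tumors with volumes", call. = FALSE)
  if (stats::sd(d$tumor_volume_mm3) == 0 || stats::sd(d$pct_id_g) == 0 ||
      stats::sd(d$pct_id) == 0) {
    stop("zero variance in volume or uptake", call. = FALSE)
  }
  cg <- stats::cor.test(d$tumor_volume_mm3, d$pct_id_g)
  ci <- stats::cor.test(d$tumor_volume_mm3, d$pct_id)
  list(corr_idg = unname(cg$estimate), p_idg = cg$p.value,
       corr_id = unname(ci$estimate), p_id = ci$p.value, n = nrow(d))
}

#' Construct a chromatogram object
#'
#' @param time_s Fraction collection times in seconds, strictly increasing.
#' @param counts Radioactivity counts per fraction.
#' @param main_peak_window Optional \code{c(start, end)} in seconds bounding
#'   the intact-compound peak; when absent, \code{chromatogram_purity} fits a
#'   Gaussian to the tallest peak and uses +/- 3 sigma.
#' @return Object of class \code{chromatogram}.
#' @export
chromatogram <- function(time_s, counts, main_peak_window = NULL) {
  if (length(time_s) != length(counts)) stop("length mismatch", call. = FALSE)
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (!is.null(main_peak_window)) {
    if (main_peak_window[1] >= main_peak_window[2] ||
        main_peak_window[1] < min(time_s) || main_peak_window[2] > max(time_s)) {
      stop("`main_peak_window` must lie within the time range", call. = FALSE)
    }
  }
  structure(list(time_s = time_s, counts = counts,
                 main_peak_window = main_peak_window),
            class = "chromatogram")
}

#' Read a chromatogram CSV (columns time_s, counts)
#' @param path CSV path.
#' @param main_peak_window Optional window, see \code{\link{chromatogram}}.
#' @export
read_chromatogram <- function(path, main_peak_window = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  chromatogram(df$time_s, df$counts, main_peak_window)
}

#' Radiochemical purity: percent of counts in the main peak
#'
#' @param c A \code{chromatogram}.
#' @return Percent of total counts falling inside the main-peak window.
#' @export
chromatogram_purity <- function(c) {
  stopifnot(inherits(c, "chromatogram"))
  total <- sum(c$counts)
  if (total <= 0) stop("chromatogram has no counts", call. = FALSE)
  w <- c$main_peak_window
  if (is.null(w)) w <- fit_peak_window(c$time_s, c$counts)
  inside <- c$time_s >= w[1] & c$time_s <= w[2]
  100 * sum(c$counts[inside]) / total
}

# +/- 3 sigma window from a Gaussian fit to the tallest peak
fit_peak_window <- function(time_s, counts) {
  apex <- which.max(counts)
  span <- diff(range(time_s))
  fit <- try(minpack.lm::nlsLM(
    counts ~ a * exp(-(time_s - m)^2 / (2 * s^2)),
    start = list(a = counts[apex], m = time_s[apex], s = span / 20),
    lower = c(0, min(time_s), diff(range(time_s)) / 1000),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # moment fallback around the apex
    near <- abs(time_s - time_s[apex]) <= span / 10
    m <- sum(time_s[near] * counts[near]) / sum(counts[near])
    s <- sqrt(sum(counts[near] * (time_s[near] - m)^2) / sum(counts[near]))
  } else {
    cf <- stats::coef(fit)
    m <- cf[["m"]]; s <- cf[["s"]]
  }
  c(m - 3 * s, m + 3 * s)
}
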