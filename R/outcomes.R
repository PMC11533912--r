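# Efficacy and welfare endpoints: tumor volumes, Kaplan-Meier survival with
# median and timepoint survival fractions, and termination-criteria checks.

#' Caliper tumor volume
#'
#' Volume as length x width x height, the convention used for the 1000 mm^3
#' termination threshold.
#'
#' @param length_mm,width_mm,height_mm Caliper dimensions in mm (vectorised).
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 10, 10)  # 1000
#' @export
tumor_volume <- function(length_mm, width_mm, height_mm) {
  if (any(c(length_mm, width_mm, height_mm) < 0)) {
    stop("dimensions must be non-negative", call. = FALSE)
  }
  length_mm * width_mm * height_mm
}

#' Kaplan-Meier survival curve for one cohort
#'
#' Product-limit estimate (delegated to \pkg{survival}) with the median
#' defined as the earliest time at which the curve drops to 0.5 or below
#' (undefined if it never does). Events are processed before censorings at
#' tied times, the estimator's usual convention.
#'
#' @param time Event/censoring times (weeks), positive.
#' @param event 1 = met termination criteria, 0 = censored at study end.
#' @return Object of class \code{km_curve}: list with step-function vectors
#'   \code{time}, \code{surv}, \code{n_risk}, \code{n_event},
#'   \code{n_censor}, the \code{median} (NA if undefined), \code{n}, and the
#'   underlying \code{survfit}. Supports \code{print}, \code{summary},
#'   \code{plot} and \code{\link{survival_at}}.
#' @export
km_curve <- function(time, event) {
  if (is.data.frame(time)) {
    df <- time
    tcol <- intersect(c("time_weeks", "time"), names(df))[1]
    if (is.na(tcol) || !("event" %in% names(df))) {
      stop("data frame needs time_weeks (or time) and event columns", call. = FALSE)
    }
    event <- df$event
    time <- df[[tcol]]
  }
  if (!length(time)) stop("at least one record required", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  surv <- fit$surv
  tms <- fit$time
  med <- if (any(surv <= 0.5)) min(tms[surv <= 0.5]) else NA_real_
  structure(list(time = tms, surv = surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 median = med, n = length(time), fit = fit),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier step function at given times
#'
#' Right-continuous: \code{S(t)} is the estimate just after the last event
#' time at or before \code{t}; 1 before the first event.
#'
#' @param km A \code{km_curve}.
#' @param t Times at which to evaluate (vectorised).
#' @return Survival fractions in \code{[0, 1]}.
#' @export
survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, censored = %d\n",
              x$n, sum(x$n_event), sum(x$n_censor)))
  cat(sprintf("Median survival: %s\n",
              if (is.na(x$median)) "not reached" else sprintf("%.3g wk", x$median)))
  invisible(x)
}

#' @export
summary.km_curve <- function(object, ...) summary(object$fit, ...)

#' @export
plot.km_curve <- function(x, xlab = "Time (wk)", ylab = "Survival fraction", ...) {
  graphics::plot(x$fit, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Evaluate termination criteria for one animal's history
#'
#' Flags, in chronological order of first occurrence: tumor volume at or
#' above 1000 mm^3; body-weight loss from initial weight exceeding 15\% on
#' two consecutive measurements; weight loss of 20\% or more from initial
#' weight; or an externally supplied welfare observation code.
#'
#' @param history Data frame ordered by \code{time} with columns \code{time}
#'   (days) and any of: \code{volume_mm3} (or \code{length_mm},
#'   \code{width_mm}, \code{height_mm}), \code{weight_g}, \code{welfare}
#'   (character code, \code{NA}/"" = none).
#' @param volume_limit_mm3 Volume threshold (default 1000).
#' @param weight_loss_consecutive Fractional loss triggering the
#'   two-consecutive-measurements rule (default 0.15, strict inequality).
#' @param weight_loss_total Fractional loss from initial weight triggering
#'   immediately (default 0.20, at or above).
#' @return List: \code{terminate} (logical), \code{reason} (\code{"volume"},
#'   \code{"weight-consecutive"}, \code{"weight-total"}, a welfare code, or
#'   \code{"none"}), \code{time} of first trigger (NA if none).
#' @export
evaluate_termination <- function(history, volume_limit_mm3 = 1000,
                                 weight_loss_consecutive = 0.15,
                                 weight_loss_total = 0.20) {
  stopifnot(is.data.frame(history), "time" %in% names(history))
  if (is.unsorted(history$time, strictly = FALSE)) {
    stop("history must be ordered by time", call. = FALSE)
  }
  n <- nrow(history)
  vol <- if ("volume_mm3" %in% names(history)) {
    history$volume_mm3
  } else if (all(c("length_mm", "width_mm", "height_mm") %in% names(history))) {
    tumor_volume(history$length_mm, history$width_mm, history$height_mm)
  } else rep(NA_real_, n)
  wt <- if ("weight_g" %in% names(history)) history$weight_g else rep(NA_real_, n)
  welfare <- if ("welfare" %in% names(history)) history$welfare else rep(NA, n)
  loss <- if (any(!is.na(wt))) 1 - wt / wt[which(!is.na(wt))[1]] else rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(vol[i]) && vol[i] >= volume_limit_mm3) {
      return(list(terminate = TRUE, reason = "volume", time = history$time[i]))
    }
    if (!is.na(loss[i]) && loss[i] >= weight_loss_total - 1e-12) {
      return(list(terminate = TRUE, reason = "weight-total",
                  time = history$time[i]))
    }
    if (i > 1 && !is.na(loss[i]) && !is.na(loss[i - 1]) &&
        loss[i] > weight_loss_consecutive && loss[i - 1] > weight_loss_consecutive) {
      return(list(terminate = TRUE, reason = "weight-consecutive",
                  time = history$time[i]))
    }
    if (!is.na(welfare[i]) && nzchar(welfare[i])) {
      return(list(terminate = TRUE, reason = welfare[i], time = history$time[i]))
    }
  }
  list(terminate = FALSE, reason = "none", time = NA_real_)
}

#' Read a survival CSV (columns animal_id, group, time_weeks, event)
#' @param path CSV path.
#' @return Data frame.
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "time_weeks", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("survival table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Per-group survival summary
#'
#' @param records Survival data frame (\code{group, time_weeks, event}).
#' @param at Optional time (weeks) at which to report the survival fraction.
#' @return Data frame: group, n, events, median weeks, and (if \code{at}
#'   given) the survival fraction at that time.
#' @export
summarize_survival <- function(records, at = NULL) {
  out <- do.call(rbind, lapply(split(records, records$group), function(d) {
    km <- km_curve(d$time_weeks, d$event)
    row <- data.frame(group = d$group[1], n = km$n, events = sum(km$n_event),
                      median_weeks = km$median, stringsAsFactors = FALSE)
    if (!is.null(at)) row[[paste0("surv_at_", at, "wk")]] <- survival_at(km, at)
    row
  }))
  rownames(out) <- NULL
  out
}
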