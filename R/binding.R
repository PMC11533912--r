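# Saturation-binding analysis: nonspecific subtraction and one-site Kd/Bmax
# estimation with Jacobian-based standard errors.

#' Assemble a saturation-binding plate
#'
#' @param data Data frame with columns \code{concentration_nM},
#'   \code{replicate}, \code{well_type} (\code{"total"} or
#'   \code{"nonspecific"}, the latter being the cold-excess block wells) and
#'   \code{counts}.
#' @param cells_per_well Optional cell count per well (metadata).
#' @return Object of class \code{binding_plate}.
#' @export
binding_plate <- function(data, cells_per_well = NA) {
  need <- c("concentration_nM", "replicate", "well_type", "counts")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("plate lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$concentration_nM <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (!all(data$well_type %in% c("total", "nonspecific"))) {
    stop("well_type must be 'total' or 'nonspecific'", call. = FALSE)
  }
  structure(list(data = as.data.frame(data), cells_per_well = cells_per_well),
            class = "binding_plate")
}

#' Read a binding-plate CSV (columns concentration_nM, replicate, well_type, counts)
#' @param path CSV path.
#' @export
read_binding_plate <- function(path) {
  binding_plate(utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' Specific binding by paired nonspecific subtraction
#'
#' Per concentration, specific binding is the mean of the total wells minus
#' the mean of the cold-block (nonspecific) wells. Negative values are
#' retained, not clipped, and flagged.
#'
#' @param plate A \code{binding_plate}.
#' @return Data frame: \code{concentration_nM}, means and SDs of total and
#'   nonspecific wells, \code{specific}, its standard error
#'   \code{se_specific}, and a \code{negative} flag. A warning is emitted if
#'   any specific value is negative.
#' @export
specific_binding <- function(plate) {
  stopifnot(inherits(plate, "binding_plate"))
  d <- plate$data
  tot <- d[d$well_type == "total", ]
  ns <- d[d$well_type == "nonspecific", ]
  conc_t <- sort(unique(tot$concentration_nM))
  conc_n <- sort(unique(ns$concentration_nM))
  if (!identical(conc_t, conc_n)) {
    stop("total and nonspecific wells use different concentration grids",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(conc_t, function(cc) {
    tv <- tot$counts[tot$concentration_nM == cc]
    nv <- ns$counts[ns$concentration_nM == cc]
    data.frame(concentration_nM = cc,
               mean_total = mean(tv),
               sd_total = if (length(tv) > 1) stats::sd(tv) else NA_real_,
               mean_nonspecific = mean(nv),
               sd_nonspecific = if (length(nv) > 1) stats::sd(nv) else NA_real_,
               specific = mean(tv) - mean(nv),
               se_specific = sqrt(
                 (if (length(tv) > 1) stats::var(tv) / length(tv) else 0) +
                   (if (length(nv) > 1) stats::var(nv) / length(nv) else 0)))
  }))
  out$negative <- out$specific < 0
  if (any(out$negative)) {
    warning("negative specific binding at ",
            sum(out$negative), " concentration(s); retained unclipped")
  }
  rownames(out) <- NULL
  out
}

#' Fit a one-site saturation-binding model
#'
#' Least-squares fit of \code{B(c) = Bmax * c / (Kd + c)} to specific-binding
#' data. Starting values follow the usual scheme: \code{Bmax0} is the largest
#' observed specific binding and \code{Kd0} the concentration nearest
#' half-maximum; both parameters are bounded positive. On non-convergence the
#' fit is restarted from jittered starts a bounded number of times.
#'
#' @param specific Either the data frame returned by
#'   \code{\link{specific_binding}}, a \code{binding_plate} (subtraction is
#'   applied first), or a data frame with columns \code{concentration_nM} and
#'   \code{specific}.
#' @param max_restarts Maximum jittered restarts after a failed fit.
#' @return Object of class \code{kd_fit} with elements \code{kd}, \code{bmax}
#'   (estimates), \code{se_kd}, \code{se_bmax} (Jacobian-based SEs),
#'   \code{residual_sd}, \code{convergence}, \code{n_obs}, the underlying
#'   \code{nls}-style \code{fit} and the modeling \code{data}. Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{confint},
#'   \code{predict}, \code{residuals} and \code{plot}.
#' @examples
#' conc <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
#' b <- 1000 * conc / (3.93 + conc)
#' fit <- fit_one_site(data.frame(concentration_nM = conc, specific = b))
#' coef(fit)
#' @export
fit_one_site <- function(specific, max_restarts = 20) {
  if (inherits(specific, "binding_plate")) specific <- specific_binding(specific)
  stopifnot(all(c("concentration_nM", "specific") %in% names(specific)))
  d <- specific[, c("concentration_nM", "specific")]
  names(d) <- c("conc", "b")
  if (length(unique(d$conc)) < 4) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  bmax0 <- max(d$b)
  if (bmax0 <= 0) stop("no positive specific binding to fit", call. = FALSE)
  kd0 <- d$conc[which.min(abs(d$b - bmax0 / 2))]
  fit <- NULL
  set_start <- list(bmax = bmax0, kd = kd0)
  for (try_i in seq_len(max_restarts + 1)) {
    fit <- try(minpack.lm::nlsLM(
      b ~ bmax * conc / (kd + conc), data = d, start = set_start,
      lower = c(bmax = 1e-12, kd = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (!inherits(fit, "try-error")) break
    mult <- exp(stats::runif(2, -1, 1))
    set_start <- list(bmax = bmax0 * mult[1], kd = kd0 * mult[2])
  }
  if (inherits(fit, "try-error")) {
    stop("one-site fit failed after ", max_restarts, " restarts: ",
         attr(fit, "condition")$message, call. = FALSE)
  }
  cf <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  structure(list(kd = unname(cf["kd"]), bmax = unname(cf["bmax"]),
                 se_kd = unname(se["kd"]), se_bmax = unname(se["bmax"]),
                 residual_sd = sm$sigma,
                 convergence = fit$convInfo$isConv %||% TRUE,
                 n_obs = nrow(d), fit = fit, data = d),
            class = "kd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kd_fit <- function(x, ...) {
  cat("One-site saturation binding fit\n")
  cat(sprintf("  Kd   = %.3f +/- %.3f nM\n", x$kd, x$se_kd))
  cat(sprintf("  Bmax = %.4g +/- %.3g\n", x$bmax, x$se_bmax))
  cat(sprintf("  residual SD %.4g on %d observations\n",
              x$residual_sd, x$n_obs))
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) {
  c(kd = object$kd, bmax = object$bmax)
}

#' @export
summary.kd_fit <- function(object, ...) summary(object$fit, ...)

#' Wald confidence intervals for a one-site fit
#' @param object A \code{kd_fit}.
#' @param parm Parameters (default both).
#' @param level Confidence level.
#' @param ... Unused.
#' @export
confint.kd_fit <- function(object, parm = c("kd", "bmax"), level = 0.95, ...) {
  z <- stats::qt(1 - (1 - level) / 2, df = object$n_obs - 2)
  est <- c(kd = object$kd, bmax = object$bmax)
  se <- c(kd = object$se_kd, bmax = object$se_bmax)
  out <- cbind(lower = est - z * se, upper = est + z * se)
  out[parm, , drop = FALSE]
}

#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else {
    if (is.data.frame(newdata)) {
      newdata$concentration_nM %||% newdata$conc
    } else as.numeric(newdata)
  }
  object$bmax * conc / (object$kd + conc)
}

#' @export
residuals.kd_fit <- function(object, ...) {
  object$data$b - predict(object)
}

#' @export
plot.kd_fit <- function(x, ...) {
  cc <- exp(seq(log(min(x$data$conc)), log(max(x$data$conc)), length.out = 200))
  graphics::plot(x$data$conc, x$data$b, log = "x",
                 xlab = "Concentration (nM)", ylab = "Specific binding",
                 main = sprintf("One-site fit: Kd = %.2f nM", x$kd), ...)
  graphics::lines(cc, predict(x, cc))
  graphics::abline(v = x$kd, lty = 2)
  invisible(x)
}
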