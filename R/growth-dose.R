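# Doubling-time estimation from confluency curves and 4-parameter
# log-logistic dose-response fitting with IC-level inversion.

#' Doubling time from two confluency timepoints
#'
#' Computes `(t_b - t_a) / log2(confluency(t_b) / confluency(t_a))`, the
#' population doubling time under exponential growth between two timepoints
#' taken from the linear (log-scale) phase of a confluency curve.
#'
#' @param curve Data frame with columns `time_h` (strictly increasing) and
#'   `confluency_pct`.
#' @param t_a,t_b Timepoints present in the curve, `t_b > t_a`.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(curve, t_a, t_b) {
  check_columns(curve, c("time_h", "confluency_pct"), "confluency curve")
  if (is.unsorted(curve$time_h, strictly = TRUE)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (t_b <= t_a) stop("t_b must be later than t_a", call. = FALSE)
  ia <- match(t_a, curve$time_h)
  ib <- match(t_b, curve$time_h)
  if (is.na(ia) || is.na(ib)) {
    stop("t_a and t_b must both be observed timepoints", call. = FALSE)
  }
  ca <- curve$confluency_pct[ia]
  cb <- curve$confluency_pct[ib]
  if (ca <= 0) stop("confluency at t_a must be positive", call. = FALSE)
  if (cb <= ca) {
    stop("confluency must increase over the window (non-growing window)",
         call. = FALSE)
  }
  (t_b - t_a) / log2(cb / ca)
}

#' Automatic selection of the exponential (log-linear) phase
#'
#' Scans all contiguous windows of at least `min_points` observed timepoints
#' and returns the widest one over which `log2(confluency)` is linear in
#' time (straight-line fit with R-squared at or above `r2_threshold`); ties
#' in width are broken by the higher R-squared. Window endpoints are
#' observed timepoints, suitable for [doubling_time()].
#'
#' @inheritParams doubling_time
#' @param min_points Minimum points per window (default 3).
#' @param r2_threshold Linearity bar on R-squared (default 0.99).
#' @return List with `t_a`, `t_b`, `n_points`, `r_squared`.
#' @export
select_linear_phase <- function(curve, min_points = 3, r2_threshold = 0.99) {
  check_columns(curve, c("time_h", "confluency_pct"), "confluency curve")
  n <- nrow(curve)
  if (n < 4) stop("need at least 4 timepoints", call. = FALSE)
  t <- curve$time_h
  conf <- curve$confluency_pct
  best <- NULL
  for (len in seq(n, min_points)) {
    for (start in seq_len(n - len + 1)) {
      idx <- start:(start + len - 1)
      if (any(conf[idx] <= 0)) next
      y <- log2(conf[idx])
      if (stats::sd(y) == 0) next
      fit <- stats::lm.fit(cbind(1, t[idx]), y)
      ss_res <- sum(fit$residuals^2)
      ss_tot <- sum((y - mean(y))^2)
      r2 <- 1 - ss_res / ss_tot
      if (r2 >= r2_threshold &&
          (is.null(best) || len > best$n_points || r2 > best$r_squared)) {
        best <- list(t_a = t[idx[1]], t_b = t[idx[len]],
                     n_points = len, r_squared = r2)
      }
    }
    if (!is.null(best)) break  # widest qualifying window found at this length
  }
  if (is.null(best)) {
    stop(sprintf(
      "no window of >= %d points reaches R^2 >= %g; select timepoints manually",
      min_points, r2_threshold), call. = FALSE)
  }
  best
}

# Decreasing 4-parameter log-logistic mean function (Hill model on log dose).
ll4 <- function(dose, lower, upper, ic50, hill) {
  lower + (upper - lower) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of viability against dose under the Hill model
#' `v(d) = lower + (upper - lower) / (1 + (d/IC50)^hill)`, the standard
#' model for viability assays. Zero doses are treated as the vehicle anchor
#' and excluded from the log-dose fit. The empirical maximum response (the
#' lowest mean viability across tested doses) is always reported; when the
#' optimizer cannot converge — e.g. a flat curve with no drug effect — a
#' condition of class `"drc_nonconvergence"` is signalled that still carries
#' `max_response`.
#'
#' @param doses Dose per observation, nM (vector matching `viability`), or
#'   a data frame with columns `dose_nM` and `viability_pct`.
#' @param viability Viability per observation, percent (ignored when
#'   `doses` is a data frame).
#' @return An object of class `"drc_fit"` with components `lower`, `upper`,
#'   `ic50`, `hill`, `doses` (distinct tested doses), `mean_viability`,
#'   `max_response`, `data`, and the underlying `nls` fit.
#' @seealso [ic_value()] for IC20/IC50 inversion.
#' @examples
#' dr <- simulate_dose_response(ic50 = 5, hill = 1, lower = 0, upper = 100,
#'                              doses = 2^(0:7), noise_cv = 0, seed = 1)
#' fit <- fit_dose_response(dr)
#' coef(fit)
#' ic_value(fit, 50)
#' @export
fit_dose_response <- function(doses, viability = NULL) {
  if (is.data.frame(doses)) {
    check_columns(doses, c("dose_nM", "viability_pct"), "dose-response table")
    viability <- doses$viability_pct
    doses <- doses$dose_nM
  }
  stopifnot(length(doses) == length(viability))
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  nz <- doses > 0
  dose_levels <- sort(unique(doses))
  mean_v <- vapply(dose_levels, function(d) mean(viability[doses == d]),
                   numeric(1))
  max_response <- min(mean_v)
  if (length(unique(doses[nz])) < 4) {
    stop("need >= 4 distinct nonzero doses", call. = FALSE)
  }

  d <- doses[nz]
  v <- viability[nz]
  up0 <- max(mean_v)
  lo0 <- min(mean_v)
  fail <- function(msg) {
    cond <- structure(
      class = c("drc_nonconvergence", "error", "condition"),
      list(message = paste0("dose-response fit did not converge: ", msg),
           call = sys.call(-1), max_response = max_response)
    )
    stop(cond)
  }
  if (up0 - lo0 < 1e-8) fail("no dose effect (flat viability)")
  mid <- (up0 + lo0) / 2
  nzl <- sort(unique(d))
  nzm <- vapply(nzl, function(x) mean(v[d == x]), numeric(1))
  ic0 <- nzl[which.min(abs(nzm - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ lower + (upper - lower) / (1 + exp(hill * (log(d) - lic50))),
      start = list(lower = lo0, upper = up0, lic50 = log(ic0), hill = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) fail("optimizer failure")
  cf <- stats::coef(fit)
  if (cf[["upper"]] < cf[["lower"]]) {
    # refit is not attempted: crossed asymptotes indicate no usable signal
    fail("degenerate asymptotes")
  }
  structure(list(
    lower = unname(cf[["lower"]]),
    upper = unname(cf[["upper"]]),
    ic50 = exp(unname(cf[["lic50"]])),
    hill = unname(cf[["hill"]]),
    doses = dose_levels,
    mean_viability = mean_v,
    max_response = max_response,
    data = data.frame(dose_nM = doses, viability_pct = viability),
    nls = fit
  ), class = "drc_fit")
}

#' @export
print.drc_fit <- function(x, digits = 4, ...) {
  cat("Four-parameter log-logistic dose-response fit\n")
  cat(sprintf("  IC50: %s nM   hill: %s\n",
              format(x$ic50, digits = digits),
              format(x$hill, digits = digits)))
  cat(sprintf("  asymptotes: %s%% .. %s%%   max response: %s%%\n",
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              format(x$max_response, digits = digits)))
  invisible(x)
}

#' @export
coef.drc_fit <- function(object, ...) {
  c(lower = object$lower, upper = object$upper,
    ic50 = object$ic50, hill = object$hill)
}

#' Predicted viability at given doses
#'
#' @param object A `"drc_fit"`.
#' @param doses Doses in nM; zero returns the upper asymptote (vehicle
#'   anchor convention).
#' @param ... Unused.
#' @return Predicted viability, percent.
#' @export
predict.drc_fit <- function(object, doses, ...) {
  ifelse(doses == 0, object$upper,
         ll4(doses, object$lower, object$upper, object$ic50, object$hill))
}

#' @export
residuals.drc_fit <- function(object, ...) {
  object$data$viability_pct - predict(object, object$data$dose_nM)
}

#' @export
summary.drc_fit <- function(object, ...) {
  out <- list(coef = coef(object), max_response = object$max_response,
              rse = sqrt(mean(residuals(object)^2)),
              n = nrow(object$data))
  class(out) <- "summary.drc_fit"
  out
}

#' @export
print.summary.drc_fit <- function(x, ...) {
  cat("Dose-response fit summary\n")
  print(x$coef)
  cat(sprintf("max response %.2f%%, RMS residual %.3f over %d observations\n",
              x$max_response, x$rse, x$n))
  invisible(x)
}

#' Plot a dose-response fit
#'
#' Log-dose scatter of the observations with the fitted curve and the
#' per-dose means overlaid.
#'
#' @param x A `"drc_fit"`.
#' @param ... Passed to [plot()].
#' @export
plot.drc_fit <- function(x, ...) {
  d <- x$data[x$data$dose_nM > 0, ]
  plot(d$dose_nM, d$viability_pct, log = "x",
       xlab = "dose (nM)", ylab = "viability (% of control)",
       col = "grey50", ...)
  grid_d <- exp(seq(log(min(d$dose_nM)), log(max(d$dose_nM)), length.out = 100))
  graphics::lines(grid_d, predict(x, grid_d), col = "firebrick", lwd = 2)
  nzl <- x$doses[x$doses > 0]
  graphics::points(nzl, x$mean_viability[x$doses > 0], pch = 19)
  invisible(x)
}

#' Invert a dose-response fit at a given inhibition level
#'
#' Returns the dose producing the requested response reduction. Two
#' conventions are supported: `"asymptote"` (default) measures the reduction
#' as a fraction of the fitted span, so the level-`L` dose satisfies
#' `v = upper - (L/100) (upper - lower)` and `ic_value(fit, 50)` is exactly
#' the fitted IC50; `"absolute"` measures against the untreated 100% scale,
#' solving `v = 100 - L` (the convention under which an IC20 dose leaves
#' cells at 80% viability).
#'
#' @param fit A `"drc_fit"`.
#' @param level Inhibition level in percent, strictly between 0 and 100.
#' @param convention `"asymptote"` or `"absolute"`.
#' @return Dose in nM.
#' @export
ic_value <- function(fit, level, convention = c("asymptote", "absolute")) {
  stopifnot(inherits(fit, "drc_fit"))
  convention <- match.arg(convention)
  if (level <= 0 || level >= 100) {
    stop("level must be strictly between 0 and 100", call. = FALSE)
  }
  if (convention == "asymptote") {
    f <- level / 100
  } else {
    target <- 100 - level
    if (target >= fit$upper || target <= fit$lower) {
      stop(sprintf(
        "viability %g%% is outside the fitted range (%.3g%%, %.3g%%)",
        target, fit$lower, fit$upper), call. = FALSE)
    }
    f <- (fit$upper - target) / (fit$upper - fit$lower)
  }
  fit$ic50 * (f / (1 - f))^(1 / fit$hill)
}
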