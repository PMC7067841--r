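# First-order kinetics of fatty-acid incorporation / wash-out:
#   y(t) = y_inf + (y0 - y_inf) * exp(-k * t)
# One three-parameter model covers both rise and decay via the sign of
# (y0 - y_inf); the half-time is ln(2)/k.

#' Construct a time course
#'
#' @param times Time points in hours, strictly increasing, >= 4 points.
#' @param values Statistic values (e.g. mol%) at those times.
#' @param condition Optional condition label.
#' @return A `time_course` object.
#' @export
time_course <- function(times, values, condition = NA_character_) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) < 4L) stop("a time course needs at least 4 points")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite")
  if (any(times < 0)) stop("times must be >= 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, values = values, condition = condition),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time course: %d points over %.1f-%.1f h%s>\n",
              length(x$times), min(x$times), max(x$times),
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  invisible(x)
}

#' Fit a first-order kinetic model
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nls.lm()]) of
#' `y(t) = y_inf + (y0 - y_inf) exp(-k t)` with `k` bounded in
#' `[1e-6, 1e3]` per hour. Starting values: `y0` = first observation,
#' `y_inf` = last, `k = ln 2 / t_mid` where `t_mid` is the time of closest
#' approach to the midpoint between them. Optimizer failure sets
#' `converged = FALSE` rather than raising.
#'
#' @param tc A [time_course()] (or a data frame with `time_h` and `value`).
#' @return A `kinetic_fit`: `y0`, `y_inf`, `k` (per hour), `half_time`
#'   (`ln(2)/k`, hours), `rss`, `converged`.
#' @export
#' @examples
#' tc <- time_course(c(0, 1, 2, 4, 8, 24), 10 * (1 - exp(-log(2) / 4 * c(0, 1, 2, 4, 8, 24))))
#' fit_first_order(tc)
fit_first_order <- function(tc) {
  if (is.data.frame(tc)) tc <- time_course(tc$time_h, tc$value)
  stopifnot(inherits(tc, "time_course"))
  t <- tc$times; y <- tc$values
  if (length(unique(y)) == 1L)
    stop("all values equal: rate is unidentifiable")

  y0_start <- y[1L]
  yinf_start <- y[length(y)]
  mid <- (y0_start + yinf_start) / 2
  t_mid <- t[which.min(abs(y - mid))]
  k_start <- log(2) / max(t_mid, 1e-3)
  k_start <- min(max(k_start, 1e-6), 1e3)

  residual_fn <- function(par)
    y - (par[2] + (par[1] - par[2]) * exp(-par[3] * t))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(y0 = y0_start, y_inf = yinf_start,
                               k = k_start),
                       lower = c(-Inf, -Inf, 1e-6),
                       upper = c(Inf, Inf, 1e3),
                       fn = residual_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  ok <- !is.null(fit) && fit$info %in% 1:4
  if (!ok) {
    out <- list(y0 = y0_start, y_inf = yinf_start, k = k_start,
                half_time = log(2) / k_start, rss = NA_real_,
                converged = FALSE, condition = tc$condition)
    return(structure(out, class = "kinetic_fit"))
  }
  p <- fit$par
  structure(list(y0 = unname(p["y0"]), y_inf = unname(p["y_inf"]),
                 k = unname(p["k"]), half_time = log(2) / unname(p["k"]),
                 rss = sum(fit$fvec^2), converged = TRUE,
                 condition = tc$condition),
            class = "kinetic_fit")
}

#' Half-time of a converged first-order fit
#'
#' @param fit A `kinetic_fit` from [fit_first_order()].
#' @return `ln(2) / k` in hours.
#' @export
half_time <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; no half-time")
  log(2) / fit$k
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "First-order fit: y0=%.4g, y_inf=%.4g, k=%.4g /h (half-time %.3g h)%s\n",
    x$y0, x$y_inf, x$k, x$half_time,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Predict from a first-order fit
#' @param object A `kinetic_fit`.
#' @param times Times (hours) at which to evaluate the model.
#' @param ... Unused.
#' @return Predicted values.
#' @export
predict.kinetic_fit <- function(object, times, ...) {
  object$y_inf + (object$y0 - object$y_inf) * exp(-object$k * times)
}
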