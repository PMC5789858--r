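#' Fit a seasonal NDVI curve to one year of bimonthly composites
#'
#' Four widely used reconstructions of the annual greenness cycle:
#' \describe{
#'   \item{`hants`}{harmonic analysis — least-squares fit of a mean plus
#'     three harmonics (periods 365, 365/2, 365/3 days).}
#'   \item{`polyfit`}{sixth-order polynomial least squares.}
#'   \item{`double_logistic`}{the six-parameter double-logistic model
#'     (winter background, amplitude, two inflection days, two slopes),
#'     fitted by Levenberg-Marquardt nonlinear least squares with
#'     multi-start initialisation seeded from a slope scan. The season
#'     start/end dates are the model's own inflection parameters.}
#'   \item{`piecewise_logistic`}{a pair of four-parameter sigmoids fitted
#'     separately to the rising and falling halves of the year, split at the
#'     seasonal peak; transition dates are the extrema of each sigmoid's
#'     first derivative (its inflection).}
#' }
#' The curve is evaluated at a 1-day step over the fixed 365-day year.
#'
#' @param values NDVI composites (typically 24 per year); missing values
#'   allowed, at least 20 must be present
#' @param composite_doy mid-composite days of year matching `values`
#' @param method one of `"hants"`, `"polyfit"`, `"double_logistic"`,
#'   `"piecewise_logistic"`
#' @param amplitude_floor minimum composite amplitude (max - min) for a pixel
#'   to be treated as seasonal; below it the pixel is flagged non-seasonal
#'   and carries no dates
#' @param init optional warm-start parameters for the nonlinear methods
#'   (a previous fit's `params`), tried before the multi-start sweep
#' @param ref_rmse optional reference residual sd; a warm start is accepted
#'   without the multi-start sweep when it converges at comparable error
#' @return an object of class `fp_curve`: daily grid, fitted values, method,
#'   model parameters (nonlinear methods) and fit diagnostics
#' @export
#' @examples
#' doys <- seq(8, 358, length.out = 24)
#' y <- double_logistic(doys, 0.1, 0.6, 120, 280)
#' cf <- fit_curve(y, doys, "double_logistic")
#' round(cf$params[c("S", "E")])
fit_curve <- function(values, composite_doy, method,
                      amplitude_floor = 0.05, init = NULL, ref_rmse = NULL) {
  method <- match.arg(method, c("hants", "polyfit", "double_logistic",
                                "piecewise_logistic"))
  ok <- is.finite(values)
  if (sum(ok) < 20) {
    return(new_curve(rep(NA_real_, DAYS_PER_YEAR), method,
                     converged = FALSE, non_seasonal = FALSE,
                     residual_sd = NA_real_,
                     note = "fewer than 20 valid composites"))
  }
  t <- composite_doy[ok]; y <- values[ok]
  if (max(y) - min(y) < amplitude_floor) {
    return(new_curve(rep(mean(y), DAYS_PER_YEAR), method,
                     converged = FALSE, non_seasonal = TRUE,
                     residual_sd = stats::sd(y)))
  }
  switch(method,
    hants = fit_harmonic(t, y),
    polyfit = fit_polynomial(t, y),
    double_logistic = fit_dlog(t, y, init = init, ref_rmse = ref_rmse),
    piecewise_logistic = fit_plog(t, y, init = init, ref_rmse = ref_rmse)
  )
}

new_curve <- function(fitted, method, converged, non_seasonal = FALSE,
                      residual_sd = NA_real_, params = NULL, note = NULL) {
  structure(
    list(doy = seq_len(DAYS_PER_YEAR), fitted = fitted, method = method,
         params = params,
         diagnostics = list(residual_sd = residual_sd, converged = converged,
                            non_seasonal = non_seasonal, note = note)),
    class = "fp_curve"
  )
}

#' @export
print.fp_curve <- function(x, ...) {
  d <- x$diagnostics
  cat("<fp_curve> method=", x$method,
      if (d$non_seasonal) " [non-seasonal]" else "",
      " converged=", d$converged,
      " residual sd=", signif(d$residual_sd, 3), "\n", sep = "")
  invisible(x)
}

# ---- linear methods (closed-form least squares) ----------------------------

harmonic_design <- function(t, n_harmonics = 3L) {
  X <- matrix(1, length(t), 1L + 2L * n_harmonics)
  for (h in seq_len(n_harmonics)) {
    w <- 2 * pi * h * t / DAYS_PER_YEAR
    X[, 2L * h] <- cos(w)
    X[, 2L * h + 1L] <- sin(w)
  }
  X
}

poly_design <- function(t, degree = 6L) {
  ts <- (t - 183) / 182  # scale to ~[-1, 1] for conditioning
  outer(ts, 0:degree, `^`)
}

fit_linear_curve <- function(t, y, design_fun, method) {
  X <- design_fun(t)
  fit <- stats::lm.fit(X, y)
  fitted <- as.vector(design_fun(seq_len(DAYS_PER_YEAR)) %*% fit$coefficients)
  new_curve(fitted, method, converged = TRUE,
            residual_sd = stats::sd(fit$residuals))
}

fit_harmonic <- function(t, y) fit_linear_curve(t, y, harmonic_design, "hants")
fit_polynomial <- function(t, y) fit_linear_curve(t, y, poly_design, "polyfit")

# Batched linear fits: one design solve for many curves at once.
# Y is a (n_composites x n_curves) matrix sharing the same composite days.
fit_linear_batch <- function(composite_doy, Y, design_fun) {
  X <- design_fun(composite_doy)
  qrX <- qr(X)
  coefs <- qr.coef(qrX, Y)
  daily <- design_fun(seq_len(DAYS_PER_YEAR)) %*% coefs
  resid_sd <- sqrt(colSums((Y - X %*% coefs)^2) / (nrow(Y) - ncol(X)))
  list(daily = daily, residual_sd = resid_sd)
}

# ---- slope-scan initialisation ---------------------------------------------

# Approximate transition days from the raw composites: linear interpolation
# onto the daily grid, then the days of steepest rise (first half-year) and
# steepest fall (second half). Used to seed the nonlinear fits.
slope_scan_init <- function(t, y, half_split = 182L) {
  daily <- stats::approx(t, y, xout = seq_len(DAYS_PER_YEAR), rule = 2)$y
  sl <- diff(daily)
  first <- seq_len(half_split - 1L)
  second <- half_split:(DAYS_PER_YEAR - 1L)
  list(
    S = first[which.max(sl[first])],
    E = second[which.max(-sl[second])],
    w = min(y), A = max(y) - min(y)
  )
}

# ---- double logistic --------------------------------------------------------

dlog_model <- function(p, t) {
  double_logistic(t, p[["w"]], p[["A"]], p[["S"]], p[["E"]],
                  p[["ks"]], p[["ka"]])
}

dlog_fit_once <- function(t, y, start) {
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ w + A * (plogis(ks * (t - S)) - plogis(ka * (t - E))),
      data = data.frame(t = t, y = y),
      start = start,
      lower = c(w = -0.2, A = 0.01, S = 1, ks = 0.01, E = 1, ka = 0.01),
      upper = c(w = 1, A = 1.2, S = 365, ks = 2, E = 365, ka = 2),
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-10)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  list(params = p, sse = sum(stats::residuals(fit)^2))
}

# Accept a candidate fit without further restarts when its residual sd is
# tiny in NDVI units, comparable to a supplied reference (warm starts from
# the climatological fit of the same pixel), or within the scale of typical
# composite noise. A fit stuck in a wrong local minimum (e.g. a missed
# season) leaves residuals of the order of the seasonal amplitude and still
# triggers the full multi-start sweep.
good_enough <- function(rmse, ref_rmse) {
  if (rmse < 0.004) return(TRUE)
  if (is.null(ref_rmse) || !is.finite(ref_rmse)) return(FALSE)
  rmse <= max(1.25 * ref_rmse + 1e-4, 0.05)
}

fit_dlog <- function(t, y, n_starts = 5L, init = NULL, ref_rmse = NULL) {
  sc <- slope_scan_init(t, y)
  starts <- list()
  if (!is.null(init)) {
    starts[[length(starts) + 1L]] <-
      as.list(init[c("w", "A", "S", "ks", "E", "ka")])
  }
  offs <- list(c(0, 0), c(-8, 0), c(8, 0), c(0, -8), c(0, 8))
  for (o in offs) {
    starts[[length(starts) + 1L]] <- list(
      w = sc$w, A = sc$A,
      S = min(max(sc$S + o[1], 5), 180),
      ks = 0.15,
      E = min(max(sc$E + o[2], 185), 360),
      ka = 0.15
    )
  }
  starts <- starts[seq_len(min(length(starts), n_starts + 1L))]
  best <- NULL
  n <- length(y)
  for (s in starts) {
    cand <- dlog_fit_once(t, y, s)
    if (is.null(cand)) next
    if (is.null(best) || cand$sse < best$sse) best <- cand
    if (good_enough(sqrt(best$sse / n), ref_rmse)) break
  }
  if (is.null(best)) {
    return(new_curve(rep(NA_real_, DAYS_PER_YEAR), "double_logistic",
                     converged = FALSE, residual_sd = NA_real_,
                     note = "no start converged"))
  }
  p <- best$params
  if (p[["S"]] > p[["E"]]) {  # degenerate: inflections swapped
    return(new_curve(rep(NA_real_, DAYS_PER_YEAR), "double_logistic",
                     converged = FALSE, residual_sd = sqrt(best$sse / n),
                     note = "inflections out of order"))
  }
  new_curve(dlog_model(as.list(p), seq_len(DAYS_PER_YEAR)), "double_logistic",
            converged = TRUE, residual_sd = sqrt(best$sse / n), params = p)
}

# ---- piecewise logistic -----------------------------------------------------

plog_half_fit <- function(t, y, rising, start) {
  form <- if (rising) y ~ b + a * plogis(k * (t - d)) else
    y ~ b + a * plogis(-k * (t - d))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      form, data = data.frame(t = t, y = y), start = start,
      lower = c(b = -0.2, a = 0.01, k = 0.01, d = 1),
      upper = c(b = 1, a = 1.2, k = 2, d = 365),
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-10)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  list(params = stats::coef(fit), sse = sum(stats::residuals(fit)^2))
}

fit_plog <- function(t, y, init = NULL, ref_rmse = NULL) {
  sc <- slope_scan_init(t, y)
  peak <- t[which.max(y)]
  # overlap one composite past the peak on each side for stability
  rise_idx <- which(t <= peak + 16)
  fall_idx <- which(t >= peak - 16)
  if (length(rise_idx) < 5 || length(fall_idx) < 5) {
    return(new_curve(rep(NA_real_, DAYS_PER_YEAR), "piecewise_logistic",
                     converged = FALSE, note = "too few points in a half"))
  }
  s_rise <- list(b = sc$w, a = sc$A, k = 0.15,
                 d = if (!is.null(init)) init[["S"]] else sc$S)
  s_fall <- list(b = sc$w, a = sc$A, k = 0.15,
                 d = if (!is.null(init)) init[["E"]] else sc$E)
  rise <- plog_half_fit(t[rise_idx], y[rise_idx], TRUE, s_rise)
  fall <- plog_half_fit(t[fall_idx], y[fall_idx], FALSE, s_fall)
  if (is.null(rise)) {
    s_rise$d <- sc$S; rise <- plog_half_fit(t[rise_idx], y[rise_idx], TRUE, s_rise)
  }
  if (is.null(fall)) {
    s_fall$d <- sc$E; fall <- plog_half_fit(t[fall_idx], y[fall_idx], FALSE, s_fall)
  }
  if (is.null(rise) || is.null(fall)) {
    return(new_curve(rep(NA_real_, DAYS_PER_YEAR), "piecewise_logistic",
                     converged = FALSE, note = "half fit failed"))
  }
  pr <- rise$params; pf <- fall$params
  doy <- seq_len(DAYS_PER_YEAR)
  split_at <- round_half_up(peak)
  fitted <- ifelse(
    doy <= split_at,
    pr[["b"]] + pr[["a"]] * stats::plogis(pr[["k"]] * (doy - pr[["d"]])),
    pf[["b"]] + pf[["a"]] * stats::plogis(-pf[["k"]] * (doy - pf[["d"]]))
  )
  n <- length(y)
  rsd <- sqrt((rise$sse + fall$sse) / n)  # halves overlap near the peak
  params <- c(S = unname(pr[["d"]]), E = unname(pf[["d"]]),
              ks = unname(pr[["k"]]), ka = unname(pf[["k"]]),
              w = unname(pr[["b"]]), A = unname(pr[["a"]]))
  if (params[["S"]] > params[["E"]]) {
    return(new_curve(rep(NA_real_, DAYS_PER_YEAR), "piecewise_logistic",
                     converged = FALSE, residual_sd = rsd,
                     note = "inflections out of order"))
  }
  new_curve(fitted, "piecewise_logistic", converged = TRUE,
            residual_sd = rsd, params = params)
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy a fitted seasonal curve
#' @param x an `fp_curve`
#' @param ... unused
#' @return one row per model parameter (nonlinear methods) or per daily
#'   fitted value summary for linear methods
#' @export
tidy.fp_curve <- function(x, ...) {
  if (!is.null(x$params)) {
    tibble::tibble(term = names(x$params), estimate = unname(x$params))
  } else {
    tibble::tibble(term = c("min", "max", "argmax_doy"),
                   estimate = c(min(x$fitted), max(x$fitted),
                                which.max(x$fitted)))
  }
}

#' One-row fit summary of a seasonal curve
#' @param x an `fp_curve`
#' @param ... unused
#' @export
glance.fp_curve <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    residual_sd = x$diagnostics$residual_sd,
    converged = x$diagnostics$converged,
    non_seasonal = x$diagnostics$non_seasonal
  )
}

#' Plot a fitted seasonal curve
#' @param object an `fp_curve`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.fp_curve <- function(object, ...) {
  df <- tibble::tibble(doy = object$doy, ndvi = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$doy, .data$ndvi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day of year", y = "Fitted NDVI",
                  title = paste("Seasonal curve:", object$method)) +
    ggplot2::theme_minimal()
}
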