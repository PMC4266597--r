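#' Bell kinetic parameters
#'
#' Parameters of the Bell model for force-driven bond dissociation or
#' domain unfolding: the intrinsic (zero-force) off-rate `k_off` and the
#' distance to the transition state `delta_x` along the pulling coordinate.
#' The force-dependent off-rate is `k(F) = k_off * exp(F * delta_x / kBT)`.
#'
#' @param k_off intrinsic off-rate, 1/s, `> 0`.
#' @param delta_x distance to the transition state, nm, `> 0`.
#' @return object of class `bell_params`.
#' @examples
#' bell_params(k_off = 7.3e-7, delta_x = 0.13)   # ultrastable complex
#' @export
bell_params <- function(k_off, delta_x) {
  stopifnot(is.numeric(k_off), is.numeric(delta_x),
            k_off > 0, delta_x > 0)
  structure(list(k_off = k_off, delta_x = delta_x), class = "bell_params")
}

#' @export
print.bell_params <- function(x, ...) {
  cat(sprintf("Bell parameters: k_off = %.3g 1/s, delta_x = %.3g nm\n",
              x$k_off, x$delta_x))
  invisible(x)
}

#' Force-dependent off-rate (Bell model)
#'
#' `k(F) = k_off * exp(F * delta_x / kBT)`, computed in log space so that
#' extreme forces do not overflow prematurely.
#'
#' @param force force, pN, `>= 0` (vectorized).
#' @param p a [bell_params()] object.
#' @param kBT thermal energy, pN nm. Default 4.114.
#' @return off-rate, 1/s.
#' @export
bell_rate <- function(force, p, kBT = 4.114) {
  if (any(force < 0)) stop("bell_rate(): force must be >= 0", call. = FALSE)
  lk <- log(p$k_off) + force * p$delta_x / kBT
  out <- exp(lk)
  if (any(!is.finite(out))) {
    stop("bell_rate(): non-finite rate (force too large)", call. = FALSE)
  }
  out
}

#' Rupture-force density at constant loading rate
#'
#' Analytic probability density of the rupture force of a Bell bond loaded
#' at constant rate `r`:
#' `p(F) = k(F)/r * exp[(k_off kBT)/(delta_x r) * (1 - exp(F delta_x/kBT))]`,
#' normalized on `F in [0, Inf)`.
#'
#' @param force force, pN (vectorized).
#' @param loading_rate loading rate `r`, pN/s, `> 0`.
#' @param p a [bell_params()] object.
#' @param kBT thermal energy, pN nm.
#' @return density, 1/pN.
#' @export
rupture_force_pdf <- function(force, loading_rate, p, kBT = 4.114) {
  if (loading_rate <= 0) {
    stop("loading_rate must be > 0", call. = FALSE)
  }
  a <- p$k_off * kBT / (p$delta_x * loading_rate)
  th <- p$delta_x / kBT
  bell_rate(force, p, kBT) / loading_rate * exp(a * (1 - exp(th * force)))
}

#' Rupture-force survival and distribution functions
#'
#' Closed-form survival `S(F) = exp[a (1 - e^{F delta_x/kBT})]` with
#' `a = k_off kBT / (delta_x r)`; the CDF is `1 - S(F)`.
#'
#' @inheritParams rupture_force_pdf
#' @return probability.
#' @export
rupture_force_cdf <- function(force, loading_rate, p, kBT = 4.114) {
  if (loading_rate <= 0) stop("loading_rate must be > 0", call. = FALSE)
  a <- p$k_off * kBT / (p$delta_x * loading_rate)
  th <- p$delta_x / kBT
  1 - exp(a * (1 - exp(th * pmax(force, 0))))
}

#' Most probable rupture force at constant loading rate
#'
#' Mode of the Bell-Evans rupture-force distribution:
#' `F* = (kBT/delta_x) * log(r * delta_x / (k_off * kBT))`. Negative values
#' (very slow loading) are clamped to 0 with a warning so that dynamic force
#' spectra remain drawable.
#'
#' @param loading_rate loading rate, pN/s, `> 0` (vectorized).
#' @param p a [bell_params()] object.
#' @param kBT thermal energy, pN nm.
#' @return most probable force, pN.
#' @examples
#' ## ultrastable complex band at 10-100 nN/s
#' most_probable_force(c(1e4, 1e5), bell_params(7.3e-7, 0.13))
#' @export
most_probable_force <- function(loading_rate, p, kBT = 4.114) {
  if (any(loading_rate <= 0)) {
    stop("loading_rate must be > 0", call. = FALSE)
  }
  f <- (kBT / p$delta_x) *
    log(loading_rate * p$delta_x / (p$k_off * kBT))
  if (any(f < 0)) {
    warning("most probable force negative at low loading rate; clamped to 0",
            call. = FALSE)
    f <- pmax(f, 0)
  }
  f
}

#' Sample rupture forces from the Bell-Evans distribution
#'
#' Draws i.i.d. rupture forces at constant loading rate by inverting the
#' closed-form survival function (no rejection step). Seeded runs are
#' reproducible.
#'
#' @param n number of draws, `>= 1`.
#' @param loading_rate loading rate, pN/s, `> 0`.
#' @param p a [bell_params()] object.
#' @param kBT thermal energy, pN nm.
#' @param seed optional integer seed (local to the call).
#' @return numeric vector of forces, pN.
#' @export
sample_rupture_forces <- function(n, loading_rate, p, kBT = 4.114,
                                  seed = NULL) {
  stopifnot(n >= 1)
  if (loading_rate <= 0) stop("loading_rate must be > 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  a <- p$k_off * kBT / (p$delta_x * loading_rate)
  u <- stats::runif(n)
  # S(F) = 1 - u  =>  F = (kBT/delta_x) log(1 - log(1 - u)/a)
  (kBT / p$delta_x) * log1p(-log1p(-u) / a)
}

#' Gaussian modal estimate of a histogrammed sample
#'
#' Histograms the values (Freedman-Diaconis bins by default) and fits a
#' Gaussian `a exp(-(x - mu)^2 / (2 sigma^2))` to the bin counts by least
#' squares, as is customary for estimating the most probable rupture force
#' or loading rate at each pulling speed. Returns the fitted center and
#' width.
#'
#' @param values numeric sample (at least 10 values).
#' @param breaks passed to [graphics::hist()]; default `"FD"`.
#' @return list with `mode`, `sd`, `n`, and the histogram used.
#' @export
fit_gaussian_mode <- function(values, breaks = "FD") {
  values <- values[is.finite(values)]
  if (length(values) < 10) {
    stop("fit_gaussian_mode(): need at least 10 values", call. = FALSE)
  }
  s0 <- stats::sd(values)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  binw <- diff(h$breaks[1:2])
  if (!is.finite(s0) || s0 < binw / 100 || s0 == 0) {
    stop("fit_gaussian_mode(): degenerate spread", call. = FALSE)
  }
  df <- data.frame(x = h$mids, y = h$counts)
  start <- list(a = max(h$counts), mu = h$mids[which.max(h$counts)],
                sigma = s0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("fit_gaussian_mode(): fit did not converge: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  list(mode = unname(cf["mu"]), sd = abs(unname(cf["sigma"])),
       n = length(values), histogram = h)
}

#' Modal points of a dynamic force spectrum
#'
#' One row per pulling speed: the most probable rupture force and loading
#' rate (Gaussian modal estimates), the width of the force distribution,
#' and the number of events.
#'
#' @param pulling_speed nm/s.
#' @param most_probable_force pN.
#' @param most_probable_loading_rate pN/s, `> 0`.
#' @param force_sd pN.
#' @param n_events count, `>= 1`.
#' @return `data.frame` of class `modal_points`.
#' @export
modal_points <- function(pulling_speed, most_probable_force,
                         most_probable_loading_rate, force_sd, n_events) {
  stopifnot(all(most_probable_loading_rate > 0), all(n_events >= 1))
  df <- data.frame(
    pulling_speed = pulling_speed,
    most_probable_force = most_probable_force,
    most_probable_loading_rate = most_probable_loading_rate,
    force_sd = force_sd,
    n_events = n_events
  )
  class(df) <- c("modal_points", "data.frame")
  df
}

#' Estimate modal points from per-speed rupture events
#'
#' Groups rupture events by pulling speed and applies [fit_gaussian_mode()]
#' to the forces and to the loading rates (in log10 space by default, since
#' loading-rate distributions at fixed speed are closer to log-normal).
#'
#' @param force rupture forces, pN.
#' @param loading_rate loading rates, pN/s.
#' @param pulling_speed pulling speed per event, nm/s.
#' @param log_rates fit the loading-rate histogram in log10 space
#'   (default `TRUE`).
#' @param min_events minimum events per speed (smaller groups are dropped
#'   with a message). Default 10.
#' @return a [modal_points()] data frame, one row per retained speed.
#' @export
estimate_modal_points <- function(force, loading_rate, pulling_speed,
                                  log_rates = TRUE, min_events = 10) {
  stopifnot(length(force) == length(loading_rate),
            length(force) == length(pulling_speed))
  out <- NULL
  for (v in sort(unique(pulling_speed))) {
    i <- which(pulling_speed == v)
    if (length(i) < min_events) {
      message(sprintf("speed %g nm/s: only %d events, skipped", v, length(i)))
      next
    }
    gf <- fit_gaussian_mode(force[i])
    gr <- if (log_rates) {
      g <- fit_gaussian_mode(log10(loading_rate[i]))
      10^g$mode
    } else {
      fit_gaussian_mode(loading_rate[i])$mode
    }
    row <- modal_points(v, gf$mode, gr, gf$sd, length(i))
    out <- if (is.null(out)) row else rbind(out, row)
  }
  if (is.null(out)) {
    stop("estimate_modal_points(): no speed group had enough events",
         call. = FALSE)
  }
  class(out) <- c("modal_points", "data.frame")
  out
}

#' Bell-Evans fit of a dynamic force spectrum
#'
#' Least-squares fit of the closed-form most-probable-force relation in
#' `(log r, F*)` space: `F* = (kBT/delta_x) log r + intercept`, so the slope
#' gives `delta_x = kBT / slope` and the intercept gives
#' `k_off = (delta_x / kBT) * exp(-intercept / slope)`. Standard errors are
#' propagated from the covariance of the linear fit; `k_off` is
#' exponentially sensitive to the intercept, so its uncertainty is reported
#' as a multiplicative factor.
#'
#' @param points a [modal_points()] data frame with at least 3 rows whose
#'   loading rates span at least a factor 3.
#' @param kBT thermal energy, pN nm.
#' @param weight_by_n weight points by `n_events` (default `FALSE`).
#' @param history_class label for the bond-history class of the fitted
#'   ruptures (`"intact"`, `"shielded"`, `"xmod_unfolding"`, or other).
#' @return object of class `bell_evans_fit`: `params` ([bell_params()]),
#'   `delta_x_stderr` (nm), `k_off_factor_stderr` (multiplicative),
#'   `residuals` (pN), `points`, `history_class`, and the underlying `lm`.
#' @examples
#' p <- bell_params(2.6e-6, 0.15)
#' r <- 10^seq(4, 5, length.out = 5)
#' pts <- modal_points(r / 10, most_probable_force(r, p), r, 20, 100)
#' fit_bell_evans(pts)$params
#' @export
fit_bell_evans <- function(points, kBT = 4.114, weight_by_n = FALSE,
                           history_class = "intact") {
  stopifnot(is.data.frame(points))
  if (nrow(points) < 3) {
    stop("fit_bell_evans(): need at least 3 modal points", call. = FALSE)
  }
  r <- points$most_probable_loading_rate
  if (max(r) / min(r) < 3) {
    stop("fit_bell_evans(): loading rates must span at least a factor 3",
         call. = FALSE)
  }
  w <- if (weight_by_n) points$n_events else NULL
  fit <- stats::lm(points$most_probable_force ~ log(r), weights = w)
  cf <- stats::coef(fit)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  if (slope <= 0) {
    stop("fit_bell_evans(): non-positive slope (delta_x undefined)",
         call. = FALSE)
  }
  delta_x <- kBT / slope
  k_off <- (delta_x / kBT) * exp(-intercept / slope)
  if (k_off <= 0 || !is.finite(k_off)) {
    stop("fit_bell_evans(): invalid intercept-derived off-rate",
         call. = FALSE)
  }
  # vcov warns on noiseless (numerically perfect) fits; the zero
  # covariance is the correct answer there
  vc <- suppressWarnings(stats::vcov(fit))
  se_slope <- sqrt(vc[2, 2]); se_int <- sqrt(vc[1, 1])
  delta_x_se <- kBT * se_slope / slope^2
  # d log k / d intercept = -1/slope; d log k / d slope = intercept/slope^2
  # - 1/slope  (from the delta_x prefactor)
  dls <- intercept / slope^2 - 1 / slope
  dli <- -1 / slope
  var_logk <- dls^2 * vc[2, 2] + dli^2 * vc[1, 1] + 2 * dls * dli * vc[1, 2]
  structure(list(
    params = bell_params(k_off = k_off, delta_x = delta_x),
    delta_x_stderr = delta_x_se,
    k_off_factor_stderr = exp(sqrt(max(var_logk, 0))),
    residuals = unname(stats::residuals(fit)),
    points = points,
    history_class = history_class,
    kBT = kBT,
    lm = fit
  ), class = "bell_evans_fit")
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat("Bell-Evans dynamic force spectrum fit (", x$history_class, ")\n",
      sep = "")
  cat(sprintf("  delta_x = %.4f nm (se %.4f)\n",
              x$params$delta_x, x$delta_x_stderr))
  cat(sprintf("  k_off   = %.3g 1/s (x/ %.2f)\n",
              x$params$k_off, x$k_off_factor_stderr))
  cat(sprintf("  %d modal points, loading rates %.3g - %.3g pN/s\n",
              nrow(x$points), min(x$points$most_probable_loading_rate),
              max(x$points$most_probable_loading_rate)))
  invisible(x)
}

#' Plot a dynamic force spectrum with its Bell-Evans fit
#'
#' @param x a `bell_evans_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bell_evans_fit <- function(x, ...) {
  r <- x$points$most_probable_loading_rate
  f <- x$points$most_probable_force
  graphics::plot(r, f, log = "x", xlab = "loading rate (pN/s)",
                 ylab = "most probable rupture force (pN)", ...)
  graphics::arrows(r, f - x$points$force_sd, r, f + x$points$force_sd,
                   angle = 90, code = 3, length = 0.03)
  rr <- exp(seq(log(min(r)), log(max(r)), length.out = 100))
  graphics::lines(rr, most_probable_force(rr, x$params, x$kBT), lty = 2)
  invisible(x)
}
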