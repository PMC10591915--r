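#' One-site saturation model with a nonspecific component
#'
#' Predicted emission at 350 nm for inhibitor concentration `c`:
#' `F(c) = f0 + delta_f * c / (ki + c) + ns_slope * c`. `F(0) = f0`, the
#' half-saturation point of the specific component sits at `c = ki`, and
#' the large-concentration asymptote has slope `ns_slope`.
#'
#' @param c inhibitor concentration(s), molar, >= 0.
#' @param f0 baseline emission (a.u.).
#' @param delta_f saturable amplitude (a.u.).
#' @param ki half-saturation constant (M, > 0).
#' @param ns_slope nonspecific slope (a.u./M).
#' @return predicted emission (a.u.).
#' @export
saturation_model <- function(c, f0, delta_f, ki, ns_slope) {
  if (!(ki > 0)) stop("ki must be > 0")
  if (any(c < 0)) stop("concentrations must be >= 0")
  f0 + delta_f * c / (ki + c) + ns_slope * c
}

#' Fit a displacement titration
#'
#' Nonlinear least-squares fit of [saturation_model()] to one titration
#' (pooled points, or one replicate via `replicate`). The fitted
#' half-saturation constant is reported as the inhibition constant Ki,
#' exactly as the assay reports it; no competition correction is applied.
#'
#' Starting values are data-driven and deterministic: `f0` from the
#' minimum emission, `ns_slope` from the terminal-segment slope,
#' `delta_f` from the ns-corrected range, and `ki` from the half-range
#' crossing concentration. Optimisation uses Levenberg-Marquardt
#' (`minpack.lm::nls.lm`) with `ki` bounded in (0, 10 x max
#' concentration], `delta_f >= 0` and `ns_slope >= 0` (nonspecific
#' binding can only add signal); the relative tolerance on the
#' residual sum of squares is 1e-10. The standard error of Ki comes from
#' the variance-covariance estimate at the optimum (analytic Jacobian).
#'
#' A series with no usable signal change (emission range below
#' `flat_tol` of its mean) is non-identifiable: the fit returns
#' `converged = FALSE` with a reason instead of a spurious Ki.
#'
#' @param series a `titration_series` data frame (columns
#'   `concentration_M`, `emission350`, `replicate`).
#' @param replicate optional replicate index to fit alone.
#' @param flat_tol relative emission range below which the series is
#'   declared flat.
#' @return An object of class `binding_fit`: list with `f0`, `delta_f`,
#'   `ki`, `ns_slope`, `rss`, `se_ki`, `converged`, `reason`, `n_points`,
#'   `rss_trace`.
#' @export
fit_titration <- function(series, replicate = NULL, flat_tol = 1e-3) {
  df <- as.data.frame(series)
  if (!is.null(replicate)) df <- df[df$replicate %in% replicate, , drop = FALSE]
  conc <- df$concentration_M
  y <- df$emission350
  if (any(conc < 0)) stop("negative concentrations rejected")
  if (length(unique(conc)) < 5)
    stop("need >= 5 distinct concentrations to fit")

  failed <- function(reason) {
    structure(list(f0 = NA_real_, delta_f = NA_real_, ki = NA_real_,
                   ns_slope = NA_real_, rss = NA_real_, se_ki = NA_real_,
                   converged = FALSE, reason = reason,
                   n_points = length(y), rss_trace = numeric(0)),
              class = "binding_fit")
  }
  if (diff(range(y)) <= flat_tol * max(abs(mean(y)), .Machine$double.eps))
    return(failed("flat series: no signal change, Ki not identifiable"))

  # fit in scaled units (concentration / cmax, emission / its mean) so the
  # Jacobian is well conditioned regardless of the molar scale
  cmax <- max(conc)
  ybar <- mean(abs(y))
  cs <- conc / cmax
  ys <- y / ybar
  start <- titration_start(cs, ys)
  start[["ns_slope"]] <- max(start[["ns_slope"]], 0)
  # nonspecific binding can only add signal: ns_slope >= 0
  lower <- c(f0 = -Inf, delta_f = 0, ki = 1e-6, ns_slope = 0)
  upper <- c(f0 = Inf, delta_f = Inf, ki = 10, ns_slope = Inf)
  resid_fn <- function(p) {
    ys - saturation_model(cs, p[["f0"]], p[["delta_f"]], p[["ki"]],
                          p[["ns_slope"]])
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 1000, maxfev = 5000))
  # back to data units
  p <- fit$par
  p <- c(f0 = p[["f0"]] * ybar, delta_f = p[["delta_f"]] * ybar,
         ki = p[["ki"]] * cmax, ns_slope = p[["ns_slope"]] * ybar / cmax)
  rss <- fit$deviance * ybar^2
  conv <- fit$info %in% c(1, 2, 3, 4)
  # analytic Jacobian at the optimum, in scaled units for conditioning;
  # the ki column then carries a 1/cmax scale undone on the se below
  ks <- p[["ki"]] / cmax
  J <- cbind(f0 = rep(1, length(cs)),
             delta_f = cs / (ks + cs),
             ki = -(p[["delta_f"]] / ybar) * cs / (ks + cs)^2,
             ns_slope = cs)
  dof <- length(y) - length(p)
  se_ki <- NA_real_
  if (dof > 0) {
    sigma2 <- (rss / ybar^2) / dof
    vc <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(vc) && vc["ki", "ki"] >= 0)
      se_ki <- sqrt(vc["ki", "ki"]) * cmax
  }
  structure(list(f0 = p[["f0"]], delta_f = p[["delta_f"]], ki = p[["ki"]],
                 ns_slope = p[["ns_slope"]], rss = rss, se_ki = se_ki,
                 converged = conv,
                 reason = if (conv) NA_character_ else fit$message,
                 n_points = length(y), rss_trace = fit$rsstrace * ybar^2),
            class = "binding_fit")
}

# Deterministic data-driven starting values.
titration_start <- function(conc, y) {
  o <- order(conc)
  conc <- conc[o]; y <- y[o]
  ybar <- tapply(y, conc, mean)
  cu <- as.numeric(names(ybar))
  n <- length(cu)
  # terminal slope from the last two mean points
  ns0 <- (ybar[n] - ybar[n - 1]) / (cu[n] - cu[n - 1])
  f00 <- min(ybar)
  spec <- ybar - f00 - ns0 * cu
  df0 <- max(max(spec), diff(range(ybar)) / 2, .Machine$double.eps)
  half <- f00 + ns0 * cu + df0 / 2
  above <- which(ybar >= half & cu > 0)
  ki0 <- if (length(above) > 0) cu[above[1]] else cu[max(2, ceiling(n / 2))]
  ki0 <- min(max(ki0, cu[2] / 10), 10 * cu[n])
  c(f0 = as.numeric(f00), delta_f = as.numeric(df0),
    ki = as.numeric(ki0), ns_slope = as.numeric(ns0))
}

#' Fit each replicate of a titration separately
#'
#' @param series a `titration_series` data frame.
#' @param ... passed to [fit_titration()].
#' @return list of `binding_fit` objects, one per replicate index.
#' @export
fit_replicates <- function(series, ...) {
  reps <- sort(unique(series$replicate))
  lapply(reps, function(r) fit_titration(series, replicate = r, ...))
}

#' Replicate mean and standard deviation of Ki
#'
#' Arithmetic mean and sample (n-1) standard deviation of the fitted Ki
#' over independently fitted replicates, the "mean +/- SD over three
#' independent titrations" presentation.
#'
#' @param fits list of `binding_fit` objects.
#' @return list with `ki_mean`, `ki_sd`, `n` (converged fits used), and
#'   `ki_values`.
#' @export
replicate_summary <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (sum(ok) < 2) stop("need >= 2 converged fits for a replicate summary")
  ki <- vapply(fits[ok], function(f) f$ki, numeric(1))
  list(ki_mean = mean(ki), ki_sd = stats::sd(ki), n = length(ki),
       ki_values = ki)
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("binding_fit: NOT converged (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "binding_fit: Ki = %.4g M (se %.2g), f0 = %.4g, delta_f = %.4g, ns = %.3g, rss = %.4g\n",
    x$ki, x$se_ki, x$f0, x$delta_f, x$ns_slope, x$rss))
  invisible(x)
}
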