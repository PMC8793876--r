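#' Percentage loss of conductance from a centrifuge series
#'
#' Converts replicate conductance measurements at decreasing xylem pressures
#' into percentage loss of conductance, `PLC = 100 * (1 - kbar / kmax)`,
#' where `kbar` is the per-step replicate mean. The reference `kmax` is the
#' replicate mean at the least-negative (first) pressure step by default —
#' the step closest to zero pressure, where specific conductivity is defined
#' — or the maximum step mean with `kmax_rule = "max"`. PLC is clamped to
#' [0, 100]: small flow increases relative to the first step (negative PLC)
#' are measurement noise, not recovery.
#'
#' @param pressure Numeric vector of xylem pressures (MPa, <= 0), strictly
#'   decreasing; at least 4 steps.
#' @param k Matrix of conductances, one row per pressure step, one column per
#'   replicate (typically 3); or a numeric vector of per-step means.
#' @param kmax_rule `"first"` (default) or `"max"`.
#' @return A list with `plc` (per-step, %) and `kmax`.
#' @examples
#' compute_plc(c(-0.8, -1.6, -2.4, -3.2), c(2, 1.8, 1, 0.2))
#' @export
compute_plc <- function(pressure, k, kmax_rule = c("first", "max")) {
  kmax_rule <- match.arg(kmax_rule)
  if (is.vector(k)) k <- matrix(k, ncol = 1L)
  stopifnot(nrow(k) == length(pressure))
  if (length(pressure) < 4L) stop("need >= 4 pressure steps", call. = FALSE)
  if (any(diff(pressure) >= 0)) {
    stop("pressures must be strictly decreasing", call. = FALSE)
  }
  if (any(pressure > 0)) stop("pressures must be <= 0 (MPa)", call. = FALSE)
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("conductances must be finite and >= 0", call. = FALSE)
  }
  kbar <- rowMeans(k)
  kmax <- if (kmax_rule == "first") kbar[1L] else max(kbar)
  if (kmax <= 0) stop("kmax <= 0: unusable branch", call. = FALSE)
  plc <- pmin(pmax(100 * (1 - kbar / kmax), 0), 100)
  list(plc = plc, kmax = kmax)
}

# sigmoid vulnerability model: PLC(P) = 100 / (1 + exp(S/25 * (P - P50)))
vc_sigmoid <- function(P, P50, S) 100 / (1 + exp(S / 25 * (P - P50)))

#' Fit the sigmoid vulnerability curve
#'
#' Bounded nonlinear least squares of
#' `PLC = 100 / (1 + exp(S/25 * (P - P50)))` — `P50` (MPa) the pressure at
#' 50% conductance loss, `S` (% / MPa) the slope magnitude at the inflection.
#' Optimised with L-BFGS-B, `P50` in `[min(P) - 2, -0.1]` and `S` in
#' `(0, 500]`; initial `P50` interpolates the pressures to the 50% crossing
#' and initial `S` comes from the secant between the 20% and 80% crossings.
#' On non-convergence, up to 3 jittered restarts are tried; the result is
#' flagged, never a silent `NaN`.
#'
#' @param pressure Xylem pressures (MPa, <= 0), at least 4 values.
#' @param plc Percent loss of conductance in [0, 100], same length.
#' @return An object of class `vc_fit`: list with `p50`, `slope`, `sse`,
#'   `converged`, `low_information` (PLC span fails to cover [20, 80]),
#'   `fitted` (per-step fitted PLC), plus the data.
#' @examples
#' p <- seq(-0.8, -8, by = -0.8)
#' fit <- fit_vc(p, vc_sigmoid(p, -4, 30))
#' c(fit$p50, fit$slope)
#' @export
fit_vc <- function(pressure, plc) {
  stopifnot(length(pressure) == length(plc), length(pressure) >= 4L)
  if (any(plc < -1e-8) || any(plc > 100 + 1e-8)) {
    stop("PLC outside [0, 100]", call. = FALSE)
  }
  plc <- pmin(pmax(plc, 0), 100)
  low_information <- !(min(plc) <= 20 && max(plc) >= 80)

  interp_crossing <- function(level) {
    above <- which(plc >= level)
    if (!length(above)) return(min(pressure))
    i <- min(above)
    if (i == 1L || plc[i] == plc[i - 1L]) return(pressure[i])
    # linear interpolation between the bracketing steps
    pressure[i - 1L] + (level - plc[i - 1L]) *
      (pressure[i] - pressure[i - 1L]) / (plc[i] - plc[i - 1L])
  }
  p50_0 <- interp_crossing(50)
  p20 <- interp_crossing(20)
  p80 <- interp_crossing(80)
  s0 <- if (abs(p20 - p80) > 1e-9) 60 / abs(p20 - p80) else 30
  lower <- c(min(pressure) - 2, 1e-3)
  upper <- c(-0.1, 500)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  start0 <- clamp(c(p50_0, s0), lower, upper)

  sse_fn <- function(par) sum((plc - vc_sigmoid(pressure, par[1], par[2]))^2)
  run <- function(start) {
    stats::optim(start, sse_fn, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(maxit = 500L, factr = 10, pgtol = 0))
  }
  fit <- run(start0)
  tries <- 0L
  while (fit$convergence != 0 && tries < 3L) {
    tries <- tries + 1L
    jitter <- start0 * (1 + 0.2 * tries * c(-1, 1)^tries)
    fit2 <- run(clamp(jitter, lower, upper))
    if (fit2$value < fit$value || fit2$convergence == 0) fit <- fit2
  }
  out <- list(
    p50 = fit$par[1], slope = fit$par[2], sse = fit$value,
    converged = fit$convergence == 0, low_information = low_information,
    fitted = vc_sigmoid(pressure, fit$par[1], fit$par[2]),
    pressure = pressure, plc = plc
  )
  class(out) <- "vc_fit"
  out
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("Vulnerability curve fit: P50 = %.3f MPa, S = %.2f %%/MPa\n",
              x$p50, x$slope))
  cat(sprintf("  SSE = %.4g over %d steps; converged: %s%s\n", x$sse,
              length(x$pressure), x$converged,
              if (x$low_information) " [low information]" else ""))
  invisible(x)
}

#' Predict percent loss of conductance from a fitted curve
#'
#' Evaluates the fitted sigmoid at new pressures. At `P = P50` the prediction
#' is exactly 50%, and the derivative there is `-S` (% / MPa).
#'
#' @param fit A `vc_fit` object, or a list with `p50` and `slope`.
#' @param pressure Xylem pressures (MPa, <= 0).
#' @return Predicted PLC (%), same length as `pressure`.
#' @export
predict_plc <- function(fit, pressure) {
  stopifnot(is.numeric(fit$p50), is.numeric(fit$slope))
  if (any(pressure > 0)) stop("pressures must be <= 0 (MPa)", call. = FALSE)
  vc_sigmoid(pressure, fit$p50, fit$slope)
}

#' Xylem-specific hydraulic conductivity from maximum conductance
#'
#' The default `"standard"` mode computes `Ks = kmax * L / A`, the physically
#' conventional specific conductivity of a sample of length `L` and sapwood
#' area `A`. The `"literal"` mode computes `kmax / (L * A)`, mirroring a
#' word-for-word reading of "divided by sample length and sapwood area"; the
#' two differ by a factor `L^2` and the mode used is recorded on the result.
#'
#' @param kmax Maximum hydraulic conductance (> 0).
#' @param length_m Sample length in m (> 0; the centrifuge rotor takes
#'   0.27 m samples).
#' @param area_m2 Sapwood area in m^2 (> 0).
#' @param mode `"standard"` or `"literal"`.
#' @return Ks, with attribute `ks_mode`.
#' @export
compute_ks <- function(kmax, length_m, area_m2,
                       mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (any(kmax <= 0) || any(length_m <= 0) || any(area_m2 <= 0)) {
    stop("kmax, length and area must all be > 0", call. = FALSE)
  }
  ks <- if (mode == "standard") kmax * length_m / area_m2
        else kmax / (length_m * area_m2)
  attr(ks, "ks_mode") <- mode
  ks
}

#' Fit vulnerability curves for every branch of a conductance table
#'
#' Input follows the long centrifuge CSV layout: one row per pressure step
#' per branch, with replicate conductances in `k_rep*` columns. Each branch
#' is reduced to PLC with [compute_plc()], fitted with [fit_vc()], and its
#' specific conductivity computed with [compute_ks()].
#'
#' @param curves data.frame with columns `branch_id`, `species`,
#'   `pressure_MPa`, `k_rep1` (... `k_repN`), `length_m`, `sapwood_area_m2`.
#' @param ks_mode Passed to [compute_ks()].
#' @param kmax_rule Passed to [compute_plc()].
#' @return data.frame with one row per branch: `branch_id`, `species`,
#'   `P50_MPa`, `S_pct_per_MPa`, `kmax`, `Ks_kg_m_s_MPa`, `sse`, `converged`,
#'   `low_information`.
#' @export
fit_vc_table <- function(curves, ks_mode = c("standard", "literal"),
                         kmax_rule = c("first", "max")) {
  ks_mode <- match.arg(ks_mode)
  kmax_rule <- match.arg(kmax_rule)
  need <- c("branch_id", "species", "pressure_MPa", "length_m",
            "sapwood_area_m2")
  if (!all(need %in% names(curves))) {
    stop("missing columns: ", paste(setdiff(need, names(curves)),
                                    collapse = ", "), call. = FALSE)
  }
  rep_cols <- grep("^k_rep[0-9]+$", names(curves), value = TRUE)
  if (!length(rep_cols)) stop("no k_rep* replicate columns", call. = FALSE)
  rows <- lapply(split(curves, curves$branch_id), function(b) {
    b <- b[order(-b$pressure_MPa), , drop = FALSE]
    pl <- compute_plc(b$pressure_MPa,
                      as.matrix(b[, rep_cols, drop = FALSE]),
                      kmax_rule = kmax_rule)
    fit <- fit_vc(b$pressure_MPa, pl$plc)
    data.frame(
      branch_id = b$branch_id[1L], species = b$species[1L],
      P50_MPa = fit$p50, S_pct_per_MPa = fit$slope, kmax = pl$kmax,
      Ks_kg_m_s_MPa = as.numeric(
        compute_ks(pl$kmax, b$length_m[1L], b$sapwood_area_m2[1L], ks_mode)),
      sse = fit$sse, converged = fit$converged,
      low_information = fit$low_information,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ks_mode") <- ks_mode
  out
}

#' Species means of branch-level vulnerability fits
#'
#' Branch fits are averaged per species with equal weights. `P50_abs_MPa`
#' (the absolute value of the mean P50) is appended: embolism resistance as
#' used by the downstream comparative statistics.
#'
#' @param fits Output of [fit_vc_table()].
#' @return data.frame, one row per species.
#' @export
species_vc_means <- function(fits) {
  agg <- stats::aggregate(
    fits[, c("P50_MPa", "S_pct_per_MPa", "Ks_kg_m_s_MPa")],
    by = list(species = fits$species), FUN = mean)
  agg$P50_abs_MPa <- abs(agg$P50_MPa)
  agg$n_branches <- as.vector(table(fits$species)[agg$species])
  agg
}
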