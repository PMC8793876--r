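#' Exhaustive AICc multimodel selection with averaging and importance
#'
#' Dredge-style all-subsets OLS over a candidate predictor set. Response and
#' predictors are z-standardised first, so coefficients are comparable
#' effect sizes. For every one of the `2^p` submodels (including the
#' intercept-only null):
#' `logLik = -n/2 * (log(2*pi) + log(RSS/n) + 1)`, `k` = number of slopes +
#' intercept + residual variance, `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#' Akaike weights are normalised over *all* candidate models; the selected
#' set is `delta AICc < delta_threshold` (conventionally 2).
#'
#' Model averaging uses zero-substitution ("full") averaging with weights
#' renormalised over the selected set: a variable absent from a selected
#' model contributes coefficient 0. Importance of a variable is the summed
#' renormalised weight of the selected models containing it. The per-variable
#' p comes from a z-test on the averaged coefficient with the
#' model-averaged unconditional standard error
#' `se = sum_i w_i * sqrt(se_i^2 + (b_i - b_avg)^2)`.
#'
#' @param table Species trait data.frame.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor columns
#'   (screen them with [vif_screen()] first).
#' @param delta_threshold Selection band on delta AICc (default 2).
#' @return Object of class `aicc_selection`: list with `models` (one row per
#'   submodel: formula, k, logLik, AICc, delta, weight, selected, plus one
#'   coefficient column per candidate), `averaged` (per-variable averaged
#'   coefficient, unconditional se, z, p, `importance` over the selected
#'   set, and `importance_full` over all candidate models), `response`,
#'   `candidates`, `n`.
#' @export
aicc_model_selection <- function(table, response, candidates,
                                 delta_threshold = 2) {
  stopifnot(response %in% names(table), all(candidates %in% names(table)))
  dat <- table[, c(response, candidates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  z <- as.data.frame(scale(dat))
  y <- z[[response]]
  p <- length(candidates)

  subsets <- lapply(seq_len(2^p) - 1L,
                    function(m) candidates[bitwAnd(m, 2^(seq_len(p) - 1L)) > 0])
  rows <- vector("list", length(subsets))
  coefs <- matrix(0, length(subsets), p,
                  dimnames = list(NULL, candidates))
  ses <- matrix(0, length(subsets), p, dimnames = list(NULL, candidates))
  for (i in seq_along(subsets)) {
    vars <- subsets[[i]]
    X <- cbind(`(Intercept)` = 1,
               as.matrix(z[, vars, drop = FALSE]))
    k <- length(vars) + 2L      # slopes + intercept + residual variance
    if (n - k - 1L <= 0L) {
      warning("dropping model {", paste(vars, collapse = "+"),
              "}: n - k - 1 <= 0", call. = FALSE)
      rows[[i]] <- NULL
      next
    }
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    if (length(vars)) {
      coefs[i, vars] <- fit$coefficients[vars]
      sigma2 <- rss / fit$df.residual
      xtxi <- chol2inv(chol(crossprod(X)))
      se_all <- sqrt(sigma2 * diag(xtxi))
      ses[i, vars] <- se_all[-1L]
    }
    rows[[i]] <- data.frame(
      model = if (length(vars)) paste(vars, collapse = " + ") else "(null)",
      n_predictors = length(vars), k = k, logLik = ll, AICc = aicc,
      stringsAsFactors = FALSE)
  }
  ok <- !vapply(rows, is.null, logical(1))
  models <- do.call(rbind, rows[ok])
  coefs <- coefs[ok, , drop = FALSE]
  ses <- ses[ok, , drop = FALSE]
  subsets <- subsets[ok]

  models$delta <- models$AICc - min(models$AICc)
  w <- exp(-models$delta / 2)
  models$weight <- w / sum(w)
  models$selected <- models$delta < delta_threshold
  models <- cbind(models, as.data.frame(coefs))

  sel <- which(models$selected)
  wsel <- models$weight[sel] / sum(models$weight[sel])
  has <- vapply(candidates,
                function(v) vapply(subsets[sel], function(s) v %in% s,
                                   logical(1)),
                logical(length(sel)))
  has <- matrix(has, nrow = length(sel), dimnames = list(NULL, candidates))
  b_avg <- colSums(wsel * coefs[sel, , drop = FALSE])
  importance <- colSums(wsel * has)
  # full-set relative variable importance: Akaike-weight sum over every
  # candidate model containing the variable (does not saturate at 1 the way
  # the selected-set measure does when all selected models share a variable)
  has_all <- vapply(candidates,
                    function(v) vapply(subsets, function(s) v %in% s,
                                       logical(1)),
                    logical(length(subsets)))
  importance_full <- colSums(models$weight * has_all)
  se_avg <- vapply(candidates, function(v) {
    sum(wsel * sqrt(ses[sel, v]^2 + (coefs[sel, v] - b_avg[[v]])^2))
  }, numeric(1))
  zstat <- ifelse(se_avg > 0, b_avg / se_avg, NA_real_)
  averaged <- data.frame(
    variable = candidates, coefficient = unname(b_avg),
    se = unname(se_avg), z = unname(zstat),
    p = unname(2 * stats::pnorm(-abs(zstat))),
    importance = unname(importance),
    importance_full = unname(importance_full), stringsAsFactors = FALSE)

  out <- list(models = models[order(models$delta), ], averaged = averaged,
              response = response, candidates = candidates, n = n,
              delta_threshold = delta_threshold)
  class(out) <- "aicc_selection"
  out
}

#' @export
print.aicc_selection <- function(x, ...) {
  cat("AICc all-subsets selection for", x$response, "on {",
      paste(x$candidates, collapse = ", "), "}, n =", x$n, "\n")
  sel <- x$models[x$models$selected,
                  c("model", "k", "logLik", "AICc", "delta", "weight")]
  print(sel, row.names = FALSE, digits = 4)
  cat("\nAveraged over the delta <", x$delta_threshold, "set:\n")
  print(x$averaged, row.names = FALSE, digits = 3)
  invisible(x)
}
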