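#' Parse a recursive path-model specification
#'
#' One equation per line (or per element), `lavaan`-style syntax restricted
#' to observed-variable regressions: `"VE ~ TO + MF"`. The implied directed
#' graph must be acyclic (a *recursive* model); variables never appearing on
#' a left-hand side are exogenous.
#'
#' @param lines Character vector of equations, or a single string with
#'   newlines, or a path to a plain-text spec file.
#' @return Object of class `path_spec`: list with `equations` (named list
#'   endogenous -> predictors), `variables` (topologically ordered),
#'   `exogenous`, `endogenous`.
#' @examples
#' path_spec(c("VE ~ TO + MF", "P50_abs ~ VE + RPA"))
#' @export
path_spec <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- unlist(strsplit(lines, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty path specification", call. = FALSE)
  eqs <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "~", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("bad equation: ", ln, call. = FALSE)
    lhs <- trimws(parts[1L])
    rhs <- trimws(strsplit(parts[2L], "+", fixed = TRUE)[[1L]])
    if (lhs %in% names(eqs)) stop("duplicate equation for ", lhs,
                                  call. = FALSE)
    eqs[[lhs]] <- rhs
  }
  vars <- unique(c(names(eqs), unlist(eqs)))
  endo <- names(eqs)
  exo <- setdiff(vars, endo)
  # topological order (Kahn); failure = cycle
  remaining <- endo
  order <- exo
  while (length(remaining)) {
    ready <- remaining[vapply(remaining,
                              function(v) all(eqs[[v]] %in% order),
                              logical(1))]
    if (!length(ready)) {
      stop("cyclic path specification involving: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    }
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  structure(list(equations = eqs, variables = order, exogenous = exo,
                 endogenous = endo), class = "path_spec")
}

#' Fit a recursive path model
#'
#' Observed-variable path analysis. All variables are z-standardised, each
#' structural equation is estimated by least squares (maximum-likelihood
#' equivalent for recursive models with uncorrelated errors), exogenous
#' covariances are fixed at their sample values (saturated exogenous block),
#' and the implied covariance is assembled as
#' `Sigma = (I - B)^-1 Psi (I - B)^-T` with `B` the path-coefficient matrix
#' and `Psi` holding the exogenous covariance block and the endogenous
#' residual variances. Fit is the Wishart ML discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` with `chi^2 = (N-1) F` and
#' `df = p(p+1)/2 - free parameters`. A saturated specification gives
#' `chi^2 = 0` on `df = 0`.
#'
#' @param table Trait data.frame (complete cases over the model's variables
#'   are used; needs at least variables + 2 of them).
#' @param spec A [path_spec()] object (or input accepted by it).
#' @return Object of class `path_fit`: list with `coefficients` (data.frame
#'   of standardized edge coefficients with se, t, p), `B` (matrix, rows =
#'   child), `residual_variances`, `Sigma` (implied), `S` (sample),
#'   `chisq`, `df`, `p`, `N`, `spec`.
#' @export
fit_path_model <- function(table, spec) {
  if (!inherits(spec, "path_spec")) spec <- path_spec(spec)
  vars <- spec$variables
  miss <- setdiff(vars, names(table))
  if (length(miss)) {
    stop("variables absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dat <- table[, vars, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  N <- nrow(dat)
  if (N < length(vars) + 2L) {
    stop("need at least variables + 2 complete cases", call. = FALSE)
  }
  z <- as.data.frame(scale(dat))
  p <- length(vars)
  S <- stats::cov(z)                        # N-1 denominator
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  exo <- spec$exogenous
  Psi[exo, exo] <- S[exo, exo, drop = FALSE]
  coef_rows <- list()
  for (v in spec$endogenous) {
    preds <- spec$equations[[v]]
    fit <- stats::lm(stats::reformulate(preds, v), data = z)
    sm <- summary(fit)$coefficients
    b <- stats::coef(fit)[preds]
    B[v, preds] <- b
    # residual variance on the same N-1 scale as S, so a saturated model
    # reproduces S exactly
    Psi[v, v] <- sum(stats::residuals(fit)^2) / (N - 1)
    coef_rows[[v]] <- data.frame(
      outcome = v, predictor = preds, coefficient = unname(b),
      se = sm[preds, "Std. Error"], t = sm[preds, "t value"],
      p = sm[preds, "Pr(>|t|)"], stringsAsFactors = FALSE)
  }
  IB <- solve(diag(p) - B)
  Sigma <- IB %*% Psi %*% t(IB)
  dimnames(Sigma) <- dimnames(S)
  n_free <- length(unlist(spec$equations)) +          # path coefficients
    length(exo) * (length(exo) + 1) / 2 +             # exogenous (co)variances
    length(spec$endogenous)                           # residual variances
  df <- p * (p + 1) / 2 - n_free
  if (df < 0) stop("model has negative df (over-parameterised)",
                   call. = FALSE)
  detS <- determinant(S, logarithm = TRUE)
  detSig <- determinant(Sigma, logarithm = TRUE)
  if (detSig$sign <= 0) stop("singular implied covariance", call. = FALSE)
  Fml <- as.numeric(detSig$modulus) +
    sum(diag(S %*% solve(Sigma))) - as.numeric(detS$modulus) - p
  chisq <- max((N - 1) * Fml, 0)
  out <- list(
    coefficients = do.call(rbind, c(coef_rows, make.row.names = FALSE)),
    B = B, residual_variances = diag(Psi)[spec$endogenous],
    Sigma = Sigma, S = S, chisq = chisq, df = df,
    p = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    N = N, spec = spec)
  class(out) <- "path_fit"
  out
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Recursive path model: chi^2 = %.2f, df = %d, P = %s, N = %d\n",
              x$chisq, x$df,
              if (is.na(x$p)) "NA (saturated)" else sprintf("%.3f", x$p),
              x$N))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Direct, indirect and total effects on an outcome
#'
#' Path-tracing decomposition in a recursive model: the direct effect of a
#' variable on the outcome is its edge coefficient (0 if no edge); the
#' indirect effect sums, over every directed path of length >= 2 into the
#' outcome, the product of the path's edge coefficients; total = direct +
#' indirect. Computed via powers of the (nilpotent) coefficient matrix.
#'
#' @param fit A `path_fit` object.
#' @param outcome Outcome variable name (must be in the model).
#' @return data.frame with `variable`, `direct`, `indirect`, `total`.
#' @export
effects_decomposition <- function(fit, outcome) {
  stopifnot(inherits(fit, "path_fit"))
  vars <- colnames(fit$B)
  if (!outcome %in% vars) stop("outcome not in model: ", outcome,
                               call. = FALSE)
  B <- fit$B
  p <- length(vars)
  total <- B
  Bk <- B
  for (k in seq_len(p - 1L)) {       # B is nilpotent: B^p = 0 for a DAG
    Bk <- Bk %*% B
    if (!any(Bk != 0)) break
    total <- total + Bk
  }
  others <- setdiff(vars, outcome)
  data.frame(variable = others,
             direct = B[outcome, others],
             indirect = total[outcome, others] - B[outcome, others],
             total = total[outcome, others],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bundled path-model presets for the hydraulics analysis
#'
#' Best-effort transcriptions of the conceptual cause-effect diagrams used
#' in the conifer hydraulics analysis: `"p50"` routes pit dimensions through
#' torus overlap and margo flexibility into the valve effect, and pit
#' aperture size and wall thickness through aperture resistance, into
#' embolism resistance; `"ks"` routes tracheid traits and aperture
#' resistance into specific conductivity. Edit freely — they are plain
#' equation sets.
#'
#' @param which `"p50"` or `"ks"`.
#' @return A `path_spec`.
#' @export
path_preset <- function(which = c("p50", "ks")) {
  which <- match.arg(which)
  lines <- switch(which,
    p50 = c(
      "TO ~ DT_um + DPA_um",
      "MF ~ DPM_um + DT_um",
      "VE ~ TO + MF",
      "RPA_MPa_s_m3 ~ DPA_um + Tw_um",
      "P50_abs_MPa ~ VE + RPA_MPa_s_m3"
    ),
    ks = c(
      "RPA_MPa_s_m3 ~ DPA_um + Tw_um",
      "Ks_kg_m_s_MPa ~ Dh_um + TD_per_mm2 + Tw_um + RPA_MPa_s_m3"
    ))
  path_spec(lines)
}
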