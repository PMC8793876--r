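#' Pairwise Pearson correlation matrix with p-values
#'
#' Pairwise complete-case Pearson correlations over the numeric trait columns
#' of a species trait table, with two-sided p-values from the t distribution
#' on `n - 2` df. No multiple-testing correction is applied; the significance
#' flags mirror raw alpha = 0.05 reporting. A constant trait (or a pair with
#' fewer than 3 complete cases) yields `NA` with the reason recorded.
#'
#' @param table data.frame of species x traits (non-numeric columns such as
#'   `species` are ignored).
#' @param traits Optional character vector restricting/ordering the traits.
#' @param alpha Significance level for the flag matrix.
#' @return list with matrices `r`, `p`, `n` (complete cases), logical
#'   `significant`, and a character matrix `reason` for NA cells.
#' @export
pearson_matrix <- function(table, traits = NULL, alpha = 0.05) {
  x <- table[, vapply(table, is.numeric, logical(1)), drop = FALSE]
  if (!is.null(traits)) x <- x[, traits, drop = FALSE]
  p <- ncol(x)
  nm <- names(x)
  r <- pv <- nn <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  reason <- matrix(NA_character_, p, p, dimnames = list(nm, nm))
  for (i in seq_len(p)) {
    for (j in seq_len(i)) {
      cc <- stats::complete.cases(x[[i]], x[[j]])
      n <- sum(cc)
      nn[i, j] <- nn[j, i] <- n
      if (n < 3L) {
        reason[i, j] <- reason[j, i] <- "fewer than 3 complete cases"
        next
      }
      if (stats::sd(x[[i]][cc]) == 0 || stats::sd(x[[j]][cc]) == 0) {
        reason[i, j] <- reason[j, i] <- "constant trait"
        next
      }
      rij <- stats::cor(x[[i]][cc], x[[j]][cc])
      r[i, j] <- r[j, i] <- rij
      pij <- if (i == j) 0 else {
        tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
        2 * stats::pt(-abs(tt), df = n - 2)
      }
      pv[i, j] <- pv[j, i] <- pij
    }
  }
  list(r = r, p = pv, n = nn, significant = pv < alpha, reason = reason)
}

#' Principal component analysis on the correlation matrix
#'
#' Standardises the traits (z-scores) and runs PCA, i.e. an
#' eigen-decomposition of the trait correlation matrix. Constant traits are
#' dropped with a warning; rows with any missing value are dropped
#' (complete-case).
#'
#' @param table Species trait data.frame.
#' @param traits Optional trait subset.
#' @return list with `loadings` (traits x components), `scores`
#'   (species x components), `variance_fraction` (sums to 1), `sdev`, and
#'   `dropped` (names of constant traits removed).
#' @export
pca_traits <- function(table, traits = NULL) {
  x <- table[, vapply(table, is.numeric, logical(1)), drop = FALSE]
  if (!is.null(traits)) x <- x[, traits, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  sds <- vapply(x, stats::sd, numeric(1))
  dropped <- names(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant trait(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  if (nrow(x) < ncol(x) + 1L) {
    stop("need at least traits + 1 complete cases", call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  list(loadings = fit$rotation, scores = fit$x,
       variance_fraction = fit$sdev^2 / sum(fit$sdev^2),
       sdev = fit$sdev, dropped = dropped)
}

#' Flag (and optionally trim) extreme trait values
#'
#' No automatic outlier removal is applied anywhere in the package; this
#' helper reports values more than `z_cut` standard deviations from their
#' trait mean, and — only when `trim = TRUE` — replaces them with `NA` so
#' downstream complete-case analyses drop them explicitly.
#'
#' @param table Species trait data.frame (a `species` column, if present,
#'   labels the report).
#' @param traits Optional trait subset.
#' @param z_cut Flagging threshold in SD units (default 3).
#' @param trim Replace flagged values with `NA` (default `FALSE`).
#' @return list with `table` (unchanged unless `trim`) and `flagged`
#'   (data.frame: `species`, `trait`, `value`, `z`).
#' @export
flag_outliers <- function(table, traits = NULL, z_cut = 3, trim = FALSE) {
  num <- vapply(table, is.numeric, logical(1))
  cols <- names(table)[num]
  if (!is.null(traits)) cols <- intersect(cols, traits)
  sp <- if ("species" %in% names(table)) table$species
        else as.character(seq_len(nrow(table)))
  flagged <- list()
  for (cl in cols) {
    z <- (table[[cl]] - mean(table[[cl]], na.rm = TRUE)) /
      stats::sd(table[[cl]], na.rm = TRUE)
    hit <- which(abs(z) > z_cut)
    if (length(hit)) {
      flagged[[cl]] <- data.frame(species = sp[hit], trait = cl,
                                  value = table[[cl]][hit], z = z[hit],
                                  stringsAsFactors = FALSE)
      if (trim) table[[cl]][hit] <- NA_real_
    }
  }
  list(table = table,
       flagged = if (length(flagged)) {
         do.call(rbind, c(flagged, make.row.names = FALSE))
       } else {
         data.frame(species = character(), trait = character(),
                    value = numeric(), z = numeric())
       })
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor `j` on the remaining
#' predictors. Perfect collinearity is reported as `Inf`. The companion
#' screen flags predictors at the conventional `VIF >= 5` cut used before
#' multimodel selection.
#'
#' @param table Species trait data.frame.
#' @param predictors Character vector of predictor columns (>= 2).
#' @param threshold Screening threshold (default 5).
#' @return data.frame with `predictor`, `vif`, `flagged`.
#' @export
vif_screen <- function(table, predictors, threshold = 5) {
  stopifnot(length(predictors) >= 2L,
            all(predictors %in% names(table)))
  x <- table[, predictors, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < length(predictors) + 2L) {
    stop("need at least predictors + 2 complete cases", call. = FALSE)
  }
  vifs <- vapply(predictors, function(p) {
    fit <- stats::lm(stats::reformulate(setdiff(predictors, p), p), data = x)
    r2 <- summary(fit)$r.squared
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = predictors, vif = unname(vifs),
             flagged = unname(vifs) >= threshold, stringsAsFactors = FALSE)
}
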