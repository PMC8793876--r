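#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Standard one-way ANOVA (F, df, p) followed by Tukey-Kramer pairwise
#' comparisons on the studentized range, with a compact letter display:
#' groups that share no letter differ at the chosen alpha. Groups with a
#' single observation cannot contribute a within-group variance and are
#' excluded with a warning.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (coerced), same length.
#' @param alpha Significance level for letters (default 0.05).
#' @return list with `F`, `df` (length-2), `p`, `tukey` (data.frame of
#'   pairwise differences and adjusted p), `letters` (named character
#'   vector), and `excluded` group names.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  cc <- is.finite(values) & !is.na(groups)
  values <- values[cc]; groups <- droplevels(groups[cc])
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2L]
  if (length(excluded)) {
    warning("excluding single-observation group(s): ",
            paste(excluded, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% excluded)
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (stats::var(values) == 0) {
    # degenerate but well-defined: no variation, no differences anywhere
    return(list(F = 0, df = c(nlevels(groups) - 1L,
                              length(values) - nlevels(groups)),
                p = 1,
                tukey = data.frame(group1 = character(), group2 = character(),
                                   diff = numeric(), p_adj = numeric()),
                letters = stats::setNames(rep("A", nlevels(groups)),
                                          levels(groups)),
                excluded = excluded))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L],
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE, row.names = NULL)
  letters <- cld_letters(levels(groups), tukey, alpha)
  list(F = an$`F value`[1L], df = c(an$Df[1L], an$Df[2L]),
       p = an$`Pr(>F)`[1L], tukey = tukey, letters = letters,
       excluded = excluded)
}

# Compact letter display by greedy insert-absorb: start with one letter
# covering everything; for each significant pair sharing a letter, split
# that letter into two copies excluding one member each, then absorb
# redundant letters. Ties broken by the supplied group order.
cld_letters <- function(group_names, tukey, alpha = 0.05) {
  sig <- tukey[tukey$p_adj < alpha, , drop = FALSE]
  sets <- list(group_names)                      # letters = sets of groups
  for (k in seq_len(nrow(sig))) {
    g1 <- sig$group1[k]; g2 <- sig$group2[k]
    shared <- which(vapply(sets, function(s) g1 %in% s && g2 %in% s,
                           logical(1)))
    for (i in rev(shared)) {
      s <- sets[[i]]
      sets[[i]] <- NULL
      sets <- c(sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
    }
    # absorb: drop sets contained in another
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i != j && keep[j] &&
            all(sets[[i]] %in% sets[[j]]) &&
            (length(sets[[i]]) < length(sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- sets[keep]
  }
  # stable ordering: by first member's position in group_names
  ord <- order(vapply(sets, function(s) min(match(s, group_names)),
                      numeric(1)))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(sets)) {
    lab <- LETTERS[i]
    out[sets[[i]]] <- paste0(out[sets[[i]]], lab)
  }
  out
}
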