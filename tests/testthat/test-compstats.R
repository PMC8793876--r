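test_that("pearson_matrix matches the covariance formula and flags", {
  set.seed(11)
  tab <- data.frame(species = paste0("s", 1:28),
                    a = rnorm(28), b = rnorm(28))
  tab$c <- -tab$a
  m <- pearson_matrix(tab)
  expect_equal(diag(m$r), c(a = 1, b = 1, c = 1))
  expect_equal(m$r["a", "c"], -1)
  # brute-force covariance formula
  x <- tab$a; y <- tab$b
  r_bf <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(m$r["a", "b"], r_bf, tolerance = 1e-12)
  expect_equal(m$p["a", "b"],
               cor.test(x, y)$p.value, tolerance = 1e-12)
  # constant trait
  tab$k <- 1
  m2 <- pearson_matrix(tab)
  expect_true(is.na(m2$r["k", "a"]))
  expect_match(m2$reason["k", "a"], "constant")
})

test_that("pca_traits is the eigen-decomposition of the correlation matrix", {
  set.seed(12)
  tab <- data.frame(matrix(rnorm(28 * 5), 28))
  res <- pca_traits(tab)
  expect_equal(sum(res$variance_fraction), 1, tolerance = 1e-12)
  eig <- eigen(cor(tab), symmetric = TRUE)
  expect_equal(res$variance_fraction, eig$values / sum(eig$values),
               tolerance = 1e-10)
  expect_equal(abs(unname(res$loadings)), abs(eig$vectors), tolerance = 1e-10)
  # duplicated trait: first axis explains everything for a 2-trait table
  two <- data.frame(u = tab$X1, v = 3 * tab$X1 + 2)
  expect_equal(pca_traits(two)$variance_fraction[1], 1, tolerance = 1e-12)
  # constant dropped
  tab$z <- 5
  expect_warning(res2 <- pca_traits(tab), "constant")
  expect_equal(res2$dropped, "z")
})

test_that("vif_screen matches brute-force R^2 inversion", {
  # orthogonal polynomial basis: zero-mean, exactly orthogonal columns
  tab <- as.data.frame(unclass(stats::poly(1:40, 3)))
  names(tab) <- c("p1", "p2", "p3")
  v <- vif_screen(tab, c("p1", "p2", "p3"))
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-10)
  expect_false(any(v$flagged))
  tab$p4 <- tab$p1
  # perfect collinearity: lm warns about the perfect fit, VIF must be Inf
  v2 <- suppressWarnings(vif_screen(tab, c("p1", "p2", "p4")))
  expect_true(all(is.infinite(v2$vif[c(1, 3)])))
  # brute force on a correlated table
  set.seed(14)
  tab3 <- data.frame(a = rnorm(30))
  tab3$b <- 0.7 * tab3$a + rnorm(30, sd = 0.5)
  tab3$c <- rnorm(30)
  v3 <- vif_screen(tab3, c("a", "b", "c"))
  r2 <- summary(lm(a ~ b + c, tab3))$r.squared
  expect_equal(v3$vif[v3$predictor == "a"], 1 / (1 - r2), tolerance = 1e-10)
})

test_that("anova_tukey: F = t^2 for two groups; degenerate data give F = 0", {
  set.seed(15)
  g <- rep(c("a", "b"), each = 8)
  x <- rnorm(16) + (g == "b") * 0.8
  res <- anova_tukey(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)$statistic
  expect_equal(res$F, unname(tt^2), tolerance = 1e-10)
  expect_equal(res$df, c(1, 14))

  res0 <- anova_tukey(rep(3, 12), rep(c("a", "b", "c"), 4))
  expect_equal(res0$F, 0)
  expect_equal(unname(res0$letters), rep("A", 3))
})

test_that("a clearly shifted group earns its own letter", {
  set.seed(16)
  g <- rep(c("a", "b", "c"), each = 10)
  x <- rnorm(30, sd = 0.3) + ifelse(g == "c", 5, 0)
  res <- anova_tukey(x, g)
  expect_true(res$p < 0.001)
  expect_equal(res$letters[["a"]], res$letters[["b"]])
  expect_false(res$letters[["c"]] == res$letters[["a"]])
})

test_that("letters are consistent with pairwise significance", {
  set.seed(17)
  for (rep in 1:10) {
    g <- rep(letters[1:4], each = 6)
    x <- rnorm(24) + rep(runif(4, 0, 3), each = 6)
    res <- anova_tukey(x, g)
    share <- function(u, v) {
      any(strsplit(res$letters[[u]], "")[[1]] %in%
            strsplit(res$letters[[v]], "")[[1]])
    }
    for (k in seq_len(nrow(res$tukey))) {
      pair <- res$tukey[k, ]
      if (pair$p_adj < 0.05) {
        expect_false(share(pair$group1, pair$group2))
      } else {
        expect_true(share(pair$group1, pair$group2))
      }
    }
  }
})

test_that("single-observation groups are excluded with a warning", {
  expect_warning(res <- anova_tukey(c(1, 2, 3, 4, 9),
                                    c("a", "a", "b", "b", "c")),
                 "single-observation")
  expect_equal(res$excluded, "c")
})

test_that("outliers are flagged, and trimmed only on request", {
  set.seed(18)
  tab <- data.frame(species = paste0("s", 1:20), a = rnorm(20), b = rnorm(20))
  tab$a[3] <- 50
  res <- flag_outliers(tab)
  expect_equal(res$flagged$species, "s3")
  expect_equal(res$flagged$trait, "a")
  expect_identical(res$table, tab)            # untouched without trim
  trimmed <- flag_outliers(tab, trim = TRUE)
  expect_true(is.na(trimmed$table$a[3]))
  expect_false(anyNA(trimmed$table$b))
  clean <- flag_outliers(data.frame(x = rnorm(10)))
  expect_equal(nrow(clean$flagged), 0L)
})

test_that("AICc enumeration matches brute force exactly for p = 3", {
  tab <- planted_table(seed = 21)
  sel <- aicc_model_selection(tab, "y", c("x1", "x2", "x3"))
  bf <- brute_aicc(tab, "y", c("x1", "x2", "x3"))
  expect_equal(nrow(sel$models), 8L)
  merged <- merge(sel$models[, c("model", "AICc")], bf, by = "model")
  expect_equal(merged$AICc.x, merged$AICc.y, tolerance = 1e-10)
  expect_equal(sum(sel$models$weight), 1, tolerance = 1e-12)
  expect_equal(sel$models$delta[1], 0)
  expect_true(sel$models$selected[1])
  expect_true(all(sel$averaged$importance >= 0 &
                    sel$averaged$importance <= 1))
})

test_that("single-candidate selection yields two models with unit weight", {
  tab <- planted_table(seed = 22)
  sel <- aicc_model_selection(tab, "y", "x1")
  expect_equal(nrow(sel$models), 2L)
  expect_equal(sum(sel$models$weight), 1, tolerance = 1e-12)
})

test_that("a planted predictor dominates importance", {
  hits <- vapply(1:20, function(s) {
    sel <- aicc_model_selection(planted_table(seed = 100 + s), "y",
                                c("x1", "x2", "x3"))
    imp <- setNames(sel$averaged$importance, sel$averaged$variable)
    imp["x1"] > max(imp[c("x2", "x3")])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
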