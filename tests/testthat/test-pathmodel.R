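test_that("path_spec parses equations and rejects cycles", {
  sp <- path_spec(c("VE ~ TO + MF", "y ~ VE"))
  expect_equal(sp$endogenous, c("VE", "y"))
  expect_setequal(sp$exogenous, c("TO", "MF"))
  expect_error(path_spec(c("a ~ b", "b ~ a")), "cyclic")
  expect_error(path_spec("nonsense"), "bad equation")
})

test_that("a saturated model reproduces the sample covariance exactly", {
  set.seed(71)
  n <- 60
  tab <- data.frame(a = rnorm(n))
  tab$b <- 0.5 * tab$a + rnorm(n)
  tab$c <- 0.3 * tab$a - 0.4 * tab$b + rnorm(n)
  fit <- fit_path_model(tab, path_spec(c("b ~ a", "c ~ a + b")))
  expect_equal(fit$chisq, 0, tolerance = 1e-8)
  expect_equal(fit$df, 0)
  expect_equal(fit$Sigma, fit$S, tolerance = 1e-10)
})

test_that("a single standardized equation returns the Pearson r", {
  set.seed(72)
  tab <- data.frame(x = rnorm(40))
  tab$y <- 0.6 * tab$x + rnorm(40)
  fit <- fit_path_model(tab, path_spec("y ~ x"))
  expect_equal(fit$coefficients$coefficient, cor(tab$x, tab$y),
               tolerance = 1e-12)
})

test_that("known recursive coefficients are recovered at n = 1000", {
  set.seed(73)
  n <- 1000
  TO <- rnorm(n); MF <- rnorm(n)
  VE <- 0.8 * TO + 0.3 * MF + rnorm(n, sd = sqrt(1 - 0.8^2 - 0.3^2))
  P50 <- 0.6 * VE + rnorm(n, sd = sqrt(1 - 0.6^2))
  tab <- data.frame(TO, MF, VE, P50)
  fit <- fit_path_model(tab, path_spec(c("VE ~ TO + MF", "P50 ~ VE")))
  co <- fit$coefficients
  expect_equal(co$coefficient[co$outcome == "VE" & co$predictor == "TO"],
               0.8, tolerance = 0.05)
  expect_equal(co$coefficient[co$outcome == "VE" & co$predictor == "MF"],
               0.3, tolerance = 0.05)
  expect_equal(co$coefficient[co$outcome == "P50"], 0.6, tolerance = 0.05)
  expect_gte(fit$df, 1)
  expect_gte(fit$p, 0.0)
})

test_that("effect decomposition follows the path-tracing rule", {
  set.seed(74)
  n <- 500
  x <- rnorm(n)
  m <- 0.7 * x + rnorm(n, sd = 0.5)
  y <- 0.5 * m + rnorm(n, sd = 0.5)
  fit <- fit_path_model(data.frame(x, m, y),
                        path_spec(c("m ~ x", "y ~ m")))
  eff <- effects_decomposition(fit, "y")
  a <- fit$B["m", "x"]; b <- fit$B["y", "m"]
  xrow <- eff[eff$variable == "x", ]
  expect_equal(xrow$direct, 0)
  expect_equal(xrow$indirect, a * b, tolerance = 1e-12)
  expect_equal(xrow$total, a * b, tolerance = 1e-12)
  # two parallel mediators
  m2 <- 0.4 * x + rnorm(n, sd = 0.5)
  y2 <- 0.5 * m + 0.3 * m2 + rnorm(n, sd = 0.5)
  fit2 <- fit_path_model(data.frame(x, m, m2, y = y2),
                         path_spec(c("m ~ x", "m2 ~ x", "y ~ m + m2")))
  eff2 <- effects_decomposition(fit2, "y")
  expected <- fit2$B["m", "x"] * fit2$B["y", "m"] +
    fit2$B["m2", "x"] * fit2$B["y", "m2"]
  expect_equal(eff2[eff2$variable == "x", "indirect"], expected,
               tolerance = 1e-12)
})

test_that("decomposition matches brute-force path enumeration on random DAGs", {
  set.seed(75)
  for (rep in 1:20) {
    p <- sample(4:6, 1)
    vars <- paste0("v", seq_len(p))
    # random upper-triangular DAG over a random variable order
    B <- matrix(0, p, p, dimnames = list(vars, vars))
    for (i in 2:p) {
      for (j in 1:(i - 1)) {
        if (runif(1) < 0.6) B[i, j] <- runif(1, -0.8, 0.8)
      }
    }
    fit <- structure(list(B = B), class = "path_fit")
    out <- vars[p]
    eff <- effects_decomposition(fit, out)
    bf <- brute_path_effects(B, out)
    expect_equal(setNames(eff$total, eff$variable), bf, tolerance = 1e-12)
  }
})

test_that("total effect of the sole exogenous driver equals its correlation", {
  set.seed(76)
  n <- 4000
  x <- rnorm(n)
  m <- 0.6 * x + rnorm(n, sd = 0.8)
  y <- 0.5 * m + 0.3 * x + rnorm(n, sd = 0.6)
  tab <- data.frame(x, m, y)
  fit <- fit_path_model(tab, path_spec(c("m ~ x", "y ~ x + m")))
  eff <- effects_decomposition(fit, "y")
  expect_equal(eff[eff$variable == "x", "total"], cor(tab$x, tab$y),
               tolerance = 1e-8)
})

test_that("dropping an edge never improves chi-square", {
  set.seed(77)
  n <- 200
  x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.4 * m + 0.3 * x + rnorm(n)
  tab <- data.frame(x, m, y)
  full <- fit_path_model(tab, path_spec(c("m ~ x", "y ~ x + m")))
  reduced <- fit_path_model(tab, path_spec(c("m ~ x", "y ~ m")))
  expect_gte(reduced$chisq, full$chisq - 1e-10)
})

test_that("presets are valid DAG specs", {
  expect_s3_class(path_preset("p50"), "path_spec")
  expect_s3_class(path_preset("ks"), "path_spec")
  expect_true("VE" %in% path_preset("p50")$endogenous)
})
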