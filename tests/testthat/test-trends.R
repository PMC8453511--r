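# brute-force oracles: direct double loops over pairs
mk_s_brute <- function(y) {
  s <- 0
  for (i in seq_along(y)) for (j in seq_along(y)) {
    if (j > i) s <- s + sign(y[j] - y[i])
  }
  s
}
sen_brute <- function(x, y) {
  sl <- c()
  for (i in seq_along(x)) for (j in seq_along(x)) {
    if (j > i && x[j] != x[i]) sl <- c(sl, (y[j] - y[i]) / (x[j] - x[i]))
  }
  slope <- median(sl)
  list(slope = slope, intercept = median(y - slope * x))
}

test_that("Mann-Kendall handles perfect trends and total ties", {
  expect_equal(mann_kendall(1:8)$tau, 1)
  expect_equal(mann_kendall(8:1)$tau, -1)
  tied <- mann_kendall(rep(3, 6))
  expect_true(tied$all_tied)
  expect_equal(tied$tau, 0)
  expect_equal(tied$p_value, 1)
  expect_error(mann_kendall(1:3), "at least 4")
})

test_that("Mann-Kendall S matches exhaustive pair enumeration", {
  set.seed(37)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    y <- sample(round(rnorm(n, 0, 2), 1))   # rounding induces ties
    expect_equal(mann_kendall(y)$s, mk_s_brute(y))
  }
})

test_that("Mann-Kendall tau and p agree with the Kendall correlation test", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(6:14, 1)
    y <- rnorm(n)
    mk <- mann_kendall(y)
    ct <- suppressWarnings(cor.test(seq_along(y), y, method = "kendall"))
    expect_equal(mk$tau, unname(ct$estimate), tolerance = 1e-12)
  }
})

test_that("Sen regression is exact on linear data and matches brute force", {
  s <- sen_regression(1:10, 2 * (1:10) + 1)
  expect_equal(s$slope, 2)
  expect_equal(s$intercept, 1)
  flat <- sen_regression(1:6, rep(4.2, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 4.2)
  expect_error(sen_regression(rep(2, 5), rnorm(5)), "identical")

  set.seed(47)
  for (i in 1:30) {
    x <- sample(1:20, 10)
    y <- rnorm(10)
    got <- sen_regression(x, y)
    want <- sen_brute(x, y)
    expect_equal(got$slope, want$slope)
    expect_equal(got$intercept, want$intercept)
  }
})

test_that("MK/Sen are shift-invariant and scale-equivariant in y", {
  set.seed(53)
  x <- 1:9; y <- rnorm(9)
  expect_equal(mann_kendall(y + 5)$tau, mann_kendall(y)$tau)
  expect_equal(mann_kendall(-y)$tau, -mann_kendall(y)$tau)
  s0 <- sen_regression(x, y)
  s_shift <- sen_regression(x, y + 5)
  expect_equal(s_shift$slope, s0$slope)
  expect_equal(s_shift$intercept, s0$intercept + 5)
  s_scale <- sen_regression(x, 3 * y)
  expect_equal(s_scale$slope, 3 * s0$slope)
})

test_that("mixed trends recover deterministic and collapsed designs", {
  ages <- rep(c(8, 12, 16, 20, 24, 28, 32), each = 4)
  plots <- rep(paste0("P", 1:7), each = 4)
  suppressWarnings(tr <- mixed_trend(0.5 * ages, ages, plots))
  expect_equal(tr$slope, 0.5, tolerance = 1e-8)
  expect_equal(tr$association, 1, tolerance = 1e-6)

  # balanced design with zero between-plot variance collapses to pooled OLS
  set.seed(59)
  y <- 2 + 0.3 * ages + rnorm(length(ages), 0, 0.5)
  suppressWarnings(trm <- mixed_trend(y, ages, plots))
  ols <- coef(lm(y ~ ages))[["ages"]]
  expect_equal(trm$slope, ols, tolerance = 1e-5)
})

test_that("age-independent responses give near-zero slope on average", {
  set.seed(61)
  ages <- rep(seq(8, 32, length.out = 10), each = 4)
  plots <- rep(paste0("P", 1:10), each = 4)
  slopes <- replicate(200, {
    y <- rnorm(length(ages))
    suppressWarnings(mixed_trend(y, ages, plots)$slope)
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes)), 2 * se + 1e-3)
})

test_that("assumption checks pass clean residuals and catch violations", {
  set.seed(67)
  ages <- runif(100, 8, 32)
  ok <- check_assumptions(rnorm(100), ages)
  expect_true(ok$pass)

  het <- check_assumptions(rnorm(100, 0, ages^2 / 100), ages)
  expect_false(het$homoscedastic)

  fails <- replicate(200, {
    !check_assumptions(rt(100, df = 2), runif(100, 8, 32))$normal
  })
  expect_gte(mean(fails), 0.9)
  expect_error(check_assumptions(rnorm(2), c(1, 2)), "n < 3")
})

test_that("trend_with_age honours the fallback policy", {
  set.seed(71)
  ages <- rep(seq(8, 32, length.out = 8), each = 4)
  plots <- rep(paste0("P", 1:8), each = 4)
  y <- 1 + 0.2 * ages + rnorm(length(ages), 0, 0.4)
  expect_equal(trend_with_age(y, ages, plots, "mk")$method,
               "mann_kendall_sen")
  suppressWarnings(
    expect_equal(trend_with_age(y, ages, plots, "lmm")$method,
                 "mixed_linear"))
  suppressWarnings(tr <- trend_with_age(y, ages, plots, "auto"))
  expect_true(tr$method %in% c("mixed_linear", "mann_kendall_sen"))
  expect_gt(tr$slope, 0)
})

test_that("predictor selection follows the strongest-then-least-related rule", {
  cl <- c(A = 0.9, B = 0.5, C = 0.2)
  cb <- matrix(c(1, 0.8, 0.1, 0.8, 1, 0.4, 0.1, 0.4, 1), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(select_predictors(cl, cb), c("A", "C"))

  two <- select_predictors(c(A = 0.3, B = 0.9), cb[1:2, 1:2])
  expect_equal(two, c("B", "A"))

  # tie on the first step: alphabetical order wins
  cl_tie <- c(B = 0.7, A = 0.7, C = 0.1)
  expect_equal(select_predictors(cl_tie, cb[c("B", "A", "C"), c("B", "A", "C")])[1],
               "A")
  expect_error(select_predictors(c(A = 1), cb), "2 named")
})

test_that("path models recover identity and null edges", {
  set.seed(73)
  n <- 100
  age <- runif(n, 8, 32)
  s1 <- 0.5 * age + rnorm(n)
  s2 <- rnorm(n)
  pr <- suppressWarnings(path_model(age, s1, s2, light = s1))
  b_s1 <- pr$edges$coefficient[pr$edges$from == "s1"]
  expect_equal(b_s1, 1, tolerance = 1e-8)
  expect_equal(pr$r_squared, 1, tolerance = 1e-8)

  # independent response: both structure betas near zero over replicates
  betas <- replicate(100, {
    l <- rnorm(n)
    p <- path_model(age, s1, s2, l)
    p$edges$coefficient[p$edges$to == "light"]
  })
  expect_lt(abs(mean(betas[1, ])), 2 * sd(betas[1, ]) / sqrt(100) + 0.02)
  expect_lt(abs(mean(betas[2, ])), 2 * sd(betas[2, ]) / sqrt(100) + 0.02)

  expect_error(path_model(age, s1, s1 * 1.0000001, s2), "collinear")
  expect_error(path_model(age, s1, s2, abs(s2) - 10, log_transform = TRUE),
               "positive")
})

test_that("standardized path coefficients ignore affine rescaling", {
  set.seed(79)
  n <- 60
  age <- runif(n, 8, 32)
  s1 <- 0.4 * age + rnorm(n)
  s2 <- -0.2 * age + rnorm(n)
  light <- 0.5 * s1 - 0.3 * s2 + rnorm(n)
  p1 <- path_model(age, s1, s2, light)
  p2 <- path_model(10 * age - 3, 0.2 * s1 + 7, 5 * s2 - 1, 100 * light + 42)
  expect_equal(p1$edges$coefficient, p2$edges$coefficient, tolerance = 1e-10)
})
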