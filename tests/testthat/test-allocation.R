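test_that("module mass fractions sum covered genes per condition", {
  fr <- matrix(c(0.01, 0.02, 0.97, 0.03, 0.01, 0.96), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), c("a_r1", "b_r1")))
  md <- data.frame(sample_id = c("a_r1", "b_r1"),
                   condition_id = c("a", "b"))
  y <- module_mass_fraction(c("g1", "g2"), fr, md)
  expect_equal(unname(y), c(0.03, 0.04))
  whole <- module_mass_fraction(c("g1", "g2", "g3"), fr, md)
  expect_equal(unname(whole), c(1, 1))
  expect_message(expect_null(module_mass_fraction("gX", fr, md)), "skipped")
})

test_that("each family recovers its exact generating curve", {
  x <- seq(-3, 3, length.out = 21)  # grid contains the true breakpoint 0
  lin <- fit_family(x, 2 * x + 1, "linear")
  expect_equal(unname(lin$parameters), c(1, 2), tolerance = 1e-10)
  expect_equal(lin$r2, 1, tolerance = 1e-12)

  yb <- ifelse(x > 0, x, 0) + 0.5
  br <- fit_family(x, yb, "broken_line")
  expect_equal(unname(br$parameters["breakpoint"]), 0,
               tolerance = diff(range(x)) / 20 + 1e-9)
  expect_equal(unname(br$parameters[c("slope_left", "slope_right")]),
               c(0, 1), tolerance = 1e-6)

  ye <- 0.1 * exp(0.5 * x)
  ex <- fit_family(x, ye, "exponential")
  expect_equal(unname(ex$parameters["rate"]), 0.5, tolerance = 1e-4)
})

test_that("broken-line fit equals the exhaustive grid oracle in SSE", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(10:30, 1)
    x <- rnorm(n)
    y <- 0.3 + 0.2 * x + 0.7 * pmax(x - median(x), 0) + rnorm(n, 0, 0.1)
    fit <- fit_family(x, y, "broken_line")
    sse_fit <- sum((y - fit$fitted) ^ 2)
    cand <- sort(unique(x))
    cand <- cand[vapply(cand, function(b) sum(x < b) >= 2 && sum(x > b) >= 2,
                        TRUE)]
    sse_oracle <- min(vapply(cand, function(b) {
      sum(resid(lm(y ~ x + pmax(x - b, 0))) ^ 2)
    }, 0))
    expect_equal(sse_fit, sse_oracle, tolerance = 1e-8)
  }
})

test_that("LOOCV selection equals an explicit leave-one-out loop", {
  set.seed(33)
  x <- rnorm(15)
  y <- 0.05 + 0.01 * x + rnorm(15, 0, 0.004)
  fit <- select_model_loocv(x, y, rule = "min")
  for (fam in c("linear", "exponential", "broken_line")) {
    preds <- vapply(seq_along(x), function(i) {
      fit_family(x[-i], y[-i], fam)$predict(x[i])
    }, 0)
    expect_equal(fit$loocv_mae[[fam]], mean(abs(preds - y)),
                 tolerance = 1e-10)
  }
  expect_equal(fit$family, names(which.min(fit$loocv_mae)))
})

test_that("noiseless linear data give a strong linear model", {
  x <- seq(-2, 2, length.out = 12)
  fit <- select_model_loocv(x, 0.1 + 0.02 * x)
  expect_equal(fit$family, "linear")
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-9)
  expect_equal(fit$strength, "strong")
  expect_equal(unname(coef(fit)), c(0.1, 0.02), tolerance = 1e-9)
  expect_equal(predict(fit, 10), 0.3, tolerance = 1e-9)
  expect_equal(unname(residuals(fit)), rep(0, 12), tolerance = 1e-9)

  # appending more noiseless conditions never demotes the model
  x2 <- c(x, seq(2.1, 4, length.out = 10))
  fit2 <- select_model_loocv(x2, 0.1 + 0.02 * x2)
  expect_equal(fit2$strength, "strong")
  expect_gte(fit2$adjusted_r2, fit$adjusted_r2 - 1e-9)
})

test_that("response independent of activity is labelled weak", {
  weak <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(30)
    y <- abs(rnorm(30, 0.05, 0.01))
    suppressMessages(select_model_loocv(x, y))$strength == "weak"
  }, TRUE)
  expect_gte(mean(weak), 0.95)
})

test_that("normalized errors follow the |pred - test| / avg formula", {
  expect_equal(normalized_cv_error(c(1, 2), c(1, 2), 0.5), c(0, 0))
  expect_equal(normalized_cv_error(0.02, 0.01, 0.01), 1)
  set.seed(34)
  yp <- runif(5); yt <- runif(5); ya <- 0.3
  loop <- vapply(1:5, function(i) abs(yp[i] - yt[i]) / ya, 0)
  expect_equal(normalized_cv_error(yp, yt, ya), loop, tolerance = 1e-12)
  expect_error(normalized_cv_error(1, 1, 0), "positive")
})

test_that("holdout sweep sizes tests by round-half-up and stays stable", {
  x <- seq(-3, 3, length.out = 57)
  y <- 0.08 + 0.015 * x
  sw <- holdout_sweep(x, y, n_repeats = 2, seed = 5)
  expect_equal(unique(sw$n_test[sw$fraction == 0.10]), 6)   # 5.7 -> 6
  expect_equal(unique(sw$n_test[sw$fraction == 0.25]), 14)  # 14.25 -> 14
  expect_true(all(sw$family == "linear"))
  expect_true(all(sw$test_mae < 1e-9))
  # same seed reproduces the sweep exactly
  expect_identical(sw, holdout_sweep(x, y, n_repeats = 2, seed = 5))
})

test_that("sequential allocation consumes each gene exactly once", {
  set.seed(35)
  n_s <- 12
  fr <- matrix(rlnorm(8 * n_s, -2, 0.1), 8, n_s,
               dimnames = list(paste0("g", 1:8), paste0("s", 1:n_s)))
  fr <- sweep(fr, 2, colSums(fr), "/")
  mk_fit <- function(name, members, adj, strength) {
    structure(list(name = name, members = members, adjusted_r2 = adj,
                   strength = strength, family = "linear",
                   loocv_mae = c(linear = 0.01)), class = "allocation_fit")
  }
  fits <- structure(list(
    A = mk_fit("A", c("g1", "g2", "g3"), 0.9, "strong"),
    B = mk_fit("B", c("g3", "g4"), 0.5, "strong"),   # shares g3 with A
    C = mk_fit("C", c("g5"), 0.1, "weak")), class = "allocation_set")
  summ <- summarize_allocation(fits, fr)
  expect_equal(summ$gene_count[summ$name == "A"], 3L)
  expect_equal(summ$gene_count[summ$name == "B"], 1L)  # g3 already used
  expect_equal(sum(summ$gene_count), 8L)
  expect_equal(sum(summ$mean_mass_share), 1, tolerance = 1e-9)

  # per-sample shares of the groups close to 1 before averaging
  groups <- list(A = c("g1", "g2", "g3"), B = "g4", C = "g5",
                 rest = paste0("g", 6:8))
  per_sample <- Reduce(`+`, lapply(groups, function(g) {
    colSums(fr[g, , drop = FALSE])
  }))
  expect_equal(unname(per_sample), rep(1, n_s), tolerance = 1e-9)
})

test_that("a module covering the whole proteome takes the full budget", {
  fr <- matrix(rep(0.25, 16), 4, 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  fit <- structure(list(name = "all", members = paste0("g", 1:4),
                        adjusted_r2 = 0.8, strength = "strong",
                        family = "linear", loocv_mae = c(linear = 0)),
                   class = "allocation_fit")
  summ <- summarize_allocation(structure(list(all = fit),
                                         class = "allocation_set"), fr)
  expect_equal(summ$mean_mass_share[summ$name == "all"], 1)
  expect_equal(summ$gene_count[summ$group == "invariant"], 0L)
})
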