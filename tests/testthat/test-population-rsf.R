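test_that("buffer radius from home-range area follows circle algebra", {
  expect_equal(buffer_radius_from_area(pi)$radius_m, 1000)
  expect_equal(buffer_radius_from_area(4 * pi)$radius_m, 2000)
  b <- buffer_radius_from_area(99.7)
  expect_equal(b$radius_m, 5633, tolerance = 1e-4)
  expect_equal(b$rounded_m, 5600)
  expect_error(buffer_radius_from_area(0), "positive")
})

test_that("pseudo-absences respect the ratio, the buffer and the seed", {
  g <- scape_grid(matrix(0, 100, 100), 30)
  set.seed(41)
  pres <- scape_points(id = paste0("p", 1:25),
                       x = runif(25, 200, 2800), y = runif(25, 200, 2800),
                       role = "presence")
  abs <- generate_pseudo_absences(pres, g, ratio = 4, buffer_m = 120,
                                  seed = 2)
  expect_equal(nrow(abs), 100L)
  dmin <- apply(outer(abs$x, pres$x, "-")^2 + outer(abs$y, pres$y, "-")^2,
                1, min)
  expect_true(all(sqrt(dmin) >= 120))
  abs2 <- generate_pseudo_absences(pres, g, ratio = 4, buffer_m = 120,
                                   seed = 2)
  expect_identical(abs$x, abs2$x)
  # an impossible buffer exhausts the iteration cap with a clear error
  expect_error(generate_pseudo_absences(pres, g, ratio = 4, buffer_m = 5000,
                                        seed = 2, max_iter = 5),
               "attained")
})

test_that("logistic fits match closed forms", {
  # null model: LL = n1 log p + n0 log(1-p)
  d <- data.frame(use = c(rep(1, 30), rep(0, 70)))
  f0 <- fit_logistic(d, character(0))
  expect_equal(f0$LL, 30 * log(0.3) + 70 * log(0.7), tolerance = 1e-8)
  expect_equal(f0$k, 1L)

  # single binary covariate: slope = 2x2-table log odds ratio
  d2 <- data.frame(
    use = c(rep(1, 40), rep(0, 60)),
    z = c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40)))
  f1 <- fit_logistic(d2, "z")
  lor <- log((30 * 40) / (10 * 20))
  expect_equal(unname(f1$coef["z"]), lor, tolerance = 1e-6)

  # rank deficiency and separation are errors
  d3 <- data.frame(use = rep(c(0, 1), 20), a = rnorm(40))
  d3$b <- 2 * d3$a
  expect_error(fit_logistic(d3, c("a", "b")), "rank-deficient")
  d4 <- data.frame(use = rep(c(0, 1), each = 20),
                   s = c(rnorm(20, -5), rnorm(20, 5)))
  expect_error(fit_logistic(d4, "s"), "separation")
})

test_that("simulated data recover the generating coefficients at nominal rate", {
  set.seed(42)
  hits <- 0
  for (r in 1:200) {
    x <- rnorm(400)
    p <- plogis(-0.5 + 0.8 * x)
    d <- data.frame(use = rbinom(400, 1, p), x = x)
    f <- fit_logistic(d, "x")
    se <- sqrt(diag(vcov(f$fit)))["x"]
    hits <- hits + (abs(f$coef["x"] - 0.8) <= 1.96 * se)
  }
  expect_gt(hits / 200, 0.90)
  expect_lt(hits / 200, 0.995)
})

test_that("AICc, deltas and Akaike weights behave as an information criterion", {
  # closed form
  expect_equal(aicc(-100, 3, 50), 200 + 6 + 24 / 46)
  expect_error(aicc(-100, 10, 11), "n must exceed")
  # single model takes all the weight
  tab1 <- rank_models(data.frame(LL = -10, k = 2, n = 100))
  expect_equal(tab1$weight, 1)
  # weights always sum to one
  set.seed(43)
  for (i in 1:10) {
    tab <- rank_models(data.frame(LL = -runif(8, 50, 500),
                                  k = sample(1:6, 8, TRUE), n = 1000))
    expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
    expect_equal(tab$delta[1], 0)
    expect_true(all(diff(tab$AICc) >= 0))
  }
  # AICc converges to AIC as n grows
  expect_equal(aicc(-100, 4, 1e6), -2 * -100 + 2 * 4, tolerance = 1e-4)
})

test_that("model averaging renormalizes weights and bounds predictions", {
  w <- small_world(nrow = 40, ncol = 40)
  tm <- names(w$stack$layers)[1:2]
  truth <- truth_model(setNames(c(1, -0.5), tm))
  pres <- generate_presences(w$stack, truth, 150, seed = 5)
  abs <- generate_pseudo_absences(pres, w$landcover, 4, buffer_m = 0,
                                  seed = 5)
  ua <- use_availability_data(pres, abs, w$stack)
  f1 <- fit_logistic(ua, tm[1])
  f2 <- fit_logistic(ua, tm)

  # a single retained model is the identity on its prediction
  one <- model_average_predict(list(f1), w$stack)
  expect_equal(grid_values(one$suitability),
               grid_values(predict(f1, w$stack)), tolerance = 1e-12)

  # average of several models lies within the member envelope
  avg <- model_average_predict(list(f1, f2), w$stack, delta_cutoff = 1e6)
  p1 <- grid_values(predict(f1, w$stack))
  p2 <- grid_values(predict(f2, w$stack))
  H <- grid_values(avg$suitability)
  expect_true(all(H >= pmin(p1, p2) - 1e-12 & H <= pmax(p1, p2) + 1e-12,
                  na.rm = TRUE))
  expect_true(all(H >= 0 & H <= 1, na.rm = TRUE))
})

test_that("AUC equals the pairwise concordance oracle", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  # brute force over the 4 pairs: 3 concordant of 4
  expect_equal(auc_roc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  # random scores against exhaustive pair counting (with ties)
  set.seed(44)
  for (i in 1:10) {
    sc <- sample(seq(0, 1, 0.1), 30, TRUE)
    lb <- rbinom(30, 1, 0.5)
    if (length(unique(lb)) < 2) next
    pos <- sc[lb == 1]; neg <- sc[lb == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_roc(sc, lb), mean(pairs), tolerance = 1e-12)
  }
  expect_error(auc_roc(1:5, rep(1, 5)), "both classes")
})

test_that("repeated cross-validation scores accuracy sensibly", {
  # perfectly separable scores give accuracy 1 in every repeat
  d <- data.frame(use = rep(c(1, 0), each = 60),
                  x = rep(c(3, -3), each = 60) + rnorm(120, 0, 0.1))
  cv <- kfold_accuracy(d, "x", reps = 25, seed = 3)
  expect_true(all(cv$accuracy == 1))

  # shuffled labels fall to the majority-class rate
  set.seed(45)
  d2 <- data.frame(use = sample(rep(c(1, 0), c(40, 160))), x = rnorm(200))
  cv2 <- kfold_accuracy(d2, "x", reps = 200, seed = 3)
  expect_equal(cv2$mean_accuracy, 0.8, tolerance = 0.06)

  cv3 <- kfold_accuracy(d, "x", reps = 5, seed = 9)
  cv4 <- kfold_accuracy(d, "x", reps = 5, seed = 9)
  expect_identical(cv3$accuracy, cv4$accuracy)
  expect_error(kfold_accuracy(d[1:2, ], "x"), "too few")
})

test_that("the true model dominates the null model in AUC on synthetic data", {
  w <- small_world(nrow = 60, ncol = 60)
  tm <- names(w$stack$layers)[1]
  truth <- truth_model(setNames(1.5, tm))
  wins <- 0
  for (r in 1:20) {
    pres <- generate_presences(w$stack, truth, 150, seed = 100 + r)
    ab <- generate_pseudo_absences(pres, w$landcover, 4, buffer_m = 0,
                                   seed = 100 + r)
    ua <- use_availability_data(pres, ab, w$stack)
    ft <- fit_logistic(ua, tm)
    wins <- wins + (auc_roc(fitted(ft$fit), ua$use) >= 0.5)
  }
  expect_equal(wins, 20)
})
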