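brute_vif <- function(X) {
  vapply(seq_along(X), function(j) {
    r2 <- summary(lm(X[[j]] ~ ., data = X[-j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

test_that("VIF pruning removes exact and near collinearity", {
  set.seed(50)
  X <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  X$dup <- X$a                                # exact duplicate
  kept <- prune_collinear_vif(X)
  expect_true(xor("a" %in% kept, "dup" %in% kept))
  expect_true("a" %in% kept)                  # tie-break removes larger index

  # orthonormal features: nothing removed
  Q <- qr.Q(qr(matrix(rnorm(300), 100, 3)))
  expect_equal(prune_collinear_vif(as.data.frame(Q)), c("V1", "V2", "V3"))

  # three features with pairwise r ~ 0.99: at least one removed, final
  # max VIF <= 10 verified by an independent brute-force computation
  z <- rnorm(200)
  W <- data.frame(x = z + rnorm(200, 0, 0.1), y = z + rnorm(200, 0, 0.1),
                  w = z + rnorm(200, 0, 0.1), indep = rnorm(200))
  keptW <- prune_collinear_vif(W)
  expect_lt(length(keptW), 4)
  expect_lte(max(brute_vif(W[keptW])), 10)
})

test_that("VIF pruning agrees with the car package on a clean design", {
  skip_if_not_installed("car")
  set.seed(51)
  X <- data.frame(a = rnorm(120), b = rnorm(120))
  X$c <- 0.7 * X$a + rnorm(120, 0, 0.5)
  y <- rnorm(120)
  ours <- brute_vif(X)
  theirs <- car::vif(lm(y ~ a + b + c, data = cbind(X, y = y)))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("stepwise AIC retains informative features and is deterministic", {
  set.seed(52)
  n <- 500
  X <- as.data.frame(matrix(rnorm(n * 6), n,
                            dimnames = list(NULL, c("sig", paste0("n", 1:5)))))
  y <- rbinom(n, 1, plogis(2 * X$sig))
  s1 <- stepwise_select_aic(X, y)
  s2 <- stepwise_select_aic(X, y)
  expect_true("sig" %in% s1$features)
  expect_identical(s1$features, s2$features)

  # pure-noise labels: intercept-only selected in most replicates
  set.seed(53)
  n0 <- 0
  for (r in 1:15) {
    Xr <- as.data.frame(matrix(rnorm(250 * 2), 250,
                               dimnames = list(NULL, c("x1", "x2"))))
    yr <- rbinom(250, 1, 0.5)
    if (length(stepwise_select_aic(Xr, yr)$features) == 0) n0 <- n0 + 1
  }
  expect_gt(n0, 7)

  expect_error(stepwise_select_aic(data.frame(a = rnorm(10)), rep(1, 10)),
               "both classes")
})

test_that("complete separation falls back to a ridge fit with a warning", {
  X <- data.frame(x = c(rnorm(30, -3), rnorm(30, 3)))
  y <- rep(c(0L, 1L), each = 30)
  expect_warning(s <- stepwise_select_aic(X, y), "separation")
  expect_true(s$ridged)
  expect_true(all(is.finite(s$coef)))
  expect_gt(s$coef["x"], 0)
})

test_that("bootstrap stability is reproducible and ranks features sensibly", {
  set.seed(54)
  n <- 300
  X <- data.frame(strong = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X$strong))
  f1 <- bootstrap_stability(X, y, n_boot = 30, seed = 9)
  f2 <- bootstrap_stability(X, y, n_boot = 30, seed = 9)
  expect_identical(f1, f2)
  expect_gte(f1["strong"], 0.9)
  expect_lt(f1["noise"], f1["strong"])
  expect_error(bootstrap_stability(X, y, n_boot = 0), "n_boot")
})

# independent oracle: exhaustive scan over every threshold on the same grid
brute_threshold <- function(prob, y, grid_step = 0.005,
                            convention = "paper") {
  grid <- seq(0, 1, by = grid_step)
  rate <- function(a, b) if (b == 0) 0 else a / b
  d <- vapply(grid, function(th) {
    tp <- sum(prob >= th & y == 1); fp <- sum(prob >= th & y == 0)
    fn <- sum(prob < th & y == 1); tn <- sum(prob < th & y == 0)
    fpr <- if (convention == "paper") rate(fp, fp + fn) else rate(fp, fp + tn)
    abs(fpr - rate(fn, tp + fn))
  }, numeric(1))
  grid[which.min(d)]          # which.min returns the first (lowest) optimum
}

test_that("the probability threshold equalises the printed rates", {
  # worked micro-example: any threshold in (0.3, 0.8] gives zero rates;
  # the tie-break returns the lowest grid value above 0.3
  prob <- c(0.9, 0.8, 0.3, 0.1); y <- c(1, 1, 0, 0)
  th <- choose_probability_threshold(prob, y)
  expect_equal(th$prob_threshold, 0.305)
  expect_equal(th$fpr, 0); expect_equal(th$fnr, 0)
  expect_equal(th$prob_threshold, brute_threshold(prob, y))

  # single separable positive/negative: zero rates at the returned cutoff
  th2 <- choose_probability_threshold(c(0.9, 0.1), c(1, 0))
  expect_equal(th2$fpr, 0); expect_equal(th2$fnr, 0)

  # anti-informative model: matches the brute-force scan exactly
  set.seed(55)
  prob3 <- c(0.1, 0.2, 0.3, 0.8, 0.85, 0.9)
  y3 <- c(1, 1, 1, 0, 0, 0)
  th3 <- choose_probability_threshold(prob3, y3)
  expect_equal(th3$prob_threshold, brute_threshold(prob3, y3))

  # random toys, both conventions
  for (r in 1:20) {
    p <- round(runif(12), 3); yy <- rbinom(12, 1, 0.5)
    if (length(unique(yy)) < 2) next
    expect_equal(choose_probability_threshold(p, yy)$prob_threshold,
                 brute_threshold(p, yy))
    expect_equal(choose_probability_threshold(
      p, yy, fpr_convention = "standard")$prob_threshold,
      brute_threshold(p, yy, convention = "standard"))
  }

  expect_warning(thd <- choose_probability_threshold(rep(0.4, 6),
                                                     c(1, 1, 1, 0, 0, 0)),
                 "degenerate")
  expect_equal(thd$prob_threshold, 0.5)
})

test_that("a trained spindle classifier exposes the fitted-model interface", {
  sim <- small_sim()
  rec <- sim$recording
  periods <- data.frame(onset_s = 0, offset_s = 600)
  marks <- truth_events(sim, "C1", "spindle")[, c("onset_s", "offset_s")]
  clf <- suppressWarnings(spindle_classifier(rec, "C1", marks, periods,
                                             n_boot = 10))
  expect_s3_class(clf, "spindle_classifier")
  expect_true(clf$prob_threshold > 0 && clf$prob_threshold < 1)
  expect_true(all(clf$selected_features %in% clf$vif_surviving))
  expect_named(coef(clf))
  expect_output(print(clf), "spindle_classifier")
  expect_output(summary(clf), "coefficients")
  expect_true(all(clf$bootstrap_selection_freq >= 0 &
                    clf$bootstrap_selection_freq <= 1))

  ev <- suppressWarnings(apply_classifier(clf, rec))
  expect_true(all(ev$probability >= clf$prob_threshold))
  expect_true(all(ev$offset_s - ev$onset_s >= 0.3))
  expect_true(all(ev$class %in% c("slow", "fast")))
  expect_true(all((ev$spindle_freq <= 12) == (ev$class == "slow")))
  # post hoc: no event touches an exclusion interval
  if (nrow(rec$exclusions)) {
    for (i in seq_len(nrow(rec$exclusions))) {
      expect_false(any(ev$onset_s <= rec$exclusions$offset_s[i] &
                         ev$offset_s >= rec$exclusions$onset_s[i]))
    }
  }
})
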