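# HRF, design matrices, per-voxel GLM, fixed effects, Dice, ROI traces

test_that("the canonical HRF peaks at 6 s and the block regressor follows a convolution oracle", {
  tt <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(tt)
  expect_equal(tt[which.max(h)], 6, tolerance = 0.05)
  expect_equal(max(h), 1)
  des <- stimulus_design(10, 15, "task", 90)
  ft <- seq(0, 89, by = 0.5)
  X <- build_design_matrix(des, ft)
  # independent discrete-convolution oracle on the frame grid
  box <- as.numeric(ft >= 10 & ft < 25)
  kern <- canonical_hrf(seq(0, 32, by = 0.5))
  oracle <- numeric(length(ft))
  for (i in seq_along(ft)) {
    k <- seq_len(min(i, length(kern)))
    oracle[i] <- sum(box[i - k + 1] * kern[k]) * 0.5
  }
  expect_gt(cor(X[, "task"], oracle), 0.999)
  expect_equal(ft[which.max(X[, "task"])], ft[which.max(oracle)],
               tolerance = 1)
})

test_that("localizer protocols have the documented structure", {
  aud <- localizer_design("auditory")
  expect_equal(nrow(aud), 6)
  expect_true(all(aud$duration == 15))
  expect_equal(attr(aud, "run_duration_s") - aud$onset[1], 6 * 30)  # 180 s
  vis <- localizer_design("visual")
  expect_equal(nrow(vis), 16)
  expect_equal(sum(vis$condition == "visual_left"), 8)
  expect_true(all(vis$duration == 10))
  expect_true(all(diff(vis$onset) == 34))    # 10 s on + 24 s rest
  expect_error(stimulus_design(100, 50, "a", 120), "within the run")
  expect_error(stimulus_design(c(0, 5), c(10, 5), c("a", "a"), 60), "overlap")
})

test_that("zero-event condition columns are flagged", {
  des <- stimulus_design(c(5, 40), c(10, 10), c("a", "b"), 80)
  ft <- seq(0, 20, by = 1)        # frames end before condition b starts
  expect_warning(X <- build_design_matrix(des, ft), "zero regressor")
})

test_that("GLM recovers exact noiseless betas and is unbiased under noise", {
  des <- localizer_design("auditory")
  ft <- seq(0, attr(des, "run_duration_s") - 1, by = 1)
  X <- build_design_matrix(des, ft)
  # exact fit
  Y <- rbind(2.5 * X[, "auditory"], -1.2 * X[, "auditory"])
  fit <- fit_glm(Y, X)
  expect_equal(unname(fit$beta[, "auditory"]), c(2.5, -1.2), tolerance = 1e-10)
  expect_true(all(fit$se[, "auditory"] <= 1e-6))
  # white noise: beta distribution centred at zero
  set.seed(6)
  Yn <- matrix(rnorm(1000 * nrow(X)), 1000, nrow(X))
  fitn <- fit_glm(Yn, X)
  expect_lt(abs(mean(fitn$beta[, "auditory"])), 0.05)
  # planted amplitude 1 with noise sd 0.5: |bias| < 0.1 over 100 fits
  Yp <- matrix(rep(X[, "auditory"], each = 100), 100, nrow(X), byrow = FALSE) +
    matrix(rnorm(100 * nrow(X), sd = 0.5), 100, nrow(X))
  fitp <- fit_glm(Yp, X)
  expect_lt(abs(mean(fitp$beta[, "auditory"]) - 1), 0.1)
  # rank-deficient design rejected
  Xbad <- cbind(X, X[, "auditory"])
  expect_error(fit_glm(Y, Xbad), "collinearity")
})

test_that("contrasts are antisymmetric with propagated errors", {
  des <- localizer_design("motor")
  ft <- seq(0, attr(des, "run_duration_s") - 1, by = 1)
  X <- build_design_matrix(des, ft)
  set.seed(7)
  amp <- cbind(motor_left = c(1, 0, 0.5), motor_right = c(0, 1, 0.5))
  Y <- amp %*% t(X[, colnames(amp)]) + matrix(rnorm(3 * nrow(X), sd = 0.1),
                                              3, nrow(X))
  fit <- fit_glm(Y, X)
  cLR <- contrast(fit, fit, "motor_left", "motor_right")
  cRL <- contrast(fit, fit, "motor_right", "motor_left")
  expect_equal(cLR$beta, -cRL$beta)
  expect_true(all(cLR$se >= fit$se[, "motor_left"]))
  expect_true(all(cLR$se >= fit$se[, "motor_right"]))
  # a - a is exactly zero
  caa <- contrast(fit, fit, "motor_left", "motor_left")
  expect_true(all(caa$beta == 0))
})

test_that("fixed-effects t follows the summation formula and grows as sqrt(n)", {
  mk <- function(beta, se, nvox = 10) {
    structure(list(beta = matrix(beta, nvox, 1), se = matrix(se, nvox, 1),
                   df = 100, regressors = "c"), class = "stat_map")
  }
  # identical subjects beta 1, se 1, n = 8: t = 8/sqrt(8)
  g8 <- group_fixed_effects_t(rep(list(mk(1, 1)), 8))
  expect_equal(unique(g8$t), 8 / sqrt(8))
  # single subject: t = beta/se
  g1 <- group_fixed_effects_t(list(mk(2, 0.5)))
  expect_equal(unique(g1$t), 4)
  # sign flip
  gneg <- group_fixed_effects_t(rep(list(mk(-1, 1)), 8))
  expect_equal(gneg$t, -g8$t)
  # sqrt(n) growth for identical subjects
  tn <- vapply(c(1, 4, 9), function(n)
    unique(group_fixed_effects_t(rep(list(mk(1, 1)), n))$t), numeric(1))
  expect_equal(tn, sqrt(c(1, 4, 9)))
  # weighted variant agrees when all SEs are equal
  gw <- group_fixed_effects_t(rep(list(mk(1, 1)), 8), weighted = TRUE)
  expect_equal(gw$t, g8$t)
})

test_that("Dice overlap is symmetric, bounded, and matches the hand-counted toy case", {
  m1 <- c(4, 3, 1, 0)
  m2 <- c(4, 0, 3, 1)
  expect_equal(dice_overlap(m1, m2, 0.5), 0.5)    # {1,2} vs {1,3}
  expect_equal(dice_overlap(m2, m1, 0.5), 0.5)    # symmetric
  expect_equal(dice_overlap(m1, m1, 0.5), 1)
  expect_equal(dice_overlap(c(1, 0, 0, 0), c(0, 0, 0, 1), 0.5), 0)
  set.seed(8)
  for (k in 1:5) {
    a <- runif(50); b <- runif(50)
    expect_equal(dice_overlap(a, b, 0.25), dice_overlap(b, a, 0.25))
    d <- dice_overlap(a, b, 0.25)
    expect_gte(d, 0); expect_lte(d, 1)
  }
  expect_error(dice_overlap(m1, m2, 1.2), "frac")
  expect_error(dice_overlap(-m1, m2, 0.5), "degenerate")
})

test_that("ROI block averages show the canonical HbO-up / HbR-down response", {
  ses <- default_session()
  hb <- recon_hemo(ses)
  tt <- (seq_len(ncol(hb$HbO$values)) - 1)
  X <- build_design_matrix(ses$design, tt)
  fit <- fit_glm(hb$HbO, X)
  tmap <- fit$beta[, 1] / fit$se[, 1]
  tr <- roi_block_average(hb, tmap, ses$design, fs = 1)
  during <- tr$time_s >= 5 & tr$time_s <= 20    # response window
  expect_gt(mean(tr$HbO_mean[during]), 0)
  expect_lt(mean(tr$HbR_mean[during]), 0)
  expect_true(all(tr$HbO_se >= 0))
  # identical blocks give zero SE
  n <- 120
  v <- matrix(0, 4, n)
  block <- rep(c(0, 1, 0), c(10, 10, 10))
  v[1:4, ] <- matrix(rep(rep(block, 4), each = 4), 4, n)
  des <- stimulus_design(c(10, 40, 70, 100) - 0, rep(10, 4), rep("c", 4), n)
  tr0 <- roi_block_average(list(sig = v), rep(1, 4), des, fs = 1,
                           window_s = 20)
  expect_true(all(tr0$sig_se == 0))
})
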