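# Binomial-family MF modelling: parameter recovery, dispersion rule,
# contrasts, Sidak adjustment.

simTwoGroup <- function(seed, mf = c(1e-7, 5e-7), n = 10, depth = 5e7) {
  set.seed(seed)
  data.frame(
    dose = rep(c(0, 1), each = n),
    sum_min = c(rbinom(n, depth, mf[1]), rbinom(n, depth, mf[2])),
    group_depth = depth)
}

test_that("two-group GLM recovers the simulated fold change", {
  d <- simTwoGroup(1)
  fit <- fitMFModel(d, fixed = "dose")
  ct <- estimateContrast(fit, contrastsVsControl(fit, "dose"))
  # truth is a 5-fold increase; the estimate must be well inside
  # sampling error (log-scale SE ~ 0.15 at these counts)
  expect_gt(ct$fold_change, 5 * exp(-3 * 0.16))
  expect_lt(ct$fold_change, 5 * exp(3 * 0.16))
  expect_lt(ct$p_value, 1e-6)
})

test_that("saturated two-level estimates equal empirical count/depth ratios", {
  d <- simTwoGroup(7)
  fit <- fitMFModel(d, fixed = "dose")
  lev <- estimateLevels(fit)
  emp <- tapply(d$sum_min, d$dose, sum) / tapply(d$group_depth, d$dose, sum)
  expect_equal(lev$estimate, as.vector(emp[as.character(lev$dose)]),
               tolerance = 1e-3)
  # estimated fold change equals the empirical MF ratio
  ct <- estimateContrast(fit, contrastsVsControl(fit, "dose"))
  expect_equal(ct$fold_change, unname(emp[2] / emp[1]), tolerance = 1e-3)
})

test_that("intercept-only model returns the pooled frequency", {
  d <- data.frame(g = "all", sum_min = 1, group_depth = 1e6)
  fit <- fitMFModel(d, fixed = "g")
  expect_equal(estimateLevels(fit)$estimate, 1e-6, tolerance = 1e-9)
})

test_that("logit and log back-transforms agree at small frequencies", {
  d <- data.frame(g = c("a", "b"), sum_min = c(100, 150),
                  group_depth = 1e6)
  fit <- fitMFModel(d, fixed = "g")
  beta <- coef(fit@fit)
  eta <- c(beta[1], beta[1] + beta[2])
  expect_equal(plogis(eta), exp(eta), tolerance = 1e-3)
  # the relative gap between the back-transforms is of order MF itself:
  # ~1e-4 at MF 1e-4, and far below 1e-6 at ECS-typical MF 1e-8
  expect_lt(abs(plogis(log(1e-4)) - 1e-4) / 1e-4, 2e-4)
  expect_lt(abs(plogis(log(1e-8)) - 1e-8) / 1e-8, 1e-6)
})

test_that("dispersion rule picks binomial vs quasibinomial correctly", {
  # pure binomial sampling: phi near 1
  set.seed(11)
  d <- data.frame(dose = rep(c(0, 1, 2), each = 12),
                  sum_min = rbinom(36, 1e7, rep(c(2e-6, 4e-6, 8e-6),
                                                each = 12)),
                  group_depth = 1e7)
  fit <- fitMFModel(d, fixed = "dose")
  expect_gt(fit@dispersion, 0.8)
  expect_lt(fit@dispersion, 1.2)

  # overdispersed counts: latent logit-normal sample effects with
  # intra-class correlation 0.01 on the logistic scale
  set.seed(12)
  icc <- 0.01
  sigma <- sqrt(icc * (pi^2 / 3) / (1 - icc))
  mfs <- rep(c(2e-6, 4e-6, 8e-6), each = 12)
  p <- plogis(qlogis(mfs) + rnorm(36, 0, sigma))
  d2 <- data.frame(dose = rep(c(0, 1, 2), each = 12),
                   sum_min = rbinom(36, 1e7, p), group_depth = 1e7)
  fit2 <- fitMFModel(d2, fixed = "dose")
  expect_gt(fit2@dispersion, 1.5)
  expect_identical(fit2@family, "quasibinomial")
  # beta coefficients are unchanged by the family switch; only SEs scale
  refit_binom <- glm(cbind(sum_min, group_depth - sum_min) ~ factor(dose),
                     family = binomial(), data = d2)
  expect_equal(unname(coef(fit2@fit)), unname(coef(refit_binom)),
               tolerance = 1e-8)
  se_ratio <- summary(fit2@fit)$coefficients[, 2] /
    summary(refit_binom)$coefficients[, 2]
  expect_equal(unname(se_ratio), rep(sqrt(fit2@dispersion), 3),
               tolerance = 1e-3)
})

test_that("confidence intervals cover the true fold change", {
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    d <- simTwoGroup(1000 + r, n = 10, depth = 5e7)
    if (sum(d$sum_min[d$dose == 0]) == 0) next
    fit <- fitMFModel(d, fixed = "dose")
    ct <- estimateContrast(fit, contrastsVsControl(fit, "dose"))
    if (ct$lower <= 5 && 5 <= ct$upper) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("contrast algebra satisfies the basic identities", {
  d <- simTwoGroup(3)
  fit <- fitMFModel(d, fixed = "dose")
  k <- length(coef(fit@fit))
  # all-zero contrast: theta 0, fold change 1
  ct0 <- estimateContrast(fit, rep(0, k))
  expect_equal(ct0$theta, 0)
  expect_equal(ct0$fold_change, 1)
  # unit contrast variance equals the coefficient's squared SE
  cu <- rep(0, k); cu[2] <- 1
  ctu <- estimateContrast(fit, cu)
  expect_equal(ctu$se_theta^2, vcov(fit@fit)[2, 2], tolerance = 1e-12)
  # delta-method SE of the fold change
  expect_equal(ctu$se_fold, exp(ctu$theta) * ctu$se_theta)
  expect_error(estimateContrast(fit, rep(0, k + 1)), "match")
})

test_that("a binomial GLMM with random intercepts fits and tests", {
  set.seed(21)
  n_animal <- 16
  animal <- paste0("a", seq_len(n_animal))
  dose <- rep(c(0, 1), each = n_animal / 2)
  sigma <- 0.2  # animal-level random intercept SD on the logit scale
  mfs <- c(2e-6, 8e-6)[dose + 1]
  d <- do.call(rbind, lapply(seq_len(n_animal), function(i) {
    p <- plogis(qlogis(mfs[i]) + rnorm(1, 0, sigma))
    data.frame(animal = animal[i], dose = dose[i],
               target = c("t1", "t2"),
               sum_min = rbinom(2, 5e6, p), group_depth = 5e6)
  }))
  fit <- fitMFModel(d, fixed = "dose", random = "animal")
  expect_s4_class(fit, "ModelFit")
  expect_identical(fit@family, "binomial")
  expect_length(fit@random, 1)
  ct <- estimateContrast(fit, contrastsVsControl(fit, "dose"))
  expect_gt(ct$fold_change, 2)
  expect_lt(ct$p_value, 0.05)
})

test_that("Sidak adjustment matches its closed form and is monotone", {
  expect_equal(sidakAdjust(0.05, m = 1), 0.05)
  expect_equal(sidakAdjust(0.01, m = 3), 0.029701)
  expect_equal(sidakAdjust(c(0, 1)), c(0, 1))
  p <- seq(0.001, 0.5, length.out = 20)
  adj <- sidakAdjust(p, m = 4)
  expect_true(all(diff(adj) > 0))          # monotone in p
  expect_true(all(adj >= p))               # adjusted >= raw
  expect_true(all(sidakAdjust(0.2, m = 1:10) ==
                    cummax(sidakAdjust(0.2, m = 1:10))))  # monotone in m
  expect_error(sidakAdjust(1.2), "0, 1")
})

test_that("degenerate designs raise named errors", {
  d <- data.frame(g = c("a", "a"), sum_min = 0, group_depth = 100)
  expect_error(fitMFModel(d, fixed = "g"), "no mutations")
  d2 <- data.frame(g = "a", h = "x", sum_min = c(2, 3),
                   group_depth = 1000)
  expect_error(fitMFModel(d2, fixed = c("g", "missing_col")), "absent")
})

test_that("model diagnostics expose Pearson residuals with normal quantiles", {
  d <- simTwoGroup(5)
  fit <- fitMFModel(d, fixed = "dose")
  dg <- modelDiagnostics(fit)
  expect_equal(nrow(dg), nrow(d))
  expect_equal(sort(order(dg$residual)), sort(order(dg$theoretical)))
  expect_equal(cor(dg$residual[order(dg$residual)],
                   sort(dg$theoretical)) > 0.9, TRUE)
})
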