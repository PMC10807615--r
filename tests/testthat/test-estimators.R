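# independent brute-force oracles -------------------------------------------

# origin-constrained WLS of by on bx, weights 1/sy^2 (IVW equivalent)
ivw_oracle <- function(h) {
  fit <- lm(beta_out ~ 0 + beta_exp, data = as.data.frame(h),
            weights = 1 / h$se_out^2)
  s <- summary(fit)
  beta <- unname(coef(fit))
  # fixed-effect se: unscale lm's residual variance
  se_fixed <- unname(s$coefficients[1, 2] / s$sigma)
  list(beta = beta, se_fixed = se_fixed)
}

# WLS with intercept after orienting beta_exp >= 0 (Egger equivalent)
egger_oracle <- function(h) {
  flip <- h$beta_exp < 0
  d <- data.frame(bx = abs(h$beta_exp),
                  by = ifelse(flip, -h$beta_out, h$beta_out))
  fit <- lm(by ~ bx, data = d, weights = 1 / h$se_out^2)
  s <- summary(fit)
  scale <- max(1, s$sigma) / s$sigma
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = unname(s$coefficients[1, 2]) * scale,
       se_slope = unname(s$coefficients[2, 2]) * scale)
}

# exhaustive interpolation oracle for the weighted median: walk adjacent
# sorted ratios and solve the linear crossing of cumulative weight 0.5
wm_oracle <- function(ratio, w) {
  ord <- order(ratio)
  th <- ratio[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (s[1] >= 0.5) return(th[1])
  for (j in seq_len(length(th) - 1)) {
    if (s[j] <= 0.5 && s[j + 1] >= 0.5) {
      return(th[j] + (0.5 - s[j]) / (s[j + 1] - s[j]) * (th[j + 1] - th[j]))
    }
  }
  th[length(th)]
}

test_that("Wald ratios divide effects and propagate first-order error", {
  h <- make_h(bx = c(0.1, 0.2), by = c(0.05, 0), sx = c(0.01, 0.01),
              sy = c(0.02, 0.02))
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, c(0.5, 0))
  expect_equal(wr$se, c(0.2, 0.1))
  h0 <- make_h(bx = c(0.1, 0), by = c(0.05, 0.01), sx = c(0.01, 0.01),
               sy = c(0.02, 0.02))
  expect_error(wald_ratios(h0), class = "mrkit_degenerate_error")
})

test_that("a single SNP reduces IVW to its Wald ratio", {
  h <- make_h(bx = 0.1, by = 0.05, sx = 0.01, sy = 0.02)
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  expect_true(is.na(est$Q))
})

test_that("two equal-precision ratios average symmetrically with hand-checked Q", {
  # ratios 0.4 and 0.6 with ratio se 0.1 each: beta 0.5, Q = 2
  h <- make_h(bx = c(0.1, 0.1), by = c(0.04, 0.06), sx = c(1e-6, 1e-6),
              sy = c(0.01, 0.01))
  est <- mr_ivw(h, model = "fixed")
  expect_equal(est$beta, 0.5)
  expect_equal(est$Q, 2)
  expect_equal(est$Q_df, 1)
})

test_that("IVW and Egger match brute-force WLS oracles on random instances", {
  withr::with_seed(42, {
    for (i in 1:50) {
      h <- random_h(k = sample(4:30, 1))
      est <- mr_ivw(h, model = "fixed")
      orc <- ivw_oracle(h)
      expect_equal(est$beta, orc$beta, tolerance = 1e-10)
      expect_equal(est$se, orc$se_fixed, tolerance = 1e-10)
      eg <- mr_egger(h)
      eo <- egger_oracle(h)
      expect_equal(eg$beta, eo$slope, tolerance = 1e-10)
      expect_equal(eg$intercept, eo$intercept, tolerance = 1e-10)
      expect_equal(eg$se, eo$se_slope, tolerance = 1e-10)
      expect_equal(eg$intercept_se, eo$se_intercept, tolerance = 1e-10)
    }
  })
})

test_that("points on an exact line recover intercept and slope with zero residual", {
  bx <- c(0.02, 0.05, 0.08, 0.11)
  h <- make_h(bx = bx, by = 0.02 + 0.5 * bx, sx = rep(0.01, 4),
              sy = rep(0.02, 4))
  eg <- mr_egger(h)
  expect_equal(eg$intercept, 0.02)
  expect_equal(eg$beta, 0.5)
  expect_equal(eg$rss_w, 0, tolerance = 1e-20)
  expect_error(mr_egger(make_h(0.1, 0.1, 0.01, 0.01)),
               class = "mrkit_insufficient_error")
})

test_that("the weighted median interpolates the weight-ordered ratios", {
  # equal weights, ratios {1,2,3} -> 2
  h <- make_h(bx = c(0.1, 0.1, 0.1), by = c(0.1, 0.2, 0.3),
              sx = rep(1e-6, 3), sy = rep(0.01, 3))
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 2)
  # degenerate spread: all ratios c, bootstrap se shrinks with the ses
  h2 <- make_h(bx = rep(0.1, 3), by = rep(0.05, 3), sx = rep(1e-8, 3),
               sy = rep(1e-8, 3))
  wm <- mr_weighted_median(h2, n_boot = 50, seed = 1)
  expect_equal(wm$beta, 0.5)
  expect_lt(wm$se, 1e-5)
  expect_error(mr_weighted_median(h, n_boot = 10),
               class = "mrkit_config_error")  # bootstrap needs a seed
})

test_that("the weighted median matches the exhaustive interpolation oracle", {
  withr::with_seed(43, {
    for (i in 1:50) {
      h <- random_h(k = sample(3:25, 1))
      wr <- wald_ratios(h)
      expect_equal(mr_weighted_median(h, n_boot = 0)$beta,
                   wm_oracle(wr$ratio, 1 / wr$se^2), tolerance = 1e-12)
    }
  })
})

test_that("Cochran's Q matches hand computation and its boundary cases", {
  expect_equal(cochran_q(c(1, 1, 1), c(0.1, 0.2, 0.3))$Q, 0)
  expect_equal(cochran_q(c(1, 1, 1), c(0.1, 0.2, 0.3))$I2, 0)
  q <- cochran_q(c(0, 2), c(1, 1))
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1)
  expect_equal(q$I2, 50)
  expect_error(cochran_q(1, 0.1), class = "mrkit_insufficient_error")
})

test_that("estimators are sign-equivariant in the outcome and scale-equivariant in the exposure", {
  withr::with_seed(44, {
    h <- random_h(k = 12)
    neg <- make_h(bx = h$beta_exp, by = -h$beta_out, sx = h$se_exp,
                  sy = h$se_out)
    for (f in list(function(x) mr_ivw(x, "fixed"), mr_egger,
                   function(x) mr_weighted_median(x, n_boot = 0))) {
      a <- f(h); b <- f(neg)
      expect_equal(b$beta, -a$beta)
      expect_equal(b$se, a$se)
    }
    cc <- 3.7
    sc <- make_h(bx = cc * h$beta_exp, by = h$beta_out, sx = cc * h$se_exp,
                 sy = h$se_out)
    expect_equal(mr_ivw(sc, "fixed")$beta, mr_ivw(h, "fixed")$beta / cc)
    expect_equal(mr_egger(sc)$beta, mr_egger(h)$beta / cc)
    expect_equal(mr_weighted_median(sc, n_boot = 0)$beta,
                 mr_weighted_median(h, n_boot = 0)$beta / cc)
  })
})

test_that("auto model switches to multiplicative random effects under heterogeneity", {
  # wildly heterogeneous ratios force Q p <= 0.05
  h <- make_h(bx = rep(0.1, 4), by = c(0.1, -0.1, 0.3, -0.3),
              sx = rep(1e-6, 4), sy = rep(0.005, 4))
  est <- mr_ivw(h, model = "auto")
  expect_equal(est$model, "random")
  fixed <- mr_ivw(h, model = "fixed")
  expect_equal(est$se, fixed$se * sqrt(est$Q / est$Q_df))
  # homogeneous ratios stay fixed
  h2 <- make_h(bx = rep(0.1, 4), by = rep(0.05, 4) + c(1, -1, 1, -1) * 1e-4,
               sx = rep(1e-6, 4), sy = rep(0.01, 4))
  expect_equal(mr_ivw(h2, model = "auto")$model, "fixed")
})

test_that("tidy and glance expose broom-shaped summaries", {
  h <- random_h(k = 10, seed = 45)
  td <- tidy(mr_ivw(h))
  expect_true(all(c("estimate", "std.error", "conf.low", "conf.high",
                    "p.value", "k") %in% names(td)))
  eg <- tidy(mr_egger(h))
  expect_setequal(eg$term, c("slope", "intercept"))
  gl <- glance(mr_ivw(h))
  expect_true(all(c("Q", "Q.p.value", "I2") %in% names(gl)))
})
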