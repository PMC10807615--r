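# brute-force weighted normal-equations oracle for MV-IVW
mv_oracle <- function(X, y, w) {
  A <- t(X) %*% (w * X)
  drop(solve(A, t(X) %*% (w * y)))
}

mv_fixture <- function(seed = 1, rg = 0, theta = c(0.2, -0.1), J = 60,
                       n_out = 5e5) {
  simulate_mv_pair(J = J, rg = rg, theta = theta, n_out = n_out, seed = seed)
}

test_that("the union instrument set de-duplicates and respects presence rules", {
  sim <- mv_fixture(seed = 31)
  m <- build_mv_set(sim$exposures, sim$outcome)
  # shared panel: each SNP appears once with both beta columns populated
  expect_equal(anyDuplicated(m$rsid), 0)
  expect_true(all(c("beta_exposure1", "beta_exposure2") %in% names(m)))
  # SNP missing from one exposure table gets dropped with a reason
  ex2 <- sim$exposures
  ex2[[2]] <- ex2[[2]][-1, ]
  m2 <- build_mv_set(ex2, sim$outcome)
  d <- attr(m2, "dropped")
  expect_true(sim$exposures[[1]]$rsid[1] %in% d$rsid)
  expect_match(d$reason[d$rsid == sim$exposures[[1]]$rsid[1]], "missing_in_")
})

test_that("disjoint instrument lists union to k1 + k2 with provenance", {
  # two disjoint significant sets, but both tables cover the union
  mkpair <- function(sig_idx, seed) {
    withr::with_seed(seed, {
      rsid <- sprintf("rs%02d", 1:12)
      beta <- rnorm(12, 0, 0.002)
      beta[sig_idx] <- 0.08
      tibble::tibble(rsid = rsid, effect_allele = "A", other_allele = "G",
                     eaf = 0.3, beta = beta, se = 0.005,
                     pval = 2 * pnorm(-abs(beta / 0.005)))
    })
  }
  e1 <- sumstats(mkpair(1:4, 1), "e1", "continuous")
  e2 <- sumstats(mkpair(9:12, 2), "e2", "continuous")
  out <- sumstats(mkpair(integer(0), 3), "o", "continuous")
  m <- build_mv_set(list(e1 = e1, e2 = e2), out)
  expect_equal(nrow(m), 8)
  prov <- attr(m, "provenance")
  expect_equal(unname(prov[["rs01"]]), "e1")
  expect_equal(unname(prov[["rs09"]]), "e2")
})

test_that("cross-exposure clumping keeps the smaller-p member of a correlated pair", {
  e1 <- sumstats(tibble::tibble(
    rsid = c("rsA", "rsB"), effect_allele = "A", other_allele = "G",
    beta = c(0.08, 0.06), se = 0.005, pval = c(1e-12, 1e-9)),
    "e1", "continuous")
  e2 <- sumstats(tibble::tibble(
    rsid = c("rsA", "rsB"), effect_allele = "A", other_allele = "G",
    beta = c(0.01, 0.05), se = 0.005, pval = c(0.5, 1e-8)),
    "e2", "continuous")
  # third independent SNP keeps the design identified
  add3 <- function(t, lab) sumstats(dplyr::bind_rows(
    tibble::as_tibble(as.data.frame(t)),
    tibble::tibble(rsid = c("rsC", "rsD"), effect_allele = "A",
                   other_allele = "G", beta = c(0.07, 0.065), se = 0.005,
                   pval = c(1e-10, 1e-10))), lab, "continuous")
  e1 <- add3(e1, "e1"); e2 <- add3(e2, "e2")
  out <- sumstats(tibble::tibble(
    rsid = c("rsA", "rsB", "rsC", "rsD"), effect_allele = "A",
    other_allele = "G", beta = 0.01, se = 0.01, pval = 0.3),
    "o", "continuous")
  ld <- diag(4); dimnames(ld) <- list(c("rsA", "rsB", "rsC", "rsD"),
                                      c("rsA", "rsB", "rsC", "rsD"))
  ld["rsA", "rsB"] <- ld["rsB", "rsA"] <- 0.5
  m <- build_mv_set(list(e1 = e1, e2 = e2), out, ld = ld)
  expect_true("rsA" %in% m$rsid)   # p 1e-12 beats 1e-9
  expect_false("rsB" %in% m$rsid)
  expect_equal(attr(m, "dropped")$reason[attr(m, "dropped")$rsid == "rsB"],
               "clumped_cross_exposure")
})

test_that("MV-IVW matches the brute-force weighted normal-equations solve", {
  for (s in 1:10) {
    sim <- mv_fixture(seed = 40 + s, rg = 0.3)
    m <- build_mv_set(sim$exposures, sim$outcome)
    fit <- mvmr_ivw(m)
    X <- cbind(m$beta_exposure1, m$beta_exposure2)
    orc <- mv_oracle(X, m$beta_out, 1 / m$se_out^2)
    expect_equal(fit$estimates$beta, unname(orc), tolerance = 1e-10)
  }
})

test_that("simulated joint effects are recovered", {
  est <- sapply(1:20, function(s) {
    sim <- mv_fixture(seed = 100 + s, rg = 0.3, theta = c(0.2, -0.1))
    m <- build_mv_set(sim$exposures, sim$outcome)
    mvmr_ivw(m)$estimates$beta
  })
  expect_lt(abs(mean(est[1, ]) - 0.2), 0.02)
  expect_lt(abs(mean(est[2, ]) - (-0.1)), 0.02)
})

test_that("an all-zero covariable column leaves the other coefficient unchanged", {
  sim <- mv_fixture(seed = 61)
  m <- build_mv_set(sim$exposures, sim$outcome)
  m0 <- m
  m0$beta_exposure2 <- 0
  fit0 <- mvmr_ivw(m0)
  expect_true(is.na(fit0$estimates$beta[2]))
  # equals univariable IVW on the same SNPs (origin WLS, outcome weights)
  h <- make_h(bx = m$beta_exposure1, by = m$beta_out,
              sx = m$se_exposure1, sy = m$se_out)
  uni <- mr_ivw(h, model = "fixed")
  expect_equal(fit0$estimates$beta[1], uni$beta, tolerance = 1e-12)
})

test_that("collinear designs raise an error naming the exposures", {
  sim <- mv_fixture(seed = 62)
  m <- build_mv_set(sim$exposures, sim$outcome)
  m$beta_exposure2 <- 2 * m$beta_exposure1
  expect_error(mvmr_ivw(m), class = "mrkit_collinearity_error")
})

test_that("under-identified sets are refused", {
  sim <- mv_fixture(seed = 63, J = 40)
  ex <- lapply(sim$exposures, function(t) t[1:2, ])
  ex <- lapply(seq_along(ex), function(i) {
    sumstats(tibble::as_tibble(as.data.frame(ex[[i]])),
             names(sim$exposures)[i], "continuous")
  })
  names(ex) <- names(sim$exposures)
  expect_error(build_mv_set(ex, sim$outcome),
               class = "mrkit_underidentified_error")
})

test_that("conditional F collapses for identical columns and tracks univariable F when orthogonal", {
  sim <- mv_fixture(seed = 64)
  m <- build_mv_set(sim$exposures, sim$outcome)
  ident <- m
  ident$beta_exposure2 <- ident$beta_exposure1
  ident$se_exposure2 <- ident$se_exposure1
  cf <- conditional_f(ident)
  expect_lt(max(cf$conditional_F), 1e-20)

  # independent effects: conditional F within 10% of mean univariable F
  cfs <- sapply(1:10, function(s) {
    sim <- mv_fixture(seed = 200 + s, rg = 0, J = 150, n_out = 5e5)
    m <- build_mv_set(sim$exposures, sim$outcome)
    cf <- conditional_f(m)
    f1 <- mean((m$beta_exposure1 / m$se_exposure1)^2)
    f2 <- mean((m$beta_exposure2 / m$se_exposure2)^2)
    c(cf$conditional_F / c(f1, f2))
  })
  expect_lt(abs(mean(cfs) - 1), 0.1)
})

test_that("strongly correlated exposures drive the conditional F below 10", {
  # union-scale panel; instrument-level effect correlation 0.9
  sim <- simulate_mv_pair(J = 600, rg = 0.9, theta = c(0.1, 0),
                          n_out = 5e5, seed = 65)
  m <- build_mv_set(sim$exposures, sim$outcome)
  cf <- conditional_f(m)
  expect_lt(max(cf$conditional_F), 10)
  f1 <- mean((m$beta_exposure1 / m$se_exposure1)^2)
  expect_gt(f1, 10)  # unconditionally the instruments look strong
})
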