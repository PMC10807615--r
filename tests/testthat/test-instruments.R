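inst_table <- function(rsid, pval, beta = 0.1, se = 0.01, pos = NULL) {
  sumstats(tibble::tibble(
    rsid = rsid, effect_allele = "A", other_allele = "G",
    beta = beta, se = se, pval = pval,
    pos = pos %||% seq_along(rsid) * 1000), "t", "continuous")
}

ld_mat <- function(rsids, r2_pairs = list()) {
  m <- diag(length(rsids))
  dimnames(m) <- list(rsids, rsids)
  for (p in r2_pairs) m[p[[1]], p[[2]]] <- m[p[[2]], p[[1]]] <- p[[3]]
  m
}

test_that("greedy clumping keeps the best of a correlated pair and all independents", {
  tb <- inst_table(c("rsA", "rsB"), c(1e-9, 1e-8))
  ld <- ld_mat(c("rsA", "rsB"), list(list("rsA", "rsB", 0.9)))
  out <- select_instruments(tb, ld = ld)
  expect_equal(out$rsid, "rsA")

  tb3 <- inst_table(c("rsA", "rsB", "rsC"), c(1e-9, 1e-8, 1e-10))
  out3 <- select_instruments(tb3, ld = ld_mat(c("rsA", "rsB", "rsC")))
  expect_setequal(out3$rsid, c("rsA", "rsB", "rsC"))
})

test_that("a correlation chain resolves to the enumerated greedy solution", {
  # A-B r2 .9, B-C r2 .9, A-C 0, p(A)<p(B)<p(C); expected by hand: accept A,
  # discard B (tied to A), accept C
  tb <- inst_table(c("rsA", "rsB", "rsC"), c(1e-12, 1e-10, 1e-9))
  ld <- ld_mat(c("rsA", "rsB", "rsC"),
               list(list("rsA", "rsB", 0.9), list("rsB", "rsC", 0.9)))
  out <- select_instruments(tb, ld = ld)
  expect_setequal(out$rsid, c("rsA", "rsC"))
})

test_that("the base-pair window limits discards", {
  tb <- inst_table(c("rsA", "rsB"), c(1e-9, 1e-8), pos = c(0, 6e6))
  ld <- ld_mat(c("rsA", "rsB"), list(list("rsA", "rsB", 0.9)))
  out <- select_instruments(tb, ld = ld)  # 6 Mb apart: outside the 5 Mb window
  expect_setequal(out$rsid, c("rsA", "rsB"))
})

test_that("clumping is invariant to input row order", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      n <- 8
      rsids <- sprintf("rs%02d", 1:n)
      m <- matrix(runif(n * n, 0, 0.4), n)
      m[sample.int(n * n, 5)] <- 0.8
      m <- (m + t(m)) / 2; diag(m) <- 1
      dimnames(m) <- list(rsids, rsids)
      pv <- 10^-runif(n, 8.5, 20)
      tb <- inst_table(rsids, pv)
      perm <- sample.int(n)
      tb2 <- sumstats(tibble::as_tibble(as.data.frame(tb))[perm, ],
                      "t", "continuous")
      expect_setequal(select_instruments(tb, ld = m)$rsid,
                      select_instruments(tb2, ld = m)$rsid)
    }
  })
})

test_that("tightening thresholds never grows the instrument set", {
  withr::with_seed(6, {
    n <- 10
    rsids <- sprintf("rs%02d", 1:n)
    m <- matrix(runif(n * n, 0, 0.9), n); m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(rsids, rsids)
    tb <- inst_table(rsids, 10^-runif(n, 4, 20))
    k_loose <- nrow(select_instruments(tb, p_threshold = 1e-4, ld = m,
                                       r2_threshold = 0.5))
    k_p <- nrow(select_instruments(tb, p_threshold = 5e-8, ld = m,
                                   r2_threshold = 0.5))
    k_r2 <- nrow(select_instruments(tb, p_threshold = 1e-4, ld = m,
                                    r2_threshold = 0.1))
    expect_lte(k_p, k_loose)
    expect_lte(k_r2, k_loose)
  })
})

test_that("absent LD means pre-clumped: all passing SNPs accepted and flagged", {
  tb <- inst_table(c("rsA", "rsB"), c(1e-9, 1e-6))
  out <- select_instruments(tb)
  expect_equal(out$rsid, "rsA")
  expect_true(attr(out, "preclumped_assumed"))
  expect_error(select_instruments(tb, p_threshold = 1e-20),
               class = "mrkit_empty_set_error")
})

test_that("per-SNP F is the squared z-score of the SNP-exposure effect", {
  h <- make_h(bx = c(0.10, 0), by = c(0.05, 0.01), sx = c(0.01, 0.01),
              sy = c(0.02, 0.02))
  fs <- f_statistics(h)
  expect_equal(fs$per_snp$f, c(100, 0))
  expect_equal(fs$mean_f, 50)
  # permutation equivariance
  h2 <- make_h(bx = c(0, 0.10), by = c(0.01, 0.05), sx = c(0.01, 0.01),
               sy = c(0.02, 0.02))
  expect_equal(sort(f_statistics(h2)$per_snp$f), sort(fs$per_snp$f))
})

test_that("variance explained follows 2f(1-f)beta^2 and requires frequencies", {
  h <- make_h(bx = 0.1, by = 0, sx = 0.01, sy = 0.02, eaf = 0.5)
  expect_equal(variance_explained(h), 0.005)
  h0 <- make_h(bx = c(0, 0), by = c(0, 0), sx = c(1, 1), sy = c(1, 1),
               eaf = c(0.2, 0.3))
  expect_equal(variance_explained(h0), 0)
  hna <- make_h(bx = 0.1, by = 0, sx = 0.01, sy = 0.02)
  expect_error(variance_explained(hna), class = "mrkit_unavailable_error")
})
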