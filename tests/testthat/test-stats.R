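test_that("Fisher exact 2x2 matches enumeration properties and base R", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # empty margin -> 1 by convention
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")

  # invariance under simultaneous row and column swap; p in (0, 1]
  set.seed(81)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 12), 2)
    p <- fisher_exact_2x2(tab)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p)
    # independent oracle: base R implements the same two-sided convention
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Bonferroni adjustment caps at 1 and matches p.adjust", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 5), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.7), 1), c(0.2, 0.7))
  set.seed(82)
  p <- runif(10)
  expect_equal(bonferroni_adjust(p), stats::p.adjust(p, "bonferroni"))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
})

test_that("Krippendorff alpha agrees with a hand-built coincidence matrix", {
  # 4-item micro-example, 3 raters, one missing cell
  r <- rbind(c("a", "a", "a"),
             c("b", "b", "a"),
             c("a", NA,  "b"),
             c("b", "b", "b"))
  # oracle: build the coincidence matrix by explicit pair enumeration
  vals <- c("a", "b")
  o <- matrix(0, 2, 2)
  for (u in 1:4) {
    rr <- r[u, ][!is.na(r[u, ])]
    m <- length(rr)
    if (m < 2) next
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      o[match(rr[i], vals), match(rr[j], vals)] <-
        o[match(rr[i], vals), match(rr[j], vals)] + 1 / (m - 1)
    }
  }
  nc <- rowSums(o); n <- sum(nc)
  d_o <- o[1, 2] + o[2, 1]
  d_e <- (sum(nc %o% nc) - sum(nc^2)) / (n - 1)
  oracle <- 1 - d_o / d_e
  expect_equal(krippendorff_alpha(r)$alpha, oracle)

  # perfect agreement -> exactly 1
  perf <- matrix(rep(c("x", "y"), each = 3), 2, 3, byrow = TRUE)
  expect_equal(krippendorff_alpha(perf)$alpha, 1)

  # alpha <= 1 always; near 0 for independent ratings
  set.seed(83)
  null <- matrix(sample(c("yes", "no"), 400 * 5, TRUE), 400, 5)
  a <- krippendorff_alpha(null)$alpha
  expect_lte(a, 1)
  expect_lt(abs(a), 0.05)

  # bootstrap CI is seeded and ordered
  ci <- krippendorff_alpha(null, bootstrap = 200, seed = 9)$ci
  ci2 <- krippendorff_alpha(null, bootstrap = 200, seed = 9)$ci
  expect_identical(ci, ci2)
  expect_lte(ci[1], ci[2])
  expect_error(krippendorff_alpha(null, bootstrap = 10), "seed")

  # no pairable item -> error
  expect_error(krippendorff_alpha(cbind(c("a", "b"), c(NA, NA))),
               "2 raters|at least 2")
})

test_that("paired t-test matches base R and handles degenerate data", {
  set.seed(84)
  a <- rnorm(25); b <- rnorm(25, 0.3)
  got <- paired_t_test(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$mean_diff, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(got$ci, as.numeric(ref$conf.int), tolerance = 1e-10)

  z <- paired_t_test(rep(0, 10))
  expect_equal(z$p, 1)
  expect_true(z$degenerate)
  c1 <- paired_t_test(rep(1, 10))
  expect_true(c1$degenerate)
  expect_equal(c1$p, 0)
  expect_error(paired_t_test(c(1, 2)), "at least 3")
})

test_that("random-intercept moment fit matches a hand-computed ANOVA", {
  # balanced two-patient toy: hand mean squares
  d <- c(1, 2, 3, 7, 8, 9)
  pat <- c("p1", "p1", "p1", "p2", "p2", "p2")
  fit <- random_intercept_fit(d, patient = pat)
  # within: each patient has variance 1 -> SSW = 4, MSW = 4/(6-2) = 1
  # between: means 2 and 8, grand 5 -> SSB = 3*(9+9) = 54, MSB = 54
  # n0 = (6 - 18/6)/1 = 3 -> tau2 = (54-1)/3
  expect_equal(fit$sigma2, 1)
  expect_equal(fit$tau2, (54 - 1) / 3)
  expect_equal(fit$beta0, 5)

  # identical constant difference in every patient
  cst <- random_intercept_fit(rep(2.5, 8),
                              patient = rep(c("a", "b"), each = 4))
  expect_equal(cst$beta0, 2.5)
  expect_equal(cst$tau2, 0)
  expect_equal(cst$sigma2, 0)

  # balanced design: beta0 equals the paired-t mean difference
  set.seed(85)
  x <- rnorm(40); y <- rnorm(40)
  f2 <- random_intercept_fit(x, y, patient = rep(1:8, each = 5))
  expect_equal(f2$beta0, paired_t_test(x, y)$mean_diff)

  expect_warning(one <- random_intercept_fit(rnorm(5),
                                             patient = rep("p", 5)),
                 "single patient")
  expect_equal(one$n_patients, 1L)
})
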