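test_that("grouping follows the clinical labels and preserves counts", {
  h <- make_history(history_spec(seed = 7, n_per_zone = 10,
                                 outlier_fraction = 0, lesional_fraction = 0))
  g <- group_electrodes(h$history)
  expect_equal(length(g), 10)  # 5 zones x {entry, target}
  expect_true(all(vapply(g, function(x) nrow(x$points), 1L) == 10))
  expect_equal(group_electrodes(h$history[0, ]), list())

  # group sizes equal the label histogram
  mixed <- h$history
  mixed$target_zone[1:4] <- "amygdala"
  g2 <- group_electrodes(mixed)
  tab <- table(mixed$target_zone, mixed$approach)
  for (gr in g2)
    expect_equal(nrow(gr$points), unname(tab[gr$zone, gr$approach]))

  # missing labels are skipped with a warning
  miss <- h$history
  miss$approach[1] <- NA
  expect_warning(g3 <- group_electrodes(miss), miss$electrode_id[1])
  expect_equal(sum(vapply(g3, function(x) nrow(x$points), 1L)),
               2L * (nrow(miss) - 1L))
})

test_that("lesional exclusion filters exactly the flagged electrodes", {
  h <- make_history(history_spec(seed = 8, n_per_zone = 10,
                                 outlier_fraction = 0,
                                 lesional_fraction = 0))$history
  h$lesional <- FALSE
  expect_equal(nrow(exclude_lesional(h)), nrow(h))
  h$lesional <- TRUE
  expect_equal(nrow(exclude_lesional(h)), 0)
  h$lesional <- rep(c(TRUE, FALSE), length.out = nrow(h))
  kept <- exclude_lesional(h)
  expect_equal(nrow(kept), sum(!h$lesional))
  expect_equal(attr(kept, "n_removed"), sum(h$lesional))
})

test_that("outlier exclusion removes a planted far point and is idempotent", {
  set.seed(61)
  cloud <- matrix(rnorm(60 * 3), 60, 3)
  far <- colMeans(cloud) + 10 * apply(cloud, 2, sd) * c(1, 0, 0)
  pts <- rbind(cloud, far)
  ids <- sprintf("p%02d", seq_len(nrow(pts)))
  res <- exclude_outliers(list(points = pts, ids = ids))
  expect_equal(res$excluded_ids, "p61")

  # brute-force leave-one-out Mahalanobis oracle agrees on the first removal
  loo <- vapply(seq_len(nrow(pts)), function(i) {
    rest <- pts[-i, , drop = FALSE]
    sqrt(stats::mahalanobis(pts[i, ], colMeans(rest), stats::cov(rest)))
  }, 0)
  expect_equal(which.max(loo), 61L)
  expect_gt(max(loo), 4)

  # idempotent: a second pass removes nothing
  res2 <- exclude_outliers(list(points = res$kept, ids = res$kept_ids))
  expect_equal(nrow(res2$excluded), 0)

  expect_error(exclude_outliers(matrix(rnorm(12), 4, 3)), "at least 5")
})

test_that("ellipsoid fitting matches the hand-computed box-corner case", {
  a <- 6; b <- 4; c <- 2
  corners <- as.matrix(expand.grid(x = c(-a, a), y = c(-b, b),
                                   z = c(-c, c)))
  ell <- fit_ellipsoid(corners)
  expect_equal(ell$center, c(0, 0, 0))
  expect_equal(abs(ell$axes), diag(3), tolerance = 1e-12)
  # sample covariance of (+/-v)^8 has n-1 = 7 denominator: sd = v*sqrt(8/7)
  expect_equal(ell$semi_axes, c(a, b, c) * sqrt(8 / 7))
  expect_error(fit_ellipsoid(matrix(1, 6, 3)), "rank-deficient")
})

test_that("ellipsoid fitting recovers a known Gaussian and is equivariant", {
  set.seed(62)
  sds <- c(3, 2, 1)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  pts <- matrix(rnorm(3000), 1000, 3) %*% diag(sds) %*% t(R)
  mu <- c(12, -7, 30)
  pts <- sweep(pts, 2, mu, `+`)
  ell <- fit_ellipsoid(pts)
  expect_lt(sqrt(sum((ell$center - mu)^2)), 0.2)
  expect_lt(max(abs(ell$semi_axes - sds) / sds), 0.1)

  # rigid motion: semi-axes invariant, axes rotated
  R2 <- qr.Q(qr(matrix(rnorm(9), 3)))
  moved <- pts %*% t(R2) + rep(1, nrow(pts)) %o% c(-4, 2, 9)
  ell2 <- fit_ellipsoid(moved)
  expect_equal(ell2$semi_axes, ell$semi_axes, tolerance = 1e-9)
  expect_equal(ell2$center, as.numeric(R2 %*% ell$center + c(-4, 2, 9)))
})

test_that("ellipsoid Mahalanobis matches the inverse-covariance form", {
  set.seed(63)
  pts <- matrix(rnorm(900), 300, 3) %*% diag(c(4, 2, 1))
  ell <- fit_ellipsoid(pts)
  expect_equal(mahalanobis_ellipsoid(ell$center, ell), 0)
  shell <- ell$center + ell$semi_axes[1] * ell$axes[, 1]
  expect_equal(mahalanobis_ellipsoid(shell, ell), 1, tolerance = 1e-9)
  mu <- colMeans(pts); S <- stats::cov(pts)
  for (i in 1:20) {
    p <- rnorm(3, sd = 6)
    expect_equal(mahalanobis_ellipsoid(p, ell),
                 sqrt(stats::mahalanobis(p, mu, S)), tolerance = 1e-9)
  }
})

test_that("patient-space transport is affine-consistent", {
  set.seed(64)
  ell <- fit_ellipsoid(matrix(rnorm(300), 100, 3) %*% diag(c(3, 2, 1)))
  idt <- to_patient_space(ell, diag(4))
  expect_equal(idt$center, ell$center)
  expect_equal(idt$semi_axes, ell$semi_axes, tolerance = 1e-9)

  tr <- diag(4); tr[1:3, 4] <- c(5, -3, 8)
  sh <- to_patient_space(ell, tr)
  expect_equal(sh$center, ell$center + c(5, -3, 8))
  expect_equal(sh$semi_axes, ell$semi_axes, tolerance = 1e-9)

  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  rot <- diag(4); rot[1:3, 1:3] <- R
  rr <- to_patient_space(ell, rot)
  expect_equal(rr$semi_axes, ell$semi_axes, tolerance = 1e-8)
  # rotated axes span the same principal directions
  for (j in 1:3)
    expect_equal(abs(sum((R %*% ell$axes[, j]) * rr$axes[, j])), 1,
                 tolerance = 1e-8)

  expect_error(to_patient_space(ell, matrix(0, 4, 4)), "last row|singular")
})

test_that("library construction, QC, and JSON round-trip are stable", {
  hf <- history_fixture()
  lib <- hf$library
  expect_equal(length(lib$ellipsoids), 10)  # 5 zones x entry/target
  expect_equal(length(lib$pairings), 5)
  expect_true(all(lib$qc$status == "ok"))
  for (p in lib$pairings)
    expect_true(all(c(p$target, unlist(p$entries)) %in%
                      names(lib$ellipsoids)))

  # empty input -> empty library
  empty <- build_library(hf$history[0, ])
  expect_equal(length(empty$ellipsoids), 0)
  expect_equal(nrow(empty$qc), 0)

  # rerun with the same inputs -> byte-identical JSON
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_prior_library(lib, f1)
  write_prior_library(build_library(hf$history), f2)
  expect_identical(readLines(f1), readLines(f2))

  # lossless round-trip
  back <- read_prior_library(f1)
  for (nm in names(lib$ellipsoids)) {
    expect_equal(back$ellipsoids[[nm]]$center, lib$ellipsoids[[nm]]$center)
    expect_equal(back$ellipsoids[[nm]]$axes, lib$ellipsoids[[nm]]$axes)
    expect_equal(back$ellipsoids[[nm]]$semi_axes,
                 lib$ellipsoids[[nm]]$semi_axes)
  }
})
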