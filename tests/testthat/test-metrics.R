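test_that("risk score matches the closed-form anchor profiles", {
  expect_identical(risk_score(rep(10, 128)), 0)
  expect_identical(risk_score(rep(3, 128)), 1)
  expect_identical(risk_score(rep(0, 128)), 2)
  expect_equal(risk_score(rep(6.5, 128)), 0.5)
  # distances above d_max are clamped, so the score cannot go negative
  expect_identical(risk_score(rep(25, 128)), 0)
  expect_error(risk_score(numeric(0)), "empty")
})

test_that("mixed profile matches a direct summation of the two-branch formula", {
  f <- c(rep(5, 64), rep(2, 64))
  # independent oracle: accumulate the printed formula term by term
  d_min <- 3; d_max <- 10; N <- length(f)
  oracle <- if (all(f >= d_min)) {
    acc <- 0
    for (fi in pmin(f, d_max)) acc <- acc + (d_max - fi)
    acc / (N * (d_max - d_min))
  } else {
    acc <- 0
    for (fi in pmin(f, d_min)) acc <- acc + (d_min - fi)
    1 + acc / (N * d_min)
  }
  expect_equal(oracle, 1 + 1 / 6)
  expect_equal(risk_score(f), oracle)
})

test_that("risk score is continuous at the branch boundary and monotone", {
  n <- 128
  eps <- 1e-7
  base <- rep(3, n)
  bumped <- base; bumped[1] <- 3 - eps
  expect_equal(risk_score(bumped) - risk_score(base), eps / (n * 3),
               tolerance = 1e-6)

  # pointwise monotonicity: closer profiles never score lower
  set.seed(51)
  for (i in 1:40) {
    a <- runif(n, 0, 12)
    b <- pmax(a - runif(n, 0, 3), 0)
    expect_gte(risk_score(b), risk_score(a) - 1e-12)
  }

  # permutation invariance
  set.seed(52)
  f <- runif(n, 0, 12)
  p <- sample(n)
  expect_equal(risk_score(f[p]), risk_score(f))
  expect_equal(min_vessel_distance(f[p]), min_vessel_distance(f))
})

test_that("intracranial length matches the geometry of a spherical brain", {
  vol <- nested_head()  # gray sphere of radius 50 inside a skull shell
  expect_equal(intracranial_length(trajectory("e", c(0, 0, 80), c(0, 0, 0)),
                                   vol), 50, tolerance = 2)
  # target on the brain surface -> ~0
  expect_equal(intracranial_length(trajectory("e", c(0, 0, 80), c(0, 0, 49.5)),
                                   vol), 0, tolerance = 2)
  # oblique trajectory vs a 0.1 mm ray-march oracle
  set.seed(53)
  for (i in 1:5) {
    u <- runit()
    E <- 78 * u
    Tp <- 10 * runit()
    L <- sqrt(sum((Tp - E)^2))
    s <- seq(0, 1, by = 0.1 / L)
    pts <- outer(1 - s, E) + outer(s, Tp)
    inside <- seegplan:::labels_at(vol, pts) == 4L
    oracle <- (1 - s[which(inside)[1]]) * L
    got <- intracranial_length(trajectory("e", E, Tp), vol)
    expect_equal(got, oracle, tolerance = 2)  # within one voxel
  }
  expect_error(intracranial_length(trajectory("e", c(0, 0, 80), c(0, 0, 70)),
                                   vol), "intracranial")
})

test_that("drilling angle recovers flat-slab and spherical normals", {
  slab <- slab_head()  # outer skull table at z = 28, normal (0,0,1)
  expect_equal(drilling_angle(trajectory("e", c(0, 0, 50), c(0, 0, 0)), slab),
               0, tolerance = 2)
  expect_equal(drilling_angle(trajectory("e", c(-20, 0, 50), c(20, 0, 10)),
                              slab), 45, tolerance = 2)
  sph <- nested_head()
  set.seed(54)
  for (i in 1:5) {
    u <- runit()
    # radial trajectories drill orthogonally into a spherical skull
    expect_equal(drilling_angle(trajectory("e", 78 * u, 5 * u), sph), 0,
                 tolerance = 2)
  }
  expect_error(drilling_angle(trajectory("e", c(0, 0, 100), c(0, 0, 80)),
                              sph), "skull")
})

test_that("gray:white ratio matches a manual node-label count", {
  vol <- nested_head(r = c(scalp = 64, skull = 58, gray = 50, white = 40))
  traj <- trajectory("e", c(0, 0, 70), c(0, 0, 0))
  cfg <- risk_config()
  nodes <- sample_nodes(traj, cfg)
  lab <- seegplan:::labels_at(vol, nodes)
  manual <- sum(lab == 4L) / sum(lab == 5L)
  expect_equal(gm_wm_ratio(traj, vol, cfg), manual)
  # trajectory that never reaches white matter -> undefined
  graze <- trajectory("e", c(0, 60, 70), c(0, 48, 0))
  expect_true(is.na(gm_wm_ratio(graze, vol, cfg)))
})

test_that("metrics_table is deterministic, flags failures, and is consistent", {
  fx <- phantom_fixture()
  expect_equal(nrow(metrics_table(trajectory("x", c(0, 0, 1), c(0, 0, 2))[0, ],
                                  fx$head, fx$vessels)), 0)
  traj <- rbind(
    trajectory("a", c(-76, -8, -18), c(-28, -8, -10), "mesial_temporal_L",
               "lateral"),
    trajectory("b", c(74, -10, -6), c(28, -8, -10), "mesial_temporal_R",
               "lateral"),
    trajectory("outside", c(200, 200, 200), c(210, 210, 210)))
  m1 <- metrics_table(traj, fx$head, fx$vessels)
  m2 <- metrics_table(traj, fx$head, fx$vessels)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 3)
  expect_true(all(!is.na(m1$risk_score[1:2])))
  expect_true(all(m1$risk_score[1:2] >= 0 & m1$risk_score[1:2] <= 2))
  expect_true(all(m1$angle_deg[1:2] >= 0 & m1$angle_deg[1:2] <= 90))
  expect_match(m1$flags[3], "no_intracranial_nodes")

  # profile minimum equals the table's min-distance metric
  prof <- distance_profile(traj[1, ], fx$vessels, brain = fx$head)
  expect_equal(min_vessel_distance(prof), m1$min_dist_mm[1])
  expect_equal(risk_score(prof), m1$risk_score[1])

  # without a brain volume every node participates
  prof_all <- distance_profile(traj[1, ], fx$vessels)
  expect_true(all(prof_all$participating))
})
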