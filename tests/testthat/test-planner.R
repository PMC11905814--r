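make_sphere_ellipsoid <- function(center, r, zone = "z", role = "target",
                                  approach = "a") {
  prior_ellipsoid(zone, role, approach, center, diag(3), rep(r, 3))
}

test_that("candidate lattice respects the ellipsoid shell and symmetry", {
  ent <- make_sphere_ellipsoid(c(0, 0, 60), 4, role = "entry")
  tgt <- make_sphere_ellipsoid(c(0, 0, 0), 4)
  one <- candidate_grid(ent, tgt, resolution = 1)
  expect_equal(nrow(one), 1)
  expect_equal(as.numeric(one[1, c("entry_x_mm", "entry_y_mm", "entry_z_mm")]),
               c(0, 0, 60))
  expect_equal(as.numeric(one[1, c("target_x_mm", "target_y_mm",
                                   "target_z_mm")]), c(0, 0, 0))

  # resolution 3: kept lattice points are exactly those inside the ball
  cand <- candidate_grid(ent, tgt, resolution = 3)
  u <- seq(-1, 1, length.out = 3)
  lattice <- as.matrix(expand.grid(u, u, u))
  n_inside <- sum(rowSums(lattice^2) <= 1)
  expect_equal(n_inside, 7)
  expect_equal(nrow(cand), n_inside^2)
  tp <- unique(cand[, c("target_x_mm", "target_y_mm", "target_z_mm")])
  expect_true(all(mahalanobis_ellipsoid(as.matrix(tp), tgt) <= 1 + 1e-9))

  # swapping entry and target reverses the trajectories
  swapped <- candidate_grid(tgt, ent, resolution = 3)
  expect_setequal(
    paste(swapped$entry_x_mm, swapped$entry_y_mm, swapped$entry_z_mm),
    paste(cand$target_x_mm, cand$target_y_mm, cand$target_z_mm))

  # shrinking the ellipsoid (smaller k) never adds candidates
  small <- make_sphere_ellipsoid(c(0, 0, 0), 4)
  small$semi_axes <- small$semi_axes * 0.5
  small$k_sd <- 0.5
  cs <- candidate_grid(ent, small, resolution = 3)
  expect_lte(nrow(cs), nrow(cand))
  tps <- unique(cs[, c("target_x_mm", "target_y_mm", "target_z_mm")])
  expect_true(all(mahalanobis_ellipsoid(as.matrix(tps), tgt) <= 1 + 1e-9))
})

test_that("feasibility equals brute-force threshold application", {
  fx <- phantom_fixture()
  ent <- make_sphere_ellipsoid(c(-76, -8, -16), 5, role = "entry")
  tgt <- make_sphere_ellipsoid(c(-28, -8, -10), 4)
  cand <- candidate_grid(ent, tgt, resolution = 3)
  cons <- plan_constraints()
  fz <- feasible(cand, fx$head, fx$vessels, cons,
                 backend = "distance_field")
  manual <- !is.na(fz$min_dist_mm) & fz$min_dist_mm >= cons$safety_margin &
    !is.na(fz$angle_deg) & fz$angle_deg <= cons$max_angle &
    !is.na(fz$length_mm) & fz$length_mm <= cons$max_length &
    fz$flags == ""
  expect_equal(fz$feasible, manual)
  expect_true(any(fz$feasible))
  expect_true(all(grepl("safety_margin",
                        fz$violated[!is.na(fz$min_dist_mm) &
                                      fz$min_dist_mm < cons$safety_margin])))
})

test_that("ranking is the lexicographic order with stable ties", {
  m <- data.frame(risk_score = c(0.4, 0.2, 0.2, 0.2),
                  length_mm = c(40, 60, 40, 40),
                  angle_deg = c(5, 5, 10, 10),
                  gm_wm_ratio = c(1, 1, 0.5, NA))
  expect_equal(rank_candidates(m), c(3, 4, 2, 1))

  # exhaustive oracle on a random candidate set
  set.seed(71)
  r <- data.frame(risk_score = sample(seq(0, 1, 0.1), 40, TRUE),
                  length_mm = sample(c(40, 50, 60), 40, TRUE),
                  angle_deg = sample(c(5, 15, 25), 40, TRUE),
                  gm_wm_ratio = sample(c(0.2, 0.5, 1), 40, TRUE))
  ord <- rank_candidates(r)
  # total order: a permutation ...
  expect_setequal(ord, seq_len(40))
  # ... whose head is the brute-force lexicographic minimum
  key <- order(r$risk_score, r$length_mm, r$angle_deg, -r$gm_wm_ratio,
               seq_len(40))
  expect_equal(ord, key)
  # ranking a reordered copy yields the same sequence of metric tuples
  # (ties may resolve to different but metric-equal candidates)
  perm <- sample(40)
  ord2 <- rank_candidates(r[perm, ])
  cols <- c("risk_score", "length_mm", "angle_deg", "gm_wm_ratio")
  expect_equal(r[perm, ][ord2, cols], r[ord, cols],
               ignore_attr = TRUE)
})

test_that("greedy placement enforces constraints, spacing, and determinism", {
  fx <- phantom_fixture()
  hf <- history_fixture()
  req <- data.frame(
    id = c("A", "B"),
    target = c("amygdala/target/lateral",
               "anterior_cingulate/target/superior"),
    entry = c("amygdala/entry/lateral",
              "anterior_cingulate/entry/superior"),
    priority = 1:2)
  plan <- plan_implantation(req, hf$library, diag(4), fx$head, fx$vessels,
                            constraints = plan_constraints(resolution = 3))
  expect_s3_class(plan, "implantation_plan")
  expect_equal(nrow(plan$placements), 2)
  auto <- plan$placements[plan$placements$status == "auto", ]
  expect_gt(nrow(auto), 0)

  # rerun -> identical plan
  plan2 <- plan_implantation(req, hf$library, diag(4), fx$head, fx$vessels,
                             constraints = plan_constraints(resolution = 3))
  expect_identical(plan$placements, plan2$placements)

  # two identical electrodes with an impossible spacing: second goes manual
  req2 <- data.frame(id = c("A1", "A2"),
                     target = rep("amygdala/target/lateral", 2),
                     entry = rep("amygdala/entry/lateral", 2))
  cons2 <- plan_constraints(min_spacing = 100, resolution = 3)
  forced <- plan_implantation(req2, hf$library, diag(4), fx$head, NULL,
                              constraints = cons2)
  expect_equal(forced$placements$status, c("auto", "infeasible->manual"))

  # unknown pairing is rejected before any placement
  bad <- data.frame(id = "X", target = "amygdala/target/lateral",
                    entry = "anterior_insula/entry/superior")
  expect_error(plan_implantation(bad, hf$library, diag(4), fx$head, NULL),
               "admissible pairing")
})

test_that("manual planning rate counts statuses overall and per zone", {
  fx <- phantom_fixture()
  hf <- history_fixture()
  req <- data.frame(id = c("A", "B", "C"),
                    target = c("amygdala/target/lateral",
                               "amygdala/target/lateral",
                               "anterior_cingulate/target/superior"),
                    entry = c("amygdala/entry/lateral",
                              "amygdala/entry/lateral",
                              "anterior_cingulate/entry/superior"))
  plan <- plan_implantation(req, hf$library, diag(4), fx$head, NULL,
                            constraints = plan_constraints(min_spacing = 100,
                                                           resolution = 3))
  mr <- manual_planning_rate(plan)
  expect_equal(mr$overall,
               mean(plan$placements$status == "infeasible->manual"))
  expect_equal(sum(mr$by_zone$n), 3)
  expect_equal(sum(mr$by_zone$n_manual),
               sum(plan$placements$status == "infeasible->manual"))
})
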