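# Prior-constrained planning: candidate trajectories are generated on a
# deterministic lattice inside paired entry/target ellipsoids, filtered by
# hard feasibility constraints (vessel safety margin, drilling angle,
# intracranial length), ranked by safety, and placed greedily in priority
# order under an inter-electrode spacing guarantee. The search is a
# deterministic lattice + lexicographic ranking; the published constraints
# (prior ellipsoids, safety margin) and the primary metric (risk score)
# are what matter, the search strategy is tool design.

#' Candidate trajectories between paired prior ellipsoids
#'
#' Builds a deterministic lattice of `resolution^3` points in each
#' ellipsoid's principal-axis frame, keeps the points inside the stored
#' ellipsoid shell (Mahalanobis membership <= k), and forms the Cartesian
#' product of entry points x target points as candidate trajectories, in
#' deterministic order (entry-major).
#'
#' @param entry,target [prior_ellipsoid()]s in patient space.
#' @param resolution Lattice points per axis (default 5); resolution 1
#'   yields the single center-to-center trajectory.
#' @param id_prefix Prefix for candidate electrode ids.
#' @return Trajectory data frame of candidates.
#' @export
candidate_grid <- function(entry, target, resolution = 5L,
                           id_prefix = "cand") {
  ep <- .ellipsoid_lattice(entry, resolution)
  tp <- .ellipsoid_lattice(target, resolution)
  if (nrow(ep) == 0 || nrow(tp) == 0)
    stop("empty candidate lattice (degenerate ellipsoid)")
  ne <- nrow(ep); nt <- nrow(tp)
  i <- rep(seq_len(ne), each = nt)
  j <- rep(seq_len(nt), times = ne)
  E <- ep[i, , drop = FALSE]
  Tp <- tp[j, , drop = FALSE]
  data.frame(electrode_id = sprintf("%s_%04d", id_prefix, seq_along(i)),
             entry_x_mm = E[, 1], entry_y_mm = E[, 2], entry_z_mm = E[, 3],
             target_x_mm = Tp[, 1], target_y_mm = Tp[, 2],
             target_z_mm = Tp[, 3],
             target_zone = target$zone, approach = target$approach,
             stringsAsFactors = FALSE)
}

# lattice points inside an ellipsoid, in its axis frame; deterministic order
.ellipsoid_lattice <- function(ellipsoid, resolution) {
  resolution <- as.integer(resolution)
  if (resolution < 1L) stop("resolution must be >= 1")
  u <- if (resolution == 1L) 0 else seq(-1, 1, length.out = resolution)
  grid <- as.matrix(expand.grid(u3 = u, u2 = u, u1 = u))[, 3:1, drop = FALSE]
  keep <- rowSums(grid^2) <= 1 + 1e-12
  grid <- grid[keep, , drop = FALSE]
  local <- sweep(grid, 2, ellipsoid$semi_axes, `*`)
  sweep(local %*% t(ellipsoid$axes), 2, ellipsoid$center, `+`)
}

#' Hard feasibility check for candidate trajectories
#'
#' Applies the hard constraints to each trajectory's safety metrics:
#' minimum vessel distance >= `safety_margin`, drilling angle <=
#' `max_angle`, intracranial length <= `max_length`. A metric that could
#' not be computed fails with a named diagnostic rather than aborting.
#'
#' @param trajectories Trajectory data frame.
#' @param parcellation A `label_volume`.
#' @param vessels A [vessel_tree()], `distance_field`, or `NULL`.
#' @param constraints A [plan_constraints()].
#' @param config A [risk_config()].
#' @param backend Vessel-distance backend (see [metrics_table()]).
#' @return The metrics table plus logical `feasible` and character
#'   `violated` columns naming every violated constraint.
#' @export
feasible <- function(trajectories, parcellation, vessels,
                     constraints = plan_constraints(),
                     config = risk_config(),
                     backend = c("polyline", "distance_field")) {
  ctx <- .metrics_context(parcellation, vessels, backend)
  m <- .compute_metrics(trajectories, ctx, config)
  .apply_constraints(m, constraints)
}

.apply_constraints <- function(m, constraints) {
  k <- nrow(m)
  violated <- vector("list", k)
  note <- function(rows, what) for (r in which(rows))
    violated[[r]] <<- c(violated[[r]], what)
  note(is.na(m$min_dist_mm) | m$min_dist_mm < constraints$safety_margin,
       "safety_margin")
  note(is.na(m$angle_deg) | m$angle_deg > constraints$max_angle,
       "max_angle")
  note(is.na(m$length_mm) | m$length_mm > constraints$max_length,
       "max_length")
  note(m$flags != "", "metric_flags")
  m$feasible <- vapply(violated, function(v) length(v) == 0, TRUE)
  m$violated <- vapply(violated, function(v) paste(unique(v), collapse = ";"),
                       "")
  m
}

#' Rank candidate trajectories by safety
#'
#' Lexicographic order: risk score ascending, intracranial length
#' ascending, drilling angle ascending, GM:WM ratio descending
#' (undefined ratios last), original candidate index as the stable
#' tie-break.
#'
#' @param metrics Metrics data frame (one row per candidate).
#' @return Integer permutation ordering the rows best-first.
#' @export
rank_candidates <- function(metrics) {
  if (nrow(metrics) == 0) return(integer(0))
  gm <- metrics$gm_wm_ratio
  gm[is.na(gm)] <- -Inf  # undefined ratio ranks after any defined one
  order(metrics$risk_score, metrics$length_mm, metrics$angle_deg, -gm,
        seq_len(nrow(metrics)), na.last = TRUE)
}

# minimum distance between the intracranial segments of two trajectories;
# ic_s is the entry-crossing parameter (NA -> use the full segment)
.traj_spacing <- function(E1, T1, s1, E2, T2, s2) {
  if (is.na(s1)) s1 <- 0
  if (is.na(s2)) s2 <- 0
  .segment_segment_distance(E1 + s1 * (T1 - E1), T1,
                            E2 + s2 * (T2 - E2), T2)
}

#' Plan a multi-electrode implantation under spatial priors
#'
#' Processes electrode requests in priority order. For each request the
#' paired entry/target ellipsoids are transported to patient space,
#' candidates are generated ([candidate_grid()]), scored, filtered by the
#' hard constraints ([feasible()]), ranked ([rank_candidates()]), and the
#' best-ranked candidate whose minimum intracranial segment-to-segment
#' distance to all previously placed electrodes is at least
#' `constraints$min_spacing` is placed. If no candidate survives, the
#' request is marked `infeasible->manual` and planning continues.
#'
#' @param requests Data frame with columns `id`, `target`, `entry`
#'   (ellipsoid names in the library), and optional `priority` (lower =
#'   planned first; default = row order).
#' @param library A `prior_library` (template space).
#' @param affine 4x4 template-to-patient affine.
#' @param parcellation Patient `label_volume`.
#' @param vessels Patient [vessel_tree()], `distance_field`, or `NULL`.
#' @param config A [risk_config()].
#' @param constraints A [plan_constraints()].
#' @param backend Vessel-distance backend (default `"distance_field"`,
#'   the fast choice for dense candidate grids).
#' @return An object of class `implantation_plan`: the `placements` data
#'   frame (chosen trajectory, metrics, and status per request), the
#'   pairwise spacing matrix of auto-placed electrodes, and a config echo.
#' @export
plan_implantation <- function(requests, library, affine = diag(4),
                              parcellation, vessels,
                              config = risk_config(),
                              constraints = plan_constraints(),
                              backend = c("distance_field", "polyline")) {
  backend <- match.arg(backend)
  .check_affine(affine)
  if (!all(c("id", "target", "entry") %in% names(requests)))
    stop("requests need columns id, target, entry")
  refs <- unique(c(requests$target, requests$entry))
  missing <- setdiff(refs, names(library$ellipsoids))
  if (length(missing) > 0)
    stop(sprintf("request references ellipsoid(s) absent from the library: %s",
                 paste(missing, collapse = ", ")))
  for (r in seq_len(nrow(requests))) {
    ok <- any(vapply(library$pairings, function(p)
      identical(p$target, requests$target[r]) &&
        requests$entry[r] %in% unlist(p$entries), TRUE))
    if (!ok)
      stop(sprintf("request %s: (%s, %s) is not an admissible pairing",
                   requests$id[r], requests$target[r], requests$entry[r]))
  }
  if (is.null(requests$priority)) requests$priority <- seq_len(nrow(requests))
  requests <- requests[order(requests$priority), , drop = FALSE]

  ctx <- .metrics_context(parcellation, vessels, backend)
  placements <- list()
  placed <- list()  # list of list(E, T, s)
  for (r in seq_len(nrow(requests))) {
    ent <- to_patient_space(library$ellipsoids[[requests$entry[r]]], affine)
    tgt <- to_patient_space(library$ellipsoids[[requests$target[r]]], affine)
    cand <- candidate_grid(ent, tgt, constraints$resolution,
                           id_prefix = requests$id[r])
    m <- .apply_constraints(.compute_metrics(cand, ctx, config), constraints)
    ord <- rank_candidates(m)
    chosen <- NA_integer_
    for (i in ord) {
      if (!m$feasible[i]) next
      Ei <- as.numeric(cand[i, c("entry_x_mm", "entry_y_mm", "entry_z_mm")])
      Ti <- as.numeric(cand[i, c("target_x_mm", "target_y_mm", "target_z_mm")])
      ok <- TRUE
      for (p in placed) {
        if (.traj_spacing(Ei, Ti, m$.ic_s[i], p$E, p$T, p$s) <
            constraints$min_spacing) { ok <- FALSE; break }
      }
      if (ok) { chosen <- i; break }
    }
    if (is.na(chosen)) {
      placements[[r]] <- data.frame(
        electrode_id = requests$id[r], target = requests$target[r],
        entry = requests$entry[r], status = "infeasible->manual",
        entry_x_mm = NA_real_, entry_y_mm = NA_real_, entry_z_mm = NA_real_,
        target_x_mm = NA_real_, target_y_mm = NA_real_,
        target_z_mm = NA_real_, target_zone = tgt$zone,
        length_mm = NA_real_, angle_deg = NA_real_, risk_score = NA_real_,
        gm_wm_ratio = NA_real_, min_dist_mm = NA_real_, flags = "",
        stringsAsFactors = FALSE)
    } else {
      Ei <- as.numeric(cand[chosen, c("entry_x_mm", "entry_y_mm", "entry_z_mm")])
      Ti <- as.numeric(cand[chosen, c("target_x_mm", "target_y_mm",
                                      "target_z_mm")])
      placed[[length(placed) + 1L]] <- list(E = Ei, T = Ti,
                                            s = m$.ic_s[chosen])
      placements[[r]] <- data.frame(
        electrode_id = requests$id[r], target = requests$target[r],
        entry = requests$entry[r], status = "auto",
        entry_x_mm = Ei[1], entry_y_mm = Ei[2], entry_z_mm = Ei[3],
        target_x_mm = Ti[1], target_y_mm = Ti[2], target_z_mm = Ti[3],
        target_zone = tgt$zone,
        length_mm = m$length_mm[chosen], angle_deg = m$angle_deg[chosen],
        risk_score = m$risk_score[chosen],
        gm_wm_ratio = m$gm_wm_ratio[chosen],
        min_dist_mm = m$min_dist_mm[chosen], flags = m$flags[chosen],
        stringsAsFactors = FALSE)
    }
  }
  placements <- do.call(rbind, placements)
  auto <- placements[placements$status == "auto", , drop = FALSE]
  spacing <- NULL
  if (nrow(auto) > 1) {
    spacing <- matrix(NA_real_, nrow(auto), nrow(auto),
                      dimnames = list(auto$electrode_id, auto$electrode_id))
    for (i in seq_len(nrow(auto))) for (j in seq_len(nrow(auto))) {
      if (i == j) { spacing[i, j] <- 0; next }
      spacing[i, j] <- .traj_spacing(
        as.numeric(auto[i, c("entry_x_mm", "entry_y_mm", "entry_z_mm")]),
        as.numeric(auto[i, c("target_x_mm", "target_y_mm", "target_z_mm")]),
        placed[[i]]$s,
        as.numeric(auto[j, c("entry_x_mm", "entry_y_mm", "entry_z_mm")]),
        as.numeric(auto[j, c("target_x_mm", "target_y_mm", "target_z_mm")]),
        placed[[j]]$s)
    }
  }
  structure(list(placements = placements, spacing = spacing,
                 constraints = constraints, config = config,
                 backend = backend),
            class = "implantation_plan")
}

#' @export
print.implantation_plan <- function(x, ...) {
  n <- nrow(x$placements)
  na <- sum(x$placements$status == "auto")
  cat(sprintf("implantation_plan: %d electrode(s), %d auto, %d manual\n",
              n, na, n - na))
  invisible(x)
}

#' Manual planning rate of one or more implantation plans
#'
#' The fraction of requested electrodes for which no feasible automated
#' candidate existed (`status == "infeasible->manual"`), overall and per
#' target zone.
#'
#' @param plans An `implantation_plan` or list of them.
#' @return List with `overall` (proportion) and `by_zone` (data frame
#'   with n, n_manual, proportion per target zone).
#' @export
manual_planning_rate <- function(plans) {
  if (inherits(plans, "implantation_plan")) plans <- list(plans)
  if (length(plans) == 0) stop("manual_planning_rate: no plans supplied")
  pl <- do.call(rbind, lapply(plans, function(p) p$placements))
  manual <- pl$status == "infeasible->manual"
  by_zone <- do.call(rbind, lapply(split(manual, pl$target_zone), function(v)
    data.frame(n = length(v), n_manual = sum(v),
               proportion = mean(v))))
  by_zone <- data.frame(target_zone = rownames(by_zone), by_zone,
                        row.names = NULL, stringsAsFactors = FALSE)
  list(overall = mean(manual), by_zone = by_zone)
}
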