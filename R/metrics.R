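# Per-electrode safety metrics. The primary one is the vessel-proximity
# risk score R over the trajectory ET:
#
#   R = sum(d_max - f_i) / (N * (d_max - d_min))          if all f_i >= d_min
#   R = 1 + sum(d_min - f'_i) / (N * d_min)               otherwise
#
# where f_i are the vessel distances at N evenly spaced nodes (clamped
# above at d_max so the first branch stays in [0, 1]) and f'_i = min(f_i,
# d_min) is the capped distance. R is in [0, 1] while every node keeps the
# safety margin and in (1, 2] once any node breaches it; lower is safer.
# When a parcellation is supplied, only intracranial nodes participate and
# N is the participating count.

#' Vessel distance profile along a trajectory
#'
#' Samples `config$n_nodes` evenly spaced nodes along the trajectory and
#' measures the shortest distance from each node to the vessel surface,
#' through either the exact polyline backend or an interpolated distance
#' field. If a parcellation is supplied, nodes outside the intracranial
#' space are flagged as non-participating (vessel models are intracranial,
#' so extracranial nodes would dilute the risk score).
#'
#' @param traj A one-row trajectory data frame.
#' @param vessels A [vessel_tree()], a `distance_field`, or `NULL` for
#'   avascular evaluation (all distances `Inf`).
#' @param config A [risk_config()].
#' @param brain Optional `label_volume`; restricts participation to
#'   intracranial nodes.
#' @return An object of class `distance_profile`: node distances (mm),
#'   the node points, and the participation flags.
#' @export
distance_profile <- function(traj, vessels, config = risk_config(),
                             brain = NULL) {
  nodes <- sample_nodes(traj, config)
  d <- .node_distances(nodes, vessels)
  part <- rep(TRUE, nrow(nodes))
  if (!is.null(brain)) {
    lab <- labels_at(brain, nodes)
    part <- lab %in% .class_ids(brain, .INTRACRANIAL_CLASSES)
  }
  structure(list(distances = d, nodes = nodes, participating = part,
                 config = config),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("distance_profile: %d nodes (%d participating), min %.3g mm\n",
              length(x$distances), sum(x$participating),
              suppressWarnings(min(x$distances[x$participating]))))
  invisible(x)
}

.node_distances <- function(pts, vessels) {
  if (is.null(vessels)) return(rep(Inf, nrow(pts)))
  if (inherits(vessels, "distance_field")) return(field_at(vessels, pts))
  if (inherits(vessels, "vessel_tree"))
    return(vessel_distance_polyline(pts, vessels))
  stop("vessels must be a vessel_tree, a distance_field, or NULL")
}

#' Vessel-proximity risk score
#'
#' Two-branch normalised score in \[0, 2\] (see the package overview and
#' the methods vignette): 0 means every node is at least `d_max` from the
#' nearest vessel, 1 means every node sits exactly at the safety margin
#' `d_min`, 2 means the trajectory touches vessels at every node.
#'
#' @param profile A [distance_profile()] or a bare numeric vector of node
#'   distances in mm (all participating).
#' @param config A [risk_config()]; defaults to the profile's own config
#'   when a profile object is given.
#' @return Numeric score in \[0, 2\].
#' @export
#' @examples
#' risk_score(rep(10, 128))  # 0
#' risk_score(rep(3, 128))   # 1
#' risk_score(rep(0, 128))   # 2
risk_score <- function(profile, config = NULL) {
  if (inherits(profile, "distance_profile")) {
    if (is.null(config)) config <- profile$config
    f <- profile$distances[profile$participating]
  } else {
    if (is.null(config)) config <- risk_config()
    f <- as.numeric(profile)
  }
  if (length(f) == 0) stop("risk_score: empty distance profile")
  if (any(is.na(f)) || any(f < 0))
    stop("risk_score: distances must be non-negative (NA not allowed)")
  .risk_from_distances(f, config$d_min, config$d_max)
}

.risk_from_distances <- function(f, d_min, d_max) {
  n <- length(f)
  if (all(f >= d_min)) {
    fcap <- pmin(f, d_max)
    sum(d_max - fcap) / (n * (d_max - d_min))
  } else {
    fprime <- pmin(f, d_min)
    1 + sum(d_min - fprime) / (n * d_min)
  }
}

#' Minimum vessel distance of a profile
#'
#' The minimum of the un-clamped participating node distances.
#'
#' @param profile A [distance_profile()] or numeric vector.
#' @return Minimum distance in mm.
#' @export
min_vessel_distance <- function(profile) {
  f <- if (inherits(profile, "distance_profile"))
    profile$distances[profile$participating] else as.numeric(profile)
  if (length(f) == 0) stop("min_vessel_distance: empty distance profile")
  min(f)
}

## ---- batched metric engine --------------------------------------------

# A metrics context bundles everything the per-electrode metrics need:
# the parcellation, the vessel backend, and the smoothed inner-skull level
# set whose gradient supplies drilling normals.
.metrics_context <- function(parcellation = NULL, vessels = NULL,
                             backend = c("polyline", "distance_field")) {
  backend <- match.arg(backend)
  field <- NULL
  if (inherits(vessels, "distance_field")) {
    field <- vessels
    backend <- "distance_field"
    vessels_tree <- NULL
  } else {
    vessels_tree <- vessels
    if (!is.null(vessels) && backend == "distance_field") {
      if (is.null(parcellation))
        stop("distance_field backend needs a parcellation grid")
      field <- vessel_distance_field(vessels, parcellation)
    }
  }
  ctx <- list(vol = parcellation, backend = backend,
              vessels = vessels_tree, field = field,
              skull_smooth = NULL,
              ic_ids = NULL, skull_ids = NULL,
              gray_ids = NULL, white_ids = NULL)
  if (!is.null(parcellation)) {
    ctx$ic_ids <- .class_ids(parcellation, .INTRACRANIAL_CLASSES)
    ctx$skull_ids <- .class_ids(parcellation, .SKULL_IN_CLASSES)
    ctx$gray_ids <- .class_ids(parcellation, "gray")
    ctx$white_ids <- .class_ids(parcellation, "white")
    inmask <- array(0, dim(parcellation$data))
    inmask[parcellation$data %in% ctx$skull_ids] <- 1
    ctx$skull_smooth <- .smooth3d(inmask, sigma = 2.5)
  }
  ctx
}

.ctx_distances <- function(ctx, pts) {
  if (ctx$backend == "distance_field" && !is.null(ctx$field))
    field_at(ctx$field, pts)
  else
    .node_distances(pts, ctx$vessels)
}

# vectorised bisection for the crossing of each ray E->T with a label-class
# mask, between per-row params lo (outside) and hi (inside); returns hi
.bisect_crossing <- function(E, Tp, lo, hi, vol, ids, iters = 40L) {
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pts <- E * (1 - mid) + Tp * mid
    inside <- labels_at(vol, pts) %in% ids
    hi[inside] <- mid[inside]
    lo[!inside] <- mid[!inside]
  }
  hi
}

# core batched computation; returns the metrics data frame with hidden
# helper columns .ic_s (intracranial crossing parameter) for spacing clips
.compute_metrics <- function(traj, ctx, config = risk_config()) {
  traj <- .as_traj_table(traj)
  k <- nrow(traj)
  empty <- data.frame(electrode_id = character(0), length_mm = numeric(0),
                      angle_deg = numeric(0), risk_score = numeric(0),
                      gm_wm_ratio = numeric(0), min_dist_mm = numeric(0),
                      n_participating = integer(0), flags = character(0),
                      .ic_s = numeric(0), stringsAsFactors = FALSE)
  if (k == 0) return(empty)
  E <- .entry_matrix(traj)
  Tp <- .target_matrix(traj)
  L <- sqrt(rowSums((Tp - E)^2))
  n <- config$n_nodes
  flags <- vector("list", k)
  add_flag <- function(rows, f) for (r in which(rows))
    flags[[r]] <<- c(flags[[r]], f)

  degenerate <- L == 0
  add_flag(degenerate, "degenerate_trajectory")

  P <- .batch_nodes(E, Tp, n)
  Fd <- matrix(.ctx_distances(ctx, P), nrow = n, ncol = k)

  if (!is.null(ctx$vol)) {
    lab <- matrix(labels_at(ctx$vol, P), nrow = n, ncol = k)
    ic <- matrix(lab %in% ctx$ic_ids, nrow = n, ncol = k)
    sk <- matrix(lab %in% ctx$skull_ids, nrow = n, ncol = k)
    gray <- matrix(lab %in% ctx$gray_ids, nrow = n, ncol = k)
    white <- matrix(lab %in% ctx$white_ids, nrow = n, ncol = k)
  } else {
    ic <- matrix(TRUE, nrow = n, ncol = k)
  }

  npart <- colSums(ic)
  no_ic <- npart == 0 & !degenerate
  add_flag(no_ic, "no_intracranial_nodes")

  risk <- rep(NA_real_, k)
  mind <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    if (degenerate[j] || npart[j] == 0) next
    fj <- Fd[ic[, j], j]
    risk[j] <- .risk_from_distances(fj, config$d_min, config$d_max)
    mind[j] <- min(fj)
  }

  gmwm <- rep(NA_real_, k)
  len <- rep(NA_real_, k)
  ang <- rep(NA_real_, k)
  ic_s <- rep(NA_real_, k)

  if (!is.null(ctx$vol)) {
    ngray <- colSums(gray & ic)
    nwhite <- colSums(white & ic)
    gmwm <- ifelse(nwhite > 0, ngray / nwhite, NA_real_)
    add_flag(nwhite == 0 & !degenerate & !no_ic, "gm_wm_undefined")

    s <- seq(0, 1, length.out = n)
    # intracranial entry crossing
    j0 <- apply(ic, 2, function(col) if (any(col)) which(col)[1] else NA_integer_)
    has_ic <- !is.na(j0) & !degenerate
    cpar <- rep(NA_real_, k)
    cpar[has_ic & j0 == 1] <- 0
    needs <- has_ic & j0 > 1
    if (any(needs)) {
      idx <- which(needs)
      cpar[idx] <- .bisect_crossing(E[idx, , drop = FALSE],
                                    Tp[idx, , drop = FALSE],
                                    s[j0[idx] - 1L], s[j0[idx]],
                                    ctx$vol, ctx$ic_ids)
    }
    len <- (1 - cpar) * L
    ic_s <- cpar

    # outer-skull crossing and drilling angle
    j0s <- apply(sk, 2, function(col) if (any(col)) which(col)[1] else NA_integer_)
    crossed <- !is.na(j0s) & !degenerate & j0s > 1
    add_flag((is.na(j0s) | j0s == 1) & !degenerate, "no_skull_crossing")
    if (any(crossed)) {
      idx <- which(crossed)
      spar <- .bisect_crossing(E[idx, , drop = FALSE],
                               Tp[idx, , drop = FALSE],
                               s[j0s[idx] - 1L], s[j0s[idx]],
                               ctx$vol, ctx$skull_ids)
      S <- E[idx, , drop = FALSE] * (1 - spar) + Tp[idx, , drop = FALSE] * spar
      normal <- .level_set_normal(ctx, S)
      dirs <- (Tp[idx, , drop = FALSE] - E[idx, , drop = FALSE]) / L[idx]
      cosang <- abs(rowSums(dirs * normal))
      bad <- is.na(cosang)
      add_flag(seq_len(k) %in% idx[bad], "flat_skull_gradient")
      ang[idx] <- acos(pmin(1, cosang)) * 180 / pi
    }
  }

  data.frame(electrode_id = traj$electrode_id,
             length_mm = len, angle_deg = ang, risk_score = risk,
             gm_wm_ratio = gmwm, min_dist_mm = mind,
             n_participating = as.integer(npart),
             flags = vapply(flags, function(f)
               paste(unique(f), collapse = ";"), ""),
             .ic_s = ic_s,
             stringsAsFactors = FALSE, row.names = NULL)
}

# outward unit normal of the smoothed inner-skull level set at world
# points (rows of S); the smoothed mask decreases outward so the outward
# normal is minus the normalised gradient
.level_set_normal <- function(ctx, S) {
  delta <- 0.5 * min(voxel_spacing(ctx$vol))
  g <- matrix(0, nrow(S), 3)
  for (axis in 1:3) {
    e <- c(0, 0, 0); e[axis] <- delta
    up <- .trilinear(ctx$skull_smooth,
                     world_to_voxel(ctx$vol, sweep(S, 2, e, `+`)))
    dn <- .trilinear(ctx$skull_smooth,
                     world_to_voxel(ctx$vol, sweep(S, 2, e, `-`)))
    g[, axis] <- (up - dn) / (2 * delta)
  }
  nrm <- sqrt(rowSums(g * g))
  out <- -g / nrm
  out[nrm < 1e-9, ] <- NA_real_
  out
}

#' Per-electrode safety metrics table
#'
#' Computes, for every trajectory, the five safety metrics: intracranial
#' length (mm), drilling angle to the outer skull table (degrees, 0 =
#' orthogonal), vessel-proximity risk score, gray:white matter sampling
#' ratio over the risk nodes, and minimum vessel distance (mm).
#' Per-electrode problems (degenerate trajectory, no intracranial nodes,
#' no skull crossing, undefined GM:WM ratio) are recorded in a `flags`
#' column rather than aborting the table.
#'
#' @param trajectories Trajectory data frame (one row per electrode).
#' @param parcellation A `label_volume`, or `NULL` (length/angle/GM:WM
#'   then unavailable).
#' @param vessels A [vessel_tree()], `distance_field`, or `NULL`.
#' @param config A [risk_config()].
#' @param backend `"polyline"` (exact) or `"distance_field"` (interpolated,
#'   fast for dense candidate grids).
#' @return Data frame with one row per electrode and columns
#'   `electrode_id`, `length_mm`, `angle_deg`, `risk_score`,
#'   `gm_wm_ratio`, `min_dist_mm`, `n_participating`, `flags`.
#' @export
metrics_table <- function(trajectories, parcellation = NULL, vessels = NULL,
                          config = risk_config(),
                          backend = c("polyline", "distance_field")) {
  ctx <- .metrics_context(parcellation, vessels, backend)
  out <- .compute_metrics(trajectories, ctx, config)
  out$.ic_s <- NULL
  out
}

#' Intracranial length of a trajectory
#'
#' Distance in mm from the first intersection of the entry-to-target ray
#' with the intracranial space to the target point.
#'
#' @param traj One-row trajectory data frame.
#' @param parcellation A `label_volume`.
#' @param config A [risk_config()] (controls ray sampling density).
#' @return Length in mm.
#' @export
intracranial_length <- function(traj, parcellation, config = risk_config()) {
  ctx <- .metrics_context(parcellation, NULL)
  m <- .compute_metrics(traj, ctx, config)
  if (grepl("no_intracranial_nodes|degenerate", m$flags[1]))
    stop("trajectory never enters the intracranial space")
  m$length_mm[1]
}

#' Drilling angle to the outer skull table
#'
#' Angle in degrees between the trajectory direction and the outward
#' skull-surface normal at the skull-entry point; 0 is perfectly
#' orthogonal drilling. The normal is the gradient of a Gaussian-smoothed
#' skull-mask level set.
#'
#' @inheritParams intracranial_length
#' @return Angle in degrees, in \[0, 90\].
#' @export
drilling_angle <- function(traj, parcellation, config = risk_config()) {
  ctx <- .metrics_context(parcellation, NULL)
  m <- .compute_metrics(traj, ctx, config)
  if (is.na(m$angle_deg[1]))
    stop("trajectory does not cross the outer skull surface")
  m$angle_deg[1]
}

#' Gray:white matter sampling ratio
#'
#' Count of intracranial risk nodes in gray matter divided by the count in
#' white matter; `NA` (undefined) when no node falls in white matter.
#'
#' @inheritParams intracranial_length
#' @return Ratio (dimensionless) or `NA`.
#' @export
gm_wm_ratio <- function(traj, parcellation, config = risk_config()) {
  ctx <- .metrics_context(parcellation, NULL)
  .compute_metrics(traj, ctx, config)$gm_wm_ratio[1]
}

#' Write a metrics table as CSV
#'
#' @param metrics Data frame from [metrics_table()].
#' @param path Output path.
#' @export
write_metrics_csv <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE, na = "")
  invisible(path)
}
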