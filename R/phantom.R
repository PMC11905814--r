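# Seeded synthetic head phantoms: concentric perturbed-ellipsoid tissue
# shells (scalp/skull/CSF/gray/white) with deep ellipsoidal target
# structures, branching intracranial vessel trees, and synthetic
# implantation histories drawn from known Gaussians. Everything any other
# module needs is generated here, deterministically per seed, so the full
# build-priors -> plan -> score chain runs without any download.

# named per-component substream so changing one component's draw count
# does not perturb the others
.substream <- function(seed, name) {
  (as.integer(seed) + sum(utf8ToInt(name)) * 10007L) %% 2147483647L
}

#' Specification of a synthetic head phantom
#'
#' @param seed Integer seed fixing every stochastic draw.
#' @param dim Grid shape (default 96^3 voxels).
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @param radii Named outer radii (mm) of the nested shells; must be
#'   strictly decreasing scalp > skull > csf > gray > white.
#' @param axis_scale Per-axis scale factors making the head ellipsoidal.
#' @param gyral_amp Amplitude (mm) of the angular perturbation applied to
#'   the cortical boundaries to emulate gyri.
#' @param gyral_freq Angular frequency of the perturbation.
#' @param targets Data frame of deep target structures: `name`,
#'   `cx, cy, cz` (world mm), `rx, ry, rz` (semi-axes mm).
#' @param n_roots,branch_depth,step_mm,radius0_mm,radius_decay,jitter
#'   Vessel-tree parameters: number of cortical root branches, branching
#'   depth, polyline step length, root radius, per-level radius decay,
#'   and direction jitter (0--1).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 17L,
                         dim = c(96L, 96L, 96L),
                         voxel_mm = 2,
                         radii = c(scalp = 88, skull = 80, csf = 74,
                                   gray = 70, white = 60),
                         axis_scale = c(0.9, 1.0, 0.85),
                         gyral_amp = 3, gyral_freq = 8,
                         targets = NULL,
                         n_roots = 12L, branch_depth = 3L, step_mm = 5,
                         radius0_mm = 1.5, radius_decay = 0.7,
                         jitter = 0.25) {
  if (is.null(targets))
    targets <- data.frame(
      name = c("mesial_temporal_L", "mesial_temporal_R"),
      cx = c(-28, 28), cy = c(-8, -8), cz = c(-10, -10),
      rx = c(14, 14), ry = c(7, 7), rz = c(7, 7),
      stringsAsFactors = FALSE)
  need <- c("scalp", "skull", "csf", "gray", "white")
  if (!all(need %in% names(radii)))
    stop("radii must name scalp, skull, csf, gray, white")
  r <- radii[need]
  if (any(diff(r) >= 0))
    stop("shell radii must be strictly nested (scalp > skull > csf > gray > white)")
  structure(list(seed = as.integer(seed), dim = as.integer(dim),
                 voxel_mm = as.numeric(voxel_mm), radii = r,
                 axis_scale = as.numeric(axis_scale),
                 gyral_amp = gyral_amp, gyral_freq = gyral_freq,
                 targets = targets,
                 n_roots = as.integer(n_roots),
                 branch_depth = as.integer(branch_depth),
                 step_mm = step_mm, radius0_mm = radius0_mm,
                 radius_decay = radius_decay, jitter = jitter),
            class = "phantom_spec")
}

# centered voxel-to-world affine of a phantom grid
.phantom_affine <- function(dim, voxel_mm) {
  A <- diag(c(rep(voxel_mm, 3), 1))
  A[1:3, 4] <- -voxel_mm * (dim - 1) / 2
  A
}

# scaled radius and angular coordinates of world points
.head_coords <- function(pts, spec) {
  sc <- sweep(pts, 2, spec$axis_scale, `/`)
  r <- sqrt(rowSums(sc^2))
  theta <- acos(ifelse(r > 0, sc[, 3] / r, 1))
  phi <- atan2(sc[, 2], sc[, 1])
  list(r = r, theta = theta, phi = phi)
}

.gyral_shift <- function(theta, phi, spec, phase) {
  spec$gyral_amp * sin(spec$gyral_freq * theta + phase[1]) *
    cos(spec$gyral_freq * phi + phase[2])
}

#' Generate a synthetic head label volume
#'
#' Concentric perturbed-ellipsoid shells labelled scalp(1) / skull(2) /
#' CSF(3) / gray(4) / white(5) plus deep ellipsoidal target structures
#' (labels 6, 7, ...; class `"structure"`). The gray/white and CSF/gray
#' boundaries share a smooth angular perturbation that emulates gyral
#' folding. Deterministic per seed.
#'
#' @param spec A [phantom_spec()].
#' @return A `label_volume`.
#' @export
make_head_phantom <- function(spec = phantom_spec()) {
  set.seed(.substream(spec$seed, "head"))
  phase <- runif(2, 0, 2 * pi)
  dm <- spec$dim
  A <- .phantom_affine(dm, spec$voxel_mm)
  i <- seq(0, dm[1] - 1); j <- seq(0, dm[2] - 1); k <- seq(0, dm[3] - 1)
  w1 <- A[1, 1] * i + A[1, 4]
  w2 <- A[2, 2] * j + A[2, 4]
  w3 <- A[3, 3] * k + A[3, 4]
  pts <- cbind(rep(w1, times = dm[2] * dm[3]),
               rep(rep(w2, each = dm[1]), times = dm[3]),
               rep(w3, each = dm[1] * dm[2]))
  hc <- .head_coords(pts, spec)
  h <- .gyral_shift(hc$theta, hc$phi, spec, phase)
  r <- hc$r
  rad <- spec$radii
  lab <- integer(nrow(pts))
  lab[r <= rad["scalp"]] <- 1L
  lab[r <= rad["skull"]] <- 2L
  lab[r <= rad["csf"]] <- 3L
  lab[r <= rad["gray"] + h] <- 4L
  lab[r <= rad["white"] + h] <- 5L
  labmap <- data.frame(id = 1:5,
                       name = c("scalp", "skull", "csf", "gray", "white"),
                       class = c("scalp", "skull", "csf", "gray", "white"),
                       stringsAsFactors = FALSE)
  for (t in seq_len(nrow(spec$targets))) {
    tg <- spec$targets[t, ]
    q <- ((pts[, 1] - tg$cx) / tg$rx)^2 + ((pts[, 2] - tg$cy) / tg$ry)^2 +
      ((pts[, 3] - tg$cz) / tg$rz)^2
    inside <- q <= 1 & lab == 5L  # structures live in white matter
    lab[inside] <- 5L + t
    labmap <- rbind(labmap, data.frame(id = 5L + t, name = tg$name,
                                       class = "structure",
                                       stringsAsFactors = FALSE))
  }
  label_volume(array(lab, dm), A, labmap)
}

# rotate v toward u by mixing and renormalising
.unit <- function(v) v / sqrt(sum(v^2))

#' Generate a branching intracranial vessel tree on a head phantom
#'
#' Root branches start just inside the cortical surface and grow inward
#' with bounded direction jitter; each branch spawns two children with
#' decayed radius until `branch_depth` is exhausted. Branches stop (clip)
#' before leaving the intracranial space, so every vertex is
#' intracranial. Deterministic per seed.
#'
#' @param spec A [phantom_spec()].
#' @param head The matching `label_volume` from [make_head_phantom()]
#'   (used for bounds checks).
#' @return A [vessel_tree()].
#' @export
make_vessel_tree <- function(spec = phantom_spec(), head = NULL) {
  set.seed(.substream(spec$seed, "vessels"))
  rad <- spec$radii
  r_start <- rad["gray"] - 2
  r_stop <- 18
  r_max <- rad["csf"] - 1
  polylines <- list()
  grow <- function(start, dir, radius, depth, steps) {
    pts <- matrix(start, nrow = 1)
    pos <- start
    d <- dir
    for (s in seq_len(steps)) {
      jit <- .unit(rnorm(3))
      inward <- -.unit(pos / spec$axis_scale)
      d <- .unit((1 - spec$jitter) * d + spec$jitter * jit + 0.2 * inward)
      cand <- pos + spec$step_mm * d
      rc <- sqrt(sum((cand / spec$axis_scale)^2))
      if (rc >= r_max || rc <= r_stop) break
      pos <- cand
      pts <- rbind(pts, pos)
    }
    if (nrow(pts) >= 2)
      polylines[[length(polylines) + 1L]] <<-
        list(points = pts, radii_mm = rep(radius, nrow(pts)))
    if (depth > 0 && nrow(pts) >= 2) {
      for (b in 1:2) {
        nd <- .unit(d + 0.6 * .unit(rnorm(3)))
        grow(pos, nd, radius * spec$radius_decay, depth - 1, steps)
      }
    }
  }
  for (root in seq_len(spec$n_roots)) {
    u <- .unit(rnorm(3))
    start <- r_start * (u * spec$axis_scale)
    grow(start, -.unit(start / spec$axis_scale), spec$radius0_mm,
         spec$branch_depth, steps = 5L)
  }
  vessel_tree(polylines)
}

#' Specification of a synthetic implantation history
#'
#' Each zone has a true entry Gaussian and a true target Gaussian in
#' template space; electrodes are drawn from them, a stated fraction is
#' displaced far out (outliers), and a stated fraction is flagged
#' lesional. Defaults follow the synthetic recovery conditions: 5 zones,
#' 200 electrodes per zone, 10% outliers displaced by 10 SD, 5% lesional.
#'
#' @param seed Integer seed.
#' @param zones List of zone definitions; each a list with `name`,
#'   `approach`, `target_mean`, `target_cov`, `entry_mean`, `entry_cov`.
#'   `NULL` builds the default 5-zone set.
#' @param n_per_zone Electrodes drawn per zone (default 200).
#' @param outlier_fraction Fraction displaced as outliers (default 0.1).
#' @param outlier_sd Displacement magnitude in Mahalanobis SD units
#'   (default 10).
#' @param lesional_fraction Fraction flagged lesional (default 0.05;
#'   disjoint from the outliers).
#' @return An object of class `history_spec`.
#' @export
history_spec <- function(seed = 202L, zones = NULL, n_per_zone = 200L,
                         outlier_fraction = 0.1, outlier_sd = 10,
                         lesional_fraction = 0.05) {
  if (any(c(outlier_fraction, lesional_fraction) < 0) ||
      any(c(outlier_fraction, lesional_fraction) > 1) ||
      outlier_fraction + lesional_fraction > 1)
    stop("fractions must lie in [0, 1] and sum to at most 1")
  if (is.null(zones)) zones <- .default_zones(seed)
  for (z in zones) {
    for (S in list(z$target_cov, z$entry_cov)) {
      if (max(abs(S - t(S))) > 1e-9 || any(eigen(S, TRUE)$values <= 0))
        stop(sprintf("zone %s: covariance must be symmetric positive-definite",
                     z$name))
    }
  }
  structure(list(seed = as.integer(seed), zones = zones,
                 n_per_zone = as.integer(n_per_zone),
                 outlier_fraction = outlier_fraction,
                 outlier_sd = outlier_sd,
                 lesional_fraction = lesional_fraction),
            class = "history_spec")
}

# default zones: realistic template-space targets with entries near the
# head surface; SDs of a few mm as seen in clinical prior ellipsoids
.default_zones <- function(seed) {
  set.seed(.substream(seed, "zones"))
  defs <- list(
    list(name = "amygdala", approach = "lateral",
         tm = c(-24, -6, -18), em = c(-80, -6, -14)),
    list(name = "anterior_hippocampus", approach = "lateral",
         tm = c(-28, -16, -14), em = c(-82, -16, -8)),
    list(name = "posterior_hippocampus", approach = "lateral",
         tm = c(-30, -30, -6), em = c(-82, -32, 0)),
    list(name = "anterior_insula", approach = "superior",
         tm = c(-34, 12, 6), em = c(-30, 24, 74)),
    list(name = "anterior_cingulate", approach = "superior",
         tm = c(-8, 24, 24), em = c(-22, 28, 72)))
  lapply(defs, function(d) {
    Rt <- qr.Q(qr(matrix(rnorm(9), 3)))
    Re <- qr.Q(qr(matrix(rnorm(9), 3)))
    list(name = d$name, approach = d$approach,
         target_mean = d$tm,
         target_cov = Rt %*% diag(c(2, 1.5, 1)^2) %*% t(Rt),
         entry_mean = d$em,
         entry_cov = Re %*% diag(c(2.5, 2, 1.5)^2) %*% t(Re))
  })
}

# draw n samples from N(mu, Sigma)
.rmvnorm <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  matrix(rnorm(n * 3), n, 3) %*% L + rep(1, n) %o% mu
}

#' Generate a synthetic labelled implantation history
#'
#' Draws entry/target points per zone from the true Gaussians, displaces
#' the outlier fraction by `outlier_sd` Mahalanobis units along a random
#' direction (both endpoints), flags the lesional fraction, and returns
#' both the history table and a ground-truth record for recovery tests.
#'
#' @param spec A [history_spec()].
#' @return List with `history` (trajectory data frame + `lesional` column)
#'   and `truth` (true means/covariances, outlier ids, lesional ids per
#'   zone).
#' @export
make_history <- function(spec = history_spec()) {
  set.seed(.substream(spec$seed, "history"))
  rows <- list()
  truth <- list()
  for (z in spec$zones) {
    n <- spec$n_per_zone
    ids <- sprintf("%s_%03d", z$name, seq_len(n))
    tg <- .rmvnorm(n, z$target_mean, z$target_cov)
    en <- .rmvnorm(n, z$entry_mean, z$entry_cov)
    n_out <- round(spec$outlier_fraction * n)
    n_les <- round(spec$lesional_fraction * n)
    pick <- sample.int(n, n_out + n_les)
    out_i <- pick[seq_len(n_out)]
    les_i <- pick[n_out + seq_len(n_les)]
    for (i in out_i) {
      u <- .unit(rnorm(3))
      tg[i, ] <- tg[i, ] + spec$outlier_sd *
        sqrt(drop(t(u) %*% z$target_cov %*% u)) * u
      v <- .unit(rnorm(3))
      en[i, ] <- en[i, ] + spec$outlier_sd *
        sqrt(drop(t(v) %*% z$entry_cov %*% v)) * v
    }
    lesional <- rep(FALSE, n)
    lesional[les_i] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      electrode_id = ids,
      entry_x_mm = en[, 1], entry_y_mm = en[, 2], entry_z_mm = en[, 3],
      target_x_mm = tg[, 1], target_y_mm = tg[, 2], target_z_mm = tg[, 3],
      target_zone = z$name, approach = z$approach, lesional = lesional,
      stringsAsFactors = FALSE)
    truth[[z$name]] <- list(zone = z$name, approach = z$approach,
                            target_mean = z$target_mean,
                            target_cov = z$target_cov,
                            entry_mean = z$entry_mean,
                            entry_cov = z$entry_cov,
                            outlier_ids = ids[sort(out_i)],
                            lesional_ids = ids[sort(les_i)])
  }
  list(history = do.call(rbind, rows), truth = truth)
}

#' Write / read a history table as CSV
#'
#' Trajectory CSV columns plus `lesional` (0/1), `target_zone`, `approach`.
#'
#' @param history History data frame.
#' @param path File path.
#' @export
write_history_csv <- function(history, path) {
  out <- history
  out$lesional <- as.integer(out$lesional)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_history_csv
#' @export
read_history_csv <- function(path) {
  h <- read.csv(path, stringsAsFactors = FALSE)
  h <- .as_traj_table(h)
  if (!is.null(h$lesional)) h$lesional <- as.logical(h$lesional)
  h
}
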