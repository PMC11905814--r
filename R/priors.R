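# Spatial priors: ellipsoidal entry and target zones summarising where
# previous electrodes of a given clinical class were placed, in template
# space (MNI-152 ICBM 2009a nonlinear asymmetric). Each zone is modelled
# as a multivariate Gaussian: the ellipsoid is centered at the group mean
# with axes along the principal directions of variance and semi-axis
# lengths of k standard deviations (k = 1 by default; k ~ 2.8 would cover
# 95% trivariate mass).

.TEMPLATE_SPACE <- "MNI152-ICBM2009a-nlin-asym"
.MIN_GROUP <- 5L

#' Construct a prior ellipsoid
#'
#' @param zone Target-zone name (e.g. `"anterior_cingulate"`).
#' @param role `"entry"` or `"target"`.
#' @param approach Approach label (e.g. `"superior"`).
#' @param center Length-3 center in template mm.
#' @param axes 3x3 matrix whose *columns* are orthonormal principal
#'   directions, sorted by descending variance.
#' @param semi_axes Length-3 positive semi-axis lengths in mm
#'   (k standard deviations along each axis).
#' @param k_sd Scale k applied to the 1-SD lengths (default 1).
#' @param n_electrodes Number of electrodes the fit used.
#' @param space Space tag (default the MNI-152 template).
#' @return An object of class `prior_ellipsoid`.
#' @export
prior_ellipsoid <- function(zone, role, approach, center, axes, semi_axes,
                            k_sd = 1, n_electrodes = NA_integer_,
                            space = .TEMPLATE_SPACE) {
  role <- match.arg(role, c("entry", "target"))
  center <- .as_point3(center, "center")
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3, 3)) ||
      max(abs(crossprod(axes) - diag(3))) > 1e-8)
    stop("axes must be a 3x3 matrix with orthonormal columns (tol 1e-8)")
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3 || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0))
    stop("semi_axes must be 3 positive lengths (degenerate fits rejected)")
  structure(list(zone = as.character(zone), role = role,
                 approach = as.character(approach),
                 center = center, axes = axes, semi_axes = semi_axes,
                 k_sd = as.numeric(k_sd),
                 n_electrodes = as.integer(n_electrodes),
                 space = as.character(space)),
            class = "prior_ellipsoid")
}

#' @export
print.prior_ellipsoid <- function(x, ...) {
  cat(sprintf("prior_ellipsoid %s/%s/%s (%s): center (%s) mm, semi-axes (%s) mm [k = %g SD, n = %d]\n",
              x$zone, x$role, x$approach, x$space,
              paste(signif(x$center, 4), collapse = ", "),
              paste(signif(x$semi_axes, 4), collapse = ", "),
              x$k_sd, x$n_electrodes))
  invisible(x)
}

.ellipsoid_name <- function(e) paste(e$zone, e$role, e$approach, sep = "/")

#' Group labelled electrodes into entry and target point sets
#'
#' Grouping is driven entirely by the clinical `target_zone` and
#' `approach` labels carried by each trajectory (labels are inputs, never
#' inferred): for every (zone, approach) pair two groups are formed, one
#' of entry points and one of target points. Trajectories with missing
#' labels are listed and skipped with a warning.
#'
#' @param history Trajectory data frame with `target_zone` and `approach`
#'   columns (template-space coordinates).
#' @return List of electrode groups, each a list with `zone`, `role`,
#'   `approach`, `points` (n x 3 matrix), and `ids`.
#' @export
group_electrodes <- function(history) {
  history <- .as_traj_table(history)
  bad <- is.na(history$target_zone) | is.na(history$approach) |
    history$target_zone == "" | history$approach == ""
  if (any(bad)) {
    warning(sprintf("skipping %d trajectory(ies) with missing zone/approach labels: %s",
                    sum(bad),
                    paste(history$electrode_id[bad], collapse = ", ")))
    history <- history[!bad, , drop = FALSE]
  }
  if (nrow(history) == 0) return(list())
  keys <- unique(history[, c("target_zone", "approach")])
  keys <- keys[order(keys$target_zone, keys$approach), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- history$target_zone == keys$target_zone[i] &
      history$approach == keys$approach[i]
    sub <- history[sel, , drop = FALSE]
    for (role in c("entry", "target")) {
      pts <- if (role == "entry") .entry_matrix(sub) else .target_matrix(sub)
      dimnames(pts) <- NULL
      out[[length(out) + 1L]] <- list(zone = keys$target_zone[i],
                                      role = role,
                                      approach = keys$approach[i],
                                      points = pts,
                                      ids = sub$electrode_id)
    }
  }
  out
}

#' Remove lesional electrodes before prior construction
#'
#' Electrodes placed to target a lesion are patient-specific and excluded
#' from the priors library.
#'
#' @param history Trajectory data frame.
#' @param lesional Logical (or 0/1) vector, one flag per row; defaults to
#'   the `lesional` column of `history`.
#' @return The retained rows, with attribute `n_removed`.
#' @export
exclude_lesional <- function(history, lesional = history$lesional) {
  if (is.null(lesional))
    stop("exclude_lesional: no lesional flags supplied")
  lesional <- as.logical(lesional)
  if (length(lesional) != nrow(history) || any(is.na(lesional)))
    stop("exclude_lesional: need one non-missing flag per trajectory")
  out <- history[!lesional, , drop = FALSE]
  attr(out, "n_removed") <- sum(lesional)
  out
}

# leave-one-out Mahalanobis distance (SD units) of each point from the
# ellipsoid of the remaining points
.loo_mahalanobis <- function(pts) {
  n <- nrow(pts)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rest <- pts[-i, , drop = FALSE]
    mu <- colMeans(rest)
    S <- stats::cov(rest)
    si <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(si)) next
    v <- pts[i, ] - mu
    q <- drop(t(v) %*% si %*% v)
    d[i] <- sqrt(max(q, 0))
  }
  d
}

#' Iterative Mahalanobis outlier exclusion for an electrode group
#'
#' Repeatedly removes the point with the largest leave-one-out
#' Mahalanobis distance (its distance, in SD units, from the ellipsoid of
#' the *remaining* points) while that distance exceeds `threshold`,
#' stopping when no point exceeds it or when a floor of `min_points`
#' points is reached. Removal order is deterministic: largest distance
#' first, ties broken by the lexicographically smallest provenance id.
#'
#' The default threshold of 4 SD units captures "clear outliers": the
#' expected extreme leave-one-out distance of a few-hundred-point
#' trivariate Gaussian sample is about 3.9 SD, so clean clusters survive
#' intact while grossly displaced electrodes are removed (see the methods
#' vignette for the calibration argument).
#'
#' @param group An electrode group from [group_electrodes()], or an n x 3
#'   point matrix.
#' @param threshold Exclusion threshold in SD units (default 4).
#' @param min_points Floor below which no further points are removed and
#'   below which fitting is refused (default 5).
#' @return List with `kept`, `excluded` (point matrices), `kept_ids`,
#'   `excluded_ids`.
#' @export
exclude_outliers <- function(group, threshold = 4, min_points = .MIN_GROUP) {
  if (is.matrix(group)) group <- list(points = group,
                                      ids = as.character(seq_len(nrow(group))))
  pts <- group$points
  ids <- as.character(group$ids)
  if (nrow(pts) < min_points)
    stop(sprintf("group has %d point(s); at least %d required for a fit",
                 nrow(pts), min_points))
  excluded <- integer(0)
  active <- seq_len(nrow(pts))
  repeat {
    if (length(active) <= min_points) break
    d <- .loo_mahalanobis(pts[active, , drop = FALSE])
    if (all(is.na(d)) || max(d, na.rm = TRUE) <= threshold) break
    worst <- max(d, na.rm = TRUE)
    cand <- active[which(!is.na(d) & d == worst)]
    drop_i <- cand[order(ids[cand])][1]
    excluded <- c(excluded, drop_i)
    active <- setdiff(active, drop_i)
  }
  list(kept = pts[active, , drop = FALSE],
       excluded = pts[excluded, , drop = FALSE],
       kept_ids = ids[active], excluded_ids = ids[excluded])
}

#' Fit a prior ellipsoid to a point set by PCA
#'
#' Center = arithmetic mean; axes = eigenvectors of the sample covariance
#' (n-1 denominator) sorted by descending eigenvalue with signs fixed so
#' each axis' largest-magnitude component is positive; semi-axes =
#' `k_sd * sqrt(eigenvalue)`.
#'
#' @param points n x 3 matrix (n >= 5), not collinear/coplanar.
#' @param zone,role,approach Labels stored on the ellipsoid.
#' @param k_sd Semi-axis scale in SD units (default 1).
#' @return A [prior_ellipsoid()].
#' @export
fit_ellipsoid <- function(points, zone = "zone", role = "target",
                          approach = "any", k_sd = 1) {
  points <- as.matrix(points)
  if (nrow(points) < .MIN_GROUP)
    stop(sprintf("need at least %d points to fit an ellipsoid", .MIN_GROUP))
  ctr <- colMeans(points)
  S <- stats::cov(points)
  eg <- eigen(S, symmetric = TRUE)
  tol <- 1e-10 * max(eg$values, 1)
  if (any(eg$values <= tol)) {
    dir <- eg$vectors[, which(eg$values <= tol)[1]]
    stop(sprintf("rank-deficient covariance: no spread along direction (%s)",
                 paste(signif(dir, 3), collapse = ", ")))
  }
  axes <- .fix_signs(eg$vectors)
  prior_ellipsoid(zone, role, approach, ctr, axes,
                  k_sd * sqrt(eg$values), k_sd = k_sd,
                  n_electrodes = nrow(points))
}

# deterministic eigenvector signs: largest-magnitude component positive,
# ties by lowest component index
.fix_signs <- function(V) {
  for (j in 1:3) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Mahalanobis distance of points from a prior ellipsoid
#'
#' `sqrt(sum_j (<p - center, axis_j> / (semi_axes_j / k_sd))^2)`, i.e. the
#' distance in SD units under the fitted Gaussian. A point lies inside the
#' stored (k-scaled) ellipsoid iff the distance is `<= k_sd`.
#'
#' @param pts n x 3 matrix or length-3 vector (same space as the
#'   ellipsoid).
#' @param ellipsoid A [prior_ellipsoid()].
#' @return Numeric vector of distances in SD units.
#' @export
mahalanobis_ellipsoid <- function(pts, ellipsoid) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  proj <- sweep(pts, 2, ellipsoid$center) %*% ellipsoid$axes
  sd_len <- ellipsoid$semi_axes / ellipsoid$k_sd
  sqrt(rowSums(sweep(proj, 2, sd_len, `/`)^2))
}

#' Transport a prior ellipsoid to patient space
#'
#' Maps the center affinely and transports the quadratic form (covariance
#' -> A Sigma A') before re-eigendecomposing so the axes stay orthonormal.
#'
#' @param ellipsoid A [prior_ellipsoid()].
#' @param affine Invertible 4x4 template-to-patient affine.
#' @param space Space tag for the result (default `"patient"`).
#' @return A [prior_ellipsoid()] in the new space.
#' @export
to_patient_space <- function(ellipsoid, affine, space = "patient") {
  .check_affine(affine)
  A <- affine[1:3, 1:3]
  sd_len <- ellipsoid$semi_axes / ellipsoid$k_sd
  Sigma <- ellipsoid$axes %*% diag(sd_len^2) %*% t(ellipsoid$axes)
  Sigma2 <- A %*% Sigma %*% t(A)
  eg <- eigen((Sigma2 + t(Sigma2)) / 2, symmetric = TRUE)
  prior_ellipsoid(ellipsoid$zone, ellipsoid$role, ellipsoid$approach,
                  apply_affine(affine, ellipsoid$center),
                  .fix_signs(eg$vectors),
                  ellipsoid$k_sd * sqrt(pmax(eg$values, 0)),
                  k_sd = ellipsoid$k_sd,
                  n_electrodes = ellipsoid$n_electrodes,
                  space = space)
}

#' Build a spatial-priors library from a labelled implantation history
#'
#' Runs the full construction pipeline: lesional exclusion, grouping by
#' (zone, approach) into entry and target point sets, iterative
#' Mahalanobis outlier exclusion, and PCA ellipsoid fitting. Groups whose
#' fit fails (too few points, rank-deficient spread) are reported in the
#' QC table and omitted, not fatal. The QC report (per-group counts,
#' exclusions, covariance condition numbers) stands in for the manual
#' expert review of the clinical workflow.
#'
#' @param history Trajectory data frame in template space with
#'   `target_zone`, `approach`, and `lesional` columns.
#' @param k_sd Semi-axis scale in SD units (default 1).
#' @param outlier_threshold Passed to [exclude_outliers()].
#' @param metadata Optional named list stored in the library.
#' @return An object of class `prior_library`: ellipsoids (named list),
#'   pairings (target name -> admissible entry names), `qc` data frame,
#'   and metadata.
#' @export
build_library <- function(history, k_sd = 1, outlier_threshold = 4,
                          metadata = list()) {
  if (nrow(history) > 0 && !is.null(history$lesional)) {
    history <- exclude_lesional(history)
  }
  groups <- if (nrow(history) > 0) group_electrodes(history) else list()
  ellipsoids <- list()
  qc <- data.frame(zone = character(0), role = character(0),
                   approach = character(0), n_input = integer(0),
                   n_excluded = integer(0), n_used = integer(0),
                   condition_number = numeric(0), status = character(0),
                   stringsAsFactors = FALSE)
  for (g in groups) {
    n_in <- nrow(g$points)
    res <- tryCatch({
      ex <- exclude_outliers(g, threshold = outlier_threshold)
      ell <- fit_ellipsoid(ex$kept, zone = g$zone, role = g$role,
                           approach = g$approach, k_sd = k_sd)
      list(ell = ell, n_excl = nrow(ex$excluded),
           cond = (max(ell$semi_axes) / min(ell$semi_axes))^2,
           status = "ok")
    }, error = function(e) list(ell = NULL, n_excl = NA_integer_,
                                cond = NA_real_,
                                status = conditionMessage(e)))
    if (!is.null(res$ell))
      ellipsoids[[.ellipsoid_name(res$ell)]] <- res$ell
    qc <- rbind(qc, data.frame(zone = g$zone, role = g$role,
                               approach = g$approach, n_input = n_in,
                               n_excluded = res$n_excl,
                               n_used = if (is.null(res$ell)) NA_integer_
                                        else res$ell$n_electrodes,
                               condition_number = res$cond,
                               status = res$status,
                               stringsAsFactors = FALSE))
  }
  # pair each target ellipsoid with the entry ellipsoid(s) of its
  # (zone, approach)
  pairings <- list()
  for (nm in names(ellipsoids)) {
    e <- ellipsoids[[nm]]
    if (e$role != "target") next
    entry_nm <- paste(e$zone, "entry", e$approach, sep = "/")
    if (entry_nm %in% names(ellipsoids))
      pairings[[length(pairings) + 1L]] <- list(target = nm,
                                                entries = list(entry_nm))
  }
  structure(list(space = .TEMPLATE_SPACE, ellipsoids = ellipsoids,
                 pairings = pairings, qc = qc,
                 metadata = c(metadata,
                              list(n_history = nrow(history),
                                   k_sd = k_sd,
                                   outlier_threshold = outlier_threshold))),
            class = "prior_library")
}

#' @export
print.prior_library <- function(x, ...) {
  nt <- sum(vapply(x$ellipsoids, function(e) e$role == "target", TRUE))
  cat(sprintf("prior_library (%s): %d ellipsoid(s) (%d target, %d entry), %d pairing(s)\n",
              x$space, length(x$ellipsoids), nt,
              length(x$ellipsoids) - nt, length(x$pairings)))
  invisible(x)
}

#' Read / write a priors library as JSON
#'
#' Schema: `{"space", "ellipsoids": [{"zone","role","approach",
#' "center_mm","axes","semi_axes_mm","k_sd","n_electrodes"}],
#' "pairings": [{"target","entries"}], "metadata": {...}}`. Numeric
#' values round-trip losslessly.
#'
#' @param path File path.
#' @return `read_prior_library` returns a `prior_library`.
#' @export
write_prior_library <- function(library, path) {
  obj <- list(
    space = library$space,
    ellipsoids = lapply(unname(library$ellipsoids), function(e) list(
      zone = e$zone, role = e$role, approach = e$approach,
      center_mm = e$center,
      axes = lapply(1:3, function(j) e$axes[, j]),
      semi_axes_mm = e$semi_axes, k_sd = e$k_sd,
      n_electrodes = e$n_electrodes)),
    pairings = library$pairings,
    qc = library$qc,
    metadata = library$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(path)
}

#' @param library A `prior_library`.
#' @rdname write_prior_library
#' @export
read_prior_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ells <- list()
  for (e in obj$ellipsoids) {
    ell <- prior_ellipsoid(e$zone, e$role, e$approach,
                           as.numeric(unlist(e$center_mm)),
                           do.call(cbind, lapply(e$axes, function(a)
                             as.numeric(unlist(a)))),
                           as.numeric(unlist(e$semi_axes_mm)),
                           k_sd = e$k_sd,
                           n_electrodes = e$n_electrodes %||% NA_integer_,
                           space = obj$space)
    ells[[.ellipsoid_name(ell)]] <- ell
  }
  pairings <- lapply(obj$pairings, function(p)
    list(target = p$target, entries = lapply(p$entries, as.character)))
  for (p in pairings) {
    refs <- c(p$target, unlist(p$entries))
    if (!all(refs %in% names(ells)))
      stop(sprintf("priors JSON %s: pairing references unknown ellipsoid(s): %s",
                   path, paste(setdiff(refs, names(ells)), collapse = ", ")))
  }
  qc <- if (!is.null(obj$qc)) do.call(rbind, lapply(obj$qc, function(r) {
    r <- lapply(r, function(v) if (is.null(v)) NA else v)
    data.frame(r, stringsAsFactors = FALSE)
  })) else NULL
  structure(list(space = obj$space, ellipsoids = ells, pairings = pairings,
                 qc = qc, metadata = obj$metadata),
            class = "prior_library")
}
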