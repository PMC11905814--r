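# World coordinates are mm, RAS. Trajectories are straight lines from a
# scalp/skull entry point E to an intracerebral target point T.

.traj_cols <- c("electrode_id",
                "entry_x_mm", "entry_y_mm", "entry_z_mm",
                "target_x_mm", "target_y_mm", "target_z_mm",
                "target_zone", "approach")

.as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3 || any(!is.finite(p)))
    stop(sprintf("%s must be 3 finite coordinates (mm)", what))
  p
}

#' Construct a trajectory table
#'
#' A trajectory is the straight electrode path from an entry point to a
#' target point, both in world mm. Trajectories are kept in a plain
#' data frame (one row per electrode) with canonical columns
#' `electrode_id`, `entry_{x,y,z}_mm`, `target_{x,y,z}_mm`,
#' `target_zone`, `approach`.
#'
#' @param id Electrode identifier (character).
#' @param entry,target Numeric length-3 world coordinates in mm.
#' @param target_zone,approach Optional clinical labels.
#' @return A one-row trajectory data frame.
#' @export
#' @examples
#' trajectory("e1", c(0, 0, 80), c(0, 0, 0))
trajectory <- function(id, entry, target, target_zone = NA_character_,
                       approach = NA_character_) {
  entry <- .as_point3(entry, "entry")
  target <- .as_point3(target, "target")
  if (all(entry == target))
    stop("degenerate trajectory: entry and target coincide")
  data.frame(electrode_id = as.character(id),
             entry_x_mm = entry[1], entry_y_mm = entry[2],
             entry_z_mm = entry[3],
             target_x_mm = target[1], target_y_mm = target[2],
             target_z_mm = target[3],
             target_zone = as.character(target_zone),
             approach = as.character(approach),
             stringsAsFactors = FALSE)
}

# validate/coerce a trajectory table; returns the data.frame
.as_traj_table <- function(x) {
  if (!is.data.frame(x)) stop("expected a trajectory data frame")
  missing <- setdiff(.traj_cols[1:7], names(x))
  if (length(missing) > 0)
    stop(sprintf("trajectory table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  if (!"target_zone" %in% names(x)) x$target_zone <- NA_character_
  if (!"approach" %in% names(x)) x$approach <- NA_character_
  x
}

.entry_matrix <- function(traj) {
  as.matrix(traj[, c("entry_x_mm", "entry_y_mm", "entry_z_mm")])
}

.target_matrix <- function(traj) {
  as.matrix(traj[, c("target_x_mm", "target_y_mm", "target_z_mm")])
}

#' Sample evenly spaced nodes along a trajectory
#'
#' Places `n_nodes` points on the straight entry-to-target line, endpoints
#' included, so the spacing is `||T - E|| / (n_nodes - 1)`. These are the
#' nodes at which vessel distances are measured for the risk score.
#'
#' @param traj A one-row trajectory data frame (see [trajectory()]).
#' @param config A [risk_config()]; `config$n_nodes` nodes are returned.
#' @return An `n_nodes` x 3 matrix of world coordinates in mm, row 1 the
#'   entry point and the last row the target.
#' @export
#' @examples
#' nodes <- sample_nodes(trajectory("e1", c(0, 0, 0), c(0, 0, 127)))
#' nrow(nodes)  # 128
sample_nodes <- function(traj, config = risk_config()) {
  traj <- .as_traj_table(traj)
  if (nrow(traj) != 1) stop("sample_nodes expects a single trajectory")
  E <- .entry_matrix(traj)[1, ]
  Tp <- .target_matrix(traj)[1, ]
  if (all(E == Tp))
    stop("degenerate trajectory: entry and target coincide")
  s <- seq(0, 1, length.out = config$n_nodes)
  out <- outer(1 - s, E) + outer(s, Tp)
  dimnames(out) <- NULL
  out
}

# nodes for a whole table at once: (k*n) x 3 matrix, trajectory-major
.batch_nodes <- function(E, Tp, n) {
  k <- nrow(E)
  s <- seq(0, 1, length.out = n)
  ii <- rep(seq_len(k), each = n)
  ss <- rep(s, times = k)
  out <- E[ii, , drop = FALSE] * (1 - ss) + Tp[ii, , drop = FALSE] * ss
  dimnames(out) <- NULL
  out
}

## ---- affine transforms ------------------------------------------------

.check_affine <- function(A) {
  if (!is.matrix(A) || !all(dim(A) == c(4, 4)) || any(!is.finite(A)))
    stop("affine must be a finite 4x4 matrix")
  if (any(abs(A[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("affine last row must be (0, 0, 0, 1)")
  if (abs(det(A[1:3, 1:3])) < 1e-12)
    stop("affine upper-left 3x3 block is singular")
  A
}

#' Read / write a 4x4 affine as whitespace-delimited plain text
#'
#' The affine maps homogeneous template-space mm to patient-space mm (or
#' voxel indices to world mm for volumes); last row must be (0, 0, 0, 1).
#'
#' @param path File path.
#' @return `read_affine` returns the validated 4x4 matrix.
#' @export
read_affine <- function(path) {
  A <- as.matrix(read.table(path, header = FALSE))
  if (!all(dim(A) == c(4, 4)))
    stop(sprintf("affine file %s: expected 4 rows x 4 columns, got %dx%d",
                 path, nrow(A), ncol(A)))
  dimnames(A) <- NULL
  .check_affine(A)
}

#' @param A A 4x4 affine matrix.
#' @rdname read_affine
#' @export
write_affine <- function(A, path) {
  .check_affine(A)
  write.table(format(A, digits = 17, scientific = FALSE, trim = TRUE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply an affine transform to world points
#'
#' @param A 4x4 affine.
#' @param pts n x 3 matrix (or length-3 vector) of points.
#' @return Transformed points, same shape.
#' @export
apply_affine <- function(A, pts) {
  .check_affine(A)
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, nrow = 1)
  out <- pts %*% t(A[1:3, 1:3]) + rep(1, nrow(pts)) %o% A[1:3, 4]
  if (single) out[1, ] else out
}

## ---- segment distance primitives --------------------------------------

# distance from points P (n x 3) to segment a-b, with linearly interpolated
# radius subtracted; returns (distance, not floored)
.points_to_segment <- function(P, a, b, ra = 0, rb = 0) {
  ab <- b - a
  len2 <- sum(ab * ab)
  d <- sweep(P, 2, a)
  if (len2 == 0) {
    t <- rep(0, nrow(P))
  } else {
    t <- pmin(1, pmax(0, (d %*% ab)[, 1] / len2))
  }
  closest <- outer(t, ab)
  diff <- d - closest
  sqrt(rowSums(diff * diff)) - (ra + t * (rb - ra))
}

# minimum distance between two 3-D segments p1-q1 and p2-q2
# (clamped closest-point computation)
.segment_segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1
  d2 <- q2 - p2
  r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) {
    s <- 0
    t <- min(1, max(0, f / e))
  } else {
    c1 <- sum(d1 * r)
    if (e <= eps) {
      t <- 0
      s <- min(1, max(0, -c1 / a))
    } else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > eps) min(1, max(0, (b * f - c1 * e) / denom)) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0
        s <- min(1, max(0, -c1 / a))
      } else if (t > 1) {
        t <- 1
        s <- min(1, max(0, (b - c1) / a))
      }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}
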