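# Shared fixtures, built once per test run and cached. All synthetic,
# all seeded.

.fx_env <- new.env(parent = emptyenv())

# default head phantom + vessel tree (seed 17)
phantom_fixture <- function() {
  if (is.null(.fx_env$phantom)) {
    spec <- phantom_spec()
    head <- make_head_phantom(spec)
    vessels <- make_vessel_tree(spec, head)
    .fx_env$phantom <- list(spec = spec, head = head, vessels = vessels)
  }
  .fx_env$phantom
}

# default synthetic implantation history + fitted priors library
history_fixture <- function() {
  if (is.null(.fx_env$history)) {
    h <- make_history(history_spec())
    .fx_env$history <- c(h, list(library = build_library(h$history)))
  }
  .fx_env$history
}

# concentric-sphere head: labels scalp(1)/skull(2)/csf(3)/gray(4)/white(5)
# assigned by the named outer radii supplied (names from that set, strictly
# decreasing); omitted shells are absent
nested_head <- function(r = c(scalp = 64, skull = 58, gray = 50, white = 40),
                        dim = 72L, voxel = 2) {
  ids <- c(scalp = 1L, skull = 2L, csf = 3L, gray = 4L, white = 5L)
  A <- diag(c(voxel, voxel, voxel, 1))
  A[1:3, 4] <- -voxel * (dim - 1) / 2
  w <- seq(0, dim - 1) * voxel + A[1, 4]
  rad <- sqrt(outer(outer(w^2, w^2, `+`), w^2, `+`))
  lab <- array(0L, rep(dim, 3))
  for (nm in names(r)) lab[rad <= r[[nm]]] <- ids[[nm]]
  labels <- data.frame(id = unname(ids[names(r)]), name = names(r),
                       class = names(r), stringsAsFactors = FALSE)
  label_volume(lab, A, labels)
}

# flat-slab head: gray below z = z_gray, skull slab above it, scalp above
# that; x/y spanning the whole grid
slab_head <- function(z_gray = 20, z_skull = 28, z_scalp = 36,
                      dim = 64L, voxel = 2) {
  A <- diag(c(voxel, voxel, voxel, 1))
  A[1:3, 4] <- -voxel * (dim - 1) / 2
  w <- seq(0, dim - 1) * voxel + A[3, 4]
  lab <- array(0L, rep(dim, 3))
  z <- rep(w, each = dim * dim)
  lab[z <= z_scalp] <- 1L
  lab[z <= z_skull] <- 2L
  lab[z <= z_gray] <- 4L
  labels <- data.frame(id = c(1L, 2L, 4L),
                       name = c("scalp", "skull", "gray"),
                       class = c("scalp", "skull", "gray"),
                       stringsAsFactors = FALSE)
  label_volume(lab, A, labels)
}

# radius-0 copy of a vessel tree (centerline distances)
zero_radius <- function(vessels) {
  vessel_tree(lapply(vessels$polylines, function(p)
    list(points = p$points, radii_mm = rep(0, nrow(p$points)))))
}

# random unit vector
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
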