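# Constructive-solid-geometry scene and analytic straight-line ray tracing.
#
# Scene descriptions use metres (as in the study's drawings); everything is
# converted to centimetres internally because the attenuation tables and the
# inverse-square kernel are cm-based. All chord lengths are exact quadratic
# surface intersections; no voxelization anywhere.

M2CM <- 100
.EPS <- 1e-12

unit3 <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 3)
  n <- sqrt(sum(v^2))
  if (n < .EPS) stop("zero-length axis vector")
  v / n
}

#' Geometric primitives
#'
#' Shapes are built in metres. A cylindrical or spherical *shell* has
#' `r_inner > 0`; `r_inner = 0` gives the full solid. A spherical cap shell
#' restricts the shell to `h_range` (metres along `axis`, relative to the
#' centre). Closed surfaces belong to the shape.
#'
#' @param lower,upper opposite box corners (metres).
#' @return object of class `shape`.
#' @export
shape_box <- function(lower, upper) {
  lower <- as.numeric(lower) * M2CM; upper <- as.numeric(upper) * M2CM
  if (any(upper <= lower)) stop("box extents must be positive")
  structure(list(type = "box", lower = lower, upper = upper), class = "shape")
}

#' @rdname shape_box
#' @param base centre of the bottom face (metres).
#' @param axis cylinder/sphere-cap axis direction (normalized internally).
#' @param r_outer,r_inner outer/inner radii (metres); `r_inner < r_outer`.
#' @param height cylinder height (metres).
#' @export
shape_cylinder <- function(base, axis = c(0, 0, 1), r_outer, height,
                           r_inner = 0) {
  stopifnot_scalar_num(r_outer, "r_outer", positive = TRUE)
  stopifnot_scalar_num(height, "height", positive = TRUE)
  stopifnot_scalar_num(r_inner, "r_inner", nonneg = TRUE)
  if (r_inner >= r_outer) stop("r_inner must be < r_outer")
  structure(list(type = "cylinder", base = as.numeric(base) * M2CM,
                 axis = unit3(axis), r_outer = r_outer * M2CM,
                 r_inner = r_inner * M2CM, height = height * M2CM),
            class = "shape")
}

#' @rdname shape_box
#' @param center sphere centre (metres).
#' @param h_range optional `c(h_min, h_max)` (metres along `axis` from the
#'   centre) restricting the shell to a cap/slab; default is the full shell.
#' @export
shape_sphere <- function(center, r_outer, r_inner = 0, axis = c(0, 0, 1),
                         h_range = NULL) {
  stopifnot_scalar_num(r_outer, "r_outer", positive = TRUE)
  stopifnot_scalar_num(r_inner, "r_inner", nonneg = TRUE)
  if (r_inner >= r_outer) stop("r_inner must be < r_outer")
  if (is.null(h_range)) h_range <- c(-r_outer, r_outer)
  h_range <- as.numeric(h_range)
  if (length(h_range) != 2 || h_range[2] <= h_range[1])
    stop("h_range must be c(h_min, h_max) with h_min < h_max")
  structure(list(type = "sphere", center = as.numeric(center) * M2CM,
                 axis = unit3(axis), r_outer = r_outer * M2CM,
                 r_inner = r_inner * M2CM, h_range = h_range * M2CM),
            class = "shape")
}

# ---- internal geometry kernels (all cm) -----------------------------------

shape_bbox <- function(s) {
  switch(s$type,
    box = rbind(s$lower, s$upper),
    cylinder = {
      # conservative box around the finite cylinder (any axis)
      c0 <- s$base; c1 <- s$base + s$axis * s$height
      rbind(pmin(c0, c1) - s$r_outer, pmax(c0, c1) + s$r_outer)
    },
    sphere = rbind(s$center - s$r_outer, s$center + s$r_outer))
}

shape_volume <- function(s) {
  switch(s$type,
    box = prod(s$upper - s$lower),
    cylinder = pi * (s$r_outer^2 - s$r_inner^2) * s$height,
    sphere = {
      slab_vol <- function(r) {
        h0 <- max(s$h_range[1], -r); h1 <- min(s$h_range[2], r)
        if (h1 <= h0) return(0)
        # integral of pi (r^2 - z^2) dz
        pi * (r^2 * (h1 - h0) - (h1^3 - h0^3) / 3)
      }
      slab_vol(s$r_outer) - slab_vol(s$r_inner)
    })
}

# Points P: n x 3 matrix in cm. Closed (boundary-inclusive) membership.
inside_pts <- function(s, P) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  switch(s$type,
    box = P[, 1] >= s$lower[1] & P[, 1] <= s$upper[1] &
          P[, 2] >= s$lower[2] & P[, 2] <= s$upper[2] &
          P[, 3] >= s$lower[3] & P[, 3] <= s$upper[3],
    cylinder = {
      M <- sweep(P, 2, s$base)
      h <- as.vector(M %*% s$axis)
      r2 <- rowSums(M^2) - h^2
      h >= -1e-9 & h <= s$height + 1e-9 &
        r2 <= s$r_outer^2 + 1e-6 & r2 >= s$r_inner^2 - 1e-6
    },
    sphere = {
      M <- sweep(P, 2, s$center)
      h <- as.vector(M %*% s$axis)
      r2 <- rowSums(M^2)
      h >= s$h_range[1] - 1e-9 & h <= s$h_range[2] + 1e-9 &
        r2 <= s$r_outer^2 + 1e-6 & r2 >= s$r_inner^2 - 1e-6
    })
}

# Slab interval along axis: solve lo <= m + t*d <= hi elementwise.
.slab_interval <- function(m, d, lo, hi) {
  t0 <- ifelse(abs(d) > .EPS, pmin((lo - m) / d, (hi - m) / d),
               ifelse(m >= lo & m <= hi, -Inf, Inf))
  t1 <- ifelse(abs(d) > .EPS, pmax((lo - m) / d, (hi - m) / d),
               ifelse(m >= lo & m <= hi, Inf, -Inf))
  cbind(t0, t1)
}

# Quadratic interval: |M_perp + t D_perp|^2 <= r^2 given a, b, c with
# a = |D|^2, b = 2 M.D, c = |M|^2 - r^2 (all vectors length n).
.quad_interval <- function(a, b, cc) {
  degen <- a <= .EPS
  disc <- b^2 - 4 * a * cc
  sq <- sqrt(pmax(disc, 0))
  t0 <- ifelse(degen, ifelse(cc <= 0, -Inf, Inf), (-b - sq) / (2 * a))
  t1 <- ifelse(degen, ifelse(cc <= 0, Inf, -Inf), (-b + sq) / (2 * a))
  empty <- !degen & disc < 0
  t0[empty] <- Inf; t1[empty] <- -Inf
  cbind(t0, t1)
}

# Parametric interval(s) of segment P0 + t (P1 - P0), t in [0,1], inside the
# *outer* solid (radius r) of shape s intersected with its slab constraint.
# Returns a 2-column matrix (t0, t1), one row per ray; empty rows have t0>t1.
.solid_interval <- function(s, P0, P1, r) {
  D <- P1 - P0
  switch(s$type,
    box = {
      iv <- .slab_interval(P0[, 1] - s$lower[1], D[, 1], 0, s$upper[1] - s$lower[1])
      for (k in 2:3) {
        ivk <- .slab_interval(P0[, k] - s$lower[k], D[, k], 0,
                              s$upper[k] - s$lower[k])
        iv <- cbind(pmax(iv[, 1], ivk[, 1]), pmin(iv[, 2], ivk[, 2]))
      }
      cbind(pmax(iv[, 1], 0), pmin(iv[, 2], 1))
    },
    cylinder = {
      M <- sweep(P0, 2, s$base)
      du <- as.vector(D %*% s$axis); mu_ <- as.vector(M %*% s$axis)
      slab <- .slab_interval(mu_, du, 0, s$height)
      a <- rowSums(D^2) - du^2
      b <- 2 * (rowSums(M * D) - mu_ * du)
      cc <- rowSums(M^2) - mu_^2 - r^2
      q <- .quad_interval(a, b, cc)
      cbind(pmax(q[, 1], slab[, 1], 0), pmin(q[, 2], slab[, 2], 1))
    },
    sphere = {
      M <- sweep(P0, 2, s$center)
      du <- as.vector(D %*% s$axis); mu_ <- as.vector(M %*% s$axis)
      slab <- .slab_interval(mu_, du, s$h_range[1], s$h_range[2])
      q <- .quad_interval(rowSums(D^2), 2 * rowSums(M * D), rowSums(M^2) - r^2)
      cbind(pmax(q[, 1], slab[, 1], 0), pmin(q[, 2], slab[, 2], 1))
    })
}

# Total in-shape chord length (cm) for each segment row. Exact for all
# bundled shapes: shell chord = outer-solid chord - inner-solid chord.
seg_chord <- function(s, P0, P1) {
  seg_len <- sqrt(rowSums((P1 - P0)^2))
  outer <- .solid_interval(s, P0, P1, if (s$type == "box") NA else s$r_outer)
  len <- pmax(outer[, 2] - outer[, 1], 0)
  ri <- if (s$type == "box") 0 else s$r_inner
  if (ri > 0) {
    inner <- .solid_interval(s, P0, P1, ri)
    len <- len - pmax(inner[, 2] - inner[, 1], 0)
  }
  len * seg_len
}

# Boundary-crossing parameters in (0,1) for one segment (scalar ray).
seg_events <- function(s, p0, p1) {
  P0 <- matrix(p0, 1); P1 <- matrix(p1, 1)
  ts <- as.vector(.solid_interval(s, P0, P1, if (s$type == "box") NA else s$r_outer))
  ri <- if (s$type == "box") 0 else s$r_inner
  if (ri > 0)
    ts <- c(ts, as.vector(.solid_interval(s, P0, P1, ri)))
  ts[is.finite(ts) & ts > 0 & ts < 1]
}

# ---- regions and scenes ---------------------------------------------------

#' Region: a shape filled with a material at a priority
#'
#' Where regions overlap, the highest priority wins; overlapping regions of
#' equal priority are rejected at scene validation time.
#'
#' @param shape a [shape_box()], [shape_cylinder()] or [shape_sphere()].
#' @param material material name (resolved against the scene's library) or a
#'   [material()] object.
#' @param priority integer; larger wins on overlap.
#' @param name optional label.
#' @export
region <- function(shape, material, priority = 1L, name = NULL) {
  stopifnot(inherits(shape, "shape"))
  structure(list(shape = shape, material = material,
                 priority = as.integer(priority),
                 name = name %||% "region"),
            class = "scene_region")
}

#' Build and validate a scene
#'
#' A scene is a list of prioritized regions embedded in an ambient material
#' (air by default). Validation samples a deterministic lattice inside every
#' pair of intersecting bounding boxes and rejects equal-priority overlaps;
#' it also records whether all regions are pairwise disjoint, which enables
#' the vectorized transport fast path used by the dose engine.
#'
#' @param regions list of [region()] objects.
#' @param ambient ambient material name or [material()] object.
#' @param materials material library, default [material_library()].
#' @param validate logical; run the overlap check.
#' @return object of class `scene_model`.
#' @export
scene_model <- function(regions, ambient = "air",
                        materials = material_library(), validate = TRUE) {
  stopifnot(is.list(regions), all(vapply(regions, inherits, TRUE, "scene_region")))
  resolve <- function(m) {
    if (inherits(m, "material")) return(m)
    if (is.character(m)) {
      if (!m %in% names(materials)) stop("unknown material: ", m)
      return(materials[[m]])
    }
    stop("material must be a name or a material object")
  }
  ambient <- resolve(ambient)
  mats <- list()
  mats[[ambient$name]] <- ambient
  for (i in seq_along(regions)) {
    m <- resolve(regions[[i]]$material)
    regions[[i]]$material <- m$name
    mats[[m$name]] <- m
  }
  ord <- order(vapply(regions, `[[`, 1L, "priority"), decreasing = TRUE)
  scene <- structure(list(regions = regions[ord], ambient = ambient$name,
                          materials = mats, disjoint = TRUE),
                     class = "scene_model")
  if (length(regions) > 1) {
    for (i in seq_along(scene$regions)[-1]) for (j in seq_len(i - 1)) {
      ri <- scene$regions[[i]]; rj <- scene$regions[[j]]
      bi <- shape_bbox(ri$shape); bj <- shape_bbox(rj$shape)
      lo <- pmax(bi[1, ], bj[1, ]); hi <- pmin(bi[2, ], bj[2, ])
      if (any(hi < lo)) next
      g <- expand.grid(x = seq(lo[1], hi[1], length.out = 8),
                       y = seq(lo[2], hi[2], length.out = 8),
                       z = seq(lo[3], hi[3], length.out = 8))
      P <- as.matrix(g)
      both <- inside_pts(ri$shape, P) & inside_pts(rj$shape, P)
      if (any(both)) {
        scene$disjoint <- FALSE
        if (validate && ri$priority == rj$priority)
          stop(sprintf("regions '%s' and '%s' overlap at equal priority %d",
                       ri$name, rj$name, ri$priority))
      }
    }
  }
  scene
}

# Material index (into names below) per point; Pcm n x 3 in cm.
# Regions are pre-sorted by decreasing priority, so first hit wins.
.material_names_at_cm <- function(scene, Pcm) {
  n <- nrow(Pcm)
  out <- rep(scene$ambient, n)
  unassigned <- rep(TRUE, n)
  for (rg in scene$regions) {
    if (!any(unassigned)) break
    idx <- which(unassigned)
    hit <- inside_pts(rg$shape, Pcm[idx, , drop = FALSE])
    out[idx[hit]] <- rg$material
    unassigned[idx[hit]] <- FALSE
  }
  out
}

#' Material at a point
#'
#' @param scene a [scene_model()].
#' @param point position in metres (length-3 vector).
#' @return the [material()] at the point (highest-priority region, else
#'   ambient). `material_names_at()` is the vectorized variant over an
#'   `n x 3` matrix of points, returning material names.
#' @export
material_at <- function(scene, point) {
  stopifnot(inherits(scene, "scene_model"))
  nm <- .material_names_at_cm(scene, matrix(as.numeric(point) * M2CM, 1))
  scene$materials[[nm]]
}

#' @rdname material_at
#' @param points `n x 3` matrix of positions in metres.
#' @export
material_names_at <- function(scene, points) {
  stopifnot(inherits(scene, "scene_model"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  .material_names_at_cm(scene, points * M2CM)
}

#' Trace a straight ray through the scene
#'
#' Splits the segment `from -> to` at every analytic surface crossing and
#' reports ordered per-material chord lengths in cm, together with the total
#' distance and (via [optical_depth()]) the optical depth.
#'
#' @param scene a [scene_model()].
#' @param from,to endpoints in metres; must differ.
#' @return object of class `path_result`: `segments` (data.frame `material`,
#'   `length_cm`), `distance_cm`, and the scene's material objects.
#' @export
trace_ray <- function(scene, from, to) {
  stopifnot(inherits(scene, "scene_model"))
  p0 <- as.numeric(from) * M2CM; p1 <- as.numeric(to) * M2CM
  d <- sqrt(sum((p1 - p0)^2))
  if (d < .EPS) stop("degenerate zero-length ray")
  ts <- c(0, 1)
  for (rg in scene$regions) ts <- c(ts, seg_events(rg$shape, p0, p1))
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  mid <- (ts[-length(ts)] + ts[-1]) / 2
  Pmid <- matrix(p0, length(mid), 3, byrow = TRUE) +
    outer(mid, p1 - p0)
  mats <- .material_names_at_cm(scene, Pmid)
  lens <- diff(ts) * d
  # merge consecutive identical materials
  keep <- c(TRUE, mats[-1] != mats[-length(mats)])
  grp <- cumsum(keep)
  segments <- data.frame(material = mats[keep],
                         length_cm = as.vector(tapply(lens, grp, sum)),
                         stringsAsFactors = FALSE)
  structure(list(segments = segments, distance_cm = d,
                 materials = scene$materials),
            class = "path_result")
}

#' Optical depth of a traced path
#'
#' Mean free paths along the ray at a given photon energy:
#' `sum over segments of mu/rho(E) * density * length`.
#'
#' @param path a `path_result` from [trace_ray()].
#' @param energy_mev photon energy, MeV (scalar or vector).
#' @return optical depth (dimensionless), one value per energy.
#' @export
optical_depth <- function(path, energy_mev) {
  stopifnot(inherits(path, "path_result"))
  out <- numeric(length(energy_mev))
  for (i in seq_len(nrow(path$segments))) {
    m <- path$materials[[path$segments$material[i]]]
    out <- out + mu_linear(m, energy_mev) * path$segments$length_cm[i]
  }
  out
}

# Vectorized transport: per-material path lengths (cm) from n start points
# (metres, n x 3) to one end point. Fast path requires pairwise-disjoint
# regions (checked at scene build); otherwise falls back to scalar tracing.
# Returns list(dist_cm, lengths = n x n_materials matrix, names from scene).
path_lengths_matrix <- function(scene, from_pts, to) {
  if (is.null(dim(from_pts))) from_pts <- matrix(from_pts, ncol = 3)
  P0 <- from_pts * M2CM
  p1 <- as.numeric(to) * M2CM
  n <- nrow(P0)
  P1 <- matrix(p1, n, 3, byrow = TRUE)
  dist <- sqrt(rowSums((P1 - P0)^2))
  mat_names <- names(scene$materials)
  L <- matrix(0, n, length(mat_names), dimnames = list(NULL, mat_names))
  if (scene$disjoint) {
    for (rg in scene$regions)
      L[, rg$material] <- L[, rg$material] + seg_chord(rg$shape, P0, P1)
    inreg <- rowSums(L)
    L[, scene$ambient] <- L[, scene$ambient] + pmax(dist - inreg, 0)
  } else {
    for (i in seq_len(n)) {
      pr <- trace_ray(scene, from_pts[i, ], to)
      for (k in seq_len(nrow(pr$segments)))
        L[i, pr$segments$material[k]] <- L[i, pr$segments$material[k]] +
          pr$segments$length_cm[k]
    }
  }
  list(dist_cm = dist, lengths = L)
}
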