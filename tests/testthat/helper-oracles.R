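# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's computation paths: histogram counting by direct
# thresholding, areas by dense point sampling with pracma's point-in-polygon,
# distances by a plain double loop, rank-sum tails by enumeration.

# A small family of seeded phantoms covering shapes and dose models.
oracle_phantom <- function(seed) {
  set.seed(seed)
  model <- switch(seed %% 3 + 1,
                  dose_uniform(40 + 5 * (seed %% 4)),
                  dose_z_gradient(0.08 + 0.01 * (seed %% 3)),
                  dose_spherical_falloff(c(0, 0, 0), 70, 30))
  shape <- switch(seed %% 4 + 1,
                  shape_sphere(10 + (seed %% 5)),
                  shape_box(24, 20, 16),
                  shape_cylinder(8, 20),
                  shape_ring(12, 6, 16))
  make_phantom(phantom_spec(
    grid_shape = c(24, 24, 16), spacing = c(2.5, 2.5, 2.5),
    dose_model = model,
    structures = list(structure_spec("PTV", "PTV", shape)),
    seed = seed))
}

# Cumulative histogram by direct thresholding of the masked voxel doses.
oracle_cumulative <- function(doses, voxel_cc, bin_width, nbins) {
  edges <- (seq_len(nbins) - 1L) * bin_width
  vapply(edges, function(e) sum(doses >= e) * voxel_cc, 0)
}

# Even-odd membership via pracma, one ring at a time (parity count).
oracle_in_region <- function(px, py, rings) {
  parity <- rep(0L, length(px))
  for (r in rings)
    parity <- parity + as.integer(pracma::inpolygon(px, py, r$x, r$y))
  parity %% 2L == 1L
}

# Region area by dense even-odd point sampling (absolute error ~ step^2/cell).
oracle_area <- function(rings, step = 0.25) {
  xs <- range(unlist(lapply(rings, `[[`, "x")))
  ys <- range(unlist(lapply(rings, `[[`, "y")))
  # midpoint (cell-center) sampling avoids boundary-lattice coincidences
  gx <- seq(xs[1] + step / 2, xs[2], by = step)
  gy <- seq(ys[1] + step / 2, ys[2], by = step)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  sum(oracle_in_region(px, py, rings)) * step^2
}

# Plain double-loop distance summaries between two point matrices (mm).
oracle_distances <- function(p1, p2) {
  d <- numeric(nrow(p1) * nrow(p2))
  k <- 0L
  for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
    k <- k + 1L
    d[k] <- sqrt(sum((p1[i, ] - p2[j, ])^2))
  }
  list(min = min(d), mean = mean(d), median = median(d), max = max(d))
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments.
oracle_ranksum_p <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  pooled <- c(g1, g2)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2    # Mann-Whitney U
  combs <- utils::combn(n1 + n2, n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Square-contour ROI stack used across geometry tests.
square_roi <- function(name = "roi", type = "PTV", xoff = 0, yoff = 0,
                       side = 20, nz = 10, dz = 3, z0 = 0) {
  roi_contours(name, type, lapply(seq_len(nz) - 1L, function(i)
    list(z = z0 + dz * i,
         rings = list(list(x = xoff + c(0, side, side, 0),
                           y = yoff + c(0, 0, side, side))))))
}
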