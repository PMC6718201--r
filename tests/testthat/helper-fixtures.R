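# Shared fixtures and independent oracles for the test suite.

row_norms_test <- function(m) sqrt(rowSums(m^2))

# Noise-free nodes of a cubic lattice with edge a, as an n x 3 q matrix.
cubic_nodes <- function(a = 40, hmax = 3, n = 25, seed = 1) {
  g <- as.matrix(expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -hmax:hmax))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  set.seed(seed)
  g <- g[sample.int(nrow(g), min(n, nrow(g))), , drop = FALSE]
  g / a
}

# Independent inverse of the detector mapping: project a node on the Ewald
# sphere back to (fs, ss) pixels. Coded from the geometry directly, not via
# the package's forward mapping.
project_node_to_detector <- function(q, geom) {
  s <- geom$wavelength_A * q + c(0, 0, 1)     # scattered direction
  stopifnot(abs(sqrt(sum(s^2)) - 1) < 0.01)   # node must be near the sphere
  s <- s / sqrt(sum(s^2))
  # intersect the ray with the (possibly tilted) detector plane through
  # (0, 0, D) with normal tilt.z
  n <- geom$tilt %*% c(0, 0, 1)
  p0 <- c(0, 0, geom$detector_distance_mm)
  lab <- s * (sum(p0 * n) / sum(s * n))
  plane <- t(geom$tilt) %*% (lab - p0)
  c(fs = plane[1L] / geom$pixel_size_mm + geom$beam_center_px[1L],
    ss = plane[2L] / geom$pixel_size_mm + geom$beam_center_px[2L])
}

# Quaternion (Horn) superposition oracle for the optimal proper rotation
# angle between two paired vector triads, independent of the svd route.
quaternion_rotation_angle <- function(A, B) {
  A <- if (inherits(A, "lattice_basis")) A$mat else A
  B <- if (inherits(B, "lattice_basis")) B$mat else B
  S <- matrix(0, 4L, 4L)
  for (i in 1:3) {
    a <- A[i, ]; b <- B[i, ]
    # Horn's N matrix accumulated over pairs
    M <- outer(a, b)
    tr <- sum(diag(M))
    D <- c(M[2, 3] - M[3, 2], M[3, 1] - M[1, 3], M[1, 2] - M[2, 1])
    N <- rbind(c(tr, D),
               cbind(D, M + t(M) - diag(tr, 3)))
    S <- S + N
  }
  ev <- eigen(S, symmetric = TRUE)
  qv <- ev$vectors[, 1L]
  ang <- 2 * acos(min(1, abs(qv[1L])))
  ang * 180 / pi
}

# Random basis whose successive minima are reachable with small integer
# coefficients of the input vectors: a well-conditioned random cell times a
# random small unimodular matrix.
random_skewed_basis <- function() {
  cell <- c(runif(1, 20, 60), runif(1, 20, 60), runif(1, 20, 60),
            runif(1, 75, 105), runif(1, 75, 105), runif(1, 75, 105))
  B <- basis_from_cell(cell)$mat
  U <- diag(3)
  for (k in 1:3) {
    i <- sample(3, 1); j <- sample(setdiff(1:3, i), 1)
    E <- diag(3); E[i, j] <- sample(c(-1, 1), 1)
    U <- U %*% E
  }
  list(mat = U %*% B, cell = cell, U = U)
}

# Brute-force successive minima of the lattice spanned by the rows of B,
# over integer coefficient combinations in [-4, 4]^3.
brute_force_minima <- function(B, range = 4L) {
  g <- as.matrix(expand.grid(-range:range, -range:range, -range:range))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  V <- g %*% B
  n2 <- rowSums(V^2)
  o <- order(n2)
  mins <- numeric(3)
  picked <- matrix(0, 0, 3)
  for (i in o) {
    cand <- rbind(picked, g[i, ])
    if (qr(cand)$rank == nrow(cand)) {
      picked <- cand
      mins[nrow(picked)] <- sqrt(n2[i])
      if (nrow(picked) == 3L) break
    }
  }
  mins
}

# Rotation matrix about a (unit) axis by an angle in degrees.
rotation_about <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Uniformly random rotation for tests (axis-angle construction).
random_rot_test <- function() rotation_about(rnorm(3), runif(1, 0, 180))

# Default triclinic test cell used by the synthetic generator.
test_cell <- c(35, 45, 60, 85, 95, 100)

# Central differences are meaningless within h of a kink (piecewise-linear
# proximities, the tolerant inclusion boundary), where only one-sided
# derivatives exist; gradient tests redraw such points.
away_from_kinks <- function(q, t0, eps, guard = 1e-4) {
  x <- abs(fractional_offset(drop(q %*% t0)))
  kinks <- c(0, 0.15, eps, 0.5)
  all(vapply(x, function(xi) min(abs(xi - kinks)), 0) > guard)
}
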