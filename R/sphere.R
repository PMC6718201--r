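#' Approximately uniform points on the unit sphere
#'
#' Generates `n` unit vectors whose nearest-neighbour angular spacing is
#' uniform to within a factor ~2 of the ideal `sqrt(4 pi / n)`, using a
#' Fibonacci spiral lattice. The construction is deterministic and O(n);
#' `n = 1` returns the pole and `n = 2` an antipodal pair (the
#' minimum-distance-maximising placements).
#'
#' @param n Number of points (>= 1).
#' @return An n x 3 matrix of unit vectors.
#' @export
generate_sphere_points <- function(n) {
  stopifnot(n >= 1)
  n <- as.integer(n)
  if (n == 1L) return(matrix(c(0, 0, 1), 1L, 3L))
  if (n == 2L) return(rbind(c(0, 0, 1), c(0, 0, -1)))
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (i - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Search volume for candidate lattice vectors
#'
#' The maxima search is restricted to a region of real space that can contain
#' the lattice basis vectors. With no prior cell knowledge this is a spherical
#' shell from the smallest to the largest plausible lattice-vector magnitude.
#' With a known cell the volume shrinks to thin shells centred on the three
#' axis lengths, optionally extended by the face-diagonal (110/011/101)
#' lengths, which adds redundancy when spurious peaks or competing lattices
#' suppress score maxima of the primary basis vectors.
#'
#' @param r_min,r_max Shell radii in Angstrom for the unknown-cell mode
#'   (`0 < r_min < r_max`).
#' @param cell Optional numeric `c(a, b, c, alpha, beta, gamma)` prior; when
#'   given, known-cell mode is used.
#' @param half_width Shell half-width in Angstrom for known-cell mode.
#' @param extended Logical; include the 110/011/101 diagonal radii.
#' @return An object of class `search_volume`.
#' @export
search_volume <- function(r_min = 20, r_max = 300, cell = NULL,
                          half_width = 2, extended = FALSE) {
  if (is.null(cell)) {
    stopifnot(r_min > 0, r_max > r_min)
    structure(list(mode = "unknown_cell", r_min = r_min, r_max = r_max,
                   shell_radii = NULL, half_width = NULL),
              class = "search_volume")
  } else {
    stopifnot(length(cell) == 6L, all(cell[1:3] > 0), half_width > 0)
    B <- basis_from_cell(cell)
    radii <- row_norms(B$mat)
    if (extended) {
      radii <- c(radii,
                 vnorm(B$mat[1L, ] + B$mat[2L, ]),   # 110
                 vnorm(B$mat[2L, ] + B$mat[3L, ]),   # 011
                 vnorm(B$mat[1L, ] + B$mat[3L, ]))   # 101
    }
    radii <- sort(unique(round(radii, 6)))
    structure(list(mode = "known_cell", r_min = max(min(radii) - half_width,
                                                    1e-6),
                   r_max = max(radii) + half_width,
                   shell_radii = radii, half_width = half_width),
              class = "search_volume")
  }
}

#' @export
print.search_volume <- function(x, ...) {
  if (x$mode == "unknown_cell") {
    cat(sprintf("Search volume: shell %g - %g A (unknown cell)\n",
                x$r_min, x$r_max))
  } else {
    cat(sprintf("Search volume: shells at {%s} A, half-width %g A\n",
                paste(sprintf("%.4g", x$shell_radii), collapse = ", "),
                x$half_width))
  }
  invisible(x)
}

# Fill one radial interval [lo, hi] with concentric spheres whose radial
# increment equals the local in-sphere point spacing r*sqrt(4*pi/n): a
# geometric radius progression with ratio (1 + sqrt(4*pi/n)).
fill_shell <- function(lo, hi, n_sphere) {
  c0 <- sqrt(4 * pi / n_sphere)
  if (hi <= lo * (1 + c0)) return((lo + hi) / 2)
  r <- lo
  radii <- numeric(0)
  while (r <= hi + 1e-9) {
    radii <- c(radii, r)
    r <- r * (1 + c0)
  }
  radii
}

#' Starting points for the maxima search
#'
#' Builds a set of real-space starting positions filling the search volume:
#' approximately uniform point sets on concentric spheres, with the radial
#' increment between neighbouring spheres equal to the mean point spacing on
#' the sphere. Each sphere's point set is given an independent random
#' rotation to avoid systematic alignment. Because even proximity functions
#' make the score centrosymmetric about the origin, only one point of each
#' antipodal pair is kept (the half-space `z > 0`, with deterministic
#' tie-breaking on the equator), halving the work.
#'
#' @param vol A [search_volume()].
#' @param budget Maximum number of generated points before the centrosymmetry
#'   halving (>= 1). A typical full-quality budget is 50000.
#' @param seed Integer seed controlling the per-sphere rotations.
#' @return An object of class `sampling_points`: list with `pos` (n x 3
#'   matrix), per-point previous step direction `dir`, step length `len`,
#'   `score` and `inliers` state.
#' @export
build_starting_points <- function(vol, budget, seed = 1L) {
  stopifnot(inherits(vol, "search_volume"))
  if (budget < 1) stop("budget too small to place a single sphere of points")
  intervals <- if (vol$mode == "unknown_cell") {
    list(c(vol$r_min, vol$r_max))
  } else {
    lapply(vol$shell_radii, function(r)
      c(max(r - vol$half_width, 1e-6), r + vol$half_width))
  }
  # Points per sphere: with geometric radii the sphere count over the
  # intervals is ~ L/sqrt(4 pi / n) for L = sum(log(hi/lo)), so the budget
  # constraint n * m = budget gives n = (budget * sqrt(4 pi) / L)^(2/3).
  L <- sum(vapply(intervals, function(iv)
    log(max(iv[2L] / iv[1L], 1 + 1e-9)), 0))
  n_sphere <- max(1L, min(budget,
                          as.integer((budget * sqrt(4 * pi) / L)^(2 / 3))))
  radii <- unlist(lapply(intervals, function(iv)
    fill_shell(iv[1L], iv[2L], n_sphere)))
  # Trim sphere budget if rounding overflowed the total budget.
  while (length(radii) * n_sphere > budget && n_sphere > 1L)
    n_sphere <- as.integer(floor(budget / length(radii)))
  base_pts <- generate_sphere_points(n_sphere)
  pos <- with_local_seed(seed, {
    do.call(rbind, lapply(radii, function(r) {
      R <- random_rotation()
      r * (base_pts %*% t(R))
    }))
  })
  # Centrosymmetry: keep one point of each antipodal pair (half-space +z;
  # ties on the equator resolved by x then y sign).
  keep <- pos[, 3L] > 1e-12 |
    (abs(pos[, 3L]) <= 1e-12 &
       (pos[, 1L] > 1e-12 |
          (abs(pos[, 1L]) <= 1e-12 & pos[, 2L] >= 0)))
  pos <- pos[keep, , drop = FALSE]
  n <- nrow(pos)
  structure(list(pos = pos,
                 dir = matrix(0, n, 3L),
                 len = rep(0.5, n),
                 score = rep(NA_real_, n),
                 inliers = rep(NA_integer_, n)),
            class = "sampling_points")
}

#' @export
print.sampling_points <- function(x, ...) {
  cat(sprintf("Sampling points: %d positions", nrow(x$pos)))
  if (!anyNA(x$score))
    cat(sprintf(", score in [%.3f, %.3f]", min(x$score), max(x$score)))
  cat("\n")
  invisible(x)
}
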