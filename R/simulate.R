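#' Parameters of a synthetic diffraction scene
#'
#' Describes the ground-truth conditions the generator emulates: one to
#' three independently oriented lattices, reciprocal-lattice nodes selected
#' up to a resolution limit (optionally restricted to a thin Ewald shell as
#' in a still exposure), isotropic Gaussian positional noise, and spurious
#' (non-lattice) nodes uniform in the resolution ball.
#'
#' The default cell is a triclinic 35/45/60 Angstrom cell with angles
#' 85/95/100 degrees, chosen to avoid accidental symmetry degeneracies that
#' would confound basis-equivalence checks. The default noise is 1% of the
#' smallest reciprocal basis-vector norm, and the default spurious count is
#' 30% of the per-lattice node count.
#'
#' @param cell Numeric `c(a, b, c, alpha, beta, gamma)`.
#' @param n_lattices Number of lattices (1-3).
#' @param n_nodes Lattice nodes per lattice.
#' @param noise_frac Noise sigma as a fraction of the smallest reciprocal
#'   basis-vector norm; ignored if `noise_sigma` is given.
#' @param noise_sigma Absolute noise sigma in 1/Angstrom (overrides
#'   `noise_frac`).
#' @param n_spurious Number of spurious nodes; `NULL` means
#'   `round(0.3 * n_nodes)`.
#' @param q_max Resolution limit in 1/Angstrom (default 0.25, i.e. 4 A).
#' @param ewald_mode Restrict lattice nodes to a thin Ewald shell (still
#'   geometry); `FALSE` samples the full resolution ball, convenient for
#'   unit tests.
#' @param wavelength_A Wavelength defining the Ewald sphere (default 1.0).
#' @param shell_half_width Ewald shell half-thickness in 1/Angstrom
#'   (default 0.002).
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(cell = c(35, 45, 60, 85, 95, 100),
                         n_lattices = 1L, n_nodes = 25L,
                         noise_frac = 0.01, noise_sigma = NULL,
                         n_spurious = NULL, q_max = 0.25,
                         ewald_mode = TRUE, wavelength_A = 1.0,
                         shell_half_width = 0.002) {
  stopifnot(length(cell) == 6L, n_lattices >= 1L, n_lattices <= 3L,
            n_nodes >= 1L, q_max > 0)
  if (is.null(n_spurious)) n_spurious <- round(0.3 * n_nodes)
  structure(list(cell = cell, n_lattices = as.integer(n_lattices),
                 n_nodes = as.integer(n_nodes), noise_frac = noise_frac,
                 noise_sigma = noise_sigma,
                 n_spurious = as.integer(n_spurious), q_max = q_max,
                 ewald_mode = isTRUE(ewald_mode),
                 wavelength_A = wavelength_A,
                 shell_half_width = shell_half_width),
            class = "scene_params")
}

# All reciprocal-lattice points of basis B (rows a,b,c) with 0 < |q| <= q_max.
reciprocal_points <- function(B, q_max) {
  lim <- pmax(1L, ceiling(row_norms(B) * q_max))
  g <- expand.grid(h = -lim[1L]:lim[1L], k = -lim[2L]:lim[2L],
                   l = -lim[3L]:lim[3L])
  H <- as.matrix(g)
  Qall <- H %*% t(solve(B))
  r <- row_norms(Qall)
  keep <- r > 1e-12 & r <= q_max
  list(q = Qall[keep, , drop = FALSE], hkl = H[keep, , drop = FALSE])
}

#' Simulate a synthetic diffraction scene
#'
#' For each lattice: draw a uniformly random orientation (quaternion
#' method), enumerate the reciprocal-lattice points within the resolution
#' limit (restricted to a thin Ewald shell in `ewald_mode`), sample
#' `n_nodes` distinct points, and add isotropic Gaussian positional noise.
#' Spurious nodes are appended uniformly in the resolution ball. The scene
#' is fully determined by `params` and `seed`.
#'
#' @param params A [scene_params()].
#' @param seed Integer seed.
#' @return An object of class `diffraction_scene`: list with `true_bases`
#'   (list of oriented [lattice_basis()]), `nodes` (a [node_set()]),
#'   `labels` (per-node lattice id, 0 for spurious), `noise_sigma`, `params`
#'   and `seed`.
#' @export
simulate_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  B0 <- basis_from_cell(params$cell)$mat
  sigma <- if (!is.null(params$noise_sigma)) params$noise_sigma else
    params$noise_frac * min(row_norms(t(solve(B0))))
  with_local_seed(seed, {
    qs <- list()
    labels <- integer(0)
    true_bases <- vector("list", params$n_lattices)
    for (li in seq_len(params$n_lattices)) {
      R <- random_rotation()
      B <- B0 %*% t(R)
      true_bases[[li]] <- lattice_basis(B)
      rp <- reciprocal_points(B, params$q_max)
      if (params$ewald_mode) {
        centre <- c(0, 0, -1 / params$wavelength_A)
        d <- abs(row_norms(rp$q - matrix(centre, nrow(rp$q), 3L,
                                         byrow = TRUE)) -
                   1 / params$wavelength_A)
        sel <- d <= params$shell_half_width
        rp$q <- rp$q[sel, , drop = FALSE]
      }
      if (nrow(rp$q) == 0L)
        stop("no reciprocal-lattice points within the resolution limit")
      if (nrow(rp$q) < params$n_nodes)
        stop(sprintf(
          "only %d reachable reciprocal-lattice points for %d requested nodes",
          nrow(rp$q), params$n_nodes))
      pick <- sample.int(nrow(rp$q), params$n_nodes)
      qq <- rp$q[pick, , drop = FALSE]
      # truncate the Gaussian at 5 sigma so labelled nodes stay attributable
      noise <- matrix(stats::rnorm(length(qq), sd = sigma), nrow(qq), 3L)
      noise[] <- pmax(pmin(noise, 5 * sigma), -5 * sigma)
      qs[[li]] <- qq + noise
      labels <- c(labels, rep.int(li, params$n_nodes))
    }
    if (params$n_spurious > 0L) {
      u <- matrix(stats::rnorm(3L * params$n_spurious), params$n_spurious, 3L)
      u <- u / row_norms(u)
      r <- params$q_max * stats::runif(params$n_spurious)^(1 / 3)
      qs[[length(qs) + 1L]] <- u * r
      labels <- c(labels, rep.int(0L, params$n_spurious))
    }
    qmat <- do.call(rbind, qs)
    nodes <- node_set(qmat,
                      source = ifelse(labels == 0L, "spurious-synthetic",
                                      "synthetic"))
    structure(list(true_bases = true_bases, nodes = nodes, labels = labels,
                   noise_sigma = sigma, params = params, seed = seed),
              class = "diffraction_scene")
  })
}

#' @export
print.diffraction_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic diffraction scene: %d lattice(s), %d node(s) (%d spurious), sigma = %.3g 1/A\n",
    length(x$true_bases), x$nodes$K, sum(x$labels == 0L), x$noise_sigma))
  invisible(x)
}

#' Write a scene's ground truth as JSON
#'
#' @param scene A `diffraction_scene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene_truth <- function(scene, path) {
  truth <- list(
    bases = lapply(scene$true_bases, function(b) unname(b$mat)),
    labels = scene$labels,
    noise_sigma = scene$noise_sigma,
    cell = scene$params$cell,
    seed = scene$seed)
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a scene ground-truth JSON
#'
#' @param path Path written by [write_scene_truth()].
#' @return List with `bases` (list of [lattice_basis()]), `labels`,
#'   `noise_sigma`, `cell`, `seed`.
#' @export
read_scene_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- truth$bases
  bases <- if (is.array(raw) && length(dim(raw)) == 3L) {
    lapply(seq_len(dim(raw)[1L]), function(i)
      lattice_basis(matrix(raw[i, , ], 3L, 3L)))
  } else if (is.list(raw)) {
    lapply(raw, function(m) lattice_basis(matrix(unlist(m), 3L, 3L,
                                                 byrow = is.null(dim(m)))))
  } else {
    list(lattice_basis(matrix(unlist(raw), 3L, 3L)))
  }
  for (b in bases)
    if (abs(b$det) < 1e-9) stop("truth file contains a singular basis")
  list(bases = bases, labels = truth$labels,
       noise_sigma = truth$noise_sigma, cell = truth$cell,
       seed = truth$seed)
}
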