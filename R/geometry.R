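#' Detector geometry for a flat single-panel detector
#'
#' Describes the experiment geometry needed to map Bragg-peak positions on the
#' detector into reciprocal space. The incident beam travels along +z in the
#' lab frame; the detector plane is normal to the beam at `detector_distance`,
#' with the fast-scan (fs) and slow-scan (ss) pixel axes mapping to lab x and
#' y. An optional tilt rotation can be applied to the detector plane.
#'
#' @param wavelength_A Incident wavelength in Angstrom (> 0).
#' @param detector_distance_mm Sample-to-detector distance in mm (> 0).
#' @param pixel_size_mm Pixel edge length in mm (> 0).
#' @param beam_center_px Length-2 numeric, beam centre in (fs, ss) pixels.
#' @param tilt 3x3 rotation applied to the detector plane; default identity.
#' @return An object of class `detector_geometry`.
#' @examples
#' geom <- detector_geometry(1.3, 100, 0.11, c(720, 710))
#' @export
detector_geometry <- function(wavelength_A, detector_distance_mm,
                              pixel_size_mm, beam_center_px,
                              tilt = diag(3)) {
  stopifnot(is.numeric(wavelength_A), wavelength_A > 0,
            is.numeric(detector_distance_mm), detector_distance_mm > 0,
            is.numeric(pixel_size_mm), pixel_size_mm > 0,
            length(beam_center_px) == 2L, all(is.finite(beam_center_px)))
  tilt <- as.matrix(tilt)
  if (!all(dim(tilt) == c(3L, 3L)) ||
      max(abs(crossprod(tilt) - diag(3))) > 1e-8)
    stop("'tilt' must be a 3x3 rotation matrix")
  structure(list(wavelength_A = wavelength_A,
                 detector_distance_mm = detector_distance_mm,
                 pixel_size_mm = pixel_size_mm,
                 beam_center_px = as.numeric(beam_center_px),
                 tilt = tilt),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("Detector geometry (flat single panel)\n")
  cat(sprintf("  wavelength:        %g A\n", x$wavelength_A))
  cat(sprintf("  detector distance: %g mm\n", x$detector_distance_mm))
  cat(sprintf("  pixel size:        %g mm\n", x$pixel_size_mm))
  cat(sprintf("  beam centre:       (%g, %g) px\n",
              x$beam_center_px[1L], x$beam_center_px[2L]))
  invisible(x)
}

#' Set of reciprocal-space nodes
#'
#' A node is the 3D momentum-transfer vector derived from one Bragg peak: a
#' noisy sample of a reciprocal-lattice point. The crystallographic convention
#' is used throughout (no 2*pi factor), so `q . t` is an integer when `t` is a
#' real-space lattice vector and `q` a reciprocal-lattice point. Units are
#' 1/Angstrom.
#'
#' @param q Numeric n x 3 matrix of reciprocal-space vectors (1/Angstrom).
#' @param weight Non-negative per-node weights (recycled); typically unity or
#'   peak intensities.
#' @param source Character vector of provenance labels, one of `"observed"`,
#'   `"synthetic"`, `"spurious-synthetic"` (recycled).
#' @return An object of class `node_set` with elements `q`, `weight`, `source`
#'   and node count `K`.
#' @export
node_set <- function(q, weight = 1, source = "observed") {
  q <- as_matrix3(q, "q")
  n <- nrow(q)
  weight <- rep_len(as.numeric(weight), n)
  source <- rep_len(as.character(source), n)
  if (any(!is.finite(q))) stop("node coordinates must be finite")
  if (any(weight < 0)) stop("node weights must be >= 0")
  ok <- source %in% c("observed", "synthetic", "spurious-synthetic")
  if (!all(ok)) stop("unknown node source label")
  structure(list(q = q, weight = weight, source = source, K = n),
            class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("Node set: %d reciprocal-space nodes", x$K))
  if (x$K > 0L) {
    r <- row_norms(x$q)
    cat(sprintf(", |q| in [%.4g, %.4g] 1/A", min(r), max(r)))
  }
  cat("\n")
  invisible(x)
}

#' @export
`[.node_set` <- function(x, i) {
  node_set(x$q[i, , drop = FALSE], x$weight[i], x$source[i])
}

#' Map detector peaks to reciprocal-space nodes
#'
#' Applies the Ewald construction: a peak at lab-frame position `p` scatters
#' the beam along the unit vector `s = p/|p|`, and the momentum transfer is
#' `q = (s - s0)/lambda` with `s0` the unit incident-beam direction (+z).
#' Every mapped node lies on the Ewald sphere of radius `1/lambda` centred at
#' `-s0/lambda`, and `|q| = 2 sin(theta)/lambda` for scattering angle
#' `2 theta`.
#'
#' Peaks at exactly zero scattering angle carry no lattice information
#' (`q = 0`); they are dropped with a warning rather than failing the whole
#' pattern. A peak whose lab-frame position has non-positive beam-axis
#' component under the detector tilt cannot be reached by forward scattering
#' and raises an error identifying the peak.
#'
#' @param peaks Data frame with columns `fs_px`, `ss_px` and optionally
#'   `intensity` (as returned by [read_peak_list()]).
#' @param geom A [detector_geometry()].
#' @param weighting Either `"unity"` (default) or `"intensity"`; sets the node
#'   weights carried into scoring.
#' @return A [node_set()] with source `"observed"`.
#' @seealso [read_peak_list()], [plane_spacing()]
#' @export
peaks_to_nodes <- function(peaks, geom, weighting = c("unity", "intensity")) {
  stopifnot(inherits(geom, "detector_geometry"),
            all(c("fs_px", "ss_px") %in% names(peaks)))
  weighting <- match.arg(weighting)
  n <- nrow(peaks)
  if (n == 0L) return(node_set(matrix(numeric(0), 0L, 3L)))
  xy <- cbind((peaks$fs_px - geom$beam_center_px[1L]) * geom$pixel_size_mm,
              (peaks$ss_px - geom$beam_center_px[2L]) * geom$pixel_size_mm,
              0)
  pos <- xy %*% t(geom$tilt)
  pos[, 3L] <- pos[, 3L] + geom$detector_distance_mm
  if (any(pos[, 3L] <= 0))
    stop(sprintf("peak %d lies behind the detector plane given the tilt",
                 which(pos[, 3L] <= 0)[1L]))
  s <- pos / row_norms(pos)
  q <- s
  q[, 3L] <- q[, 3L] - 1
  q <- q / geom$wavelength_A
  usable <- row_norms(q) > 0
  if (!all(usable))
    warning(sprintf("dropping %d peak(s) at zero scattering angle",
                    sum(!usable)))
  w <- if (weighting == "intensity" && !is.null(peaks$intensity))
    peaks$intensity else 1
  node_set(q[usable, , drop = FALSE],
           weight = rep_len(w, n)[usable],
           source = "observed")
}

#' Map a single peak to a node
#'
#' Convenience scalar wrapper around [peaks_to_nodes()].
#'
#' @param fs_px,ss_px Detector coordinates in pixels.
#' @param geom A [detector_geometry()].
#' @param intensity Peak intensity (>= 0).
#' @return A [node_set()] of size one (or zero if the peak sits at the beam
#'   centre).
#' @export
map_peak_to_node <- function(fs_px, ss_px, geom, intensity = 1) {
  peaks_to_nodes(data.frame(fs_px = fs_px, ss_px = ss_px,
                            intensity = intensity), geom)
}

#' Real-space spacing of the plane family generated by a node
#'
#' Each node `q` defines a family of equidistant parallel real-space planes
#' `q . t = m`, orthogonal to `q`, with spacing `1/|q|`.
#'
#' @param x A [node_set()] or an n x 3 matrix of q vectors.
#' @return Numeric vector of plane spacings in Angstrom.
#' @export
plane_spacing <- function(x) {
  q <- if (inherits(x, "node_set")) x$q else as_matrix3(x, "x")
  r <- row_norms(q)
  if (any(r == 0)) stop("degenerate node with |q| = 0 has no plane spacing")
  1 / r
}

parse_numeric_row <- function(fields, n_expected, path, line_no) {
  vals <- suppressWarnings(as.numeric(fields))
  if (length(vals) < n_expected || anyNA(vals[seq_len(n_expected)]))
    stop(sprintf("malformed row at %s:%d", path, line_no))
  vals
}

#' Read a Bragg-peak list
#'
#' Peak lists are UTF-8 tab-separated text with columns `fs_px`, `ss_px`,
#' `intensity`, one file per pattern. Lines starting with `#` are comments; an
#' optional header naming the columns is skipped. A file with no data rows
#' yields an empty (zero-row) data frame.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `fs_px`, `ss_px`, `intensity`.
#' @export
read_peak_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("peak list '%s' not found", path))
  lines <- readLines(path, encoding = "UTF-8")
  out <- matrix(numeric(0), 0L, 3L)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "[\t ]+")[[1L]]
    if (length(rows) == 0L &&
        anyNA(suppressWarnings(as.numeric(fields[1L])))) next  # header line
    vals <- parse_numeric_row(fields, 3L, path, i)
    if (vals[3L] < 0)
      stop(sprintf("negative intensity at %s:%d", path, i))
    rows[[length(rows) + 1L]] <- vals[1:3]
  }
  if (length(rows)) out <- do.call(rbind, rows)
  data.frame(fs_px = out[, 1L], ss_px = out[, 2L], intensity = out[, 3L])
}

#' Read a node list
#'
#' Alternative direct input: a TSV with columns `qx`, `qy`, `qz` in
#' 1/Angstrom, bypassing the geometry mapping. `#` comments and an optional
#' header are skipped.
#'
#' @param path Path to the TSV file.
#' @return A [node_set()].
#' @export
read_node_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("node list '%s' not found", path))
  lines <- readLines(path, encoding = "UTF-8")
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "[\t ]+")[[1L]]
    if (length(rows) == 0L &&
        anyNA(suppressWarnings(as.numeric(fields[1L])))) next
    rows[[length(rows) + 1L]] <- parse_numeric_row(fields, 3L, path, i)[1:3]
  }
  q <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), 0L, 3L)
  node_set(q)
}

#' Write a node list
#'
#' @param nodes A [node_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_list <- function(nodes, path) {
  stopifnot(inherits(nodes, "node_set"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("qx\tqy\tqz", con)
  if (nodes$K > 0L)
    writeLines(sprintf("%.10g\t%.10g\t%.10g",
                       nodes$q[, 1L], nodes$q[, 2L], nodes$q[, 3L]), con)
  invisible(path)
}

#' Read an experiment geometry file
#'
#' Flat YAML key-value file with keys `wavelength_A`, `detector_distance_mm`,
#' `pixel_size_mm` and `beam_center_px` (a two-element list).
#'
#' @param path Path to the YAML file.
#' @return A [detector_geometry()].
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop(sprintf("geometry file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  need <- c("wavelength_A", "detector_distance_mm", "pixel_size_mm",
            "beam_center_px")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(sprintf("geometry file missing key(s): %s",
                 paste(miss, collapse = ", ")))
  detector_geometry(cfg$wavelength_A, cfg$detector_distance_mm,
                    cfg$pixel_size_mm, unlist(cfg$beam_center_px))
}

#' Read a unit-cell prior
#'
#' Key-value YAML file with keys `a_A`, `b_A`, `c_A`, `alpha_deg`, `beta_deg`,
#' `gamma_deg`.
#'
#' @param path Path to the YAML file.
#' @return Named numeric vector `c(a, b, c, alpha, beta, gamma)` in Angstrom
#'   and degrees.
#' @export
read_cell_prior <- function(path) {
  if (!file.exists(path)) stop(sprintf("cell file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  need <- c("a_A", "b_A", "c_A", "alpha_deg", "beta_deg", "gamma_deg")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(sprintf("cell file missing key(s): %s", paste(miss, collapse = ", ")))
  cell <- as.numeric(cfg[need])
  names(cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
  if (any(cell[1:3] <= 0) || any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    stop("invalid unit-cell parameters")
  cell
}
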