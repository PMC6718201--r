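#' Index a still diffraction pattern
#'
#' Fits one or more real-space lattice bases to a set of reciprocal-space
#' nodes. The pipeline: candidate lattice vectors are located as maxima of
#' the periodic score transform (five-stage extended gradient descent over a
#' seeded search volume), bases are assembled from peak triples, reduced to
#' shortest vectors, filtered by prediction counts, determinant and (when
#' given) the prior cell, the best are selected greedily by the nodes they
#' explain, and each accepted basis is refined by alternating
#' assignment/least-squares. With `multi = "delete_and_retry"` the strongest
#' lattice's nodes are removed and the pipeline re-runs on the remainder (up
#' to `control$max_rounds` rounds); the default one-pass mode can already
#' return several lattices.
#'
#' @param nodes A [node_set()], an n x 3 matrix of q vectors (1/Angstrom),
#'   or a data frame of detector peaks (then `geometry` is required).
#' @param cell Optional prior unit cell `c(a, b, c, alpha, beta, gamma)`.
#' @param profile `"fast"` (default) or `"precise"`: trade speed for search
#'   thoroughness (starting-point budget and per-stage step counts).
#' @param multi `"one_pass"` (default) or `"delete_and_retry"`.
#' @param seed Integer seed; the whole fit is deterministic given inputs and
#'   seed.
#' @param control An [index_control()].
#' @param geometry A [detector_geometry()], required when `nodes` is a peak
#'   data frame.
#' @return An object of class `still_index` with elements `solutions` (list,
#'   possibly empty: each with `basis`, `cell`, `hkl`, `predicted`,
#'   `n_predicted`, `absolute_defect`, `relative_defect`, `score`,
#'   `lattice_id`), `nodes`, `cell`, `profile`, `multi`, `seed`, `control`
#'   and `call`. Fewer than 5 usable nodes yields an empty solution list,
#'   not an error.
#' @seealso [simulate_scene()] to generate test scenes,
#'   [bases_equivalent()] to check solutions against a ground truth.
#' @examples
#' scene <- simulate_scene(scene_params(n_nodes = 25, noise_frac = 0,
#'                                      n_spurious = 0), seed = 7)
#' fit <- index_still(scene$nodes, seed = 7)
#' fit
#' @export
index_still <- function(nodes, cell = NULL,
                        profile = c("fast", "precise"),
                        multi = c("one_pass", "delete_and_retry"),
                        seed = 1L, control = index_control(),
                        geometry = NULL) {
  profile <- match.arg(profile)
  multi <- match.arg(multi)
  if (is.data.frame(nodes)) {
    if (is.null(geometry))
      stop("peak-table input requires a detector geometry")
    nodes <- peaks_to_nodes(nodes, geometry)
  }
  if (!inherits(nodes, "node_set")) nodes <- node_set(nodes)
  budget <- if (!is.null(control$budget)) control$budget else
    if (profile == "precise") 50000L else 12000L
  fit <- structure(list(solutions = list(), nodes = nodes, cell = cell,
                        profile = profile, multi = multi, seed = seed,
                        control = control, call = match.call()),
                   class = "still_index")
  if (nodes$K < 5L) return(fit)
  if (multi == "one_pass") {
    fit$solutions <- index_one_pass(nodes, cell, profile, seed, control,
                                    budget)
  } else {
    remaining <- rep(TRUE, nodes$K)
    sols <- list()
    for (round in seq_len(control$max_rounds)) {
      if (sum(remaining) < 5L) break
      sub <- nodes[which(remaining)]
      got <- index_one_pass(sub, cell, profile, derive_seed(seed, round),
                            control, budget)
      if (!length(got)) break
      best <- got[[1L]]
      # lift the per-subset masks back to the full node set
      idx <- which(remaining)
      full_pred <- rep(FALSE, nodes$K)
      full_pred[idx[best$predicted]] <- TRUE
      full_hkl <- matrix(NA_integer_, nodes$K, 3L)
      full_hkl[idx, ] <- best$hkl
      best$predicted <- full_pred
      best$hkl <- full_hkl
      sols[[length(sols) + 1L]] <- best
      remaining[full_pred] <- FALSE
    }
    fit$solutions <- sols
  }
  if (length(fit$solutions))
    for (i in seq_along(fit$solutions))
      fit$solutions[[i]]$lattice_id <- i
  fit
}

# Single-pass pipeline on a node set; returns solution records sorted
# strongest-first.
index_one_pass <- function(nodes, cell, profile, seed, control, budget) {
  vol <- if (is.null(cell))
    search_volume(r_min = control$r_min, r_max = control$r_max)
  else
    search_volume(cell = cell, half_width = control$cell_half_width,
                  extended = control$extended_search)
  stages <- default_stages(profile, epsilon = control$epsilon)
  peaks <- find_lattice_vector_candidates(
    nodes, vol, stages = stages, seed = seed, budget = budget,
    environment_radius = control$environment_radius)
  cands <- enumerate_candidate_bases(peaks, nodes, control, cell)
  sols <- select_lattices(cands, nodes, control)
  out <- list()
  for (s in sols) {
    refined <- suppressWarnings(
      refine_basis(s$basis, nodes, relative_tol = control$relative_tol))
    refined <- reduce_basis(refined)
    d <- compute_defects(refined, nodes, control$relative_tol)
    if (d$n_predicted < control$min_predicted) next
    # cell-multiplicity guard: collapse supercells / expand halved cells to
    # the primitive cell that best explains the nodes
    corr <- rational_cell_correction(refined, nodes, control$relative_tol,
                                     control$min_predicted)
    refined <- corr$basis
    d <- corr$defects
    out[[length(out) + 1L]] <- list(
      basis = refined, cell = cell_parameters(refined), hkl = d$hkl,
      predicted = d$predicted, n_predicted = d$n_predicted,
      absolute_defect = d$absolute_defect,
      relative_defect = d$relative_defect, score = s$score,
      lattice_id = NA_integer_)
  }
  if (length(out) > 1L) {
    o <- order(-vapply(out, `[[`, 0L, "n_predicted"),
               vapply(out, `[[`, 0, "relative_defect"))
    out <- out[o]
    drop <- logical(length(out))
    for (u in seq_along(out)) for (v in seq_along(out)) {
      if (u >= v || drop[u] || drop[v]) next
      if (bases_equivalent(out[[u]]$basis, out[[v]]$basis,
                           angle_tol_deg = control$dedupe_angle_deg))
        drop[v] <- TRUE
    }
    out <- out[!drop]
  }
  out
}

#' Write indexing solutions as TSV
#'
#' One row per lattice: id, cell parameters, the basis matrix (9 floats,
#' row-major a, b, c), prediction count and defects.
#'
#' @param fit A `still_index` fit.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_solutions <- function(fit, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("lattice_id", "a_A", "b_A", "c_A", "alpha_deg",
                     "beta_deg", "gamma_deg",
                     paste0("m", rep(1:3, each = 3), 1:3),
                     "n_predicted", "absolute_defect", "relative_defect"),
                   collapse = "\t"), con)
  for (s in fit$solutions) {
    vals <- c(s$lattice_id, sprintf("%.6f", s$cell),
              sprintf("%.8g", as.vector(t(s$basis$mat))),
              s$n_predicted, sprintf("%.8g", s$absolute_defect),
              sprintf("%.8g", s$relative_defect))
    writeLines(paste(vals, collapse = "\t"), con)
  }
  invisible(path)
}

#' Write per-node Miller assignments as TSV
#'
#' @param fit A `still_index` fit.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(fit, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("node_index\th\tk\tl\tlattice_id", con)
  if (length(fit$solutions)) {
    claimed <- rep(FALSE, fit$nodes$K)
    for (s in fit$solutions) {
      idx <- which(s$predicted & !claimed)
      claimed[idx] <- TRUE
      for (i in idx)
        writeLines(sprintf("%d\t%d\t%d\t%d\t%d", i, s$hkl[i, 1L],
                           s$hkl[i, 2L], s$hkl[i, 3L], s$lattice_id), con)
    }
  }
  invisible(path)
}
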