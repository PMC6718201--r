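#' Kabsch rotation angle between two bases
#'
#' Finds the proper rotation that best superposes the three paired basis
#' vectors (minimal RMSD over the pairs a-a, b-b, c-c) and returns its
#' rotation angle in degrees. The result is invariant under a joint rotation
#' of both bases and is zero iff the triads can be superposed exactly by a
#' proper rotation.
#'
#' @param basisA,basisB [lattice_basis()] objects or 3 x 3 matrices (rows a,
#'   b, c), both non-singular.
#' @return Rotation angle in degrees, in `[0, 180]`.
#' @export
kabsch_rotation_angle <- function(basisA, basisB) {
  A <- basis_mat(basisA)
  B <- basis_mat(basisB)
  if (abs(det(A)) < 1e-12 || abs(det(B)) < 1e-12)
    stop("bases must be non-singular")
  H <- t(A) %*% B            # sum over paired vectors of a_i b_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

signed_permutations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  out <- vector("list", 48L)
  n <- 0L
  for (p in perms) for (s in seq_len(nrow(signs))) {
    n <- n + 1L
    out[[n]] <- list(perm = p, sign = signs[s, ])
  }
  out
}

#' Are two bases equivalent descriptions of the same lattice?
#'
#' Reduces both bases, then minimises the Kabsch rotation angle over the 48
#' signed axis permutations of the second basis whose vector lengths match
#' the first within `length_tol`. Equivalence holds when the minimal angle is
#' at most `angle_tol_deg`. This is the correctness criterion used for
#' evaluating indexing solutions: a solution is counted correct when it can
#' be rotated onto the ground truth by no more than 3 degrees.
#'
#' @param basisA,basisB [lattice_basis()] objects or 3 x 3 matrices.
#' @param angle_tol_deg Maximum rotation angle in degrees (default 3).
#' @param length_tol Relative tolerance on matching cell lengths (default
#'   0.05).
#' @return Logical flag.
#' @export
bases_equivalent <- function(basisA, basisB, angle_tol_deg = 3,
                             length_tol = 0.05) {
  A <- reduce_basis(basisA)$mat
  B <- reduce_basis(basisB)$mat
  na <- row_norms(A)
  nb <- row_norms(B)
  if (any(abs(sort(na) - sort(nb)) / sort(na) > length_tol)) return(FALSE)
  best <- Inf
  for (sp in signed_permutations()) {
    Bp <- B[sp$perm, , drop = FALSE] * sp$sign
    if (any(abs(row_norms(Bp) - na) / na > length_tol)) next
    ang <- kabsch_rotation_angle(A, Bp)
    if (ang < best) best <- ang
    if (best <= angle_tol_deg) return(TRUE)
  }
  best <= angle_tol_deg
}

#' Indexing success rate over seeded synthetic scenes
#'
#' Simulates `n_trials` scenes, runs the indexer on each and scores the
#' result against the ground truth: a trial succeeds when at least one
#' returned solution is equivalent (within the 3-degree Kabsch criterion) to
#' a true basis.
#'
#' @param params A [scene_params()] description of the scene conditions.
#' @param n_trials Number of trials (>= 1); ignored if `seeds` is given.
#' @param seeds Optional explicit integer seeds, one per trial.
#' @param angle_tol_deg Kabsch angle threshold for correctness (default 3).
#' @param ... Passed on to [index_still()] (e.g. `cell`, `profile`,
#'   `control`).
#' @return List with `rate` (fraction of successful trials) and `trials`, a
#'   data frame with per-trial seed, success flag, minimal Kabsch angle,
#'   relative cell-length error, and the number of lattices found and true.
#' @export
success_rate <- function(params, n_trials = 10L, seeds = NULL,
                         angle_tol_deg = 3, ...) {
  if (is.null(seeds)) seeds <- seq_len(n_trials)
  res <- lapply(seeds, function(s) {
    scene <- simulate_scene(params, seed = s)
    fit <- index_still(scene$nodes, seed = derive_seed(s, 1L), ...)
    evaluate_solutions(fit, scene, angle_tol_deg = angle_tol_deg)
  })
  trials <- do.call(rbind, res)
  trials$seed <- seeds
  list(rate = mean(trials$recovered), trials = trials)
}

#' Evaluate a fit against a synthetic scene's ground truth
#'
#' @param fit A `still_index` fit.
#' @param scene A `diffraction_scene` from [simulate_scene()].
#' @param angle_tol_deg Kabsch correctness threshold in degrees.
#' @return One-row data frame: `recovered`, `kabsch_angle_deg` (minimum over
#'   solution/truth pairs; `NA` when no solution), `cell_error` (max relative
#'   cell-length error of the best pair), `n_lattices_found`,
#'   `n_lattices_true`, `n_true_recovered`.
#' @export
evaluate_solutions <- function(fit, scene, angle_tol_deg = 3) {
  sols <- fit$solutions
  truths <- scene$true_bases
  best_ang <- NA_real_
  best_cell <- NA_real_
  hit_truth <- logical(length(truths))
  if (length(sols)) {
    for (ti in seq_along(truths)) {
      Tred <- reduce_basis(truths[[ti]])
      tn <- sort(row_norms(Tred$mat))
      for (s in sols) {
        eq <- bases_equivalent(s$basis, Tred, angle_tol_deg = angle_tol_deg)
        ang <- min_relabelled_angle(s$basis, Tred)
        cl <- max(abs(sort(row_norms(reduce_basis(s$basis)$mat)) - tn) / tn)
        if (is.na(best_ang) || ang < best_ang) {
          best_ang <- ang
          best_cell <- cl
        }
        if (eq) hit_truth[ti] <- TRUE
      }
    }
  }
  data.frame(recovered = any(hit_truth),
             kabsch_angle_deg = best_ang,
             cell_error = best_cell,
             n_lattices_found = length(sols),
             n_lattices_true = length(truths),
             n_true_recovered = sum(hit_truth))
}

# Minimal Kabsch angle over signed axis permutations (no length gate).
min_relabelled_angle <- function(basisA, basisB) {
  A <- reduce_basis(basisA)$mat
  B <- reduce_basis(basisB)$mat
  na <- row_norms(A)
  best <- Inf
  for (sp in signed_permutations()) {
    Bp <- B[sp$perm, , drop = FALSE] * sp$sign
    if (any(abs(row_norms(Bp) - na) / na > 0.2)) next
    ang <- kabsch_rotation_angle(A, Bp)
    if (ang < best) best <- ang
  }
  if (!is.finite(best)) best <- kabsch_rotation_angle(A, B)
  best
}
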