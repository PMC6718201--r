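#' Control parameters for indexing
#'
#' Collects the thresholds of the basis-assembly pipeline. Defaults follow
#' the package's calibrated values; all are exposed for tuning.
#'
#' @param relative_tol Max-norm fractional-index tolerance defining a
#'   "correctly predicted" node (default 0.15).
#' @param min_predicted Minimum number of predicted nodes for a vector, pair
#'   or basis to survive (default 5); also the minimum for an accepted
#'   solution.
#' @param det_floor Absolute lower bound on `|det|` in cubic Angstrom
#'   (default 1000), guarding against collapsed cells.
#' @param det_angle_frac Reject bases with `|det| < det_angle_frac *
#'   |a||b||c|` (default 0.2): a sine-of-angles degeneracy guard.
#' @param max_candidates Keep at most this many candidate bases after ranking
#'   by summed peak scores (default 500).
#' @param shortlist_score,shortlist_defect Sizes of the final-stage
#'   shortlists: best by summed score (15) and smallest relative defect (50);
#'   their union goes to greedy selection.
#' @param defect_improvement A later basis replaces an accepted one covering
#'   the same nodes when its relative defect is below this fraction of the
#'   incumbent's (default 0.7).
#' @param overlap_frac Fraction of shared predicted nodes defining "the same
#'   lattice" (default 0.8).
#' @param cell_length_tol,cell_angle_tol Known-cell filter tolerances:
#'   relative on lengths (0.05), absolute degrees on angles (2.5).
#' @param epsilon Tolerant-score inclusion tolerance (default 0.15).
#' @param environment_radius Sparse peak-finding radius in Angstrom (2).
#' @param r_min,r_max Unknown-cell search shell in Angstrom (20, 300).
#' @param cell_half_width Known-cell shell half-width in Angstrom (2).
#' @param extended_search Also search the 110/011/101 diagonal shells in
#'   known-cell mode.
#' @param budget Starting-point budget; `NULL` selects 6000 (fast) or 50000
#'   (precise) by profile.
#' @param max_rounds Maximum delete-and-retry rounds (default 5).
#' @param dedupe_angle_deg Solutions whose bases match within this Kabsch
#'   angle (and cell tolerance) are considered duplicates (default 3).
#' @return An object of class `index_control`.
#' @export
index_control <- function(relative_tol = 0.15, min_predicted = 5L,
                          det_floor = 1000, det_angle_frac = 0.2,
                          max_candidates = 500L, shortlist_score = 15L,
                          shortlist_defect = 50L, defect_improvement = 0.7,
                          overlap_frac = 0.8, cell_length_tol = 0.05,
                          cell_angle_tol = 2.5, epsilon = 0.15,
                          environment_radius = 2, r_min = 20, r_max = 300,
                          cell_half_width = 2, extended_search = FALSE,
                          budget = NULL, max_rounds = 5L,
                          dedupe_angle_deg = 3) {
  structure(list(relative_tol = relative_tol,
                 min_predicted = as.integer(min_predicted),
                 det_floor = det_floor, det_angle_frac = det_angle_frac,
                 max_candidates = as.integer(max_candidates),
                 shortlist_score = as.integer(shortlist_score),
                 shortlist_defect = as.integer(shortlist_defect),
                 defect_improvement = defect_improvement,
                 overlap_frac = overlap_frac,
                 cell_length_tol = cell_length_tol,
                 cell_angle_tol = cell_angle_tol, epsilon = epsilon,
                 environment_radius = environment_radius,
                 r_min = r_min, r_max = r_max,
                 cell_half_width = cell_half_width,
                 extended_search = isTRUE(extended_search),
                 budget = budget, max_rounds = as.integer(max_rounds),
                 dedupe_angle_deg = dedupe_angle_deg),
            class = "index_control")
}

# Does a reduced basis match the prior cell (lengths sorted ascending by
# reduction; angles compared up to the 180-deg supplement from sign flips)?
cell_matches_prior <- function(basis, cell, length_tol, angle_tol) {
  p <- cell_parameters(basis)
  ref_len <- sort(cell[1:3])
  if (any(abs(p[1:3] - ref_len) / ref_len > length_tol)) return(FALSE)
  da <- abs(p[4:6] - cell[4:6])
  da <- pmin(da, abs(180 - p[4:6] - cell[4:6]))
  all(da <= angle_tol)
}

candidate_record <- function(basis, score, nodes, relative_tol) {
  d <- compute_defects(basis, nodes, relative_tol)
  list(basis = basis, score = score, n_predicted = d$n_predicted,
       relative_defect = d$relative_defect,
       absolute_defect = d$absolute_defect,
       predicted = d$predicted, hkl = d$hkl, det = abs(basis$det))
}

#' Enumerate candidate lattice bases from score-function peaks
#'
#' Forms bases from triples of candidate peak vectors and prunes them in
#' pipeline order: (1) drop peaks individually predicting fewer than
#' `min_predicted` nodes (a one-vector plane-fit count); (2) form triples of
#' the survivors; (3) reject near-degenerate determinants; (4) reject on the
#' two-vector and then three-vector predicted-node counts; (5) when a prior
#' cell is given, reject candidates whose reduced cell does not match it;
#' (6) rank by the summed peak scores and keep at most `max_candidates`.
#' Kept candidates are reduced to shortest vectors, deduplicated, and
#' annotated with defect statistics.
#'
#' @param peaks A `candidate_peaks` object (positions + scores).
#' @param nodes A [node_set()].
#' @param control An [index_control()].
#' @param cell Optional prior `c(a, b, c, alpha, beta, gamma)`.
#' @return List of candidate records (possibly empty), each with elements
#'   `basis` (reduced), `score`, `n_predicted`, `relative_defect`,
#'   `absolute_defect`, `predicted`, `hkl`, `det`.
#' @export
enumerate_candidate_bases <- function(peaks, nodes,
                                      control = index_control(),
                                      cell = NULL) {
  P <- peaks$pos
  if (is.null(P) || nrow(P) < 3L) return(list())
  tol <- control$relative_tol
  Q <- nodes$q
  # (1) one-vector prediction counts
  Fr <- fractional_offset(Q %*% t(P))           # K x P
  inc <- abs(Fr) <= tol
  keep1 <- colSums(inc) >= control$min_predicted
  if (sum(keep1) < 3L) return(list())
  P <- P[keep1, , drop = FALSE]
  inc <- inc[, keep1, drop = FALSE]
  sc <- peaks$score[keep1]
  np <- nrow(P)
  # (2) triples
  tri <- utils::combn(np, 3L)
  i <- tri[1L, ]; j <- tri[2L, ]; k <- tri[3L, ]
  # (3) determinant filter
  cjk <- cbind(P[j, 2L] * P[k, 3L] - P[j, 3L] * P[k, 2L],
               P[j, 3L] * P[k, 1L] - P[j, 1L] * P[k, 3L],
               P[j, 1L] * P[k, 2L] - P[j, 2L] * P[k, 1L])
  dets <- abs(rowSums(P[i, , drop = FALSE] * cjk))
  nrm <- row_norms(P)
  det_ok <- dets >= pmax(control$det_floor,
                         control$det_angle_frac * nrm[i] * nrm[j] * nrm[k])
  # (4) two-vector counts (joint inlier counts for all pairs), then 3-vector
  pc <- crossprod(inc)                          # np x np joint counts
  pair_ok <- pc[cbind(i, j)] >= control$min_predicted &
    pc[cbind(i, k)] >= control$min_predicted &
    pc[cbind(j, k)] >= control$min_predicted
  sel <- which(det_ok & pair_ok)
  if (!length(sel)) return(list())
  cnt3 <- colSums(inc[, i[sel], drop = FALSE] &
                    inc[, j[sel], drop = FALSE] &
                    inc[, k[sel], drop = FALSE])
  sel <- sel[cnt3 >= control$min_predicted]
  if (!length(sel)) return(list())
  tsc <- sc[i[sel]] + sc[j[sel]] + sc[k[sel]]
  tnrm <- nrm[i[sel]] + nrm[j[sel]] + nrm[k[sel]]
  # score quantised so that ties go to the shortest (most fundamental) triples
  o <- order(-round(tsc, 2), tnrm)
  sel <- sel[o]; tsc <- tsc[o]
  # (5)+(6): with a prior cell, reduce before filtering (capped), else rank
  # first and reduce the kept candidates.
  pre_cap <- if (is.null(cell)) control$max_candidates else
    min(length(sel), 4L * control$max_candidates)
  sel <- sel[seq_len(min(pre_cap, length(sel)))]
  tsc <- tsc[seq_len(length(sel))]
  out <- list()
  seen <- character(0)
  for (t_idx in seq_along(sel)) {
    s <- sel[t_idx]
    B <- lattice_basis(P[c(i[s], j[s], k[s]), , drop = FALSE])
    R <- tryCatch(reduce_basis(B), error = function(e) NULL)
    if (is.null(R)) next
    if (!is.null(cell) &&
        !cell_matches_prior(R, cell, control$cell_length_tol,
                            control$cell_angle_tol)) next
    key <- paste(sprintf("%.4f", R$mat), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- candidate_record(R, tsc[t_idx], nodes, tol)
    if (length(out) >= control$max_candidates) break
  }
  dedupe_candidate_cells(out)
}

# Collapse near-duplicate candidates (triples of different peaks describing
# the same lattice) to the best representative per quantised unit cell, so
# one dominant lattice cannot flood the selection shortlists.
dedupe_candidate_cells <- function(cands) {
  if (length(cands) < 2L) return(cands)
  keys <- vapply(cands, function(cc) {
    p <- cell_parameters(cc$basis)
    paste(c(round(p[1:3]), round(p[4:6] / 2)), collapse = "_")
  }, "")
  keep <- integer(0)
  for (k in unique(keys)) {
    idx <- which(keys == k)
    if (length(idx) > 1L) {
      np <- vapply(cands[idx], `[[`, 0, "n_predicted")
      rd <- vapply(cands[idx], `[[`, 0, "relative_defect")
      idx <- idx[order(-np, rd)][1L]
    }
    keep <- c(keep, idx)
  }
  cands[sort(keep)]
}

#' Select lattices from candidate bases
#'
#' Final-stage selection: shortlist the union of the `shortlist_score` best
#' candidates by summed peak score and the `shortlist_defect` candidates with
#' the smallest relative defects; sort by descending predicted-node count
#' (ties: smaller determinant first, to avoid supercells, then smaller
#' relative defect); then greedily accept a candidate if it predicts at least
#' `min_predicted` nodes not predicted by any accepted basis, or replace an
#' accepted basis covering the same nodes if the candidate's relative defect
#' is significantly smaller (`defect_improvement`).
#'
#' @param candidates List of candidate records from
#'   [enumerate_candidate_bases()].
#' @param nodes A [node_set()].
#' @param control An [index_control()].
#' @return List of accepted candidate records, strongest first (an empty
#'   list when no candidate predicts enough nodes).
#' @export
select_lattices <- function(candidates, nodes, control = index_control()) {
  if (!length(candidates)) return(list())
  npred <- vapply(candidates, `[[`, 0, "n_predicted")
  candidates <- candidates[npred >= control$min_predicted]
  if (!length(candidates)) return(list())
  score <- vapply(candidates, `[[`, 0, "score")
  rdef <- vapply(candidates, `[[`, 0, "relative_defect")
  # Whole-pattern defect for shortlisting: nodes a basis does not predict
  # enter at the typical residual of an unrelated node, so a basis cannot
  # buy a small defect by predicting only a handful of nodes.
  K <- nodes$K
  npred <- vapply(candidates, `[[`, 0, "n_predicted")
  rdef_all <- (rdef * npred + 0.3 * (K - npred)) / K
  short <- union(order(-score)[seq_len(min(control$shortlist_score,
                                           length(candidates)))],
                 order(rdef_all)[seq_len(min(control$shortlist_defect,
                                             length(candidates)))])
  cand <- candidates[short]
  # Lightly refine the shortlisted bases before ranking them: an unrefined
  # triple systematically under-counts the nodes its lattice explains, which
  # would let spurious partial lattices outrank genuine ones.
  cand <- lapply(cand, function(cc) {
    ref <- tryCatch(
      reduce_basis(suppressWarnings(
        refine_basis(cc$basis, nodes, relative_tol = control$relative_tol,
                     max_iter = 30L))),
      error = function(e) NULL)
    if (is.null(ref)) return(cc)
    rec <- candidate_record(ref, cc$score, nodes, control$relative_tol)
    if (rec$n_predicted >= cc$n_predicted) rec else cc
  })
  npred <- vapply(cand, `[[`, 0, "n_predicted")
  dets <- vapply(cand, `[[`, 0, "det")
  rdef <- vapply(cand, `[[`, 0, "relative_defect")
  cand <- cand[order(-npred, dets, rdef)]
  accepted <- list()
  for (cc in cand) {
    if (!length(accepted)) {
      accepted <- list(cc)
      next
    }
    covered <- Reduce(`|`, lapply(accepted, `[[`, "predicted"))
    fresh <- sum(cc$predicted & !covered)
    if (fresh >= control$min_predicted) {
      accepted[[length(accepted) + 1L]] <- cc
      next
    }
    # same-lattice replacement on significantly smaller defects; "same
    # lattice" means the predicted node sets largely coincide (Jaccard)
    for (ai in seq_along(accepted)) {
      a <- accepted[[ai]]
      ov <- sum(cc$predicted & a$predicted) /
        max(1L, sum(cc$predicted | a$predicted))
      if (ov >= control$overlap_frac && is.finite(a$relative_defect) &&
          (cc$relative_defect <
             control$defect_improvement * a$relative_defect ||
           # supercell avoidance: same nodes, much smaller cell
           (cc$det < 0.6 * a$det &&
              cc$n_predicted >= a$n_predicted - 2L &&
              cc$relative_defect <= 1.2 * a$relative_defect))) {
        accepted[[ai]] <- cc
        break
      }
    }
  }
  # Drop duplicate lattices (equivalent reduced bases), keeping the stronger.
  if (length(accepted) > 1L) {
    drop <- logical(length(accepted))
    for (u in seq_along(accepted)) for (v in seq_along(accepted)) {
      if (u >= v || drop[u] || drop[v]) next
      if (bases_equivalent(accepted[[u]]$basis, accepted[[v]]$basis,
                           angle_tol_deg = control$dedupe_angle_deg))
        drop[v] <- TRUE
    }
    accepted <- accepted[!drop]
  }
  accepted
}
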