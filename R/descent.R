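#' Extended gradient descent configuration
#'
#' The maxima search ascends the score function with a custom step-size rule:
#' ordinary gradient steps perform poorly here because the gradient is often
#' largest close to a maximum. Instead the step length is generated from the
#' previous step length, the change in step direction, the current score and
#' a relative-step parameter `gamma`, then clipped to
#' `[min_step, max_step]`:
#' `new_len = prev_len * f(cos) * (1 + gamma (1 - S)/2)` with `f = 1.5` on
#' straight runs (`cos > 0.7`), `0.5` on reversals (`cos < 0`), `1`
#' otherwise. Steps therefore grow on straight runs, shrink on turns and slow
#' near maxima.
#'
#' Zigzag suppression: when the proposed direction is nearly opposite the
#' previous one (`cos < zigzag_cos_threshold`), the direction is replaced by
#' the normalised sum of the two unit directions, turning the search almost
#' orthogonal to the oscillation. If the two are exactly antipodal the sum
#' degenerates to zero and a deterministic unit vector orthogonal to the
#' previous direction is used instead.
#'
#' @param gamma Relative step parameter (> 0), default 1.
#' @param min_step,max_step Step-length clip bounds in Angstrom.
#' @param max_iterations Default per-stage iteration cap.
#' @param zigzag_cos_threshold Direction-reversal threshold in (-1, 0).
#' @param tol Convergence tolerance in Angstrom: a point whose unclipped step
#'   falls below `tol` is frozen.
#' @return An object of class `descent_config`.
#' @export
descent_config <- function(gamma = 1, min_step = 0.01, max_step = 2,
                           max_iterations = 200L,
                           zigzag_cos_threshold = -0.8, tol = 1e-3) {
  stopifnot(gamma > 0, min_step > 0, min_step <= max_step,
            zigzag_cos_threshold > -1, zigzag_cos_threshold < 0)
  structure(list(gamma = gamma, min_step = min_step, max_step = max_step,
                 max_iterations = as.integer(max_iterations),
                 zigzag_cos_threshold = zigzag_cos_threshold, tol = tol),
            class = "descent_config")
}

# Deterministic unit vector orthogonal to each row of `v` (rows unit-length):
# cross with the coordinate axis least aligned with v.
orthogonal_fallback <- function(v) {
  ax <- apply(abs(v), 1L, which.min)
  E <- diag(3)[ax, , drop = FALSE]
  o <- cbind(v[, 2L] * E[, 3L] - v[, 3L] * E[, 2L],
             v[, 3L] * E[, 1L] - v[, 1L] * E[, 3L],
             v[, 1L] * E[, 2L] - v[, 2L] * E[, 1L])
  o / row_norms(o)
}

# Vectorised step update shared by descent_step() and run_stage().
# pos/dir: n x 3; len: n; G: n x 3 gradients; S: n scores.
step_update <- function(pos, dir, len, G, S, cfg,
                        min_step = cfg$min_step, max_step = cfg$max_step) {
  n <- nrow(pos)
  gn <- row_norms(G)
  moving <- gn > 0
  d <- G
  d[moving, ] <- G[moving, , drop = FALSE] / gn[moving]
  cosv <- rowSums(d * dir)                     # 0 when no previous direction
  zig <- moving & cosv < cfg$zigzag_cos_threshold
  if (any(zig)) {
    s <- d[zig, , drop = FALSE] + dir[zig, , drop = FALSE]
    sn <- row_norms(s)
    degen <- sn < 1e-12
    if (any(degen))
      s[degen, ] <- orthogonal_fallback(dir[zig, , drop = FALSE][degen, ,
                                                                 drop = FALSE])
    sn[degen] <- 1
    d[zig, ] <- s / row_norms(s)
  }
  f <- 1 + 0.5 * (cosv > 0.7) - 0.5 * (cosv < 0)
  raw <- len * f * (1 + cfg$gamma * (1 - S) / 2)
  newlen <- pmin(pmax(raw, min_step), max_step)
  converged <- raw < cfg$tol
  pos2 <- pos
  upd <- moving & !converged
  pos2[upd, ] <- pos[upd, , drop = FALSE] +
    newlen[upd] * d[upd, , drop = FALSE]
  newlen[!moving] <- min_step                 # zero gradient: reset step
  d[!moving, ] <- dir[!moving, , drop = FALSE]
  list(pos = pos2, dir = d, len = newlen, converged = converged | !moving)
}

#' Single extended-gradient-descent step
#'
#' Advances one sampling point given its gradient, score and previous-step
#' state. This is the scalar interface to the same update rule used
#' internally by [run_stage()].
#'
#' @param position Length-3 position (Angstrom).
#' @param gradient Length-3 score gradient at `position`.
#' @param score_now Current score value at `position`.
#' @param inliers_now Current inlier count (carried in the state; reserved
#'   for step heuristics).
#' @param state List with `dir` (previous unit step direction, zero vector if
#'   none) and `len` (previous step length).
#' @param cfg A [descent_config()].
#' @return List with updated `position`, `dir`, `len` and a `converged`
#'   flag.
#' @export
descent_step <- function(position, gradient, score_now, inliers_now = NA,
                         state = list(dir = c(0, 0, 0), len = 0.5),
                         cfg = descent_config()) {
  u <- step_update(matrix(position, 1L, 3L), matrix(state$dir, 1L, 3L),
                   state$len, matrix(gradient, 1L, 3L), score_now, cfg)
  list(position = drop(u$pos), dir = drop(u$dir), len = u$len,
       converged = u$converged)
}

#' Specification of one heuristic stage
#'
#' The five-stage maxima-finding heuristic alternates gradient-descent stages
#' (with progressively sharper proximity functions) and a sparse peak-finding
#' stage. Each descent stage fixes the proximity kind, the score mode
#' (plain weighted sum vs the tolerant variant), the weighting scheme and the
#' number of steps.
#'
#' @param proximity Proximity kind (see [proximity_function()]).
#' @param mode `"plain"` or `"tolerant"`.
#' @param weighting `"unity"`, `"inverse_radial"` or `"intensity"`.
#' @param n_steps Number of descent steps (>= 0).
#' @param epsilon Tolerance for the tolerant score.
#' @param min_step,max_step Optional per-stage step-length clip overrides.
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(proximity, mode = c("plain", "tolerant"),
                       weighting = "unity", n_steps = 10L, epsilon = 0.15,
                       min_step = NULL, max_step = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_steps >= 0)
  structure(list(proximity = proximity, mode = mode, weighting = weighting,
                 n_steps = as.integer(n_steps), epsilon = epsilon,
                 min_step = min_step, max_step = max_step),
            class = "stage_spec")
}

stage_score_config <- function(stage) {
  score_config(proximity = stage$proximity, weighting = stage$weighting,
               epsilon = stage$epsilon,
               use_tolerance = stage$mode == "tolerant")
}

#' Run one descent stage over a sampling-point set
#'
#' Migrates every point for up to `stage$n_steps` extended-gradient steps (or
#' until its step length falls below the convergence tolerance), then
#' refreshes the per-point score and inlier count under the stage's score
#' mode.
#'
#' @param points A `sampling_points` object (see [build_starting_points()]).
#' @param nodes A [node_set()].
#' @param stage A [stage_spec()].
#' @param cfg A [descent_config()].
#' @return The updated `sampling_points` object.
#' @export
run_stage <- function(points, nodes, stage, cfg = descent_config()) {
  stopifnot(inherits(points, "sampling_points"), inherits(stage, "stage_spec"))
  scfg <- stage_score_config(stage)
  min_step <- if (is.null(stage$min_step)) cfg$min_step else stage$min_step
  max_step <- if (is.null(stage$max_step)) cfg$max_step else stage$max_step
  n <- nrow(points$pos)
  if (n == 0L || stage$n_steps == 0L || nodes$K == 0L) {
    if (n > 0L && nodes$K > 0L) {
      ev <- score_eval(points$pos, nodes, scfg, want_gradient = FALSE)
      points$score <- ev$score
      points$inliers <- ev$inliers
    }
    return(points)
  }
  pos <- points$pos; dir <- points$dir; len <- points$len
  active <- rep(TRUE, n)
  for (it in seq_len(min(stage$n_steps, cfg$max_iterations))) {
    idx <- which(active)
    if (!length(idx)) break
    ev <- score_eval(pos[idx, , drop = FALSE], nodes, scfg)
    u <- step_update(pos[idx, , drop = FALSE], dir[idx, , drop = FALSE],
                     len[idx], ev$gradient, ev$score, cfg,
                     min_step, max_step)
    pos[idx, ] <- u$pos; dir[idx, ] <- u$dir; len[idx] <- u$len
    active[idx[u$converged]] <- FALSE
  }
  ev <- score_eval(pos, nodes, scfg, want_gradient = FALSE)
  points$pos <- pos; points$dir <- dir; points$len <- len
  points$score <- ev$score; points$inliers <- ev$inliers
  points
}

#' Sparse peak finding on sampling points
#'
#' Keeps only points that carry the highest score within their local
#' environment: point `i` survives iff no other point within
#' `environment_radius` has a strictly higher score (ties resolved by input
#' order). At most `max_keep` peaks are returned, ordered by descending score
#' (equal scores: shorter vectors first).
#'
#' @param points A `sampling_points` object with scores, or an n x 3 matrix
#'   (then `score` must be supplied).
#' @param environment_radius Local environment radius in Angstrom (> 0).
#' @param max_keep Maximum number of peaks returned (default 50).
#' @param score Optional score vector when `points` is a bare matrix.
#' @return An object of class `candidate_peaks`: list with `pos` (m x 3),
#'   `score` and `inliers`.
#' @export
sparse_peak_find <- function(points, environment_radius = 2, max_keep = 50L,
                             score = NULL) {
  stopifnot(environment_radius > 0)
  if (inherits(points, "sampling_points")) {
    pos <- points$pos; sc <- points$score; inl <- points$inliers
  } else {
    pos <- as_matrix3(points, "points"); sc <- score
    inl <- rep(NA_integer_, nrow(pos))
  }
  n <- nrow(pos)
  if (n == 0L)
    return(structure(list(pos = pos, score = numeric(0),
                          inliers = integer(0)), class = "candidate_peaks"))
  if (is.null(sc) || anyNA(sc)) stop("sparse_peak_find needs point scores")
  # Priority order: higher score first, earlier index breaks ties. A point
  # survives iff no higher-priority point lies within the radius, i.e. (after
  # sorting by priority) its nearest earlier point is farther than the radius.
  o <- order(-sc, seq_len(n))
  ps <- pos[o, , drop = FALSE]
  sq <- rowSums(ps^2)
  r2 <- environment_radius^2 + 1e-9
  keep_s <- logical(n)
  chunk <- 512L
  scs <- sc[o]
  for (a in seq(1L, n, by = chunk)) {
    b <- min(a + chunk - 1L, n)
    ii <- a:b
    D <- (-2 * ps[ii, , drop = FALSE] %*% t(ps[seq_len(b), , drop = FALSE]) +
            sq[ii]) + rep(sq[seq_len(b)], each = length(ii))
    for (r in seq_along(ii)) D[r, ii[r]:b] <- Inf  # only earlier points exclude
    nearest <- D[cbind(seq_along(ii), max.col(-D, ties.method = "first"))]
    keep_s[ii] <- nearest > r2
    # Points are scanned in descending score order, so once the max_keep-th
    # best keep outranks (in quantised score) every unscanned point, the
    # returned set is determined and the scan can stop.
    if (is.finite(max_keep) && b < n && sum(keep_s) >= max_keep) {
      kth <- sort(round(scs[keep_s], 3), decreasing = TRUE)[max_keep]
      if (round(scs[b + 1L], 3) < kth) break
    }
  }
  idx <- o[keep_s]
  # Rank with the score quantised to 1e-3 so that among numerically tied
  # maxima the shortest vectors (the fundamental lattice vectors) win.
  o <- order(-round(sc[idx], 3), row_norms(pos[idx, , drop = FALSE]))
  idx <- idx[o][seq_len(min(max_keep, length(idx)))]
  structure(list(pos = pos[idx, , drop = FALSE], score = sc[idx],
                 inliers = inl[idx]),
            class = "candidate_peaks")
}

#' @export
print.candidate_peaks <- function(x, ...) {
  cat(sprintf("Candidate peaks: %d positions", nrow(x$pos)))
  if (nrow(x$pos) > 0L)
    cat(sprintf(", best score %.3f", max(x$score)))
  cat("\n")
  invisible(x)
}

#' Default stage sequence of the maxima-finding heuristic
#'
#' Stage (i) uses the smooth cosine proximity with the plain score and
#' inverse-radial weighting (down-weighting high-resolution nodes keeps the
#' score smooth and the convergence radius large); stages (ii) and (iii) use
#' progressively sharper proximity functions with the tolerant score; stage
#' (iv) is the sparse peak finding; stage (v) polishes the surviving peaks
#' with many fine steps of the sharpest proximity function.
#'
#' @param profile `"fast"` (default) or `"precise"`; scales the step counts.
#' @param epsilon Tolerance for the tolerant-score stages.
#' @return List of [stage_spec()]s (the descent stages, in order).
#' @export
default_stages <- function(profile = c("fast", "precise"), epsilon = 0.15) {
  profile <- match.arg(profile)
  k <- if (profile == "precise") c(60L, 20L, 10L, 40L) else c(40L, 14L, 8L, 24L)
  list(
    stage_spec("cosine", "plain", "inverse_radial", n_steps = k[1L],
               max_step = 2),
    stage_spec("sharp_b", "tolerant", "unity", n_steps = k[2L],
               epsilon = epsilon, max_step = 0.5),
    stage_spec("sharp_a", "tolerant", "unity", n_steps = k[3L],
               epsilon = epsilon, max_step = 0.2),
    stage_spec("sharp_a", "tolerant", "unity", n_steps = k[4L],
               epsilon = epsilon, min_step = 0.005, max_step = 0.2)
  )
}

#' Find candidate lattice vectors for a pattern
#'
#' Runs the full five-stage heuristic: seed the search volume with starting
#' points, migrate them through the descent stages, keep the best-scoring
#' local peaks, and polish those. The returned peak positions are candidate
#' real-space lattice vectors from which bases are assembled.
#'
#' @param nodes A [node_set()] with at least 3 nodes.
#' @param vol A [search_volume()].
#' @param stages List of descent [stage_spec()]s; default [default_stages()].
#' @param cfg A [descent_config()].
#' @param seed Integer seed (starting-point rotations).
#' @param budget Starting-point budget before centrosymmetry halving.
#' @param environment_radius Sparse peak-finding radius in Angstrom.
#' @param max_keep Maximum number of peaks kept.
#' @return A `candidate_peaks` object, ordered by descending score.
#' @export
find_lattice_vector_candidates <- function(nodes, vol,
                                           stages = default_stages(),
                                           cfg = descent_config(),
                                           seed = 1L, budget = 6000L,
                                           environment_radius = 2,
                                           max_keep = 50L) {
  stopifnot(inherits(nodes, "node_set"))
  if (nodes$K < 3L)
    stop("at least 3 nodes are required to span a 3D lattice")
  pts <- build_starting_points(vol, budget, seed = seed)
  n_desc <- length(stages)
  for (s in stages[seq_len(n_desc - 1L)]) pts <- run_stage(pts, nodes, s, cfg)
  peaks <- sparse_peak_find(pts, environment_radius, max_keep)
  if (nrow(peaks$pos) == 0L) return(peaks)
  final <- structure(list(pos = peaks$pos,
                          dir = matrix(0, nrow(peaks$pos), 3L),
                          len = rep(0.1, nrow(peaks$pos)),
                          score = peaks$score, inliers = peaks$inliers),
                     class = "sampling_points")
  final <- run_stage(final, nodes, stages[[n_desc]], cfg)
  # enforce the search-volume prior: a candidate lattice vector outside the
  # shell (within the peak-merging radius) contradicts the assumed cell range
  rr <- row_norms(final$pos)
  ok <- rr >= vol$r_min - environment_radius &
    rr <= vol$r_max + environment_radius
  o <- which(ok)[order(-round(final$score[ok], 3), rr[ok])]
  structure(list(pos = final$pos[o, , drop = FALSE],
                 score = final$score[o], inliers = final$inliers[o]),
            class = "candidate_peaks")
}
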