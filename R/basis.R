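#' Real-space lattice basis
#'
#' Three real-space vectors (rows a, b, c, in Angstrom) defining a candidate
#' crystal lattice. A node `q` belongs to the lattice when its fractional
#' Miller indices `(a.q, b.q, c.q)` are integers.
#'
#' @param mat 3 x 3 numeric matrix with rows a, b, c.
#' @return An object of class `lattice_basis`.
#' @export
lattice_basis <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(all(dim(mat) == c(3L, 3L)), all(is.finite(mat)))
  storage.mode(mat) <- "double"
  rownames(mat) <- c("a", "b", "c")
  colnames(mat) <- c("x", "y", "z")
  structure(list(mat = mat, det = det(mat)), class = "lattice_basis")
}

#' @export
print.lattice_basis <- function(x, ...) {
  p <- cell_parameters(x)
  cat(sprintf(
    "Lattice basis: a=%.3f b=%.3f c=%.3f A, alpha=%.2f beta=%.2f gamma=%.2f deg (det %.1f A^3)\n",
    p[1L], p[2L], p[3L], p[4L], p[5L], p[6L], x$det))
  invisible(x)
}

#' Construct a basis from unit-cell parameters
#'
#' Standard crystallographic construction: a along x, b in the xy plane.
#'
#' @param cell Numeric `c(a, b, c, alpha, beta, gamma)` in Angstrom and
#'   degrees, or the six values as separate arguments.
#' @return A [lattice_basis()].
#' @export
basis_from_cell <- function(cell) {
  if (length(cell) != 6L) stop("cell must have 6 parameters")
  a <- cell[1L]; b <- cell[2L]; cc <- cell[3L]
  al <- cell[4L] * pi / 180; be <- cell[5L] * pi / 180; ga <- cell[6L] * pi / 180
  cx <- cos(be)
  cy <- (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- 1 - cx^2 - cy^2
  if (cz2 <= 0) stop("invalid unit-cell angles")
  lattice_basis(rbind(
    c(a, 0, 0),
    c(b * cos(ga), b * sin(ga), 0),
    cc * c(cx, cy, sqrt(cz2))))
}

#' Unit-cell parameters of a basis
#'
#' @param basis A [lattice_basis()] or 3 x 3 matrix (rows a, b, c).
#' @return Named numeric `c(a, b, c, alpha, beta, gamma)` (Angstrom,
#'   degrees).
#' @export
cell_parameters <- function(basis) {
  B <- if (inherits(basis, "lattice_basis")) basis$mat else as.matrix(basis)
  n <- row_norms(B)
  ang <- function(u, v) acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
  c(a = n[1L], b = n[2L], c = n[3L],
    alpha = ang(B[2L, ], B[3L, ]), beta = ang(B[1L, ], B[3L, ]),
    gamma = ang(B[1L, ], B[2L, ]))
}

basis_mat <- function(basis) {
  if (inherits(basis, "lattice_basis")) basis$mat else as.matrix(basis)
}

#' Fractional Miller indices of nodes under a basis
#'
#' Returns `(a.q, b.q, c.q)` for each node: real-valued Miller indices that
#' are integers exactly when the node lies on the reciprocal lattice of the
#' basis.
#'
#' @param basis A [lattice_basis()] (must be non-singular).
#' @param nodes A [node_set()] or n x 3 matrix of q vectors.
#' @return n x 3 matrix of fractional indices.
#' @export
fractional_indices <- function(basis, nodes) {
  B <- basis_mat(basis)
  if (abs(det(B)) < 1e-12) stop("singular basis")
  Q <- if (inherits(nodes, "node_set")) nodes$q else as_matrix3(nodes, "nodes")
  M <- Q %*% t(B)
  colnames(M) <- c("h", "k", "l")
  M
}

#' Count the nodes a basis correctly predicts
#'
#' A node is predicted when the max-component distance of its fractional
#' Miller indices to the nearest integer triple is at most `relative_tol`.
#'
#' @param basis A [lattice_basis()].
#' @param nodes A [node_set()].
#' @param relative_tol Max-norm tolerance on the fractional-index residual
#'   (default 0.15).
#' @return List with `count`, integer `hkl` (n x 3, `NA` rows for
#'   unpredicted nodes) and logical `predicted`.
#' @export
count_predicted <- function(basis, nodes, relative_tol = 0.15) {
  M <- fractional_indices(basis, nodes)
  H <- round(M)
  resid <- M - H
  pred <- apply(abs(resid), 1L, max) <= relative_tol
  if (nrow(M) == 0L) pred <- logical(0)
  Hout <- H
  Hout[!pred, ] <- NA_real_
  storage.mode(Hout) <- "integer"
  list(count = sum(pred), hkl = Hout, predicted = pred)
}

# integer cross-correction grid used by reduce_basis (constant)
reduce_combos <- local({
  g <- as.matrix(expand.grid(m = -2:2, n = -2:2))
  g[!(g[, 1L] == 0 & g[, 2L] == 0), , drop = FALSE]
})

#' Reduce a basis to shortest vectors
#'
#' Replaces a basis by an equivalent basis of the same lattice (a unimodular
#' transform; the determinant magnitude is preserved) whose sorted vector
#' norms equal the three successive minima of the lattice. The reduction
#' iterates pairwise Lagrange-Gauss steps (subtracting the rounded projection
#' of one vector on another) together with small integer cross-corrections
#' `v_i + m v_j + n v_k`, `m, n` in `[-2, 2]`, until no vector norm
#' decreases. Output rows are sorted by increasing norm and the handedness is
#' normalised to a positive determinant.
#'
#' @param basis A [lattice_basis()] (non-singular).
#' @return The reduced [lattice_basis()].
#' @export
reduce_basis <- function(basis) {
  B <- basis_mat(basis)
  if (abs(det(B)) < 1e-12) stop("cannot reduce a singular basis")
  combos <- reduce_combos
  repeat {
    improved <- FALSE
    # Lagrange-Gauss pair steps handle large integer coefficients quickly.
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      mu <- round(sum(B[i, ] * B[j, ]) / sum(B[j, ]^2))
      if (mu != 0) {
        cand <- B[i, ] - mu * B[j, ]
        if (sum(cand^2) < sum(B[i, ]^2) - 1e-12) {
          B[i, ] <- cand
          improved <- TRUE
        }
      }
    }
    # Cross-corrections involving both other vectors.
    for (i in 1:3) {
      oth <- setdiff(1:3, i)
      cand <- matrix(B[i, ], nrow(combos), 3L, byrow = TRUE) +
        combos %*% B[oth, , drop = FALSE]
      n2 <- rowSums(cand^2)
      b <- which.min(n2)
      if (n2[b] < sum(B[i, ]^2) - 1e-12) {
        B[i, ] <- cand[b, ]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  B <- B[order(row_norms(B)), , drop = FALSE]
  if (det(B) < 0) B[3L, ] <- -B[3L, ]
  lattice_basis(B)
}

#' Defect statistics of a basis against a node set
#'
#' The absolute defect is the mean reciprocal-space distance between the
#' predicted nodes and the positions the basis predicts for them (the exact
#' reciprocal-lattice points of the rounded Miller indices); the relative
#' defect is the mean Euclidean distance between the fractional and rounded
#' integer Miller indices. Both are means over predicted nodes only; a basis
#' predicting no node gets `Inf` defects.
#'
#' @inheritParams count_predicted
#' @return List with `absolute_defect` (1/Angstrom), `relative_defect`
#'   (dimensionless), `n_predicted`, plus the `hkl` assignment and
#'   `predicted` mask.
#' @export
compute_defects <- function(basis, nodes, relative_tol = 0.15) {
  B <- basis_mat(basis)
  cp <- count_predicted(basis, nodes, relative_tol)
  Q <- if (inherits(nodes, "node_set")) nodes$q else as_matrix3(nodes, "nodes")
  if (cp$count == 0L)
    return(list(absolute_defect = Inf, relative_defect = Inf,
                n_predicted = 0L, hkl = cp$hkl, predicted = cp$predicted))
  idx <- which(cp$predicted)
  H <- cp$hkl[idx, , drop = FALSE]
  storage.mode(H) <- "double"
  Qpred <- H %*% t(solve(B))
  M <- fractional_indices(basis, Q[idx, , drop = FALSE])
  list(absolute_defect = mean(row_norms(Q[idx, , drop = FALSE] - Qpred)),
       relative_defect = mean(row_norms(M - H)),
       n_predicted = cp$count, hkl = cp$hkl, predicted = cp$predicted)
}

# Hermite-style integer triangularisation of the row space of H (n x 3
# integer matrix). Returns a 3 x 3 integer matrix whose rows generate the
# same integer lattice as the rows of H, or NULL when the rank is < 3.
integer_row_basis <- function(H) {
  M <- matrix(as.numeric(H), nrow(H), 3L)
  M <- M[rowSums(abs(M)) > 0, , drop = FALSE]
  out <- matrix(0, 3L, 3L)
  for (col in 1:3) {
    repeat {
      nz <- which(M[, col] != 0)
      if (!length(nz)) break
      p <- nz[which.min(abs(M[nz, col]))]
      piv <- M[p, ]
      M[-p, ] <- M[-p, , drop = FALSE] -
        outer(round(M[-p, col] / piv[col]), piv)
      if (all(M[-p, col] == 0)) {
        out[col, ] <- piv
        M <- M[-p, , drop = FALSE]
        break
      }
    }
    if (all(out[col, ] == 0)) return(NULL)
  }
  out
}

#' Collapse a supercell basis to the primitive cell of its assignments
#'
#' A basis whose real-space lattice is a proper sublattice of the true
#' lattice still predicts every node, but assigns Miller indices that
#' occupy only a sublattice of the integer triples (of index `g =` the
#' supercell multiplicity). This function detects that situation from the
#' assigned indices of the predicted nodes and divides the basis down to the
#' primitive cell that indexes the same nodes with coprime integers. A basis
#' whose assignments already span the full integer lattice is returned
#' unchanged.
#'
#' @param basis A [lattice_basis()].
#' @param hkl Integer n x 3 matrix of assigned Miller indices (rows with
#'   `NA` are ignored).
#' @return A [lattice_basis()] with determinant `det(basis)/g`.
#' @export
collapse_supercell <- function(basis, hkl) {
  B <- basis_mat(basis)
  H <- hkl[stats::complete.cases(hkl), , drop = FALSE]
  if (nrow(H) < 3L) return(lattice_basis(B))
  W <- integer_row_basis(H)
  if (is.null(W)) return(lattice_basis(B))
  g <- abs(W[1L, 1L] * W[2L, 2L] * W[3L, 3L])
  if (g <= 1 + 1e-9) return(lattice_basis(B))
  # h = W^T m for integer m  =>  primitive real basis B' = (W^T)^{-1} B
  lattice_basis(solve(t(W)) %*% B)
}

# Correct the multiplicity of a fitted cell. A supercell basis assigns the
# nodes Miller indices confined to a proper sublattice of Z^3; a sub-cell
# (over-dense) basis leaves many nodes near *rational* indices with a small
# denominator s. Both cases are detected by triangularising the integer
# lattice spanned by round(s * M) over the tightly fitting nodes (s = 1, 2,
# 3) and rebuilding the cell from it. A candidate replaces the current basis
# only if, after refinement, it still predicts every tightly fitting node
# and either shrinks the cell or explains at least three more nodes.
rational_cell_correction <- function(basis, nodes, relative_tol,
                                     min_predicted = 5L, max_rounds = 3L) {
  current <- basis
  d <- compute_defects(current, nodes, relative_tol)
  # "tight" predictions (residual within half the tolerance) are almost
  # never coincidental captures, so they are the robust yardstick below
  n_tight_of <- function(b) {
    Mb <- fractional_indices(b, nodes)
    sum(apply(abs(Mb - round(Mb)), 1L, max) <= 0.5 * relative_tol)
  }
  cur_tight <- n_tight_of(current)
  for (round_i in seq_len(max_rounds)) {
    M <- fractional_indices(current, nodes)
    best <- NULL
    best_d <- NULL
    best_tight <- -1L
    for (s in 1:3) {
      Ms <- s * M
      resid <- apply(abs(Ms - round(Ms)), 1L, max)
      tight <- which(resid <= min(0.5 * relative_tol * s, 0.35))
      if (length(tight) < max(min_predicted, 3L)) next
      # one coincidentally captured foreign node can mask the structure:
      # fall back to leave-one-out subsets when the full set shows none
      Hfull <- round(Ms[tight, , drop = FALSE])
      Ws <- list()
      add_W <- function(W, rows) {
        if (is.null(W)) return()
        g <- abs(W[1L, 1L] * W[2L, 2L] * W[3L, 3L])
        if (s == 1L && g <= 1 + 1e-9) return()   # no structure at s = 1
        key <- paste(W, collapse = ",")
        if (is.null(Ws[[key]])) Ws[[key]] <<- list(W = W, rows = rows)
      }
      add_W(integer_row_basis(Hfull), tight)
      if (length(Ws) == 0L && length(tight) > max(min_predicted, 3L)) {
        ord <- order(-resid[tight])
        for (dropi in ord[seq_len(min(6L, length(ord)))])
          add_W(integer_row_basis(Hfull[-dropi, , drop = FALSE]),
                tight[-dropi])
      }
      for (Wrec in Ws) {
        W <- Wrec$W
        Bc <- s * solve(t(W)) %*% basis_mat(current)
        if (abs(abs(det(Bc) / det(basis_mat(current))) - 1) < 1e-6) next
        cand <- tryCatch(
          reduce_basis(suppressWarnings(
            refine_basis(reduce_basis(lattice_basis(Bc)), nodes,
                         relative_tol = relative_tol))),
          error = function(e) NULL)
        if (is.null(cand)) next
        dc <- compute_defects(cand, nodes, relative_tol)
        if (dc$n_predicted < min_predicted) next
        cand_tight <- n_tight_of(cand)
        shrinks <- abs(cand$det) < abs(current$det) * (1 - 1e-6)
        ok <- if (shrinks)
          cand_tight >= length(Wrec$rows) && all(dc$predicted[Wrec$rows])
        else
          cand_tight >= cur_tight + 3L
        if (!ok) next
        if (cand_tight > best_tight ||
            (cand_tight == best_tight && !is.null(best) &&
               abs(cand$det) < abs(best$det))) {
          best <- cand
          best_d <- dc
          best_tight <- cand_tight
        }
      }
    }
    if (is.null(best)) break
    current <- best
    d <- best_d
    cur_tight <- best_tight
  }
  list(basis = current, defects = d)
}

#' Refine a basis against the nodes it predicts
#'
#' Minimises the mean reciprocal-space distance between observed nodes and
#' the node positions predicted by the basis, using only nodes close to a
#' predicted position (within `relative_tol` on the fractional Miller
#' indices). Each iteration (a) assigns inlier nodes their integer Miller
#' triples and (b) updates the basis by solving the resulting linear
#' least-squares problem in the reciprocal basis exactly. A step is accepted
#' only if the objective does not increase, so the reported objective
#' trajectory is non-increasing; iteration stops when the decrease falls
#' below `tol` (1/Angstrom) or after `max_iter` iterations.
#'
#' @inheritParams count_predicted
#' @param max_iter Iteration cap (default 100).
#' @param tol Objective-decrease tolerance in 1/Angstrom (default 1e-8).
#' @return The refined [lattice_basis()], with attributes `"objective"` (the
#'   per-iteration objective trajectory, in 1/Angstrom) and `"n_inliers"`.
#'   If fewer than 5 inliers remain at any iteration the last valid basis is
#'   returned with a warning.
#' @export
refine_basis <- function(basis, nodes, relative_tol = 0.15,
                         max_iter = 100L, tol = 1e-8) {
  B <- basis_mat(basis)
  Q <- if (inherits(nodes, "node_set")) nodes$q else as_matrix3(nodes, "nodes")
  objective <- function(Bm, idx, H)
    mean(row_norms(Q[idx, , drop = FALSE] - H %*% t(solve(Bm))))
  assign_inliers <- function(Bm) {
    M <- Q %*% t(Bm)
    H <- round(M)
    idx <- which(apply(abs(M - H), 1L, max) <= relative_tol)
    list(idx = idx, H = H[idx, , drop = FALSE])
  }
  asg <- assign_inliers(B)
  if (length(asg$idx) < 5L) {
    warning("fewer than 5 inlier nodes; refinement aborted")
    out <- lattice_basis(B)
    attr(out, "objective") <- numeric(0)
    attr(out, "n_inliers") <- length(asg$idx)
    return(out)
  }
  obj <- objective(B, asg$idx, asg$H)
  traj <- obj
  for (it in seq_len(max_iter)) {
    H <- asg$H
    # q_pred = C h with C = B^{-1}; || Q - H C^T ||_F minimised exactly.
    Ct <- tryCatch(solve(crossprod(H), crossprod(H, Q[asg$idx, , drop = FALSE])),
                   error = function(e) NULL)
    if (is.null(Ct)) break
    Bnew <- tryCatch(solve(t(Ct)), error = function(e) NULL)
    if (is.null(Bnew) || abs(det(Bnew)) < 1e-12) break
    asg_new <- assign_inliers(Bnew)
    if (length(asg_new$idx) < 5L) {
      warning("fewer than 5 inlier nodes during refinement; keeping last basis")
      break
    }
    # A step is accepted only if the objective, evaluated with the fresh
    # assignment under the new basis, does not increase.
    obj_new <- objective(Bnew, asg_new$idx, asg_new$H)
    if (obj_new > obj - tol) break
    B <- Bnew
    asg <- asg_new
    obj <- obj_new
    traj <- c(traj, obj)
  }
  out <- lattice_basis(B)
  attr(out, "objective") <- traj
  attr(out, "n_inliers") <- length(asg$idx)
  out
}
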