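# S3 methods for still_index fits.

#' @export
print.still_index <- function(x, ...) {
  cat(sprintf("Still-pattern indexing fit (%s profile, %s)\n",
              x$profile, x$multi))
  cat(sprintf("  nodes: %d", x$nodes$K))
  if (!is.null(x$cell))
    cat(sprintf("  (prior cell: %s)", paste(sprintf("%g", x$cell),
                                            collapse = " ")))
  cat("\n")
  if (!length(x$solutions)) {
    cat("  no lattice found\n")
  } else {
    for (s in x$solutions)
      cat(sprintf(
        "  lattice %d: a=%.2f b=%.2f c=%.2f A  al=%.1f be=%.1f ga=%.1f deg  (%d/%d nodes)\n",
        s$lattice_id, s$cell[1L], s$cell[2L], s$cell[3L], s$cell[4L],
        s$cell[5L], s$cell[6L], s$n_predicted, x$nodes$K))
  }
  invisible(x)
}

#' @export
summary.still_index <- function(object, ...) {
  sols <- object$solutions
  tab <- if (length(sols)) {
    data.frame(
      lattice_id = vapply(sols, `[[`, 0L, "lattice_id"),
      a = vapply(sols, function(s) s$cell[1L], 0),
      b = vapply(sols, function(s) s$cell[2L], 0),
      c = vapply(sols, function(s) s$cell[3L], 0),
      alpha = vapply(sols, function(s) s$cell[4L], 0),
      beta = vapply(sols, function(s) s$cell[5L], 0),
      gamma = vapply(sols, function(s) s$cell[6L], 0),
      volume_A3 = vapply(sols, function(s) abs(s$basis$det), 0),
      n_predicted = vapply(sols, `[[`, 0L, "n_predicted"),
      absolute_defect = vapply(sols, `[[`, 0, "absolute_defect"),
      relative_defect = vapply(sols, `[[`, 0, "relative_defect"))
  } else {
    data.frame()
  }
  structure(list(table = tab, n_nodes = object$nodes$K,
                 n_assigned = if (length(sols))
                   sum(Reduce(`|`, lapply(sols, `[[`, "predicted")))
                 else 0L,
                 profile = object$profile, multi = object$multi),
            class = "summary.still_index")
}

#' @export
print.summary.still_index <- function(x, ...) {
  cat(sprintf("Indexing summary (%s profile, %s)\n", x$profile, x$multi))
  cat(sprintf("  %d of %d nodes assigned across %d lattice(s)\n",
              x$n_assigned, x$n_nodes, nrow(x$table)))
  if (nrow(x$table)) {
    print(x$table, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.still_index <- function(object, ...) {
  sols <- object$solutions
  if (!length(sols))
    return(matrix(numeric(0), 0L, 6L,
                  dimnames = list(NULL, c("a", "b", "c", "alpha", "beta",
                                          "gamma"))))
  out <- t(vapply(sols, `[[`, numeric(6L), "cell"))
  dimnames(out) <- list(
    paste0("lattice", vapply(sols, `[[`, 0L, "lattice_id")),
    c("a", "b", "c", "alpha", "beta", "gamma"))
  out
}

#' Predict node positions and Miller indices from a fit
#'
#' For each node (of the fitted pattern or of `newdata`), finds the solution
#' lattice that predicts it (fractional Miller residual within the fit's
#' tolerance) and reports the integer indices and the exact
#' reciprocal-lattice position.
#'
#' @param object A `still_index` fit.
#' @param newdata Optional [node_set()] or q matrix; default: the fitted
#'   nodes.
#' @param ... Unused.
#' @return Data frame with columns `node`, `lattice_id` (`NA` if
#'   unassigned), `h`, `k`, `l`, `qx_pred`, `qy_pred`, `qz_pred` and
#'   `dist` (|q_obs - q_pred| in 1/Angstrom).
#' @export
predict.still_index <- function(object, newdata = NULL, ...) {
  nodes <- if (is.null(newdata)) object$nodes else
    if (inherits(newdata, "node_set")) newdata else node_set(newdata)
  n <- nodes$K
  out <- data.frame(node = seq_len(n), lattice_id = NA_integer_,
                    h = NA_integer_, k = NA_integer_, l = NA_integer_,
                    qx_pred = NA_real_, qy_pred = NA_real_,
                    qz_pred = NA_real_, dist = NA_real_)
  tol <- object$control$relative_tol
  for (s in object$solutions) {
    cp <- count_predicted(s$basis, nodes, tol)
    idx <- which(cp$predicted & is.na(out$lattice_id))
    if (!length(idx)) next
    H <- cp$hkl[idx, , drop = FALSE]
    storage.mode(H) <- "double"
    Qp <- H %*% t(solve(s$basis$mat))
    out$lattice_id[idx] <- s$lattice_id
    out[idx, c("h", "k", "l")] <- cp$hkl[idx, , drop = FALSE]
    out[idx, c("qx_pred", "qy_pred", "qz_pred")] <- Qp
    out$dist[idx] <- row_norms(nodes$q[idx, , drop = FALSE] - Qp)
  }
  out
}

#' @export
residuals.still_index <- function(object, ...) {
  pr <- predict(object)
  ok <- !is.na(pr$lattice_id)
  res <- as.matrix(pr[ok, c("qx_pred", "qy_pred", "qz_pred")])
  out <- object$nodes$q[ok, , drop = FALSE] - res
  rownames(out) <- pr$node[ok]
  colnames(out) <- c("dqx", "dqy", "dqz")
  out
}

#' Plot an indexing fit
#'
#' Shows the nodes of the pattern projected on the two detector-like axes,
#' scaled by |q|, coloured by assigned lattice (grey when unassigned), with
#' predicted positions overplotted as crosses.
#'
#' @param x A `still_index` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.still_index <- function(x, ...) {
  pr <- predict(x)
  q <- x$nodes$q
  cols <- ifelse(is.na(pr$lattice_id), "grey60",
                 grDevices::palette()[1L + (pr$lattice_id %% 7L)])
  graphics::plot(q[, 1L], q[, 2L], col = cols, pch = 19,
                 xlab = "qx (1/A)", ylab = "qy (1/A)",
                 main = "Indexed nodes (projection)", asp = 1, ...)
  ok <- !is.na(pr$lattice_id)
  if (any(ok))
    graphics::points(pr$qx_pred[ok], pr$qy_pred[ok], pch = 3,
                     col = cols[ok])
  invisible(x)
}

#' Simulate node sets from a fitted lattice
#'
#' Draws new synthetic node sets at the predicted reciprocal-lattice
#' positions of the fit's assigned nodes, with isotropic Gaussian noise at
#' the RMS of the fitted residuals.
#'
#' @param object A `still_index` fit with at least one solution.
#' @param nsim Number of simulated node sets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` [node_set()] objects.
#' @export
simulate.still_index <- function(object, nsim = 1, seed = NULL, ...) {
  if (!length(object$solutions))
    stop("cannot simulate from a fit without solutions")
  pr <- predict(object)
  ok <- !is.na(pr$lattice_id)
  mu <- as.matrix(pr[ok, c("qx_pred", "qy_pred", "qz_pred")])
  sigma <- sqrt(mean(pr$dist[ok]^2) / 3)
  gen <- function() node_set(mu + matrix(stats::rnorm(length(mu), sd = sigma),
                                         nrow(mu), 3L),
                             source = "synthetic")
  if (!is.null(seed)) with_local_seed(seed, replicate(nsim, gen(),
                                                      simplify = FALSE))
  else replicate(nsim, gen(), simplify = FALSE)
}
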