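#' Periodic proximity functions
#'
#' A proximity function scores how close a real-space trial vector lies to the
#' family of parallel lattice planes generated by one node. It is periodic
#' with period 1 and defined on `[-0.5, 0.5]`: equal to 1 on the planes
#' (`x = 0`), -1 midway between planes (`x = +/- 0.5`), even, and
#' non-increasing on `[0, 0.5]`. Smooth, broad members give a large
#' convergence radius for the maxima search; sharply peaked members give
#' precise maxima and stronger suppression of spurious nodes.
#'
#' Available kinds:
#' \describe{
#'   \item{`cosine`}{`cos(2 pi x)`. With unit weights the score becomes the
#'     real part of the Fourier transform of the node arrangement.}
#'   \item{`triangle`}{`1 - 4 |x|`, the piecewise-linear interpolant.}
#'   \item{`sharp_a`}{A narrow Gaussian bump of width `sigma = 0.1`,
#'     affinely rescaled so the value is exactly 1 at `x = 0` and -1 at
#'     `x = +/- 0.5`.}
#'   \item{`sharp_b`}{A narrow triangle of half-width 0.15:
#'     `2 max(0, 1 - |x|/0.15) - 1`.}
#' }
#'
#' @param kind One of `"cosine"`, `"triangle"`, `"sharp_a"`, `"sharp_b"`.
#' @return An object of class `proximity_function`: a list with the `kind`
#'   and vectorised `value(x)` and `derivative(x)` functions. At
#'   non-differentiable points of the piecewise-linear kinds the derivative is
#'   one-sided (0 at `x = 0` by evenness).
#' @examples
#' pf <- proximity_function("cosine")
#' pf$value(0)      # 1
#' pf$value(0.5)    # -1
#' @export
proximity_function <- function(kind = c("cosine", "triangle",
                                        "sharp_a", "sharp_b")) {
  kind <- match.arg(kind)
  f <- switch(kind,
    cosine = list(
      value = function(x) cos(2 * pi * x),
      derivative = function(x) -2 * pi * sin(2 * pi * x)),
    triangle = list(
      value = function(x) 1 - 4 * abs(x),
      derivative = function(x) -4 * sign(x)),
    sharp_a = local({
      sigma <- 0.1
      g0 <- exp(-(0.5 / sigma)^2)          # value of the raw bump at the edge
      a <- 2 / (1 - g0)
      list(
        value = function(x) a * (exp(-(x / sigma)^2) - g0) - 1,
        derivative = function(x)
          a * exp(-(x / sigma)^2) * (-2 * x / sigma^2))
    }),
    sharp_b = local({
      hw <- 0.15
      list(
        # pmax takes shape from its first argument: keep the matrix first
        value = function(x) 2 * pmax(1 - abs(x) / hw, 0) - 1,
        derivative = function(x) (abs(x) < hw) * (-2 / hw) * sign(x))
    })
  )
  structure(list(kind = kind, value = f$value, derivative = f$derivative),
            class = "proximity_function")
}

#' @export
print.proximity_function <- function(x, ...) {
  cat(sprintf("Proximity function '%s' on [-0.5, 0.5]\n", x$kind))
  invisible(x)
}

#' Score configuration
#'
#' Bundles the ingredients of the lattice score: the proximity function, the
#' per-node weighting scheme, and (for the tolerant variant) the inclusion
#' tolerance `epsilon`.
#'
#' The plain score of a trial vector `t` is the normalised weighted sum
#' `S(t) = sum_k w_k c(x_k) / sum_k w_k`, where `x_k` is the fractional
#' offset of `t` from the nearest plane of node `k`. The tolerant score
#' excludes nodes whose nearest plane is further than `epsilon` (in fractional
#' units) from `t`; included offsets are rescaled by `1/(2 epsilon)` so the
#' proximity function spans its full range inside the inclusion band. The sum
#' is still normalised by the total weight of *all* nodes, so solutions
#' explaining few nodes are penalised; an empty inclusion set scores -1.
#'
#' @param proximity A [proximity_function()] or its kind name.
#' @param weighting `"unity"`, `"inverse_radial"` (`w_k = 1/|q_k|`) or
#'   `"intensity"` (use the node weights).
#' @param epsilon Inclusion tolerance in (0, 0.5]; default 0.15. Smaller
#'   values resist spurious peaks more strongly.
#' @param use_tolerance Logical; select the tolerant score.
#' @return An object of class `score_config`.
#' @export
score_config <- function(proximity = "cosine",
                         weighting = c("unity", "inverse_radial", "intensity"),
                         epsilon = 0.15, use_tolerance = FALSE) {
  if (!inherits(proximity, "proximity_function"))
    proximity <- proximity_function(proximity)
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(epsilon), epsilon > 0, epsilon <= 0.5)
  structure(list(proximity = proximity, weighting = weighting,
                 epsilon = epsilon, use_tolerance = isTRUE(use_tolerance)),
            class = "score_config")
}

resolve_weights <- function(nodes, weighting) {
  switch(weighting,
         unity = rep(1, nodes$K),
         inverse_radial = 1 / row_norms(nodes$q),
         intensity = nodes$weight,
         stop("unknown weighting scheme"))
}

#' Fractional offset from the nearest lattice plane
#'
#' For `d = q . t`, returns `x = d - round(d)` mapped into `(-0.5, 0.5]`,
#' with the midway tie broken toward `+0.5`. `|x|` is the distance of `t`
#' from its nearest plane of the node, in units of the plane spacing `1/|q|`.
#'
#' @param d Numeric vector or matrix of plane coordinates `q . t`.
#' @return Offsets in `(-0.5, 0.5]`, same shape as `d`.
#' @examples
#' fractional_offset(c(3, 2.5, 7.3))   # 0, 0.5, 0.3
#' @export
fractional_offset <- function(d) d - ceiling(d - 0.5)

# Vectorised score/gradient workhorse.
# P: n x 3 matrix of trial vectors; returns list(score, gradient, inliers).
score_eval <- function(P, nodes, cfg, want_gradient = TRUE) {
  if (nodes$K == 0L) stop("score is undefined for an empty node set")
  P <- as_matrix3(P, "t")
  w <- resolve_weights(nodes, cfg$weighting)
  W <- sum(w)
  if (W <= 0) stop("total node weight must be positive")
  Q <- nodes$q
  X <- fractional_offset(P %*% t(Q))          # n x K fractional offsets
  pf <- cfg$proximity
  Qw <- Q * w                    # fold the weights into the node matrix
  if (!cfg$use_tolerance) {
    S <- drop(pf$value(X) %*% w) / W
    inl <- rep.int(nodes$K, nrow(P))
    G <- if (want_gradient) (pf$derivative(X) %*% Qw) / W
  } else {
    eps <- cfg$epsilon
    inc <- abs(X) <= eps
    V <- pf$value(X / (2 * eps)) * inc
    S <- drop(V %*% w) / W
    inl <- as.integer(rowSums(inc))
    S[inl == 0L] <- -1            # defined floor for an empty inclusion set
    G <- if (want_gradient)
      ((pf$derivative(X / (2 * eps)) * inc) %*% Qw) / (2 * eps * W)
  }
  list(score = S, gradient = if (want_gradient) G, inliers = inl)
}

#' Lattice score of trial real-space vectors
#'
#' Evaluates the score transform at one or more trial vectors `t`. A score of
#' 1 means every (included) node has a lattice plane passing exactly through
#' `t`; maxima of the score over `t` are candidate real-space lattice
#' vectors.
#'
#' @param t A length-3 vector or n x 3 matrix of trial vectors (Angstrom).
#' @param nodes A [node_set()].
#' @param cfg A [score_config()].
#' @return Numeric vector of scores in `[-1, 1]`, with an integer attribute
#'   `"inliers"` giving the number of included nodes at each point.
#' @examples
#' ns <- node_set(rbind(c(0.1, 0, 0)))
#' lattice_score(c(10, 0, 0), ns, score_config())   # 1: t on a plane
#' @export
lattice_score <- function(t, nodes, cfg = score_config()) {
  ev <- score_eval(t, nodes, cfg, want_gradient = FALSE)
  structure(ev$score, inliers = ev$inliers)
}

#' Analytic gradient of the lattice score
#'
#' Gradient of [lattice_score()] with respect to the trial vector:
#' `sum_k w_k c'(x_k) q_k / sum_k w_k` for the plain score; the tolerant
#' variant restricts the sum to included nodes and rescales by
#' `1/(2 epsilon)`. At non-differentiable points of piecewise-linear
#' proximity functions a one-sided derivative is used.
#'
#' @inheritParams lattice_score
#' @return An n x 3 matrix of gradients (rows correspond to rows of `t`).
#' @export
score_gradient <- function(t, nodes, cfg = score_config()) {
  score_eval(t, nodes, cfg, want_gradient = TRUE)$gradient
}
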