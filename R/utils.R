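# Internal helpers shared across modules.

vnorm <- function(x) sqrt(sum(x^2))

row_norms <- function(m) sqrt(rowSums(m^2))

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed; stays inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647L)
}

# 3x3 rotation matrix from a unit quaternion (w, x, y, z).
quat_to_rotation <- function(q) {
  q <- q / vnorm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# Uniformly random rotation (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4L)
  quat_to_rotation(q)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

as_matrix3 <- function(x, arg = "x") {
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) {
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("'%s' must have 3 columns", arg))
  storage.mode(x) <- "double"
  x
}
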