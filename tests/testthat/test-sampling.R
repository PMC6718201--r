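test_that("sphere points are unit vectors with near-uniform spacing", {
  p2 <- generate_sphere_points(2)
  expect_equal(p2[1, ], -p2[2, ])   # antipodal placement for n = 2
  p <- generate_sphere_points(1000)
  expect_true(all(abs(row_norms_test(p) - 1) < 1e-12))
  # exhaustive pairwise check of the minimum angular separation
  G <- p %*% t(p)
  diag(G) <- -1
  min_angle <- acos(max(G))
  expect_gt(min_angle, 0.5 * sqrt(4 * pi / 1000))
  expect_identical(p, generate_sphere_points(1000))   # deterministic
})

test_that("starting points fill the search volume in a half-space", {
  vol <- search_volume(20, 300)
  pts <- build_starting_points(vol, 4000, seed = 1)
  r <- row_norms_test(pts$pos)
  expect_true(all(r >= 20 - 1e-9 & r <= 300 + 1e-9))
  expect_true(all(pts$pos[, 3] >= -1e-9))   # half-space z >= 0
  expect_lte(nrow(pts$pos), 4000)
  # reproducibility
  pts2 <- build_starting_points(vol, 4000, seed = 1)
  expect_identical(pts$pos, pts2$pos)
  pts3 <- build_starting_points(vol, 4000, seed = 2)
  expect_false(identical(pts$pos, pts3$pos))
})

test_that("a degenerate shell collapses to a single sphere", {
  vol <- search_volume(20, 20.0001)
  pts <- build_starting_points(vol, 500, seed = 1)
  expect_true(all(abs(row_norms_test(pts$pos) - 20) < 0.01))
})

test_that("known-cell mode confines points to the axis shells", {
  vol <- search_volume(cell = c(30, 40, 50, 90, 90, 90), half_width = 1)
  pts <- build_starting_points(vol, 3000, seed = 1)
  r <- row_norms_test(pts$pos)
  d <- pmin(abs(r - 30), abs(r - 40), abs(r - 50))
  expect_true(all(d <= 1 + 1e-9))
  # extended search adds the face-diagonal shells
  vole <- search_volume(cell = c(30, 40, 50, 90, 90, 90), half_width = 1,
                        extended = TRUE)
  # |a+b| = 50 coincides with |c| and is deduplicated
  expect_setequal(round(vole$shell_radii, 4),
                  round(c(30, 40, 50, sqrt(30^2 + 50^2),
                          sqrt(40^2 + 50^2)), 4))
})

test_that("too small a budget errors", {
  expect_error(build_starting_points(search_volume(20, 300), 0), "budget")
})

test_that("descent step follows the documented update rule", {
  cfg <- descent_config(gamma = 1, min_step = 0.01, max_step = 2,
                        zigzag_cos_threshold = -0.9)
  # nearly opposite directions trigger the zigzag sum rule
  st <- descent_step(position = c(0, 0, 0), gradient = c(-0.95, 0.31, 0),
                     score_now = 1, state = list(dir = c(1, 0, 0), len = 0.5),
                     cfg = cfg)
  expected_dir <- c(-0.95, 0.31, 0) / sqrt(sum(c(-0.95, 0.31, 0)^2)) +
    c(1, 0, 0)
  expected_dir <- expected_dir / sqrt(sum(expected_dir^2))
  expect_equal(st$dir, expected_dir, tolerance = 1e-9)
  expect_lt(abs(sum(st$dir * c(1, 0, 0))), 0.3)   # nearly orthogonal to prev
  # exactly antipodal: deterministic orthogonal fallback
  st2 <- descent_step(c(0, 0, 0), gradient = c(-1, 0, 0), score_now = 0.5,
                      state = list(dir = c(1, 0, 0), len = 0.5), cfg = cfg)
  expect_lt(abs(sum(st2$dir * c(1, 0, 0))), 1e-9)
  expect_equal(sqrt(sum(st2$dir^2)), 1, tolerance = 1e-12)
  # zero gradient: position unchanged, step reset to the minimum
  st3 <- descent_step(c(1, 2, 3), gradient = c(0, 0, 0), score_now = 0,
                      state = list(dir = c(1, 0, 0), len = 1.4), cfg = cfg)
  expect_equal(st3$position, c(1, 2, 3))
  expect_equal(st3$len, cfg$min_step)
})

test_that("step lengths always respect the clip bounds", {
  cfg <- descent_config(min_step = 0.05, max_step = 1.5)
  set.seed(11)
  st <- list(dir = c(0, 0, 1), len = 1)
  for (i in 1:100) {
    g <- rnorm(3)
    st_new <- descent_step(runif(3), g, score_now = runif(1, -1, 1),
                           state = st, cfg = cfg)
    expect_gte(st_new$len, 0.05)
    expect_lte(st_new$len, 1.5)
    st <- list(dir = st_new$dir, len = st_new$len)
  }
})

test_that("a zero-step stage leaves positions unchanged but refreshes scores", {
  ns <- node_set(cubic_nodes(a = 40, n = 10, seed = 1))
  pts <- build_starting_points(search_volume(20, 100), 200, seed = 1)
  st <- stage_spec("cosine", "plain", n_steps = 0)
  out <- run_stage(pts, ns, st)
  expect_identical(out$pos, pts$pos)
  expect_false(anyNA(out$score))
})

test_that("descent on a single-node problem converges to a plane", {
  ns <- node_set(rbind(c(0.1, 0, 0)))
  pts <- build_starting_points(search_volume(20, 60), 100, seed = 2)
  st <- stage_spec("cosine", "plain", n_steps = 200)
  out <- run_stage(pts, ns, st, descent_config(min_step = 0.001))
  offs <- abs(fractional_offset(drop(out$pos %*% c(0.1, 0, 0))))
  expect_lt(median(offs), 1e-3)
  expect_lt(mean(offs < 1e-2), 1.01)  # sanity: offsets are fractional
})

test_that("the median score does not decrease across a stage", {
  sc <- simulate_scene(scene_params(n_nodes = 25, ewald_mode = FALSE),
                       seed = 6)
  pts <- build_starting_points(search_volume(20, 300), 2000, seed = 6)
  st <- stage_spec("cosine", "plain", weighting = "inverse_radial",
                   n_steps = 30)
  cfg0 <- score_config("cosine", weighting = "inverse_radial")
  before <- median(lattice_score(pts$pos, sc$nodes, cfg0))
  out <- run_stage(pts, sc$nodes, st)
  expect_gte(median(out$score), before)
})

test_that("sparse peak finding matches its contracts", {
  # all points identical: exactly one peak
  pos <- matrix(1, 40, 3)
  pk <- sparse_peak_find(pos, 2, score = rep(0.5, 40))
  expect_equal(nrow(pk$pos), 1L)
  # two distant clusters: both cluster bests kept
  set.seed(12)
  c1 <- matrix(rnorm(60, sd = 0.2), 20, 3)
  c2 <- matrix(rnorm(60, sd = 0.2), 20, 3) + 100
  sc <- c(runif(20, 0, 0.5), runif(20, 0, 0.5))
  pk2 <- sparse_peak_find(rbind(c1, c2), 5, score = sc)
  expect_equal(nrow(pk2$pos), 2L)
  best1 <- which.max(sc[1:20]); best2 <- 20 + which.max(sc[21:40])
  expect_true(any(apply(pk2$pos, 1, function(r)
    all(abs(r - rbind(c1, c2)[best1, ]) < 1e-12))))
  expect_true(any(apply(pk2$pos, 1, function(r)
    all(abs(r - rbind(c1, c2)[best2, ]) < 1e-12))))
  # cap contract
  pos3 <- matrix(runif(3000, -500, 500), 1000, 3)
  pk3 <- sparse_peak_find(pos3, 0.5, max_keep = 50, score = runif(1000))
  expect_lte(nrow(pk3$pos), 50L)
  # empty input
  pk4 <- sparse_peak_find(matrix(numeric(0), 0, 3), 2, score = numeric(0))
  expect_equal(nrow(pk4$pos), 0L)
})

test_that("the full heuristic finds the basis vectors of a clean lattice", {
  p <- scene_params(cell = c(40, 40, 40, 90, 90, 90), n_nodes = 25,
                    noise_frac = 0, n_spurious = 0, ewald_mode = FALSE)
  scene <- simulate_scene(p, seed = 11)
  pk <- find_lattice_vector_candidates(scene$nodes, search_volume(20, 300),
                                       seed = 11, budget = 12000)
  B <- scene$true_bases[[1]]$mat
  for (i in 1:3) {
    d <- pmin(row_norms_test(sweep(pk$pos, 2, B[i, ])),
              row_norms_test(sweep(pk$pos, 2, -B[i, ])))
    expect_lt(min(d), 0.1)
  }
  # with 30% spurious nodes the basis vectors are still among the peaks
  p2 <- scene_params(cell = c(40, 40, 40, 90, 90, 90), n_nodes = 25,
                     noise_frac = 0, n_spurious = 8, ewald_mode = FALSE)
  scene2 <- simulate_scene(p2, seed = 11)
  pk2 <- find_lattice_vector_candidates(scene2$nodes, search_volume(20, 300),
                                        seed = 11, budget = 12000)
  B2 <- scene2$true_bases[[1]]$mat
  for (i in 1:3) {
    d <- pmin(row_norms_test(sweep(pk2$pos, 2, B2[i, ])),
              row_norms_test(sweep(pk2$pos, 2, -B2[i, ])))
    expect_lt(min(d), 0.1)
  }
  # determinism
  pk3 <- find_lattice_vector_candidates(scene$nodes, search_volume(20, 300),
                                        seed = 11, budget = 12000)
  expect_identical(pk$pos, pk3$pos)
  expect_error(find_lattice_vector_candidates(
    node_set(rbind(c(0.1, 0, 0))), search_volume(20, 300)), "3 nodes")
})

test_that("stage (i) inverse-radial weights reproduce an independent sum", {
  set.seed(13)
  q <- matrix(rnorm(36, sd = 0.07), 12, 3)
  ns <- node_set(q)
  cfg <- score_config("cosine", weighting = "inverse_radial")
  w <- 1 / sqrt(rowSums(q^2))
  for (i in 1:20) {
    t0 <- runif(3, -50, 50)
    oracle <- sum(w * cos(2 * pi * drop(q %*% t0))) / sum(w)
    expect_equal(as.numeric(lattice_score(t0, ns, cfg)), oracle,
                 tolerance = 1e-12)
  }
})
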