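# Candidate enumeration, lattice selection and the end-to-end fit.

make_candidate <- function(basis, nodes, score = 1,
                           relative_tol = 0.15) {
  d <- compute_defects(basis, nodes, relative_tol)
  list(basis = basis, score = score, n_predicted = d$n_predicted,
       relative_defect = d$relative_defect,
       absolute_defect = d$absolute_defect,
       predicted = d$predicted, hkl = d$hkl, det = abs(basis$det))
}

test_that("a lone true triple survives enumeration on its own scene", {
  scene <- simulate_scene(scene_params(n_nodes = 25, noise_frac = 0,
                                       n_spurious = 0, ewald_mode = FALSE),
                          seed = 21)
  B <- scene$true_bases[[1]]$mat
  peaks <- structure(list(pos = B, score = c(1, 1, 1),
                          inliers = rep(25L, 3)),
                     class = "candidate_peaks")
  cands <- enumerate_candidate_bases(peaks, scene$nodes, index_control())
  expect_equal(length(cands), 1L)
  expect_equal(cands[[1]]$n_predicted, 25L)
  expect_true(bases_equivalent(cands[[1]]$basis, scene$true_bases[[1]]))
})

test_that("coplanar triples are rejected by the determinant filter", {
  scene <- simulate_scene(scene_params(n_nodes = 25, noise_frac = 0,
                                       n_spurious = 0, ewald_mode = FALSE),
                          seed = 21)
  B <- scene$true_bases[[1]]$mat
  coplanar <- rbind(B[1, ], B[2, ], B[1, ] + B[2, ])
  peaks <- structure(list(pos = coplanar, score = c(1, 1, 1),
                          inliers = rep(25L, 3)),
                     class = "candidate_peaks")
  expect_equal(length(enumerate_candidate_bases(peaks, scene$nodes,
                                                index_control())), 0L)
})

test_that("enumeration output is capped", {
  scene <- simulate_scene(scene_params(n_nodes = 30, ewald_mode = FALSE),
                          seed = 22)
  pk <- find_lattice_vector_candidates(scene$nodes, search_volume(20, 300),
                                       seed = 22, budget = 8000)
  ctl <- index_control(max_candidates = 40L)
  cands <- enumerate_candidate_bases(pk, scene$nodes, ctl)
  expect_lte(length(cands), 40L)
})

test_that("selection prefers the smaller determinant in a supercell trap", {
  B <- basis_from_cell(test_cell)
  recip <- solve(B$mat)
  set.seed(23)
  H <- 2 * matrix(sample(-3:3, 75, TRUE), 25, 3)  # even indices only
  nodes <- node_set(H %*% t(recip))
  true_c <- make_candidate(B, nodes)
  super_c <- make_candidate(lattice_basis(2 * B$mat), nodes)
  # both predict every node (indices even), counts equal
  expect_equal(true_c$n_predicted, super_c$n_predicted)
  sols <- select_lattices(list(super_c, true_c), nodes, index_control())
  expect_equal(length(sols), 1L)
  expect_equal(sols[[1]]$det, abs(B$det), tolerance = 1e-9)
})

test_that("selection returns disjoint lattices and no duplicates", {
  scene <- simulate_scene(scene_params(n_lattices = 2, n_nodes = 25,
                                       n_spurious = 0), seed = 24)
  fit <- index_still(scene$nodes, seed = 24)
  expect_gte(length(fit$solutions), 2L)
  for (u in seq_along(fit$solutions)) for (v in seq_along(fit$solutions)) {
    if (u >= v) next
    expect_false(bases_equivalent(fit$solutions[[u]]$basis,
                                  fit$solutions[[v]]$basis))
  }
})

test_that("end-to-end: clean scene indexes within 3 degrees, exact cell", {
  scene <- simulate_scene(scene_params(n_nodes = 25, noise_frac = 0,
                                       n_spurious = 0), seed = 25)
  fit <- index_still(scene$nodes, seed = 25)
  expect_equal(length(fit$solutions), 1L)
  ev <- evaluate_solutions(fit, scene)
  expect_true(ev$recovered)
  expect_lt(ev$kabsch_angle_deg, 3)
  expect_lt(ev$cell_error, 0.01)
  # with the cell prior the result is at least as good
  fitc <- index_still(scene$nodes, cell = test_cell, seed = 25)
  evc <- evaluate_solutions(fitc, scene)
  expect_true(evc$recovered)
  expect_true(all(abs(coef(fitc)[1, 1:3] - sort(test_cell[1:3])) /
                    sort(test_cell[1:3]) < 0.05))
})

test_that("too few nodes and pure noise are data outcomes, not errors", {
  fit <- index_still(matrix(c(0.1, 0, 0, 0, 0.1, 0, 0, 0, 0.1), 3, 3,
                           byrow = TRUE), seed = 1)
  expect_s3_class(fit, "still_index")
  expect_equal(length(fit$solutions), 0L)
  set.seed(26)
  noise_fit <- index_still(matrix(runif(60, -0.2, 0.2), 20, 3), seed = 26)
  expect_s3_class(noise_fit, "still_index")
  for (s in noise_fit$solutions) expect_gte(s$n_predicted, 5L)
})

test_that("fits are deterministic under a fixed seed", {
  scene <- simulate_scene(scene_params(n_nodes = 25), seed = 27)
  f1 <- index_still(scene$nodes, seed = 27)
  f2 <- index_still(scene$nodes, seed = 27)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-15)
})

test_that("fit methods expose the solution coherently", {
  scene <- simulate_scene(scene_params(n_nodes = 25, noise_frac = 0,
                                       n_spurious = 5), seed = 28)
  fit <- index_still(scene$nodes, seed = 28)
  expect_output(print(fit), "lattice 1")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.still_index")
  expect_output(print(sm), "nodes assigned")
  co <- coef(fit)
  expect_equal(dim(co), c(length(fit$solutions), 6L))
  pr <- predict(fit)
  expect_equal(nrow(pr), scene$nodes$K)
  assigned <- !is.na(pr$lattice_id)
  expect_gte(sum(assigned), 25L - 2L)
  expect_true(all(pr$dist[assigned] < 0.01))
  res <- residuals(fit)
  expect_equal(nrow(res), sum(assigned))
  expect_lt(max(abs(res)), 0.01)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "node_set")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("solution and assignment files round-trip", {
  scene <- simulate_scene(scene_params(n_nodes = 25, noise_frac = 0,
                                       n_spurious = 0), seed = 29)
  fit <- index_still(scene$nodes, seed = 29)
  sf <- withr::local_tempfile(fileext = ".tsv")
  af <- withr::local_tempfile(fileext = ".tsv")
  write_solutions(fit, sf)
  write_assignments(fit, af)
  sols <- read_solutions(sf)
  expect_length(sols, length(fit$solutions))
  expect_equal(sols[[1]]$mat, fit$solutions[[1]]$basis$mat,
               tolerance = 1e-6, ignore_attr = TRUE)
  atab <- read.delim(af)
  expect_true(all(atab$lattice_id == 1L))
  expect_gte(nrow(atab), 5L)
})
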