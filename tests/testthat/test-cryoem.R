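test_that("simulated maps are linear, peaked at atoms, and integrate correctly", {
  one <- matrix(c(1.3, 2.1, -0.7), 1)
  m1 <- simulate_map(one, resolution = 8, voxel = 2)
  a <- array(m1$values, m1$dims)
  peak <- which(a == max(a), arr.ind = TRUE)[1, ]
  peak_pos <- m1$origin + (peak - 1) * m1$voxel
  expect_lt(sqrt(sum((peak_pos - one)^2)), sqrt(3) * m1$voxel)

  d <- toy2()$domains[[1]]
  ma <- simulate_map(d$xyz, 8, 2)
  mb <- simulate_map(rbind(d$xyz, d$xyz), 8, 2)
  expect_equal(mb$values, 2 * ma$values, tolerance = 1e-9)

  # integral ~ N (2 pi)^{3/2} sigma^3 / voxel^3
  sigma <- 0.425 * 8
  expected <- nrow(d$xyz) * (2 * pi)^1.5 * sigma^3 / 2^3
  expect_equal(sum(ma$values), expected, tolerance = 0.02)
  expect_error(simulate_map(d$xyz[0, , drop = FALSE]), "empty")
  expect_error(simulate_map(d$xyz, resolution = 3, voxel = 2), "resolution")
})

test_that("density correlation is near 1 for self, near 0 off-map, locally monotone", {
  toy <- toy2()
  map <- simulate_map(toy$native$xyz, 8, 2)
  expect_gte(density_correlation(toy$native$xyz, map, 8), 0.999)
  expect_lt(abs(suppressWarnings(
    density_correlation(toy$native$xyz + 500, map, 8))), 0.05)
  # correlation decreases monotonically over a 0-5 A translation scan
  prof <- vapply(0:5, function(dx)
    density_correlation(sweep(toy$native$xyz, 2, c(dx, 0, 0), "+"), map, 8),
    numeric(1))
  expect_true(all(diff(prof) < 0))
  # zero-variance map
  flat <- density_grid(rep(1, 8 * 8 * 8), c(0, 0, 0), 2, c(8, 8, 8))
  expect_warning(z <- density_correlation(toy$native$xyz[1:5, ] * 0 + 6, flat, 8))
  expect_equal(z, 0)
})

test_that("correlation is invariant under a common rigid motion of model and map", {
  d <- toy2()$domains[[1]]
  base_map <- simulate_map(d$xyz, 8, 2)
  base <- density_correlation(d$xyz, base_map, 8)
  R <- rigidom:::axis_angle_matrix(c(1, 1, 0), 0.6)
  XT <- sweep(d$xyz %*% t(R), 2, c(5, -3, 2), "+")
  mapT <- simulate_map(XT, 8, 2)  # regridded on the moved frame
  expect_equal(density_correlation(XT, mapT, 8), base, tolerance = 0.02)
})

test_that("per-domain map fitting recovers the planted pose", {
  ok <- 0
  for (s in 1:4) {
    d <- make_toy_domain(60, "helix-bundle", seed = 40 + s)
    map <- simulate_map(d$xyz, 8, 2)
    fits <- fit_domain_to_map(d, map, 8, seed = s)
    X <- apply_pose(d, fits[[1]]$pose)
    cen_err <- sqrt(sum((rigidom:::centroid(X) - rigidom:::centroid(d$xyz))^2))
    R <- rigidom:::euler_to_matrix(as.numeric(fits[[1]]$pose)[1:3])
    ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
    if (cen_err <= 2 && ang <= 10) ok <- ok + 1
  }
  expect_gte(ok, 3)
})

test_that("two identical domains in a two-blob map land on both blobs", {
  d <- make_toy_domain(40, "helix-bundle", seed = 6)
  far <- d$xyz + matrix(c(40, 0, 0), nrow(d$xyz), 3, byrow = TRUE)
  map <- simulate_map(rbind(d$xyz, far), 8, 2)
  fits <- fit_domain_to_map(d, map, 8, seed = 2)
  cens <- t(vapply(fits[1:8], function(f)
    rigidom:::centroid(apply_pose(d, f$pose)), numeric(3)))
  c0 <- rigidom:::centroid(d$xyz)
  near_a <- sqrt(rowSums(sweep(cens, 2, c0)^2)) < 10
  near_b <- sqrt(rowSums(sweep(cens, 2, c0 + c(40, 0, 0))^2)) < 10
  expect_true(any(near_a) && any(near_b))
})

test_that("flat maps give degenerate but deterministic fits", {
  d <- make_toy_domain(30, "helix-bundle", seed = 3)
  flat <- density_grid(rep(1, 15^3), c(-20, -20, -20), 3, c(15, 15, 15))
  f1 <- suppressWarnings(fit_domain_to_map(d, flat, 8, seed = 5))
  f2 <- suppressWarnings(fit_domain_to_map(d, flat, 8, seed = 5))
  expect_equal(vapply(f1, `[[`, 0, "correlation"), rep(0, length(f1)))
  expect_identical(lapply(f1, `[[`, "pose"), lapply(f2, `[[`, "pose"))
})

test_that("CCP4 mode-2 maps round-trip", {
  d <- toy2()$domains[[1]]
  map <- simulate_map(d$xyz, 8, 2)
  tmp <- withr::local_tempfile(fileext = ".mrc")
  write_ccp4(map, tmp)
  back <- read_ccp4(tmp)
  expect_equal(back$dims, map$dims)
  expect_equal(back$voxel, map$voxel, tolerance = 1e-5)
  expect_equal(back$origin, map$origin, tolerance = 1e-4)
  expect_equal(back$values, map$values, tolerance = 1e-5)
})

test_that("density-guided assembly recovers the native from map + restraints", {
  toy <- toy2()
  map <- simulate_map(toy$native$xyz, 8, 2)
  prob <- assembly_problem(toy$domains, toy$layout, toy2_restraints(),
                           map = map, resolution = 8)
  res <- suppressWarnings(density_guided_assemble(prob, assembly_config(seed = 2)))
  expect_gte(r_tm_score(res$models[[1]]$xyz, toy$native$xyz,
                        dom = toy$native$dom), 0.95)
  expect_gte(res$models[[1]]$correlation, 0.6)
})

test_that("coincident stage-1 fits fall back to the best-correlation start", {
  # a single-blob map forces every domain fit onto the same blob
  toy <- toy2()
  blob <- simulate_map(toy$domains[[1]]$xyz, 8, 2)
  prob <- assembly_problem(toy$domains, toy$layout, toy2_restraints(),
                           map = blob, resolution = 8)
  res <- suppressWarnings(density_guided_assemble(
    prob, assembly_config(seed = 3, max_steps = 40)))
  expect_gte(length(res$models), 1)
})
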