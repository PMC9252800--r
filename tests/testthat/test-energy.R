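test_that("each energy term matches its independent double-loop oracle", {
  toy <- toy2()
  fc <- toy2_scrambled_flat()
  rs <- toy2_restraints()
  expect_equal(e_distance(fc, rs), oracle_e_dist_gauss(fc, rs$gaussians),
               tolerance = 1e-9)
  con <- data.frame(i = c(1L, 10L, 20L), j = c(70L, 90L, 110L),
                    prob = c(1, 0.7, 0.3))
  expect_equal(e_contact(fc, con), oracle_e_contact(fc, con), tolerance = 1e-9)
  expect_equal(e_clash(fc), oracle_e_clash(fc), tolerance = 1e-9)
  expect_equal(e_generic_contact(fc, toy$layout), oracle_e_generic(fc, toy$layout),
               tolerance = 1e-9)
  expect_equal(e_connectivity(fc, toy$layout), oracle_e_conn(fc, toy$layout),
               tolerance = 1e-9)
  # coincident domains: clash equals the brute-force pairwise sum
  fc0 <- fc
  fc0$xyz[fc0$dom == 2, ] <- fc0$xyz[fc0$dom == 1, ]
  expect_equal(e_clash(fc0), oracle_e_clash(fc0), tolerance = 1e-9)
  expect_gt(e_clash(fc0), 0)
})

test_that("distance term has unit residual and cap semantics", {
  fc <- toy2()$native
  i <- fc$resno[1]; j <- fc$resno[100]
  d <- sqrt(sum((fc$xyz[1, ] - fc$xyz[100, ])^2))
  one <- function(mean, w = 2) restraint_set(gaussians = data.frame(
    i = i, j = j, atom = "CA", mean = mean, sd = 1.5, weight = w))
  expect_equal(e_distance(fc, one(d)), 0, tolerance = 1e-9)
  expect_equal(e_distance(fc, one(d - 1.5)), 2 * 1.0, tolerance = 1e-9)
  expect_equal(e_distance(fc, one(d - 15)), 2 * 16, tolerance = 1e-9)  # cap
  # exact native restraints give zero at the native pose
  expect_equal(e_distance(fc, toy2_restraints()), 0, tolerance = 1e-9)
})

test_that("contact term penalizes only confident contacts beyond 18 A", {
  fc <- list(resno = c(1L, 2L), dom = c(1L, 2L),
             xyz = rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(e_contact(fc, data.frame(i = 1L, j = 2L, prob = 1)), 1.0)
  expect_equal(e_contact(fc, data.frame(i = 1L, j = 2L, prob = 0.4)), 0)
  fc$xyz[2, 1] <- 17
  expect_equal(e_contact(fc, data.frame(i = 1L, j = 2L, prob = 1)), 0)
})

test_that("clash, generic-contact and connectivity terms follow their definitions", {
  mk_fc <- function(d) list(resno = c(1L, 2L), dom = c(1L, 2L),
                            xyz = rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(e_clash(mk_fc(4.0)), 0)
  expect_equal(e_clash(mk_fc(2.8)), 1.0, tolerance = 1e-12)

  toy <- toy2()
  # fully separated domains: no generic reward
  poses <- identity_poses(2)
  poses[[2]] <- rigid_pose(trans = c(500, 0, 0))
  far <- flat_at(toy, poses)
  expect_equal(e_generic_contact(far, toy$layout), 0)
  # native interface is saturated by construction
  expect_equal(e_generic_contact(toy$native, toy$layout), -1)

  # connectivity: native zero; a 1 A overshoot costs 1
  expect_equal(e_connectivity(toy$native, toy$layout), 0, tolerance = 1e-9)
  fc2 <- list(resno = c(1L, 2L), dom = c(1L, 2L),
              xyz = rbind(c(0, 0, 0), c(4.8, 0, 0)))
  ly2 <- infer_layout(list(domain_model(1L, 1L, matrix(c(0, 0, 0), 1)),
                           domain_model(2L, 2L, matrix(c(4.8, 0, 0), 1))))
  expect_equal(e_connectivity(fc2, ly2), 1.0, tolerance = 1e-9)
  # discontinuous insertion: both crossings contribute
  toyD <- toyd()
  expect_equal(nrow(toyD$layout$boundaries), 2)
  posesD <- identity_poses(2)
  posesD[[2]] <- rigid_pose(trans = c(0, 0, 60))
  fcD <- flat_at(toyD, posesD)
  expect_equal(e_connectivity(fcD, toyD$layout),
               oracle_e_conn(fcD, toyD$layout), tolerance = 1e-9)
  expect_gt(e_connectivity(fcD, toyD$layout), 2 * 30^2)  # both junctions stretched
})

test_that("template profile energy is the tm_h-weighted mean of per-hit wells", {
  toy <- toy2()
  lib <- list(native = toy$native$xyz)
  hit <- local_evaluate(toy$domains, list(id = "native", xyz = toy$native$xyz))
  # self-template at the native pose: zero
  expect_lt(e_template_profile(toy$native, list(hit)), 1e-6)
  # a hit covering one domain only contributes nothing; compact walks are
  # mutually dissimilar so the other domain stays below the fold threshold
  toyCW <- make_toy_multidomain(toy_spec(2, 60, fold = "compact-walk", seed = 6))
  hit1 <- local_evaluate(toyCW$domains, list(id = "d1", xyz = toyCW$domains[[1]]$xyz))
  expect_lt(hit1$tm_scores[2], 0.5)
  expect_equal(nrow(hit1$tpl_pairs), 0)
  expect_equal(e_template_profile(toyCW$native, list(hit1)), 0)
  # two conflicting templates: tm_h-weighted mean, checked against the oracle
  fake <- hit
  fake$tm_h <- 0.6
  fake$tpl_pairs$d <- fake$tpl_pairs$d + 3
  fc <- toy2_scrambled_flat()
  expect_equal(e_template_profile(fc, list(hit, fake)),
               oracle_e_template(fc, list(hit, fake)), tolerance = 1e-9)
  e1 <- oracle_e_template(fc, list(hit))
  e2 <- oracle_e_template(fc, list(fake))
  expect_equal(e_template_profile(fc, list(hit, fake)),
               (hit$tm_h * e1 + fake$tm_h * e2) / (hit$tm_h + fake$tm_h),
               tolerance = 1e-9)
})

test_that("orientation energy is zero at its reference angles and 2w at a pi flip", {
  # two residues with explicit N/CA/CB frames
  fc <- list(resno = c(1L, 2L),
             xyz = rbind(c(0, 0, 0), c(8, 1, 0)),
             cb = rbind(c(0.8, 1.1, 0.4), c(7.4, 2.2, 0.5)),
             n = rbind(c(-1.2, 0.6, 0), c(9.1, 0.2, 0.6)))
  ang <- with(fc, c(
    rigidom:::dihedral(xyz[1, ], cb[1, ], cb[2, ], xyz[2, ]),
    rigidom:::dihedral(n[1, ], xyz[1, ], cb[1, ], cb[2, ]),
    rigidom:::dihedral(n[2, ], xyz[2, ], cb[2, ], cb[1, ]),
    rigidom:::angle3(xyz[1, ], cb[1, ], cb[2, ]),
    rigidom:::angle3(xyz[2, ], cb[2, ], cb[1, ])))
  ori <- data.frame(i = 1L, j = 2L, omega = ang[1], theta_ij = ang[2],
                    theta_ji = ang[3], phi_ij = ang[4], phi_ji = ang[5],
                    weight = 1.5)
  expect_equal(e_orientation(fc, ori), 0, tolerance = 1e-9)
  flip <- ori
  wrap <- function(x) atan2(sin(x), cos(x))
  flip$omega <- wrap(ori$omega + pi)
  expect_equal(e_orientation(fc, flip), 1.5 * 2, tolerance = 1e-9)
  flip2 <- ori
  flip2$omega <- wrap(ori$omega - pi)
  expect_equal(e_orientation(fc, flip2), e_orientation(fc, flip), tolerance = 1e-9)
  # no CB information: the term is skipped
  expect_equal(e_orientation(list(resno = 1:2, xyz = fc$xyz), ori), 0)
})

test_that("total energy sums its breakdown and is invariant under global motion", {
  toy <- toy2()
  rs <- toy2_restraints()
  hit <- local_evaluate(toy$domains, list(id = "native", xyz = toy$native$xyz))
  prob <- assembly_problem(toy$domains, toy$layout, rs, hits = list(hit))
  st <- scramble(identity_poses(2), 35, 12, seed = 21)
  e <- total_energy(st$poses, prob)
  expect_equal(sum(e$breakdown), e$total, tolerance = 1e-9)
  # matches the full R oracle recomputation
  fc <- flat_at(toy, st$poses)
  expect_equal(e$total, oracle_total(fc, toy$layout, rs, list(hit)),
               tolerance = 1e-9)
  # apply one common rigid motion to every domain: non-density total unchanged
  R <- rigidom:::axis_angle_matrix(c(2, -1, 0.5), 0.9)
  shift <- c(7, -9, 4)
  glob <- lapply(seq_along(st$poses), function(k) {
    p <- as.numeric(st$poses[[k]])
    c0 <- rigidom:::centroid(toy$domains[[k]]$xyz)
    R0 <- rigidom:::euler_to_matrix(p[1:3])
    # x -> R (R0 (x - c0) + c0 + t) + shift
    rigid_pose(rigidom:::matrix_to_euler(R %*% R0),
               as.numeric(R %*% (c0 + p[4:6]) + shift - c0))
  })
  e2 <- total_energy(glob, prob)
  expect_equal(e2$total, e$total, tolerance = 1e-6)

  # native pose with exact restraints and the self-template: only the
  # generic-contact reward remains
  e_nat <- total_energy(identity_poses(2), prob)
  expect_equal(unname(e_nat$breakdown[c("dist", "contact", "clash",
                                        "connectivity", "template")]),
               rep(0, 5), tolerance = 1e-6)
  expect_equal(e_nat$total, e_nat$breakdown[["generic"]], tolerance = 1e-6)
  expect_error(total_energy(rep(NaN, 12), prob), "non-finite")
})

test_that("finite-difference gradients are self-consistent across step sizes", {
  toy <- toy2()
  prob <- assembly_problem(toy$domains, toy$layout, toy2_restraints())
  params <- rigidom:::poses_to_params(
    scramble(identity_poses(2), 25, 8, seed = 31)$poses, 2)
  wv <- rigidom:::cpp_weight_vec(energy_weights())
  g4 <- rigidom:::cpp_energy_grad(params, prob$X0, prob$dom_idx0,
                                  prob$centroids, prob$pdata, wv, step = 1e-4)
  g5 <- rigidom:::cpp_energy_grad(params, prob$X0, prob$dom_idx0,
                                  prob$centroids, prob$pdata, wv, step = 1e-5)
  expect_equal(as.numeric(g4), as.numeric(g5),
               tolerance = 1e-3 * max(abs(g5)))
  # gradient returned by total_energy matches the kernel
  e <- total_energy(params, prob, gradient = TRUE)
  expect_equal(e$gradient, as.numeric(g4), tolerance = 1e-12)
})
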