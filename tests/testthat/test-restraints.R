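uniform_distogram <- function(i = 1L, j = 30L) {
  edges <- rigidom:::default_bin_edges()
  nb <- length(edges) - 1
  list(bin_edges = edges,
       records = data.frame(i = i, j = j, atom = "CA"),
       probs = matrix(1 / nb, 1, nb))
}

test_that("contact probabilities are the cumulative distogram mass below 18 A", {
  edges <- rigidom:::default_bin_edges()
  nb <- length(edges) - 1
  below <- matrix(0, 1, nb); below[1, 5] <- 1        # bin fully below 18
  above <- matrix(0, 1, nb); above[1, nb] <- 1       # last bin: 19.5-20
  rs_below <- restraint_set(distograms = list(bin_edges = edges,
    records = data.frame(i = 1L, j = 30L, atom = "CA"), probs = below))
  rs_above <- restraint_set(distograms = list(bin_edges = edges,
    records = data.frame(i = 1L, j = 30L, atom = "CA"), probs = above))
  rs_unif <- restraint_set(distograms = uniform_distogram())
  expect_equal(contacts_from_distograms(rs_below)$prob, 1.0)
  expect_equal(contacts_from_distograms(rs_above)$prob, 0.0)
  # uniform over [2, 20]: mass below 18 is 16/18
  expect_equal(contacts_from_distograms(rs_unif)$prob, 16 / 18)
  # monotone non-decreasing in the cutoff
  cuts <- seq(3, 20, by = 0.5)
  probs <- vapply(cuts, function(ct)
    contacts_from_distograms(rs_unif, cutoff = ct)$prob, numeric(1))
  expect_true(all(diff(probs) >= -1e-12))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("native-derived restraints are exact at the native pose and seed-stable", {
  toy <- toy2()
  rs <- synth_restraints_from_native(toy$native, toy$layout, "exact",
                                     sd = 1, subsample = 1, seed = 1)
  # every restraint satisfied with zero residual at the native pose
  d <- vapply(seq_len(nrow(rs$gaussians)), function(k) {
    i <- match(rs$gaussians$i[k], toy$native$resno)
    j <- match(rs$gaussians$j[k], toy$native$resno)
    sqrt(sum((toy$native$xyz[i, ] - toy$native$xyz[j, ])^2))
  }, numeric(1))
  expect_equal(d, rs$gaussians$mean, tolerance = 1e-9)
  expect_equal(nrow(rs$gaussians), 60 * 60)  # all inter-domain pairs
  # only inter-domain pairs are restrained
  dom_of <- toy$native$dom[match(rs$gaussians$i, toy$native$resno)]
  dom_of_j <- toy$native$dom[match(rs$gaussians$j, toy$native$resno)]
  expect_true(all(dom_of != dom_of_j))

  # subsampling keeps exactly round(frac * n) pairs, reproducibly
  rs25a <- synth_restraints_from_native(toy$native, toy$layout, "exact",
                                        sd = 1, subsample = 0.25, seed = 5)
  rs25b <- synth_restraints_from_native(toy$native, toy$layout, "exact",
                                        sd = 1, subsample = 0.25, seed = 5)
  expect_equal(nrow(rs25a$gaussians), round(0.25 * 3600))
  expect_identical(rs25a$gaussians, rs25b$gaussians)
})

test_that("noisy restraints have the half-normal mean absolute residual", {
  toy <- toy2()
  rs <- synth_restraints_from_native(toy$native, toy$layout, "noisy",
                                     sd = 1, subsample = 0.25, seed = 2)
  expect_gte(nrow(rs$gaussians), 200)
  res <- vapply(seq_len(nrow(rs$gaussians)), function(k) {
    i <- match(rs$gaussians$i[k], toy$native$resno)
    j <- match(rs$gaussians$j[k], toy$native$resno)
    abs(sqrt(sum((toy$native$xyz[i, ] - toy$native$xyz[j, ])^2)) - rs$gaussians$mean[k])
  }, numeric(1))
  # E|N(0,1)| = sqrt(2/pi) ~ 0.798
  expect_equal(mean(res), sqrt(2 / pi), tolerance = 0.15)
  expect_error(synth_restraints_from_native(toy$native, toy$layout, "noisy", sd = 0),
               "sd")
})

test_that("restraint files round-trip losslessly and validate on read", {
  toy <- toy2()
  set.seed(3)
  ori <- data.frame(i = 1L, j = 70L, omega = 1.2, theta_ij = -0.4, theta_ji = 2.0,
                    phi_ij = 0.8, phi_ji = 2.2, weight = 1)
  con <- data.frame(i = c(2L, 5L), j = c(65L, 80L), prob = c(0.9, 0.4))
  rs <- restraint_set(
    gaussians = data.frame(i = 3L, j = 71L, atom = "CA", mean = 10.5, sd = 1, weight = 1),
    distograms = uniform_distogram(4L, 90L),
    contacts = con, orientations = ori)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_restraints(rs, tmp)
  back <- read_restraints(tmp)
  expect_equal(back$gaussians$mean, 10.5)
  expect_equal(back$contacts$prob, con$prob)
  expect_equal(back$orientations$omega, ori$omega)
  expect_equal(back$distograms$probs, rs$distograms$probs, tolerance = 1e-9)
  expect_equal(back$distograms$bin_edges, rs$distograms$bin_edges)

  # single DIST line parses to one Gaussian restraint
  writeLines("DIST 3 71 CA 10.5 1.0 1.0", tmp)
  one <- read_restraints(tmp)
  expect_equal(nrow(one$gaussians), 1)
  expect_equal(one$gaussians$sd, 1.0)

  # a distogram whose probabilities sum to 0.8 is rejected with its line
  nb <- length(rigidom:::default_bin_edges()) - 1
  writeLines(paste("DGRAM 1 30 CA", paste(rep(0.8 / nb, nb), collapse = " ")), tmp)
  expect_error(read_restraints(tmp), "sum to 1")

  writeLines("DIST 3 71 CA ten 1.0 1.0", tmp)
  expect_error(read_restraints(tmp), "line 1")

  writeLines(c("FOO 1 2 3", "CON 1 70 0.5"), tmp)
  expect_warning(skipped <- read_restraints(tmp), "unknown record")
  expect_equal(nrow(skipped$contacts), 1)
})
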