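write_ca_pdb <- function(resno, xyz, path, resid = "ALA", extra = NULL) {
  lines <- c(extra, vapply(seq_along(resno), function(k) sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    k, resid, resno[k], xyz[k, 1], xyz[k, 2], xyz[k, 3], 1.0, 0.0),
    character(1)), "END")
  writeLines(lines, path)
  path
}

test_that("read_domain_pdb parses CA traces and infers segments from numbering gaps", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  xyz <- cbind(3.8 * (0:2), 0, 0)
  read1 <- read_domain_pdb(write_ca_pdb(1:3, xyz, tmp), 1L)
  expect_s3_class(read1, "domain_model")
  expect_equal(read1$resno, 1:3)
  expect_equal(nrow(read1$segments), 1)
  expect_equal(read1$xyz, xyz, tolerance = 1e-3)

  # a continuous 1-94 domain yields the single segment (1, 94)
  d <- make_toy_domain(94, "helix-bundle", seed = 2)
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  r2 <- read_domain_pdb(write_ca_pdb(1:94, d$xyz, tmp2), 1L)
  expect_equal(unname(r2$segments[1, ]), c(1, 94))

  # a numbering gap >= 2 splits segments (discontinuous domain)
  tmp3 <- withr::local_tempfile(fileext = ".pdb")
  dd <- make_toy_domain(36, "helix-bundle", seed = 3)
  r3 <- read_domain_pdb(write_ca_pdb(c(5:20, 41:60), dd$xyz, tmp3), 2L)
  expect_equal(nrow(r3$segments), 2)
  expect_equal(unname(r3$segments[, "start"]), c(5, 41))
  expect_equal(unname(r3$segments[, "end"]), c(20, 60))
})

test_that("read_domain_pdb rejects insertion codes, empty files and missing CA", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", tmp)
  expect_error(read_domain_pdb(tmp), "ATOM|parse")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2A      3.800   0.000   0.000  1.00  0.00",
    "END"), tmp)
  expect_error(read_domain_pdb(tmp), "insertion")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  N   ALA A   2       3.800   0.000   0.000  1.00  0.00",
    "END"), tmp)
  expect_error(read_domain_pdb(tmp), "without CA")
  expect_error(read_domain_pdb(file.path(tempdir(), "no-such-file.pdb")), "no such")
})

test_that("infer_layout computes linker gaps and orders domains by segment start", {
  mk <- function(id, resno) domain_model(id, resno, cbind(3.8 * seq_along(resno), id, 0))
  ly <- infer_layout(list(mk(1, 1:50), mk(2, 61:110)))
  expect_equal(ly$linker_gaps, 10L)
  ly0 <- infer_layout(list(mk(1, 1:50), mk(2, 51:100)))
  expect_equal(ly0$linker_gaps, 0L)
  # permutation invariance
  ly_swap <- infer_layout(list(mk(2, 61:110), mk(1, 1:50)))
  expect_equal(ly_swap$domain_order, ly$domain_order)
  expect_equal(ly_swap$linker_gaps, ly$linker_gaps)
  expect_equal(ly_swap$boundaries, ly$boundaries)
})

test_that("infer_layout handles a discontinuous middle domain and rejects overlaps", {
  mk <- function(id, resno) domain_model(id, resno, cbind(3.8 * seq_along(resno), id, 0))
  # domain 2 is discontinuous, flanking domain 3 inserted in its middle
  doms <- list(mk(1, 1:30), mk(2, c(31:60, 91:120)), mk(3, 61:90))
  ly <- infer_layout(doms)
  expect_equal(ly$domain_order, c(1L, 2L, 3L))
  # three inter-domain junctions: 30|31, 60|61, 90|91
  expect_equal(nrow(ly$boundaries), 3)
  expect_equal(ly$boundaries$gap, c(0, 0, 0))
  expect_error(infer_layout(list(mk(1, 1:50), mk(2, 40:80))), "overlap")
})

test_that("infer_layout validates residue names against a full sequence", {
  mk <- function(id, resno, resid) domain_model(id, resno,
    cbind(3.8 * seq_along(resno), id, 0), resid = resid)
  doms <- list(mk(1, 1:3, c("ALA", "GLY", "SER")), mk(2, 4:6, c("LEU", "LYS", "TRP")))
  expect_silent(infer_layout(doms, "AGSLKW"))
  err <- expect_error(infer_layout(doms, "AGSLKY"), "mismatch")
  expect_match(conditionMessage(err), "6")
})

test_that("apply_pose is rigid, the identity pose is exact, and rotations involute", {
  d <- toy2()$domains[[1]]
  expect_identical(apply_pose(d, rigid_pose()), d$xyz)
  shifted <- apply_pose(d, rigid_pose(trans = c(1, 0, 0)))
  expect_equal(shifted - d$xyz, matrix(c(1, 0, 0), nrow(d$xyz), 3, byrow = TRUE))
  # rot (pi,0,0) twice returns the input
  once <- apply_pose(d, rigid_pose(rot = c(pi, 0, 0)))
  d2 <- d; d2$xyz <- once
  expect_equal(apply_pose(d2, rigid_pose(rot = c(pi, 0, 0))), d$xyz, tolerance = 1e-9)
  # rigidity: all pairwise intra-domain distances preserved
  p <- rigid_pose(c(0.4, -1.1, 2.2), c(5, -3, 8))
  moved <- apply_pose(d, p)
  expect_equal(as.matrix(dist(moved)), as.matrix(dist(d$xyz)), tolerance = 1e-9)
})

test_that("model PDB round-trip preserves indices, coordinates, domain ids and linkers", {
  toy <- toy2()
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(toy$native, tmp)
  back <- rigidom:::read_model_pdb(tmp)
  expect_identical(back$resno, toy$native$resno)
  expect_equal(back$xyz, toy$native$xyz, tolerance = 1e-3)
  expect_identical(back$dom, toy$native$dom)
  expect_true(!is.unsorted(back$resno, strictly = TRUE))

  # gap toy: rebuilt linker residues appear as GLY with the right indices
  spec <- toy_spec(2, 30, linker_gap = 2, seed = 8)
  toyg <- make_toy_multidomain(spec)
  m <- rebuild_linkers(toyg$native, toyg$layout)
  expect_equal(sum(m$resid == "GLY" & m$dom == 0), sum(toyg$layout$linker_gaps))
  write_model_pdb(m, tmp)
  back2 <- rigidom:::read_model_pdb(tmp)
  expect_equal(length(back2$resno), length(toyg$native$resno) + 2)
})
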