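# Shared seeded fixtures, built once per test run.
.fx <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, expr, envir = .fx)
  get(key, envir = .fx)
}

toy2 <- function() cached("toy2", make_toy_multidomain(toy_spec(2, 60, seed = 3)))
toy3 <- function() cached("toy3", make_toy_multidomain(toy_spec(3, 60, seed = 5)))
toyd <- function() cached("toyd", make_toy_multidomain(
  toy_spec(2, 60, topology = "discontinuous", seed = 4)))

toy2_restraints <- function() cached("toy2_rs", synth_restraints_from_native(
  toy2()$native, toy2()$layout, "exact", sd = 1, subsample = 0.25, seed = 7))

# decoy library around a toy: the native full chain + 9 compact decoys
toy_library <- function(toy, seed = 1) {
  c(list(native = toy$native$xyz),
    setNames(lapply(1:9, function(k)
      make_toy_domain(nrow(toy$native$xyz), "compact-walk",
                      seed = seed * 1000 + k)$xyz),
      paste0("decoy", 1:9)))
}

# flattened coordinates for a pose set
flat_at <- function(toy, poses) {
  coords <- lapply(seq_along(toy$domains), function(k)
    apply_pose(toy$domains[[k]], poses[[k]]))
  rigidom:::flatten_domains(toy$domains, coords)
}

# a scrambled flattened model (non-trivial geometry for oracle checks)
toy2_scrambled_flat <- function() cached("toy2_sc", {
  st <- scramble(identity_poses(2), 40, 12, seed = 9)
  flat_at(toy2(), st$poses)
})

# one 20-seed recovery suite shared by the confidence and acceptance tests
recovery_suite_2dom <- function() cached("rec2", {
  lapply(1:20, function(s) {
    toy <- make_toy_multidomain(toy_spec(2, 60, seed = s))
    rs <- synth_restraints_from_native(toy$native, toy$layout, "exact", sd = 1,
                                       subsample = 0.25, seed = s)
    prob <- assembly_problem(toy$domains, toy$layout, rs)
    starts <- lapply(1:20, function(k)
      scramble(identity_poses(2), 30, 10, seed = s * 100 + k))
    res <- assemble(prob, assembly_config(seed = s), initial_models = starts)
    rtm <- vapply(res$all_final, function(m)
      r_tm_score(m$xyz, toy$native$xyz, dom = toy$native$dom), numeric(1))
    list(toy = toy, restraints = rs, result = res, rtm_all = rtm,
         rtm_top1 = r_tm_score(res$models[[1]]$xyz, toy$native$xyz,
                               dom = toy$native$dom))
  })
})
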