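test_that("local evaluation scores self-templates perfectly and decoys low", {
  toy <- toy2()
  hit <- local_evaluate(toy$domains, list(id = "native", xyz = toy$native$xyz))
  expect_gte(hit$tm_h, 0.99)
  expect_equal(sort(hit$covered_domains), c(1L, 2L))
  # template shorter than the largest domain still yields a hit
  short <- local_evaluate(toy$domains, list(id = "short", xyz = toy$native$xyz[1:30, ]))
  expect_s3_class(short, "template_hit")
  expect_true(all(short$tm_scores < 1))
  # random compact decoys score below the fold threshold
  dec <- local_evaluate(toy$domains,
                        list(id = "dec", xyz = make_toy_domain(120, "compact-walk",
                                                               seed = 77)$xyz))
  expect_lt(dec$tm_h, 0.5)
})

test_that("global evaluation masks claimed template residues", {
  toy <- toy2()
  tpl <- list(id = "native", xyz = toy$native$xyz)
  g <- global_evaluate(toy$domains, tpl, "N2C", toy$layout)
  expect_gte(g$tm_h, 0.99)
  # claimed regions are disjoint and reproduce the native partition
  p1 <- g$per_domain[[1]]$pairs[, 2]
  p2 <- g$per_domain[[2]]$pairs[, 2]
  expect_length(intersect(p1, p2), 0)
  expect_true(all(p1 <= 60) && all(p2 > 60))

  # masking can only lower the score relative to local evaluation
  for (s in 1:4) {
    dec <- list(id = "t", xyz = make_toy_domain(120, "compact-walk",
                                                seed = 500 + s)$xyz)
    l <- local_evaluate(toy$domains, dec)
    gN <- global_evaluate(toy$domains, dec, "N2C", toy$layout)
    gC <- global_evaluate(toy$domains, dec, "C2N", toy$layout)
    expect_lte(max(gN$tm_h, gC$tm_h), l$tm_h + 1e-6)
  }

  # two identical domains vs a template holding one copy: the second
  # domain's masked score collapses below the first
  dup_dom <- toy$domains[[1]]
  dup2 <- domain_model(2L, dup_dom$resno + 60L, dup_dom$xyz + 40)
  doms <- list(dup_dom, dup2)
  one_copy <- list(id = "one", xyz = dup_dom$xyz)
  gd <- global_evaluate(doms, one_copy, "N2C")
  expect_lt(gd$tm_scores[2], gd$tm_scores[1])
  expect_gte(gd$tm_scores[1], 0.99)
})

test_that("rank_library recovers the planted native and breaks ties by id", {
  toy <- toy2()
  lib <- toy_library(toy, seed = 1)
  rk <- rank_library(toy$domains, lib, toy$layout)
  expect_equal(rk$global[[1]]$template_id, "native")
  expect_gte(rk$global[[1]]$tm_h, 0.99)
  # equal-scoring duplicated decoys order deterministically by id
  dup_lib <- list(b_tpl = lib$decoy1, a_tpl = lib$decoy1)
  rk2 <- rank_library(toy$domains, dup_lib, toy$layout)
  expect_equal(rk2$stage1[[1]]$template_id, "a_tpl")
  rk2b <- rank_library(toy$domains, dup_lib, toy$layout)
  expect_equal(vapply(rk2$global, `[[`, "", "template_id"),
               vapply(rk2b$global, `[[`, "", "template_id"))
})

test_that("a best hit that cannot cover all domains triggers the broken-template split", {
  toy <- toy2()
  # no template contains both domains: single-domain templates only
  lib <- list(partA = toy$domains[[1]]$xyz, partB = toy$domains[[2]]$xyz,
              junk = make_toy_domain(60, "compact-walk", seed = 9)$xyz)
  rk <- rank_library(toy$domains, lib, toy$layout)
  ids <- vapply(rk$global, `[[`, "", "template_id")
  covered <- lapply(rk$global, `[[`, "covered_domains")
  expect_true(any(vapply(seq_along(ids), function(k)
    ids[k] == "partA" && 1L %in% covered[[k]], logical(1))))
  expect_true(any(vapply(seq_along(ids), function(k)
    ids[k] == "partB" && 2L %in% covered[[k]], logical(1))))
})

test_that("local pair hits appear for three-domain targets", {
  toy <- toy3()
  lib <- list(native = toy$native$xyz,
              dec = make_toy_domain(180, "compact-walk", seed = 12)$xyz)
  rk <- rank_library(toy$domains, lib, toy$layout)
  expect_named(rk$local_pairs, c("1-2", "2-3"))
  expect_equal(rk$local_pairs[["1-2"]][[1]]$template_id, "native")
})

test_that("initial models place covered domains by their superpositions", {
  toy <- toy2()
  hit <- local_evaluate(toy$domains, list(id = "native", xyz = toy$native$xyz))
  ims <- build_initial_models(list(hit), toy$domains, toy$layout)
  expect_length(ims, 1)
  fc <- flat_at(toy, ims[[1]]$poses)
  expect_gte(r_tm_score(fc$xyz, toy$native$xyz, dom = toy$native$dom), 0.99)
  expect_equal(ims[[1]]$clash_count, 0)

  # coincident placement: the sliding step reduces hard clashes. Build a
  # hit whose second superposition drops domain 2 onto domain 1's centroid.
  c1 <- rigidom:::centroid(toy$domains[[1]]$xyz)
  c2 <- rigidom:::centroid(toy$domains[[2]]$xyz)
  co_hit <- hit
  co_hit$per_domain[[2]]$superposition <- list(rotation = diag(3),
                                               translation = c1 - c2)
  co_poses <- list(rigid_pose(),
                   rigidom:::pose_from_transform(diag(3), c1 - c2, c2))
  n_before <- rigidom:::hard_clash_count(toy$domains, co_poses)
  expect_gt(n_before, 0)
  ims2 <- build_initial_models(list(co_hit), toy$domains, toy$layout)
  expect_lt(ims2[[1]]$clash_count, n_before)
})

test_that("without hits, seeded random tandem starts are reproducible", {
  toy <- toy2()
  a <- build_initial_models(list(), toy$domains, toy$layout, seed = 4)
  b <- build_initial_models(list(), toy$domains, toy$layout, seed = 4)
  c2 <- build_initial_models(list(), toy$domains, toy$layout, seed = 5)
  expect_length(a, 20)
  expect_identical(lapply(a, `[[`, "poses"), lapply(b, `[[`, "poses"))
  expect_false(identical(lapply(a, `[[`, "poses"), lapply(c2, `[[`, "poses")))
  expect_true(all(vapply(a, function(m) m$source == "random", logical(1))))
})
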