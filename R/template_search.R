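#' Template identification and initial model construction
#'
#' Global analogous templates are found from a structure library by
#' domain-level structural alignment: a local evaluation (overlaps between
#' domain alignments allowed) ranks the library by the harmonic per-domain
#' TM-score, the top candidates are re-scored by a global evaluation in
#' which template residues claimed by earlier domains are masked (N-to-C
#' and C-to-N, keeping the better direction), and the top hits seed the
#' initial full-length models.
#'
#' @name template_search
NULL

as_template <- function(template, id = "tpl") {
  if (is.list(template) && !is.null(template$xyz)) {
    list(id = template$id %||% id, xyz = as.matrix(template$xyz))
  } else {
    list(id = id, xyz = as.matrix(template))
  }
}

# Template-derived inter-domain distance pairs for the energy profile;
# only domain pairs the template actually covers (TM-score >= 0.5)
# contribute, and alignments are subsampled on a deterministic stride
# (<= 25 residues per domain side) to bound the pair count.
hit_template_pairs <- function(domains, tpl_xyz, per_domain) {
  out <- list()
  nd <- length(domains)
  scores <- vapply(per_domain, function(p) p$tm %||% 0, numeric(1))
  for (a in seq_len(nd - 1)) {
    for (b in (a + 1):nd) {
      if (scores[a] < 0.5 || scores[b] < 0.5) next
      pa <- per_domain[[a]]$pairs; pb <- per_domain[[b]]$pairs
      if (is.null(pa) || is.null(pb) || nrow(pa) < 4 || nrow(pb) < 4) next
      ia <- round(seq(1, nrow(pa), length.out = min(nrow(pa), 25)))
      ib <- round(seq(1, nrow(pb), length.out = min(nrow(pb), 25)))
      qa <- domains[[a]]$resno[pa[ia, 1]]; ta <- pa[ia, 2]
      qb <- domains[[b]]$resno[pb[ib, 1]]; tb <- pb[ib, 2]
      grid <- expand.grid(ka = seq_along(ia), kb = seq_along(ib))
      d <- sqrt(rowSums((tpl_xyz[ta[grid$ka], , drop = FALSE] -
                           tpl_xyz[tb[grid$kb], , drop = FALSE])^2))
      out[[length(out) + 1]] <- data.frame(i = qa[grid$ka], j = qb[grid$kb], d = d)
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  }
  do.call(rbind, out)
}

make_hit <- function(domains, tpl, per_domain, mode, direction = NA_character_) {
  scores <- vapply(per_domain, function(p) p$tm, numeric(1))
  tm_h <- harmonic_tm_score(pmax(scores, 1e-3))
  ids <- vapply(domains, function(d) d$domain_id, integer(1))
  structure(list(template_id = tpl$id, per_domain = per_domain,
                 tm_scores = scores, tm_h = tm_h, mode = mode,
                 direction = direction,
                 covered_domains = ids[scores >= 0.5],
                 tpl_pairs = hit_template_pairs(domains, tpl$xyz, per_domain)),
            class = "template_hit")
}

#' Local template evaluation
#'
#' Aligns every domain independently onto the template (overlapping
#' template regions between domains are allowed) and scores the template
#' by the harmonic mean of the per-domain TM-scores.
#'
#' @param domains list of \code{domain_model}s.
#' @param template template coordinates (matrix, or list with \code{id} and
#'   \code{xyz}).
#' @return a \code{template_hit}.
#' @export
local_evaluate <- function(domains, template) {
  tpl <- as_template(template)
  stopifnot(nrow(tpl$xyz) >= 10)
  per <- lapply(domains, function(d) structural_align(d, tpl$xyz))
  make_hit(domains, tpl, per, mode = "local-eval")
}

#' Global template evaluation
#'
#' Aligns the domains in sequence order (or reverse); template residues
#' claimed by an earlier domain are masked before aligning the next, so
#' the per-domain alignments are disjoint on the template. Masking can
#' only lower scores relative to the local evaluation.
#'
#' @inheritParams local_evaluate
#' @param direction \code{"N2C"} or \code{"C2N"}.
#' @param layout optional \code{chain_layout} fixing the domain order.
#' @return a \code{template_hit}.
#' @export
global_evaluate <- function(domains, template, direction = c("N2C", "C2N"),
                            layout = NULL) {
  direction <- match.arg(direction)
  tpl <- as_template(template)
  stopifnot(nrow(tpl$xyz) >= 10)
  layout <- layout %||% infer_layout(domains)
  ids <- vapply(domains, function(d) d$domain_id, integer(1))
  ord <- match(layout$domain_order, ids)
  if (direction == "C2N") ord <- rev(ord)
  mask <- rep(FALSE, nrow(tpl$xyz))
  per <- vector("list", length(domains))
  for (k in ord) {
    al <- structural_align(domains[[k]], tpl$xyz, mask = mask)
    per[[k]] <- al
    if (nrow(al$pairs) > 0) mask[al$pairs[, 2]] <- TRUE
  }
  make_hit(domains, tpl, per, mode = "global-eval", direction = direction)
}

order_hits <- function(hits) {
  tmh <- vapply(hits, function(h) h$tm_h, numeric(1))
  ids <- vapply(hits, function(h) as.character(h$template_id), character(1))
  hits[order(-tmh, ids)]
}

#' Rank a template library
#'
#' Stage 1 scores every template by local evaluation and keeps the top
#' \code{stage1_keep}; stage 2 re-scores those globally (both chain
#' directions, better kept). If the best global hit leaves a domain with
#' TM-score < 0.5, the domain sequence is split into its covered and
#' uncovered runs and each run is ranked independently (recursion capped at
#' the domain count); the resulting partial hits are merged into the
#' output. Local hits for every consecutive domain pair are produced when
#' the target has at least 3 domains. Ties break lexicographically on
#' template id.
#'
#' @param domains list of \code{domain_model}s.
#' @param library list of templates (each a matrix or a list with
#'   \code{id}, \code{xyz}).
#' @param layout optional \code{chain_layout}.
#' @param top_n hits kept per category (default 10).
#' @param stage1_keep templates passed to the global stage (default 500).
#' @param .depth recursion depth (internal).
#' @return list with \code{global} (top hits, partial-coverage hits from a
#'   split appended), \code{local_pairs} (per consecutive pair, when
#'   N_dom >= 3) and \code{stage1} (local ranking).
#' @export
rank_library <- function(domains, library, layout = NULL, top_n = 10,
                         stage1_keep = 500, .depth = 0) {
  stopifnot(length(library) >= 1)
  layout <- layout %||% infer_layout(domains)
  tpls <- lapply(seq_along(library), function(k) {
    as_template(library[[k]], id = names(library)[k] %||% paste0("tpl", k))
  })
  loc <- order_hits(lapply(tpls, function(t) local_evaluate(domains, t)))
  keep_ids <- vapply(head(loc, stage1_keep), function(h) h$template_id, character(1))
  stage2 <- lapply(tpls[match(keep_ids, vapply(tpls, `[[`, "", "id"))], function(t) {
    h1 <- global_evaluate(domains, t, "N2C", layout)
    h2 <- global_evaluate(domains, t, "C2N", layout)
    if (h2$tm_h > h1$tm_h) h2 else h1
  })
  glob <- order_hits(stage2)
  out_global <- head(glob, top_n)
  # broken-template split
  if (length(domains) > 1 && .depth < length(domains) && length(glob) > 0) {
    best <- glob[[1]]
    ids <- vapply(domains, function(d) d$domain_id, integer(1))
    ord <- match(layout$domain_order, ids)
    covered <- best$tm_scores[ord] >= 0.5
    if (any(!covered) && any(covered)) {
      runs <- rle(covered)
      pos <- cumsum(c(1, head(runs$lengths, -1)))
      partial <- list()
      for (r in seq_along(runs$lengths)) {
        sub_idx <- ord[pos[r]:(pos[r] + runs$lengths[r] - 1)]
        sub <- domains[sub_idx]
        rr <- rank_library(sub, library, top_n = max(2, top_n %/% 2),
                           stage1_keep = stage1_keep, .depth = .depth + 1)
        partial <- c(partial, head(rr$global, 2))
      }
      out_global <- c(out_global, partial)
    }
  }
  # local hits per consecutive domain pair, recombined from stage-1 alignments
  local_pairs <- NULL
  if (length(domains) >= 3 && .depth == 0) {
    ids <- vapply(domains, function(d) d$domain_id, integer(1))
    ord <- match(layout$domain_order, ids)
    local_pairs <- list()
    loc_by_id <- setNames(loc, vapply(loc, function(h) h$template_id, character(1)))
    for (k in seq_len(length(ord) - 1)) {
      pair_idx <- ord[c(k, k + 1)]
      ph <- lapply(tpls, function(t) {
        full <- loc_by_id[[t$id]]
        make_hit(domains[pair_idx], t, full$per_domain[pair_idx], mode = "local-eval")
      })
      local_pairs[[paste(ids[pair_idx], collapse = "-")]] <- head(order_hits(ph), top_n)
    }
  }
  list(global = out_global, local_pairs = local_pairs, stage1 = head(loc, top_n))
}

# Chain-like tandem poses: domains laid out along +x with centroid spacing
# sum of radii of gyration + 5 A.
tandem_poses <- function(domains, layout) {
  ids <- vapply(domains, function(d) d$domain_id, integer(1))
  ord <- match(layout$domain_order, ids)
  rg <- vapply(domains, function(d) radius_of_gyration(d$xyz), numeric(1))
  poses <- vector("list", length(domains))
  x <- 0
  prev_rg <- NULL
  for (k in seq_along(ord)) {
    d <- ord[k]
    if (!is.null(prev_rg)) x <- x + prev_rg + rg[d] + 5
    target <- c(x, 0, 0)
    poses[[d]] <- rigid_pose(trans = target - centroid(domains[[d]]$xyz))
    prev_rg <- rg[d]
  }
  poses
}

# Compose an extra rotation (about the current centroid) + translation
# onto an existing pose.
compose_pose <- function(pose, Rp, dt) {
  p <- as.numeric(pose)
  Rnew <- Rp %*% euler_to_matrix(p[1:3])
  rigid_pose(matrix_to_euler(Rnew), p[4:6] + dt)
}

hard_clash_count <- function(domains, poses, cutoff = 3.0) {
  coords <- lapply(seq_along(domains), function(k) apply_pose(domains[[k]], poses[[k]]))
  n <- 0
  for (a in seq_len(length(domains) - 1)) {
    for (b in (a + 1):length(domains)) {
      D2 <- outer(rowSums(coords[[a]]^2), rowSums(coords[[b]]^2), "+") -
        2 * coords[[a]] %*% t(coords[[b]])
      n <- n + sum(D2 < cutoff^2)
    }
  }
  n
}

#' Build initial full-length models from template hits
#'
#' Each hit places its covered domains by the per-domain alignment
#' superposition; uncovered domains are appended next to their nearest
#' placed sequence neighbor along the neighbor's centroid-to-terminus
#' direction. A sliding step then relieves hard clashes: while any
#' inter-domain CA pair is closer than 3 Angstrom, the later domain is
#' translated in 1 Angstrom steps (at most 30) along the inter-centroid
#' vector. Without hits, seeded random perturbations of a chain-like
#' tandem layout are used.
#'
#' @param hits list of \code{template_hit}s (global + local), may be empty.
#' @param domains list of \code{domain_model}s.
#' @param layout a \code{chain_layout}.
#' @param n_max maximum number of models (default 20).
#' @param seed RNG seed for the random fallback.
#' @return list of initial models: \code{poses}, \code{source},
#'   \code{clash_count}.
#' @export
build_initial_models <- function(hits, domains, layout, n_max = 20, seed = 42) {
  ids <- vapply(domains, function(d) d$domain_id, integer(1))
  ord <- match(layout$domain_order, ids)
  models <- list()
  for (h in hits) {
    if (length(models) >= n_max) break
    poses <- vector("list", length(domains))
    placed <- logical(length(domains))
    for (k in seq_along(domains)) {
      al <- if (k <= length(h$per_domain)) h$per_domain[[k]] else NULL
      if (!is.null(al) && !is.null(al$superposition) && nrow(al$pairs) >= 4 &&
          al$tm >= 0.3) {
        poses[[k]] <- pose_from_transform(al$superposition$rotation,
                                          al$superposition$translation,
                                          centroid(domains[[k]]$xyz))
        placed[k] <- TRUE
      }
    }
    if (!any(placed)) next
    # append uncovered domains next to their nearest placed sequence neighbor
    for (pos in seq_along(ord)) {
      k <- ord[pos]
      if (placed[k]) next
      placed_pos <- which(placed[ord])
      if (length(placed_pos) == 0) break
      nb_pos <- placed_pos[which.min(abs(placed_pos - pos))]
      nb <- ord[nb_pos]
      nb_xyz <- apply_pose(domains[[nb]], poses[[nb]])
      nb_cen <- centroid(nb_xyz)
      term <- if (pos > nb_pos) nb_xyz[nrow(nb_xyz), ] else nb_xyz[1, ]
      dir <- term - nb_cen
      nd <- sqrt(sum(dir^2))
      dir <- if (nd > 1e-6) dir / nd else c(1, 0, 0)
      target <- term + dir * (radius_of_gyration(domains[[k]]$xyz) + 3.8)
      poses[[k]] <- rigid_pose(trans = target - centroid(domains[[k]]$xyz))
      placed[k] <- TRUE
    }
    poses <- slide_apart(domains, poses, ord)
    models[[length(models) + 1]] <- list(
      poses = poses, source = h$template_id,
      clash_count = hard_clash_count(domains, poses))
  }
  if (length(models) == 0) {
    base <- tandem_poses(domains, layout)
    models <- with_seed(seed, lapply(seq_len(n_max), function(m) {
      poses <- lapply(base, function(p) {
        compose_pose(p, axis_angle_matrix(rnorm(3), runif(1, 0, 30 * pi / 180)),
                     runif(3, -1, 1) / sqrt(3) * runif(1, 0, 10))
      })
      poses <- slide_apart(domains, poses, ord)
      list(poses = poses, source = "random",
           clash_count = hard_clash_count(domains, poses))
    }))
  }
  head(models, n_max)
}

# sliding clash relief: translate the later domain of the worst hard-clash
# pair 1 A along the inter-centroid vector, <= 30 steps
slide_apart <- function(domains, poses, ord) {
  for (step in 1:30) {
    coords <- lapply(seq_along(domains), function(k)
      apply_pose(domains[[k]], poses[[k]]))
    worst <- NULL; worst_n <- 0
    for (pa in seq_len(length(ord) - 1)) {
      for (pb in (pa + 1):length(ord)) {
        a <- ord[pa]; b <- ord[pb]
        D2 <- outer(rowSums(coords[[a]]^2), rowSums(coords[[b]]^2), "+") -
          2 * coords[[a]] %*% t(coords[[b]])
        nclash <- sum(D2 < 9)
        if (nclash > worst_n) { worst_n <- nclash; worst <- c(a, b) }
      }
    }
    if (worst_n == 0) break
    a <- worst[1]; b <- worst[2]
    dir <- centroid(coords[[b]]) - centroid(coords[[a]])
    nd <- sqrt(sum(dir^2))
    dir <- if (nd > 1e-6) dir / nd else c(1, 0, 0)
    p <- as.numeric(poses[[b]])
    poses[[b]] <- rigid_pose(p[1:3], p[4:6] + dir)
  }
  poses
}

#' Read a template library from a directory
#'
#' The library is a directory of single-chain PDB files plus a plain-text
#' index: one \code{id path} pair per line (paths relative to the index).
#'
#' @param index_path index file path.
#' @return named list of templates (\code{id}, \code{xyz}).
#' @export
read_template_library <- function(index_path) {
  if (!file.exists(index_path)) stop("no such index: ", index_path)
  idx <- read.table(index_path, header = FALSE, col.names = c("id", "path"),
                    stringsAsFactors = FALSE)
  base <- dirname(index_path)
  lib <- lapply(seq_len(nrow(idx)), function(k) {
    dm <- read_domain_pdb(file.path(base, idx$path[k]), domain_id = 1L)
    list(id = idx$id[k], xyz = dm$xyz)
  })
  names(lib) <- idx$id
  lib
}
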