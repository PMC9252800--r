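#' Synthetic multi-domain fixtures
#'
#' Seed-deterministic toy structures with known native poses: single
#' domains as ideal helix bundles or compact self-avoiding walks, and
#' multi-domain natives (continuous or discontinuous topology) built so
#' that every penalty term of the assembly energy is zero at the native
#' pose -- packed interfaces, no steric clashes, satisfied boundary
#' connectivity.
#'
#' @name fixtures
NULL

#' Toy specification
#'
#' @param n_domains number of domains (>= 2 for multi-domain toys).
#' @param residues residues per domain (each >= 20); recycled.
#' @param topology \code{"continuous"} or \code{"discontinuous"} (domain 2
#'   inserted between the segments of domain 1).
#' @param fold \code{"helix-bundle"} or \code{"compact-walk"}.
#' @param linker_gap missing residues between consecutive domains
#'   (continuous topology; default 0).
#' @param seed RNG seed.
#' @export
toy_spec <- function(n_domains = 2, residues = 60, topology = c("continuous", "discontinuous"),
                     fold = c("helix-bundle", "compact-walk"), linker_gap = 0, seed = 1) {
  topology <- match.arg(topology)
  fold <- match.arg(fold)
  residues <- rep_len(residues, n_domains)
  stopifnot(n_domains >= 1, all(residues >= 20), linker_gap >= 0)
  if (topology == "discontinuous" && n_domains != 2) {
    stop("discontinuous toys use 2 domains (host + insert)")
  }
  structure(list(n_domains = n_domains, residues = residues, topology = topology,
                 fold = fold, linker_gap = linker_gap, seed = seed),
            class = "toy_spec")
}

helix_bundle_coords <- function(n) {
  n_helices <- if (n < 75) 2L else 3L
  turn_len <- 3L
  n_helix_total <- n - (n_helices - 1L) * turn_len
  lens <- diff(round(seq(0, n_helix_total, length.out = n_helices + 1)))
  spacing <- 10.5
  phases <- runif(n_helices, 0, 2 * pi)
  rise <- 1.5; radius <- 2.3; twist <- 100 * pi / 180
  xyz <- NULL
  z_end <- 0
  for (h in seq_len(n_helices)) {
    m <- lens[h]
    up <- (h %% 2) == 1
    i <- seq_len(m) - 1
    z0 <- if (h == 1) 0 else z_end
    z <- if (up) z0 + i * rise else z0 - i * rise
    phi <- phases[h] + i * twist
    hx <- cbind((h - 1) * spacing + radius * cos(phi), radius * sin(phi), z)
    if (h == 1) {
      xyz <- hx
    } else {
      turn <- arc_points(xyz[nrow(xyz), ], hx[1, ], turn_len, step = 3.8)
      xyz <- rbind(xyz, turn, hx)
    }
    z_end <- z[m]
  }
  xyz
}

compact_walk_coords <- function(n) {
  xyz <- matrix(0, n, 3)
  dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
  for (i in 2:n) {
    ok <- FALSE
    cen <- colMeans(xyz[seq_len(i - 1), , drop = FALSE])
    for (try in 1:100) {
      bias <- cen - xyz[i - 1, ]
      nb <- sqrt(sum(bias^2))
      bias <- if (nb > 1e-6) bias / nb else c(0, 0, 0)
      cand <- 0.4 * dirv + 0.35 * bias + rnorm(3, 0, 0.8)
      cand <- cand / sqrt(sum(cand^2))
      newp <- xyz[i - 1, ] + 3.8 * cand
      if (i > 2) {
        dmin <- min(sqrt(rowSums(sweep(xyz[seq_len(i - 2), , drop = FALSE], 2,
                                       newp)^2)))
        if (dmin < 3.5) next
      }
      xyz[i, ] <- newp
      dirv <- cand
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  if (radius_of_gyration(xyz) > 0.8 * 3.8 * n^0.6) return(NULL)
  xyz
}

check_domain_geometry <- function(xyz) {
  dca <- sqrt(rowSums(diff(xyz)^2))
  if (any(dca < 3.6 | dca > 4.0)) return(FALSE)
  D <- as.matrix(dist(xyz))
  D[abs(row(D) - col(D)) <= 1] <- Inf
  min(D) >= 3.5
}

#' Generate a toy domain
#'
#' Helix-bundle: ideal alpha-helical CA traces (1.5 Angstrom rise,
#' 2.3 Angstrom radius, 100 degrees per residue) in 2-3 packed antiparallel
#' helices joined by 3-residue turns. Compact-walk: a self-avoiding
#' 3.8 Angstrom-step walk biased toward its running centroid, accepted when
#' the radius of gyration is at most 0.8 (3.8 n^0.6). Both guarantee
#' consecutive CA distances in [3.6, 4.0] and non-consecutive CA pairs at
#' least 3.5 Angstrom apart.
#'
#' @param n residues (>= 20).
#' @param fold \code{"helix-bundle"} or \code{"compact-walk"}.
#' @param seed RNG seed (same seed, same coordinates).
#' @param domain_id id for the returned model.
#' @return a \code{domain_model} numbered 1..n.
#' @export
make_toy_domain <- function(n, fold = c("helix-bundle", "compact-walk"),
                            seed = 1, domain_id = 1L) {
  fold <- match.arg(fold)
  stopifnot(n >= 20)
  xyz <- with_seed(seed, {
    out <- NULL
    for (attempt in 1:1000) {
      cand <- if (fold == "helix-bundle") helix_bundle_coords(n) else compact_walk_coords(n)
      if (!is.null(cand) && nrow(cand) == n && check_domain_geometry(cand)) {
        out <- cand
        break
      }
    }
    out
  })
  if (is.null(xyz)) stop("toy domain generation failed after 1000 attempts")
  domain_model(domain_id, seq_len(n), xyz)
}

pair_stats <- function(A, B) {
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  D2[D2 < 0] <- 0
  list(min = sqrt(min(D2)), n8 = sum(D2 <= 64))
}

#' Generate a toy multi-domain native
#'
#' Domains are placed with seeded random relative poses such that each
#' consecutive pair packs a real interface (>= 10 CA pairs within
#' 8 Angstrom), no inter-domain CA pair is closer than 3.8 Angstrom, and
#' the chain stays connected (flanking CA within 3.8 (g+1) of each
#' boundary). In discontinuous mode the second domain is inserted between
#' the two segments of the first.
#'
#' @param spec a \code{toy_spec}.
#' @return list with \code{native} (flattened coordinates), \code{domains}
#'   (list of \code{domain_model}s whose input coordinates ARE the native
#'   placement, so the identity pose reproduces the native) and
#'   \code{layout}.
#' @export
make_toy_multidomain <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  if (spec$topology == "discontinuous") return(make_toy_discontinuous(spec))
  g <- spec$linker_gap
  units <- lapply(seq_len(spec$n_domains), function(k)
    make_toy_domain(spec$residues[k], spec$fold, seed = spec$seed * 1000 + k,
                    domain_id = k))
  # renumber into the full-chain frame
  start <- 1L
  for (k in seq_len(spec$n_domains)) {
    nk <- spec$residues[k]
    units[[k]] <- domain_model(k, seq.int(start, start + nk - 1L), units[[k]]$xyz)
    start <- start + nk + g
  }
  placed <- with_seed(spec$seed, {
    out <- list(units[[1]]$xyz)
    ok_all <- TRUE
    for (k in 2:spec$n_domains) {
      prev <- do.call(rbind, out)
      prev_last <- out[[k - 1]][nrow(out[[k - 1]]), ]
      Xk <- units[[k]]$xyz
      done <- FALSE
      for (attempt in 1:1000) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        # keep the new domain on the far side of the previous terminus
        cen_prev <- colMeans(prev)
        outward <- prev_last - cen_prev
        if (sum(u * outward) < 0) u <- -u
        anchor <- prev_last + u * (3.8 * (g + 1) * if (g == 0) 1 else 0.85)
        R <- random_rotation()
        Xr <- sweep(sweep(Xk, 2, colMeans(Xk)) %*% t(R), 2, colMeans(Xk), "+")
        Xr <- sweep(Xr, 2, anchor - Xr[1, ], "+")
        ps_all <- pair_stats(prev, Xr)
        ps_pair <- pair_stats(out[[k - 1]], Xr)
        if (ps_all$min >= 3.8 - 1e-9 && ps_pair$n8 >= 10) {
          out[[k]] <- Xr
          done <- TRUE
          break
        }
      }
      if (!done) { ok_all <- FALSE; break }
    }
    if (ok_all) out else NULL
  })
  if (is.null(placed)) stop("multi-domain placement failed after 1000 attempts")
  domains <- lapply(seq_len(spec$n_domains), function(k)
    domain_model(k, units[[k]]$resno, placed[[k]]))
  layout <- infer_layout(domains)
  list(native = flatten_domains(domains), domains = domains, layout = layout)
}

make_toy_discontinuous <- function(spec) {
  n1 <- spec$residues[1]; n2 <- spec$residues[2]
  g <- 2L  # linker gap at both insertion crossings
  host <- make_toy_domain(n1, spec$fold, seed = spec$seed * 1000 + 1, domain_id = 1L)
  insert <- make_toy_domain(n2, spec$fold, seed = spec$seed * 1000 + 2, domain_id = 2L)
  a <- ceiling(n1 / 2)
  host_resno <- c(seq_len(a), seq.int(a + g + n2 + g + 1L, a + g + n2 + g + (n1 - a)))
  ins_resno <- seq.int(a + g + 1L, a + g + n2)
  placed <- with_seed(spec$seed, {
    Xh <- host$xyz
    p1 <- Xh[a, ]; p2 <- Xh[a + 1, ]
    m <- (p1 + p2) / 2
    u <- m - colMeans(Xh)
    u <- u / sqrt(sum(u^2))
    lim <- 3.8 * (g + 1)
    res <- NULL
    for (attempt in 1:1000) {
      dist_out <- runif(1, 5, 11)
      R <- random_rotation()
      Xi <- sweep(sweep(insert$xyz, 2, colMeans(insert$xyz)) %*% t(R), 2,
                  colMeans(insert$xyz), "+")
      term_mid <- (Xi[1, ] + Xi[nrow(Xi), ]) / 2
      Xi <- sweep(Xi, 2, (m + u * dist_out) - term_mid, "+")
      d1 <- sqrt(sum((Xi[1, ] - p1)^2))
      d2 <- sqrt(sum((Xi[nrow(Xi), ] - p2)^2))
      if (d1 > lim || d2 > lim) next
      ps <- pair_stats(Xh, Xi)
      if (ps$min >= 3.8 - 1e-9 && ps$n8 >= 10) { res <- Xi; break }
    }
    res
  })
  if (is.null(placed)) stop("discontinuous placement failed after 1000 attempts")
  domains <- list(domain_model(1L, host_resno, host$xyz),
                  domain_model(2L, ins_resno, placed))
  layout <- infer_layout(domains)
  list(native = flatten_domains(domains), domains = domains, layout = layout)
}

#' Scramble domain poses
#'
#' Rotates every domain by a uniform random angle up to \code{max_rot}
#' about a random axis (about the domain's current centroid) and
#' translates it by up to \code{max_trans}; seed-deterministic. Used to
#' generate non-trivial starting configurations for recovery experiments.
#'
#' @param poses list of \code{rigid_pose}s (e.g. identity poses at the
#'   native placement).
#' @param max_rot maximum rotation in degrees.
#' @param max_trans maximum translation in Angstrom.
#' @param seed RNG seed.
#' @return an initial model: list with perturbed \code{poses} and
#'   \code{source = "scramble"}.
#' @export
scramble <- function(poses, max_rot, max_trans, seed = 1) {
  stopifnot(max_rot >= 0, max_trans >= 0)
  new_poses <- with_seed(seed, lapply(poses, function(p) {
    ax <- rnorm(3)
    ang <- runif(1, 0, max_rot * pi / 180)
    dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    compose_pose(p, axis_angle_matrix(ax, ang), dirv * runif(1, 0, max_trans))
  }))
  list(poses = new_poses, source = "scramble")
}

#' Identity poses for n domains
#'
#' @param ndom number of domains.
#' @return list of identity \code{rigid_pose}s (which reproduce each
#'   domain's input coordinates exactly).
#' @export
identity_poses <- function(ndom) lapply(seq_len(ndom), function(k) rigid_pose())
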