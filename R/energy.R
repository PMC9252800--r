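#' Hybrid assembly energy
#'
#' The energy over domain pose parameters combines predicted-restraint
#' terms (distances/distograms, interface contacts, orientations),
#' template-derived inter-domain distance profiles, inter-domain steric
#' clash, a generic saturating interface reward, a domain-boundary
#' connectivity restraint, and optionally the cryo-EM density correlation.
#' Pairwise terms are evaluated by compiled kernels; gradients are central
#' finite differences (step 1e-4) so any term can be swapped without
#' re-deriving analytics.
#'
#' @name energy
NULL

#' Energy term weights
#'
#' The relative weights of the hybrid energy terms. The published method
#' does not report its weights, so these defaults are this package's own
#' calibration: restraint distances dominate, clash and connectivity are
#' strongly enforced, the generic interface reward is a weak tie-breaker.
#'
#' @param w_dist,w_contact,w_orient,w_template,w_clash,w_generic,w_conn,w_density
#'   non-negative weights.
#' @return named numeric vector of class \code{energy_weights}.
#' @export
energy_weights <- function(w_dist = 1.0, w_contact = 0.5, w_orient = 0.5,
                           w_template = 0.5, w_clash = 2.0, w_generic = 0.1,
                           w_conn = 2.0, w_density = 1.0) {
  w <- c(w_dist = w_dist, w_contact = w_contact, w_orient = w_orient,
         w_template = w_template, w_clash = w_clash, w_generic = w_generic,
         w_conn = w_conn, w_density = w_density)
  if (any(w < 0)) stop("energy weights must be non-negative")
  structure(w, class = "energy_weights")
}

empty_pdata <- function() {
  list(gi = integer(0), gj = integer(0), gmean = numeric(0), gsd = numeric(0),
       gw = numeric(0), dgi = integer(0), dgj = integer(0),
       dg_centers = numeric(0), dg_y = matrix(0, 0, 0), dg_m = matrix(0, 0, 0),
       ci = integer(0), cj = integer(0), cprob = numeric(0),
       pi = integer(0), pj = integer(0), gen_block = integer(0),
       gen_cap = numeric(0), bi = integer(0), bj = integer(0),
       bspan = numeric(0), ti = integer(0), tj = integer(0),
       t_hit = integer(0), t_d = numeric(0), hit_w = numeric(0))
}

# row lookup: full-chain residue index -> 0-based row in the flat matrix
row0_of <- function(resno_query, resno_flat, what = "restraint") {
  r <- match(resno_query, resno_flat)
  if (anyNA(r)) {
    stop(what, " references residue(s) absent from the model: ",
         paste(head(resno_query[is.na(r)], 5), collapse = ", "))
  }
  as.integer(r - 1L)
}

# Precompute distogram energy profiles: -log(p + 1e-4) - baseline, natural
# cubic spline over bin centers (flat beyond the range).
distogram_profiles <- function(dg) {
  centers <- (dg$bin_edges[-1] + dg$bin_edges[-length(dg$bin_edges)]) / 2
  y <- -log(dg$probs + 1e-4)
  y <- y - apply(y, 1, min)
  m <- t(apply(y, 1, function(row) natural_spline_m(centers, row)))
  list(centers = centers, y = y, m = m)
}

# Assemble the compiled-kernel data block for a problem.
build_pdata <- function(flat, layout, restraints = NULL, hits = NULL,
                        contact_threshold = 0.5) {
  pd <- empty_pdata()
  resno <- flat$resno
  dom <- flat$dom
  if (!is.null(restraints)) {
    g <- restraints$gaussians
    if (nrow(g) > 0) {
      pd$gi <- row0_of(g$i, resno); pd$gj <- row0_of(g$j, resno)
      pd$gmean <- g$mean; pd$gsd <- g$sd; pd$gw <- g$weight
    }
    dg <- restraints$distograms
    if (!is.null(dg) && nrow(dg$records) > 0) {
      pd$dgi <- row0_of(dg$records$i, resno)
      pd$dgj <- row0_of(dg$records$j, resno)
      pr <- distogram_profiles(dg)
      pd$dg_centers <- pr$centers; pd$dg_y <- pr$y; pd$dg_m <- pr$m
    }
    ct <- restraints$contacts
    if (nrow(ct) > 0) {
      keep <- ct$prob >= contact_threshold
      if (any(keep)) {
        pd$ci <- row0_of(ct$i[keep], resno); pd$cj <- row0_of(ct$j[keep], resno)
        pd$cprob <- ct$prob[keep]
      }
    }
  }
  # all inter-domain residue pairs (clash); consecutive-domain blocks (generic)
  ids <- layout$domain_order
  n <- length(resno)
  ut <- which(upper.tri(matrix(0, n, n)) & outer(dom, dom, "!="), arr.ind = TRUE)
  pd$pi <- as.integer(ut[, 1] - 1L); pd$pj <- as.integer(ut[, 2] - 1L)
  blk <- rep(-1L, nrow(ut))
  caps <- numeric(0)
  if (length(ids) > 1) {
    lens <- table(dom)
    for (k in seq_len(length(ids) - 1)) {
      d1 <- ids[k]; d2 <- ids[k + 1]
      hit <- (dom[ut[, 1]] == d1 & dom[ut[, 2]] == d2) |
             (dom[ut[, 1]] == d2 & dom[ut[, 2]] == d1)
      blk[hit] <- k - 1L
      caps <- c(caps, ceiling(3 * sqrt(min(lens[[as.character(d1)]],
                                           lens[[as.character(d2)]]))))
    }
  }
  pd$gen_block <- blk
  pd$gen_cap <- caps
  b <- layout$boundaries
  if (nrow(b) > 0) {
    pd$bi <- row0_of(b$left_res, resno, "boundary")
    pd$bj <- row0_of(b$right_res, resno, "boundary")
    pd$bspan <- 3.8 * (b$gap + 1)
  }
  if (!is.null(hits) && length(hits) > 0) {
    ti <- tj <- th <- integer(0); td <- hw <- numeric(0)
    h_id <- 0L
    for (h in hits) {
      tp <- h$tpl_pairs
      if (is.null(tp) || nrow(tp) == 0) next
      ok <- tp$i %in% resno & tp$j %in% resno
      tp <- tp[ok, , drop = FALSE]
      if (nrow(tp) == 0) next
      ti <- c(ti, row0_of(tp$i, resno, "template pair"))
      tj <- c(tj, row0_of(tp$j, resno, "template pair"))
      td <- c(td, tp$d)
      th <- c(th, rep(h_id, nrow(tp)))
      hw <- c(hw, h$tm_h)
      h_id <- h_id + 1L
    }
    pd$ti <- ti; pd$tj <- tj; pd$t_hit <- th; pd$t_d <- td; pd$hit_w <- hw
  }
  pd
}

#' Build an assembly problem
#'
#' Bundles domains, layout, restraints, template hits and an optional
#' density map into the precomputed form the energy/optimizer kernels
#' consume. Coordinates are stored domain-major; poses act about each
#' domain's input centroid.
#'
#' @param domains list of \code{domain_model}s.
#' @param layout a \code{chain_layout}; inferred from \code{domains} when
#'   \code{NULL}.
#' @param restraints optional \code{restraint_set}.
#' @param hits optional list of template hits (see \code{\link{rank_library}});
#'   the top 10 are used for the template distance profile.
#' @param map optional \code{density_grid}.
#' @param resolution map resolution in Angstrom (used when \code{map} given).
#' @param contact_threshold contact restraints below this probability carry
#'   no energy (default 0.5).
#' @return object of class \code{assembly_problem}.
#' @export
assembly_problem <- function(domains, layout = NULL, restraints = NULL,
                             hits = NULL, map = NULL, resolution = 8,
                             contact_threshold = 0.5) {
  stopifnot(length(domains) >= 1)
  layout <- layout %||% infer_layout(domains)
  X0 <- do.call(rbind, lapply(domains, function(d) d$xyz))
  dom_idx0 <- unlist(lapply(seq_along(domains), function(k)
    rep(k - 1L, nrow(domains[[k]]$xyz))))
  dom <- unlist(lapply(domains, function(d) rep(d$domain_id, length(d$resno))))
  resno <- unlist(lapply(domains, function(d) d$resno))
  resid <- unlist(lapply(domains, function(d) d$resid))
  centroids <- do.call(rbind, lapply(domains, function(d) centroid(d$xyz)))
  flat <- list(resno = resno, resid = resid, dom = dom, xyz = X0)
  hits_used <- if (!is.null(hits)) head(hits, 10) else NULL
  pd <- build_pdata(flat, layout, restraints, hits_used, contact_threshold)
  structure(list(domains = domains, layout = layout, restraints = restraints,
                 hits = hits_used, map = map, resolution = resolution,
                 X0 = X0, dom_idx0 = as.integer(dom_idx0), dom = dom,
                 resno = resno, resid = resid, centroids = centroids,
                 pdata = pd), class = "assembly_problem")
}

poses_to_params <- function(poses, ndom) {
  if (is.numeric(poses)) {
    stopifnot(length(poses) == 6 * ndom)
    return(as.numeric(poses))
  }
  stopifnot(length(poses) == ndom)
  as.numeric(unlist(lapply(poses, as.numeric)))
}

params_to_poses <- function(params) {
  lapply(seq_len(length(params) / 6), function(d)
    rigid_pose(params[6 * d - 5:3], params[6 * d - 2:0]))
}

# Transformed domain-major coordinates for a parameter vector.
problem_coords <- function(problem, params) {
  cpp_pose_coords(params, problem$X0, problem$dom_idx0, problem$centroids)
}

# Flattened (resno-sorted) model coordinates for a parameter vector.
problem_flat <- function(problem, params) {
  X <- problem_coords(problem, params)
  o <- order(problem$resno)
  list(resno = problem$resno[o], resid = problem$resid[o],
       xyz = X[o, , drop = FALSE], dom = problem$dom[o])
}

flat_coords <- function(coords) {
  if (is.list(coords) && !is.null(coords$xyz)) return(coords)
  stop("coords must be a flattened coordinate list (resno/xyz/dom)")
}

#' Distance-restraint energy
#'
#' Gaussian dialect: \code{sum w min(((d - mean)/sd)^2, 16)}; distogram
#' dialect: spline-interpolated negative log probability over bin centers,
#' shifted to zero at its minimum and flat beyond the binned range.
#' All distances are measured between CA positions.
#'
#' @param coords flattened coordinates (list with \code{resno}, \code{xyz}).
#' @param set a \code{restraint_set}.
#' @return energy value (>= 0).
#' @export
e_distance <- function(coords, set) {
  fc <- flat_coords(coords)
  pd <- empty_pdata()
  g <- set$gaussians
  if (nrow(g) > 0) {
    pd$gi <- row0_of(g$i, fc$resno); pd$gj <- row0_of(g$j, fc$resno)
    pd$gmean <- g$mean; pd$gsd <- g$sd; pd$gw <- g$weight
  }
  dg <- set$distograms
  if (!is.null(dg) && nrow(dg$records) > 0) {
    pd$dgi <- row0_of(dg$records$i, fc$resno)
    pd$dgj <- row0_of(dg$records$j, fc$resno)
    pr <- distogram_profiles(dg)
    pd$dg_centers <- pr$centers; pd$dg_y <- pr$y; pd$dg_m <- pr$m
  }
  cpp_energy_terms(fc$xyz, pd)[1]
}

#' Interface-contact energy
#'
#' Contacts with probability at or above the threshold contribute
#' \code{prob ((d - 18)/2)^2} (capped at 16) when farther than 18 Angstrom,
#' and nothing when within.
#'
#' @inheritParams e_distance
#' @param contacts data frame (i, j, prob) or a \code{restraint_set}.
#' @param prob_threshold minimum probability (default 0.5).
#' @export
e_contact <- function(coords, contacts, prob_threshold = 0.5) {
  fc <- flat_coords(coords)
  if (inherits(contacts, "restraint_set")) contacts <- contacts$contacts
  pd <- empty_pdata()
  keep <- contacts$prob >= prob_threshold
  if (any(keep)) {
    pd$ci <- row0_of(contacts$i[keep], fc$resno)
    pd$cj <- row0_of(contacts$j[keep], fc$resno)
    pd$cprob <- contacts$prob[keep]
  }
  cpp_energy_terms(fc$xyz, pd)[2]
}

inter_domain_pairs0 <- function(dom) {
  n <- length(dom)
  ut <- which(upper.tri(matrix(0, n, n)) & outer(dom, dom, "!="), arr.ind = TRUE)
  ut
}

#' Inter-domain steric-clash energy
#'
#' \code{sum max(0, 3.8 - d)^2} over all inter-domain CA pairs;
#' intra-domain pairs are excluded (rigid bodies).
#'
#' @inheritParams e_distance
#' @export
e_clash <- function(coords) {
  fc <- flat_coords(coords)
  ut <- inter_domain_pairs0(fc$dom)
  pd <- empty_pdata()
  pd$pi <- as.integer(ut[, 1] - 1L); pd$pj <- as.integer(ut[, 2] - 1L)
  pd$gen_block <- rep(-1L, nrow(ut))
  cpp_energy_terms(fc$xyz, pd)[3]
}

#' Generic inter-domain contact reward
#'
#' For each consecutive domain pair, counts inter-domain CA pairs with
#' distance in [4.5, 8] Angstrom and rewards \code{-min(n, cap)/cap} with
#' \code{cap = ceil(3 sqrt(min(len_i, len_j)))}: interface formation is
#' rewarded but saturates, so domains are pulled together without being
#' crushed.
#'
#' @inheritParams e_distance
#' @param layout a \code{chain_layout}.
#' @export
e_generic_contact <- function(coords, layout) {
  fc <- flat_coords(coords)
  stopifnot(length(layout$domain_order) >= 2)
  ut <- inter_domain_pairs0(fc$dom)
  pd <- empty_pdata()
  pd$pi <- as.integer(ut[, 1] - 1L); pd$pj <- as.integer(ut[, 2] - 1L)
  ids <- layout$domain_order
  lens <- table(fc$dom)
  blk <- rep(-1L, nrow(ut)); caps <- numeric(0)
  for (k in seq_len(length(ids) - 1)) {
    d1 <- ids[k]; d2 <- ids[k + 1]
    hit <- (fc$dom[ut[, 1]] == d1 & fc$dom[ut[, 2]] == d2) |
           (fc$dom[ut[, 1]] == d2 & fc$dom[ut[, 2]] == d1)
    blk[hit] <- k - 1L
    caps <- c(caps, ceiling(3 * sqrt(min(lens[[as.character(d1)]],
                                         lens[[as.character(d2)]]))))
  }
  pd$gen_block <- blk; pd$gen_cap <- caps
  cpp_energy_terms(fc$xyz, pd)[4]
}

#' Domain-boundary connectivity energy
#'
#' For each adjacent segment pair across a domain boundary with linker gap
#' g, penalizes \code{max(0, d_term - 3.8 (g+1))^2} where d_term is the
#' distance between the flanking CA atoms: the missing linker of g
#' residues can span at most 3.8 Angstrom per peptide step.
#'
#' @inheritParams e_generic_contact
#' @export
e_connectivity <- function(coords, layout) {
  fc <- flat_coords(coords)
  b <- layout$boundaries
  if (nrow(b) == 0) return(0)
  pd <- empty_pdata()
  pd$bi <- row0_of(b$left_res, fc$resno, "boundary")
  pd$bj <- row0_of(b$right_res, fc$resno, "boundary")
  pd$bspan <- 3.8 * (b$gap + 1)
  cpp_energy_terms(fc$xyz, pd)[5]
}

#' Template distance-profile energy
#'
#' Inter-domain CA distances between template-aligned residue pairs form
#' harmonic wells \code{((d - d_tmpl)/2)^2} capped at 16; hits are combined
#' as the tm_h-weighted mean of their per-hit mean well.
#'
#' @inheritParams e_distance
#' @param hits list of template hits carrying \code{tpl_pairs} and
#'   \code{tm_h}.
#' @export
e_template_profile <- function(coords, hits) {
  fc <- flat_coords(coords)
  stopifnot(length(hits) >= 1)
  pd <- empty_pdata()
  ti <- tj <- th <- integer(0); td <- hw <- numeric(0)
  h_id <- 0L
  for (h in hits) {
    tp <- h$tpl_pairs
    if (is.null(tp) || nrow(tp) == 0) next
    ok <- tp$i %in% fc$resno & tp$j %in% fc$resno
    tp <- tp[ok, , drop = FALSE]
    if (nrow(tp) == 0) next
    ti <- c(ti, row0_of(tp$i, fc$resno)); tj <- c(tj, row0_of(tp$j, fc$resno))
    td <- c(td, tp$d); th <- c(th, rep(h_id, nrow(tp)))
    hw <- c(hw, h$tm_h); h_id <- h_id + 1L
  }
  pd$ti <- ti; pd$tj <- tj; pd$t_hit <- th; pd$t_d <- td; pd$hit_w <- hw
  cpp_energy_terms(fc$xyz, pd)[6]
}

# ---- orientation term (trRosetta-convention angles on CB frames) ----

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / nb, sum(n1 * n2))
}

angle3 <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
}

#' Virtual CB position from backbone N/CA/C
#'
#' Standard tetrahedral construction (used for GLY and whenever an
#' explicit CB is absent).
#'
#' @param n,ca,c matrices (N x 3) of backbone positions.
#' @return N x 3 matrix of CB positions.
#' @export
virtual_cb <- function(n, ca, c) {
  b <- ca - n; cc <- c - ca
  a <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
             b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
             b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Inter-residue orientation energy
#'
#' trRosetta-convention angles (omega: CA-CB...CB-CA dihedral; theta:
#' N-CA-CB-CB dihedral; phi: CA-CB-CB angle), each contributing
#' \code{weight (1 - cos(model - restraint))}. Returns 0 when CB/backbone
#' coordinates are unavailable.
#'
#' @param coords flattened coordinates with \code{cb} (and \code{n}, \code{ca})
#'   matrices alongside \code{xyz}.
#' @param orientations data frame of orientation restraints.
#' @export
e_orientation <- function(coords, orientations) {
  fc <- coords
  if (is.null(orientations) || nrow(orientations) == 0) return(0)
  if (is.null(fc$cb) || is.null(fc$n)) return(0)
  ca <- fc$xyz; cb <- fc$cb; nn <- fc$n
  total <- 0
  for (k in seq_len(nrow(orientations))) {
    o <- orientations[k, ]
    i <- match(o$i, fc$resno); j <- match(o$j, fc$resno)
    if (is.na(i) || is.na(j)) next
    if (anyNA(cb[i, ]) || anyNA(cb[j, ]) || anyNA(nn[i, ]) || anyNA(nn[j, ])) next
    omega <- dihedral(ca[i, ], cb[i, ], cb[j, ], ca[j, ])
    th_ij <- dihedral(nn[i, ], ca[i, ], cb[i, ], cb[j, ])
    th_ji <- dihedral(nn[j, ], ca[j, ], cb[j, ], cb[i, ])
    ph_ij <- angle3(ca[i, ], cb[i, ], cb[j, ])
    ph_ji <- angle3(ca[j, ], cb[j, ], cb[i, ])
    dev <- c(omega - o$omega, th_ij - o$theta_ij, th_ji - o$theta_ji,
             ph_ij - o$phi_ij, ph_ji - o$phi_ji)
    total <- total + o$weight * sum(1 - cos(dev))
  }
  total
}

orientation_active <- function(problem) {
  !is.null(problem$restraints) && !is.null(problem$restraints$orientations) &&
    nrow(problem$restraints$orientations) > 0 &&
    !is.null(problem$domains[[1]]$backbone)
}

# Orientation energy under pose parameters: transform CA/CB/N per domain.
orientation_energy_params <- function(problem, params) {
  doms <- problem$domains
  cb <- list(); nn <- list()
  for (k in seq_along(doms)) {
    bb <- doms[[k]]$backbone
    if (is.null(bb)) return(0)
    cbk <- bb$cb
    if (is.null(cbk) || anyNA(cbk)) {
      if (is.null(bb$n) || is.null(bb$c)) return(0)
      vc <- virtual_cb(bb$n, doms[[k]]$xyz, bb$c)
      if (is.null(cbk)) cbk <- vc else cbk[is.na(cbk[, 1]), ] <- vc[is.na(cbk[, 1]), ]
    }
    if (is.null(bb$n)) return(0)
    p <- params[(6 * k - 5):(6 * k)]
    c0 <- problem$centroids[k, ]
    cb[[k]] <- apply_pose_xyz(cbk, p, c0)
    nn[[k]] <- apply_pose_xyz(bb$n, p, c0)
  }
  X <- problem_coords(problem, params)
  fc <- list(resno = problem$resno, xyz = X, cb = do.call(rbind, cb),
             n = do.call(rbind, nn))
  e_orientation(fc, problem$restraints$orientations)
}

cpp_weight_vec <- function(w) {
  as.numeric(w[c("w_dist", "w_contact", "w_clash", "w_generic", "w_conn", "w_template")])
}

#' Total hybrid energy and gradient
#'
#' Weighted sum of all active terms; when the problem carries a density
#' map, the term \code{w_density (1 - correlation)} is added. The gradient
#' over the 6 x N_dom pose parameters uses central finite differences with
#' step 1e-4 (radians / Angstrom).
#'
#' @param poses list of \code{rigid_pose}s (one per domain) or a numeric
#'   parameter vector of length 6 N_dom.
#' @param problem an \code{assembly_problem}.
#' @param weights an \code{energy_weights} vector.
#' @param gradient also return the gradient?
#' @return list with \code{total}, \code{breakdown} (named weighted term
#'   values) and optionally \code{gradient}.
#' @export
total_energy <- function(poses, problem, weights = energy_weights(),
                         gradient = FALSE) {
  params <- poses_to_params(poses, length(problem$domains))
  if (any(!is.finite(params))) stop("non-finite pose parameters")
  X <- problem_coords(problem, params)
  if (any(!is.finite(X))) stop("non-finite coordinates")
  raw <- cpp_energy_terms(X, problem$pdata)
  bk <- c(dist = weights[["w_dist"]] * raw[1],
          contact = weights[["w_contact"]] * raw[2],
          clash = weights[["w_clash"]] * raw[3],
          generic = weights[["w_generic"]] * raw[4],
          connectivity = weights[["w_conn"]] * raw[5],
          template = weights[["w_template"]] * raw[6])
  has_or <- orientation_active(problem)
  if (has_or) {
    bk <- c(bk, orientation = weights[["w_orient"]] *
              orientation_energy_params(problem, params))
  }
  has_map <- !is.null(problem$map)
  if (has_map) {
    corr <- cpp_map_correlation(X, problem$map$values, problem$map$origin,
                                problem$map$voxel, problem$map$dims,
                                0.425 * problem$resolution)
    bk <- c(bk, density = weights[["w_density"]] * (1 - corr))
  }
  out <- list(total = sum(bk), breakdown = bk)
  if (gradient) {
    wv <- cpp_weight_vec(weights)
    g <- cpp_energy_grad(params, problem$X0, problem$dom_idx0,
                         problem$centroids, problem$pdata, wv)
    if (has_map && weights[["w_density"]] > 0) {
      g <- g + weights[["w_density"]] *
        cpp_density_grad(params, problem$X0, problem$dom_idx0,
                         problem$centroids, problem$map$values,
                         problem$map$origin, problem$map$voxel,
                         problem$map$dims, 0.425 * problem$resolution)
    }
    if (has_or && weights[["w_orient"]] > 0) {
      step <- 1e-4
      go <- numeric(length(params))
      for (k in seq_along(params)) {
        pp <- params; pp[k] <- pp[k] + step
        pm <- params; pm[k] <- pm[k] - step
        go[k] <- (orientation_energy_params(problem, pp) -
                    orientation_energy_params(problem, pm)) / (2 * step)
      }
      g <- g + weights[["w_orient"]] * go
    }
    out$gradient <- as.numeric(g)
  }
  out
}
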