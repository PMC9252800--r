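#' Density-map assisted assembly
#'
#' When a density map is available the assembly starts from per-domain
#' map fits instead of template placements: each domain is positioned in
#' the map by multi-start L-BFGS maximizing the real-space density
#' correlation alone, the top per-domain poses are combined into initial
#' models, and a second L-BFGS stage optimizes all poses under the hybrid
#' energy plus the density-correlation term. The pipeline ends after the
#' rigid-body stage (no flexible refinement).
#'
#' @name cryoem
NULL

#' Construct a density grid
#'
#' @param values numeric vector (or 3-D array) of voxel values, x fastest.
#' @param origin position of voxel (0,0,0) in Angstrom.
#' @param voxel isotropic voxel size in Angstrom.
#' @param dims 3 integers (nx, ny, nz).
#' @export
density_grid <- function(values, origin, voxel, dims) {
  dims <- as.integer(dims)
  stopifnot(voxel > 0, length(dims) == 3, all(dims >= 2),
            length(values) == prod(dims))
  structure(list(values = as.numeric(values), origin = as.numeric(origin),
                 voxel = voxel, dims = dims), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("density_grid:", paste(x$dims, collapse = " x "), "voxels,",
      x$voxel, "A/voxel, origin", paste(round(x$origin, 1), collapse = " "), "\n")
  invisible(x)
}

#' Simulate a density map from coordinates
#'
#' Each CA contributes a spherical Gaussian with sigma = 0.425 resolution
#' (FWHM equal to the nominal resolution), truncated at 4 sigma; the grid
#' is padded 10 Angstrom beyond the coordinate bounding box.
#'
#' @param coords N x 3 coordinate matrix (or flattened list with
#'   \code{xyz}).
#' @param resolution nominal resolution in Angstrom (>= 2 voxel).
#' @param voxel voxel size in Angstrom.
#' @return a \code{density_grid}.
#' @export
simulate_map <- function(coords, resolution = 8, voxel = 2) {
  if (is.list(coords) && !is.null(coords$xyz)) coords <- coords$xyz
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("empty coordinate set")
  stopifnot(resolution >= 2 * voxel)
  lo <- apply(coords, 2, min) - 10
  hi <- apply(coords, 2, max) + 10
  dims <- as.integer(ceiling((hi - lo) / voxel)) + 1L
  sigma <- 0.425 * resolution
  vals <- cpp_simulate_map(coords, lo, voxel, dims, sigma)
  density_grid(vals, lo, voxel, dims)
}

#' Real-space density correlation
#'
#' Pearson correlation between the map and a model map simulated from the
#' coordinates on the same grid, over voxels where either map exceeds 1e-6
#' of its own maximum. Returns 0 (with a warning) when the masked values
#' have no variance.
#'
#' @param coords coordinates (matrix or flattened list).
#' @param map a \code{density_grid}.
#' @param resolution resolution used to simulate the model map.
#' @return correlation in [-1, 1].
#' @export
density_correlation <- function(coords, map, resolution = 8) {
  if (is.list(coords) && !is.null(coords$xyz)) coords <- coords$xyz
  cc <- cpp_map_correlation(as.matrix(coords), map$values, map$origin,
                            map$voxel, map$dims, 0.425 * resolution)
  if (cc == 0) warning("zero or undefined masked correlation")
  cc
}

# top-n local maxima (26-neighborhood) of a lightly smoothed copy of the map
map_local_maxima <- function(map, n_top = 8) {
  a <- array(map$values, dim = map$dims)
  d <- dim(a)
  # separable 1-2-1 smoothing (low-pass) along each axis
  for (ax in 1:3) {
    n <- d[ax]
    lo <- seq_len(n); lo[1] <- 1; lo[-1] <- 1:(n - 1)
    hi <- seq_len(n); hi[n] <- n; hi[-n] <- 2:n
    idx <- function(sel) switch(ax, a[sel, , , drop = FALSE],
                                a[, sel, , drop = FALSE], a[, , sel, drop = FALSE])
    a <- (idx(lo) + 2 * a + idx(hi)) / 4
  }
  peaks <- NULL
  mx <- max(a)
  if (mx > 0) {
    cand <- which(a >= 0.1 * mx, arr.ind = TRUE)
    inside <- cand[, 1] > 1 & cand[, 1] < d[1] & cand[, 2] > 1 & cand[, 2] < d[2] &
      cand[, 3] > 1 & cand[, 3] < d[3]
    cand <- cand[inside, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]; k <- cand[r, 3]
      nb <- a[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
      if (a[i, j, k] >= max(nb)) peaks <- rbind(peaks, c(i, j, k, a[i, j, k]))
    }
  }
  if (is.null(peaks)) {
    # flat (or degenerate) map: fall back to the grid center, deterministic
    peaks <- matrix(c(round(d / 2), 0), 1)
  }
  peaks <- peaks[order(-peaks[, 4]), , drop = FALSE]
  peaks <- head(peaks, n_top)
  sweep((peaks[, 1:3, drop = FALSE] - 1) * map$voxel, 2, map$origin, "+")
}

#' Fit one domain into a density map
#'
#' Multi-start L-BFGS maximizing the density correlation alone: starts
#' place the domain centroid at the top local maxima of a low-pass copy of
#' the map, each tried with several seeded orientations; the resulting
#' poses are ranked by correlation.
#'
#' @param domain a \code{domain_model}.
#' @param map a \code{density_grid}.
#' @param resolution map resolution in Angstrom.
#' @param n_peaks map maxima used as translational starts (default 8).
#' @param n_orient seeded orientations per peak (default 4).
#' @param max_steps L-BFGS iterations per start (default 60).
#' @param seed RNG seed.
#' @return data frame-free list of poses ranked by correlation: each
#'   element has \code{pose} and \code{correlation}.
#' @export
fit_domain_to_map <- function(domain, map, resolution = 8, n_peaks = 8,
                              n_orient = 4, max_steps = 60, seed = 42) {
  peaks <- map_local_maxima(map, n_peaks)
  c0 <- centroid(domain$xyz)
  sigma <- 0.425 * resolution
  X0 <- domain$xyz
  dom0 <- rep(0L, nrow(X0))
  cen <- matrix(c0, 1)
  rots <- with_seed(seed, c(list(diag(3)),
                            lapply(seq_len(max(0, n_orient - 1)),
                                   function(k) random_rotation())))
  fn <- function(p) -cpp_map_correlation(
    cpp_pose_coords(p, X0, dom0, cen), map$values, map$origin, map$voxel,
    map$dims, sigma)
  gr <- function(p) as.numeric(cpp_density_grad(
    p, X0, dom0, cen, map$values, map$origin, map$voxel, map$dims, sigma))
  # phase 1: short screen of every (peak x orientation) start;
  # phase 2: full refinement of the most promising starts
  run <- function(p0, steps) {
    res <- suppressWarnings(optim(p0, fn, gr, method = "L-BFGS-B",
                                  control = list(maxit = steps, lmm = 10)))
    list(pose = rigid_pose(res$par[1:3], res$par[4:6]), correlation = -res$value)
  }
  out <- list()
  for (pk in seq_len(nrow(peaks))) {
    for (ro in seq_along(rots)) {
      pose0 <- rigid_pose(matrix_to_euler(rots[[ro]]), peaks[pk, ] - c0)
      out[[length(out) + 1]] <- run(as.numeric(pose0), min(15, max_steps))
    }
  }
  out <- out[order(-vapply(out, function(x) x$correlation, numeric(1)))]
  # refine the best screened starts, kept spatially diverse so secondary
  # blobs are not starved of refinement by the dominant one
  rg <- radius_of_gyration(domain$xyz)
  sel <- integer(0)
  cen_of <- function(s) c0 + as.numeric(s$pose)[4:6]
  for (k in seq_along(out)) {
    if (length(sel) >= 6) break
    ck <- cen_of(out[[k]])
    if (all(vapply(sel, function(s2)
      sqrt(sum((cen_of(out[[s2]]) - ck)^2)) > 0.8 * rg, logical(1)))) {
      sel <- c(sel, k)
    }
  }
  refined <- lapply(out[sel], function(s) run(as.numeric(s$pose), max_steps))
  out <- c(refined, out[-sel])
  out[order(-vapply(out, function(x) x$correlation, numeric(1)))]
}

#' Density-guided assembly
#'
#' Stage 1 fits every domain into the map independently (correlation
#' only); initial models are the combinations of the top 2 poses per
#' domain (at most 16), discarding combinations where two domains land on
#' the same blob (fitted centroids closer than 0.55 of their summed radii
#' of gyration), with the best-correlation combination kept as fallback. Stage 2 runs the multi-start L-BFGS under
#' the hybrid energy plus \code{w_density (1 - correlation)}; models are
#' ranked by correlation, ties by energy.
#'
#' @param problem an \code{assembly_problem} whose \code{map} is set.
#' @param config an \code{assembly_config}.
#' @param fit_steps L-BFGS iterations per stage-1 start (default 60).
#' @return an \code{assembly_result} (each model also carries
#'   \code{correlation}).
#' @export
density_guided_assemble <- function(problem, config = assembly_config(),
                                    fit_steps = 60) {
  if (is.null(problem$map)) stop("problem has no density map attached")
  ndom <- length(problem$domains)
  fits <- lapply(seq_len(ndom), function(k)
    fit_domain_to_map(problem$domains[[k]], problem$map, problem$resolution,
                      max_steps = fit_steps, seed = config$seed + k))
  # top poses per domain, kept diverse in position (other blobs) and in
  # orientation (at map resolutions the chain direction within a blob is
  # ambiguous, so near-degenerate flipped fits must survive to the combos)
  n_sel <- max(2, floor(16^(1 / ndom)))
  top2 <- lapply(seq_len(ndom), function(k) {
    f <- fits[[k]]
    if (length(f) <= 1) return(f)
    rg <- radius_of_gyration(problem$domains[[k]]$xyz)
    c0 <- centroid(problem$domains[[k]]$xyz)
    cen <- function(p) c0 + as.numeric(p$pose)[4:6]
    rot <- function(p) euler_to_matrix(as.numeric(p$pose)[1:3])
    sel <- list(f[[1]])
    for (p in f[-1]) {
      if (length(sel) >= n_sel) break
      distinct <- all(vapply(sel, function(s) {
        dc <- sqrt(sum((cen(p) - cen(s))^2))
        ang <- acos(max(-1, min(1, (sum(diag(t(rot(p)) %*% rot(s))) - 1) / 2)))
        dc > 0.8 * rg || ang > pi / 3
      }, logical(1)))
      if (distinct) sel[[length(sel) + 1]] <- p
    }
    sel
  })
  combos <- expand.grid(lapply(top2, seq_along))
  if (nrow(combos) > 16) combos <- combos[seq_len(16), , drop = FALSE]
  rg <- vapply(problem$domains, function(d) radius_of_gyration(d$xyz), numeric(1))
  cen0 <- lapply(problem$domains, function(d) centroid(d$xyz))
  starts <- list()
  combo_corr <- numeric(0)
  for (r in seq_len(nrow(combos))) {
    poses <- lapply(seq_len(ndom), function(k) top2[[k]][[combos[r, k]]]$pose)
    # two domains on the same blob: fitted centroids closer than their
    # summed radii of gyration allow for side-by-side placement
    cens <- lapply(seq_len(ndom), function(k) cen0[[k]] + as.numeric(poses[[k]])[4:6])
    same_blob <- FALSE
    for (a in seq_len(ndom - 1)) {
      for (b in (a + 1):ndom) {
        if (sqrt(sum((cens[[a]] - cens[[b]])^2)) < 0.55 * (rg[a] + rg[b])) {
          same_blob <- TRUE
        }
      }
    }
    X <- do.call(rbind, lapply(seq_len(ndom), function(k)
      apply_pose(problem$domains[[k]], poses[[k]])))
    starts[[r]] <- list(poses = poses, source = "density-fit",
                        clash_count = hard_clash_count(problem$domains, poses),
                        same_blob = same_blob)
    combo_corr[r] <- suppressWarnings(
      density_correlation(X, problem$map, problem$resolution))
  }
  ok <- !vapply(starts, function(s) s$same_blob, logical(1))
  keep <- if (any(ok)) starts[ok] else starts[which.max(combo_corr)]
  keep <- head(keep, config$n_starts)
  res <- assemble(problem, config, initial_models = keep)
  # rank by correlation, ties by energy
  add_corr <- function(m) {
    m$correlation <- density_correlation(m$xyz, problem$map, problem$resolution)
    m
  }
  res$models <- lapply(res$models, add_corr)
  res$all_final <- lapply(res$all_final, add_corr)
  corr <- vapply(res$models, function(m) m$correlation, numeric(1))
  en <- vapply(res$models, function(m) m$energy, numeric(1))
  res$models <- res$models[order(-round(corr, 6), en)]
  res
}
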