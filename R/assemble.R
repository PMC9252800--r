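#' Multi-start L-BFGS rigid-body assembly
#'
#' All domain poses (6 parameters each) are optimized simultaneously by
#' L-BFGS under the hybrid energy, from up to 20 template-derived (or
#' random fallback) initial models; the final models are ranked by energy,
#' de-duplicated by pairwise rTM-score and reported with per-term energy
#' breakdowns and confidence estimates.
#'
#' @name assemble
NULL

#' Assembly configuration
#'
#' @param max_steps L-BFGS iterations per start (default 200).
#' @param n_starts maximum initial models (default 20).
#' @param tol relative energy convergence tolerance (default 1e-6).
#' @param seed RNG seed.
#' @param weights an \code{energy_weights} vector.
#' @param keep_top ranked models returned (default 5).
#' @return object of class \code{assembly_config}.
#' @export
assembly_config <- function(max_steps = 200, n_starts = 20, tol = 1e-6,
                            seed = 42, weights = energy_weights(), keep_top = 5) {
  stopifnot(max_steps >= 1, keep_top >= 1, n_starts >= 1, n_starts <= 20, tol > 0)
  structure(list(max_steps = max_steps, n_starts = n_starts, tol = tol,
                 seed = seed, weights = weights, keep_top = keep_top),
            class = "assembly_config")
}

#' Minimize the assembly energy from one start
#'
#' L-BFGS (memory 10) over the 6 N_dom pose parameters with the hybrid
#' energy value and central-difference gradient. The best-energy iterate
#' visited is returned, not necessarily the last: line searches under
#' capped potentials can terminate uphill. A non-finite starting energy is
#' retried once from a seeded 0.5 Angstrom / 5 degree jitter.
#'
#' @param start an initial model (list with \code{poses}) or a list of
#'   \code{rigid_pose}s.
#' @param problem an \code{assembly_problem}.
#' @param config an \code{assembly_config}.
#' @return an \code{assembly_model}: \code{poses}, flattened \code{resno} /
#'   \code{resid} / \code{xyz} / \code{dom}, \code{energy},
#'   \code{energy_breakdown}, \code{provenance}.
#' @export
lbfgs_minimize <- function(start, problem, config = assembly_config()) {
  poses <- if (!is.null(start$poses)) start$poses else start
  params <- poses_to_params(poses, length(problem$domains))
  w <- config$weights
  e0 <- tryCatch(total_energy(params, problem, w)$total, error = function(e) NaN)
  if (!is.finite(e0)) {
    params <- with_seed(config$seed, params + c(t(cbind(
      matrix(rnorm(3 * length(problem$domains), 0, 5 * pi / 180), ncol = 3),
      matrix(rnorm(3 * length(problem$domains), 0, 0.5), ncol = 3)))))
    e0 <- total_energy(params, problem, w)$total
    if (!is.finite(e0)) stop("non-finite energy at (jittered) start")
  }
  best <- list(par = params, value = e0)
  fn <- function(p) {
    v <- total_energy(p, problem, w)$total
    if (is.finite(v) && v < best$value) best <<- list(par = p, value = v)
    v
  }
  gr <- function(p) total_energy(p, problem, w, gradient = TRUE)$gradient
  suppressWarnings(optim(params, fn, gr, method = "L-BFGS-B",
                         control = list(maxit = config$max_steps, lmm = 10,
                                        factr = config$tol / .Machine$double.eps)))
  e <- total_energy(best$par, problem, w)
  flat <- problem_flat(problem, best$par)
  structure(list(poses = params_to_poses(best$par), resno = flat$resno,
                 resid = flat$resid, xyz = flat$xyz, dom = flat$dom,
                 energy = e$total, energy_breakdown = e$breakdown,
                 start_energy = e0,
                 provenance = list(start = start$source %||% "user")),
            class = "assembly_model")
}

#' @export
print.assembly_model <- function(x, ...) {
  cat("assembly_model:", length(x$resno), "residues,", length(x$poses),
      "domains, energy", format(x$energy, digits = 6), "\n")
  invisible(x)
}

model_rtm <- function(m1, m2) r_tm_score(m1$xyz, m2$xyz, dom = m1$dom)

#' Assemble a multi-domain structure
#'
#' Builds up to \code{n_starts} initial models from the top global and
#' local template hits (or a seeded random tandem fallback when no hits
#' are given), minimizes each with \code{\link{lbfgs_minimize}}, ranks by
#' total energy, removes near-duplicates (pairwise rTM-score > 0.98,
#' keeping the lower energy) and returns the top \code{keep_top} models
#' with energy breakdowns and confidence estimates.
#'
#' @param problem an \code{assembly_problem} (carrying restraints/hits/map).
#' @param config an \code{assembly_config}.
#' @param initial_models optional explicit list of initial models
#'   (overrides template-derived starts).
#' @return an \code{assembly_result}: list with \code{models} (ranked
#'   \code{assembly_model}s), \code{all_final} (every minimized start),
#'   \code{confidence} (per ranked model, see
#'   \code{\link{estimate_quality}}) and \code{config}.
#' @export
assemble <- function(problem, config = assembly_config(), initial_models = NULL) {
  stopifnot(length(problem$domains) >= 2)
  hits <- problem$hits
  if (is.null(initial_models)) {
    hit_pool <- c(hits %||% list())
    initial_models <- build_initial_models(hit_pool, problem$domains,
                                           problem$layout,
                                           n_max = config$n_starts,
                                           seed = config$seed)
  }
  finals <- lapply(seq_along(initial_models), function(k) {
    m <- lbfgs_minimize(initial_models[[k]], problem, config)
    m$provenance$start_index <- k
    m
  })
  ord <- order(vapply(finals, function(m) m$energy, numeric(1)))
  finals <- finals[ord]
  kept <- list()
  for (m in finals) {
    dup <- any(vapply(kept, function(km) model_rtm(km, m) > 0.98, logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- m
  }
  top <- head(kept, config$keep_top)
  conf <- lapply(top, function(m) {
    tryCatch(estimate_quality_model(m, finals, problem),
             error = function(e) NULL)
  })
  structure(list(models = top, all_final = finals, confidence = conf,
                 config = config), class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("assembly_result:", length(x$models), "model(s)\n")
  for (k in seq_along(x$models)) {
    m <- x$models[[k]]
    etm <- if (!is.null(x$confidence[[k]])) sprintf(" eTM %.3f", x$confidence[[k]]$etm) else ""
    cat(sprintf("  model%d energy %.4f start %s%s\n", k, m$energy,
                as.character(m$provenance$start %||% "?"), etm))
  }
  invisible(x)
}

#' Rebuild linker residues geometrically
#'
#' For each inter-domain boundary with a gap of g missing residues, g CA
#' atoms are placed between the flanking CA positions: on a circular arc
#' with uniform 3.8 Angstrom steps when the span allows it, otherwise on
#' the straight line at uniform spacing with a \code{"stretched"} flag.
#' Linker residues are typed GLY and carry domain id 0.
#'
#' @param model an \code{assembly_model} (or flattened coordinate list).
#' @param layout a \code{chain_layout}.
#' @return the model with linker residues merged into \code{resno} /
#'   \code{xyz} / \code{resid} / \code{dom} and a \code{linker} element
#'   (data frame, incl. the stretched flag).
#' @export
rebuild_linkers <- function(model, layout) {
  b <- layout$boundaries
  info <- data.frame(left_res = integer(0), gap = integer(0),
                     stretched = logical(0))
  add_res <- integer(0); add_xyz <- NULL
  for (k in seq_len(nrow(b))) {
    g <- b$gap[k]
    if (g == 0) next
    i1 <- match(b$left_res[k], model$resno)
    i2 <- match(b$right_res[k], model$resno)
    p <- model$xyz[i1, ]; q <- model$xyz[i2, ]
    span <- sqrt(sum((q - p)^2))
    stretched <- span > 3.8 * (g + 1)
    pts <- if (stretched) {
      t <- seq_len(g) / (g + 1)
      outer(t, q - p) + matrix(p, g, 3, byrow = TRUE)
    } else {
      arc_points(p, q, g, step = 3.8)
    }
    add_res <- c(add_res, b$left_res[k] + seq_len(g))
    add_xyz <- rbind(add_xyz, pts)
    info <- rbind(info, data.frame(left_res = b$left_res[k], gap = g,
                                   stretched = stretched))
  }
  if (length(add_res) > 0) {
    model$resno <- c(model$resno, add_res)
    model$xyz <- rbind(model$xyz, add_xyz)
    model$resid <- c(model$resid %||% rep("ALA", length(model$resno) - length(add_res)),
                     rep("GLY", length(add_res)))
    model$dom <- c(model$dom %||% rep(1L, length(model$resno) - length(add_res)),
                   rep(0L, length(add_res)))
    o <- order(model$resno)
    model$resno <- model$resno[o]; model$xyz <- model$xyz[o, , drop = FALSE]
    model$resid <- model$resid[o]; model$dom <- model$dom[o]
  }
  model$linker <- info
  model
}

# g interior points between p and q on a circular arc with uniform chord
# length `step`; falls back to the straight line when the span equals the
# maximum (step * (g+1)).
arc_points <- function(p, q, g, step = 3.8) {
  span <- sqrt(sum((q - p)^2))
  nseg <- g + 1
  if (span >= step * nseg - 1e-9) {
    t <- seq_len(g) / nseg
    return(outer(t, q - p) + matrix(p, g, 3, byrow = TRUE))
  }
  # radius R such that nseg chords of `step` subtend the chord `span`
  f <- function(R) 2 * R * sin(nseg * asin(pmin(1, step / (2 * R)))) - span
  lo <- step / 2 + 1e-9
  # ensure total arc angle <= pi at the lower bracket
  while (nseg * asin(min(1, step / (2 * lo))) > pi / 1.0001) lo <- lo * 1.1
  hi <- step * nseg * 10
  R <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  half <- nseg * asin(step / (2 * R))
  # circle center: offset from the chord midpoint along a perpendicular
  u <- (q - p) / span
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  h <- R * cos(half)
  center <- (p + q) / 2 - v * h
  # rotate p about the axis (u x v) through center in nseg equal steps
  axis <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  ang_step <- 2 * asin(step / (2 * R))
  start_vec <- p - center
  # orient the rotation so nseg steps land on q
  endpt <- center + as.numeric(axis_angle_matrix(axis, nseg * ang_step) %*% start_vec)
  if (sum((endpt - q)^2) > 1e-6) axis <- -axis
  pts <- matrix(0, g, 3)
  for (m in seq_len(g)) {
    Rm <- axis_angle_matrix(axis, m * ang_step)
    pts[m, ] <- center + as.numeric(Rm %*% start_vec)
  }
  pts
}

#' @importFrom stats uniroot
NULL
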