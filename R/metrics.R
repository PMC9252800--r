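#' Superposition and structural similarity metrics
#'
#' Kabsch least-squares superposition, TM-score with a fragment-seeded
#' superposition search, a simplified TM-align-style structural aligner,
#' the harmonic per-domain template score, and the single-superposition
#' rTM-score that penalizes inter-domain orientation errors.
#'
#' @name metrics
NULL

as_pairs <- function(pairs, n) {
  if (is.null(pairs)) pairs <- cbind(seq_len(n), seq_len(n))
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  pairs
}

#' Kabsch superposition
#'
#' Least-squares rigid superposition of paired atoms: finds rotation R
#' (det +1) and translation t minimizing the RMSD of \code{R q + t} to the
#' reference.
#'
#' @param query_coords,ref_coords N x 3 coordinate matrices.
#' @param pairs 2-column matrix of (query row, reference row) index pairs;
#'   \code{NULL} pairs rows 1:1.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3)
#'   and \code{rmsd} (Angstrom).
#' @export
kabsch <- function(query_coords, ref_coords, pairs = NULL) {
  pairs <- as_pairs(pairs, nrow(query_coords))
  if (nrow(pairs) < 3) stop("kabsch needs at least 3 atom pairs")
  q <- query_coords[pairs[, 1], , drop = FALSE]
  r <- ref_coords[pairs[, 2], , drop = FALSE]
  cq <- colMeans(q); cr <- colMeans(r)
  qc <- sweep(q, 2, cq); rc <- sweep(r, 2, cr)
  H <- t(qc) %*% rc
  s <- svd(H)
  scale <- sum(qc^2) + sum(rc^2)
  if (scale > 0 && s$d[2] / max(s$d[1], .Machine$double.eps) < 1e-9 && s$d[1] > 0) {
    stop("degenerate (collinear) atom set: superposition is not unique")
  }
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) stop("rank-deficient covariance in kabsch")
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- as.numeric(cr - R %*% cq)
  fitted <- sweep(q %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

apply_transform <- function(xyz, sup) {
  sweep(xyz %*% t(sup$rotation), 2, sup$translation, "+")
}

#' TM-score normalization distance d0
#'
#' @param L normalization length.
#' @return \code{max(0.5, 1.24 (L-15)^(1/3) - 1.8)}.
#' @export
tm_d0 <- function(L) {
  x <- L - 15
  cr <- sign(x) * abs(x)^(1 / 3)
  max(0.5, 1.24 * cr - 1.8)
}

tm_kernel_sum <- function(d, d0) sum(1 / (1 + (d / d0)^2))

#' TM-score under a fragment-seeded superposition search
#'
#' Computes the TM-score of an aligned structure pair: the distance-kernel
#' sum \code{(1/L_norm) sum 1/(1+(d_i/d0)^2)} maximized over superpositions.
#' Superpositions are seeded from every gapless window of the alignment of
#' lengths L_ali, L_ali/2 and 4, then iteratively refined by superposing on
#' the pairs currently within a distance cutoff until the selected pair set
#' is stable.
#'
#' @param query,ref coordinate matrices.
#' @param pairs alignment as a 2-column index matrix (\code{NULL} = 1:1).
#' @param L_norm normalization length (default: number of reference rows).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(query, ref, pairs = NULL, L_norm = nrow(ref)) {
  pairs <- as_pairs(pairs, nrow(query))
  if (nrow(pairs) == 0) stop("empty alignment")
  stopifnot(L_norm >= 1)
  d0 <- tm_d0(L_norm)
  q <- query[pairs[, 1], , drop = FALSE]
  r <- ref[pairs[, 2], , drop = FALSE]
  cpp_tm_search(q, r, d0, L_norm)
}

#' Structural alignment of a domain onto a reference structure
#'
#' Simplified TM-align: candidate superpositions are seeded from gapless
#' fragment pairs, then dynamic programming over the TM-score-kernel
#' similarity matrix is alternated with Kabsch refitting until the
#' alignment converges (at most 30 iterations per seed). The alignment
#' with the highest TM-score normalized by query length is returned.
#'
#' @param query a \code{domain_model} or coordinate matrix.
#' @param ref_structure reference coordinate matrix.
#' @param mask optional logical vector marking reference residues that may
#'   not be used (already claimed in a global evaluation).
#' @return list with \code{pairs} (2-column index matrix), \code{tm}
#'   (TM-score, query-length normalized) and \code{superposition}.
#' @export
structural_align <- function(query, ref_structure, mask = NULL) {
  q <- if (inherits(query, "domain_model")) query$xyz else as.matrix(query)
  r <- as.matrix(ref_structure)
  empty <- list(pairs = matrix(integer(0), 0, 2), tm = 0, superposition = NULL)
  if (!is.null(mask) && any(mask)) {
    # big kernel penalty removes claimed residues from the DP path
    avail <- which(!mask)
    if (length(avail) < 5) return(empty)
  } else mask <- rep(FALSE, nrow(r))
  Lq <- nrow(q); Lr <- nrow(r)
  if (Lq < 5 || Lr < 5) return(empty)
  d0 <- tm_d0(Lq)
  lens <- unique(pmin(c(min(Lq, Lr), floor(min(Lq, Lr) / 2), 8), min(Lq, Lr)))
  lens <- lens[lens >= 4]
  seeds <- NULL
  for (wl in lens) {
    qstep <- max(1, floor(wl / 2))
    rstep <- if (wl <= 8) 2 * wl else max(1, wl)
    for (qo in seq(1, Lq - wl + 1, by = qstep)) {
      for (ro in seq(1, Lr - wl + 1, by = rstep)) {
        seeds <- rbind(seeds, c(qo, ro, wl))
      }
    }
  }
  res <- cpp_struct_align(q, r, mask, d0, gap = -0.6, seeds = seeds,
                          max_iter = 30)
  if (res$tm <= 0 || nrow(res$pairs) < 4) return(empty)
  list(pairs = res$pairs, tm = res$tm,
       superposition = list(rotation = res$rotation,
                            translation = as.numeric(res$translation)))
}

#' Harmonic mean of per-domain TM-scores
#'
#' The template-ranking score for a multi-domain target: the harmonic mean
#' \code{N_dom / sum_d (1 / TM_d)} of the per-domain TM-scores against one
#' template. Dominated by the worst-covered domain, so a template must
#' cover every domain well to score highly.
#'
#' @param per_domain_scores numeric vector of per-domain TM-scores in (0, 1].
#' @return the harmonic mean.
#' @export
harmonic_tm_score <- function(per_domain_scores) {
  s <- as.numeric(per_domain_scores)
  stopifnot(length(s) >= 1)
  if (any(s <= 0)) stop("all per-domain TM-scores must be > 0")
  length(s) / sum(1 / s)
}

#' rTM-score: TM-score under a single fixed superposition
#'
#' Superposes the model onto the native ONCE, using the Kabsch transform
#' fitted on the residues of the single domain whose individual TM-score to
#' the native is highest, then evaluates the TM-score kernel over ALL
#' residues with that fixed transform (no re-superposition). Errors in the
#' relative orientation of the other domains are therefore fully penalized.
#'
#' @param model,native coordinate matrices covering the same residues in
#'   the same row order, or flattened model lists with \code{xyz}/\code{dom}.
#' @param dom integer vector assigning each row to a domain (required when
#'   matrices are passed).
#' @return rTM-score in (0, 1].
#' @export
r_tm_score <- function(model, native, dom = NULL) {
  if (is.list(model) && !is.null(model$xyz)) { dom <- dom %||% model$dom; model <- model$xyz }
  if (is.list(native) && !is.null(native$xyz)) { dom <- dom %||% native$dom; native <- native$xyz }
  model <- as.matrix(model); native <- as.matrix(native)
  if (nrow(model) != nrow(native)) stop("model and native cover different residue sets")
  if (is.null(dom)) dom <- rep(1L, nrow(model))
  L <- nrow(model)
  d0 <- tm_d0(L)
  uds <- unique(dom)
  tms <- vapply(uds, function(d) {
    rows <- which(dom == d)
    tm_score(model[rows, , drop = FALSE], native[rows, , drop = FALSE],
             L_norm = length(rows))
  }, numeric(1))
  bestd <- uds[which.max(tms)]
  rows <- which(dom == bestd)
  sup <- kabsch(model, native, cbind(rows, rows))
  d <- sqrt(rowSums((apply_transform(model, sup) - native)^2))
  tm_kernel_sum(d, d0) / L
}
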