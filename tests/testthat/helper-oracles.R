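# Independent plain-R oracles (explicit double loops, no shared code with
# the implementation kernels).

o_dist <- function(a, b) sqrt(sum((a - b)^2))

oracle_e_dist_gauss <- function(fc, gaussians) {
  total <- 0
  for (k in seq_len(nrow(gaussians))) {
    i <- which(fc$resno == gaussians$i[k])
    j <- which(fc$resno == gaussians$j[k])
    z <- (o_dist(fc$xyz[i, ], fc$xyz[j, ]) - gaussians$mean[k]) / gaussians$sd[k]
    total <- total + gaussians$weight[k] * min(z^2, 16)
  }
  total
}

oracle_e_contact <- function(fc, contacts, threshold = 0.5) {
  total <- 0
  for (k in seq_len(nrow(contacts))) {
    if (contacts$prob[k] < threshold) next
    i <- which(fc$resno == contacts$i[k])
    j <- which(fc$resno == contacts$j[k])
    d <- o_dist(fc$xyz[i, ], fc$xyz[j, ])
    if (d > 18) total <- total + contacts$prob[k] * min(((d - 18) / 2)^2, 16)
  }
  total
}

oracle_e_clash <- function(fc) {
  n <- length(fc$resno)
  total <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (fc$dom[i] == fc$dom[j]) next
      d <- o_dist(fc$xyz[i, ], fc$xyz[j, ])
      if (d < 3.8) total <- total + (3.8 - d)^2
    }
  }
  total
}

oracle_e_generic <- function(fc, layout) {
  ids <- layout$domain_order
  total <- 0
  for (k in seq_len(length(ids) - 1)) {
    d1 <- ids[k]; d2 <- ids[k + 1]
    r1 <- which(fc$dom == d1); r2 <- which(fc$dom == d2)
    n_int <- 0
    for (i in r1) for (j in r2) {
      d <- o_dist(fc$xyz[i, ], fc$xyz[j, ])
      if (d >= 4.5 && d <= 8) n_int <- n_int + 1
    }
    cap <- ceiling(3 * sqrt(min(length(r1), length(r2))))
    total <- total - min(n_int, cap) / cap
  }
  total
}

oracle_e_conn <- function(fc, layout) {
  b <- layout$boundaries
  total <- 0
  for (k in seq_len(nrow(b))) {
    i <- which(fc$resno == b$left_res[k])
    j <- which(fc$resno == b$right_res[k])
    over <- o_dist(fc$xyz[i, ], fc$xyz[j, ]) - 3.8 * (b$gap[k] + 1)
    if (over > 0) total <- total + over^2
  }
  total
}

oracle_e_template <- function(fc, hits) {
  num <- 0; den <- 0
  for (h in hits) {
    tp <- h$tpl_pairs
    if (is.null(tp) || nrow(tp) == 0) next
    e <- 0; m <- 0
    for (k in seq_len(nrow(tp))) {
      i <- which(fc$resno == tp$i[k])
      j <- which(fc$resno == tp$j[k])
      if (length(i) == 0 || length(j) == 0) next
      z <- (o_dist(fc$xyz[i, ], fc$xyz[j, ]) - tp$d[k]) / 2
      e <- e + min(z^2, 16)
      m <- m + 1
    }
    if (m > 0) { num <- num + h$tm_h * e / m; den <- den + h$tm_h }
  }
  if (den > 0) num / den else 0
}

# Brute-force TM-score: superpositions seeded from EVERY contiguous
# fragment (all offsets, all lengths >= 3), each refined by the
# distance-cutoff reselection rule, written in plain R.
oracle_tm <- function(q, r, L_norm = nrow(r)) {
  La <- nrow(q)
  d0 <- max(0.5, 1.24 * sign(L_norm - 15) * abs(L_norm - 15)^(1 / 3) - 1.8)
  fit <- function(idx) {
    qs <- q[idx, , drop = FALSE]; rs <- r[idx, , drop = FALSE]
    cq <- colMeans(qs); cr <- colMeans(rs)
    H <- t(sweep(qs, 2, cq)) %*% sweep(rs, 2, cr)
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    list(R = R, t = as.numeric(cr - R %*% cq))
  }
  best <- 0
  for (wl in 3:La) {
    for (off in 1:(La - wl + 1)) {
      sup <- fit(off:(off + wl - 1))
      sel_prev <- NULL
      for (it in 1:20) {
        qt <- sweep(q %*% t(sup$R), 2, sup$t, "+")
        d <- sqrt(rowSums((qt - r)^2))
        best <- max(best, sum(1 / (1 + (d / d0)^2)) / L_norm)
        cut <- max(d0, 4.5)
        sel <- which(d < cut)
        while (length(sel) < 3) { cut <- cut + 0.5; sel <- which(d < cut) }
        if (identical(sel, sel_prev)) break
        sel_prev <- sel
        sup <- fit(sel)
      }
    }
  }
  best
}

# Brute-force RMSD minimization over rotations: coarse-to-fine grid over
# Z-Y-X Euler angles ending at 0.1-degree sampling; translation solved in
# closed form at each rotation.
oracle_kabsch_rmsd <- function(q, r) {
  rot <- function(a, b, g) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(g), -sin(g), 0, sin(g), cos(g)), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  rmsd_at <- function(a, b, g) {
    R <- rot(a, b, g)
    qr <- q %*% t(R)
    tt <- colMeans(r) - colMeans(qr)
    sqrt(mean(rowSums((sweep(qr, 2, tt, "+") - r)^2)))
  }
  deg <- pi / 180
  ctr <- c(0, 0, 0)
  best <- c(0, 0, 0); bv <- Inf
  for (step_deg in c(10, 1, 0.1)) {
    h <- step_deg * deg
    span <- if (step_deg == 10) 18 else 12
    for (ia in -span:span) for (ib in -span:span) for (ig in -span:span) {
      a <- ctr[1] + ia * h; b <- ctr[2] + ib * h; g <- ctr[3] + ig * h
      v <- rmsd_at(a, b, g)
      if (v < bv) { bv <- v; best <- c(a, b, g) }
    }
    ctr <- best
  }
  bv
}

# Full non-density energy recomputed from the R oracles.
oracle_total <- function(fc, layout, restraints = NULL, hits = NULL,
                         w = energy_weights()) {
  total <- 0
  if (!is.null(restraints)) {
    if (nrow(restraints$gaussians) > 0) {
      total <- total + w[["w_dist"]] * oracle_e_dist_gauss(fc, restraints$gaussians)
    }
    if (nrow(restraints$contacts) > 0) {
      total <- total + w[["w_contact"]] * oracle_e_contact(fc, restraints$contacts)
    }
  }
  total <- total + w[["w_clash"]] * oracle_e_clash(fc)
  total <- total + w[["w_generic"]] * oracle_e_generic(fc, layout)
  total <- total + w[["w_conn"]] * oracle_e_conn(fc, layout)
  if (!is.null(hits) && length(hits) > 0) {
    total <- total + w[["w_template"]] * oracle_e_template(fc, hits)
  }
  total
}
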