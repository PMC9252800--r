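#' Inter-residue spatial restraints
#'
#' Restraints stand in for the output of a deep-learning predictor and come
#' in four channels: binned distance distributions (distograms), Gaussian
#' distance restraints (a compact dialect convenient for native-derived
#' synthetic restraints), interface contact probabilities, and
#' inter-residue orientation angles. Hydrogen-bond-network records are
#' parsed and stored but carry no energy.
#'
#' @name restraints
NULL

default_bin_edges <- function(nbins = 36, lo = 2, hi = 20) seq(lo, hi, length.out = nbins + 1)

#' Construct a restraint set
#'
#' @param gaussians data frame with columns i, j, atom, mean, sd, weight.
#' @param distograms list with \code{bin_edges} (ascending Angstrom values)
#'   and \code{records} (data frame i, j, atom) and \code{probs} (matrix,
#'   one row per record, probabilities summing to 1).
#' @param contacts data frame with columns i, j, prob.
#' @param orientations data frame with columns i, j, omega, theta_ij,
#'   theta_ji, phi_ij, phi_ji, weight (radians, trRosetta conventions).
#' @param hbonds data frame of parsed hydrogen-bond records (no energy).
#' @param provenance free-text note.
#' @return object of class \code{restraint_set}.
#' @export
restraint_set <- function(gaussians = NULL, distograms = NULL, contacts = NULL,
                          orientations = NULL, hbonds = NULL, provenance = "") {
  empty_g <- data.frame(i = integer(0), j = integer(0), atom = character(0),
                        mean = numeric(0), sd = numeric(0), weight = numeric(0))
  empty_c <- data.frame(i = integer(0), j = integer(0), prob = numeric(0))
  gaussians <- gaussians %||% empty_g
  contacts <- contacts %||% empty_c
  if (nrow(gaussians) > 0) {
    stopifnot(all(gaussians$i < gaussians$j), all(gaussians$sd > 0),
              all(gaussians$weight >= 0))
    key <- paste(gaussians$i, gaussians$j, gaussians$atom)
    if (anyDuplicated(key)) stop("duplicate (i, j, atom) keys in gaussians")
  }
  if (nrow(contacts) > 0) {
    stopifnot(all(contacts$prob >= 0 & contacts$prob <= 1))
  }
  if (!is.null(distograms) && nrow(distograms$records) > 0) {
    rs <- rowSums(distograms$probs)
    if (any(abs(rs - 1) > 1e-6)) {
      stop("distogram probabilities must sum to 1 (first offender: record ",
           which(abs(rs - 1) > 1e-6)[1], ")")
    }
    if (any(distograms$probs < 0)) stop("negative distogram probability")
    if (is.unsorted(distograms$bin_edges, strictly = TRUE)) stop("bin edges must ascend")
  }
  if (!is.null(orientations) && nrow(orientations) > 0) {
    ang_ok <- function(x, lo, hi) all(x > lo - 1e-9 & x <= hi + 1e-9)
    stopifnot(ang_ok(orientations$omega, -pi, pi),
              ang_ok(orientations$theta_ij, -pi, pi),
              ang_ok(orientations$theta_ji, -pi, pi),
              ang_ok(orientations$phi_ij, 0, pi),
              ang_ok(orientations$phi_ji, 0, pi))
  }
  structure(list(gaussians = gaussians, distograms = distograms,
                 contacts = contacts, orientations = orientations,
                 hbonds = hbonds, provenance = provenance),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  ndg <- if (is.null(x$distograms)) 0 else nrow(x$distograms$records)
  nor <- if (is.null(x$orientations)) 0 else nrow(x$orientations)
  cat("restraint_set:", nrow(x$gaussians), "gaussian,", ndg, "distogram,",
      nrow(x$contacts), "contact,", nor, "orientation record(s)\n")
  invisible(x)
}

#' Derive interface contact probabilities from distograms
#'
#' The contact probability of a pair is the cumulative distogram
#' probability of CA distances below the cutoff: the sum over bins whose
#' upper edge lies at or below the cutoff, plus the linearly interpolated
#' fraction of the straddling bin.
#'
#' @param set a \code{restraint_set} with CA distograms.
#' @param cutoff distance cutoff in Angstrom (default 18).
#' @return data frame of contact restraints (i, j, prob).
#' @export
contacts_from_distograms <- function(set, cutoff = 18) {
  dg <- set$distograms
  if (is.null(dg) || nrow(dg$records) == 0) stop("no distograms in restraint set")
  keep <- dg$records$atom == "CA"
  if (!any(keep)) stop("no CA distograms present")
  edges <- dg$bin_edges
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  frac <- pmin(1, pmax(0, (cutoff - lo) / (hi - lo)))
  probs <- pmin(1, pmax(0, dg$probs[keep, , drop = FALSE] %*% frac))
  data.frame(i = dg$records$i[keep], j = dg$records$j[keep], prob = as.numeric(probs))
}

#' Synthesize Gaussian restraints from a native structure
#'
#' Generates inter-domain CA distance restraints from known native
#' coordinates (intra-domain pairs are excluded: domains move as rigid
#' bodies, so intra-domain distances are constants). A test/benchmark
#' utility emulating a well-converged distance predictor.
#'
#' @param native flattened native coordinates (list with \code{resno},
#'   \code{xyz}, \code{dom}, e.g. from \code{\link{make_toy_multidomain}}).
#' @param layout the \code{chain_layout} (unused beyond validation; the
#'   domain assignment comes from \code{native$dom}).
#' @param mode \code{"exact"} (means = native distances) or \code{"noisy"}
#'   (means perturbed by Normal(0, sd) noise).
#' @param sd the restraint standard deviation in Angstrom.
#' @param subsample fraction of eligible pairs to keep (exactly
#'   \code{round(subsample * n)} pairs, seed-deterministic).
#' @param seed RNG seed.
#' @return a \code{restraint_set} of Gaussian restraints.
#' @export
synth_restraints_from_native <- function(native, layout = NULL, mode = c("exact", "noisy"),
                                         sd = 1, subsample = 1, seed = 42) {
  mode <- match.arg(mode)
  if (mode == "noisy" && sd <= 0) stop("sd must be > 0 in noisy mode")
  stopifnot(sd > 0, subsample > 0, subsample <= 1)
  dom <- native$dom
  n <- nrow(native$xyz)
  pr <- which(outer(dom, dom, "!=") & upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  npairs <- nrow(pr)
  if (npairs == 0) stop("no inter-domain pairs in native")
  keep <- with_seed(seed, sort(sample(npairs, round(subsample * npairs))))
  pr <- pr[keep, , drop = FALSE]
  d <- sqrt(rowSums((native$xyz[pr[, 1], , drop = FALSE] -
                       native$xyz[pr[, 2], , drop = FALSE])^2))
  if (mode == "noisy") d <- d + with_seed(seed + 1L, rnorm(length(d), 0, sd))
  i <- native$resno[pr[, 1]]; j <- native$resno[pr[, 2]]
  sw <- i > j
  tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
  g <- data.frame(i = i, j = j, atom = "CA", mean = pmax(d, 0.1), sd = sd, weight = 1)
  g <- g[order(g$i, g$j), , drop = FALSE]
  rownames(g) <- NULL
  restraint_set(gaussians = g,
                provenance = sprintf("synthetic native-derived (%s, sd=%g, subsample=%g, seed=%d)",
                                     mode, sd, subsample, seed))
}

#' Read a restraint file
#'
#' Whitespace-delimited plain text, one record per line, '#' comments.
#' Record types: \code{DIST i j atom mean sd weight};
#' \code{DGRAM i j atom p1..pB} (bin edges declared by a preceding
#' \code{# BINS e0 e1 ... eB} header, default 36 bins over 2-20 Angstrom);
#' \code{CON i j prob}; \code{ORI i j omega theta_ij theta_ji phi_ij phi_ji
#' weight}; \code{HB ...} records are stored verbatim (no energy). Unknown
#' record types produce a warning and are skipped.
#'
#' @param path input file.
#' @return a \code{restraint_set}.
#' @export
read_restraints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  edges <- default_bin_edges()
  g <- list(); dgr <- list(); dgp <- list(); con <- list(); ori <- list(); hb <- list()
  num <- function(x, ln) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v))) stop("malformed numeric field at line ", ln, ": ",
                            paste(x[is.na(v)], collapse = " "))
    v
  }
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "") next
    if (startsWith(raw, "#")) {
      tok <- strsplit(sub("^#\\s*", "", raw), "\\s+")[[1]]
      if (length(tok) > 1 && toupper(tok[1]) == "BINS") edges <- num(tok[-1], ln)
      next
    }
    tok <- strsplit(raw, "\\s+")[[1]]
    type <- toupper(tok[1])
    if (type == "DIST") {
      if (length(tok) != 7) stop("DIST record needs 6 fields at line ", ln)
      v <- num(tok[c(2, 3, 5, 6, 7)], ln)
      g[[length(g) + 1]] <- data.frame(i = v[1], j = v[2], atom = toupper(tok[4]),
                                       mean = v[3], sd = v[4], weight = v[5])
    } else if (type == "DGRAM") {
      nb <- length(edges) - 1
      if (length(tok) != 4 + nb) {
        stop("DGRAM record needs ", nb, " probabilities at line ", ln)
      }
      v <- num(tok[c(2, 3)], ln)
      p <- num(tok[-(1:4)], ln)
      if (abs(sum(p) - 1) > 1e-6) {
        stop("distogram probabilities do not sum to 1 at line ", ln,
             " (sum = ", format(sum(p)), ")")
      }
      dgr[[length(dgr) + 1]] <- data.frame(i = v[1], j = v[2], atom = toupper(tok[4]))
      dgp[[length(dgp) + 1]] <- p
    } else if (type == "CON") {
      if (length(tok) != 4) stop("CON record needs 3 fields at line ", ln)
      v <- num(tok[2:4], ln)
      con[[length(con) + 1]] <- data.frame(i = v[1], j = v[2], prob = v[3])
    } else if (type == "ORI") {
      if (length(tok) != 9) stop("ORI record needs 8 fields at line ", ln)
      v <- num(tok[2:9], ln)
      ori[[length(ori) + 1]] <- data.frame(i = v[1], j = v[2], omega = v[3],
                                           theta_ij = v[4], theta_ji = v[5],
                                           phi_ij = v[6], phi_ji = v[7], weight = v[8])
    } else if (type == "HB") {
      hb[[length(hb) + 1]] <- data.frame(record = raw)
    } else {
      warning("skipping unknown record type '", tok[1], "' at line ", ln)
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  dg <- NULL
  if (length(dgr) > 0) {
    dg <- list(bin_edges = edges, records = bind(dgr), probs = do.call(rbind, dgp))
  }
  restraint_set(gaussians = bind(g), distograms = dg, contacts = bind(con),
                orientations = bind(ori), hbonds = bind(hb),
                provenance = paste("read from", path))
}

#' Write a restraint set
#'
#' @param set a \code{restraint_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @rdname read_restraints
#' @export
write_restraints <- function(set, path) {
  lines <- c("# rigidom restraint file")
  if (!is.null(set$distograms)) {
    lines <- c(lines, paste("# BINS", paste(format(set$distograms$bin_edges,
                                                   trim = TRUE), collapse = " ")))
  }
  fmt <- function(x) format(x, trim = TRUE, digits = 10)
  if (nrow(set$gaussians) > 0) {
    lines <- c(lines, sprintf("DIST %d %d %s %s %s %s", set$gaussians$i, set$gaussians$j,
                              set$gaussians$atom, fmt(set$gaussians$mean),
                              fmt(set$gaussians$sd), fmt(set$gaussians$weight)))
  }
  if (!is.null(set$distograms) && nrow(set$distograms$records) > 0) {
    rec <- set$distograms$records
    for (k in seq_len(nrow(rec))) {
      lines <- c(lines, paste("DGRAM", rec$i[k], rec$j[k], rec$atom[k],
                              paste(fmt(set$distograms$probs[k, ]), collapse = " ")))
    }
  }
  if (nrow(set$contacts) > 0) {
    lines <- c(lines, sprintf("CON %d %d %s", as.integer(set$contacts$i),
                              as.integer(set$contacts$j), fmt(set$contacts$prob)))
  }
  if (!is.null(set$orientations) && nrow(set$orientations) > 0) {
    o <- set$orientations
    lines <- c(lines, sprintf("ORI %d %d %s %s %s %s %s %s", as.integer(o$i),
                              as.integer(o$j), fmt(o$omega), fmt(o$theta_ij),
                              fmt(o$theta_ji), fmt(o$phi_ij), fmt(o$phi_ji),
                              fmt(o$weight)))
  }
  if (!is.null(set$hbonds) && nrow(set$hbonds) > 0) lines <- c(lines, set$hbonds$record)
  writeLines(lines, path)
  invisible(path)
}
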