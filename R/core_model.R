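#' Domain models, chain layout and rigid poses
#'
#' A multi-domain chain is represented as a set of rigid folding units
#' (\code{domain_model}s) in a common full-chain residue numbering, plus a
#' \code{chain_layout} recording domain order and linker gaps. Each domain
#' carries CA coordinates (and optionally N/C/O/CB) and one or more
#' residue-index segments; a domain with more than one segment is
#' discontinuous (another domain is inserted between its segments).
#'
#' @name core_model
NULL

# Split a sorted residue-index vector into contiguous segments; a numbering
# gap >= 2 starts a new segment (discontinuous-domain support).
infer_segments <- function(resno) {
  stopifnot(length(resno) > 0, !is.unsorted(resno))
  breaks <- which(diff(resno) > 1)
  starts <- resno[c(1, breaks + 1)]
  ends <- resno[c(breaks, length(resno))]
  cbind(start = starts, end = ends)
}

#' Construct a domain model from residue records
#'
#' @param domain_id integer ordinal of the domain.
#' @param resno integer residue indices (1-based, full-chain numbering).
#' @param xyz numeric N x 3 matrix of CA coordinates (Angstrom).
#' @param resid character residue names (default \code{"ALA"}).
#' @param backbone optional named list of N x 3 matrices (\code{n}, \code{c},
#'   \code{o}, \code{cb}) in the same row order as \code{xyz}.
#' @return an object of class \code{domain_model}.
#' @export
domain_model <- function(domain_id, resno, xyz, resid = NULL, backbone = NULL) {
  resno <- as.integer(resno)
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  stopifnot(nrow(xyz) == length(resno), ncol(xyz) == 3)
  if (!is.null(backbone)) {
    backbone <- lapply(backbone, function(m) {
      if (!is.null(m)) { m <- as.matrix(m); dimnames(m) <- NULL }
      m
    })
  }
  if (is.unsorted(resno, strictly = TRUE)) {
    o <- order(resno)
    if (anyDuplicated(resno)) stop("duplicate residue indices in domain ", domain_id)
    resno <- resno[o]; xyz <- xyz[o, , drop = FALSE]
    if (!is.null(resid)) resid <- resid[o]
    if (!is.null(backbone)) backbone <- lapply(backbone, function(m) m[o, , drop = FALSE])
  }
  if (any(resno < 1)) stop("residue indices must be >= 1")
  if (is.null(resid)) resid <- rep("ALA", length(resno))
  structure(list(domain_id = as.integer(domain_id), resno = resno,
                 resid = as.character(resid), xyz = xyz,
                 backbone = backbone, segments = infer_segments(resno)),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  segs <- apply(x$segments, 1, function(s) paste0(s[1], "-", s[2]))
  cat("domain_model", x$domain_id, ":", length(x$resno), "residues, segments",
      paste(segs, collapse = ", "), "\n")
  invisible(x)
}

#' Read a single-domain PDB file
#'
#' Reads CA (and, when present, N/C/O/CB) coordinates of ATOM records.
#' Residues are keyed by their PDB residue number, which must already be in
#' the full-chain frame. Insertion codes are rejected; for alternate
#' locations only blank or 'A' is kept; the chain identifier is ignored for
#' numbering.
#'
#' @param path PDB file path.
#' @param domain_id integer ordinal assigned to this domain.
#' @return a \code{domain_model}.
#' @export
read_domain_pdb <- function(path, domain_id = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stop("cannot parse PDB file ", path, ": ",
                                           conditionMessage(e)))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no ATOM records in ", path)
  if (any(!is.na(atoms$insert) & atoms$insert != "")) {
    stop("insertion codes are not supported (file ", path, ")")
  }
  keep_alt <- is.na(atoms$alt) | atoms$alt %in% c("", "A")
  atoms <- atoms[keep_alt, , drop = FALSE]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atoms in ", path)
  all_res <- unique(atoms$resno)
  missing_ca <- setdiff(all_res, ca$resno)
  if (length(missing_ca) > 0) {
    stop("residue(s) without CA in ", path, ": ",
         paste(head(missing_ca, 5), collapse = ", "))
  }
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  o <- order(ca$resno)
  ca <- ca[o, , drop = FALSE]
  resno <- ca$resno
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  grab <- function(elety) {
    sub <- atoms[atoms$elety == elety, , drop = FALSE]
    sub <- sub[!duplicated(sub$resno), , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    m <- matrix(NA_real_, length(resno), 3)
    idx <- match(sub$resno, resno)
    ok <- !is.na(idx)
    m[idx[ok], ] <- as.matrix(sub[ok, c("x", "y", "z")])
    m
  }
  backbone <- list(n = grab("N"), c = grab("C"), o = grab("O"), cb = grab("CB"))
  if (all(vapply(backbone, is.null, logical(1)))) backbone <- NULL
  dm <- domain_model(domain_id, resno, xyz, resid = ca$resid, backbone = backbone)
  dca <- sqrt(rowSums(diff(dm$xyz)^2))
  gaps <- diff(dm$resno) == 1L
  bad <- which(gaps & (dca < 1.5 | dca > 4.5))
  if (length(bad) > 0) {
    warning("unusual consecutive CA-CA distance(s) in ", path, " near residue ",
            dm$resno[bad[1]])
  }
  dm
}

#' Infer the chain layout from a set of domain models
#'
#' Orders domains by first segment start, computes linker gaps between
#' consecutive domains and the full list of adjacent segment boundaries
#' (used by the connectivity energy term), and optionally checks residue
#' names against a full-chain sequence.
#'
#' @param domains list of \code{domain_model}s.
#' @param full_sequence optional one-letter amino-acid string for the full
#'   chain; residue names must match it at their indices.
#' @return an object of class \code{chain_layout} with fields
#'   \code{domain_order}, \code{linker_gaps}, \code{boundaries} (data frame
#'   of inter-domain segment junctions) and \code{full_sequence}.
#' @export
infer_layout <- function(domains, full_sequence = NULL) {
  stopifnot(length(domains) >= 1)
  ids <- vapply(domains, function(d) d$domain_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate domain ids")
  # overlap check
  all_res <- unlist(lapply(domains, function(d) d$resno))
  if (anyDuplicated(all_res)) {
    dup <- sort(unique(all_res[duplicated(all_res)]))
    if (is.null(full_sequence)) {
      stop("overlapping residue numbering without a full sequence: residues ",
           paste(head(dup, 10), collapse = ", "))
    }
    stop("overlapping residue numbering cannot be re-mapped: residues ",
         paste(head(dup, 10), collapse = ", "))
  }
  if (!is.null(full_sequence)) {
    seq1 <- strsplit(toupper(full_sequence), "")[[1]]
    for (d in domains) {
      aa1 <- aa321_safe(d$resid)
      idx <- d$resno
      if (any(idx > length(seq1))) {
        stop("residue index ", max(idx), " beyond sequence length ", length(seq1))
      }
      mm <- which(!is.na(aa1) & aa1 != "X" & seq1[idx] != aa1)
      if (length(mm) > 0) {
        stop("sequence mismatch at full-chain index ", idx[mm[1]],
             ": sequence has ", seq1[idx[mm[1]]], ", domain ", d$domain_id,
             " has ", aa1[mm[1]])
      }
    }
  }
  firsts <- vapply(domains, function(d) d$segments[1, 1], numeric(1))
  ord <- order(firsts)
  domain_order <- ids[ord]
  # global sorted segment table
  seg <- do.call(rbind, lapply(domains, function(d) {
    cbind(dom = d$domain_id, d$segments)
  }))
  seg <- seg[order(seg[, "start"]), , drop = FALSE]
  bounds <- NULL
  if (nrow(seg) > 1) {
    for (k in seq_len(nrow(seg) - 1)) {
      l <- seg[k, ]; r <- seg[k + 1, ]
      gap <- r[["start"]] - l[["end"]] - 1
      if (gap < 0) stop("overlapping segments between domains ", l[["dom"]],
                        " and ", r[["dom"]])
      if (l[["dom"]] != r[["dom"]]) {
        bounds <- rbind(bounds, data.frame(left_dom = l[["dom"]], left_res = l[["end"]],
                                           right_dom = r[["dom"]], right_res = r[["start"]],
                                           gap = gap))
      }
    }
  }
  if (is.null(bounds)) {
    bounds <- data.frame(left_dom = integer(0), left_res = integer(0),
                         right_dom = integer(0), right_res = integer(0),
                         gap = integer(0))
  }
  # linker gap per consecutive domain pair (first junction between them)
  linker_gaps <- integer(0)
  if (length(domain_order) > 1) {
    linker_gaps <- vapply(seq_len(length(domain_order) - 1), function(k) {
      hit <- which((bounds$left_dom == domain_order[k] & bounds$right_dom == domain_order[k + 1]) |
                   (bounds$left_dom == domain_order[k + 1] & bounds$right_dom == domain_order[k]))
      if (length(hit) == 0) NA_integer_ else as.integer(bounds$gap[hit[1]])
    }, integer(1))
  }
  structure(list(full_sequence = full_sequence, domain_order = domain_order,
                 linker_gaps = linker_gaps, boundaries = bounds),
            class = "chain_layout")
}

#' @export
print.chain_layout <- function(x, ...) {
  cat("chain_layout:", length(x$domain_order), "domains, order",
      paste(x$domain_order, collapse = " "), "| linker gaps",
      paste(x$linker_gaps, collapse = " "), "\n")
  invisible(x)
}

# three-letter -> one-letter without warnings for unknowns
aa321_safe <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out)] <- "X"
  out
}

#' Create a rigid pose
#'
#' A pose is 3 intrinsic Z-Y-X Euler angles (radians) applied about the
#' centroid of the domain's input coordinates, followed by a translation
#' (Angstrom). The identity pose \code{rigid_pose()} reproduces the input
#' coordinates exactly.
#'
#' @param rot numeric length-3 Euler angles (radians).
#' @param trans numeric length-3 translation (Angstrom).
#' @export
rigid_pose <- function(rot = c(0, 0, 0), trans = c(0, 0, 0)) {
  structure(c(as.numeric(rot), as.numeric(trans)), class = "rigid_pose")
}

pose_params <- function(pose) unclass(pose)

# pose from a rotation matrix + translation acting as x -> R x + v,
# re-expressed about the domain centroid c: t = v + R c - c.
pose_from_transform <- function(R, v, centroid) {
  rigid_pose(matrix_to_euler(R), as.numeric(v + R %*% centroid - centroid))
}

#' Apply a rigid pose to a domain
#'
#' @param domain a \code{domain_model}.
#' @param pose a \code{rigid_pose} (or numeric length 6).
#' @return N x 3 matrix of transformed CA coordinates.
#' @export
apply_pose <- function(domain, pose) {
  p <- as.numeric(pose)
  if (all(p == 0)) return(domain$xyz)  # identity pose is bit-exact
  R <- euler_to_matrix(p[1:3])
  c0 <- centroid(domain$xyz)
  sweep(sweep(domain$xyz, 2, c0) %*% t(R), 2, c0 + p[4:6], "+")
}

# Apply a pose to an arbitrary coordinate matrix about a given centroid.
apply_pose_xyz <- function(xyz, pose, c0) {
  p <- as.numeric(pose)
  R <- euler_to_matrix(p[1:3])
  sweep(sweep(xyz, 2, c0) %*% t(R), 2, c0 + p[4:6], "+")
}

#' Write an assembly model as a PDB file
#'
#' Writes CA ATOM records in full-chain residue order on a single chain
#' 'A', with the domain id in the B-factor column (0 for rebuilt linker
#' residues, which are typed GLY), a REMARK header documenting that
#' convention, and a terminating TER record. Coordinates are written at
#' PDB precision (3 decimals).
#'
#' @param model an \code{assembly_model} (see \code{\link{assemble}}) or any
#'   list with \code{resno}, \code{resid}, \code{xyz}, \code{dom} fields.
#' @param path output file path.
#' @param remarks optional extra REMARK strings.
#' @return \code{path}, invisibly.
#' @export
write_model_pdb <- function(model, path, remarks = character(0)) {
  resno <- model$resno
  xyz <- model$xyz
  resid <- model$resid %||% rep("ALA", length(resno))
  dom <- model$dom %||% rep(1L, length(resno))
  o <- order(resno)
  lines <- c(
    "REMARK   3 RIGIDOM ASSEMBLY MODEL",
    "REMARK   3 B-FACTOR COLUMN HOLDS THE DOMAIN ID (0 = REBUILT LINKER)",
    if (length(remarks)) paste("REMARK   3", remarks)
  )
  ser <- 0L
  for (k in o) {
    ser <- ser + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      ser, resid[k], resno[k], xyz[k, 1], xyz[k, 2], xyz[k, 3], 1.00, as.numeric(dom[k])))
  }
  lines <- c(lines, sprintf("TER   %5d      %3s A%4d", ser + 1L,
                            resid[o[length(o)]], resno[o[length(o)]]), "END")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

# Concatenate domain coordinates in full-chain order; returns list with
# resno, resid, xyz, dom (domain id per residue).
flatten_domains <- function(domains, coords = NULL) {
  if (is.null(coords)) coords <- lapply(domains, function(d) d$xyz)
  resno <- unlist(lapply(domains, function(d) d$resno))
  resid <- unlist(lapply(domains, function(d) d$resid))
  dom <- unlist(lapply(seq_along(domains),
                       function(i) rep(domains[[i]]$domain_id, length(domains[[i]]$resno))))
  xyz <- do.call(rbind, coords)
  o <- order(resno)
  list(resno = resno[o], resid = resid[o], xyz = xyz[o, , drop = FALSE], dom = dom[o])
}
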