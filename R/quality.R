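#' Model confidence estimation (eTM-score / eRMSD)
#'
#' Without a native structure, model accuracy is estimated from what the
#' run itself knows: the significance of the best template (tm_h), the
#' consistency of the model with the predicted inter-domain restraints,
#' the convergence of the multi-start assembly, and the supplied
#' per-domain model confidences. The composite eTM-score lives in [0, 1];
#' by convention models with eTM-score > 0.5 generally have the correct
#' global fold. The eRMSD proxy inverts the TM-score distance kernel and
#' is flagged as a heuristic in the output.
#'
#' @name quality
NULL

#' Fraction of satisfied distance restraints
#'
#' Gaussian dialect: the model distance lies within 2 sd of the mean.
#' Distogram dialect: the model distance falls inside the 90% highest-
#' density bin set.
#'
#' @param model an \code{assembly_model} or flattened coordinate list.
#' @param set a \code{restraint_set} with distance restraints.
#' @return fraction in [0, 1].
#' @export
restraint_satisfaction <- function(model, set) {
  n_g <- nrow(set$gaussians)
  n_d <- if (is.null(set$distograms)) 0 else nrow(set$distograms$records)
  if (n_g + n_d == 0) stop("restraint set has no distance restraints")
  fc <- model
  sat <- 0; tot <- 0
  dist_of <- function(i, j) {
    ri <- match(i, fc$resno); rj <- match(j, fc$resno)
    sqrt(rowSums((fc$xyz[ri, , drop = FALSE] - fc$xyz[rj, , drop = FALSE])^2))
  }
  if (n_g > 0) {
    g <- set$gaussians
    d <- dist_of(g$i, g$j)
    sat <- sat + sum(abs(d - g$mean) <= 2 * g$sd)
    tot <- tot + n_g
  }
  if (n_d > 0) {
    dg <- set$distograms
    d <- dist_of(dg$records$i, dg$records$j)
    edges <- dg$bin_edges
    for (k in seq_len(n_d)) {
      p <- dg$probs[k, ]
      o <- order(p, decreasing = TRUE)
      hd <- o[seq_len(which(cumsum(p[o]) >= 0.9)[1])]
      bin <- findInterval(d[k], edges, rightmost.closed = TRUE)
      if (bin >= 1 && bin <= length(p) && bin %in% hd) sat <- sat + 1
      tot <- tot + 1
    }
  }
  sat / tot
}

#' Convergence of the multi-start assembly
#'
#' Mean pairwise rTM-score between the top-5 final models: near 1 when the
#' starts all converge to one pose, low when they scatter.
#'
#' @param models list of \code{assembly_model}s (final multi-start set).
#' @return score in [0, 1].
#' @export
convergence_score <- function(models) {
  if (length(models) < 2) {
    warning("convergence undefined for a single model; returning 0.5")
    return(0.5)
  }
  top <- head(models, 5)
  vals <- c()
  for (a in seq_len(length(top) - 1)) {
    for (b in (a + 1):length(top)) {
      vals <- c(vals, model_rtm(top[[a]], top[[b]]))
    }
  }
  mean(vals)
}

#' Estimate model confidence
#'
#' \code{etm = clamp(0.25 best_tm_h + 0.25 restraint_satisfaction +
#' 0.2 convergence + 0.3 mean(domain_conf), 0, 1)};
#' \code{ermsd = d0(L) sqrt(max(0, 1/etm - 1))} (inverted TM-score kernel,
#' heuristic). A missing component (no templates, no restraints) enters as
#' a neutral 0.5.
#'
#' @param result an \code{assembly_result} (the top model is scored) or a
#'   single \code{assembly_model}.
#' @param hits template hits (best tm_h used); may be \code{NULL}.
#' @param set a \code{restraint_set}; may be \code{NULL}.
#' @param domain_conf per-domain confidences in [0, 1] (default 0.8,
#'   standing in for an external per-domain accuracy estimator).
#' @param all_models final multi-start models for the convergence term;
#'   taken from \code{result} when available.
#' @return a \code{confidence_report}: \code{etm}, \code{ermsd},
#'   \code{components}.
#' @export
estimate_quality <- function(result, hits = NULL, set = NULL,
                             domain_conf = NULL, all_models = NULL) {
  if (inherits(result, "assembly_result")) {
    all_models <- all_models %||% result$all_final
    model <- result$models[[1]]
  } else model <- result
  L <- length(model$resno)
  ndom <- length(unique(model$dom[model$dom > 0]))
  domain_conf <- domain_conf %||% rep(0.8, max(1, ndom))
  stopifnot(all(domain_conf >= 0 & domain_conf <= 1))
  tpl_term <- if (!is.null(hits) && length(hits) > 0) {
    max(vapply(hits, function(h) h$tm_h, numeric(1)))
  } else 0.5
  rs_term <- if (!is.null(set) &&
                 (nrow(set$gaussians) > 0 ||
                  (!is.null(set$distograms) && nrow(set$distograms$records) > 0))) {
    restraint_satisfaction(model, set)
  } else 0.5
  cv_term <- if (!is.null(all_models) && length(all_models) >= 2) {
    convergence_score(all_models)
  } else 0.5
  dm_term <- mean(domain_conf)
  etm <- max(0, min(1, 0.25 * tpl_term + 0.25 * rs_term + 0.2 * cv_term +
                      0.3 * dm_term))
  ermsd <- tm_d0(L) * sqrt(max(0, 1 / etm - 1))
  structure(list(etm = etm, ermsd = ermsd,
                 components = c(template = tpl_term, restraint = rs_term,
                                convergence = cv_term, domain_quality = dm_term),
                 note = "eRMSD is a heuristic kernel inversion"),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("eTM-score %.3f | eRMSD %.2f A (heuristic)\n", x$etm, x$ermsd))
  cat("  components:", paste(sprintf("%s=%.3f", names(x$components),
                                     x$components), collapse = " "), "\n")
  invisible(x)
}

# internal: confidence for one ranked model inside assemble()
estimate_quality_model <- function(model, all_finals, problem) {
  estimate_quality(model, hits = problem$hits, set = problem$restraints,
                   all_models = all_finals)
}
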