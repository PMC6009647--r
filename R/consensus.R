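## Consensus-map construction: project aligned molecules onto reference
## coordinates, collapse putative dual-strand labels, histogram the pooled
## placements and quantify off-target labeling.

#' Place a molecule's labels on the reference coordinate axis
#'
#' Matched labels are placed exactly at their site's coordinate.  Unmatched
#' labels are placed by piecewise-linear interpolation between the flanking
#' matched anchor pairs (label bp position -> site coordinate); beyond the
#' outermost anchors, and for molecules with no matches at all, the
#' molecule-level affine fit (fitted stretch + global offset) is used
#' directly.
#'
#' @param alignment a \code{label_alignment} produced from this trace/map.
#' @param trace the \code{molecule_trace} the alignment was computed from
#'   (only its molecule id is used; coordinates are taken from the
#'   alignment).
#' @param refmap the \code{\link{reference_map}}.
#' @return data frame of placed labels: \code{molecule}, \code{coord}
#'   (reference bp), \code{status} (\code{"matched"}/\code{"unmatched"}),
#'   \code{site} (site index or NA).
#' @export
place_labels <- function(alignment, trace, refmap) {
  L <- alignment$n_labels
  if (L == 0)
    return(data.frame(molecule = integer(), coord = numeric(),
                      status = character(), site = integer()))
  sites <- refmap$sites$position
  bp <- alignment$label_bp
  coord <- bp                       # affine fallback
  status <- rep("unmatched", L)
  site <- rep(NA_integer_, L)
  if (nrow(alignment$pairs)) {
    li <- alignment$pairs[, 1]; si <- alignment$pairs[, 2]
    coord[li] <- sites[si]
    status[li] <- "matched"
    site[li] <- si
    if (length(li) >= 2) {
      ## interpolate unmatched labels between flanking anchors
      anchors_x <- bp[li]; anchors_y <- sites[si]
      um <- which(status == "unmatched")
      inside <- um[bp[um] > min(anchors_x) & bp[um] < max(anchors_x)]
      if (length(inside))
        coord[inside] <- stats::approx(anchors_x, anchors_y,
                                       xout = bp[inside], ties = mean)$y
    }
  }
  data.frame(molecule = rep(trace$molecule, L), coord = coord,
             status = status, site = site)
}

#' Remove putative dual-strand labels
#'
#' Palindromic sites can be alkylated on both strands, producing a second
#' label a few bp from the matched one.  Iterating over the matched labels
#' in coordinate order, at most one not-yet-removed unmatched label within
#' \code{window} bp of each matched label is marked \code{"removed_dual"}
#' (nearest first by default; ties to the lower coordinate).  Removed labels
#' are excluded from all downstream statistics.
#'
#' @param placed placements of one molecule (from \code{\link{place_labels}}).
#' @param window removal window, bp (default 100).
#' @param rule \code{"nearest"}: remove the nearest candidate;
#'   \code{"leftmost"}: remove the lowest-coordinate candidate.
#' @return \code{placed} with \code{status} updated.
#' @export
remove_dual_strand <- function(placed, window = 100,
                               rule = c("nearest", "leftmost")) {
  rule <- match.arg(rule)
  if (!nrow(placed)) return(placed)
  matched <- which(placed$status == "matched")
  matched <- matched[order(placed$coord[matched])]
  for (m in matched) {
    cand <- which(placed$status == "unmatched" &
                  abs(placed$coord - placed$coord[m]) <= window)
    if (!length(cand)) next
    pick <- if (rule == "nearest") {
      d <- abs(placed$coord[cand] - placed$coord[m])
      cand[order(d, placed$coord[cand])][1]
    } else {
      cand[order(placed$coord[cand])][1]
    }
    placed$status[pick] <- "removed_dual"
  }
  placed
}

#' Build the consensus histogram of placed labels
#'
#' Histogram over reference coordinates of all non-removed placed labels
#' from the pooled molecules, the "consensus map" of the fragment.
#'
#' @param placed pooled placements (rows from \code{\link{place_labels}},
#'   possibly after \code{\link{remove_dual_strand}}).
#' @param refmap the \code{\link{reference_map}}.
#' @param bin_width histogram bin width, bp (default 50, below the
#'   100-150 bp precision scale).
#' @return an object of class \code{"consensus_histogram"}: list with
#'   \code{breaks}, \code{counts}, \code{bin_width}, \code{n_molecules}.
#' @export
build_consensus <- function(placed, refmap, bin_width = 50) {
  if (bin_width <= 0) stop("bin_width must be positive")
  keep <- placed$status != "removed_dual"
  x <- placed$coord[keep]
  breaks <- seq(0, bin_width * ceiling(refmap$length / bin_width),
                by = bin_width)
  x <- pmin(pmax(x, 0), max(breaks) - 1e-9)
  counts <- if (length(x))
    as.vector(table(cut(x, breaks, right = FALSE,
                        include.lowest = TRUE))) else
    integer(length(breaks) - 1)
  structure(list(breaks = breaks, counts = counts, bin_width = bin_width,
                 n_molecules = length(unique(placed$molecule))),
            class = "consensus_histogram")
}

#' @export
print.consensus_histogram <- function(x, ...) {
  cat(sprintf("consensus_histogram: %d bins of %g bp, %d labels from %d molecules\n",
              length(x$counts), x$bin_width, sum(x$counts), x$n_molecules))
  invisible(x)
}

## truncated-normal moment estimate of the localization SD from matched
## residuals r in [-W, W]: solves E[r^2 | |r|<=W] = sigma^2 * (1 - 2a phi(a)
## / (2 Phi(a) - 1)), a = W/sigma
estimate_sigma_trunc <- function(residuals, width) {
  m2 <- mean(residuals^2)
  if (!is.finite(m2) || m2 <= 0) return(1e-6)
  if (m2 >= width^2 / 3 * 0.999) return(2 * width)  # uniform limit
  f <- function(s) {
    a <- width / s
    s^2 * (1 - 2 * a * dnorm(a) / (2 * pnorm(a) - 1)) - m2
  }
  tryCatch(uniroot(f, c(1e-3, 10 * width))$root,
           error = function(e) sqrt(m2))
}

#' Off-site labeling statistics
#'
#' Quantifies off-target labeling from pooled placements: the unmatched
#' fraction, the unmatched density per kb (denominator: molecule count times
#' reference length), the mean matched labels per site, and a
#' Kolmogorov-Smirnov test of the unmatched coordinates against
#' Uniform(0, length).
#'
#' Because a match requires the label to fall within \code{match_width} of
#' its site, genuinely on-site labels whose localization error exceeds the
#' window inflate the raw unmatched counts.  The corrected estimators
#' account for this truncation: with capture probability
#' \code{c = 2*Phi(W/sigma) - 1} (sigma estimated from the matched residuals
#' by truncated-normal moment matching, after rescaling for the two affine
#' transform parameters fitted per molecule, unless supplied), the per-site
#' labeling efficiency is \code{M/(n_molecules * n_sites * c)} and the
#' expected number of escaped on-site labels \code{M (1-c)/c} is moved from
#' the unmatched to the matched side of the corrected fraction and density.
#'
#' @param placed pooled placements after any dual-strand removal; rows with
#'   status \code{"removed_dual"} are excluded.
#' @param refmap the \code{\link{reference_map}}.
#' @param n_molecules number of molecules contributing.
#' @param match_width the alignment match window, bp.
#' @param sigma known localization SD in bp, or \code{NULL} to estimate it
#'   from the matched residuals.
#' @param residuals optional matched-pair residuals (label bp - site bp)
#'   used for the sigma estimate; when \code{NULL}, sigma estimation is
#'   skipped unless \code{sigma} is given and the capture correction uses
#'   \code{c = 1}.
#' @return an object of class \code{"offsite_stats"}: list with
#'   \code{n_matched}, \code{n_unmatched}, \code{offsite_fraction},
#'   \code{offsite_density}, \code{onsite_per_site}, \code{uniformity_p},
#'   \code{sigma_hat}, \code{capture}, \code{efficiency},
#'   \code{offsite_fraction_corrected}, \code{offsite_density_corrected},
#'   \code{fraction_defined}.
#' @export
offsite_stats <- function(placed, refmap, n_molecules,
                          match_width = 150, sigma = NULL,
                          residuals = NULL) {
  keep <- placed$status != "removed_dual"
  M <- sum(placed$status[keep] == "matched")
  U <- sum(placed$status[keep] == "unmatched")
  L_kb <- refmap$length / 1000
  S <- n_sites(refmap)
  total <- M + U
  frac <- if (total > 0) U / total else NA_real_
  dens <- if (n_molecules > 0) U / (n_molecules * L_kb) else 0
  ux <- placed$coord[keep & placed$status == "unmatched"]
  unif_p <- if (length(ux) >= 3)
    suppressWarnings(ks.test(ux, "punif", 0, refmap$length)$p.value) else
    NA_real_
  sigma_hat <- if (!is.null(sigma)) sigma else
    if (!is.null(residuals) && length(residuals) >= 10) {
      ## two affine parameters (offset + stretch) are fit per molecule, so
      ## the matched residuals are shrunk; rescale by the residual degrees
      ## of freedom before moment matching
      N <- length(residuals)
      scale <- if (n_molecules > 0 && N > 2 * n_molecules + 5)
        sqrt(N / (N - 2 * n_molecules)) else 1
      estimate_sigma_trunc(residuals * scale, match_width)
    } else NA_real_
  capture <- if (is.finite(sigma_hat) && sigma_hat > 0)
    2 * pnorm(match_width / sigma_hat) - 1 else 1
  escaped <- M * (1 - capture) / capture
  U_corr <- max(U - escaped, 0)
  structure(list(
    n_matched = M, n_unmatched = U,
    offsite_fraction = frac,
    offsite_density = dens,
    onsite_per_site = if (n_molecules > 0 && S > 0)
      M / (n_molecules * S) else NA_real_,
    uniformity_p = unif_p,
    sigma_hat = sigma_hat, capture = capture,
    efficiency = if (n_molecules > 0 && S > 0)
      M / (n_molecules * S * capture) else NA_real_,
    offsite_fraction_corrected = if (total > 0) U_corr / total else NA_real_,
    offsite_density_corrected = if (n_molecules > 0)
      U_corr / (n_molecules * L_kb) else 0,
    fraction_defined = total > 0),
    class = "offsite_stats")
}

#' @export
print.offsite_stats <- function(x, ...) {
  cat(sprintf("offsite_stats: %d matched, %d unmatched\n", x$n_matched,
              x$n_unmatched))
  cat(sprintf("  off-site fraction %.1f%% (corrected %.1f%%), density %.3f/kb (corrected %.3f/kb)\n",
              100 * x$offsite_fraction, 100 * x$offsite_fraction_corrected,
              x$offsite_density, x$offsite_density_corrected))
  cat(sprintf("  per-site matched mean %.3f, efficiency %.3f (capture %.3f, sigma %.1f bp), uniformity p %.3f\n",
              x$onsite_per_site, x$efficiency, x$capture, x$sigma_hat,
              x$uniformity_p))
  invisible(x)
}

#' Matched-pair residuals of an alignment
#'
#' @param alignment a \code{label_alignment}.
#' @param refmap the reference map.
#' @return numeric vector of (label bp - site bp) residuals.
#' @export
alignment_residuals <- function(alignment, refmap) {
  if (!nrow(alignment$pairs)) return(numeric())
  alignment$label_bp[alignment$pairs[, 1]] -
    refmap$sites$position[alignment$pairs[, 2]]
}
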