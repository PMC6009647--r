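## Stretch-tolerant, orientation-aware alignment of a molecule's label
## positions to a reference motif map.
##
## The aligner searches a grid of candidate stretch factors around the
## nominal combing stretch, and for each stretch a set of candidate global
## offsets (from label/site anchor pairs), running a monotone dynamic
## program with transitions {match, skip-site, skip-label}.  A match within
## the window contributes a triangular score 1 - |d|/width; skipped sites
## and extra labels pay penalties; terminal skipped sites are free when
## free_ends is set (molecules are full-length fragments).

#' Alignment parameters
#'
#' @param stretch nominal stretch factor (default 1.6).
#' @param stretch_tol fractional stretch search half-range (default 0.1).
#' @param n_stretch number of evenly spaced candidate stretches.
#' @param match_width maximum label-to-site distance for a match, bp
#'   (default 150).
#' @param match_score score of a perfect match.
#' @param miss_site_penalty cost of skipping an interior site.
#' @param extra_label_penalty cost of an unmatched label.
#' @param nm_per_bp physical conversion at stretch 1.
#' @param free_ends terminal skipped sites are free.
#' @param flat_score flat \code{match_score} instead of the triangular taper.
#' @param local fully local (non-negative running score) mode.
#' @param offset_max half-range of the global-offset search, bp.
#' @return an object of class \code{"alignment_params"}.
#' @export
alignment_params <- function(stretch = 1.6, stretch_tol = 0.1,
                             n_stretch = 11, match_width = 150,
                             match_score = 1,
                             miss_site_penalty = 0.5 * match_score,
                             extra_label_penalty = 0.25 * match_score,
                             nm_per_bp = 0.34, free_ends = TRUE,
                             flat_score = FALSE, local = FALSE,
                             offset_max = 2 * match_width) {
  stopifnot(match_width > 0, stretch_tol >= 0, stretch_tol < 1,
            stretch > 0, n_stretch >= 1, miss_site_penalty >= 0,
            extra_label_penalty >= 0)
  structure(list(stretch = stretch, stretch_tol = stretch_tol,
                 n_stretch = as.integer(n_stretch),
                 match_width = match_width, match_score = match_score,
                 miss_site_penalty = miss_site_penalty,
                 extra_label_penalty = extra_label_penalty,
                 nm_per_bp = nm_per_bp, free_ends = free_ends,
                 flat_score = flat_score, local = local,
                 offset_max = offset_max),
            class = "alignment_params")
}

#' Convert physical label positions to sequence coordinates
#'
#' \code{bp = nm / (nm_per_bp * stretch)}; order is preserved.
#'
#' @param trace a \code{molecule_trace} or a numeric vector of nm positions.
#' @param stretch stretch factor (> 0).
#' @param nm_per_bp physical conversion at stretch 1.
#' @return numeric vector of bp positions.
#' @export
to_bp <- function(trace, stretch, nm_per_bp = 0.34) {
  stopifnot(stretch > 0)
  pos <- if (inherits(trace, "molecule_trace")) trace$positions_nm else trace
  pos / (nm_per_bp * stretch)
}

## run the DP for fixed label bp positions (already offset-corrected)
.dp_run <- function(labels_bp, sites, params) {
  dp_align_cpp(labels_bp, sites, params$match_width, params$match_score,
               params$miss_site_penalty, params$extra_label_penalty,
               params$free_ends, params$flat_score, params$local)
}

## candidate global offsets: 0 plus anchor-pair differences within
## offset_max, thinned to a minimal spacing
.candidate_offsets <- function(labels_bp, sites, params) {
  if (!length(labels_bp) || !length(sites)) return(0)
  d <- as.vector(outer(sites, labels_bp, "-"))
  d <- d[abs(d) <= params$offset_max]
  d <- sort(unique(c(0, d)))
  if (length(d) > 1) {
    keep <- c(TRUE, diff(d) > params$match_width / 15)
    d <- d[keep]
  }
  d
}

.better <- function(score, matches, best) {
  score > best$score + 1e-9 ||
    (score > best$score - 1e-9 && matches > best$matches)
}

#' Align a molecule trace to a reference map
#'
#' Searches \code{n_stretch} evenly spaced stretches in
#' \code{stretch * (1 +- stretch_tol)}; at each stretch the labels are
#' converted to bp, a set of candidate global offsets is derived from
#' label/site anchor pairs, and the monotone DP is run for each offset.
#' The grid optimum is then polished: the molecule-level affine transform
#' (global offset and stretch) is refit by least squares over the matched
#' anchor pairs and the matching re-derived at that transform, which is
#' returned.  Ties break toward higher match count.
#'
#' @param trace a \code{molecule_trace} (positions sorted ascending).
#' @param refmap a \code{\link{reference_map}} (non-empty).
#' @param params an \code{\link{alignment_params}}.
#' @param orientation orientation recorded on the result.
#' @return an object of class \code{"label_alignment"}: orientation,
#'   \code{fitted_stretch}, \code{offset}, \code{pairs} (matrix of 1-based
#'   label/site indices, strictly increasing in both), \code{unmatched_labels},
#'   \code{skipped_sites}, \code{score}, \code{label_bp} (offset-corrected
#'   label positions in reference bp at the fitted stretch) and
#'   \code{n_labels}.
#' @export
align <- function(trace, refmap, params = alignment_params(),
                  orientation = "forward") {
  if (n_sites(refmap) == 0) stop("reference map has no sites")
  sites <- refmap$sites$position
  pos_nm <- trace$positions_nm
  L <- length(pos_nm)
  if (L == 0) {
    score <- if (params$free_ends || params$local) 0 else
      -length(sites) * params$miss_site_penalty
    return(structure(list(orientation = orientation,
                          fitted_stretch = params$stretch, offset = 0,
                          pairs = matrix(integer(), ncol = 2,
                                         dimnames = list(NULL, c("label", "site"))),
                          unmatched_labels = integer(),
                          skipped_sites = seq_along(sites),
                          score = score, label_bp = numeric(),
                          n_labels = 0L),
                     class = "label_alignment"))
  }
  if (is.unsorted(pos_nm)) stop("trace positions must be sorted")
  ss <- if (params$n_stretch == 1 || params$stretch_tol == 0)
    params$stretch else
      seq(params$stretch * (1 - params$stretch_tol),
          params$stretch * (1 + params$stretch_tol),
          length.out = params$n_stretch)
  best <- list(score = -Inf, matches = -1L)
  for (s in ss) {
    bp <- pos_nm / (params$nm_per_bp * s)
    for (off in .candidate_offsets(bp, sites, params)) {
      r <- .dp_run(bp + off, sites, params)
      if (.better(r$score, r$matches, best))
        best <- list(score = r$score, matches = r$matches, pairs = r$pairs,
                     stretch = s, offset = off, bp = bp)
    }
  }
  ## polish: refit the molecule-level affine transform (global offset +
  ## stretch) by least squares over the matched anchor pairs, then re-derive
  ## the matching once at that transform.  Unlike keeping the grid-search
  ## maximum, adopting the least-squares transform does not select for
  ## configurations that happen to rescue borderline matches, so residual
  ## and matched-count statistics stay unbiased (up to the two fitted
  ## parameters per molecule).
  stretch <- best$stretch
  offset <- best$offset
  bp <- best$bp
  for (it in 1:2) {
    np <- nrow(best$pairs)
    if (np == 0) break
    x <- pos_nm[best$pairs[, 1]]
    y <- sites[best$pairs[, 2]]
    if (np >= 3 && stats::var(x) > 0) {
      cf <- unname(coef(lm(y ~ x)))
      beta <- cf[2]
      s2 <- 1 / (beta * params$nm_per_bp)
      lo <- params$stretch * (1 - params$stretch_tol)
      hi <- params$stretch * (1 + params$stretch_tol)
      if (!is.finite(s2) || s2 < lo || s2 > hi) {
        s2 <- stretch
        cf <- c(mean(y - x / (params$nm_per_bp * s2)),
                1 / (params$nm_per_bp * s2))
      }
      stretch <- s2
      offset <- unname(cf[1])
      bp <- pos_nm / (params$nm_per_bp * stretch)
    } else {
      offset <- mean(y - bp[best$pairs[, 1]])
    }
    r2 <- .dp_run(bp + offset, sites, params)
    if (identical(r2$pairs, best$pairs)) {
      best <- list(score = r2$score, matches = r2$matches, pairs = r2$pairs,
                   stretch = stretch, offset = offset, bp = bp)
      break
    }
    best <- list(score = r2$score, matches = r2$matches, pairs = r2$pairs,
                 stretch = stretch, offset = offset, bp = bp)
  }
  pairs <- best$pairs
  colnames(pairs) <- c("label", "site")
  structure(list(orientation = orientation, fitted_stretch = best$stretch,
                 offset = best$offset, pairs = pairs,
                 unmatched_labels = setdiff(seq_len(L), pairs[, 1]),
                 skipped_sites = setdiff(seq_along(sites), pairs[, 2]),
                 score = best$score,
                 label_bp = best$bp + best$offset, n_labels = L),
            class = "label_alignment")
}

#' Align trying both molecule orientations
#'
#' Deposited molecules have unknown polarity: runs \code{\link{align}} on
#' the trace and on its mirror and returns the higher-scoring alignment
#' (ties break to forward).
#'
#' @inheritParams align
#' @return a \code{label_alignment} with \code{orientation} set to
#'   \code{"forward"} or \code{"reverse"}.
#' @export
align_best_orientation <- function(trace, refmap,
                                   params = alignment_params()) {
  fwd <- align(trace, refmap, params, orientation = "forward")
  rev <- align(mirror_trace(trace), refmap, params, orientation = "reverse")
  if (rev$score > fwd$score + 1e-9) rev else fwd
}

#' Recompute an alignment's score from its parts
#'
#' Independent re-evaluation of the scoring objective on the recorded
#' matching, used to check internal consistency.
#'
#' @param alignment a \code{label_alignment}.
#' @param refmap the reference map it was computed against.
#' @param params the \code{alignment_params} used.
#' @return the recomputed score.
#' @export
score_alignment <- function(alignment, refmap, params) {
  sites <- refmap$sites$position
  sc <- 0
  if (nrow(alignment$pairs)) {
    d <- abs(alignment$label_bp[alignment$pairs[, 1]] -
             sites[alignment$pairs[, 2]])
    sc <- sc + sum(if (params$flat_score) rep(params$match_score, length(d))
                   else params$match_score * pmax(0, 1 - d / params$match_width))
  }
  sc <- sc - length(alignment$unmatched_labels) * params$extra_label_penalty
  skipped <- alignment$skipped_sites
  if (params$free_ends && length(skipped)) {
    matched_sites <- alignment$pairs[, 2]
    if (length(matched_sites)) {
      interior <- skipped[skipped > min(matched_sites) &
                          skipped < max(matched_sites)]
    } else interior <- integer()
    sc <- sc - length(interior) * params$miss_site_penalty
  } else {
    sc <- sc - length(skipped) * params$miss_site_penalty
  }
  sc
}

#' @export
print.label_alignment <- function(x, ...) {
  cat(sprintf("label_alignment (%s): score %.3f, stretch %.3f, offset %.1f bp, %d/%d labels matched, %d site(s) skipped\n",
              x$orientation, x$score, x$fitted_stretch, x$offset,
              nrow(x$pairs), x$n_labels, length(x$skipped_sites)))
  invisible(x)
}

#' Write alignments as JSON lines
#'
#' One molecule per line: orientation, fitted stretch, offset, pairs,
#' unmatched labels, skipped sites, score.
#'
#' @param alignments list of \code{label_alignment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in alignments) {
    writeLines(jsonlite::toJSON(list(
      orientation = a$orientation, stretch = a$fitted_stretch,
      offset = a$offset,
      pairs = if (nrow(a$pairs)) unname(apply(a$pairs, 1, as.list)) else list(),
      unmatched = a$unmatched_labels, skipped = a$skipped_sites,
      score = a$score), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
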