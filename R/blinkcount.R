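## Bleaching-assisted localization, plasmid-mask reconstruction and
## per-plasmid label counting.
##
## The localization pass works backwards through the movie: in the terminal
## frames only the longest-lived fluorophores survive and are isolated, so
## they can be fitted by a 2D Gaussian; subtracting each fitted PSF from all
## frames up to its bleach frame reveals emitters that bleached earlier,
## even when their PSFs overlapped.

#' Localization parameters
#'
#' @param n_sigma detection threshold in robust SDs (median/MAD) above
#'   background on the window-averaged image.
#' @param window number of frames averaged per backward step.
#' @param roi half-width in px of the square fitting region.
#' @param psf_sigma initial PSF SD guess, px; fits whose SD falls outside
#'   [0.5, 2.5] times this value are discarded as implausible.
#' @param max_emitters safety cap on the number of fitted emitters.
#' @param min_sep minimum separation (px) between maxima handled in the same
#'   backward step; closer maxima are left to later steps after subtraction.
#' @return an object of class \code{"localize_params"}.
#' @export
localize_params <- function(n_sigma = 5, window = 10, roi = 4,
                            psf_sigma = 1.2, max_emitters = 200,
                            min_sep = 2) {
  structure(list(n_sigma = n_sigma, window = as.integer(window),
                 roi = as.integer(roi), psf_sigma = psf_sigma,
                 max_emitters = as.integer(max_emitters), min_sep = min_sep),
            class = "localize_params")
}

## local maxima of `img` above `thresh`, as (row, col) pairs
.local_maxima <- function(img, thresh) {
  H <- nrow(img); W <- ncol(img)
  if (H < 3 || W < 3) return(cbind(integer(), integer()))
  c0 <- img[2:(H - 1), 2:(W - 1)]
  ok <- c0 > thresh &
    c0 >= img[1:(H - 2), 2:(W - 1)] & c0 >= img[3:H, 2:(W - 1)] &
    c0 >= img[2:(H - 1), 1:(W - 2)] & c0 >= img[2:(H - 1), 3:W] &
    c0 >= img[1:(H - 2), 1:(W - 2)] & c0 >= img[1:(H - 2), 3:W] &
    c0 >= img[3:H, 1:(W - 2)] & c0 >= img[3:H, 3:W]
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) return(cbind(integer(), integer()))
  cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
}

## least-squares 2D Gaussian fit (amplitude, x0, y0, sigma, offset) on an
## ROI; coordinates 0-based.  Returns NULL when the fit fails to converge.
.fit_gaussian2d <- function(img, row0, col0, roi, sigma0) {
  H <- nrow(img); W <- ncol(img)
  yi <- max(1, row0 - roi):min(H, row0 + roi)
  xi <- max(1, col0 - roi):min(W, col0 + roi)
  z <- as.vector(img[yi, xi])
  grid <- expand.grid(y = yi - 1, x = xi - 1)
  off0 <- min(z)
  amp0 <- max(z) - off0
  if (amp0 <= 0) return(NULL)
  st <- list(A = amp0, x0 = col0 - 1, y0 = row0 - 1, s = sigma0, c = off0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)) + c,
      data = cbind(grid, z = z), start = st,
      lower = c(A = 0, x0 = min(xi) - 2, y0 = min(yi) - 2,
                s = 0.35 * sigma0, c = -Inf),
      upper = c(A = Inf, x0 = max(xi), y0 = max(yi), s = 4 * sigma0,
                c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- coef(fit)
  list(amplitude = unname(p["A"]), x = unname(p["x0"]), y = unname(p["y0"]),
       sigma = unname(p["s"]), offset = unname(p["c"]),
       residual = sqrt(mean(stats::resid(fit)^2)))
}

#' Maximum-likelihood single-step change point of an intensity trace
#'
#' Fits the two-level step model (mean \code{mu_on} for frames
#' \code{1..b}, \code{mu_off} after) at every candidate \code{b} and returns
#' the residual-sum-of-squares minimizer; this is the ML estimate of the
#' bleach frame under Gaussian noise and single-step bleaching.
#'
#' @param trace numeric intensity trace.
#' @param min_frame restrict candidate step positions to frames
#'   \code{>= min_frame} (used when the step is known to occur at or after a
#'   given frame, e.g. an emitter known to survive into the current
#'   detection window; steps from earlier-bleaching neighbours are thereby
#'   excluded).
#' @return list with \code{frame}, \code{mu_on}, \code{mu_off}.
#' @export
step_change_point <- function(trace, min_frame = 1) {
  T <- length(trace)
  if (T < 2) return(list(frame = T, mu_on = mean(trace), mu_off = NA_real_))
  cs <- cumsum(trace); tot <- cs[T]
  b <- seq(max(1, min_frame), T - 1)
  m1 <- cs[b] / b
  m2 <- (tot - cs[b]) / (T - b)
  ## RSS(b) = sum(x^2) - b*m1^2 - (T-b)*m2^2; maximize the explained part
  gain <- b * m1^2 + (T - b) * m2^2
  k <- which.max(gain)
  list(frame = b[k], mu_on = m1[k], mu_off = m2[k])
}

## subtract a fitted PSF from frames 1..bleach of the working stack
.subtract_psf <- function(stack, fit, bleach) {
  H <- dim(stack)[1]; W <- dim(stack)[2]
  half <- ceiling(5 * fit$sigma)
  xi <- max(1, floor(fit$x + 1 - half)):min(W, ceiling(fit$x + 1 + half))
  yi <- max(1, floor(fit$y + 1 - half)):min(H, ceiling(fit$y + 1 + half))
  psf <- fit$amplitude *
    outer(exp(-((yi - 1 - fit$y)^2) / (2 * fit$sigma^2)),
          exp(-((xi - 1 - fit$x)^2) / (2 * fit$sigma^2)))
  for (t in seq_len(bleach)) stack[yi, xi, t] <- stack[yi, xi, t] - psf
  stack
}

#' Bleaching-assisted localization of fluorophores in a movie
#'
#' Iterative backward pass: (1) average the last \code{window} frames of the
#' current (residual) movie; (2) detect local maxima above background +
#' \code{n_sigma} robust SDs; (3) fit a 2D Gaussian to each; (4) estimate the
#' emitter's bleach frame by a single-step change point on its ROI-integrated
#' trace; (5) subtract the fitted PSF from all frames up to the bleach frame;
#' (6) when no maxima remain in the window, move the window one step earlier
#' and repeat until the start of the movie.  Non-converging fits are
#' discarded with a warning, never an error.
#'
#' @param stack movie array of dim \code{c(H, W, frames)} (>= 2 frames).
#' @param params a \code{\link{localize_params}}.
#' @return data frame of fitted emitters: \code{x}, \code{y} (0-based
#'   subpixel), \code{sigma}, \code{amplitude}, \code{bleach_frame},
#'   \code{residual}.
#' @export
bleaching_localization <- function(stack, params = localize_params()) {
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] >= 2)
  H <- dim(stack)[1]; W <- dim(stack)[2]; T <- dim(stack)[3]
  out <- list()
  work <- stack
  end <- T
  K <- min(params$window, T)
  while (end >= 1 && length(out) < params$max_emitters) {
    lo <- max(1, end - K + 1)
    img <- if (end > lo) rowMeans(work[, , lo:end, drop = FALSE], dims = 2) else
      work[, , lo]
    bg <- median(img)
    ## noise floor guards against numerically-flat (noiseless) frames
    s <- max(mad(img), 0.01 * max(bg, 1), 1e-9)
    mx <- .local_maxima(img, bg + params$n_sigma * s)
    if (!nrow(mx)) { end <- end - max(K %/% 2, 1); next }
    ## brightest first; defer maxima too close to an already-handled one
    o <- order(img[mx], decreasing = TRUE)
    mx <- mx[o, , drop = FALSE]
    handled <- matrix(numeric(0), ncol = 2)
    found <- FALSE
    for (i in seq_len(nrow(mx))) {
      if (nrow(handled) &&
          min(sqrt((handled[, 1] - mx[i, 1])^2 +
                   (handled[, 2] - mx[i, 2])^2)) < params$min_sep) next
      fit <- .fit_gaussian2d(img, mx[i, 1], mx[i, 2], params$roi,
                             params$psf_sigma)
      if (is.null(fit) ||
          !all(is.finite(c(fit$x, fit$y, fit$sigma, fit$amplitude))) ||
          fit$amplitude <= params$n_sigma * s ||
          fit$sigma < 0.5 * params$psf_sigma ||
          fit$sigma > 2.5 * params$psf_sigma) {
        warning("discarding non-converging or sub-threshold emitter fit")
        handled <- rbind(handled, mx[i, ])
        next
      }
      ## bleach frame from the ROI-integrated residual trace
      yi <- max(1, round(fit$y) + 1 - params$roi):
        min(H, round(fit$y) + 1 + params$roi)
      xi <- max(1, round(fit$x) + 1 - params$roi):
        min(W, round(fit$x) + 1 + params$roi)
      tr <- apply(work[yi, xi, , drop = FALSE], 3, sum)
      ## the emitter survived into [lo, end], so its step is at frame >= lo
      cp <- step_change_point(tr, min_frame = lo)
      if (cp$mu_on <= cp$mu_off && end < T) {
        ## a stepless emitter should have been found in the terminal
        ## window already; this is subtraction residue
        warning("discarding stepless detection away from the movie end")
        handled <- rbind(handled, mx[i, ])
        next
      }
      bleach <- if (cp$mu_on > cp$mu_off) cp$frame else T
      ## the detection window may straddle the bleach, diluting the fitted
      ## amplitude; refit on frames where the emitter is fully on
      lo2 <- max(1, bleach - K + 1)
      img2 <- if (bleach > lo2)
        rowMeans(work[, , lo2:bleach, drop = FALSE], dims = 2) else
        work[, , lo2]
      fit2 <- .fit_gaussian2d(img2, mx[i, 1], mx[i, 2], params$roi,
                              params$psf_sigma)
      if (!is.null(fit2) &&
          all(is.finite(c(fit2$x, fit2$y, fit2$sigma, fit2$amplitude))) &&
          fit2$amplitude > 0 &&
          fit2$sigma >= 0.5 * params$psf_sigma &&
          fit2$sigma <= 2.5 * params$psf_sigma &&
          sqrt((fit2$x - fit$x)^2 + (fit2$y - fit$y)^2) < params$min_sep)
        fit <- fit2
      work <- .subtract_psf(work, fit, bleach)
      out[[length(out) + 1]] <-
        data.frame(x = fit$x, y = fit$y, sigma = fit$sigma,
                   amplitude = fit$amplitude, bleach_frame = bleach,
                   residual = fit$residual)
      handled <- rbind(handled, mx[i, ])
      found <- TRUE
      if (length(out) >= params$max_emitters) break
    }
    if (!found) end <- end - max(K %/% 2, 1)
  }
  if (!length(out))
    return(data.frame(x = numeric(), y = numeric(), sigma = numeric(),
                      amplitude = numeric(), bleach_frame = integer(),
                      residual = numeric()))
  res <- do.call(rbind, out)
  ## drop near-duplicates: subtraction residue occasionally re-fits the
  ## same emitter; a later fit within min_sep of an earlier one with a
  ## similar bleach frame is residue, not a new fluorophore
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1]) {
    prev <- which(keep[seq_len(i - 1)])
    d <- sqrt((res$x[prev] - res$x[i])^2 + (res$y[prev] - res$y[i])^2)
    close <- d < params$min_sep &
      abs(res$bleach_frame[prev] - res$bleach_frame[i]) <= 2 * K
    if (any(close)) keep[i] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res[order(-res$bleach_frame), , drop = FALSE]
}

#' Mask reconstruction parameters
#'
#' @param bin_px super-resolution bin size in px of the original frame.
#' @param threshold \code{"otsu"} or a fixed minimum localization count per
#'   bin.
#' @param min_area,max_area accepted component area bounds, in bins.
#' @param circ_min minimum circularity \code{4*pi*A/P^2} for acceptance.
#' @param dilate number of 3x3 binary dilation passes applied before hole
#'   filling; closes small gaps in the binarized backbone and extends the
#'   mask so labels sitting on the contour fall within it.
#' @return an object of class \code{"mask_params"}.
#' @export
mask_params <- function(bin_px = 1, threshold = 1, min_area = 20,
                        max_area = Inf, circ_min = 0.6, dilate = 1) {
  structure(list(bin_px = bin_px, threshold = threshold,
                 min_area = min_area, max_area = max_area,
                 circ_min = circ_min, dilate = as.integer(dilate)),
            class = "mask_params")
}

## perimeter as exposed 4-neighbour pixel edges, scaled by pi/4 (Cauchy-
## Crofton style isotropic correction; exact for disks)
.perimeter <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb <- pad[1:H, 2:(W + 1)] + pad[3:(H + 2), 2:(W + 1)] +
    pad[2:(H + 1), 1:W] + pad[2:(H + 1), 3:(W + 2)]
  sum((4L - nb)[core == 1L]) * pi / 4
}

#' Reconstruct plasmid masks from backbone localizations
#'
#' Bins the localization set into a super-resolution 2D histogram, applies a
#' threshold (fixed count or Otsu), fills holes (a plasmid backbone is a
#' ring), labels connected components, and computes per-component area,
#' perimeter and circularity \code{4*pi*A/P^2} (clamped at 1.05).  A
#' component is accepted when its circularity is at least \code{circ_min}
#' and its area lies within the configured bounds.
#'
#' @param locs data frame of localizations with columns \code{x}, \code{y}
#'   (same px coordinate frame as the emitters).
#' @param params a \code{\link{mask_params}}.
#' @param field optional \code{c(width, height)} of the field in px;
#'   defaults to the localization extent.
#' @return a list of \code{plasmid_mask} objects (id, area, perimeter,
#'   circularity, accepted, centroid_x, centroid_y) with attributes
#'   \code{"labels"} (labeled bin image) and \code{"bin_px"}.
#' @export
reconstruct_masks <- function(locs, params = mask_params(), field = NULL) {
  if (is.null(locs) || nrow(locs) == 0) return(list())
  if (is.null(field)) field <- c(ceiling(max(locs$x)) + 2,
                                 ceiling(max(locs$y)) + 2)
  nx <- ceiling(field[1] / params$bin_px)
  ny <- ceiling(field[2] / params$bin_px)
  ix <- pmin(pmax(floor(locs$x / params$bin_px), 0), nx - 1) + 1L
  iy <- pmin(pmax(floor(locs$y / params$bin_px), 0), ny - 1) + 1L
  hist2 <- matrix(0L, nrow = ny, ncol = nx)
  for (i in seq_along(ix)) hist2[iy[i], ix[i]] <- hist2[iy[i], ix[i]] + 1L
  if (identical(params$threshold, "otsu")) {
    img <- hist2 / max(hist2)
    th <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    bin <- (img > th) + 0L
  } else {
    bin <- (hist2 >= params$threshold) + 0L
  }
  bin <- EBImage::Image(bin)
  if (params$dilate > 0) {
    brush <- EBImage::makeBrush(3, shape = "box")
    for (i in seq_len(params$dilate)) bin <- EBImage::dilate(bin, brush)
  }
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  labm <- EBImage::imageData(lab)
  nobj <- max(labm)
  if (nobj == 0) return(list())
  masks <- vector("list", nobj)
  for (k in seq_len(nobj)) {
    mk <- (labm == k) + 0L
    A <- sum(mk)
    P <- .perimeter(mk)
    circ <- min(4 * pi * A / P^2, 1.05)
    idx <- which(mk == 1L, arr.ind = TRUE)
    masks[[k]] <- structure(list(
      id = k, area = A, perimeter = P, circularity = circ,
      accepted = circ >= params$circ_min && A >= params$min_area &&
        A <= params$max_area,
      centroid_x = (mean(idx[, 2]) - 0.5) * params$bin_px,
      centroid_y = (mean(idx[, 1]) - 0.5) * params$bin_px),
      class = "plasmid_mask")
  }
  attr(masks, "labels") <- labm
  attr(masks, "bin_px") <- params$bin_px
  masks
}

#' Count labels per plasmid
#'
#' Assigns each emitter to the accepted mask whose footprint contains it
#' (point-in-mask on the super-resolution grid); emitters falling in no
#' accepted mask are ignored.  The histogram runs over all accepted plasmids
#' including those with zero labels; \code{mean} is total labels divided by
#' the number of plasmids and \code{sem} is \code{sd(counts)/sqrt(n)}.
#'
#' @param masks result of \code{\link{reconstruct_masks}}.
#' @param emitters data frame with emitter coordinates \code{x}, \code{y}
#'   in the same frame as the localizations.
#' @return an object of class \code{"label_count_summary"}: list with
#'   \code{counts} (per accepted plasmid), \code{histogram} (table),
#'   \code{n_plasmids}, \code{mean}, \code{sem}, \code{n_unassigned}.
#' @export
count_labels <- function(masks, emitters) {
  accepted <- Filter(function(m) m$accepted, masks)
  ids <- vapply(accepted, function(m) m$id, integer(1))
  counts <- stats::setNames(rep(0L, length(ids)), ids)
  unassigned <- 0L
  if (!is.null(emitters) && nrow(emitters) && length(ids)) {
    labm <- attr(masks, "labels")
    bin <- attr(masks, "bin_px")
    iy <- pmin(pmax(floor(emitters$y / bin), 0), nrow(labm) - 1) + 1L
    ix <- pmin(pmax(floor(emitters$x / bin), 0), ncol(labm) - 1) + 1L
    lab <- labm[cbind(iy, ix)]
    for (l in lab) {
      if (l > 0 && as.character(l) %in% names(counts))
        counts[as.character(l)] <- counts[as.character(l)] + 1L
      else unassigned <- unassigned + 1L
    }
  } else if (!is.null(emitters)) {
    unassigned <- nrow(emitters)
  }
  label_count_summary(as.integer(counts), n_unassigned = unassigned)
}

#' Build a label-count summary from per-plasmid counts
#'
#' @param counts integer vector of per-plasmid label counts.
#' @param n_unassigned emitters outside every accepted plasmid.
#' @return an object of class \code{"label_count_summary"}.
#' @export
label_count_summary <- function(counts, n_unassigned = 0L) {
  n <- length(counts)
  structure(list(
    counts = as.integer(counts),
    histogram = if (n) table(factor(counts, levels = 0:max(counts, 0))) else
      table(integer()),
    n_plasmids = n,
    mean = if (n) sum(counts) / n else NA_real_,
    sem = if (n > 1) sd(counts) / sqrt(n) else if (n == 1) 0 else NA_real_,
    n_unassigned = as.integer(n_unassigned)),
    class = "label_count_summary")
}

#' @export
print.label_count_summary <- function(x, ...) {
  cat(sprintf("label_count_summary: %d plasmids, mean %.3f +- %.3f labels/plasmid (%d unassigned)\n",
              x$n_plasmids, x$mean, x$sem, x$n_unassigned))
  invisible(x)
}
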