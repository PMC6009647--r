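## Photobleaching-movie simulation: single-step bleaching, Gaussian PSF,
## Poisson shot noise plus Gaussian read noise.

#' Movie simulation configuration
#'
#' @param pixel_nm pixel size in nm (metadata only).
#' @param psf_sigma PSF standard deviation in px (>= 0.5).
#' @param n_frames number of frames.
#' @param photons mean photon count per emitter per frame (PSF integral).
#' @param bleach_mean mean single-step bleach lifetime in frames; emitter
#'   bleach frames are drawn geometrically unless fixed per emitter.
#' @param background background level, photons per pixel per frame.
#' @param read_noise Gaussian read-noise SD, photons.
#' @param field field size in px, \code{c(width, height)}.
#' @param shot_noise apply Poisson shot noise (disable for noiseless tests).
#' @param seed RNG seed.
#' @return an object of class \code{"movie_config"}.
#' @export
movie_config <- function(pixel_nm = 100, psf_sigma = 1.2, n_frames = 200,
                         photons = 2000, bleach_mean = 80, background = 20,
                         read_noise = 2, field = c(32, 32),
                         shot_noise = TRUE, seed = 1) {
  stopifnot(pixel_nm > 0, psf_sigma >= 0.5, n_frames >= 1, photons > 0,
            bleach_mean > 0, background >= 0, read_noise >= 0,
            all(field >= 4))
  structure(list(pixel_nm = pixel_nm, psf_sigma = psf_sigma,
                 n_frames = as.integer(n_frames), photons = photons,
                 bleach_mean = bleach_mean, background = background,
                 read_noise = read_noise, field = as.integer(field),
                 shot_noise = shot_noise, seed = as.integer(seed)),
            class = "movie_config")
}

## noiseless image of a set of emitters: normalized 2D Gaussian PSF so that
## each emitter contributes `photons` photons per frame in total
.render_emitters <- function(x, y, photons, sigma, W, H) {
  img <- matrix(0, nrow = H, ncol = W)
  if (!length(x)) return(img)
  half <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    cx <- x[i]; cy <- y[i]
    xi <- max(1, floor(cx + 1 - half)):min(W, ceiling(cx + 1 + half))
    yi <- max(1, floor(cy + 1 - half)):min(H, ceiling(cy + 1 + half))
    gx <- dnorm(xi - 1, cx, sigma)
    gy <- dnorm(yi - 1, cy, sigma)
    img[yi, xi] <- img[yi, xi] + photons[i] * outer(gy, gx)
  }
  img
}

#' Simulate a single-step photobleaching movie
#'
#' Frame \code{t} is the sum of the PSFs of all emitters still active at
#' \code{t} (an emitter is on for frames \code{1..bleach_frame} and off
#' after, with no blinking) plus the background, with optional Poisson shot
#' noise and Gaussian read noise.  Emitters without a \code{bleach_frame}
#' get one drawn geometrically with mean \code{bleach_mean}.
#'
#' @param emitters data frame with columns \code{x}, \code{y} (subpixel
#'   coordinates, 0-based, x = column, y = row) and optionally
#'   \code{brightness} (photons/frame) and \code{bleach_frame}.
#' @param mcfg a \code{\link{movie_config}}.
#' @return a numeric array of dim \code{c(H, W, n_frames)} with attribute
#'   \code{"emitters"} holding the completed ground-truth emitter table.
#' @export
simulate_movie <- function(emitters, mcfg) {
  W <- mcfg$field[1]; H <- mcfg$field[2]
  n <- nrow(emitters)
  if (n > 0 && (any(emitters$x < 0 | emitters$x > W - 1) ||
                any(emitters$y < 0 | emitters$y > H - 1)))
    stop("emitter outside field")
  .with_stream(mcfg$seed, "movie", {
    if (n > 0) {
      if (is.null(emitters$brightness))
        emitters$brightness <- rep(mcfg$photons, n)
      if (is.null(emitters$bleach_frame))
        emitters$bleach_frame <- pmin(1L + rgeom(n, 1 / mcfg$bleach_mean),
                                      mcfg$n_frames)
      emitters$bleach_frame <- as.integer(emitters$bleach_frame)
    }
    stack <- array(0, dim = c(H, W, mcfg$n_frames))
    ## frames between bleach events share the same noiseless image
    bounds <- sort(unique(c(0L, if (n) pmin(emitters$bleach_frame, mcfg$n_frames),
                            mcfg$n_frames)))
    for (b in seq_len(length(bounds) - 1)) {
      lo <- bounds[b] + 1L; hi <- bounds[b + 1]
      act <- if (n) which(emitters$bleach_frame >= lo) else integer()
      img <- .render_emitters(emitters$x[act], emitters$y[act],
                              emitters$brightness[act], mcfg$psf_sigma,
                              W, H) + mcfg$background
      for (t in lo:hi) {
        fr <- if (mcfg$shot_noise)
          matrix(rpois(H * W, img), nrow = H) else img
        if (mcfg$read_noise > 0)
          fr <- fr + matrix(rnorm(H * W, 0, mcfg$read_noise), nrow = H)
        stack[, , t] <- fr
      }
    }
    attr(stack, "emitters") <- if (n) emitters else
      data.frame(x = numeric(), y = numeric(), brightness = numeric(),
                 bleach_frame = integer())
    stack
  })
}

#' Write a movie stack as multi-frame TIFF
#'
#' Intensities are photon counts: frames are rounded to integers, clamped to
#' [0, 65535] and written as 16-bit TIFF (camera-style storage).
#'
#' @param stack array of dim \code{c(H, W, frames)}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_movie <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]), function(t)
    pmin(pmax(round(stack[, , t]), 0), 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' Read a multi-frame TIFF movie
#' @param path TIFF path written by \code{\link{write_movie}}.
#' @return array of dim \code{c(H, W, frames)}, photon counts.
#' @export
read_movie <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                          length(frames)))
  for (t in seq_along(frames)) arr[, , t] <- round(frames[[t]] * 65535)
  arr
}
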