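## Synthetic-data generator: labeled/stretched molecules, plasmid fields and
## kinetic time courses, all with ground truth.  One master seed; each stage
## draws from a deterministically derived child stream so that stages are
## reproducible independently of one another.

## derive a 31-bit child seed from the master seed and a stream label
.child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}

.with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.child_seed(seed, stream))
  expr
}

#' Simulation configuration
#'
#' Holds the statistical regime of a labeling experiment.  The defaults are
#' the combed-fragment regime (per-site labeling probability 0.92, off-target
#' density 0.46 labels/kb, stretch 1.6 with 0.1 fractional variation,
#' localization error 100 bp, random orientation); the \code{"plasmid"}
#' preset switches to the plasmid counting regime (0.63, 0.37 labels/kb).
#'
#' @param preset \code{"combed-fragment"} or \code{"plasmid"}.
#' @param p_site per-site labeling probability in [0, 1].
#' @param p_second probability that the second strand of a labeled
#'   palindromic site is also alkylated-and-labeled (double-strand mode;
#'   conditional on the first label, so the per-site fluorophore count is 1 +
#'   Bernoulli(p_second) when the site is labeled).
#' @param rho_off off-target label density, labels per kb (homogeneous
#'   Poisson along the molecule).
#' @param sigma_loc localization error SD in bp, applied to true positions
#'   before stretch conversion.
#' @param stretch_mean per-molecule stretch factor (physical length of 1 bp
#'   = \code{nm_per_bp * stretch}).
#' @param stretch_tol fractional stretch variation around
#'   \code{stretch_mean}.
#' @param stretch_dist \code{"tnorm"}: per-molecule stretch ~
#'   Normal(stretch_mean, stretch_mean * stretch_tol) truncated at +-2
#'   tolerances; \code{"uniform"}: uniform on stretch_mean * (1 +- stretch_tol).
#' @param nm_per_bp physical conversion at stretch 1 (0.34 nm/bp).
#' @param flip_prob probability a molecule is deposited reversed.
#' @param n_molecules number of molecules to simulate.
#' @param seed master RNG seed.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(preset = c("combed-fragment", "plasmid"),
                       p_site = NULL, p_second = 0, rho_off = NULL,
                       sigma_loc = 100, stretch_mean = 1.6,
                       stretch_tol = 0.1,
                       stretch_dist = c("tnorm", "uniform"),
                       nm_per_bp = 0.34, flip_prob = 0.5,
                       n_molecules = 100, seed = 1) {
  preset <- match.arg(preset)
  stretch_dist <- match.arg(stretch_dist)
  if (is.null(p_site)) p_site <- if (preset == "plasmid") 0.63 else 0.92
  if (is.null(rho_off)) rho_off <- if (preset == "plasmid") 0.37 else 0.46
  stopifnot(p_site >= 0, p_site <= 1, p_second >= 0, p_second <= 1,
            rho_off >= 0, sigma_loc >= 0, stretch_tol >= 0, stretch_tol < 1,
            stretch_mean * (1 - stretch_tol) > 0, nm_per_bp > 0,
            flip_prob >= 0, flip_prob <= 1)
  structure(list(preset = preset, p_site = p_site, p_second = p_second,
                 rho_off = rho_off, sigma_loc = sigma_loc,
                 stretch_mean = stretch_mean, stretch_tol = stretch_tol,
                 stretch_dist = stretch_dist, nm_per_bp = nm_per_bp,
                 flip_prob = flip_prob,
                 n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config (%s): p_site %.2f, p_second %.2f, ",
                     "rho_off %.2f/kb, sigma_loc %g bp\n  stretch %.2f +- %.0f%% (%s), ",
                     "%.2f nm/bp, flip %.2f, n %d, seed %d\n"),
              x$preset, x$p_site, x$p_second, x$rho_off, x$sigma_loc,
              x$stretch_mean, 100 * x$stretch_tol, x$stretch_dist,
              x$nm_per_bp, x$flip_prob, x$n_molecules, x$seed))
  invisible(x)
}

.draw_stretch <- function(n, cfg) {
  if (cfg$stretch_tol == 0) return(rep(cfg$stretch_mean, n))
  if (cfg$stretch_dist == "uniform") {
    runif(n, cfg$stretch_mean * (1 - cfg$stretch_tol),
          cfg$stretch_mean * (1 + cfg$stretch_tol))
  } else {
    lo <- cfg$stretch_mean * (1 - 2 * cfg$stretch_tol)
    hi <- cfg$stretch_mean * (1 + 2 * cfg$stretch_tol)
    s <- rnorm(n, cfg$stretch_mean, cfg$stretch_mean * cfg$stretch_tol)
    while (any(bad <- s < lo | s > hi))
      s[bad] <- rnorm(sum(bad), cfg$stretch_mean,
                      cfg$stretch_mean * cfg$stretch_tol)
    s
  }
}

#' Simulate labeled, stretched molecules
#'
#' Per molecule: each reference site is labeled with probability
#' \code{p_site}; when \code{p_second > 0}, a labeled site additionally
#' carries a second-strand label with probability \code{p_second}, offset by
#' the motif width.  Off-target labels follow a homogeneous Poisson process
#' with density \code{rho_off} per kb at uniform positions.  True bp
#' positions are perturbed by Gaussian localization noise (SD
#' \code{sigma_loc} bp), converted to physical coordinates via
#' \code{pos_nm = bp * nm_per_bp * stretch} with a per-molecule stretch, and
#' mirrored with probability \code{flip_prob}.
#'
#' @param refmap a \code{\link{reference_map}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return a list with \code{traces} (list of \code{molecule_trace}: id,
#'   sorted \code{positions_nm}, \code{length_nm}) and \code{truth} (list of
#'   \code{molecule_truth}: realized \code{stretch}, \code{flipped}, data
#'   frame \code{on_site} of (site, bp), numeric \code{off_site} bp).
#' @export
simulate_molecules <- function(refmap, cfg) {
  if (cfg$n_molecules <= 0) stop("n_molecules must be positive")
  L <- refmap$length
  sites <- refmap$sites$position
  w <- nchar(refmap$motif)
  .with_stream(cfg$seed, "molecules", {
    traces <- vector("list", cfg$n_molecules)
    truth <- vector("list", cfg$n_molecules)
    stretches <- .draw_stretch(cfg$n_molecules, cfg)
    for (m in seq_len(cfg$n_molecules)) {
      lab1 <- which(runif(length(sites)) < cfg$p_site)
      on_site <- data.frame(site = lab1, bp = sites[lab1])
      if (cfg$p_second > 0 && length(lab1)) {
        second <- lab1[runif(length(lab1)) < cfg$p_second]
        if (length(second))
          on_site <- rbind(on_site,
                           data.frame(site = second, bp = sites[second] + w))
      }
      n_off <- rpois(1, cfg$rho_off * L / 1000)
      off <- sort(runif(n_off, 0, L))
      true_bp <- c(on_site$bp, off)
      obs_bp <- true_bp + rnorm(length(true_bp), 0, cfg$sigma_loc)
      s <- stretches[m]
      len_nm <- L * cfg$nm_per_bp * s
      pos_nm <- pmin(pmax(obs_bp * cfg$nm_per_bp * s, 0), len_nm)
      flipped <- runif(1) < cfg$flip_prob
      if (flipped) pos_nm <- len_nm - pos_nm
      traces[[m]] <- structure(list(molecule = m,
                                    positions_nm = sort(pos_nm),
                                    length_nm = len_nm),
                               class = "molecule_trace")
      truth[[m]] <- structure(list(molecule = m, stretch = s,
                                   flipped = flipped, on_site = on_site,
                                   off_site = off),
                              class = "molecule_truth")
    }
    list(traces = traces, truth = truth)
  })
}

#' Mirror a molecule trace
#'
#' Reverses the coordinate axis of a trace (positions become
#' \code{length_nm - positions}, re-sorted); mirroring twice restores the
#' original.
#'
#' @param trace a \code{molecule_trace}.
#' @return the mirrored \code{molecule_trace}.
#' @export
mirror_trace <- function(trace) {
  trace$positions_nm <- sort(trace$length_nm - trace$positions_nm)
  trace
}

#' Flatten molecule traces to a data frame
#' @param traces list of \code{molecule_trace}.
#' @return data frame with columns \code{molecule_id}, \code{position_nm},
#'   \code{molecule_length_nm}.
#' @export
traces_to_df <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    n <- length(tr$positions_nm)
    data.frame(molecule_id = rep(tr$molecule, n),
               position_nm = tr$positions_nm,
               molecule_length_nm = rep(tr$length_nm, n))
  }))
}

#' Write molecule traces as CSV
#' @param traces list of \code{molecule_trace}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- traces_to_df(traces)
  if (is.null(df))
    df <- data.frame(molecule_id = integer(), position_nm = numeric(),
                     molecule_length_nm = numeric())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read molecule traces from CSV
#' @param path CSV written by \code{\link{write_traces}}.
#' @return list of \code{molecule_trace}.
#' @export
read_traces <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$molecule_id), function(d) {
    structure(list(molecule = d$molecule_id[1],
                   positions_nm = sort(d$position_nm),
                   length_nm = d$molecule_length_nm[1]),
              class = "molecule_trace")
  })
}

#' Simulate a two-channel plasmid field
#'
#' Each plasmid is rendered as a closed, roughly circular contour of backbone
#' localization points (the intercalator channel) at a random field position;
#' its fluorophore count is drawn from the site/off-target model of
#' \code{\link{simulate_molecules}} and the emitters are collapsed onto the
#' contour.  A configurable fraction of non-circular (linear) decoys is added
#' for testing the circularity filter; decoys are flagged in the truth table
#' and excluded from truth counts.
#'
#' @param refmap a \code{\link{reference_map}} (the plasmid).
#' @param cfg a \code{\link{sim_config}}; \code{p_site}, \code{p_second} and
#'   \code{rho_off} set the label-count model.
#' @param n_plasmids number of (circular) plasmids.
#' @param field field size in px, \code{c(width, height)}.
#' @param radius_px mean plasmid contour radius, px.
#' @param decoy_frac fraction of additional linear decoy objects.
#' @param n_backbone backbone localizations per object.
#' @param jitter_px localization scatter around the contour, px.
#' @param min_sep_px minimum centre-to-centre separation; a packing failure
#'   after many rejection-sampling attempts is an error.
#' @return list with \code{backbone} (data frame x, y, object),
#'   \code{emitters} (data frame object, x, y), and \code{truth} (data frame
#'   object, x, y, radius, n_labels, decoy).
#' @export
simulate_plasmid_field <- function(refmap, cfg, n_plasmids,
                                   field = c(64, 64), radius_px = 5,
                                   decoy_frac = 0, n_backbone = 250,
                                   jitter_px = 0.3, min_sep_px = NULL) {
  if (n_plasmids < 0) stop("n_plasmids must be >= 0")
  n_decoy <- round(n_plasmids * decoy_frac)
  n_obj <- n_plasmids + n_decoy
  if (is.null(min_sep_px)) min_sep_px <- 2.5 * radius_px
  empty <- list(backbone = data.frame(x = numeric(), y = numeric(),
                                      object = integer()),
                emitters = data.frame(object = integer(), x = numeric(),
                                      y = numeric()),
                truth = data.frame(object = integer(), x = numeric(),
                                   y = numeric(), radius = numeric(),
                                   n_labels = integer(), decoy = logical()))
  if (n_obj == 0) return(empty)
  sites <- refmap$sites$position
  .with_stream(cfg$seed, "field", {
    margin <- 2 * radius_px + 2
    cx <- numeric(0); cy <- numeric(0)
    for (i in seq_len(n_obj)) {
      ok <- FALSE
      for (try in 1:2000) {
        x <- runif(1, margin, field[1] - margin)
        y <- runif(1, margin, field[2] - margin)
        if (!length(cx) || min(sqrt((cx - x)^2 + (cy - y)^2)) >= min_sep_px) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("generation error: could not place objects at this density (packing limit)")
      cx <- c(cx, x); cy <- c(cy, y)
    }
    is_decoy <- c(rep(FALSE, n_plasmids), rep(TRUE, n_decoy))
    backbone <- list(); emitters <- list()
    n_labels <- integer(n_obj)
    radius <- numeric(n_obj)
    for (i in seq_len(n_obj)) {
      r <- radius_px * runif(1, 0.85, 1.15)
      radius[i] <- r
      if (is_decoy[i]) {
        ang <- runif(1, 0, pi)
        t <- runif(n_backbone, -2 * r, 2 * r)
        bx <- cx[i] + t * cos(ang) + rnorm(n_backbone, 0, jitter_px)
        by <- cy[i] + t * sin(ang) + rnorm(n_backbone, 0, jitter_px)
      } else {
        th <- runif(n_backbone, 0, 2 * pi)
        rr <- r * (1 + rnorm(n_backbone, 0, 0.05))
        bx <- cx[i] + rr * cos(th) + rnorm(n_backbone, 0, jitter_px)
        by <- cy[i] + rr * sin(th) + rnorm(n_backbone, 0, jitter_px)
      }
      backbone[[i]] <- data.frame(x = bx, y = by, object = i)
      k1 <- sum(runif(length(sites)) < cfg$p_site)
      k2 <- if (cfg$p_second > 0 && k1 > 0)
        sum(runif(k1) < cfg$p_second) else 0L
      k <- k1 + k2 + rpois(1, cfg$rho_off * refmap$length / 1000)
      n_labels[i] <- k
      if (k > 0) {
        th <- runif(k, 0, 2 * pi)
        emitters[[i]] <- data.frame(object = i,
                                    x = cx[i] + r * cos(th),
                                    y = cy[i] + r * sin(th))
      }
    }
    list(backbone = do.call(rbind, backbone),
         emitters = if (length(emitters)) do.call(rbind, emitters) else
           empty$emitters,
         truth = data.frame(object = seq_len(n_obj), x = cx, y = cy,
                            radius = radius, n_labels = n_labels,
                            decoy = is_decoy))
  })
}

#' Simulate a labeling time course
#'
#' Pseudo-first-order site occupancy: at reaction time \code{t} the per-site
#' labeling probability is \code{p_inf * (1 - exp(-k t))}; label counts per
#' plasmid are the site count draw plus the off-target Poisson draw of the
#' \code{\link{simulate_molecules}} model.
#'
#' @param times reaction times in minutes (>= 0).
#' @param k pseudo-first-order rate constant, 1/min (default the combed-
#'   fragment estimate 0.28/min).
#' @param p_inf plateau per-site labeling probability.
#' @param refmap a \code{\link{reference_map}}.
#' @param cfg a \code{\link{sim_config}} (supplies \code{rho_off},
#'   \code{p_second} and the seed).
#' @param n_per_time plasmids sampled per time point.
#' @return list with \code{times}, \code{counts} (list of integer vectors,
#'   one per time) and \code{truth} (list with k, p_inf).
#' @export
simulate_kinetics <- function(times, k = 0.28, p_inf = 0.875, refmap, cfg,
                              n_per_time = 300) {
  if (any(times < 0)) stop("negative time")
  if (k <= 0) stop("k must be positive")
  S <- n_sites(refmap)
  lam <- cfg$rho_off * refmap$length / 1000
  .with_stream(cfg$seed, "kinetics", {
    counts <- lapply(times, function(t) {
      p <- p_inf * (1 - exp(-k * t))
      k1 <- rbinom(n_per_time, S, p)
      k2 <- if (cfg$p_second > 0) rbinom(n_per_time, k1, cfg$p_second) else 0L
      k1 + k2 + rpois(n_per_time, lam)
    })
    list(times = times, counts = counts, truth = list(k = k, p_inf = p_inf))
  })
}

#' Generate a synthetic DNA sequence with motif sites at given positions
#'
#' Builds a random A/C/G/T sequence that contains the motif exactly at the
#' requested 0-based positions and nowhere else on either strand.  Used to
#' construct synthetic stand-ins for published sequences (for example a
#' pUC19-like 2686 bp plasmid with four TCGA sites, or a 5 kb amplicon with
#' nine sites); optionally plants unique primer annealing sequences for
#' in-silico PCR.
#'
#' @param length sequence length, bp.
#' @param motif motif to plant.
#' @param site_positions 0-based motif start positions (non-overlapping).
#' @param seed RNG seed.
#' @param fwd_primer,rev_primer optional primers; the forward primer is
#'   planted at \code{amplicon_start} and the reverse-primer binding site
#'   ends at \code{amplicon_end} (0-based, exclusive).
#' @param amplicon_start,amplicon_end amplicon bounds used when primers are
#'   given.
#' @return the sequence as a character string.
#' @export
synthetic_sequence <- function(length, motif = "TCGA", site_positions,
                               seed = 1, fwd_primer = NULL, rev_primer = NULL,
                               amplicon_start = 0, amplicon_end = length) {
  .check_dna(motif, "motif")
  w <- nchar(motif)
  site_positions <- sort(as.integer(site_positions))
  if (any(diff(site_positions) < w)) stop("site positions overlap")
  if (length(site_positions) &&
      (min(site_positions) < 0 || max(site_positions) > length - w))
    stop("site positions out of range")
  rc <- .revcomp(motif)
  .with_stream(seed, "synthseq", {
    repeat {
      seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                   collapse = "")
      for (p in site_positions)
        substr(seq, p + 1L, p + w) <- motif
      if (!is.null(fwd_primer)) {
        .check_dna(fwd_primer, "fwd_primer"); .check_dna(rev_primer, "rev_primer")
        substr(seq, amplicon_start + 1L,
               amplicon_start + nchar(fwd_primer)) <- fwd_primer
        rcp <- .revcomp(rev_primer)
        substr(seq, amplicon_end - nchar(rcp) + 1L, amplicon_end) <- rcp
      }
      hits <- .match_starts(motif, seq)
      if (rc != motif) hits <- c(hits, .match_starts(rc, seq))
      extra <- setdiff(hits, site_positions)
      if (!length(extra)) {
        if (!is.null(fwd_primer)) {
          if (length(.match_starts(fwd_primer, seq)) != 1) next
          if (length(.match_starts(.revcomp(rev_primer), seq)) != 1) next
        }
        return(seq)
      }
      ## scrub spurious occurrences by mutating one base inside each, then
      ## re-verify (planting could re-create sites at junctions)
      for (p in extra) {
        i <- p + sample.int(w, 1)
        old <- substr(seq, i, i)
        substr(seq, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
      hits <- .match_starts(motif, seq)
      if (rc != motif) hits <- c(hits, .match_starts(rc, seq))
      ok_sites <- all(site_positions %in% hits) &&
        !length(setdiff(hits, site_positions))
      ok_primers <- is.null(fwd_primer) ||
        (length(.match_starts(fwd_primer, seq)) == 1 &&
         length(.match_starts(.revcomp(rev_primer), seq)) == 1)
      if (ok_sites && ok_primers) return(seq)
    }
  })
}
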