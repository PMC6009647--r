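## Summary statistics: saturation kinetics, the Poisson zero-class bound on
## non-specific binding, fold changes and site-count titration regression.

#' Fit pseudo-first-order labeling kinetics
#'
#' Nonlinear least squares of the saturating time course
#' \code{N(t) = plateau * (1 - exp(-k' t))} to per-time mean label counts
#' (optionally with a fitted constant baseline for data that include an
#' off-target floor).  Initialization: \code{plateau0 = max(means)}, with
#' \code{k0} from a log-linear regression of \code{1 - N/plateau0};
#' convergence tolerance 1e-8 on the parameters.
#'
#' @param times reaction times, minutes (>= 3 distinct values, >= 0).
#' @param means mean labels per plasmid at each time.
#' @param baseline also fit an additive constant \code{b0}.
#' @return an object of class \code{"kinetics_fit"}: list with
#'   \code{k_prime} (1/min), \code{plateau}, \code{baseline},
#'   \code{residual_norm}, \code{cov} (covariance of (k', plateau)).
#' @export
fit_pseudo_first_order <- function(times, means, baseline = FALSE) {
  if (length(times) != length(means)) stop("times/means length mismatch")
  if (length(unique(times)) < 3) stop("need >= 3 distinct time points")
  if (any(times < 0)) stop("negative time")
  if (all(means <= 0)) stop("fitting error: all means are zero (degenerate)")
  b0 <- if (baseline) min(means) else 0
  plateau0 <- max(means) - b0
  ## log-linear initial rate from the rising part
  frac <- 1 - (means - b0) / (plateau0 * 1.05)
  ok <- frac > 1e-6 & times > 0
  k0 <- if (sum(ok) >= 2) {
    sl <- coef(lm(log(frac[ok]) ~ 0 + times[ok]))[1]
    max(-sl, 1e-3)
  } else 0.1
  df <- data.frame(t = times, y = means)
  fit <- tryCatch({
    if (baseline)
      minpack.lm::nlsLM(y ~ b + A * (1 - exp(-k * t)), data = df,
                        start = list(A = plateau0, k = k0, b = b0),
                        lower = c(A = 0, k = 1e-6, b = 0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ptol = 1e-8))
    else
      minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = df,
                        start = list(A = plateau0, k = k0),
                        lower = c(A = 0, k = 1e-6),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ptol = 1e-8))
  }, error = function(e)
    stop(sprintf("fitting error (init plateau %.3g, k %.3g): %s",
                 plateau0, k0, conditionMessage(e))))
  p <- coef(fit)
  v <- tryCatch(vcov(fit), error = function(e)
    matrix(NA_real_, length(p), length(p)))
  structure(list(k_prime = unname(p["k"]), plateau = unname(p["A"]),
                 baseline = if (baseline) unname(p["b"]) else 0,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 cov = v[c("k", "A"), c("k", "A")]),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("kinetics_fit: k' = %.4f /min, plateau = %.3f labels/plasmid",
              x$k_prime, x$plateau))
  if (x$baseline != 0) cat(sprintf(", baseline = %.3f", x$baseline))
  cat(sprintf(" (residual norm %.3g)\n", x$residual_norm))
  invisible(x)
}

#' Poisson zero-class bound on non-specific labeling
#'
#' From the fraction \code{f_zero} of molecules carrying zero fluorophores,
#' the Poisson count model gives a mean of \code{lambda = -log(f_zero)}
#' labels per molecule, hence one non-specific fluorophore per
#' \code{length_kb / lambda} kb of DNA.  The cruder odds form
#' \code{length_kb * f_zero / (1 - f_zero)} is available via \code{method}.
#'
#' @param f_zero fraction of molecules with zero labels, in (0, 1].
#' @param length_kb molecule length in kb.
#' @param method \code{"poisson"} (default) or \code{"odds"}.
#' @return kb of DNA per non-specific fluorophore; \code{Inf} when
#'   \code{f_zero = 1}.
#' @examples
#' poisson_zero_bound(0.97, 2.6)  # ~85 kb per fluorophore
#' @export
poisson_zero_bound <- function(f_zero, length_kb,
                               method = c("poisson", "odds")) {
  method <- match.arg(method)
  if (f_zero <= 0 || f_zero > 1) stop("f_zero must be in (0, 1]")
  if (length_kb <= 0) stop("length_kb must be positive")
  if (f_zero == 1) return(Inf)
  if (method == "poisson") length_kb / (-log(f_zero))
  else length_kb * f_zero / (1 - f_zero)
}

#' Fold change between two means
#'
#' @param mean_a numerator mean.
#' @param mean_b denominator mean (> 0).
#' @return \code{mean_a / mean_b}.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (mean_b <= 0) stop("mean_b must be positive")
  mean_a / mean_b
}

#' Site-count titration regression
#'
#' Ordinary least squares of mean labels per plasmid on the number of
#' recognition sites; the slope estimates the per-site labeling efficiency
#' and the intercept the mean number of off-target labels per plasmid
#' ("sites plus one" when both are ~1).
#'
#' @param site_counts recognition sites per construct (>= 2 distinct).
#' @param mean_labels mean labels per plasmid per construct.
#' @return an object of class \code{"titration_fit"}: list with
#'   \code{slope}, \code{intercept}, \code{slope_se}, \code{intercept_se},
#'   and the underlying \code{lm} fit.
#' @export
titration_regression <- function(site_counts, mean_labels) {
  if (length(site_counts) != length(mean_labels))
    stop("length mismatch")
  if (length(unique(site_counts)) < 2)
    stop("input error: need >= 2 distinct site counts (rank deficient)")
  fit <- lm(mean_labels ~ site_counts)
  ## exact collinear input is legitimate; silence lm's perfect-fit warning
  cf <- suppressWarnings(summary(fit)$coefficients)
  structure(list(slope = unname(cf["site_counts", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 slope_se = unname(cf["site_counts", "Std. Error"]),
                 intercept_se = unname(cf["(Intercept)", "Std. Error"]),
                 fit = fit),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("titration_fit: %.3f labels/site (SE %.3f) + %.3f off-target labels/plasmid (SE %.3f)\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se))
  invisible(x)
}
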