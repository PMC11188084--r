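#' Simulation parameters for synthetic contact maps
#'
#' Bundles the parameters of the generative contact-map model. The model
#' combines a power-law distance decay with a compartment checkerboard, a
#' loop array (Gaussian contact bumps at consecutive loop anchors), focal
#' CTCF-anchored dots, oriented architectural stripes, and optional
#' self-interaction domains with attenuated inter-domain contact.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp.
#' @param alpha power-law decay exponent; cis contact weight scales as
#'   \code{s^-alpha}.
#' @param sigma compartment strength (log-scale factor). Same-label bin
#'   pairs are up-weighted by \code{exp(sigma)}, cross-label pairs
#'   down-weighted by \code{exp(-sigma)}.
#' @param sigma_range maximum separation (bp) at which the compartment
#'   factor applies; \code{Inf} gives a whole-chromosome checkerboard,
#'   a finite value restricts compartmentalization to short range.
#' @param mean_interval mean compartment interval length (bp); interval
#'   lengths are exponential and labels alternate.
#' @param loop_mean mean loop-anchor spacing L (bp).
#' @param loop_shape Gamma shape k for anchor spacings; the spacing mode
#'   \code{(k-1)/k * L} defines the ground-truth loop size.
#' @param loop_amp dot amplitude lambda at consecutive anchor pairs.
#' @param dot_amp amplitude delta of designated CTCF dot pairs.
#' @param dot_width Gaussian sd w (bp) of the dot/loop contact blur;
#'   defaults to \code{loop_mean / 4}, so the loop-array "hump" in P(s)
#'   keeps a loop-size-independent amplitude (contact enrichment around
#'   larger loops is proportionally broader).
#' @param n_dots number of designated dot pairs (drawn from consecutive
#'   loop-anchor pairs).
#' @param ctcf_fraction probability that a dot-pair end carries a CTCF
#'   site.
#' @param orientation_mix probabilities over the four CTCF orientation
#'   categories \code{c(convergent, divergent, tandem_plus, tandem_minus)}.
#' @param stripe_amp stripe amplitude; the geometric-mean contact
#'   enrichment along rows/columns through oriented CTCF bins is
#'   \code{1 + stripe_amp}.
#' @param stripe_beta downstream/upstream contact ratio of the stripes
#'   (1 = symmetric). Downstream is defined in the motif frame: for a
#'   reverse-oriented site, genomic upstream is its downstream.
#' @param domain_junctions number of implanted domain junctions per
#'   chromosome (0 = no domain structure).
#' @param domain_attenuation multiplicative factor in (0, 1] applied to
#'   contacts crossing a domain junction.
#' @param contamination mixing fraction in [0, 1] used by contamination
#'   experiments (see \code{\link{mix_maps}}).
#' @param n_contacts default number of contacts N for \code{\link{sample_map}}.
#' @param trans_frac fraction of contacts that are trans (uniform over
#'   inter-chromosomal bin pairs); only used with more than one chromosome.
#' @param seed default random seed.
#'
#' @return an object of class \code{sim_params} (a validated list).
#' @export
sim_params <- function(chrom_lengths = c(chr1 = 100e6),
                       bin_size = 50e3,
                       alpha = 1.1,
                       sigma = 0.4,
                       sigma_range = Inf,
                       mean_interval = 1e6,
                       loop_mean = 100e3,
                       loop_shape = 4,
                       loop_amp = 1,
                       dot_amp = 1,
                       dot_width = NULL,
                       n_dots = 50,
                       ctcf_fraction = 0.8,
                       orientation_mix = c(convergent = 0.25, divergent = 0.25,
                                           tandem_plus = 0.25, tandem_minus = 0.25),
                       stripe_amp = 0,
                       stripe_beta = 1,
                       domain_junctions = 0,
                       domain_attenuation = 1,
                       contamination = 0,
                       n_contacts = 1e6,
                       trans_frac = 0.05,
                       seed = 1L) {
  p <- list(chrom_lengths = chrom_lengths, bin_size = bin_size, alpha = alpha,
            sigma = sigma, sigma_range = sigma_range,
            mean_interval = mean_interval,
            loop_mean = loop_mean, loop_shape = loop_shape,
            loop_amp = loop_amp, dot_amp = dot_amp, dot_width = dot_width,
            n_dots = n_dots, ctcf_fraction = ctcf_fraction,
            orientation_mix = orientation_mix,
            stripe_amp = stripe_amp, stripe_beta = stripe_beta,
            domain_junctions = domain_junctions,
            domain_attenuation = domain_attenuation,
            contamination = contamination, n_contacts = n_contacts,
            trans_frac = trans_frac, seed = as.integer(seed))
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(is.list(p))
  if (is.null(p$dot_width)) p$dot_width <- p$loop_mean / 4
  if (is.null(names(p$chrom_lengths)))
    names(p$chrom_lengths) <- paste0("chr", seq_along(p$chrom_lengths))
  if (any(p$chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (p$bin_size <= 0) stop("bin_size must be positive")
  if (p$alpha <= 0) stop("alpha must be positive")
  for (amp in c("sigma", "loop_amp", "dot_amp", "stripe_amp"))
    if (p[[amp]] < 0) stop(amp, " must be non-negative")
  if (p$dot_width <= 0) stop("dot_width must be positive")
  if (p$loop_mean <= 0 || p$loop_shape <= 0)
    stop("loop_mean and loop_shape must be positive")
  if (abs(sum(p$orientation_mix) - 1) > 1e-8)
    stop("orientation_mix must sum to 1")
  if (length(p$orientation_mix) != 4)
    stop("orientation_mix must have 4 entries")
  names(p$orientation_mix) <- c("convergent", "divergent",
                                "tandem_plus", "tandem_minus")
  if (p$contamination < 0 || p$contamination > 1)
    stop("contamination must lie in [0, 1]")
  if (p$ctcf_fraction < 0 || p$ctcf_fraction > 1)
    stop("ctcf_fraction must lie in [0, 1]")
  if (p$domain_attenuation <= 0 || p$domain_attenuation > 1)
    stop("domain_attenuation must lie in (0, 1]")
  if (p$trans_frac < 0 || p$trans_frac >= 1)
    stop("trans_frac must lie in [0, 1)")
  if (p$stripe_beta <= 0) stop("stripe_beta must be positive")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic contact-map parameters\n")
  cat(sprintf("  genome: %d chromosome(s), %.1f Mb total, %g kb bins\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              x$bin_size / 1e3))
  cat(sprintf("  decay alpha = %g; compartments sigma = %g (range %s, mean interval %g kb)\n",
              x$alpha, x$sigma,
              if (is.finite(x$sigma_range)) sprintf("%g Mb", x$sigma_range / 1e6) else "genome-wide",
              x$mean_interval / 1e3))
  cat(sprintf("  loops: L = %g kb (shape %g), lambda = %g; dots: n = %d, delta = %g, w = %g kb\n",
              x$loop_mean / 1e3, x$loop_shape, x$loop_amp, x$n_dots,
              x$dot_amp, x$dot_width / 1e3))
  cat(sprintf("  stripes: amp = %g, beta = %g; domains: %d junctions, attenuation %g\n",
              x$stripe_amp, x$stripe_beta, x$domain_junctions,
              x$domain_attenuation))
  invisible(x)
}

#' Stage presets for the synthetic generator
#'
#' Illustrative parameter sets emulating a germline interphase-like stage
#' (typical interphase loops and whole-chromosome compartments) and a
#' pachytene-like stage (extended loop array, no global compartment
#' signal). These presets are qualitative: they reproduce the direction of
#' the mitotic-to-meiotic changes (larger loops, loss of long-range
#' checkerboard), not fitted magnitudes.
#'
#' @param stage one of \code{"interphase"} or \code{"pachytene"}.
#' @param ... overrides passed on to \code{\link{sim_params}}.
#' @return a \code{sim_params} object.
#' @export
stage_preset <- function(stage = c("interphase", "pachytene"), ...) {
  stage <- match.arg(stage)
  base <- switch(stage,
    interphase = list(alpha = 1.1, loop_amp = 1, loop_mean = 100e3,
                      sigma = 0.4),
    pachytene  = list(alpha = 1.1, loop_amp = 2, loop_mean = 800e3,
                      sigma = 0))
  do.call(sim_params, utils::modifyList(base, list(...)))
}
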