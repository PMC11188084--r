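#' Simulate a fine-resolution regulatory region
#'
#' Ground truth for a single region binned at a few hundred bp, carrying
#' regulatory elements instead of the large-scale loop array: promoters
#' with expression levels, enhancers, and oriented TSSs. Promoter pairs
#' (within [5 kb, 5 Mb]) and promoter-enhancer pairs receive Gaussian
#' contact bumps; the promoter-promoter amplitude scales with the
#' expression tertile of both partners (factors \code{tertile_factors}),
#' so interaction strength tracks transcription as a testable ground
#' truth. TSSs carry symmetric stripes.
#'
#' @param region_length region size in bp (kept small - fine-scale maps
#'   are simulated for one region, not genome-wide).
#' @param bin_size fine bin width (200-400 bp).
#' @param alpha distance-decay exponent.
#' @param n_promoters,n_enhancers element counts.
#' @param pp_amp,pe_amp base bump amplitudes.
#' @param tss_stripe_amp TSS stripe amplitude (beta = 1, two-sided).
#' @param bump_width Gaussian sd of the fine bumps (bp).
#' @param tertile_factors per-tertile amplitude factors (Low, Mid, High);
#'   a promoter pair's amplitude is \code{pp_amp * f_a * f_b}.
#' @param d_min,d_max pair separation range receiving bumps (bp).
#' @param seed integer seed.
#' @return a \code{ground_truth} for the region (single chromosome
#'   \code{"region"}), with \code{promoters} (incl. \code{expression}),
#'   \code{enhancers} and \code{tss} tables filled in.
#' @export
simulate_fine_features <- function(region_length = 2e6, bin_size = 400,
                                   alpha = 1.1,
                                   n_promoters = 30, n_enhancers = 30,
                                   pp_amp = 1, pe_amp = 1,
                                   tss_stripe_amp = 0.5,
                                   bump_width = 800,
                                   tertile_factors = c(Low = 0.5, Mid = 1,
                                                       High = 2),
                                   d_min = 5e3, d_max = 5e6,
                                   seed = 1L) {
  params <- sim_params(chrom_lengths = c(region = region_length),
                       bin_size = bin_size, alpha = alpha, sigma = 0,
                       loop_amp = 0, dot_amp = 0, n_dots = 0,
                       stripe_amp = 0, dot_width = bump_width,
                       mean_interval = max(bin_size, region_length / 10),
                       trans_frac = 0, seed = seed)
  truth <- simulate_features(params, seed = seed)
  truth$bumps <- NULL
  set.seed(seed + 1L)

  pr_pos <- sort(stats::runif(n_promoters, 0.02, 0.98)) * region_length
  en_pos <- sort(stats::runif(n_enhancers, 0.02, 0.98)) * region_length
  expr <- stats::rlnorm(n_promoters, meanlog = 2, sdlog = 1)
  ter <- cut(rank(expr, ties.method = "first"), breaks = 3,
             labels = c("Low", "Mid", "High"))
  fac <- tertile_factors[as.character(ter)]

  truth$promoters <- data.frame(chrom = "region", pos = pr_pos,
                                expression = expr, tertile = ter,
                                amp_factor = as.numeric(fac))
  truth$enhancers <- data.frame(chrom = "region", pos = en_pos)
  truth$tss <- data.frame(chrom = "region", pos = pr_pos,
                          orientation = sample(c("+", "-"), n_promoters,
                                               replace = TRUE))

  bumps <- list()
  if (n_promoters >= 2 && pp_amp > 0) {
    cmb <- utils::combn(n_promoters, 2)
    d <- pr_pos[cmb[2, ]] - pr_pos[cmb[1, ]]
    ok <- d >= d_min & d <= d_max
    if (any(ok))
      bumps[[length(bumps) + 1L]] <-
        data.frame(chrom = "region", a = pr_pos[cmb[1, ok]],
                   b = pr_pos[cmb[2, ok]],
                   amp = pp_amp * fac[cmb[1, ok]] * fac[cmb[2, ok]],
                   width = bump_width, kind = "pp")
  }
  if (n_enhancers >= 1 && pe_amp > 0) {
    grid <- expand.grid(i = seq_len(n_promoters), j = seq_len(n_enhancers))
    a <- pmin(pr_pos[grid$i], en_pos[grid$j])
    b <- pmax(pr_pos[grid$i], en_pos[grid$j])
    ok <- (b - a) >= d_min & (b - a) <= d_max
    if (any(ok))
      bumps[[length(bumps) + 1L]] <-
        data.frame(chrom = "region", a = a[ok], b = b[ok], amp = pe_amp,
                   width = bump_width, kind = "pe")
  }
  if (length(bumps) > 0) truth$bumps <- do.call(rbind, bumps)

  if (tss_stripe_amp > 0)
    truth$stripes <- data.frame(chrom = "region", pos = pr_pos,
                                orientation = truth$tss$orientation,
                                amp = tss_stripe_amp, beta = 1)
  truth$params <- params
  truth
}
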