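# Reusable end-to-end experiment drivers. These bundle the study
# conditions used by the analysis scripts, so the same computation can be
# re-run from tests or from a shell with nothing but a seed.

#' Contamination-detection threshold experiment
#'
#' Builds a compartment-free pachytene-like loop-array map (lambda 2,
#' L = 800 kb, sigma 0) and a compartmentalized meiotic-S-like map
#' (sigma 0.4, 1 Mb mean intervals) on the same 100 Mb single-chromosome
#' bin table, mixes the compartmentalized map into the loop-array map at
#' each fraction, and asks at which fraction PC1 (at 100 kb, GC
#' oriented) detects the A/B structure (absolute Spearman correlation
#' with the generator's labels > 0.7). The per-seed thresholds are
#' combined by majority (median over seeds).
#'
#' @param seed base seed.
#' @param fractions ascending mixing fractions.
#' @param n_seeds number of independent mixing replicates.
#' @param N contacts per map and per mixture.
#' @param genome_mb genome size in Mb.
#' @param gen_bin generation bin size (bp); PC1 runs at
#'   \code{pc1_factor} times this.
#' @param pc1_factor coarsening factor to the PC1 resolution.
#' @param threshold detectability threshold.
#' @return list: \code{detect_at} (majority threshold fraction, in
#'   percent), \code{per_seed} (per-seed threshold fractions), and the
#'   per-fraction detectability curves (\code{curves}).
#' @export
contamination_threshold_experiment <- function(seed = 1L,
                                               fractions = c(0.01, 0.02, 0.05,
                                                             0.10, 0.20),
                                               n_seeds = 5L,
                                               N = 1e7,
                                               genome_mb = 100,
                                               gen_bin = 50e3,
                                               pc1_factor = 2L,
                                               threshold = 0.7) {
  p_loop <- sim_params(chrom_lengths = c(chr1 = genome_mb * 1e6),
                       bin_size = gen_bin, alpha = 1.1, sigma = 0,
                       loop_amp = 2, loop_mean = 800e3, dot_width = 50e3,
                       n_dots = 0, n_contacts = N, seed = seed)
  p_comp <- sim_params(chrom_lengths = c(chr1 = genome_mb * 1e6),
                       bin_size = gen_bin, alpha = 1.1, sigma = 0.4,
                       mean_interval = 1e6, loop_amp = 0, n_dots = 0,
                       n_contacts = N, seed = seed + 1L)
  tr_loop <- simulate_features(p_loop, seed = seed)
  tr_comp <- simulate_features(p_comp, seed = seed + 1L)
  map_loop <- sample_map(tr_loop, p_loop, N = N, seed = seed)
  map_comp <- sample_map(tr_comp, p_comp, N = N, seed = seed + 1L)

  # truth labels and GC at the PC1 resolution (majority label per bin)
  coarse <- coarsen_matrix(map_loop, pc1_factor)
  grp <- pos_to_bin(coarse$bins, tr_comp$bins$chrom, tr_comp$bins$start)
  lab_sum <- rowsum(as.numeric(tr_comp$comp), grp)
  labels <- sign(as.vector(lab_sum))
  labels[labels == 0] <- 1
  gc <- 0.5 + 0.05 * labels

  curves <- vector("list", n_seeds)
  per_seed <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    sc <- contamination_scan(map_loop, map_comp, fractions, labels,
                             N = N, seed = seed + 100L * k, gc = gc,
                             pc1_factor = pc1_factor,
                             threshold = threshold)
    curves[[k]] <- sc
    per_seed[k] <- attr(sc, "detect_at")
  }
  list(detect_at = 100 * stats::median(per_seed, na.rm = TRUE),
       per_seed = 100 * per_seed, curves = curves)
}

#' Loop-size recovery experiment
#'
#' Samples maps from loop-array models and compares the loop size
#' estimated from each sampled map with the loop size of the exact
#' analytic P(s) curve of the same model (both through the identical
#' smoothing/derivative machinery).
#'
#' @param seed base seed.
#' @param L_values anchor-spacing means tested (bp).
#' @param lambda_values loop amplitudes tested.
#' @param n_seeds replicates per condition.
#' @param N contacts per map.
#' @param genome_mb genome size (Mb).
#' @param gen_bin bin size (bp).
#' @param bins_per_decade P(s) binning density.
#' @param window_decades smoothing window.
#' @return data.frame with one row per condition x seed: the analytic
#'   and sampled loop sizes and their relative error.
#' @export
loop_recovery_experiment <- function(seed = 1L,
                                     L_values = c(100e3, 800e3),
                                     lambda_values = c(0.5, 2),
                                     n_seeds = 5L, N = 1e7,
                                     genome_mb = 100, gen_bin = 10e3,
                                     bins_per_decade = 24,
                                     window_decades = 0.08) {
  rows <- list()
  for (L in L_values) for (lam in lambda_values) {
    for (k in seq_len(n_seeds)) {
      sd_k <- seed + 1000L * k + as.integer(L / 1e3) + round(100 * lam)
      p <- sim_params(chrom_lengths = c(chr1 = genome_mb * 1e6),
                      bin_size = gen_bin, sigma = 0, loop_amp = lam,
                      loop_mean = L, n_dots = 0, seed = sd_k)
      tr <- simulate_features(p, seed = sd_k)
      an <- analytic_ps(tr, p, bins_per_decade = bins_per_decade)
      an <- derivative_loglog(smooth_loglog(an, window_decades))
      st_an <- estimate_loop_stats(an)
      map <- balance_matrix(sample_map(tr, p, N = N, seed = sd_k + 7L))
      st <- loop_stats_from_map(map, bins_per_decade = bins_per_decade,
                                window_decades = window_decades)
      rows[[length(rows) + 1L]] <-
        data.frame(L = L, lambda = lam, seed = sd_k,
                   analytic_loop_size = st_an$loop_size,
                   sampled_loop_size = st$loop_size,
                   found = st$found,
                   rel_err = abs(st$loop_size - st_an$loop_size) /
                     st_an$loop_size)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohesin-density monotonicity experiment
#'
#' The valley-depth density metric should order loop amplitudes: for
#' each seed, maps are sampled at each lambda (same L) and the density
#' is compared across every lambda pair.
#'
#' @param seed base seed.
#' @param lambda_values loop amplitudes (ascending).
#' @param n_seeds replicates.
#' @param N contacts per map.
#' @param L anchor-spacing mean (bp).
#' @param genome_mb genome size (Mb).
#' @param gen_bin bin size (bp).
#' @return list: \code{densities} (seed x lambda matrix),
#'   \code{n_correct}, \code{n_comparisons}.
#' @export
density_monotonicity_experiment <- function(seed = 1L,
                                            lambda_values = c(0.5, 1, 2),
                                            n_seeds = 5L, N = 5e6,
                                            L = 200e3, genome_mb = 50,
                                            gen_bin = 10e3) {
  dens <- matrix(NA_real_, n_seeds, length(lambda_values),
                 dimnames = list(NULL, paste0("lambda", lambda_values)))
  for (k in seq_len(n_seeds)) {
    sd_k <- seed + 17L * k
    # one anchor layout per seed so only lambda varies within a seed
    for (li in seq_along(lambda_values)) {
      p <- sim_params(chrom_lengths = c(chr1 = genome_mb * 1e6),
                      bin_size = gen_bin, sigma = 0,
                      loop_amp = lambda_values[li], loop_mean = L,
                      n_dots = 0, seed = sd_k)
      tr <- simulate_features(p, seed = sd_k)
      map <- balance_matrix(sample_map(tr, p, N = N, seed = sd_k + li))
      st <- loop_stats_from_map(map, bins_per_decade = 16,
                                window_decades = 0.08)
      dens[k, li] <- if (st$found) st$density else 0
    }
  }
  cmp <- utils::combn(length(lambda_values), 2)
  correct <- 0L
  for (k in seq_len(n_seeds)) for (cc in seq_len(ncol(cmp))) {
    if (dens[k, cmp[2, cc]] > dens[k, cmp[1, cc]]) correct <- correct + 1L
  }
  list(densities = dens, n_correct = correct,
       n_comparisons = n_seeds * ncol(cmp))
}
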