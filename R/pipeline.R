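#' Run the simulate-and-analyze pipeline from a configuration
#'
#' Configuration-driven orchestration: for each named stage in the
#' config, simulates a map, balances it and runs the enabled analyses
#' (P(s) + loop stats, insulation + boundaries + delta, compartment PC1
#' and local ranks, dots + CTCF annotation, stripe profiles, dot-pair
#' pileup), writing per-stage artifacts and one flat machine-readable
#' report (\code{stage, statistic, value}) to the output directory.
#' Identical (config, seed) pairs give identical outputs.
#'
#' @param config a YAML file path or an equivalent nested list. Required
#'   per-stage keys: \code{bin_size}, \code{chrom_lengths}; any
#'   \code{\link{sim_params}} argument may be set. Top-level keys:
#'   \code{stages} (required), \code{out_dir}, \code{seed},
#'   \code{analysis} (toggles/parameters).
#' @param seed overrides the config seed.
#' @param out_dir overrides the config output directory.
#' @return the report data.frame, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$stages) || length(cfg$stages) == 0)
    stop("config error: missing required key 'stages'")
  if (is.null(seed)) seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  seed <- as.integer(seed)
  if (is.null(out_dir))
    out_dir <- if (!is.null(cfg$out_dir)) cfg$out_dir else "pipeline_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- if (is.null(cfg$analysis)) list() else cfg$analysis
  get_an <- function(key, default) if (is.null(an[[key]])) default else an[[key]]

  report <- list()
  note <- function(stage, statistic, value) {
    report[[length(report) + 1L]] <<-
      data.frame(stage = stage, statistic = statistic,
                 value = as.numeric(value))
  }

  for (si in seq_along(cfg$stages)) {
    stage <- names(cfg$stages)[si]
    spec <- cfg$stages[[si]]
    for (key in c("bin_size", "chrom_lengths")) {
      if (is.null(spec[[key]]))
        stop("config error: stage '", stage, "' missing required key '",
             key, "'")
    }
    spec$chrom_lengths <- unlist(spec$chrom_lengths)
    known <- intersect(names(spec), names(formals(sim_params)))
    params <- do.call(sim_params, spec[known])
    st_seed <- seed + 1000L * si
    message("stage ", stage, ": simulating")
    truth <- simulate_features(params, seed = st_seed)
    map <- sample_map(truth, params, N = params$n_contacts,
                      seed = st_seed + 1L)
    map <- balance_matrix(map)
    prefix <- file.path(out_dir, stage)
    write_matrix(map, prefix)
    note(stage, "total_contacts", total_contacts(map))

    if (isTRUE(get_an("ps", TRUE))) {
      st <- loop_stats_from_map(map,
        bins_per_decade = get_an("bins_per_decade", 8),
        window_decades = get_an("window_decades", 0.1))
      curve <- attr(st, "curve")
      utils::write.table(curve, paste0(prefix, ".ps.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note(stage, "loop_size", if (st$found) st$loop_size else NA)
      note(stage, "loop_density", if (st$found) st$density else NA)
    }

    if (isTRUE(get_an("insulation", TRUE))) {
      window <- get_an("insulation_window", 100e3)
      ok <- min(table(map$bins$chrom)) * map$resolution > 2 * window
      if (ok) {
        trk <- insulation(map, window = window)
        write_bedgraph(trk, paste0(prefix, ".insulation.bedgraph"))
        bds <- call_boundaries(trk)
        note(stage, "n_boundaries", nrow(bds))
        if (nrow(bds) > 0) {
          utils::write.table(
            bds[, c("chrom", "start", "end", "strength")],
            paste0(prefix, ".boundaries.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
          prof <- try(boundary_profile(trk, bds,
                                       flank = get_an("profile_flank", 150e3)),
                      silent = TRUE)
          if (!inherits(prof, "try-error"))
            note(stage, "insulation_delta", insulation_delta(prof))
        }
      }
    }

    if (isTRUE(get_an("compartments", TRUE))) {
      fac <- get_an("pc1_factor", max(1L, as.integer(100e3 / map$resolution)))
      cmap <- if (fac > 1) balance_matrix(coarsen_matrix(map, fac)) else map
      trk <- eigen_compartments(cmap)
      utils::write.table(trk, paste0(prefix, ".pc1.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      lab <- pos_to_bin(cmap$bins, truth$bins$chrom, truth$bins$start)
      lsum <- rowsum(as.numeric(truth$comp), lab)
      labs <- sign(as.vector(lsum))
      ok <- !is.na(trk$pc1) & labs != 0
      if (sum(ok) > 2)
        note(stage, "pc1_truth_cor",
             abs(stats::cor(trk$pc1[ok], labs[ok], method = "spearman")))
    }

    if (isTRUE(get_an("dots", TRUE)) && !is.null(truth$dot_pairs)) {
      oem <- oe_matrix(map)
      dots <- call_dots(oem,
                        min_dist = get_an("dot_min_dist", 50e3),
                        max_dist = get_an("dot_max_dist", 10e6),
                        min_sep = get_an("dot_min_sep", 10e3),
                        corr_min = get_an("dot_corr_min", 0.4))
      note(stage, "n_dots", nrow(dots))
      if (nrow(dots) > 0) {
        write_bedpe(dots, paste0(prefix, ".dots.bedpe"), map$resolution)
        if (!is.null(truth$ctcf)) {
          ann <- annotate_dots(dots, anchor_set(truth$ctcf), map$resolution)
          note(stage, "dot_ctcf_fraction", ann$fraction_with_ctcf_anchor)
          note(stage, "dot_median_distance", ann$median_anchor_distance)
        }
      }
      pu <- try(pileup(oem, data.frame(chrom = truth$dot_pairs$chrom,
                                       pos1 = truth$dot_pairs$a,
                                       pos2 = truth$dot_pairs$b),
                       flank = get_an("pileup_flank", 500e3)),
                silent = TRUE)
      if (!inherits(pu, "try-error"))
        note(stage, "dot_pileup_enrichment", pu$central_enrichment)
      if (!is.null(truth$stripes)) {
        sp <- stripe_bias(oem, anchor_set(truth$stripes),
                          flank = get_an("stripe_flank", 2e6))
        use <- sp$offset >= 0.5e6 & !is.na(sp$bias)
        if (any(use)) note(stage, "stripe_bias_mean", mean(sp$bias[use]))
      }
    }
  }
  report <- do.call(rbind, report)
  utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(report)
}
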