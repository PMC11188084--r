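#' A/B compartments from the leading eigenvector
#'
#' Per chromosome: observed/expected matrix, Pearson correlation of its
#' columns over unmasked bins, leading eigenvector of the correlation
#' matrix, sign-oriented so that its correlation with GC content is
#' positive (A = positive, GC-rich). The classic analysis resolution is
#' 100 kb. The first \code{ignore_diags} diagonals carry distance
#' residuals rather than compartment signal and are neutralized
#' (replaced by the column mean) before the correlation.
#'
#' @param cm a balanced \code{contact_matrix} (at the analysis
#'   resolution).
#' @param gc per-bin GC fraction; defaults to the \code{gc} column of the
#'   bin table.
#' @param min_bins chromosomes with fewer unmasked bins are skipped with
#'   a warning.
#' @param ignore_diags number of near-diagonal bins excluded from the
#'   correlation (2 is the ecosystem convention).
#' @return a data.frame of class \code{compartment_track}: \code{chrom},
#'   \code{start}, \code{end}, \code{bin}, \code{pc1} (unit norm per
#'   chromosome), \code{label} (+1 = A, -1 = B, NA masked).
#' @export
eigen_compartments <- function(cm, gc = cm$bins$gc, min_bins = 10,
                               ignore_diags = 2L) {
  if (is.null(gc)) stop("gc track required to orient the eigenvector")
  oem <- oe_matrix(cm)
  idx <- chrom_index(cm$bins)
  out <- lapply(idx$chroms, function(ch) {
    n <- idx$n[[ch]]
    off <- idx$offset[[ch]]
    res <- data.frame(chrom = ch,
                      start = cm$bins$start[off + seq_len(n)],
                      end = cm$bins$end[off + seq_len(n)],
                      bin = off + seq_len(n),
                      pc1 = NA_real_, label = NA_integer_)
    M <- as.matrix(oem$mats[[ch]])
    if (ignore_diags > 0 && n > 2 * ignore_diags) {
      for (d in 0:(ignore_diags - 1L)) {
        ii <- seq_len(n - d)
        M[cbind(ii, ii + d)] <- NA
        M[cbind(ii + d, ii)] <- NA
      }
      cmeans <- colMeans(M, na.rm = TRUE)
      nas <- which(is.na(M), arr.ind = TRUE)
      M[nas] <- cmeans[nas[, 2]]
    }
    use <- oem$mask[off + seq_len(n)]
    use[use] <- apply(M[, use, drop = FALSE], 2, stats::sd) > 0
    if (sum(use) < min_bins) {
      warning("chromosome ", ch, " skipped (fewer than ", min_bins,
              " usable bins)")
      return(res)
    }
    C <- stats::cor(M[use, use, drop = FALSE])
    C[!is.finite(C)] <- 0
    ev <- eigen(C, symmetric = TRUE)
    v <- ev$vectors[, 1]
    g <- gc[off + seq_len(n)][use]
    if (stats::sd(g) > 0 && stats::cor(v, g) < 0) v <- -v
    res$pc1[use] <- v
    res$label[use] <- ifelse(v >= 0, 1L, -1L)
    res
  })
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  attr(track, "resolution") <- cm$resolution
  class(track) <- c("compartment_track", "data.frame")
  track
}

#' Local compartment ranks from short-range interactions
#'
#' A windowed substitute for global PC1 that works when long-range
#' checkerboard structure is absent (as on meiotic prophase
#' chromosomes): the leading eigenvector of the O/E correlation matrix
#' is computed in overlapping windows (10 Mb, 5 Mb step by default),
#' locally oriented by GC, averaged per bin over windows, and converted
#' to genome-wide quantile ranks in [0, 1]. Subtract 0.5 for a
#' PC1-comparable display scale.
#'
#' @param cm a balanced \code{contact_matrix} (classically at 50 kb).
#' @param window,step window size and step in bp.
#' @param max_range maximal interaction range used (bp); windows are not
#'   allowed to exceed it, so all pairs entering a window's correlation
#'   are short-range.
#' @param gc per-bin GC for local orientation.
#' @param min_bins windows with fewer usable bins are skipped.
#' @return a \code{compartment_track} data.frame with a
#'   \code{local_rank} column in [0, 1].
#' @export
local_ranks <- function(cm, window = 10e6, step = 5e6, max_range = 10e6,
                        gc = cm$bins$gc, min_bins = 20) {
  if (window > max_range)
    stop("window must not exceed max_range (short-range contract)")
  oem <- oe_matrix(cm)
  idx <- chrom_index(cm$bins)
  wbins <- as.integer(round(window / cm$resolution))
  sbins <- as.integer(round(step / cm$resolution))
  val_sum <- numeric(nrow(cm$bins))
  val_n <- numeric(nrow(cm$bins))
  for (ch in idx$chroms) {
    n <- idx$n[[ch]]
    off <- idx$offset[[ch]]
    M <- as.matrix(oem$mats[[ch]])
    mask <- oem$mask[off + seq_len(n)]
    starts <- seq(1L, max(1L, n - wbins + 1L), by = sbins)
    if (n > wbins && (starts[length(starts)] + wbins - 1L) < n)
      starts <- c(starts, n - wbins + 1L)
    for (s0 in starts) {
      sel <- s0:min(s0 + wbins - 1L, n)
      use <- sel[mask[sel]]
      sub <- M[use, use, drop = FALSE]
      use <- use[apply(sub, 2, stats::sd) > 0]
      if (length(use) < min_bins) next
      C <- stats::cor(M[use, use, drop = FALSE])
      C[!is.finite(C)] <- 0
      v <- eigen(C, symmetric = TRUE)$vectors[, 1]
      g <- gc[off + use]
      if (stats::sd(g) > 0 && stats::cor(v, g) < 0) v <- -v
      val_sum[off + use] <- val_sum[off + use] + v
      val_n[off + use] <- val_n[off + use] + 1
    }
  }
  avg <- ifelse(val_n > 0, val_sum / val_n, NA_real_)
  rk <- rank(avg, na.last = "keep")
  nv <- sum(!is.na(avg))
  track <- data.frame(chrom = cm$bins$chrom, start = cm$bins$start,
                      end = cm$bins$end, bin = seq_len(nrow(cm$bins)),
                      local_value = avg,
                      local_rank = (rk - 0.5) / nv)
  attr(track, "resolution") <- cm$resolution
  class(track) <- c("compartment_track", "data.frame")
  track
}

#' Cluster stages by their local compartment ranks
#'
#' Pairwise similarity is the Spearman correlation of \code{local_rank}
#' over mutually valid bins; stages are clustered by average-linkage
#' hierarchical clustering on 1 - similarity.
#'
#' @param tracks a named list of \code{\link{local_ranks}} tracks on
#'   identical bin tables.
#' @return list with the similarity matrix, the \code{hclust} object and
#'   the dendrogram leaf order.
#' @export
cluster_stages <- function(tracks) {
  if (length(tracks) < 2) stop("need at least two tracks to cluster")
  if (is.null(names(tracks)))
    names(tracks) <- paste0("stage", seq_along(tracks))
  nb <- nrow(tracks[[1]])
  if (!all(vapply(tracks, nrow, integer(1)) == nb))
    stop("tracks are not on identical bin tables")
  k <- length(tracks)
  S <- matrix(1, k, k, dimnames = list(names(tracks), names(tracks)))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    xa <- tracks[[a]]$local_rank
    xb <- tracks[[b]]$local_rank
    ok <- !is.na(xa) & !is.na(xb)
    S[a, b] <- S[b, a] <- stats::cor(xa[ok], xb[ok], method = "spearman")
  }
  h <- stats::hclust(stats::as.dist(1 - S), method = "average")
  list(similarity = S, hclust = h, order = h$order)
}

#' Contamination sensitivity of compartment detection
#'
#' Mixes increasing fractions of a compartmentalized map into a
#' compartment-free map, re-balances, runs PC1 compartment calling, and
#' measures detectability as the absolute Spearman correlation between
#' PC1 and the ground-truth labels. Reports the smallest fraction whose
#' detectability exceeds the threshold.
#'
#' @param map_pure the compartment-free map (e.g. a pachytene-like loop
#'   array).
#' @param map_contaminant the compartmentalized map (e.g. interphase- or
#'   meiotic-S-like).
#' @param fractions ascending mixing fractions.
#' @param truth_labels per-bin ground-truth labels (+1/-1) at the PC1
#'   analysis resolution.
#' @param N contacts resampled per mixture.
#' @param seed integer seed.
#' @param gc per-bin GC at the analysis resolution.
#' @param pc1_factor coarsening factor from the map resolution to the
#'   PC1 analysis resolution (classically PC1 runs at 100 kb).
#' @param threshold detectability threshold.
#' @return data.frame (fraction, detectability) with attribute
#'   \code{detect_at}: the smallest fraction above threshold (NA if
#'   none).
#' @export
contamination_scan <- function(map_pure, map_contaminant, fractions,
                               truth_labels, N, seed = 1L, gc = NULL,
                               pc1_factor = 1, threshold = 0.7) {
  stopifnot(!is.unsorted(fractions))
  det <- vapply(seq_along(fractions), function(i) {
    mixed <- mix_maps(map_pure, map_contaminant, fractions[i], N,
                      seed = seed + i)
    if (pc1_factor > 1) mixed <- coarsen_matrix(mixed, pc1_factor)
    mixed <- balance_matrix(mixed)
    trk <- eigen_compartments(mixed, gc = if (is.null(gc)) mixed$bins$gc else gc)
    ok <- !is.na(trk$pc1) & !is.na(truth_labels)
    abs(stats::cor(trk$pc1[ok], truth_labels[ok], method = "spearman"))
  }, numeric(1))
  out <- data.frame(fraction = fractions, detectability = det)
  hit <- which(det > threshold)
  attr(out, "detect_at") <- if (length(hit)) fractions[min(hit)] else NA_real_
  out
}
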