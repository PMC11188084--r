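#' Contact probability versus genomic distance, P(s)
#'
#' Pools balanced cis contacts over autosomes into geometric distance
#' bins: P(s) is the sum of balanced values over pairs in the bin divided
#' by the number of unmasked pairs in the bin. Chromosomes named in
#' \code{exclude_chroms} (sex chromosomes by default, reflecting their
#' special configuration in meiotic prophase) are left out; same-bin
#' pairs (s = 0) are excluded.
#'
#' @param cm a balanced \code{contact_matrix}.
#' @param min_s,max_s distance range (bp); defaults to one bin and the
#'   longest chromosome.
#' @param bins_per_decade geometric binning density.
#' @param exclude_chroms chromosomes excluded from the curve.
#' @return a data.frame of class \code{ps_curve} with columns \code{s}
#'   (geometric bin center, bp), \code{P}, \code{n_pairs}.
#' @export
compute_ps <- function(cm, min_s = 2 * cm$resolution, max_s = NULL,
                       bins_per_decade = 8,
                       exclude_chroms = c("chrX", "chrY", "chrM")) {
  ex <- expected_cis(cm)
  ex <- ex[!(ex$chrom %in% exclude_chroms) & ex$diag > 0, ]
  if (nrow(ex) == 0) stop("no usable cis diagonals")
  s <- ex$diag * cm$resolution
  if (is.null(max_s)) max_s <- max(s)
  keep <- s >= min_s & s <= max_s
  aggregate_ps(s[keep], ex$sum_balanced[keep], ex$n_valid[keep],
               min_s, max_s, bins_per_decade)
}

# Aggregate per-distance sums and pair counts into geometric bins. The
# reported s of each bin is the pair-weighted mean distance inside it,
# not the geometric bin center: at small s a bin holds only one or two
# integer diagonals, and the center-vs-content mismatch would imprint a
# sawtooth on the log-log derivative.
aggregate_ps <- function(s, sums, npairs, min_s, max_s, bins_per_decade) {
  lo <- log10(min_s)
  hi <- log10(max_s)
  edges <- 10^seq(lo, hi + 1 / bins_per_decade,
                  by = 1 / bins_per_decade)
  bin <- findInterval(s, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1
  ssum <- rowsum(sums, bin)
  nsum <- rowsum(npairs, bin)
  dsum <- rowsum(s * npairs, bin)
  out <- data.frame(s = as.vector(dsum) / as.vector(nsum),
                    P = as.vector(ssum) / as.vector(nsum),
                    n_pairs = as.vector(nsum))
  out <- out[out$n_pairs > 0, ]
  rownames(out) <- NULL
  class(out) <- c("ps_curve", "data.frame")
  out
}

#' Smooth a P(s) curve in log-log space
#'
#' Gaussian-weighted local linear fit of log10 P over log10 s with
#' kernel sd \code{window_decades}. The local-linear form (rather than a
#' running mean) keeps straight log-log segments exactly invariant,
#' including at the curve ends where the kernel is truncated - a running
#' mean would bend a pure power law there and fabricate derivative
#' extrema. Points with P = 0 are excluded from the kernel.
#' \code{window_decades = 0} returns the curve unchanged.
#'
#' @param ps a \code{ps_curve}.
#' @param window_decades kernel sd in decades of s.
#' @return the curve with a \code{P_smooth} column.
#' @export
smooth_loglog <- function(ps, window_decades = 0.1) {
  stopifnot(nrow(ps) >= 5)
  x <- log10(ps$s)
  y <- log10(ps$P)
  ok <- is.finite(y)
  if (window_decades <= 0) {
    ps$P_smooth <- ps$P
    return(ps)
  }
  sm <- vapply(seq_along(x), function(i) {
    k <- exp(-(x[ok] - x[i])^2 / (2 * window_decades^2))
    xw <- sum(k * x[ok]) / sum(k)
    yw <- sum(k * y[ok]) / sum(k)
    sxx <- sum(k * (x[ok] - xw)^2)
    b <- if (sxx > 0) sum(k * (x[ok] - xw) * (y[ok] - yw)) / sxx else 0
    yw + b * (x[i] - xw)
  }, numeric(1))
  ps$P_smooth <- 10^sm
  ps
}

#' Log-log derivative of a smoothed P(s) curve
#'
#' Central finite differences of log10 P_smooth with respect to log10 s;
#' one-sided differences at the endpoints.
#'
#' @param ps a \code{ps_curve} with a \code{P_smooth} column (see
#'   \code{\link{smooth_loglog}}); falls back to \code{P}.
#' @return the curve with a \code{deriv} column.
#' @export
derivative_loglog <- function(ps) {
  y <- log10(if ("P_smooth" %in% names(ps)) ps$P_smooth else ps$P)
  x <- log10(ps$s)
  n <- length(x)
  stopifnot(n >= 3)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  ps$deriv <- d
  ps
}

#' Loop size and relative cohesin density from a P(s) derivative
#'
#' The loop-array "hump" in P(s) appears as a local maximum of the
#' log-log derivative: the distance of the first local maximum within
#' \code{search_range} estimates the average loop size, and the depth of
#' the valley that follows it (derivative at the maximum minus the
#' minimum beyond it, within range) is a relative cohesin-density
#' metric. A maximum whose valley depth is below \code{min_density} is
#' treated as noise and skipped, so loop-free curves report
#' \code{found = FALSE}. Plateaus resolve to their leftmost point.
#'
#' @param ps a curve with a \code{deriv} column
#'   (\code{\link{derivative_loglog}}).
#' @param search_range distances (bp) searched for the maximum.
#' @param min_density minimal valley depth for a maximum to count as a
#'   loop signal (log-slope units).
#' @return a list of class \code{loop_stats}: \code{loop_size} (bp),
#'   \code{density}, \code{found}.
#' @export
estimate_loop_stats <- function(ps, search_range = c(20e3, 4e6),
                                min_density = 0.1) {
  stopifnot("deriv" %in% names(ps))
  inr <- which(ps$s >= search_range[1] & ps$s <= search_range[2])
  res <- list(loop_size = NA_real_, density = NA_real_, found = FALSE)
  class(res) <- "loop_stats"
  if (length(inr) < 3) return(res)
  d <- ps$deriv[inr]
  m <- length(d)
  cand <- which(d[2:(m - 1)] > d[1:(m - 2)] & d[2:(m - 1)] >= d[3:m]) + 1L
  for (ci in cand) {
    later <- if (ci < m) d[(ci + 1):m] else numeric(0)
    higher <- which(later > d[ci])
    if (length(higher) > 0) {
      # a taller peak follows: this maximum only counts as the first
      # bump if it has a genuine valley of its own before that peak
      own_drop <- d[ci] - min(later[seq_len(min(higher) )])
      if (own_drop < min_density) next
    }
    depth <- d[ci] - min(d[ci:m])
    if (depth >= min_density) {
      res$loop_size <- ps$s[inr[ci]]
      res$density <- depth
      res$found <- TRUE
      break
    }
  }
  res
}

#' @export
print.loop_stats <- function(x, ...) {
  if (x$found)
    cat(sprintf("Loop stats: size = %.0f kb, relative density = %.3f\n",
                x$loop_size / 1e3, x$density))
  else cat("Loop stats: no loop signal found\n")
  invisible(x)
}

#' One-call loop statistics from a contact matrix
#'
#' Convenience wrapper: \code{\link{compute_ps}} then
#' \code{\link{smooth_loglog}}, \code{\link{derivative_loglog}} and
#' \code{\link{estimate_loop_stats}}.
#'
#' @param cm a balanced \code{contact_matrix}.
#' @param ... passed to \code{compute_ps}.
#' @param window_decades smoothing window.
#' @param search_range,min_density see \code{\link{estimate_loop_stats}}.
#' @return a \code{loop_stats} with the curve attached as
#'   \code{attr(, "curve")}.
#' @export
loop_stats_from_map <- function(cm, ..., window_decades = 0.1,
                                search_range = c(20e3, 4e6),
                                min_density = 0.1) {
  ps <- compute_ps(cm, ...)
  ps <- derivative_loglog(smooth_loglog(ps, window_decades))
  st <- estimate_loop_stats(ps, search_range, min_density)
  attr(st, "curve") <- ps
  st
}
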