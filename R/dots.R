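#' Call dots (focal contact enrichments) by template matching
#'
#' Slides a 7x7 Gaussian dot template (sd 1 bin) over the distance band
#' [min_dist, max_dist] of each chromosome's O/E matrix; the score of a
#' pixel is the Pearson correlation between the template and the local
#' O/E patch. Local score maxima with score >= corr_min and center O/E >
#' 1 are kept, then greedily pruned so that no call lies within min_sep
#' of a stronger call (Chebyshev distance in bp; ties resolved toward
#' the smaller (a, b)).
#'
#' Template correlation alone is amplitude-blind, so on sparse count
#' data it also fires on Poisson noise. Two guards handle this: a
#' candidate's center must dominate its window outside the central 3x3
#' (a dot is focal), and, when the raw count matrix is supplied, the
#' center count must be Poisson-significantly above its
#' distance-expected value.
#'
#' @param oe an \code{\link{oe_matrix}}.
#' @param min_dist,max_dist distance band in bp (classically 50 kb -
#'   10 Mb).
#' @param min_sep minimum separation between calls in bp.
#' @param corr_min template-correlation threshold (classically 0.4).
#' @param template_size,template_sd dot template geometry (bins).
#' @param min_nonzero_frac minimum fraction of nonzero pixels in the
#'   template window; sparse windows (undersampled distances, where a
#'   lone nonzero pixel mimics a dot) are rejected. Dot calling is
#'   depth-dependent by nature; this guard makes that explicit.
#' @param cm optionally the raw \code{contact_matrix} behind \code{oe};
#'   enables the Poisson center-count filter.
#' @param p_max Poisson upper-tail threshold for the center count
#'   (used only with \code{cm}).
#' @return data.frame of class \code{dot_calls}: \code{chrom},
#'   \code{bin1}, \code{bin2} (chromosome-local), \code{pos1},
#'   \code{pos2} (bin starts, bp), \code{distance}, \code{score},
#'   \code{oe}.
#' @export
call_dots <- function(oe, min_dist = 50e3, max_dist = 10e6,
                      min_sep = 10e3, corr_min = 0.4,
                      template_size = 7L, template_sd = 1,
                      min_nonzero_frac = 0.75, cm = NULL, p_max = 1e-4) {
  res <- oe$resolution
  d_lo <- as.integer(ceiling(min_dist / res))
  d_hi <- as.integer(floor(max_dist / res))
  if (d_hi < d_lo) stop("distance band is empty at this resolution")
  h <- (template_size - 1L) %/% 2L
  og <- seq(-h, h)
  Tm <- exp(-outer(og^2, og^2, "+") / (2 * template_sd^2))
  tv <- as.vector(Tm)
  K <- length(tv)
  t_c <- tv - mean(tv)
  t_ss <- sqrt(sum(t_c^2))

  calls <- list()
  for (ch in names(oe$mats)) {
    M <- as.matrix(oe$mats[[ch]])
    n <- nrow(M)
    if (n < template_size) next
    off <- chrom_index(oe$bins)$offset[[ch]]
    msk <- oe$mask[off + seq_len(n)]
    M[!msk, ] <- 0
    M[, !msk] <- 0
    # sliding sums via template-shaped shifts on the padded matrix
    P <- matrix(0, n + 2L * h, n + 2L * h)
    P[h + seq_len(n), h + seq_len(n)] <- M
    s_tx <- matrix(0, n, n)
    s_x <- matrix(0, n, n)
    s_xx <- matrix(0, n, n)
    s_nz <- matrix(0, n, n)
    s_mx <- matrix(-Inf, n, n)
    for (a in seq_along(og)) for (b in seq_along(og)) {
      blk <- P[og[a] + h + seq_len(n), og[b] + h + seq_len(n)]
      s_tx <- s_tx + Tm[a, b] * blk
      s_x <- s_x + blk
      s_xx <- s_xx + blk * blk
      s_nz <- s_nz + (blk != 0)
      if (abs(og[a]) > 1 || abs(og[b]) > 1) s_mx <- pmax(s_mx, blk)
    }
    num <- s_tx - mean(tv) * s_x
    den <- t_ss * sqrt(pmax(s_xx - s_x^2 / K, 0))
    r <- ifelse(den > 0, num / den, 0)

    band <- outer(seq_len(n), seq_len(n), function(i, j) {
      d <- j - i
      d >= d_lo & d <= d_hi
    })
    # a dot is a focal enrichment: its center must dominate the window
    # outside the central 3x3
    cand <- band & r >= corr_min & M > 1 & s_nz >= min_nonzero_frac * K &
      M >= s_mx
    # strict local maxima of the score over the 8-neighborhood
    if (any(cand)) {
      Rp <- matrix(-Inf, n + 2L, n + 2L)
      Rp[1L + seq_len(n), 1L + seq_len(n)] <- r
      ismax <- matrix(TRUE, n, n)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ismax <- ismax & (r >= Rp[di + 1L + seq_len(n), dj + 1L + seq_len(n)])
      }
      cand <- cand & ismax
    }
    hit <- which(cand, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    df <- data.frame(chrom = ch, bin1 = hit[, 1], bin2 = hit[, 2],
                     score = r[hit], oe = M[hit])
    if (!is.null(cm)) {
      Mc <- chrom_sparse(cm, ch, what = "count")
      w <- cm$weights[off + seq_len(n)]
      ev <- rep(NA_real_, n)
      esub <- oe$expected[oe$expected$chrom == ch, ]
      ev[esub$diag + 1L] <- esub$expected
      cnt <- Mc[cbind(df$bin1, df$bin2)]
      # expected raw count of the pixel from the balanced expected value
      e_raw <- ev[df$bin2 - df$bin1 + 1L] / (w[df$bin1] * w[df$bin2])
      pval <- stats::ppois(cnt - 1, e_raw, lower.tail = FALSE)
      df <- df[!is.na(pval) & pval <= p_max, , drop = FALSE]
      if (nrow(df) == 0) next
    }
    calls[[length(calls) + 1L]] <- df
  }
  if (length(calls) == 0) {
    out <- data.frame(chrom = character(0), bin1 = integer(0),
                      bin2 = integer(0), pos1 = numeric(0),
                      pos2 = numeric(0), distance = numeric(0),
                      score = numeric(0), oe = numeric(0))
    class(out) <- c("dot_calls", "data.frame")
    return(out)
  }
  df <- do.call(rbind, calls)
  # greedy non-maximum suppression, strongest first
  sep_bins <- min_sep / res
  df <- df[order(-df$score, df$bin1, df$bin2), ]
  keep <- logical(nrow(df))
  for (ch in unique(df$chrom)) {
    sel <- which(df$chrom == ch)
    kept_i <- integer(0)
    kept_j <- integer(0)
    for (r0 in sel) {
      if (length(kept_i) == 0 ||
          all(pmax(abs(df$bin1[r0] - kept_i),
                   abs(df$bin2[r0] - kept_j)) * res >= min_sep)) {
        keep[r0] <- TRUE
        kept_i <- c(kept_i, df$bin1[r0])
        kept_j <- c(kept_j, df$bin2[r0])
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df$pos1 <- (df$bin1 - 1) * res
  df$pos2 <- (df$bin2 - 1) * res
  df$distance <- df$pos2 - df$pos1
  df <- df[order(df$chrom, df$bin1, df$bin2),
           c("chrom", "bin1", "bin2", "pos1", "pos2", "distance",
             "score", "oe")]
  rownames(df) <- NULL
  class(df) <- c("dot_calls", "data.frame")
  df
}

#' Annotate dot calls with CTCF anchors
#'
#' A dot "has a CTCF anchor" when either end lies within \code{slack}
#' bins of a CTCF site. The orientation composition is computed only
#' over dots whose two ends each match exactly one oriented motif
#' (category semantics as in \code{\link{pair_by_orientation}}); the
#' median anchor distance is over all dots.
#'
#' @param dots a \code{dot_calls} data.frame.
#' @param ctcf an \code{anchor_set} of CTCF sites.
#' @param resolution bin size in bp.
#' @param slack matching slack in bins.
#' @return list with \code{fraction_with_ctcf_anchor},
#'   \code{orientation_composition} (proportions over the four
#'   categories), \code{n_oriented} (dots entering the composition),
#'   \code{median_anchor_distance}.
#' @export
annotate_dots <- function(dots, ctcf, resolution, slack = 1L) {
  if (nrow(dots) == 0)
    return(list(fraction_with_ctcf_anchor = NA_real_,
                orientation_composition = NULL, n_oriented = 0L,
                median_anchor_distance = NA_real_))
  tol <- slack * resolution
  match_end <- function(ch, pos) {
    sub <- ctcf[ctcf$chrom == ch, , drop = FALSE]
    cb <- floor(sub$pos / resolution)
    eb <- floor(pos / resolution)
    sub[abs(cb - eb) <= slack, , drop = FALSE]
  }
  n_anchor <- integer(nrow(dots))
  cats <- character(0)
  for (r in seq_len(nrow(dots))) {
    m1 <- match_end(dots$chrom[r], dots$pos1[r])
    m2 <- match_end(dots$chrom[r], dots$pos2[r])
    n_anchor[r] <- (nrow(m1) > 0) + (nrow(m2) > 0)
    o1 <- m1$orientation[m1$orientation %in% c("+", "-")]
    o2 <- m2$orientation[m2$orientation %in% c("+", "-")]
    if (nrow(m1) == 1 && nrow(m2) == 1 &&
        length(o1) == 1 && length(o2) == 1) {
      cats <- c(cats,
                if (o1 == "+" && o2 == "-") "convergent"
                else if (o1 == "-" && o2 == "+") "divergent"
                else if (o1 == "+") "tandem_plus" else "tandem_minus")
    }
  }
  comp <- NULL
  if (length(cats) > 0) {
    comp <- table(factor(cats, levels = c("convergent", "divergent",
                                          "tandem_plus", "tandem_minus")))
    comp <- as.vector(comp) / length(cats)
    names(comp) <- c("convergent", "divergent", "tandem_plus",
                     "tandem_minus")
  }
  list(fraction_with_ctcf_anchor = mean(n_anchor >= 1),
       orientation_composition = comp,
       n_oriented = length(cats),
       median_anchor_distance = stats::median(dots$distance))
}
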