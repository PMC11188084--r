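#' Insulation score
#'
#' For each bin b, the mean balanced contact in the w x w diamond of
#' pairs crossing b (upstream bins b-w..b-1 against downstream bins
#' b+1..b+w, with w = window/resolution), log2-normalized by the
#' chromosome-wide mean diamond value. Bins within one window of a
#' chromosome end, or masked, are invalid.
#'
#' @param cm a balanced \code{contact_matrix} at the analysis resolution
#'   (the classic choice is 10 kb bins with a 100 kb window).
#' @param window diamond window size in bp; must be a multiple of the
#'   resolution.
#' @return a data.frame of class \code{insulation_track}: \code{chrom},
#'   \code{start}, \code{end}, \code{bin} (global id), \code{score},
#'   \code{valid}.
#' @export
insulation <- function(cm, window = 100e3) {
  if (!cm$balanced) stop("balance the matrix first")
  w <- window / cm$resolution
  if (abs(w - round(w)) > 1e-8) stop("window must be a multiple of the resolution")
  w <- as.integer(round(w))
  idx <- chrom_index(cm$bins)
  out <- lapply(idx$chroms, function(ch) {
    n <- idx$n[[ch]]
    off <- idx$offset[[ch]]
    res <- data.frame(chrom = ch,
                      start = cm$bins$start[off + seq_len(n)],
                      end = cm$bins$end[off + seq_len(n)],
                      bin = off + seq_len(n),
                      score = NA_real_, valid = FALSE)
    if (n < 2 * w + 1) {
      warning("chromosome ", ch, " shorter than twice the window; all bins invalid")
      return(res)
    }
    sel <- cm$pixels$bin1 > off & cm$pixels$bin1 <= off + n &
      cm$pixels$bin2 > off & cm$pixels$bin2 <= off + n
    px <- cm$pixels[sel, , drop = FALSE]
    i <- px$bin1 - off
    j <- px$bin2 - off
    val <- px$count * cm$weights[px$bin1] * cm$weights[px$bin2]
    keep <- !is.na(val) & val != 0 & j > i
    i <- i[keep]; j <- j[keep]; val <- val[keep]
    # pixel (i, j) contributes to diamonds of b in [max(i+1, j-w), min(i+w, j-1)]
    b_lo <- pmax(i + 1L, j - w)
    b_hi <- pmin(i + w, j - 1L)
    ok <- b_hi >= b_lo
    acc <- numeric(n + 1L)
    if (any(ok)) {
      add <- rowsum(val[ok], b_lo[ok])
      acc[as.integer(rownames(add))] <- acc[as.integer(rownames(add))] + add
      subtr <- rowsum(val[ok], b_hi[ok] + 1L)
      ii <- as.integer(rownames(subtr))
      acc[ii] <- acc[ii] - subtr
    }
    dsum <- cumsum(acc)[seq_len(n)]
    # unmasked-pair count per diamond
    valid_bin <- as.numeric(!is.na(cm$weights[off + seq_len(n)]))
    cs <- c(0, cumsum(valid_bin))
    b <- seq_len(n)
    n_up <- ifelse(b - w >= 1, cs[b] - cs[pmax(b - w, 1)], NA)
    n_dn <- ifelse(b + w <= n, cs[pmin(b + w, n) + 1L] - cs[b + 1L], NA)
    npair <- n_up * n_dn
    dmean <- ifelse(!is.na(npair) & npair > 0, dsum / npair, NA)
    center_ok <- valid_bin == 1
    dmean[!center_ok] <- NA
    mu <- mean(dmean, na.rm = TRUE)
    res$score <- log2(dmean / mu)
    res$valid <- is.finite(res$score)
    res
  })
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  attr(track, "window") <- window
  attr(track, "resolution") <- cm$resolution
  class(track) <- c("insulation_track", "data.frame")
  track
}

#' Li's minimum cross-entropy threshold
#'
#' Iterative version of Li's minimum cross-entropy thresholding on a
#' positive-valued sample; used to separate genuine boundary strengths
#' from noise.
#'
#' @param x positive values.
#' @return the threshold (scalar).
#' @export
li_threshold <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 2 || diff(range(x)) < .Machine$double.eps)
    return(min(x))
  t_old <- mean(x)
  for (it in 1:200) {
    lo <- x[x <= t_old]
    hi <- x[x > t_old]
    if (length(lo) == 0 || length(hi) == 0) break
    m1 <- mean(lo); m2 <- mean(hi)
    t_new <- (m1 - m2) / (log(m1) - log(m2))
    if (!is.finite(t_new)) break
    if (abs(t_new - t_old) < 1e-10) { t_old <- t_new; break }
    t_old <- t_new
  }
  t_old
}

#' Call TAD boundaries from an insulation track
#'
#' Candidate boundaries are local minima of the insulation score; each
#' minimum's strength is its topographic prominence (the smaller of the
#' left and right ascents to the bounding maxima). With
#' \code{method = "Li"}, Li's minimum cross-entropy threshold on the
#' strength distribution separates boundaries from noise; minima with
#' strength at or above the threshold are kept.
#'
#' @param track an \code{\link{insulation}} result.
#' @param method thresholding method (\code{"Li"} or \code{"none"}).
#' @return a data.frame of class \code{boundary_set}: \code{chrom},
#'   \code{start}, \code{end}, \code{bin}, \code{pos} (bin midpoint),
#'   \code{score} (insulation at the minimum), \code{strength}.
#' @export
call_boundaries <- function(track, method = c("Li", "none")) {
  method <- match.arg(method)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), bin = integer(0), pos = numeric(0),
                      score = numeric(0), strength = numeric(0))
  class(empty) <- c("boundary_set", "data.frame")
  if (sum(track$valid) < 3) return(empty)
  rows <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch & track$valid, , drop = FALSE]
    if (nrow(tr) < 3) next
    sc <- tr$score
    m <- length(sc)
    is_min <- c(FALSE, sc[2:(m - 1)] < sc[1:(m - 2)] &
                  sc[2:(m - 1)] <= sc[3:m], FALSE)
    for (b in which(is_min)) {
      left_max <- -Inf
      for (k in (b - 1):1) {
        if (sc[k] < sc[b]) break
        left_max <- max(left_max, sc[k])
      }
      right_max <- -Inf
      for (k in (b + 1):m) {
        if (sc[k] < sc[b]) break
        right_max <- max(right_max, sc[k])
      }
      if (!is.finite(left_max)) left_max <- max(sc[1:(b - 1)])
      if (!is.finite(right_max)) right_max <- max(sc[(b + 1):m])
      strength <- min(left_max, right_max) - sc[b]
      if (strength <= 0) next
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ch, start = tr$start[b], end = tr$end[b],
                   bin = tr$bin[b], pos = (tr$start[b] + tr$end[b]) / 2,
                   score = sc[b], strength = strength)
    }
  }
  if (length(rows) == 0) return(empty)
  bs <- do.call(rbind, rows)
  if (method == "Li" && nrow(bs) > 1) {
    thr <- li_threshold(bs$strength)
    bs <- bs[bs$strength >= thr, , drop = FALSE]
  }
  bs <- bs[order(bs$chrom, bs$pos), ]
  rownames(bs) <- NULL
  class(bs) <- c("boundary_set", "data.frame")
  bs
}

#' Boundaries conserved between two sets
#'
#' A boundary of \code{set_a} is conserved when its position, expanded by
#' \code{slack} on each side, touches the expanded position of some
#' boundary of \code{set_b} (i.e. the positions are within
#' \code{2 * slack}). Also derives conserved domains as the regions
#' between adjacent conserved boundaries on each chromosome.
#'
#' @param set_a,set_b \code{boundary_set} objects on the same genome.
#' @param slack expansion in bp (classically 10 kb).
#' @return the conserved subset of \code{set_a}, with the domain table
#'   attached as \code{attr(, "domains")}.
#' @export
conserved_boundaries <- function(set_a, set_b, slack = 10e3) {
  keep <- vapply(seq_len(nrow(set_a)), function(i) {
    pb <- set_b$pos[set_b$chrom == set_a$chrom[i]]
    length(pb) > 0 && any(abs(pb - set_a$pos[i]) <= 2 * slack)
  }, logical(1))
  out <- set_a[keep, , drop = FALSE]
  rownames(out) <- NULL
  doms <- do.call(rbind, lapply(unique(out$chrom), function(ch) {
    p <- sort(out$pos[out$chrom == ch])
    if (length(p) < 2) return(NULL)
    data.frame(chrom = ch, start = p[-length(p)], end = p[-1])
  }))
  attr(out, "domains") <- doms
  class(out) <- c("boundary_set", "data.frame")
  out
}

#' Mean insulation profile around boundaries
#'
#' Element-wise average of per-boundary insulation windows (boundary bin
#' plus/minus \code{flank}), shifted so the profile minimum is zero.
#' Boundaries whose window leaves the valid part of the track are
#' excluded (their count is messaged).
#'
#' @param track an \code{\link{insulation}} result.
#' @param boundaries a \code{boundary_set}.
#' @param flank half-width of the profile in bp.
#' @return numeric vector of the profile with an \code{offsets} attribute
#'   (bp) and \code{n_boundaries} used.
#' @export
boundary_profile <- function(track, boundaries, flank = 150e3) {
  res <- attr(track, "resolution")
  Fw <- as.integer(round(flank / res))
  acc <- numeric(2 * Fw + 1)
  used <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(boundaries))) {
    tr_idx <- which(track$bin == boundaries$bin[i])
    if (length(tr_idx) != 1) { skipped <- skipped + 1L; next }
    lo <- tr_idx - Fw
    hi <- tr_idx + Fw
    if (lo < 1 || hi > nrow(track) ||
        any(track$chrom[lo:hi] != boundaries$chrom[i]) ||
        any(!track$valid[lo:hi])) {
      skipped <- skipped + 1L
      next
    }
    acc <- acc + track$score[lo:hi]
    used <- used + 1L
  }
  if (used == 0) stop("no boundary with full flank coverage")
  if (skipped > 0) message(skipped, " boundary(ies) excluded (incomplete flank)")
  prof <- acc / used
  prof <- prof - min(prof)
  attr(prof, "offsets") <- seq(-Fw, Fw) * res
  attr(prof, "n_boundaries") <- used
  prof
}

#' Insulation delta of a boundary profile
#'
#' Difference between the maximum and minimum of the profile; with the
#' zero-normalized profile from \code{\link{boundary_profile}} this is
#' simply its maximum.
#'
#' @param profile a numeric profile.
#' @return the max - min score.
#' @export
insulation_delta <- function(profile) {
  stopifnot(length(profile) > 0)
  max(profile) - min(profile)
}
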