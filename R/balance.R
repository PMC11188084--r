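#' Matrix balancing by iterative correction
#'
#' ICE-style balancing: bins whose raw marginal is zero, or more than
#' \code{mad_max} median absolute deviations below the median marginal,
#' are masked; the remaining weights are iterated so that every unmasked
#' row of the balanced matrix sums to 1, stopping when the coefficient of
#' variation of the row sums drops below \code{tol}.
#'
#' @param cm a \code{contact_matrix}.
#' @param tol convergence tolerance on the CV of balanced row sums.
#' @param max_iter maximum number of iterations; if not converged, the
#'   best iterate is returned with a warning and
#'   \code{balance_converged = FALSE}.
#' @param mad_max bin-filter threshold in median absolute deviations.
#' @return the \code{contact_matrix} with \code{weights} filled in
#'   (\code{NA} for masked bins) and \code{balanced = TRUE}.
#' @export
balance_matrix <- function(cm, tol = 1e-5, max_iter = 200, mad_max = 5) {
  n <- nrow(cm$bins)
  px <- cm$pixels
  M <- Matrix::sparseMatrix(i = px$bin1, j = px$bin2,
                            x = as.numeric(px$count),
                            dims = c(n, n), symmetric = TRUE)
  marg <- Matrix::rowSums(M)
  mask <- marg == 0
  nz <- marg[!mask]
  if (length(nz) == 0) stop("matrix has no unmasked bin")
  med <- stats::median(nz)
  mad <- stats::mad(nz)
  mask <- mask | (marg < med - mad_max * mad)
  if (all(mask)) stop("all bins masked by MAD filter")

  w <- as.numeric(!mask)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- w * as.vector(M %*% w)
    ru <- r[!mask]
    mu <- mean(ru)
    if (mu == 0) stop("balancing degenerate: zero marginals on unmasked bins")
    cv <- stats::sd(ru) / mu
    if (cv < tol) { converged <- TRUE; break }
    s <- r / mu
    s[mask | s == 0] <- 1
    w <- w / sqrt(s)   # symmetric (square-root damped) update
  }
  # scale so unmasked balanced rows sum to 1
  r <- w * as.vector(M %*% w)
  mu <- mean(r[!mask])
  w <- w / sqrt(mu)
  if (!converged)
    warning(sprintf("balancing did not converge in %d iterations (CV = %.2e)",
                    max_iter, cv))
  w[mask] <- NA_real_
  cm$weights <- w
  cm$balanced <- TRUE
  cm$balance_converged <- converged
  cm
}

#' Expected contact frequency by distance
#'
#' Per chromosome, the mean balanced contact over all unmasked bin pairs
#' at each diagonal offset. Offsets with no unmasked pair are dropped.
#'
#' @param cm a balanced \code{contact_matrix}.
#' @return a data.frame with columns \code{chrom}, \code{diag} (offset in
#'   bins), \code{sum_balanced}, \code{n_valid}, \code{expected}; class
#'   \code{expected_profile}.
#' @export
expected_cis <- function(cm) {
  if (!cm$balanced) stop("balance the matrix first")
  idx <- chrom_index(cm$bins)
  out <- lapply(idx$chroms, function(ch) {
    n <- idx$n[[ch]]
    off <- idx$offset[[ch]]
    sel <- cm$pixels$bin1 > off & cm$pixels$bin1 <= off + n &
      cm$pixels$bin2 > off & cm$pixels$bin2 <= off + n
    px <- cm$pixels[sel, , drop = FALSE]
    val <- px$count * cm$weights[px$bin1] * cm$weights[px$bin2]
    d <- px$bin2 - px$bin1
    keep <- !is.na(val)
    sums <- numeric(n)
    if (any(keep)) {
      agg <- rowsum(val[keep], d[keep])
      sums[as.integer(rownames(agg)) + 1L] <- agg
    }
    valid <- as.numeric(!is.na(cm$weights[off + seq_len(n)]))
    nv <- valid_pairs_by_offset(valid)
    data.frame(chrom = ch, diag = 0:(n - 1L), sum_balanced = sums,
               n_valid = nv,
               expected = ifelse(nv > 0, sums / nv, NA_real_))
  })
  res <- do.call(rbind, out)
  res <- res[res$n_valid > 0, ]
  rownames(res) <- NULL
  class(res) <- c("expected_profile", "data.frame")
  res
}

# Number of unmasked pairs (i, i+d) for d = 0..n-1, via FFT
# autocorrelation of the validity indicator.
valid_pairs_by_offset <- function(valid) {
  n <- length(valid)
  if (n == 1) return(sum(valid))
  m <- stats::nextn(2 * n, 2)
  fv <- stats::fft(c(valid, rep(0, m - n)))
  ac <- Re(stats::fft(fv * Conj(fv), inverse = TRUE)) / m
  round(ac[seq_len(n)])
}

#' Observed/expected matrix
#'
#' Divides each balanced cis value by the distance-matched expected value
#' of its chromosome. Cells with zero counts have O/E 0 (not missing);
#' rows/columns of masked bins are undefined, recorded in \code{mask}.
#' The mean O/E over each diagonal equals 1 on unmasked pairs by
#' construction.
#'
#' @param cm a balanced \code{contact_matrix}.
#' @param expected optionally a precomputed \code{\link{expected_cis}}.
#' @return an object of class \code{oe_matrix}: list with \code{bins},
#'   \code{resolution}, per-chromosome symmetric sparse matrices
#'   \code{mats}, the per-bin validity \code{mask} (TRUE = usable) and
#'   the expected profile.
#' @export
oe_matrix <- function(cm, expected = NULL) {
  if (!cm$balanced) stop("balance the matrix first")
  if (is.null(expected)) expected <- expected_cis(cm)
  idx <- chrom_index(cm$bins)
  mats <- lapply(idx$chroms, function(ch) {
    n <- idx$n[[ch]]
    off <- idx$offset[[ch]]
    sel <- cm$pixels$bin1 > off & cm$pixels$bin1 <= off + n &
      cm$pixels$bin2 > off & cm$pixels$bin2 <= off + n
    px <- cm$pixels[sel, , drop = FALSE]
    val <- px$count * cm$weights[px$bin1] * cm$weights[px$bin2]
    d <- px$bin2 - px$bin1
    e <- expected[expected$chrom == ch, ]
    ev <- rep(NA_real_, n)
    ev[e$diag + 1L] <- e$expected
    oe <- val / ev[d + 1L]
    ok <- !is.na(oe)
    Matrix::sparseMatrix(i = (px$bin1 - off)[ok], j = (px$bin2 - off)[ok],
                         x = oe[ok], dims = c(n, n), symmetric = TRUE)
  })
  names(mats) <- idx$chroms
  structure(list(bins = cm$bins, resolution = cm$resolution, mats = mats,
                 mask = !is.na(cm$weights), expected = expected),
            class = "oe_matrix")
}
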