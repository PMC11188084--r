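#' Aggregate O/E pileup (APA)
#'
#' Element-wise mean of square O/E snippets centered on a set of targets:
#' either anchor pairs (snippets centered at the (a, b) pixel) or single
#' oriented anchors (snippets centered on the diagonal at (a, a);
#' reverse-oriented snippets are rotated 180 degrees so "downstream" is a
#' consistent axis). Snippets crossing a chromosome end are discarded and
#' counted; masked bins contribute nothing to the means.
#'
#' @param oe an \code{\link{oe_matrix}}.
#' @param targets a data.frame: pairs (\code{chrom}, \code{pos1},
#'   \code{pos2}) or single anchors (\code{chrom}, \code{pos}, optional
#'   \code{orientation}).
#' @param flank half-width of the snippet in bp.
#' @return an object of class \code{pileup}: list with the mean matrix
#'   \code{mat} (odd side length), \code{flank}, \code{resolution},
#'   \code{n_snippets}, \code{n_discarded}, \code{central_enrichment}.
#' @export
pileup <- function(oe, targets, flank) {
  res <- oe$resolution
  Fw <- as.integer(round(flank / res))
  side <- 2L * Fw + 1L
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  idx <- chrom_index(oe$bins)
  paired <- all(c("pos1", "pos2") %in% names(targets))
  if (!paired) stopifnot("pos" %in% names(targets))
  used <- 0L
  dropped <- 0L
  for (r in seq_len(nrow(targets))) {
    ch <- targets$chrom[r]
    if (!ch %in% names(oe$mats)) { dropped <- dropped + 1L; next }
    n <- idx$n[[ch]]
    off <- idx$offset[[ch]]
    if (paired) {
      bi <- floor(targets$pos1[r] / res) + 1
      bj <- floor(targets$pos2[r] / res) + 1
      if (bi > bj) { tmp <- bi; bi <- bj; bj <- tmp }
    } else {
      bi <- bj <- floor(targets$pos[r] / res) + 1
    }
    if (bi - Fw < 1 || bj + Fw > n || bj - Fw < 1 || bi + Fw > n) {
      dropped <- dropped + 1L
      next
    }
    snip <- as.matrix(oe$mats[[ch]][(bi - Fw):(bi + Fw),
                                    (bj - Fw):(bj + Fw), drop = FALSE])
    vi <- oe$mask[off + (bi - Fw):(bi + Fw)]
    vj <- oe$mask[off + (bj - Fw):(bj + Fw)]
    ok <- outer(vi, vj, "&")
    if (!paired && !is.null(targets$orientation) &&
        targets$orientation[r] == "-") {
      snip <- snip[side:1, side:1]
      ok <- ok[side:1, side:1]
    }
    snip[!ok] <- 0
    acc <- acc + snip
    cnt <- cnt + ok
    used <- used + 1L
  }
  if (used == 0) stop("no usable snippet")
  if (dropped > 0) message(dropped, " snippet(s) discarded (chromosome edge)")
  mat <- ifelse(cnt > 0, acc / cnt, NA_real_)
  out <- structure(list(mat = mat, flank = flank, resolution = res,
                        n_snippets = used, n_discarded = dropped),
                   class = "pileup")
  out$central_enrichment <- central_enrichment(out)
  out
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("Pileup: %dx%d at %g kb (flank %g kb), %d snippet(s), central enrichment %.3f\n",
              nrow(x$mat), ncol(x$mat), x$resolution / 1e3, x$flank / 1e3,
              x$n_snippets, x$central_enrichment))
  invisible(x)
}

#' Central enrichment of a pileup
#'
#' Mean of the three central pixels: the center and its two immediate
#' neighbors along the main diagonal (offsets (-1,-1), (0,0), (+1,+1)).
#' The diagonal triplet is used because pair pileups blur along the
#' diagonal; the alternative center-row triplet would mix in the
#' distance-decay direction.
#'
#' @param p a \code{pileup} (or a plain square matrix with odd side
#'   length of at least 3).
#' @return the enrichment score.
#' @export
central_enrichment <- function(p) {
  m <- if (inherits(p, "pileup")) p$mat else p
  stopifnot(nrow(m) == ncol(m), nrow(m) >= 3)
  c0 <- (nrow(m) + 1L) %/% 2L
  mean(c(m[c0 - 1L, c0 - 1L], m[c0, c0], m[c0 + 1L, c0 + 1L]))
}

#' Stripe orientation-bias profile
#'
#' Aggregates the O/E values along the row/column through oriented CTCF
#' anchors (the center lines of a single-anchor diagonal pileup):
#' \code{downstream(d)} is the mean O/E between an anchor and the locus
#' d bp downstream in the motif frame, \code{upstream(d)} the mean
#' toward the upstream locus (reverse-oriented anchors are flipped into
#' the forward frame), and \code{bias(d) = downstream(d)/upstream(d)}.
#'
#' @param oe an \code{\link{oe_matrix}}.
#' @param anchors an oriented \code{anchor_set} (\code{+} or \code{-}).
#' @param flank maximal offset in bp.
#' @return data.frame of class \code{stripe_profile}: \code{offset} (bp),
#'   \code{downstream}, \code{upstream}, \code{bias} (NA where the
#'   upstream mean is 0 or unobserved).
#' @export
stripe_bias <- function(oe, anchors, flank = 4e6) {
  a <- anchors[anchors$orientation %in% c("+", "-"), , drop = FALSE]
  if (nrow(a) == 0) stop("no oriented anchor")
  res <- oe$resolution
  Fw <- as.integer(round(flank / res))
  idx <- chrom_index(oe$bins)
  dn_sum <- numeric(Fw); dn_n <- numeric(Fw)
  up_sum <- numeric(Fw); up_n <- numeric(Fw)
  for (r in seq_len(nrow(a))) {
    ch <- a$chrom[r]
    if (!ch %in% names(oe$mats)) next
    n <- idx$n[[ch]]
    off <- idx$offset[[ch]]
    b <- floor(a$pos[r] / res) + 1
    if (b < 1 || b > n || !oe$mask[off + b]) next
    M <- oe$mats[[ch]]
    fwd <- a$orientation[r] == "+"
    # genomic right arm: pairs (b, b+d); genomic left arm: (b-d, b)
    d_hi_r <- min(Fw, n - b)
    if (d_hi_r >= 1) {
      dd <- seq_len(d_hi_r)
      vals <- as.vector(M[b, b + dd])
      ok <- oe$mask[off + b + dd]
      side <- if (fwd) "dn" else "up"
      if (side == "dn") {
        dn_sum[dd[ok]] <- dn_sum[dd[ok]] + vals[ok]
        dn_n[dd[ok]] <- dn_n[dd[ok]] + 1
      } else {
        up_sum[dd[ok]] <- up_sum[dd[ok]] + vals[ok]
        up_n[dd[ok]] <- up_n[dd[ok]] + 1
      }
    }
    d_hi_l <- min(Fw, b - 1)
    if (d_hi_l >= 1) {
      dd <- seq_len(d_hi_l)
      vals <- as.vector(M[b - dd, b])
      ok <- oe$mask[off + b - dd]
      side <- if (fwd) "up" else "dn"
      if (side == "dn") {
        dn_sum[dd[ok]] <- dn_sum[dd[ok]] + vals[ok]
        dn_n[dd[ok]] <- dn_n[dd[ok]] + 1
      } else {
        up_sum[dd[ok]] <- up_sum[dd[ok]] + vals[ok]
        up_n[dd[ok]] <- up_n[dd[ok]] + 1
      }
    }
  }
  dn <- ifelse(dn_n > 0, dn_sum / dn_n, NA_real_)
  up <- ifelse(up_n > 0, up_sum / up_n, NA_real_)
  out <- data.frame(offset = seq_len(Fw) * res, downstream = dn,
                    upstream = up,
                    bias = ifelse(!is.na(up) & up > 0, dn / up, NA_real_))
  class(out) <- c("stripe_profile", "data.frame")
  out
}

#' Fine-scale regulatory-element pileups
#'
#' Aggregation modes for fine-resolution (hundreds of bp) maps of a
#' simulated region: \code{tss_stripe} piles up oriented single-anchor
#' snippets around TSSs; \code{pp} and \code{pe} pile up
#' promoter-promoter and promoter-enhancer pairs with separations in
#' [d_min, d_max] (5 kb - 5 Mb by default; promoter-promoter pairs
#' exclude self-pairs). With \code{by_expression = TRUE}, promoters are
#' split into three equal-count expression groups and one
#' promoter-promoter pileup per group (within-group pairs) is returned.
#'
#' @param oe an \code{\link{oe_matrix}} of the fine-resolution map.
#' @param truth a fine-region ground truth
#'   (\code{\link{simulate_fine_features}}) providing \code{promoters},
#'   \code{enhancers}, \code{tss}.
#' @param mode one of \code{"tss_stripe"}, \code{"pp"}, \code{"pe"}.
#' @param flank snippet half-width (bp): classically 20 kb at 200 bp for
#'   TSS stripes, 30 kb at 400 bp for pp/pe.
#' @param d_min,d_max pair separation range (bp).
#' @param by_expression split promoters into expression tertiles
#'   (\code{"pp"} mode only).
#' @return a \code{pileup}, or a named list of pileups (High/Mid/Low)
#'   when splitting by expression; groups with zero usable pairs are
#'   omitted with a warning.
#' @export
fine_pileups <- function(oe, truth, mode = c("tss_stripe", "pp", "pe"),
                         flank = if (mode == "tss_stripe") 20e3 else 30e3,
                         d_min = 5e3, d_max = 5e6,
                         by_expression = FALSE) {
  mode <- match.arg(mode)
  if (mode == "tss_stripe") {
    return(pileup(oe, truth$tss, flank))
  }
  pr <- truth$promoters
  if (mode == "pe") {
    en <- truth$enhancers
    pairs <- expand.grid(i = seq_len(nrow(pr)), j = seq_len(nrow(en)))
    df <- data.frame(chrom = pr$chrom[pairs$i],
                     pos1 = pmin(pr$pos[pairs$i], en$pos[pairs$j]),
                     pos2 = pmax(pr$pos[pairs$i], en$pos[pairs$j]))
    df <- df[pr$chrom[pairs$i] == en$chrom[pairs$j], , drop = FALSE]
    df$distance <- df$pos2 - df$pos1
    df <- df[df$distance >= d_min & df$distance <= d_max, , drop = FALSE]
    return(pileup(oe, df, flank))
  }
  pp_pairs <- function(sub) {
    if (nrow(sub) < 2) return(NULL)
    cmb <- utils::combn(seq_len(nrow(sub)), 2)
    df <- data.frame(chrom = sub$chrom[cmb[1, ]],
                     pos1 = pmin(sub$pos[cmb[1, ]], sub$pos[cmb[2, ]]),
                     pos2 = pmax(sub$pos[cmb[1, ]], sub$pos[cmb[2, ]]))
    df <- df[sub$chrom[cmb[1, ]] == sub$chrom[cmb[2, ]], , drop = FALSE]
    d <- df$pos2 - df$pos1
    df[d >= d_min & d <= d_max, , drop = FALSE]
  }
  if (!by_expression) {
    return(pileup(oe, pp_pairs(pr), flank))
  }
  stopifnot(!is.null(pr$expression))
  ter <- cut(rank(pr$expression, ties.method = "first"),
             breaks = 3, labels = c("Low", "Mid", "High"))
  out <- list()
  for (g in c("High", "Mid", "Low")) {
    pg <- pp_pairs(pr[ter == g, , drop = FALSE])
    if (is.null(pg) || nrow(pg) == 0) {
      warning("no usable promoter pair in group ", g)
      next
    }
    out[[g]] <- pileup(oe, pg, flank)
  }
  out
}
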