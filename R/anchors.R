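#' Genomic anchor sets
#'
#' An anchor set is a sorted data.frame of point features (CTCF sites,
#' TSSs, promoters, enhancers) with columns \code{chrom}, \code{pos}
#' (bp), \code{orientation} (\code{"+"}, \code{"-"} or \code{"."}),
#' and optionally \code{strength}, \code{motif_p}, \code{class}.
#'
#' @param df a data.frame with at least \code{chrom} and \code{pos}.
#' @return the validated, sorted data.frame of class \code{anchor_set}.
#' @export
anchor_set <- function(df) {
  stopifnot(all(c("chrom", "pos") %in% names(df)))
  if (is.null(df$orientation)) df$orientation <- "."
  stopifnot(all(df$orientation %in% c("+", "-", ".")))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("anchor_set", "data.frame")
  df
}

#' Select strong, confident anchors
#'
#' Keeps the intersection of the top quartile of peak strength and the
#' quartile with the lowest motif p-values; both cuts are inclusive
#' (ties at the 75th / 25th percentile pass).
#'
#' @param anchors an \code{anchor_set} with \code{strength} and
#'   \code{motif_p}.
#' @return the filtered \code{anchor_set} (empty with a warning if
#'   nothing passes).
#' @export
select_anchors <- function(anchors) {
  if (nrow(anchors) == 0) return(anchors)
  stopifnot(!is.null(anchors$strength), !is.null(anchors$motif_p))
  s_cut <- stats::quantile(anchors$strength, 0.75)
  p_cut <- stats::quantile(anchors$motif_p, 0.25)
  out <- anchors[anchors$strength >= s_cut & anchors$motif_p <= p_cut, ,
                 drop = FALSE]
  if (nrow(out) == 0) warning("no anchor passed both quartile filters")
  rownames(out) <- NULL
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' Pair oriented anchors by motif orientation
#'
#' All same-chromosome pairs with separation in [d_min, d_max],
#' categorized by the orientations of the left and right anchors:
#' convergent (+,-), divergent (-,+), tandem_plus (+,+), tandem_minus
#' (-,-). Unoriented anchors are ignored.
#'
#' @param anchors an oriented \code{anchor_set}.
#' @param d_min,d_max separation range in bp (classically 100 kb - 2 Mb).
#' @return data.frame with \code{chrom}, \code{pos1}, \code{pos2},
#'   \code{distance}, \code{category}.
#' @export
pair_by_orientation <- function(anchors, d_min = 100e3, d_max = 2e6) {
  if (d_min > d_max) stop("d_min must not exceed d_max")
  a <- anchors[anchors$orientation %in% c("+", "-"), , drop = FALSE]
  rows <- list()
  for (ch in unique(a$chrom)) {
    sub <- a[a$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), ]
    n <- nrow(sub)
    if (n < 2) next
    ij <- which(outer(sub$pos, sub$pos, function(x, y) {
      d <- y - x
      d >= d_min & d <= d_max
    }), arr.ind = TRUE)
    if (nrow(ij) == 0) next
    i <- ij[, 1]; j <- ij[, 2]
    left <- sub$orientation[i]; right <- sub$orientation[j]
    category <- ifelse(left == "+" & right == "-", "convergent",
                ifelse(left == "-" & right == "+", "divergent",
                ifelse(left == "+", "tandem_plus", "tandem_minus")))
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = ch, pos1 = sub$pos[i], pos2 = sub$pos[j],
                 distance = sub$pos[j] - sub$pos[i], category = category)
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(0), pos1 = numeric(0),
                      pos2 = numeric(0), distance = numeric(0),
                      category = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos1, out$pos2), ]
}

#' Write / read anchors as BED6
#'
#' The strand column carries the CTCF motif orientation (\code{.} for
#' unoriented); the score column the peak strength. Coordinates are
#' 0-based half-open points of width 1.
#'
#' @param anchors an \code{anchor_set}.
#' @param path output file.
#' @export
write_bed <- function(anchors, path) {
  score <- if (is.null(anchors$strength)) 0 else anchors$strength
  df <- data.frame(anchors$chrom, as.integer(anchors$pos),
                   as.integer(anchors$pos) + 1L,
                   if (is.null(anchors$class)) "anchor" else anchors$class,
                   score, anchors$orientation)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  out <- data.frame(chrom = df$chrom, pos = df$start)
  if (ncol(df) >= 4) out$class <- df[[4]]
  if (ncol(df) >= 5) out$strength <- df[[5]]
  out$orientation <- if (ncol(df) >= 6) df[[6]] else "."
  anchor_set(out)
}

#' Write dot calls as BEDPE
#'
#' @param dots a dot-call data.frame (see \code{\link{call_dots}}).
#' @param path output file.
#' @param resolution bin size in bp.
#' @export
write_bedpe <- function(dots, path, resolution) {
  df <- data.frame(dots$chrom, as.integer(dots$pos1),
                   as.integer(dots$pos1 + resolution),
                   dots$chrom, as.integer(dots$pos2),
                   as.integer(dots$pos2 + resolution),
                   sprintf("dot%d", seq_len(nrow(dots))), dots$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
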