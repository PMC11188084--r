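#' Build a binned genome table
#'
#' Partitions each chromosome into consecutive 0-based half-open bins of
#' width \code{bin_size}; the last bin of a chromosome may be shorter.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width (bp).
#' @return a data.frame with columns \code{chrom}, \code{start},
#'   \code{end}; row \code{i} is bin id \code{i} (1-based). File exports
#'   use 0-based bin ids.
#' @export
build_genome <- function(chrom_lengths, bin_size) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (length(bin_size) != 1 || bin_size <= 0) stop("bin_size must be positive")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  pieces <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  attr(bins, "bin_size") <- bin_size
  attr(bins, "chrom_lengths") <- chrom_lengths
  bins
}

# Per-chromosome bin bookkeeping: first global bin id and bin count.
chrom_index <- function(bins) {
  chroms <- unique(bins$chrom)
  n <- vapply(chroms, function(ch) sum(bins$chrom == ch), integer(1))
  offset <- cumsum(c(0L, n[-length(n)]))
  names(offset) <- chroms
  list(chroms = chroms, n = n, offset = offset)
}

#' Map genomic positions to bin ids
#'
#' Bin assignment is \code{floor(pos / bin_size)} within the chromosome;
#' positions on unknown chromosomes or beyond the chromosome end map to
#' \code{NA}.
#'
#' @param bins a bin table from \code{\link{build_genome}}.
#' @param chrom,pos vectors of chromosome names and positions (bp).
#' @return global 1-based bin ids (row indices into \code{bins}).
#' @export
pos_to_bin <- function(bins, chrom, pos) {
  idx <- chrom_index(bins)
  bin_size <- attr(bins, "bin_size")
  if (is.null(bin_size)) bin_size <- stats::median(bins$end - bins$start)
  lens <- attr(bins, "chrom_lengths")
  if (is.null(lens)) {
    lens <- vapply(idx$chroms, function(ch) max(bins$end[bins$chrom == ch]),
                   numeric(1))
  }
  out <- rep(NA_real_, length(pos))
  known <- chrom %in% idx$chroms
  ok <- known & pos >= 0 & pos < lens[match(chrom, names(lens))]
  ok[is.na(ok)] <- FALSE
  out[ok] <- idx$offset[chrom[ok]] + floor(pos[ok] / bin_size) + 1
  out
}
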