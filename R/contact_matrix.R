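#' Binned contact matrix
#'
#' Sparse upper-triangle storage of binned contact counts over a genome
#' bin table, with optional balancing weights. Counts are stored with
#' \code{bin1 <= bin2} (global 1-based bin ids); balanced values are
#' \code{count * w[bin1] * w[bin2]}; masked bins have weight \code{NA}.
#'
#' @param bins a bin table from \code{\link{build_genome}} (optionally
#'   with a \code{gc} column).
#' @param pixels data.frame with columns \code{bin1}, \code{bin2},
#'   \code{count}; duplicate cells are summed, (i, j) is folded to
#'   \code{i <= j}.
#' @param resolution bin width in bp.
#' @return an object of class \code{contact_matrix}.
#' @export
contact_matrix <- function(bins, pixels, resolution = attr(bins, "bin_size")) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)),
            all(c("bin1", "bin2", "count") %in% names(pixels)))
  if (nrow(pixels) > 0) {
    stopifnot(all(pixels$count >= 0),
              all(pixels$bin1 >= 1), all(pixels$bin2 <= nrow(bins)))
    lo <- pmin(pixels$bin1, pixels$bin2)
    hi <- pmax(pixels$bin1, pixels$bin2)
    key <- (lo - 1) * nrow(bins) + hi
    agg <- rowsum(as.numeric(pixels$count), group = key)
    key <- as.numeric(rownames(agg))
    pixels <- data.frame(bin1 = (key - 1) %/% nrow(bins) + 1,
                         bin2 = (key - 1) %% nrow(bins) + 1,
                         count = as.vector(agg))
    pixels <- pixels[order(pixels$bin1, pixels$bin2), ]
    rownames(pixels) <- NULL
  }
  structure(list(bins = bins, pixels = pixels,
                 resolution = resolution,
                 weights = rep(NA_real_, nrow(bins)),
                 balanced = FALSE, balance_converged = NA),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("Contact matrix: %d bins (%d chromosome(s)) at %g kb, %s contacts%s\n",
              nrow(x$bins), length(unique(x$bins$chrom)),
              x$resolution / 1e3,
              format(sum(x$pixels$count), big.mark = ","),
              if (x$balanced) ", balanced" else ""))
  invisible(x)
}

#' Total contact count
#' @param cm a \code{contact_matrix}.
#' @export
total_contacts <- function(cm) sum(cm$pixels$count)

# Per-chromosome symmetric sparse matrix of counts or balanced values.
# Chromosome-local 1-based indexing. Masked bins carry zero balanced
# values; callers needing NA semantics consult cm$weights.
chrom_sparse <- function(cm, chrom, what = c("balanced", "count")) {
  what <- match.arg(what)
  idx <- chrom_index(cm$bins)
  stopifnot(chrom %in% idx$chroms)
  n <- idx$n[[chrom]]
  off <- idx$offset[[chrom]]
  sel <- cm$pixels$bin1 > off & cm$pixels$bin1 <= off + n &
    cm$pixels$bin2 > off & cm$pixels$bin2 <= off + n
  px <- cm$pixels[sel, , drop = FALSE]
  x <- px$count
  if (what == "balanced") {
    if (!cm$balanced) stop("matrix is not balanced")
    w <- cm$weights
    x <- x * w[px$bin1] * w[px$bin2]
    x[is.na(x)] <- 0
  }
  Matrix::sparseMatrix(i = px$bin1 - off, j = px$bin2 - off, x = x,
                       dims = c(n, n), symmetric = TRUE)
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Aggregates counts into bins of \code{factor * resolution}; GC content
#' is averaged with bin-width weights. Balancing weights are dropped
#' (re-balance at the new resolution).
#'
#' @param cm a \code{contact_matrix}.
#' @param factor integer coarsening factor.
#' @return a \code{contact_matrix} at the coarser resolution.
#' @export
coarsen_matrix <- function(cm, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(cm)
  lens <- attr(cm$bins, "chrom_lengths")
  if (is.null(lens)) {
    lens <- tapply(cm$bins$end, cm$bins$chrom, max)
    lens <- lens[unique(cm$bins$chrom)]
  }
  new_res <- cm$resolution * factor
  new_bins <- build_genome(lens, new_res)
  map <- pos_to_bin(new_bins, cm$bins$chrom, cm$bins$start)
  if ("gc" %in% names(cm$bins)) {
    wds <- cm$bins$end - cm$bins$start
    gc_sum <- rowsum(cm$bins$gc * wds, map)
    w_sum <- rowsum(wds, map)
    gc <- rep(NA_real_, nrow(new_bins))
    gc[as.numeric(rownames(gc_sum))] <- gc_sum / w_sum
    new_bins$gc <- gc
  }
  px <- cm$pixels
  pixels <- data.frame(bin1 = map[px$bin1], bin2 = map[px$bin2],
                       count = px$count)
  contact_matrix(new_bins, pixels, resolution = new_res)
}

#' Write / read a contact matrix as plain text
#'
#' Bins go to a BED-like TSV (\code{chrom, start, end[, gc]}); pixels to a
#' COO text file \code{bin1_id<TAB>bin2_id<TAB>count} with 0-based bin ids
#' and a header line naming the resolution. The round trip is lossless.
#'
#' @param cm a \code{contact_matrix}.
#' @param prefix output path prefix; writes \code{<prefix>.bins.tsv} and
#'   \code{<prefix>.coo.tsv}.
#' @return \code{prefix}, invisibly.
#' @export
write_matrix <- function(cm, prefix) {
  bins <- cm$bins
  utils::write.table(bins, paste0(prefix, ".bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(paste0(prefix, ".coo.tsv"), "w")
  writeLines(sprintf("# resolution=%d", as.integer(cm$resolution)), con)
  writeLines("bin1_id\tbin2_id\tcount", con)
  if (nrow(cm$pixels) > 0) {
    writeLines(sprintf("%d\t%d\t%s", cm$pixels$bin1 - 1L, cm$pixels$bin2 - 1L,
                       format(cm$pixels$count, scientific = FALSE,
                              trim = TRUE)), con)
  }
  close(con)
  invisible(prefix)
}

#' @rdname write_matrix
#' @param prefix path prefix used by \code{write_matrix}.
#' @export
read_matrix <- function(prefix) {
  bins <- utils::read.table(paste0(prefix, ".bins.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  lens <- tapply(bins$end, bins$chrom, max)
  lens <- lens[unique(bins$chrom)]
  attr(bins, "chrom_lengths") <- structure(as.numeric(lens),
                                           names = names(lens))
  hdr <- readLines(paste0(prefix, ".coo.tsv"), n = 1)
  res <- as.numeric(sub("# resolution=", "", hdr, fixed = TRUE))
  attr(bins, "bin_size") <- res
  coo <- utils::read.table(paste0(prefix, ".coo.tsv"), header = TRUE,
                           sep = "\t", comment.char = "#")
  contact_matrix(bins,
                 data.frame(bin1 = coo$bin1_id + 1L, bin2 = coo$bin2_id + 1L,
                            count = coo$count),
                 resolution = res)
}

#' Read a 4DN-style pairs file
#'
#' Expects whitespace/tab-separated columns \code{readID chrom1 pos1
#' chrom2 pos2 strand1 strand2}; lines starting with \code{#} are header.
#' Plain or gzip input.
#'
#' @param path pairs file path.
#' @return a data.frame of pairs.
#' @export
read_pairs <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- utils::read.table(con, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("readID", "chrom1", "pos1",
                                        "chrom2", "pos2",
                                        "strand1", "strand2"))
  if (!is.numeric(df$pos1) || !is.numeric(df$pos2))
    stop("malformed pairs file: non-numeric positions in ", path)
  df
}

#' Bin a pair stream into a contact matrix
#'
#' Bin assignment is \code{floor(pos / bin_size)}; pairs on unknown
#' chromosomes or beyond chromosome ends are skipped with a message.
#' (a, b) and (b, a) accumulate in the same cell; cis and trans pairs are
#' both stored.
#'
#' @param pairs a data.frame from \code{\link{read_pairs}}.
#' @param bins a bin table from \code{\link{build_genome}}.
#' @return a \code{contact_matrix}.
#' @export
bin_pairs <- function(pairs, bins) {
  b1 <- pos_to_bin(bins, pairs$chrom1, pairs$pos1)
  b2 <- pos_to_bin(bins, pairs$chrom2, pairs$pos2)
  ok <- !is.na(b1) & !is.na(b2)
  if (any(!ok))
    message(sum(!ok), " pair(s) skipped (unknown chromosome or position out of range)")
  pixels <- data.frame(bin1 = b1[ok], bin2 = b2[ok], count = 1L)
  cm <- contact_matrix(bins, pixels)
  cm$n_skipped <- sum(!ok)
  cm
}
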