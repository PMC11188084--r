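# Small shared helpers.

#' Write a per-bin track as bedGraph
#'
#' @param track data.frame with chrom/start/end plus a value column.
#' @param path output file.
#' @param column name of the value column.
#' @export
write_bedgraph <- function(track, path, column = "score") {
  stopifnot(column %in% names(track))
  df <- track[, c("chrom", "start", "end", column)]
  df <- df[is.finite(df[[column]]), ]
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Area under the ROC curve of score for binary labels (rank statistic).
rank_auc <- function(score, positive) {
  ok <- !is.na(score) & !is.na(positive)
  score <- score[ok]
  positive <- as.logical(positive[ok])
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
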