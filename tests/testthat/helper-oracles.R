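# Independent dense oracles and tiny fixture builders used across tests.

# Dense symmetric matrix from a contact_matrix (counts or balanced).
dense_counts <- function(cm, chrom = NULL) {
  bins <- cm$bins
  if (!is.null(chrom)) {
    keep <- bins$chrom == chrom
    off <- which(keep)[1] - 1
    n <- sum(keep)
    px <- cm$pixels[cm$pixels$bin1 > off & cm$pixels$bin1 <= off + n &
                      cm$pixels$bin2 > off & cm$pixels$bin2 <= off + n, ]
    px$bin1 <- px$bin1 - off
    px$bin2 <- px$bin2 - off
  } else {
    n <- nrow(bins)
    px <- cm$pixels
  }
  M <- matrix(0, n, n)
  for (r in seq_len(nrow(px))) {
    M[px$bin1[r], px$bin2[r]] <- M[px$bin1[r], px$bin2[r]] + px$count[r]
    if (px$bin1[r] != px$bin2[r])
      M[px$bin2[r], px$bin1[r]] <- M[px$bin2[r], px$bin1[r]] + px$count[r]
  }
  M
}

# Dense ICE oracle: plain elementwise iteration on the full matrix.
dense_ice <- function(M, tol = 1e-12, max_iter = 5000) {
  n <- nrow(M)
  w <- rep(1, n)
  mask <- rowSums(M) == 0
  w[mask] <- 0
  for (it in seq_len(max_iter)) {
    B <- outer(w, w) * M
    r <- rowSums(B)
    mu <- mean(r[!mask])
    if (stats::sd(r[!mask]) / mu < tol) break
    s <- r / mu
    s[mask | s == 0] <- 1
    w <- w / sqrt(s)
  }
  r <- rowSums(outer(w, w) * M)
  w / sqrt(mean(r[!mask]))
}

# Dense insulation oracle: literal diamond means per bin.
dense_insulation <- function(B, w) {
  n <- nrow(B)
  dmean <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    if (b - w < 1 || b + w > n) next
    dmean[b] <- mean(B[(b - w):(b - 1), (b + 1):(b + w)])
  }
  log2(dmean / mean(dmean, na.rm = TRUE))
}

# Dense expected-by-distance oracle.
dense_expected <- function(B) {
  n <- nrow(B)
  vapply(0:(n - 1), function(d) {
    mean(B[cbind(seq_len(n - d), seq_len(n - d) + d)])
  }, numeric(1))
}

# A quick balanced toy map sampled from the generator.
toy_map <- function(seed = 1, chrom_mb = 20, bin = 50e3, N = 2e5, ...) {
  p <- sim_params(chrom_lengths = c(chr1 = chrom_mb * 1e6), bin_size = bin,
                  seed = seed, ...)
  tr <- simulate_features(p, seed = seed)
  list(params = p, truth = tr,
       map = balance_matrix(sample_map(tr, p, N = N, seed = seed + 1)))
}

# Contact matrix with prescribed dense counts on a 1-chromosome genome.
cm_from_dense <- function(M, bin = 1e4) {
  n <- nrow(M)
  bins <- build_genome(c(chr1 = n * bin), bin)
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  contact_matrix(bins, data.frame(bin1 = idx[, 1], bin2 = idx[, 2],
                                  count = M[idx]), resolution = bin)
}

auc_of <- function(score, positive) meioc:::rank_auc(score, positive)
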