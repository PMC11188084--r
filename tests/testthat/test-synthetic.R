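test_that("genome binning produces consecutive half-open bins", {
  b1 <- build_genome(c(chr1 = 1e6), 1e4)
  expect_equal(nrow(b1), 100)
  expect_equal(b1$start[1], 0)
  expect_equal(b1$end[100], 1e6)

  b2 <- build_genome(c(chr1 = 1005000), 1e4)
  expect_equal(nrow(b2), 101)
  expect_equal(b2$end[101] - b2$start[101], 5000)

  b3 <- build_genome(c(a = 2e6, b = 1e6, c = 0.5e6), 5e4)
  expect_equal(nrow(b3), sum(ceiling(c(2e6, 1e6, 0.5e6) / 5e4)))
  expect_equal(nrow(b3), 70)

  expect_error(build_genome(c(chr1 = -5), 1e4), "positive")
  expect_error(build_genome(c(chr1 = 1e6), 0), "positive")
})

test_that("simulated features follow the prescribed distributions", {
  p <- sim_params(chrom_lengths = c(chr1 = 100e6), bin_size = 50e3,
                  loop_mean = 200e3, loop_shape = 4, n_dots = 100,
                  ctcf_fraction = 0.8, seed = 11)
  tr <- simulate_features(p)

  # determinism
  tr2 <- simulate_features(p, seed = 11)
  expect_identical(tr$anchors, tr2$anchors)
  expect_identical(tr$comp, tr2$comp)

  # anchors strictly increasing, spacing moments match Gamma(k, L/k)
  aa <- tr$anchors$chr1
  expect_true(all(diff(aa) > 0))
  sp <- diff(aa)
  expect_gt(length(sp), 400)
  se <- sd(sp) / sqrt(length(sp))
  expect_lt(abs(mean(sp) - 200e3), 3 * se)

  # GC is strictly higher on A bins
  expect_true(all(tr$bins$gc[tr$comp > 0] > max(tr$bins$gc[tr$comp < 0])))

  # dot pairs ordered; CTCF assignment frequency matches ctcf_fraction
  expect_true(all(tr$dot_pairs$a < tr$dot_pairs$b))
  hits <- c(tr$dot_pairs$ctcf_left, tr$dot_pairs$ctcf_right)
  phat <- mean(hits)
  se_b <- sqrt(0.8 * 0.2 / length(hits))
  expect_lt(abs(phat - 0.8), 4 * se_b)

  # every CTCF site sits at a dot-pair end
  ends <- c(tr$dot_pairs$a, tr$dot_pairs$b)
  expect_true(all(tr$ctcf$pos %in% ends))
})

test_that("degenerate orientation mix yields only convergent pairs", {
  p <- sim_params(chrom_lengths = c(chr1 = 50e6), bin_size = 50e3,
                  loop_mean = 500e3, n_dots = 40, ctcf_fraction = 1,
                  orientation_mix = c(1, 0, 0, 0), seed = 5)
  tr <- simulate_features(p)
  expect_true(all(tr$dot_pairs$category == "convergent"))
  expect_true(all(tr$dot_pairs$orient_left == "+"))
  expect_true(all(tr$dot_pairs$orient_right == "-"))
})

test_that("invalid parameters are rejected", {
  expect_error(sim_params(alpha = 0), "alpha")
  expect_error(sim_params(orientation_mix = c(1, 1, 0, 0)), "sum to 1")
  expect_error(sim_params(contamination = 1.5), "\\[0, 1\\]")
  p <- sim_params(mean_interval = 1e3, bin_size = 50e3)
  expect_error(simulate_features(p), "mean_interval")
})

test_that("contact weights obey the model formula", {
  p <- sim_params(chrom_lengths = c(chr1 = 20e6), bin_size = 50e3,
                  sigma = 0.3, loop_amp = 1, loop_mean = 300e3,
                  n_dots = 15, stripe_amp = 1, stripe_beta = 2, seed = 3)
  tr <- simulate_features(p)

  # pure power law: doubling the distance scales by 2^-alpha exactly
  p0 <- sim_params(chrom_lengths = c(chr1 = 20e6), bin_size = 50e3,
                   sigma = 0, loop_amp = 0, dot_amp = 0, n_dots = 0,
                   stripe_amp = 0, alpha = 1.1, seed = 3)
  tr0 <- simulate_features(p0)
  w1 <- contact_probability(1, 51, tr0, p0)
  w2 <- contact_probability(1, 101, tr0, p0)
  expect_equal(w2 / w1, 2^-1.1, tolerance = 1e-12)

  # symmetry on random pairs
  set.seed(42)
  i <- sample(400, 1000, replace = TRUE)
  j <- sample(400, 1000, replace = TRUE)
  expect_equal(contact_probability(i, j, tr, p),
               contact_probability(j, i, tr, p))

  # same-label over cross-label ratio at equal separation = exp(2 sigma)
  v <- tr$comp
  d <- 40  # beyond loop blur at these settings
  same <- which(v[1:(400 - d)] * v[(1 + d):400] > 0)
  cross <- which(v[1:(400 - d)] * v[(1 + d):400] < 0)
  # pick pairs without bump or stripe contamination
  clean <- function(ii) {
    w <- contact_probability(ii, ii + d, tr, p)
    ii[abs(w / ((d * 50e3)^(-1.1) * exp(p$sigma * v[ii] * v[ii + d])) - 1) < 1e-6]
  }
  s_ok <- clean(same); c_ok <- clean(cross)
  expect_gt(length(s_ok), 0); expect_gt(length(c_ok), 0)
  ratio <- contact_probability(s_ok[1], s_ok[1] + d, tr, p) /
    contact_probability(c_ok[1], c_ok[1] + d, tr, p)
  expect_equal(ratio, exp(2 * p$sigma), tolerance = 1e-9)

  # fast per-diagonal path equals the reference on every sampled pair
  W <- meioc:::diag_weights(tr, p, "chr1")
  set.seed(7)
  dd <- sample(0:100, 300, replace = TRUE)
  ii <- vapply(dd, function(d) sample(400 - d, 1), numeric(1))
  ref <- contact_probability(ii, ii + dd, tr, p)
  fast <- mapply(function(i, d) W[[d + 1]][i], ii, dd)
  # the two paths factor the Gaussian differently; equality is to
  # floating-point reassociation error
  expect_lt(max(abs(fast - ref) / ref), 1e-8)
})

test_that("sampled maps conserve totals, are deterministic and fit the model", {
  p <- sim_params(chrom_lengths = c(chr1 = 5e6), bin_size = 50e3,
                  sigma = 0.4, loop_amp = 1, loop_mean = 500e3,
                  n_dots = 5, seed = 9)
  tr <- simulate_features(p)

  expect_equal(total_contacts(sample_map(tr, p, N = 0, seed = 1)), 0)

  m1 <- sample_map(tr, p, N = 1e5, seed = 2)
  m2 <- sample_map(tr, p, N = 1e5, seed = 2)
  expect_identical(m1$pixels, m2$pixels)
  expect_equal(total_contacts(m1), 1e5)
  expect_true(all(m1$pixels$bin1 <= m1$pixels$bin2))

  # goodness of fit on a 100-bin toy at N = 1e6: chi-square over pairs
  m <- sample_map(tr, p, N = 1e6, seed = 3)
  W <- meioc:::diag_weights(tr, p, "chr1")
  n <- 100
  E <- matrix(0, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    E[cbind(i, i + d)] <- W[[d + 1]]
  }
  E <- E / sum(E) * 1e6
  O <- matrix(0, n, n)
  O[cbind(m$pixels$bin1, m$pixels$bin2)] <- m$pixels$count
  keep <- upper.tri(E, diag = TRUE) & E >= 5
  chi <- sum((O[keep] - E[keep])^2 / E[keep])
  df <- sum(keep) - 1
  expect_gt(stats::pchisq(chi, df, lower.tail = FALSE), 0.001)
})

test_that("analytic P(s) matches the average of sampled curves", {
  p <- sim_params(chrom_lengths = c(chr1 = 20e6), bin_size = 50e3,
                  sigma = 0, loop_amp = 1, loop_mean = 500e3,
                  n_dots = 0, seed = 13)
  tr <- simulate_features(p)
  an <- analytic_ps(tr, p, bins_per_decade = 8, normalize = TRUE)

  acc <- NULL
  n_rep <- 20
  for (k in seq_len(n_rep)) {
    m <- sample_map(tr, p, N = 2e5, seed = 100 + k)
    # unit weights: the oracle is the expectation of the raw counts
    # (balancing reweights chromosome-end bins and is tested elsewhere)
    m$weights <- rep(1, nrow(m$bins)); m$balanced <- TRUE
    cur <- compute_ps(m, bins_per_decade = 8)
    stopifnot(nrow(cur) == nrow(an))
    v <- cur$P / sum(cur$P * cur$n_pairs)
    acc <- if (is.null(acc)) v else acc + v
  }
  mean_curve <- acc / n_rep
  # Monte-Carlo agreement where the aggregate count is large enough
  # that the MC standard error is ~2% (3 SE margin below)
  exp_counts <- an$P * an$n_pairs * 2e5 * n_rep
  deep <- exp_counts >= 2000
  expect_gt(sum(deep), 10)
  expect_lt(max(abs(log(mean_curve[deep] / an$P[deep]))), 0.07)

  # lambda = 0: constant log-log slope equal to -alpha
  p0 <- sim_params(chrom_lengths = c(chr1 = 20e6), bin_size = 50e3,
                   sigma = 0, loop_amp = 0, n_dots = 0, alpha = 1.3,
                   seed = 13)
  tr0 <- simulate_features(p0)
  an0 <- derivative_loglog(smooth_loglog(analytic_ps(tr0, p0), 0.1))
  # binned power law: slope constant away from the chromosome-length
  # tail, where bins run out of pairs
  interior <- an0$s <= 20e6 / 8
  expect_true(all(abs(an0$deriv[interior] + 1.3) < 0.02))

  # lambda > 0 exceeds the lambda = 0 curve maximally near the mode of
  # the anchor-spacing density, (k-1)/k * L (large genome so the
  # realized spacing histogram localizes the mode)
  # narrow blur so the excess profile localizes the spacing density
  pL <- sim_params(chrom_lengths = c(chr1 = 100e6), bin_size = 50e3,
                   sigma = 0, loop_amp = 1, loop_mean = 500e3,
                   dot_width = 50e3, n_dots = 0, seed = 14)
  trL <- simulate_features(pL)
  anL <- analytic_ps(trL, pL, normalize = FALSE)
  tr0L <- trL
  tr0L$bumps <- NULL   # same model without the loop array
  an0b <- analytic_ps(tr0L, pL, normalize = FALSE)
  excess <- anL$P / an0b$P
  expect_true(all(excess >= 1 - 1e-12))
  s_peak <- anL$s[which.max(excess)]
  expect_lt(abs(s_peak - 375e3) / 375e3, 0.4)  # near the spacing mode
})

test_that("map mixing matches the brute-force expectation", {
  p <- sim_params(chrom_lengths = c(chr1 = 1e6), bin_size = 50e3,
                  sigma = 0.4, loop_amp = 0, n_dots = 0, seed = 21)
  tr <- simulate_features(p)
  a <- sample_map(tr, p, N = 5e4, seed = 1)
  p2 <- sim_params(chrom_lengths = c(chr1 = 1e6), bin_size = 50e3,
                   sigma = 0, loop_amp = 0, n_dots = 0, alpha = 0.8,
                   seed = 22)
  tr2 <- simulate_features(p2)
  b <- sample_map(tr2, p2, N = 5e4, seed = 2)

  mx <- mix_maps(a, b, 0.3, N = 2e6, seed = 3)
  expect_equal(total_contacts(mx), 2e6)

  # expected count per pair = N * (0.7 pa + 0.3 pb), checked cell by cell
  key <- function(m) (m$pixels$bin1 - 1) * 20 + m$pixels$bin2
  all_keys <- sort(unique(c(key(a), key(b))))
  pa <- pb <- numeric(length(all_keys))
  pa[match(key(a), all_keys)] <- a$pixels$count / 5e4
  pb[match(key(b), all_keys)] <- b$pixels$count / 5e4
  expected <- 2e6 * (0.7 * pa + 0.3 * pb)
  obs <- numeric(length(all_keys))
  obs[match(key(mx), all_keys)] <- mx$pixels$count
  z <- (obs - expected) / sqrt(pmax(expected, 1))
  expect_lt(max(abs(z)), 5)

  # f = 0 / f = 1 recover the marginal distributions
  m0 <- mix_maps(a, b, 0, N = 2e6, seed = 4)
  obs0 <- numeric(length(all_keys))
  obs0[match(key(m0), all_keys)] <- m0$pixels$count
  z0 <- (obs0 - 2e6 * pa) / sqrt(pmax(2e6 * pa, 1))
  expect_lt(max(abs(z0)), 5)

  # incompatible bin tables are refused
  p3 <- sim_params(chrom_lengths = c(chr1 = 2e6), bin_size = 50e3, seed = 1)
  tr3 <- simulate_features(p3)
  c3 <- sample_map(tr3, p3, N = 1e3, seed = 5)
  expect_error(mix_maps(a, c3, 0.5, 100, 1), "bin tables differ")
})
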