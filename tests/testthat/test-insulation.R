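test_that("insulation matches the dense diamond oracle", {
  # 40-bin random toy, window 5 bins
  set.seed(14)
  R <- matrix(rpois(1600, 12), 40); R <- R + t(R)
  cm <- balance_matrix(cm_from_dense(R, bin = 1e4), tol = 1e-10)
  trk <- insulation(cm, window = 5e4)
  B <- outer(cm$weights, cm$weights) * dense_counts(cm)
  oracle <- dense_insulation(B, 5)
  ok <- trk$valid
  expect_equal(trk$score[ok], oracle[ok], tolerance = 1e-12)
  expect_true(all(is.na(oracle[!ok]) | !is.finite(oracle[!ok])) ||
                all(which(ok) == which(is.finite(oracle))))

  # uniform matrix: all valid scores are zero
  cmu <- balance_matrix(cm_from_dense(matrix(3, 40, 40), bin = 1e4))
  tru <- insulation(cmu, window = 5e4)
  expect_true(all(abs(tru$score[tru$valid]) < 1e-10))

  # two-block toy: unique minimum at the junction
  Bl <- matrix(0.01, 40, 40)
  Bl[1:20, 1:20] <- 5; Bl[21:40, 21:40] <- 5
  cmb <- balance_matrix(cm_from_dense(round(Bl * 10), bin = 1e4))
  trb <- insulation(cmb, window = 5e4)
  v <- which(trb$valid)
  expect_equal(trb$bin[v][which.min(trb$score[v])], 21, tolerance = 1)

  # chromosome shorter than twice the window: all invalid with warning
  expect_warning(ts <- insulation(balance_matrix(cm_from_dense(
    matrix(2, 8, 8), bin = 1e4)), window = 5e4), "shorter")
  expect_true(all(!ts$valid))
})

test_that("boundary calling separates real minima from noise by Li threshold", {
  # flat track: no boundaries
  flat <- data.frame(chrom = "chr1", start = (0:49) * 1e4,
                     end = (1:50) * 1e4, bin = 1:50,
                     score = rep(0, 50), valid = TRUE)
  attr(flat, "resolution") <- 1e4
  class(flat) <- c("insulation_track", "data.frame")
  expect_equal(nrow(call_boundaries(flat)), 0)

  # one deep minimum (prominence 2.0) and one negligible dip (0.01):
  # only the deep one is retained
  sc <- rep(0, 60)
  sc[20] <- -2.0
  sc[40] <- -0.01
  tr <- flat[rep(1, 60), ]
  tr$start <- (0:59) * 1e4; tr$end <- (1:60) * 1e4; tr$bin <- 1:60
  tr$score <- sc
  attr(tr, "resolution") <- 1e4
  class(tr) <- c("insulation_track", "data.frame")
  bd <- call_boundaries(tr)
  expect_equal(bd$bin, 20)
  expect_equal(bd$strength, 2.0)

  # without thresholding both minima appear
  bd_all <- call_boundaries(tr, method = "none")
  expect_setequal(bd_all$bin, c(20, 40))

  # Li threshold separates a bimodal strength sample
  x <- c(rep(0.01, 20), rep(2, 5))
  thr <- li_threshold(x)
  expect_gt(thr, 0.01)
  expect_lt(thr, 2)
})

test_that("implanted domain junctions are recovered with high fidelity", {
  p <- sim_params(chrom_lengths = c(chr1 = 20e6), bin_size = 10e3,
                  sigma = 0, loop_amp = 0, n_dots = 0,
                  domain_junctions = 10, domain_attenuation = 0.2,
                  seed = 5)
  tr <- simulate_features(p)
  m <- balance_matrix(sample_map(tr, p, N = 5e6, seed = 6))
  trk <- insulation(m, window = 100e3)
  bd <- call_boundaries(trk)
  true_pos <- tr$domain_bounds$chr1
  hit <- vapply(true_pos, function(tp) any(abs(bd$pos - tp) <= 1.5e4),
                logical(1))
  prec <- vapply(bd$pos, function(bp) any(abs(true_pos - bp) <= 1.5e4),
                 logical(1))
  expect_gte(mean(hit), 0.9)
  expect_gte(mean(prec), 0.9)

  # translation equivariance: the track minima sit at the junction bins
  jb <- floor(true_pos / 1e4) + 1
  expect_true(all(vapply(bd$bin, function(b) min(abs(jb - b)) <= 1,
                         logical(1))))
})

test_that("conserved boundaries follow the expansion-overlap rule", {
  mk <- function(pos) {
    df <- data.frame(chrom = "chr1", start = pos - 5e3, end = pos + 5e3,
                     bin = seq_along(pos), pos = pos,
                     score = -1, strength = 1)
    class(df) <- c("boundary_set", "data.frame")
    df
  }
  a <- mk(c(100e3, 500e3))
  expect_equal(conserved_boundaries(a, a)$pos, a$pos)   # identity

  b1 <- mk(115e3)
  expect_equal(conserved_boundaries(mk(100e3), b1, slack = 10e3)$pos, 100e3)
  b2 <- mk(125e3)
  expect_equal(nrow(conserved_boundaries(mk(100e3), b2, slack = 10e3)), 0)

  # conserved domains span adjacent conserved boundaries
  cons <- conserved_boundaries(a, mk(c(98e3, 502e3)), slack = 10e3)
  doms <- attr(cons, "domains")
  expect_equal(nrow(doms), 1)
  expect_equal(doms$start, 100e3)
  expect_equal(doms$end, 500e3)
})

test_that("boundary profiles average windows and normalize minima to zero", {
  set.seed(15)
  n <- 200
  sc <- rnorm(n, sd = 0.05)
  bpos <- c(50, 120, 170)
  for (b in bpos) sc[b] <- sc[b] - 1
  tr <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e4,
                   end = (1:n) * 1e4, bin = 1:n, score = sc, valid = TRUE)
  attr(tr, "resolution") <- 1e4
  class(tr) <- c("insulation_track", "data.frame")
  bd <- data.frame(chrom = "chr1", start = (bpos - 1) * 1e4,
                   end = bpos * 1e4, bin = bpos,
                   pos = (bpos - 0.5) * 1e4, score = sc[bpos], strength = 1)
  prof <- boundary_profile(tr, bd, flank = 150e3)
  expect_equal(min(prof), 0)
  # element-wise oracle
  Fw <- 15
  oracle <- rowMeans(vapply(bpos, function(b) sc[(b - Fw):(b + Fw)],
                            numeric(2 * Fw + 1)))
  oracle <- oracle - min(oracle)
  expect_equal(as.numeric(prof), oracle, tolerance = 1e-12)

  # single boundary: profile equals that window minus its minimum
  p1 <- boundary_profile(tr, bd[1, ], flank = 150e3)
  w1 <- sc[(50 - Fw):(50 + Fw)]
  expect_equal(as.numeric(p1), w1 - min(w1), tolerance = 1e-12)

  # flat track gives an all-zero profile
  trf <- tr; trf$score <- 0
  class(trf) <- class(tr); attr(trf, "resolution") <- 1e4
  expect_true(all(boundary_profile(trf, bd, flank = 150e3) == 0))

  # boundary too close to the end is excluded with a message
  bd_edge <- rbind(bd, data.frame(chrom = "chr1", start = (n - 2) * 1e4,
                                  end = (n - 1) * 1e4, bin = n - 1,
                                  pos = (n - 1.5) * 1e4, score = 0,
                                  strength = 1))
  expect_message(boundary_profile(tr, bd_edge, flank = 150e3), "excluded")
})

test_that("insulation delta is max minus min and shift-invariant", {
  expect_equal(insulation_delta(c(0, 0.3, 1.1, 0.2)), 1.1)
  expect_equal(insulation_delta(rep(0.4, 10)), 0)
  x <- runif(20)
  expect_equal(insulation_delta(x + 5), insulation_delta(x))
})

test_that("insulation delta increases with inter-domain attenuation", {
  deltas <- vapply(c(0.8, 0.5, 0.2), function(att) {
    p <- sim_params(chrom_lengths = c(chr1 = 20e6), bin_size = 10e3,
                    sigma = 0, loop_amp = 0, n_dots = 0,
                    domain_junctions = 10, domain_attenuation = att,
                    seed = 5)
    tr <- simulate_features(p)
    m <- balance_matrix(sample_map(tr, p, N = 2e6, seed = 6))
    trk <- insulation(m, window = 100e3)
    jb <- floor(tr$domain_bounds$chr1 / 1e4) + 1
    bds <- data.frame(chrom = "chr1", start = (jb - 1) * 1e4,
                      end = jb * 1e4, bin = jb, pos = (jb - 0.5) * 1e4,
                      score = 0, strength = 1)
    suppressMessages(insulation_delta(boundary_profile(trk, bds,
                                                       flank = 150e3)))
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))
})
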