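test_that("anchor selection intersects the two quartile filters", {
  a <- anchor_set(data.frame(chrom = "chr1", pos = (1:8) * 1e5,
                             orientation = "+",
                             strength = 1:8, motif_p = 8:1))
  sel <- select_anchors(a)
  expect_setequal(sel$strength, c(7, 8))

  # all-equal strengths: ties at the cut are included
  a2 <- anchor_set(data.frame(chrom = "chr1", pos = (1:8) * 1e5,
                              orientation = "+",
                              strength = 5, motif_p = 8:1))
  sel2 <- select_anchors(a2)
  expect_setequal(sel2$motif_p, 1:2)

  # empty input stays empty
  a0 <- anchor_set(data.frame(chrom = character(0), pos = numeric(0),
                              orientation = character(0),
                              strength = numeric(0), motif_p = numeric(0)))
  expect_equal(nrow(select_anchors(a0)), 0)

  # disjoint quartiles produce an empty set with a warning
  a3 <- anchor_set(data.frame(chrom = "chr1", pos = (1:8) * 1e5,
                              orientation = "+",
                              strength = 1:8, motif_p = 1:8))
  expect_warning(sel3 <- select_anchors(a3), "no anchor")
  expect_equal(nrow(sel3), 0)
})

test_that("orientation pairing matches exhaustive enumeration", {
  a <- anchor_set(data.frame(chrom = "chr1", pos = c(1.0e6, 1.5e6),
                             orientation = c("+", "-")))
  pr <- pair_by_orientation(a)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$category, "convergent")

  # 4 anchors alternating orientations at 300 kb spacing: all 6 pairs
  # are in range; categories from brute force
  a4 <- anchor_set(data.frame(chrom = "chr1", pos = (1:4) * 3e5 + 1e6,
                              orientation = c("+", "-", "+", "-")))
  pr4 <- pair_by_orientation(a4, d_min = 100e3, d_max = 2e6)
  expect_equal(nrow(pr4), 6)
  expect_equal(sum(pr4$category == "convergent"), 3)   # (1,2),(1,4),(3,4)
  expect_equal(sum(pr4$category == "divergent"), 1)    # (2,3)
  expect_equal(sum(pr4$category == "tandem_plus"), 1)  # (1,3)
  expect_equal(sum(pr4$category == "tandem_minus"), 1) # (2,4)

  # spacing below d_min excluded
  a5 <- anchor_set(data.frame(chrom = "chr1", pos = c(1e6, 1.05e6),
                              orientation = c("+", "-")))
  expect_equal(nrow(pair_by_orientation(a5)), 0)

  expect_error(pair_by_orientation(a, d_min = 2e6, d_max = 1e6), "d_min")
})

test_that("BED round trips preserve anchors", {
  a <- anchor_set(data.frame(chrom = c("chr1", "chr1", "chr2"),
                             pos = c(1e5, 3e5, 2e5),
                             orientation = c("+", "-", "."),
                             strength = c(2, 1, 3),
                             class = "CTCF"))
  path <- tempfile(fileext = ".bed")
  write_bed(a, path)
  b <- read_bed(path)
  expect_equal(b$pos, a$pos)
  expect_equal(b$orientation, a$orientation)
  expect_equal(b$strength, a$strength)
})

test_that("pileups average O/E snippets exactly", {
  # uniform O/E: all-ones pileup
  cmu <- balance_matrix(cm_from_dense(matrix(5, 60, 60), bin = 1e4))
  oeu <- oe_matrix(cmu)
  pu <- pileup(oeu, data.frame(chrom = "chr1", pos1 = 2e5, pos2 = 4e5),
               flank = 5e4)
  expect_true(all(abs(pu$mat - 1) < 1e-10))
  expect_equal(pu$central_enrichment, 1)

  # mean of 2 snippets equals hand-computed element-wise average
  set.seed(17)
  R <- matrix(rpois(3600, 10), 60); R <- R + t(R)
  cm <- balance_matrix(cm_from_dense(R, bin = 1e4))
  oem <- oe_matrix(cm)
  tg <- data.frame(chrom = "chr1", pos1 = c(2e5, 3.1e5),
                   pos2 = c(4.4e5, 5.2e5))
  pu2 <- pileup(oem, tg, flank = 2e4)
  M <- as.matrix(oem$mats$chr1)
  sn <- function(i, j, F) M[(i - F):(i + F), (j - F):(j + F)]
  oracle <- (sn(21, 45, 2) + sn(32, 53, 2)) / 2
  expect_equal(pu2$mat, oracle, tolerance = 1e-12)

  # linearity: union pileup is the snippet-count-weighted mean
  puA <- pileup(oem, tg[1, ], flank = 2e4)
  puB <- pileup(oem, tg[2, ], flank = 2e4)
  expect_equal(pu2$mat, (puA$mat + puB$mat) / 2, tolerance = 1e-12)

  # snippets crossing the chromosome end are discarded with a message
  expect_message(
    pu3 <- pileup(oem, rbind(tg, data.frame(chrom = "chr1", pos1 = 1e4,
                                            pos2 = 5.9e5)), flank = 2e4),
    "discarded")
  expect_equal(pu3$n_snippets, 2)
  expect_error(pileup(oem, data.frame(chrom = "chr1", pos1 = 0, pos2 = 5.9e5),
                      flank = 2e4), "no usable snippet")
})

test_that("central enrichment is the mean of the three diagonal pixels", {
  m <- matrix(1, 5, 5)
  expect_equal(central_enrichment(m), 1)
  m[3, 3] <- 3; m[2, 2] <- 2; m[4, 4] <- 1
  expect_equal(central_enrichment(m), 2)
  # increases monotonically with the generator dot amplitude
  enr <- vapply(c(0.5, 1, 2), function(delta) {
    p <- sim_params(chrom_lengths = c(chr1 = 30e6), bin_size = 50e3,
                    sigma = 0, loop_amp = 0, dot_amp = delta, n_dots = 30,
                    loop_mean = 500e3, dot_width = 50e3, seed = 18)
    tr <- simulate_features(p, seed = 18)   # same layout, varying delta
    m <- balance_matrix(sample_map(tr, p, N = 3e6, seed = 19))
    oem <- oe_matrix(m)
    pu <- pileup(oem, data.frame(chrom = tr$dot_pairs$chrom,
                                 pos1 = tr$dot_pairs$a,
                                 pos2 = tr$dot_pairs$b), flank = 2e5)
    pu$central_enrichment
  }, numeric(1))
  expect_true(all(diff(enr) > 0))
})

test_that("dot calls respect the band, the separation and the truth", {
  # uniform O/E: no calls
  cmu <- balance_matrix(cm_from_dense(matrix(5, 80, 80), bin = 1e4))
  expect_equal(nrow(call_dots(oe_matrix(cmu), min_dist = 5e4,
                              max_dist = 5e5)), 0)

  # implanted dots: recovery, band contract, min separation
  p <- sim_params(chrom_lengths = c(chr1 = 50e6), bin_size = 50e3,
                  sigma = 0, loop_amp = 0, dot_amp = 2, n_dots = 50,
                  loop_mean = 500e3, dot_width = 50e3,
                  ctcf_fraction = 0.8, seed = 12)
  tr <- simulate_features(p)
  m <- balance_matrix(sample_map(tr, p, N = 1e7, seed = 13))
  oem <- oe_matrix(m)
  dots <- call_dots(oem, min_dist = 100e3, max_dist = 10e6, cm = m)
  expect_true(all(dots$distance >= 100e3 & dots$distance <= 10e6))
  # pairwise Chebyshev separation respects min_sep
  if (nrow(dots) > 1) {
    dd <- as.matrix(dist(cbind(dots$bin1, dots$bin2), method = "maximum"))
    diag(dd) <- Inf
    expect_true(all(dd * 50e3 >= 10e3))
  }
  tb <- cbind(floor(tr$dot_pairs$a / 5e4) + 1, floor(tr$dot_pairs$b / 5e4) + 1)
  hit <- vapply(seq_len(nrow(tb)), function(k)
    any(abs(dots$bin1 - tb[k, 1]) <= 1 & abs(dots$bin2 - tb[k, 2]) <= 1),
    logical(1))
  prec <- vapply(seq_len(nrow(dots)), function(k)
    any(abs(tb[, 1] - dots$bin1[k]) <= 1 & abs(tb[, 2] - dots$bin2[k]) <= 1),
    logical(1))
  expect_gte(mean(hit), 0.9)
  expect_gte(mean(prec), 0.8)

  # a dot implanted below min_dist is never called
  p2 <- sim_params(chrom_lengths = c(chr1 = 10e6), bin_size = 1e4,
                   sigma = 0, loop_amp = 0, dot_amp = 3, n_dots = 5,
                   loop_mean = 30e3, loop_shape = 100, dot_width = 1e4,
                   seed = 14)
  tr2 <- simulate_features(p2)
  # all dot pairs are ~30 kb apart, below the 50 kb floor
  expect_true(all(tr2$dot_pairs$b - tr2$dot_pairs$a < 5e4))
  m2 <- balance_matrix(sample_map(tr2, p2, N = 2e6, seed = 15))
  d2 <- call_dots(oe_matrix(m2), min_dist = 5e4, max_dist = 5e6, cm = m2)
  tb2 <- cbind(floor(tr2$dot_pairs$a / 1e4) + 1,
               floor(tr2$dot_pairs$b / 1e4) + 1)
  called_truth <- any(vapply(seq_len(nrow(tb2)), function(k)
    any(abs(d2$bin1 - tb2[k, 1]) <= 1 & abs(d2$bin2 - tb2[k, 2]) <= 1),
    logical(1)))
  expect_false(called_truth)
})

test_that("dot annotation matches brute-force counting", {
  dots <- data.frame(chrom = "chr1",
                     bin1 = c(10, 30, 50, 70, 90),
                     bin2 = c(20, 45, 62, 85, 110))
  dots$pos1 <- (dots$bin1 - 1) * 1e4
  dots$pos2 <- (dots$bin2 - 1) * 1e4
  dots$distance <- dots$pos2 - dots$pos1
  # CTCF at one end of four dots; the fifth has none
  ctcf <- anchor_set(data.frame(
    chrom = "chr1",
    pos = c(9.2e4, 29.5e4, 49.1e4, 69.8e4),
    orientation = c("+", "+", "-", "-")))
  ann <- annotate_dots(dots, ctcf, resolution = 1e4)
  expect_equal(ann$fraction_with_ctcf_anchor, 0.8)
  expect_equal(ann$median_anchor_distance, median(dots$distance))
  expect_equal(ann$n_oriented, 0)  # no dot has motifs at both ends

  # both ends forward: tandem category consistent with pair semantics
  ctcf2 <- anchor_set(data.frame(chrom = "chr1", pos = c(9.2e4, 19.5e4),
                                 orientation = c("+", "+")))
  ann2 <- annotate_dots(dots[1, ], ctcf2, resolution = 1e4)
  expect_equal(ann2$n_oriented, 1)
  expect_equal(unname(ann2$orientation_composition["tandem_plus"]), 1)

  # an end matching two overlapping motifs is excluded from the
  # composition but still counts for the fraction and the median
  ctcf3 <- anchor_set(data.frame(chrom = "chr1",
                                 pos = c(9.2e4, 9.6e4, 19.5e4),
                                 orientation = c("+", "-", "-")))
  ann3 <- annotate_dots(dots[1, ], ctcf3, resolution = 1e4)
  expect_equal(ann3$n_oriented, 0)
  expect_equal(ann3$fraction_with_ctcf_anchor, 1)
})

test_that("stripe profiles recover symmetry and asymmetry", {
  # uniform O/E: bias identically 1
  cmu <- balance_matrix(cm_from_dense(matrix(5, 80, 80), bin = 1e4))
  anch <- anchor_set(data.frame(chrom = "chr1", pos = c(3e5, 5e5),
                                orientation = c("+", "-")))
  sp <- stripe_bias(oe_matrix(cmu), anch, flank = 1e5)
  expect_true(all(abs(sp$bias - 1) < 1e-10))

  # orientation-flip consistency: reversing every anchor swaps the arms
  set.seed(20)
  R <- matrix(rpois(6400, 10), 80); R <- R + t(R)
  cm <- balance_matrix(cm_from_dense(R, bin = 1e4))
  oem <- oe_matrix(cm)
  s1 <- stripe_bias(oem, anch, flank = 1e5)
  anch_flip <- anch
  anch_flip$orientation <- ifelse(anch$orientation == "+", "-", "+")
  s2 <- stripe_bias(oem, anch_flip, flank = 1e5)
  expect_equal(s1$downstream, s2$upstream, tolerance = 1e-12)
  expect_equal(s1$bias, 1 / s2$bias, tolerance = 1e-10)
})
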