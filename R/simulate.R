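#' Simulate the latent structure of a synthetic contact map
#'
#' Draws the ground truth underlying a synthetic map: alternating A/B
#' compartment intervals with exponential lengths, loop anchors with
#' Gamma-distributed spacings, designated dot pairs with CTCF sites and
#' motif orientations, oriented stripe anchors, and optional domain
#' junctions. GC content is assigned 0.55 to A bins and 0.45 to B bins so
#' that eigenvector orientation by GC is well defined.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param seed integer seed (defaults to \code{params$seed}).
#' @return an object of class \code{ground_truth}: a list with the bin
#'   table (\code{bins}, including \code{gc}), per-bin compartment labels
#'   (\code{comp}, +1 = A), per-chromosome anchor positions
#'   (\code{anchors}), Gaussian contact bumps (\code{bumps}; kinds
#'   \code{"loop"} and \code{"dot"}), the dot-pair table
#'   (\code{dot_pairs}), CTCF sites (\code{ctcf}), stripe anchors
#'   (\code{stripes}), and per-bin domain ids (\code{domain}).
#' @export
simulate_features <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (params$mean_interval < params$bin_size)
    stop("mean_interval must be at least one bin")
  set.seed(seed)
  bins <- build_genome(params$chrom_lengths, params$bin_size)
  idx <- chrom_index(bins)

  comp <- integer(nrow(bins))
  domain <- integer(nrow(bins))
  anchors <- vector("list", length(idx$chroms))
  names(anchors) <- idx$chroms
  domain_bounds <- anchors

  for (ch in idx$chroms) {
    n <- idx$n[[ch]]
    len <- params$chrom_lengths[[ch]]

    # Alternating compartment intervals, exponential lengths (in bins).
    lab <- sample(c(1L, -1L), 1)
    labs <- integer(0)
    while (length(labs) < n) {
      k <- max(1L, round(stats::rexp(1, rate = 1 / params$mean_interval) /
                           params$bin_size))
      labs <- c(labs, rep(lab, k))
      lab <- -lab
    }
    comp[idx$offset[[ch]] + seq_len(n)] <- labs[seq_len(n)]

    # Loop anchors: Gamma(k, L/k) spacings from a random phase.
    pos <- stats::runif(1, 0, params$loop_mean)
    n_exp <- ceiling(len / params$loop_mean) + 50
    sp <- stats::rgamma(n_exp, shape = params$loop_shape,
                        scale = params$loop_mean / params$loop_shape)
    aa <- pos + cumsum(sp)
    aa <- c(pos, aa)
    while (aa[length(aa)] < len) {
      more <- stats::rgamma(n_exp, shape = params$loop_shape,
                            scale = params$loop_mean / params$loop_shape)
      aa <- c(aa, aa[length(aa)] + cumsum(more))
    }
    anchors[[ch]] <- aa[aa < len]

    # Domain junctions: uniform positions snapped to bin edges.
    if (params$domain_junctions > 0) {
      jb <- sort(sample(seq_len(n - 1), min(params$domain_junctions, n - 1)))
      domain_bounds[[ch]] <- jb * params$bin_size
      domain[idx$offset[[ch]] + seq_len(n)] <-
        findInterval(seq_len(n) - 1L, jb) + 1L
    } else {
      domain_bounds[[ch]] <- numeric(0)
      domain[idx$offset[[ch]] + seq_len(n)] <- 1L
    }
  }

  bins$gc <- ifelse(comp > 0, 0.55, 0.45)

  # Loop bumps at every consecutive anchor pair.
  loop_bumps <- do.call(rbind, lapply(idx$chroms, function(ch) {
    aa <- anchors[[ch]]
    if (length(aa) < 2) return(NULL)
    data.frame(chrom = ch, a = aa[-length(aa)], b = aa[-1],
               amp = params$loop_amp, width = params$dot_width,
               kind = "loop", stringsAsFactors = FALSE)
  }))

  # Designated dot pairs: a sample of consecutive anchor pairs.
  dot_pairs <- NULL
  ctcf <- NULL
  if (params$n_dots > 0 && !is.null(loop_bumps) && nrow(loop_bumps) > 0) {
    take <- sample(nrow(loop_bumps), min(params$n_dots, nrow(loop_bumps)))
    take <- sort(take)
    dp <- loop_bumps[take, c("chrom", "a", "b")]
    cat_lab <- sample(names(params$orientation_mix), nrow(dp),
                      replace = TRUE, prob = params$orientation_mix)
    ori <- orientation_of_category(cat_lab)
    dp$orient_left <- ori$left
    dp$orient_right <- ori$right
    dp$category <- cat_lab
    dp$ctcf_left <- stats::runif(nrow(dp)) < params$ctcf_fraction
    dp$ctcf_right <- stats::runif(nrow(dp)) < params$ctcf_fraction
    rownames(dp) <- NULL
    dot_pairs <- dp
    ctcf <- rbind(
      if (any(dp$ctcf_left))
        data.frame(chrom = dp$chrom[dp$ctcf_left], pos = dp$a[dp$ctcf_left],
                   orientation = dp$orient_left[dp$ctcf_left],
                   stringsAsFactors = FALSE),
      if (any(dp$ctcf_right))
        data.frame(chrom = dp$chrom[dp$ctcf_right], pos = dp$b[dp$ctcf_right],
                   orientation = dp$orient_right[dp$ctcf_right],
                   stringsAsFactors = FALSE))
    if (!is.null(ctcf) && nrow(ctcf) > 0) {
      ctcf$strength <- stats::rlnorm(nrow(ctcf), 0, 0.5)
      ctcf$motif_p <- stats::runif(nrow(ctcf), 1e-8, 1e-3)
      ctcf <- ctcf[order(ctcf$chrom, ctcf$pos), ]
      rownames(ctcf) <- NULL
    }
  }

  dot_bumps <- NULL
  if (!is.null(dot_pairs) && nrow(dot_pairs) > 0)
    dot_bumps <- data.frame(chrom = dot_pairs$chrom, a = dot_pairs$a,
                            b = dot_pairs$b, amp = params$dot_amp,
                            width = params$dot_width, kind = "dot",
                            stringsAsFactors = FALSE)
  bumps <- rbind(loop_bumps, dot_bumps)

  stripes <- NULL
  if (params$stripe_amp > 0 && !is.null(ctcf) && nrow(ctcf) > 0)
    stripes <- data.frame(chrom = ctcf$chrom, pos = ctcf$pos,
                          orientation = ctcf$orientation,
                          amp = params$stripe_amp, beta = params$stripe_beta,
                          stringsAsFactors = FALSE)

  structure(list(bins = bins, comp = comp, anchors = anchors,
                 bumps = bumps, dot_pairs = dot_pairs, ctcf = ctcf,
                 stripes = stripes, domain = domain,
                 domain_bounds = domain_bounds,
                 promoters = NULL, enhancers = NULL, tss = NULL,
                 params = params, seed = as.integer(seed)),
            class = "ground_truth")
}

orientation_of_category <- function(category) {
  left <- c(convergent = "+", divergent = "-",
            tandem_plus = "+", tandem_minus = "-")[category]
  right <- c(convergent = "-", divergent = "+",
             tandem_plus = "+", tandem_minus = "-")[category]
  list(left = unname(left), right = unname(right))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  cat(sprintf("  %d bins over %d chromosome(s); %d loop anchors; %d dot pairs; %d CTCF sites\n",
              nrow(x$bins), length(x$anchors),
              sum(lengths(x$anchors)),
              if (is.null(x$dot_pairs)) 0L else nrow(x$dot_pairs),
              if (is.null(x$ctcf)) 0L else nrow(x$ctcf)))
  invisible(x)
}

# Bin midpoints used by the generator: bins are treated as full-width,
# so midpoint of within-chromosome bin i is (i - 1/2) * bin_size. The
# trailing short bin is treated as full width for contact geometry.
.mids <- function(n, bin_size) (seq_len(n) - 0.5) * bin_size

#' Unnormalized contact weight of the generative model
#'
#' Reference (pair-by-pair) evaluation of the model weight
#' \deqn{w(i,j) = s^{-\alpha}\, e^{\sigma v_i v_j}\,(1+\lambda G_{loop})\,
#'   (1+\delta G_{dot})\, F_{stripe}\, F_{domain}}
#' for cis bin pairs, where \eqn{s} is the midpoint separation (same-bin
#' pairs use \code{bin_size/2}), Gaussian bumps of sd \eqn{w} sit at each
#' consecutive-anchor pair and each designated dot pair, stripes multiply
#' rows/columns through oriented CTCF bins with downstream/upstream
#' factors \eqn{(1+a)\sqrt\beta} and \eqn{(1+a)/\sqrt\beta}, and contacts
#' crossing a domain junction are attenuated. Symmetric in (i, j).
#'
#' This is the slow oracle form; \code{\link{sample_map}} and
#' \code{\link{analytic_ps}} use an equivalent per-diagonal evaluation.
#'
#' @param i,j vectors of within-chromosome bin indices (1-based).
#' @param truth a \code{\link{simulate_features}} result.
#' @param params the matching \code{\link{sim_params}}.
#' @param chrom chromosome name (single).
#' @return numeric vector of unnormalized weights.
#' @export
contact_probability <- function(i, j, truth, params, chrom = NULL) {
  idx <- chrom_index(truth$bins)
  if (is.null(chrom)) chrom <- idx$chroms[[1]]
  n <- idx$n[[chrom]]
  off <- idx$offset[[chrom]]
  stopifnot(all(i >= 1 & i <= n), all(j >= 1 & j <= n))
  lo <- pmin(i, j); hi <- pmax(i, j)
  bs <- params$bin_size
  mi <- (lo - 0.5) * bs
  mj <- (hi - 0.5) * bs
  s <- mj - mi
  s[s == 0] <- bs / 2   # same-bin pairs act as separated by half a bin
  mj <- mi + s
  w <- s^(-params$alpha)

  if (params$sigma != 0) {
    v <- truth$comp[off + seq_len(n)]
    fac <- exp(params$sigma * v[lo] * v[hi])
    fac[s > params$sigma_range] <- 1
    w <- w * fac
  }

  if (!is.null(truth$bumps)) {
    bb <- truth$bumps[truth$bumps$chrom == chrom, , drop = FALSE]
    for (kind in unique(bb$kind)) {
      bk <- bb[bb$kind == kind, , drop = FALSE]
      g <- numeric(length(w))
      for (r in seq_len(nrow(bk))) {
        g <- g + bk$amp[r] * exp(-((mi - bk$a[r])^2 + (mj - bk$b[r])^2) /
                                   (2 * bk$width[r]^2))
      }
      w <- w * (1 + g)
    }
  }

  if (!is.null(truth$stripes)) {
    st <- truth$stripes[truth$stripes$chrom == chrom, , drop = FALSE]
    if (nrow(st) > 0) {
      sbin <- floor(st$pos / bs) + 1
      for (r in seq_len(nrow(st))) {
        fd <- (1 + st$amp[r]) * sqrt(st$beta[r])
        fu <- (1 + st$amp[r]) / sqrt(st$beta[r])
        if (st$orientation[r] == "-") { tmp <- fd; fd <- fu; fu <- tmp }
        hit_lo <- lo == sbin[r] & hi > lo   # partner genomically downstream
        hit_hi <- hi == sbin[r] & hi > lo   # partner genomically upstream
        w[hit_lo] <- w[hit_lo] * fd
        w[hit_hi] <- w[hit_hi] * fu
      }
    }
  }

  if (params$domain_attenuation < 1) {
    dom <- truth$domain[off + seq_len(n)]
    w <- w * ifelse(dom[lo] == dom[hi], 1, params$domain_attenuation)
  }
  w
}

# Fast per-diagonal weights for one chromosome: returns a list W where
# W[[d + 1]] is the weight vector over pairs (i, i + d), i = 1..n-d.
# Exactly equal to contact_probability() on every pair.
diag_weights <- function(truth, params, chrom, max_diag = NULL) {
  idx <- chrom_index(truth$bins)
  n <- idx$n[[chrom]]
  off <- idx$offset[[chrom]]
  bs <- params$bin_size
  if (is.null(max_diag)) max_diag <- n - 1L
  max_diag <- min(max_diag, n - 1L)
  v <- truth$comp[off + seq_len(n)]
  dom <- truth$domain[off + seq_len(n)]
  use_dom <- params$domain_attenuation < 1
  mids <- .mids(n, bs)

  W <- vector("list", max_diag + 1L)
  for (d in 0:max_diag) {
    s <- if (d == 0) bs / 2 else d * bs
    m <- n - d
    w <- rep(s^(-params$alpha), m)
    if (params$sigma != 0 && s <= params$sigma_range)
      w <- w * exp(params$sigma * v[seq_len(m)] * v[d + seq_len(m)])
    if (use_dom) {
      cross <- dom[seq_len(m)] != dom[d + seq_len(m)]
      if (any(cross)) w[cross] <- w[cross] * params$domain_attenuation
    }
    W[[d + 1L]] <- w
  }

  # Gaussian bumps: pair (i, i+d) gets, from bump (a, b, w0),
  #   amp * exp(-t^2 / (4 w0^2)) * exp(-(m_i - c)^2 / w0^2)
  # with t = s_d - (b - a) and c = a - t/2 (sd w0 / sqrt(2) in i).
  if (!is.null(truth$bumps)) {
    bb <- truth$bumps[truth$bumps$chrom == chrom, , drop = FALSE]
    for (kind in unique(bb$kind)) {
      bk <- bb[bb$kind == kind, , drop = FALSE]
      G <- vector("list", max_diag + 1L)
      touched <- logical(max_diag + 1L)
      for (r in seq_len(nrow(bk))) {
        a <- bk$a[r]; b <- bk$b[r]; w0 <- bk$width[r]; amp <- bk$amp[r]
        d_lo <- max(0L, floor((b - a - 6 * sqrt(2) * w0) / bs))
        d_hi <- min(max_diag, ceiling((b - a + 6 * sqrt(2) * w0) / bs))
        if (d_hi < d_lo) next
        for (d in d_lo:d_hi) {
          s <- if (d == 0) bs / 2 else d * bs
          t <- s - (b - a)
          scale <- amp * exp(-t^2 / (4 * w0^2))
          if (scale < 1e-10) next
          cc <- a - t / 2
          m <- n - d
          i_lo <- max(1L, floor((cc - 5 * w0) / bs))
          i_hi <- min(m, ceiling((cc + 5 * w0) / bs))
          if (i_hi < i_lo) next
          ii <- i_lo:i_hi
          add <- scale * exp(-(mids[ii] - cc)^2 / w0^2)
          if (!touched[d + 1L]) {
            G[[d + 1L]] <- numeric(m)
            touched[d + 1L] <- TRUE
          }
          G[[d + 1L]][ii] <- G[[d + 1L]][ii] + add
        }
      }
      for (d in which(touched) - 1L)
        W[[d + 1L]] <- W[[d + 1L]] * (1 + G[[d + 1L]])
    }
  }

  if (!is.null(truth$stripes)) {
    st <- truth$stripes[truth$stripes$chrom == chrom, , drop = FALSE]
    if (nrow(st) > 0) {
      sbin <- floor(st$pos / bs) + 1
      fd <- (1 + st$amp) * sqrt(st$beta)
      fu <- (1 + st$amp) / sqrt(st$beta)
      rev_ <- st$orientation == "-"
      tmp <- fd[rev_]; fd[rev_] <- fu[rev_]; fu[rev_] <- tmp
      # several stripes can share a bin: combine their factors first
      pd <- tapply(fd, sbin, prod)
      pu <- tapply(fu, sbin, prod)
      ubin <- as.integer(names(pd))
      pd <- as.numeric(pd); pu <- as.numeric(pu)
      for (d in seq_len(max_diag)) {
        m <- n - d
        # anchor on the left end: pair (ubin, ubin + d)
        okL <- ubin <= m
        if (any(okL))
          W[[d + 1L]][ubin[okL]] <- W[[d + 1L]][ubin[okL]] * pd[okL]
        # anchor on the right end: pair (ubin - d, ubin)
        iR <- ubin - d
        okR <- iR >= 1
        if (any(okR))
          W[[d + 1L]][iR[okR]] <- W[[d + 1L]][iR[okR]] * pu[okR]
      }
    }
  }
  W
}

#' Sample a contact map from the generative model
#'
#' Draws exactly \code{N} contacts multinomially over bin pairs with
#' probabilities proportional to \code{\link{contact_probability}}; trans
#' pairs (with more than one chromosome) share a single uniform weight
#' sized so that the expected trans fraction is \code{params$trans_frac}.
#'
#' @param truth a \code{\link{simulate_features}} result.
#' @param params the matching \code{\link{sim_params}}.
#' @param N total number of contacts.
#' @param seed integer seed.
#' @return a \code{\link{contact_matrix}}.
#' @export
sample_map <- function(truth, params, N = params$n_contacts,
                       seed = params$seed) {
  stopifnot(N >= 0)
  set.seed(seed)
  idx <- chrom_index(truth$bins)
  n_chrom <- length(idx$chroms)

  n_trans <- 0L
  if (n_chrom > 1 && params$trans_frac > 0 && N > 0)
    n_trans <- stats::rbinom(1, N, params$trans_frac)
  n_cis <- N - n_trans

  pix <- list()
  if (n_cis > 0) {
    Ws <- lapply(idx$chroms, function(ch) diag_weights(truth, params, ch))
    names(Ws) <- idx$chroms
    tot <- vapply(Ws, function(W) sum(vapply(W, sum, numeric(1))),
                  numeric(1))
    per_chrom <- as.vector(stats::rmultinom(1, n_cis, tot))
    for (ci in seq_along(idx$chroms)) {
      if (per_chrom[ci] == 0) next
      ch <- idx$chroms[[ci]]
      W <- Ws[[ch]]
      dsum <- vapply(W, sum, numeric(1))
      per_diag <- as.vector(stats::rmultinom(1, per_chrom[ci], dsum))
      off <- idx$offset[[ch]]
      for (d in which(per_diag > 0) - 1L) {
        cnt <- as.vector(stats::rmultinom(1, per_diag[d + 1L], W[[d + 1L]]))
        nz <- which(cnt > 0)
        pix[[length(pix) + 1L]] <-
          data.frame(bin1 = off + nz, bin2 = off + nz + d,
                     count = cnt[nz])
      }
    }
  }

  if (n_trans > 0) {
    # Uniform over inter-chromosomal pairs: rejection-sample bin pairs.
    got <- 0L
    while (got < n_trans) {
      m <- (n_trans - got) * 2L
      b1 <- sample.int(nrow(truth$bins), m, replace = TRUE)
      b2 <- sample.int(nrow(truth$bins), m, replace = TRUE)
      keep <- truth$bins$chrom[b1] != truth$bins$chrom[b2]
      b1 <- b1[keep]; b2 <- b2[keep]
      take <- min(length(b1), n_trans - got)
      if (take > 0) {
        lo <- pmin(b1[seq_len(take)], b2[seq_len(take)])
        hi <- pmax(b1[seq_len(take)], b2[seq_len(take)])
        pix[[length(pix) + 1L]] <- data.frame(bin1 = lo, bin2 = hi,
                                              count = 1L)
        got <- got + take
      }
    }
  }

  pixels <- if (length(pix)) do.call(rbind, pix) else
    data.frame(bin1 = integer(0), bin2 = integer(0), count = integer(0))
  contact_matrix(truth$bins, pixels, resolution = params$bin_size)
}

#' Exact expected distance-decay curve of the generative model
#'
#' Averages \code{\link{contact_probability}} over all cis pairs at each
#' bin separation (per-diagonal means of the model weights, pooled over
#' chromosomes), then aggregates into the same geometric distance bins as
#' \code{\link{compute_ps}}. Serves as the deterministic oracle for the
#' P(s) machinery: it is what \code{compute_ps} on a sampled map estimates.
#'
#' @param truth,params the generative model.
#' @param min_s,max_s,bins_per_decade distance binning (bp), as in
#'   \code{\link{compute_ps}}.
#' @param normalize rescale so total probability mass is 1.
#' @return a \code{ps_curve} data.frame (columns \code{s}, \code{P},
#'   \code{n_pairs}).
#' @export
analytic_ps <- function(truth, params, min_s = 2 * params$bin_size,
                        max_s = NULL, bins_per_decade = 8,
                        normalize = TRUE) {
  idx <- chrom_index(truth$bins)
  max_d <- max(idx$n) - 1L
  if (is.null(max_s)) max_s <- max_d * params$bin_size
  sums <- numeric(max_d + 1L)
  npairs <- numeric(max_d + 1L)
  for (ch in idx$chroms) {
    W <- diag_weights(truth, params, ch)
    for (d in seq_along(W)) {
      sums[d] <- sums[d] + sum(W[[d]])
      npairs[d] <- npairs[d] + length(W[[d]])
    }
  }
  d <- seq_len(max_d)  # skip d = 0 (same-bin pairs excluded from P(s))
  s <- d * params$bin_size
  keep <- s >= min_s & s <= max_s
  curve <- aggregate_ps(s[keep], sums[d + 1L][keep], npairs[d + 1L][keep],
                        min_s, max_s, bins_per_decade)
  if (normalize && sum(curve$P * curve$n_pairs) > 0)
    curve$P <- curve$P / sum(curve$P * curve$n_pairs)
  curve
}

#' Mix two contact maps in silico
#'
#' Resamples \code{N} contacts with per-pair probability
#' \code{(1 - f) * p_a + f * p_b}, where \code{p_a}, \code{p_b} are the
#' normalized count distributions of the inputs. Used for contamination
#' experiments (adding compartmentalized interphase-like contacts into a
#' compartment-free meiotic-like map).
#'
#' @param map_a,map_b \code{contact_matrix} objects on identical bin tables.
#' @param f mixing fraction of \code{map_b} in [0, 1].
#' @param N number of contacts to resample.
#' @param seed integer seed.
#' @return a \code{contact_matrix}.
#' @export
mix_maps <- function(map_a, map_b, f, N, seed = 1L) {
  stopifnot(f >= 0, f <= 1, N >= 0)
  if (!identical(map_a$bins[c("chrom", "start", "end")],
                 map_b$bins[c("chrom", "start", "end")]))
    stop("mix_maps: bin tables differ")
  set.seed(seed)
  key_a <- (map_a$pixels$bin1 - 1) * nrow(map_a$bins) + map_a$pixels$bin2
  key_b <- (map_b$pixels$bin1 - 1) * nrow(map_b$bins) + map_b$pixels$bin2
  keys <- sort(unique(c(key_a, key_b)))
  pa <- numeric(length(keys))
  pb <- numeric(length(keys))
  pa[match(key_a, keys)] <- map_a$pixels$count / sum(map_a$pixels$count)
  pb[match(key_b, keys)] <- map_b$pixels$count / sum(map_b$pixels$count)
  p <- (1 - f) * pa + f * pb
  cnt <- as.vector(stats::rmultinom(1, N, p))
  nz <- cnt > 0
  nb <- nrow(map_a$bins)
  pixels <- data.frame(bin1 = (keys[nz] - 1) %/% nb + 1,
                       bin2 = (keys[nz] - 1) %% nb + 1,
                       count = cnt[nz])
  contact_matrix(map_a$bins, pixels, resolution = map_a$resolution)
}
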