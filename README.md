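# meioc

Chromatin-architecture analysis of Hi-C / Micro-C contact maps through
the mitotic-to-meiotic transition, as an R package plus a set of
numbered analysis scripts.

When germ cells enter meiotic prophase I, chromosomes reorganize into
an axis-anchored loop array: TADs and whole-chromosome A/B
compartmentalization disappear from contact maps, average loop size
grows from ~100 kb toward the megabase scale, CTCF-anchored focal
contacts ("dots") persist without a convergent-motif preference, and
architectural stripes lose their orientation bias — while local
subcompartments and promoter–enhancer contacts survive. `meioc`
implements the quantitative toolkit behind those observations:

* **Contact-map core** — 4DN-style pairs binning, COO text I/O,
  ICE-style balancing (square-root damped iterative correction with
  MAD bin filtering), expected-by-distance and observed/expected
  normalization.
* **P(s) decay** — pooled autosomal P(s) in geometric distance bins,
  Gaussian local-linear smoothing and derivative in log–log space, and
  the two derivative summaries: loop size (distance of the first local
  maximum) and relative cohesin density (depth of the valley that
  follows).
* **Insulation / TADs** — diamond insulation score (10 kb bins,
  100 kb window), boundary calling by topographic prominence with Li's
  minimum cross-entropy threshold, conserved-boundary overlap (±10 kb),
  zero-normalized boundary profiles and the max−min insulation delta.
* **Compartments** — per-chromosome PC1 of the O/E correlation matrix
  oriented by GC; a windowed "local compartment rank" that detects
  short-range subcompartments where global PC1 fails; stage clustering
  on rank tracks; and an in-silico contamination scan that mixes a
  compartmentalized map into a compartment-free one and measures when
  PC1 starts seeing A/B structure.
* **Anchor aggregation** — CTCF anchor selection (top strength
  quartile ∩ lowest motif-p quartile), orientation-aware pairing,
  O/E pileups (APA) with three-central-pixel enrichment, a simplified
  template-matching dot caller (7×7 Gaussian kernel, Pearson ≥ 0.4,
  focality and Poisson-significance guards), CTCF annotation of dots,
  stripe orientation-bias profiles, and fine-scale (200–400 bp)
  TSS/promoter/enhancer pileups with expression-tertile splits.
* **Synthetic generator** — binned maps with power-law decay,
  checkerboard compartments (optionally short-range only), Gamma-spaced
  loop arrays, oriented CTCF dots, asymmetric stripes, implanted domain
  junctions and a closed-form expected P(s), so every estimator is
  tested by recovering known ground truth.

The model behind the generator, for cis pairs at separation *s*:

    w(i,j) = s^-alpha * exp(sigma * v_i * v_j) * (1 + lambda*G_loop)
             * (1 + delta*G_dot) * F_stripe * F_domain

with multinomial sampling of exactly N contacts. See the methods
vignette (`vignettes/meiotic-contact-maps.Rmd`) for every component,
default and numerical choice.

## Worked example

Simulate a small interphase-like map, balance it, and read off loop
statistics and compartments:

```r
library(meioc)

p <- stage_preset("interphase", chrom_lengths = c(chr1 = 20e6),
                  bin_size = 10e3, n_contacts = 2e6)
truth <- simulate_features(p)
map   <- balance_matrix(sample_map(truth, p))
map
#> Contact matrix: 2000 bins (1 chromosome(s)) at 10 kb, 2e+06 contacts, balanced

loop_stats_from_map(map, bins_per_decade = 16, window_decades = 0.08)
#> Loop stats: size = 50 kb, relative density = 0.503

# PC1 at 100 kb against the generator's A/B labels
trk <- eigen_compartments(balance_matrix(coarsen_matrix(map, 10)))
lab <- sign(as.vector(rowsum(as.numeric(truth$comp),
             pos_to_bin(coarsen_matrix(map, 10)$bins,
                        truth$bins$chrom, truth$bins$start))))
cor(trk$pc1, lab, use = "complete.obs")
#> [1] 0.989
```

The loop size reported is the distance of the first local maximum of
the log–log P(s) derivative — for this preset (L = 100 kb, Gamma shape
4) the analytic curve puts it at 50 kb, just below the anchor-spacing
mode of 75 kb — and the density is the depth of the valley behind it,
which grows with loop amplitude. The PC1 correlation of 0.989 shows
the eigenvector recovering the simulated checkerboard.

The `analysis/` directory holds the narrative drivers, each writing
tables under `results/`:

    01_simulate_stages.R   stage maps (interphase-like, pachytene-like)
    02_distance_decay.R    P(s), loop size / density, estimator validation
    03_insulation_tads.R   insulation, boundaries, conserved sets, delta
    04_compartments.R      PC1, local ranks, clustering, contamination scan
    05_dots_stripes.R      dot calling + CTCF annotation, APA, stripe bias
    06_fine_scale.R        TSS/P-P/P-E pileups, expression tertiles

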