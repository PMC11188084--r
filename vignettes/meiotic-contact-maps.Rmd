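---
title: "Analyzing meiotic chromatin architecture with meioc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing meiotic chromatin architecture with meioc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioc)
```

## Scope

`meioc` implements the contact-map analyses used to characterize
chromatin reorganization through the mitotic-to-meiotic transition:
matrix construction and ICE balancing, distance-decay P(s) curves with
loop-size and cohesin-density estimation, insulation/TAD boundary
dynamics, A/B compartment eigenvectors with a local-rank substitute for
short-range compartments, in-silico contamination scans, and
anchor-centric aggregation (dots, stripes, promoter/enhancer pileups).
Because public meiotic data sets are billions of contacts deep and far
beyond desk scale, every analysis here is exercised on a synthetic
contact-map generator with known ground truth; the generator is
first-class, tested code, and each estimator is validated by recovery
of the latent structure it targets.

## The generative model

For cis bin pairs $(i, j)$ at midpoint separation $s$ the unnormalized
contact weight is

$$w(i,j) = s^{-\alpha}\; e^{\sigma v_i v_j \mathbf{1}[s \le r_\sigma]}
 \;\bigl(1 + \lambda G_{\mathrm{loop}}(i,j)\bigr)
 \;\bigl(1 + \delta G_{\mathrm{dot}}(i,j)\bigr)
 \; F_{\mathrm{stripe}}(i,j)\; F_{\mathrm{dom}}(i,j),$$

with maps sampled multinomially (exactly $N$ contacts; trans contacts,
when more than one chromosome is simulated, share a single uniform
weight sized to a 5% trans fraction). Same-bin pairs are assigned
$s = \text{bin}/2$ to avoid the $s = 0$ singularity, and the trailing
short bin of a chromosome is treated as full-width for contact
geometry. The components:

* **Distance decay** $s^{-\alpha}$, default $\alpha = 1.1$, the slope
  regime typical of mammalian interphase cis contacts.
* **Compartments**: alternating A/B intervals with exponential lengths
  (mean `mean_interval`, default 1 Mb; exponential gives a scale-free
  interval mix), labels $v_i = \pm 1$, factor $e^{\sigma v_i v_j}$, so
  the same-vs-cross contrast is $e^{2\sigma}$. A finite `sigma_range`
  $r_\sigma$ restricts the checkerboard to short range, emulating
  meiotic prophase chromosomes whose subcompartments survive only
  locally. GC content is fixed at 0.55 (A) / 0.45 (B) so eigenvector
  orientation by GC is well defined and testable.
* **Loop array**: anchors with Gamma($k$, $L/k$) spacings (default
  $k = 4$); each consecutive anchor pair carries a 2-D Gaussian contact
  bump of sd $w$ and amplitude $\lambda$. The ground-truth "loop size"
  for recovery tests is the spacing mode $(k-1)L/k$, which is interior
  and distinct from the mean. The blur defaults to $w = L/4$: with a
  fixed $w$ the P(s) hump amplitude would scale as $1/L^2$ (fewer
  anchor pairs and a thinner spacing density at larger $L$) and vanish
  for megabase loops, whereas a blur proportional to loop size keeps
  the hump amplitude loop-size-invariant, matching the self-similar
  appearance of real P(s) humps across stages.
* **Dots**: a designated subset of anchor pairs (`n_dots`) with
  amplitude $\delta$; with probability `ctcf_fraction` each end carries
  a CTCF site whose motif orientations follow `orientation_mix` over
  convergent / divergent / tandem categories.
* **Stripes**: rows/columns through oriented CTCF bins are multiplied
  by $F_{\mathrm{down}} = (1+a)\sqrt{\beta}$ on the downstream arm (in
  the motif frame) and $F_{\mathrm{up}} = (1+a)/\sqrt{\beta}$ upstream.
  This parametrization makes `stripe_beta` *equal* to the
  downstream/upstream O/E ratio that the bias profile estimates, and
  `1 + stripe_amp` the geometric-mean enrichment; an additive
  $\beta{:}1$ weighting would conflate the two.
* **Domains**: optional implanted junctions; contacts crossing a
  junction are attenuated by `domain_attenuation`. This provides exact
  ground truth for boundary calling and the insulation delta.

`contact_probability()` is the pair-by-pair reference form;
`sample_map()` and `analytic_ps()` use an algebraically identical
per-diagonal evaluation (tested for exact agreement). `analytic_ps()`
averages the weights over all pairs at each separation and is the
closed-form oracle for the whole P(s) stack.

```{r quick-sim}
p <- stage_preset("interphase", chrom_lengths = c(chr1 = 20e6),
                  bin_size = 50e3, n_contacts = 5e5)
truth <- simulate_features(p)
map <- balance_matrix(sample_map(truth, p))
map
```

## Matrix core

Pairs files (4DN layout) are binned by `floor(pos / bin_size)` on a
0-based half-open bin table. Balancing is ICE-style iterative
correction with the square-root damped (symmetric Sinkhorn) update,
which converges in tens rather than hundreds of iterations on these
matrices; bins with zero marginals, or marginals more than `mad_max`
(default 5) median absolute deviations below the median, are masked.
Convergence means the coefficient of variation of balanced row sums
falls below `tol` (default 1e-5); non-convergence returns the best
iterate with a warning and a flag. Expected-by-distance is computed per
chromosome (diagonals differ in pair counts across chromosomes), and
O/E divides each balanced value by the distance-matched expectation, so
every diagonal has mean 1 by construction.

## P(s), loop size and cohesin density

`compute_ps()` pools balanced cis contacts over autosomes (sex
chromosomes are excluded by name, reflecting their special pairing
status in meiotic prophase) into geometric distance bins. Two numerical
choices matter and are worth recording:

* Each distance bin is labeled by the **pair-weighted mean distance**
  of its content, not by its geometric center. At fine binning a bin
  holds only one or two integer diagonals, and the center-vs-content
  mismatch imprints a sawtooth of $\pm 0.2$ on the log-log derivative
  (visible even on the exact analytic curve).
* Smoothing is a **Gaussian-weighted local linear fit** in log-log
  space (sd `window_decades`, default 0.1). A Gaussian running mean
  bends a pure power law at the truncated curve ends and fabricates
  derivative extrema there; the local-linear form leaves straight
  log-log segments exactly invariant, endpoints included.

The derivative is taken by central differences in log-log space.
`estimate_loop_stats()` reports the distance of the first local
maximum of the derivative (the average loop size) and the depth of the
valley that follows (derivative at the maximum minus the minimum
beyond it), a relative cohesin-density metric. Two guards make the
estimator robust on sampled curves: a maximum whose valley depth is
below `min_density` (default 0.1 in log-slope units) is treated as
noise, so loop-free maps report `found = FALSE`; and a candidate with
a taller peak later in the search range only counts if it has a
genuine valley of its own before that peak, which stops sampling
wiggles on the rising flank of a real hump from being mistaken for the
first maximum. The default 0.1 sits well below the analytic valley
depths of all simulated conditions used here (0.2 to 0.9, computed
from the closed-form oracle) and well above the wiggle depth of
smoothed curves at $10^7$ contacts.

Loop-size recovery is validated against `analytic_ps()` run through
the *identical* smoothing/derivative machinery, so the comparison
isolates sampling error from grid quantization.

## Insulation and TADs

The insulation score of bin $b$ is the log2 ratio of the mean balanced
contact in the $w \times w$ diamond crossing $b$ (upstream bins
$b-w..b-1$ against downstream $b+1..b+w$; 10 kb bins with a 100 kb
window are the classic choice) to the chromosome-wide mean diamond
value. The sparse implementation accumulates each pixel's contribution
interval with a difference array and is tested to $10^{-12}$ against a
literal dense oracle. Boundaries are local minima of the track,
weighted by topographic prominence (the smaller of the left and right
ascents); Li's minimum cross-entropy threshold on the prominence
distribution separates genuine boundaries from noise. Thresholding
prominences rather than raw scores is a deliberate reading of
"stronger insulation than the threshold": prominence is
shift-invariant, while raw-score thresholds would move with the
chromosome-wide normalization. Conserved boundaries are those whose
positions, expanded by `slack` (10 kb), touch across two sets; domains
span adjacent boundaries. Boundary profiles average fixed flanks
(150 kb) around each boundary and are shifted so the minimum is zero;
the insulation delta is then simply the profile maximum.

## Compartments: global PC1 and local ranks

`eigen_compartments()` follows the classic recipe: per chromosome,
Pearson correlation of O/E columns over unmasked bins, leading
eigenvector, sign oriented so its correlation with GC is positive. The
first two diagonals are neutralized before the correlation (they carry
distance residuals, not compartment signal — the ecosystem
convention). On a genome-wide checkerboard at $\sigma = 0.4$ the PC1
track correlates with truth above 0.9 (Pearson; note that the
*Spearman* correlation between a continuous score and binary labels
has a hard ceiling of $\sqrt{3}/2 \approx 0.866$, so rank correlations
against $\pm 1$ labels are only used where thresholds below that
ceiling are intended).

`local_ranks()` is a deliberately simple substitute for nested
subcompartment callers: leading eigenvectors of the O/E correlation in
overlapping 10 Mb windows (5 Mb step), locally GC-oriented, averaged
per bin, and converted to genome-wide quantile ranks in $[0,1]$
(subtract 0.5 for a PC1-comparable display). It uses only short-range
information, so it still works when the long-range checkerboard is
gone.

The qualitative contrast that motivates the local method — local ranks
recover compartments while whole-chromosome PC1 does not — is
reproduced on ground truth with the compartment factor restricted to
5 Mb and maps of $2 \times 10^6$ contacts on a 100 Mb chromosome. Two
aspects of that choice deserve note. The generator's compartment range
must sit strictly inside the 10 Mb analysis window: if the two
coincide, a deep enough map lets global PC1 chain the short-range
signal genome-wide and the contrast disappears. And the contrast is
depth-dependent in the model, because what defeats global PC1 is
far-cis sampling noise overwhelming label chaining — the same
mechanism, at vastly greater depth, that makes the real pachytene PC1
flat.

### Contamination sensitivity

`mix_maps()` resamples $N$ contacts from
$(1-f)\,p_A + f\,p_B$ over the normalized count distributions of two
maps. The contamination experiment mixes a compartmentalized
meiotic-S-like map ($\sigma = 0.4$, 1 Mb intervals) into a
compartment-free pachytene-like loop array ($\lambda = 2$,
$L = 800$ kb), both $10^7$ contacts on a 100 Mb chromosome, and asks
for the smallest fraction in $\{1, 2, 5, 10, 20\}\%$ at which PC1 at
100 kb detects the A/B labels (|Spearman| > 0.7), by majority over
five mixing replicates.

At this desk-scale depth the measured threshold is 20%: with roughly
20 contacts per 100 kb pixel, a 5% admixture perturbs far-cis O/E by
only about $\pm 2\%$, which leaves the compartment eigen-mode below
the noise edge of the correlation matrix's spectrum — the mode is
absent from the leading eigenvectors up to $f = 0.1$ and appears
abruptly between 10% and 20%, a spiked-covariance phase transition.
Detection thresholds scale inversely with the square of per-pixel
signal-to-noise, so the behavior reported for billion-contact maps
(detection at 5%) is expected to need on the order of 10-fold more
information than these simulations carry. The experiment reports the
measured value rather than tuning the generator to force agreement;
the detectability curves per fraction are part of its output.

## Dots, annotation, stripes, pileups

`call_dots()` is a simplified template matcher honoring the classic
parameter contract (band 50 kb to 10 Mb, minimum separation 10 kb,
correlation threshold 0.4): a 7x7 Gaussian dot template (sd 1 bin) is
correlated with the local O/E patch, local score maxima with center
O/E above 1 are kept, and greedy strongest-first suppression enforces
the minimum separation (Chebyshev distance; ties to the smaller pair).
Pearson correlation is amplitude-blind, and with 49 template pixels
its null sd is about 0.14, so on sparse counts the bare threshold
fires on Poisson noise. Two documented guards restore precision
without touching the contract: the center must dominate its window
outside the central 3x3 (a dot is focal), and — when the raw count
matrix is supplied — the center count must exceed its
distance-expected value at a Poisson upper-tail level of $10^{-4}$.
Windows with fewer than 75% nonzero pixels are rejected outright;
dot calling is depth-dependent by nature and this makes the dependence
explicit. On 50 implanted dots of amplitude 2 at $10^7$ contacts the
caller reaches recall 0.96 / precision 0.92.

`annotate_dots()` matches dot ends to CTCF sites within one bin; the
orientation composition uses only dots with exactly one motif at each
end, while the anchored fraction and median distance use all dots.
`pileup()` averages O/E snippets over anchor pairs (or single oriented
anchors on the diagonal, 180-degree-rotating reverse-oriented
snippets), drops snippets that cross chromosome ends (zero-padding
would bias O/E means), and summarizes dot strength as the mean of the
three central pixels along the main diagonal — the diagonal triplet,
because pair pileups blur along the diagonal, whereas a row triplet
would mix in the distance-decay direction. `stripe_bias()` reads the
center lines of the single-anchor pileup: downstream and upstream mean
O/E per offset in the motif frame and their ratio, which recovers the
generator's `stripe_beta` within a few percent at $10^7$ contacts.

## Fine-scale regulatory structure

`simulate_fine_features()` builds a single 1-2 Mb region at a few
hundred bp per bin (fine-scale maps are simulated regionally, not
genome-wide) carrying promoters with lognormal expression, enhancers,
and oriented TSSs. Promoter-promoter bump amplitudes scale with the
product of per-promoter expression-tertile factors (0.5 / 1 / 2), so
the expression split of P-P pileups has an ordered ground truth;
promoter-enhancer pairs and symmetric TSS stripes are injected
analogously, all restricted to 5 kb - 5 Mb separations.
`fine_pileups()` aggregates at 200 bp (TSS stripes, 20 kb flank) or
400 bp (P-P / P-E, 30 kb flank) and can split promoters into three
equal-count expression groups.

## Problem sizes and determinism

Simulated study sizes were chosen so each experiment completes in
minutes on one CPU while keeping estimator behavior in its asymptotic
regime: 100 Mb single chromosomes at 10-50 kb bins with $10^6$ to
$10^7$ contacts for P(s), compartment and contamination work; 20-60 Mb
toys for insulation, dots and stripes; 1 Mb regions at 400 bp with
$10^7$ contacts for fine-scale aggregation. Every stochastic step is
seeded explicitly, and all operations are bit-reproducible given
(parameters, seed); `run_pipeline()` writes byte-identical reports for
identical (config, seed).

## What the synthetic tests do and do not show

The generator reproduces the *structural grammar* of real maps -
power-law decay, checkerboards, loop arrays, focal dots, oriented
stripes, domains - with independent Poisson-like sampling noise. It
does not model ligation artifacts, mappability and copy-number biases
(balancing is exercised on cleaner marginals than real data), polymer
physics beyond the imposed decay exponent (no Rosetta-like
loop-extrusion dynamics; stage presets are illustrative, not fitted),
translocations, or the X/Y pairing peculiarities (sex chromosomes are
simply excluded, as in the analyses it supports). Passing recovery
tests therefore demonstrates estimator correctness and calibration on
a faithful idealization, not robustness to every artifact of real
libraries.

## Known limitations

* Dense per-chromosome O/E matrices are materialized for eigenvector
  and dot analyses; chromosomes beyond ~8000 bins at the analysis
  resolution should be coarsened first.
* The local-rank method is a substitute for nested subcompartment
  callers: it yields a one-dimensional rank, not a compartment
  hierarchy or eight-state typing.
* Li's threshold assumes the boundary-strength distribution is
  reasonably separable; on very shallow domain structure it degrades
  toward keeping most candidates.
* The contamination detection threshold is information-limited at
  desk-scale depth, as analyzed above.
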