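---
title: "The Microdosimetric Gamma Model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Microdosimetric Gamma Model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgamma)
```

## The problem and the model

Monte Carlo track-structure simulation resolves radiation-induced DNA
damage lesion by lesion, but is far too expensive for clinical-scale
studies. The Microdosimetric Gamma Model (MGM) replaces the simulation
with closed-form functions of a single radiation-quality variable, the
frequency-mean lineal energy $y_F$ (keV/µm): the mean energy imparted to a
microscopic site per event divided by the site's mean chord length. For a
convex site the mean chord length is $4V/S$ (Cauchy), i.e. $2d/3$ for a
sphere of diameter $d$; microdosimetric convention evaluates $y_F$ on a
1 µm liquid-water sphere, and the package keeps that default.

Per ionizing track the model predicts:

* direct damage $N_D(y_F) = k\,y_F$ — energy-proportional;
* indirect damage $N_I(y_F) = N_{max}\left[1 - e^{-a\,y_F}\right]$ —
  radical-mediated damage saturates with ionization density because
  neighbouring OH radicals recombine before reaching the DNA;
* DSB-containing damage sites $N_{DS+DSB}(y_F) = c_1 y_F + c_2 y_F^2$ —
  linear-quadratic because ionization positions along a dense track are
  strongly correlated. The fit is forced through the origin: no track, no
  damage. (Whether an intercept belongs in this law is genuinely open; we
  chose the origin-constrained form as the physically interpretable one,
  and `fit_linear_quadratic()` documents the choice.)

These laws apply separately to strand breaks (SB) and base damages (BD),
each split into direct and indirect components, so totals decompose
exactly as direct + indirect.

A *damage site* (DS) is a block of lesions within 10 consecutive base
pairs — the reporting unit of the Standard DNA Damage (SDD) format. The
*complexity* $C$ of a site is its total lesion count (strand breaks plus
base damages) *provided the site holds at least one double-strand break*;
a simple DSB therefore scores exactly 2, and DSB-free sites carry no
score. Across the sites of one radiation quality, $C$ follows a Gamma law

$$f(C; y_F) = \frac{b(y_F)^{a(y_F)}}{\Gamma(a(y_F))}\,
  C^{a(y_F)-1} e^{-b(y_F) C},$$

whose shape $a(y_F)$ and rate $b(y_F)$ vary smoothly with radiation
quality and are modelled as second-order polynomials in $y_F$. The trends
hold over roughly $2 \le y_F \le 200$ keV/µm (about 100-MeV protons down
to 2-MeV alphas); outside that range every function still evaluates but
logs a warning rather than failing, since extrapolation a little beyond
the calibrated range is routine in practice and should be visible, not
fatal.

The polynomials are in $y_F$ directly by default. Because quality grids
are log-spaced in practice, a `log10yF` abscissa mode is available, and
the mode is serialized with the parameters so a parameter file is never
ambiguous.

### Mixed beams

A beam is a weighted list of $(w_i, y_{F,i})$ components
(`beam_spectrum()`), with derived moments $\langle y_F\rangle$,
$\langle y_F^2\rangle$ and the dose-mean lineal energy
$y_D \equiv \langle y_F^2\rangle / \langle y_F\rangle$. The generator and
the survival models treat the weights as **dose fractions**: each
component receives $w_i D$ and contributes its own Poisson track count and
its own Gamma complexity law. This per-component mixture sampling is our
generative reading of beam averaging; it preserves the component-wise
distributions rather than collapsing them to a single effective quality,
which matters because mixing Gamma laws of different qualities is not
itself Gamma.

### From dose to tracks

Under the short-track condition (energy loss per unit length approximately
constant across the site), a track of quality $y_F$ deposits
$y_F \cdot \ell$ keV along a chord of length $\ell$, so the single-event
frequency-mean specific energy of a spherical nucleus is
$z_F = y_F\,\bar\ell\,k / m$ with $\bar\ell = 2d/3$, $m$ the sphere mass
and $k$ the keV→J conversion. The expected number of tracks at dose $D$ is
$D / z_F$. We implement the conversion in this dimensionally consistent
direction ($z_F$ from $y_F$ via chord and mass) and provide the exact
inverse; the two compose to the identity at machine precision. For the
default 9.65 µm nucleus, 6 Gy of $y_F = 115.3$ keV/µm alpha particles
corresponds to about 23.8 tracks.

## The damage generator

`generate_damage()` realizes a dose explicitly:

1. per component, the track count is Poisson with mean
   $w_i D / z_F(y_{F,i})$ — Poisson because tracks are independent events
   of a stationary exposure (a fixed-mean variant would understate
   event-number fluctuations, which dominate high-LET stochasticity);
2. each track enters uniformly over the nucleus' projected disk and
   traverses it as a straight chord of length $2\sqrt{R^2 - r^2}$
   (µ-randomness; the sampled mean chord reproduces $2d/3$). Tracks are
   parallel to one axis by default, matching a broad external beam; an
   isotropic mode rotates each chord randomly for internal-emitter
   geometries;
3. the number of DSB-containing sites on a track is Poisson with mean
   $c_1 y_F + c_2 y_F^2$, and sites are placed uniformly along the chord —
   damage in straight lines, as particle tracks produce;
4. complexities are iid draws from the Gamma law at the component's
   $y_F$, rounded to the nearest integer and clamped at 2.

The discretization in step 4 reconciles the continuous fitted law with the
definition of complexity as an integer count ≥ 2. All downstream
expectations (e.g. mean lethality) use the same rounded-and-clamped
probability masses, so analytic and sampled paths agree exactly in
distribution rather than only asymptotically.

Cross-track damage accumulation is deliberately *not* part of the
generator: track independence is the model's stated regime ("not too large
doses"). Record-level accumulation lives in `accumulate_tracks()`, which
merges overlapping 10-bp windows on the same chromosome (transitively,
via `IRanges::reduce`), sums lesion and cause counts, keeps the minimum
start coordinate, and re-derives the DSB flag — so two opposite
single-strand breaks from different tracks can combine into a DSB.

For SDD export, an integer complexity $C$ is decomposed into one strand
break per strand (the DSB) plus $C-2$ surplus lesions split evenly between
strand breaks and base damages (configurable ratio; surplus strand breaks
alternate between strands). The inverse mapping from a score to a lesion
pattern is underdetermined, so we chose the minimal symmetric pattern;
`complexity_score()` recovers $C$ exactly for any ratio.

## Repair and biological endpoints

The repair model is deliberately illustrative: a site becomes lethal with
probability $p(C) = 1/(1+e^{-d(C - C_{0.5})})$, where $d$ sets repair
efficiency (steepness per complexity unit) and $C_{0.5}$ the complexity of
50% lethality — `p_lethal(C0_5) = 0.5` holds exactly by construction.
After $N$ sites the cell dies with probability
$1 - \prod_N (1 - p(C_i))$.

Two survival paths are implemented and tested against each other:

* `survival_mc()` draws full realizations and reports the fraction with no
  lethal site;
* `survival_closed_form()` evaluates the expectation analytically. Under
  the generator's two-level statistics (Poisson tracks, Poisson sites per
  track, iid complexities) the exact survival is the compound-Poisson
  generating function
  $$S(D) = \exp\!\Big(-\sum_i \lambda_{T,i}(D)\,
    \big(1 - e^{-\lambda_{s,i}\,\bar p_i}\big)\Big),$$
  with $\bar p_i$ the mean lethality under the (discretized) complexity
  law. This derivation is the package's own; in the small
  $\lambda_s \bar p$ limit it reduces to the single-level Poisson form
  $e^{-\mu(D)\bar p}$ (`poisson_survival()`), and the Monte Carlo path
  verifies it within binomial error.

Survival curves carry linear-quadratic fits
($-\ln S = \alpha D + \beta D^2$, both coefficients constrained
non-negative). RBE at a survival level is the ratio of reference to test
dose, with doses solved from the fitted LQ parameters analytically — we
use the rationalized quadratic root
$D = 2\varepsilon / (\alpha + \sqrt{\alpha^2 + 4\beta\varepsilon})$, which
stays numerically stable as $\beta \to 0$ (the naive formula suffers
catastrophic cancellation there). The low-dose limit is the α-ratio,
labelled "RBE min" for continuity with the model's original naming,
although for high-LET radiation this limit is conventionally the maximum
of RBE over dose; the label is a naming choice only.

## Calibration

`calibrate_mgm()` takes one row per radiation quality — per-track mean
yields and per-quality Gamma parameters — and runs:

* linear least squares through the origin for the direct-damage slopes;
* Levenberg–Marquardt nonlinear least squares (`minpack.lm::nlsLM`) for
  the saturation laws, started at $N_{max} = 1.2\max(N)$,
  $a = 1/\mathrm{median}(y_F)$, positivity-bounded, relative tolerance
  $10^{-12}$;
* origin-constrained linear-quadratic least squares with $c_2 \ge 0$
  (an active constraint is reported, not silently absorbed);
* two independent quadratic fits for the $a(y_F)$, $b(y_F)$ trends, with
  positivity of both trends verified over the validity range.

Per-quality Gamma parameters come from `fit_gamma()`: continuous maximum
likelihood on the raw scores (the profile score equation
$\log a - \psi(a) = \log\bar x - \overline{\log x}$ solved by root
finding; statistically efficient, and the default) or least squares of the
density against the unit-bin normalized histogram, which mirrors how
binned complexity distributions are fitted in figures. $R^2$ is reported
against the unit-bin histogram in both modes so fit qualities are
comparable; on which scale such an $R^2$ "should" be computed is not
standardized, and the normalized-histogram scale is our choice.

All least-squares routines accept optional weights. The `weighting =
"relative"` mode of `calibrate_mgm()` uses inverse squared-value weights —
the inverse-variance choice when measurement errors scale with the
measured yield, as they do for bootstrapped yields whose relative
uncertainty is roughly constant. With unweighted fitting, the large
absolute scatter of high-$y_F$ yields drowns the low-$y_F$ points that
identify the linear coefficient $c_1$; relative weighting restores
balanced leverage. Unweighted remains the default.

## The synthetic ground truth

`mgm_ground_truth()` fixes a complete parameter set and study design so
every estimator can be validated by parameter recovery. Defaults:

* 15 qualities log-spaced over 2–200 keV/µm, emulating a campaign of
  monoenergetic protons and alphas across the validity range;
* yield coefficients (`default_truth_params()`) chosen once to be
  order-of-magnitude plausible for a mammalian nucleus — e.g. ~70% of
  strand breaks indirect at low LET, saturation of the indirect component
  well within the calibrated range, a few tenths of a DSB-containing site
  per track at 2 keV/µm rising to ~10² at 200 keV/µm, mean complexity
  rising from ≈2.5 to ≈11. They are labelled synthetic everywhere: they
  are not a published calibration;
* multiplicative lognormal noise with sdlog σ (`noise_sigma`), the
  natural error model for positive yields with constant relative
  uncertainty; σ = 0 reproduces the truth functions exactly, which is what
  makes sub-0.1% recovery meaningful;
* `make_track_summaries()` draws per-track Poisson counts and discretized
  Gamma complexities for record-level tests; `make_sdd_fixture()` writes
  the same content as an SDD file, with lesions attributed to direct /
  indirect causes binomially at the truth's direct fraction.

What the generator does **not** emulate: track-structure physics and
chemistry (lesion positions within a track are uniform along a chord, not
clustered at track ends), damage-induction thresholds, chromatin
heterogeneity, cell-cycle variation, and inter-track correlation. Passing
recovery tests therefore demonstrates that the estimators are consistent
and correctly implemented under the model's own assumptions — not that the
model describes any particular experiment.

## Numerical and format choices

* **SDD dialect.** The reader/writer keeps the SDD v1.0 header shape (one
  `Key, value;` line each, `***EndOfHeader***;` sentinel) and
  semicolon-separated data fields, restricted to the fields this model
  consumes: track, chromosome, genomic position (0-based site start),
  spatial position (µm, nucleus-centered, 9 significant digits), per-strand
  break counts, base damages, DSB flag, and direct/indirect cause counts
  (`.` when absent). Unknown header keys pass through verbatim with a
  message. An explicit DSB flag is trusted; a missing one is derived as
  "at least one break on each strand". Write→read→write is byte-identical
  on the data section.
* **Per-lesion causes.** SDD sites carry cause counts per site, not per
  lesion type, so per-type direct/indirect splits in `summarize_tracks()`
  apportion a site's direct fraction proportionally to its SB and BD
  counts — exact for single-type sites, an estimate otherwise, and `NA`
  (flagged) when cause information is absent.
* **Bootstrap.** The resampling unit is the whole track, 40 resamples by
  default, yields normalized by the nominal dose of the resampled track
  count; bit-reproducible given a seed.
* **Degenerate inputs.** Constant complexity samples, all-zero beam
  weights, sub-minimal point counts, unreachable survival levels and
  invariant-violating records all fail fast with named errors; saturation
  non-convergence reports its starting point.
* **Problem sizes.** The shipped tests run the Monte Carlo oracles at
  10⁴ survival realizations per dose, 10⁶ chord draws, and a 10⁶-sample
  histogram fit — sizes at which binomial/CLT error bands are a few
  tenths of a percent, chosen so the whole suite completes in seconds.

## Known limitations

The model inherits the validity limits of its inputs: the short-track
condition fails for very low-energy particles; qualities outside
2–200 keV/µm extrapolate with a warning; X-ray spectra (as opposed to
near-monoenergetic components) lose the Gamma shape and should be handled
as explicit mixtures; and the sigmoid repair model is a conceptual device
— its RBE output is qualitative, not a clinical prediction. Chromosome
aberrations, repair kinetics, protracted irradiation and scavenger
modulation of the indirect component are outside the package's scope.
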