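# microgamma

An R implementation of the Microdosimetric Gamma Model (MGM) of
radiation-induced DNA damage, for radiation biophysicists working on
proton therapy, helium therapy and targeted alpha therapy who need
track-by-track DNA damage distributions without re-running Monte Carlo
track-structure simulation for every beam.

## The model

The MGM predicts, for a single ionizing track of frequency-mean lineal
energy *y*<sub>F</sub> (keV/μm, valid over roughly 2–200 keV/μm):

- **direct damage** per track, proportional to the deposited energy:
  *N*<sub>D</sub>(*y*<sub>F</sub>) = *k*·*y*<sub>F</sub>;
- **indirect (radical-mediated) damage**, which saturates as ionization
  density grows and nearby OH radicals recombine:
  *N*<sub>I</sub>(*y*<sub>F</sub>) = *N*<sub>max</sub>[1 −
  exp(−*a*·*y*<sub>F</sub>)];
- **DSB-containing damage sites** per track, linear-quadratic in
  *y*<sub>F</sub>: *c*<sub>1</sub>*y*<sub>F</sub> +
  *c*<sub>2</sub>*y*<sub>F</sub>²;
- the **complexity** *C* of each DSB-containing 10-bp damage site (total
  strand breaks + base damages; a simple DSB scores 2), distributed as a
  Gamma law *f*(*C*; *y*<sub>F</sub>) with shape *a*(*y*<sub>F</sub>) and
  rate *b*(*y*<sub>F</sub>) that follow second-order polynomial trends in
  *y*<sub>F</sub>.

Around this core the package provides: a reader/writer for a minimal
dialect of the Standard DNA Damage (SDD) text format; per-track damage
summaries, cross-track damage accumulation and bootstrapped yields per Gy;
microdosimetric conversions (mean chord length, *y*<sub>F</sub> ↔
*z*<sub>F</sub>, beam-spectrum moments and *y*<sub>D</sub>); calibration of
every model function from per-quality damage yields; a spatial damage
generator that realizes a dose as Poisson tracks through a spherical
nucleus with Gamma-distributed site complexities along each chord; and a
sigmoid repair model (*p*(*C*) = 1/(1 + e^(−*d*(*C*−*C*₀.₅)))) propagated
to cell survival curves, linear-quadratic fits and RBE at fixed survival
levels or as the α-ratio.

No published calibration ships with the package: coefficients are inputs,
fitted from damage summaries (`calibrate_mgm()`) or supplied by the
synthetic ground-truth generator for validation studies.

## Worked example

Calibrate from synthetic per-quality yields (15 qualities spanning
2–200 keV/μm, 5% multiplicative noise), predict, generate and evaluate
biological endpoints:

```r
library(microgamma)

truth  <- mgm_ground_truth(noise_sigma = 0.05, seed = 1)
params <- calibrate_mgm(make_quality_yields(truth), weighting = "relative")
print(params)
#> MGM parameters (units: yF in keV/um, yields per track)
#>   SB:     k_direct = 0.9012, N_max = 115.7, a_sat = 0.02112
#>   BD:     k_direct = 1.103, N_max = 179.4, a_sat = 0.01519
#>   DS+DSB: c1 = 0.08236, c2 = 0.002923
#>   Gamma:  a(yF) = 2.172, 0.02627, -4.383e-05;  b(yF) = 0.9107, -0.004037, 1.023e-05

gp <- gamma_params_at(50, params$gamma)
n_ds_with_dsb(50, params$ds_dsb$c1, params$ds_dsb$c2)
#> DSB-containing sites per track at yF = 50: 11.42
#> complexity law at yF = 50: a = 3.376, b = 0.734 (mean C = 4.60)

# 2 Gy of yF = 115.3 keV/um alpha particles in a 9.65 um nucleus
real <- generate_damage(2, beam_spectrum(115.3), params, seed = 42)
print(real)
#> damage realization: 2 Gy, 12 tracks, 629 DSB-containing sites

rp   <- repair_model_params(d = 1, C0_5 = 6)
doses <- seq(0, 8, by = 0.5)
ref  <- survival_closed_form(doses, beam_spectrum(2),     params, repair = rp)
test <- survival_closed_form(doses, beam_spectrum(115.3), params, repair = rp)
rbe(ref, test, 0.1)
#> RBE at 10% survival: 1.18 (D_ref = 0.69 Gy, D_test = 0.58 Gy)
rbe_alpha_ratio(attr(ref, "alpha"), attr(test, "alpha"))
#> RBE min (alpha ratio): 1.18
```

The recovered coefficients sit within a few percent of the generating
truth (`default_truth_params()`); the realization drew 12 tracks (Poisson
mean 7.9 for 2 Gy at this quality) and its 629 sites sit near the
conditional expectation 12 × 48.4 ≈ 581 sites; and the RBE above 1
reflects the higher per-site complexity (mean C ≈ 8 vs ≈ 2.5) of the
high-LET beam against the low-LET reference.

A command-line interface wraps the same functions
(`Rscript inst/exec/mgm --help`; subcommands `analyze-sdd`, `fit`,
`predict`, `generate`, `survival`, `rbe`, `fixtures`).

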