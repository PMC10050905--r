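# hsqcmult

Automated identification and decomposition of ¹³C–¹³C scalar-coupling
multiplets in processed 2D-¹H,¹³C-HSQC NMR spectra from stable-isotope
tracing experiments.

## The problem

When cells metabolise a ¹³C-enriched tracer, each metabolite ends up as
a mixture of *isotopomers* — molecules with different ¹³C label
patterns.  In a 2D-¹H,¹³C-HSQC spectrum every CH pair gives one cross
peak whose ¹³C fine structure reads out the labelling of the
neighbouring carbons: a singlet (s) when no neighbour is labelled, a
doublet (d) split by the one-bond coupling ¹J(CC) ≈ 30–60 Hz per
labelled neighbour, a doublet of doublets (dd) for two.  The relative
intensities of these multiplet components are the isotopomer fractions,
the quantity of interest for pathway analysis.  Analysing them manually
requires expert knowledge, because resonance positions drift with pH
and sample matrix and the multiplet shape depends on the tracer.

`hsqcmult` automates the analysis per resonance, for users who are not
NMR specialists:

1. restrict the spectrum to a window around the library shifts
   (±0.15 ppm ¹H, ±3.0 ppm ¹³C);
2. unmix the window's ¹H columns into statistically independent ¹³C
   source traces with fixed-point ICA (the model `Y = W S`, where the
   columns of the window are the observations `Y` and the sources `S`
   are candidate multiplet traces);
3. localise each source along ¹H by correlation against the window
   columns, discarding sources below a minimum correlation (0.8);
4. identify the multiplet by matching all `2^n − 1` subsets of the
   simulated first-order components against each source, scoring each
   candidate position by its nonnegative-regression coefficient of
   determination ρ weighted by the squared distance Δppm from the
   library shifts (`score = ρ / (ε + Δppm²)`, with the ¹³C deviation
   compressed by 20·γH/γC ≈ 79.5);
5. refine the ¹H position by hill climbing and quantify the component
   fractions **B** by nonnegative least squares, `F = X B`, `B ≥ 0`,
   normalised so the fractions sum to 1;
6. report ρ (percent of variance explained over the multiplet extent)
   with a trust flag: trustworthy (ρ ≥ 80), borderline (70 < ρ < 80),
   not trustworthy (ρ ≤ 70), or not found (ρ = 0) when no signal
   survives the correlation gate.

Apparent-J scaling factors (1, 2, 4, 8) used to enhance splitting
resolution are detected automatically and compensated in the
simulation.

The package includes readers for NMRPipe ft2 and Sparky ucsf spectra, a
portable JSON grid format for text-only fixtures, a shipped reference
library (lactate, alanine, glutamate, aspartate — 11 CH resonances),
and a synthetic-spectrum generator with ground truth used by the whole
test-suite.

## Worked example

Generate a synthetic spectrum with known lactate isotopomer fractions,
then analyse it:

```r
library(hsqcmult)

lib <- load_library()                     # shipped reference library
entries <- resonances_of(lib, "lactate")  # C2 (p = 4) and C3 (p = 2)

sp <- generate_spectrum(entries,
                        fractions = list(c(0.10, 0.20, 0.30, 0.40),
                                         c(0.55, 0.45)),
                        snr = 50, seed = 7)

cfg <- analysis_config(j_scaling = 1, linewidth_c = 3)
res <- analyze_metabolite(sp$grid, lib, "lactate", cfg)
print(res)
#> <multiplet_results>
#>   lactate    C2    1H  4.1562  13C  69.228  rho  95.67%  trustworthy
#>   lactate    C3    1H  1.2770  13C  20.410  rho  99.30%  trustworthy

print(res[[1]]$fit)
#> <multiplet_fit> rho 95.67%  trust: trustworthy
#>   s             10.39%
#>   d(C1)         19.57%
#>   d(C3)         29.86%
#>   dd(C1,C3)     40.17%
```

The true C2 position was 4.1489 / 69.2278 ppm (the generator perturbed
the library shifts to emulate pH drift) and the true fractions were
10 / 20 / 30 / 40 % — the pipeline localised the resonance to the
nearest ¹H column and recovered every fraction within half a
percentage point, flagging the result trustworthy.  Weak multiplets
behave differently by design: at lower SNR a resonance whose signal
disappears into the noise is reported `not_found` with ρ = 0 rather
than fitted to noise.

The same pipeline is scriptable from a shell via the installed
executable:

```sh
hsqcmult simulate --metabolites lactate,alanine --snr 30 --out demo.json
hsqcmult analyze --spectrum demo.json --metabolites lactate,alanine \
                 --j-scaling 1 --linewidth 3 --out results/
```

which writes `results/report.json` (machine-readable; per-resonance
shifts, Δppm, percentage contributions, ρ, trust flag) and optionally a
markdown rendering.

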