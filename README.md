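# usvloc

Hybrid localization and emitter assignment of mouse ultrasonic
vocalizations (USVs).

## What it is for

Mice court, compete and communicate with 30–110 kHz calls. When two or
three animals interact at snout-to-snout range, knowing *who* vocalized is
the bottleneck for every downstream analysis, and it requires localizing
each call with millimetre precision. `usvloc` implements a complete
acoustic pipeline for a standard recording geometry — a 40 × 30 cm
elevated platform under a 64-microphone planar array (Fermat spiral,
46.5 cm above the platform) plus four high-quality ultrasonic microphones
at the platform corners — and a ground-truthed synthetic scene generator
so the whole method can be exercised and validated without experimental
data.

The pipeline, per detected call:

1. **Delay-and-sum beamforming** on the 64-channel array. The density of
   sound origin over a plane 1 cm above the platform,

   DSO(x, y) = Σ_f |Σ_m S_m(f) · exp(i2πf τ(m, x, y, z))|²,

   is scanned coarse-to-fine (10 mm full surface → 1 mm over a 30 × 30 mm
   window), summing only frequencies inside the call's own band; the
   DSO-weighted centroid is the origin and 1/SNR of the field
   (max/sd) its raw uncertainty.
2. **Four-microphone TDOA localization**: GCC-PHAT time differences per
   microphone pair, each constraining the source to a hyperbola on the
   platform plane; the curves are accumulated on a 1 mm grid and the
   density peak is the estimate, with the spread of cells above 90% of
   the maximum as its uncertainty.
3. **Mouse Probability Index (MPI) assignment**: per mouse,
   P_k = N(Ẋ_method − X_mouth,k; σ²_method) with P_k = 0 beyond 50 mm, and
   MPI_k = P_k / Σ_m P_m. Uncertainties are calibrated against residuals
   in the far condition (all snouts > 100 mm apart). A method is trusted
   when its top MPI exceeds 0.95; if both methods qualify, the smaller
   residual wins; otherwise the call is excluded.
4. **Spatial statistics**: relative polar occurrence maps of the receiver
   around the emitter (10° × 1 cm raw-count bins, folded into one
   hemispace), bootstrap per-bin significance (100 resamples,
   extreme-value bounds), sex fractions with optional distance gating, and
   dominance classification within same-sex pairs.

## Worked example

```r
library(usvloc)

b   <- simulate_scene(n_mice = 2, n_usvs = 12, band_snr_db = 10, seed = 7)
loc <- localize_bundle(b)   # band-pass, clock sync, detect, localize
res <- assign_bundle(b, loc)
res$summary
#> $n_detected           [1] 12
#> $n_assigned           [1] 12
#> $assigned_fraction    [1] 1
#> $mae_mm               [1] 0.393
#> $correct_emitter_rate [1] 1
```

All twelve simulated calls are detected, assigned to the correct mouse,
and localized with a 0.39 mm median error against the ground-truth snout
positions (a noise-free-geometry simulation is much easier than a real
recording; see the methods vignette for what the generator does and does
not emulate). `analyze_assignments()` then turns an assignment table into
the relative polar occurrence map.

File-based stage drivers (`cli_simulate`, `cli_localize`, `cli_assign`,
`cli_analyze`) read and write plain artifacts (multichannel WAV, CSV,
JSON) in a bundle directory, and `inst/cli/usvloc` wraps them as a shell
command:

```sh
Rscript inst/cli/usvloc simulate --out run1 --seed 7
Rscript inst/cli/usvloc localize --out run1
Rscript inst/cli/usvloc assign   --out run1
Rscript inst/cli/usvloc analyze  --out run1
```

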