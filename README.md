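# feedscreen

Mechanical feedability screening for FDM 3D-printing filaments.

Fused deposition modelling (FDM) printers push a 1.75 mm filament between two
counter-rotating rollers into a heated nozzle, leaving it under axial
compression the whole way. Brittle hot-melt-extruded (HME) filaments fracture
there and block the printing head; over-plasticized ones coil up and never
thread through. `feedscreen` implements a texture-analyzer screening method
that predicts this *feedability* — a Boolean: will the filament feed? —
before any printer is risked, aimed at pharmaceutical formulators developing
HME filaments for printed dosage forms.

## The method

A 5 cm filament specimen stands vertically in conical end caps and is
compressed axially by 15 mm at 3.15 mm/s (the printer's roller speed), then
released, while force is recorded from a 0.05 N trigger. The recorded
force–distance curve (the *flexibility profile*) is

1. resampled onto a fixed 128 + 128-station compress-and-release grid,
2. range-normalized, `y_norm(n) = y(n) / sum(y)`, removing the force scale,
3. correlated (Pearson) with each member of a library of known-feedable
   commercial reference filaments (ABS, PLA, a dissolvable support
   filament),
4. averaged, `C_mean = (C_ABS + C_Dissolvable + C_PLA) / 3`, and
5. rounded: `C_mean < 0.5 → 0` (non-feedable), `> 0.5 → 1` (feedable).

Specimens that never reach the trigger force are *floppy* and reported
not-testable (they are not feedable either — they coil). Panels are
additionally sorted in component space: PCA on the filament correlation
matrix, Kaiser rule (eigenvalue ≥ 1), varimax rotation (25-iteration
budget), where feedable, "tunable" and non-feedable filaments separate into
clusters.

Because no raw instrument curves are publicly deposited, the package also
ships a physics-based profile simulator (Euler column buckling,
`F_cr = π²EI/L²`, plus phenomenological fracture) that generates labelled
synthetic profiles for the four observed morphologies — sharp brittle,
strain-bearing brittle, pliable, floppy — making every pipeline stage
testable end to end.

## Worked example

Simulate a reference library and a small candidate panel, then screen it:

```r
library(feedscreen)
cfg   <- protocol_config()                      # 15 mm, 3.15 mm/s, 0.05 N trigger
refs  <- make_reference_library(cfg, seed = 42) # ABS-, PLA-, dissolvable-like
panel <- make_panel(c(pliable = 2, strain_bearing_brittle = 1, floppy = 1),
                    cfg, seed = 7)
res <- screen_panel(panel, refs, cfg)
res$table
```

```
                filament_id C_ABS_like C_PLA_like C_Dissolvable_like display_score         call
1                pliable_01      0.951      0.986              0.986          0.97     feedable
2                pliable_02      0.953      0.983              0.990          0.97     feedable
3 strain_bearing_brittle_01      0.279      0.350              0.438          0.36 non-feedable
4                 floppy_01         NA         NA                 NA            NA not-testable
```

Each row is one filament: its Pearson correlation with each reference curve,
the 2-decimal mean score, and the Boolean call. The two pliable filaments
correlate above 0.95 with every reference and are called feedable; the
strain-bearing brittle one peaks and fractures early, scores 0.36 and is
called non-feedable; the floppy one never reached the trigger force and is
not-testable. `res$library` holds the reference consistency matrix and any
reference excluded from PCA as an outlier.

Real instrument exports (CSV with columns `distance_mm,force_N,phase`, one
file per replicate, stem `<filament_id>__rep<k>`) are read with
`read_profile()` / `read_profile_dir()` and screened the same way. A thin
command-line front end covers the same operations:

```sh
Rscript inst/scripts/feedscreen.R simulate --spec spec.json --out panel/ --seed 7
Rscript inst/scripts/feedscreen.R score    --candidates panel/ --references refs/ --out report
Rscript inst/scripts/feedscreen.R pca      --candidates panel/ --references refs/ --out coords.csv
```

For panel sorting, `pca_profiles()` returns eigenvalues, retained
components and varimax-rotated loadings; `space_plot_coordinates()` and
`plot_space()` turn them into a space plot, and `silhouette_separation()`
quantifies cluster separation.

The bundled dataset `feedability_panel()` carries the per-reference
correlation coefficients of a published 17-filament HME screening panel;
`score_coefficients()` reproduces its reported average and rounded columns
from the coefficients alone.

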