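# beamext

Estimating the **spatial extent** of cortical sources in MEG with
extended-source beamformers.

Conventional minimum-variance beamformers (SAM/LCMV) model the source as a
single equivalent current dipole (ECD). `beamext` replaces the point model
with an *extended* source model — a disc-shaped grid of ECDs, or a
surface-following patch grown along the cortical mesh — and scans the model's
radius: the radius at which the beamformer output peaks is the estimated
spatial extent. The package is aimed at MEG methods researchers who want to
study when extent is and is not recoverable (as a function of SNR, cortical
curvature, noise colour and co-registration accuracy), entirely in
simulation: it ships its own synthetic folded-cortex generator, spherical
volume conductor, helmet arrays, and multi-epoch noise simulator, so no
anatomical or recorded data are needed.

## The method

For a sensor covariance `C` (estimated per analysis window, no
regularisation) and a model lead field `l`, the unit-gain minimum-variance
weights are

    w = C⁻¹ l / (lᵀ C⁻¹ l)

and the beamformer output is the **pseudo-Z** statistic

    pseudo-Z = (wᵀ C w) / (σ² wᵀ w)

with `σ²` the per-channel sensor noise variance. Three modifications make
this an extent estimator:

1. **Extended-source lead fields** — `l` is the moment-weighted sum of the
   element ECD fields (Sarvas spherical-conductor formula), i.e. the patch is
   one scalar source with a single time course, modelling within-patch
   correlation exactly.
2. **Orientation** — for disc models the disc orientation is solved per
   location either by a linearised generalized-eigenvalue method (fast;
   exact for points, biased for large discs) or by an exhaustive "spinning"
   search that physically re-grows the disc in each direction. Cortical
   patch models use the local surface normals (fixed).
3. **Radius scan** — the model radius is swept (default 0–20 mm) and the
   argmax of pseudo-Z is the estimated extent; the model centre is either
   held at the target, optimised by a simplex search, or constrained to
   cortical vertices within 2.5 cm of the target.

## Worked example

```r
library(beamext)

head    <- head_model(sphere_radius = 90)             # mm
sensors <- make_helmet_array(120, helmet_radius = 110,
                             coverage_angle = 120, kind = "magnetometer")

# truth: a 10 mm disc source, 25 mm below the helmet, tangential orientation
truth <- build_disc_patch(centre = c(0, 0, 65), normal = c(1, 0, 0),
                          radius = 10)
lf    <- patch_lead_field(head, truth, sensors)

# 100 epochs x 200 ms at Q = 20 nAm, white noise 10 fT/sqrt(Hz) over 80 Hz
noise <- noise_spec()
w20 <- simulate_window(lf, Q = 20, noise, seed = 11)
w0  <- simulate_window(lf, Q = 0,  noise, seed = 12)
estimate_snr(w20, w0)
#> [1] 27.85

res <- scan_disc_extent(w20, head, sensors, centre = c(0, 0, 65),
                        radii = seq(0, 20, 2),
                        noise_variance = white_noise_variance(noise))
res
#> scan_result: estimated extent 10.0 mm (pseudo-Z 62.01), localisation error 0.00 mm
round(res$pseudo_z / max(res$pseudo_z), 3)
#>  [1] 0.558 0.578 0.636 0.749 0.892 1.000 0.883 0.586 0.353 0.212 0.132
```

The pseudo-Z curve peaks at the true 10 mm radius; its shallowness at small
radii is why a plain dipole model loses little output even when the source
is extended.

For surface-following sources, generate a folded sheet and run the full
experiment loop (this is the package's core study):

```r
cfg <- experiment_config(truth_kind = "cortical", position = "constrained",
                         n_sources = 10, Q = 20, seed = 7)
tbl <- run_extent_experiment(cfg)          # ~5 min
rep <- report_extent_table(tbl)
rep$contrasts   # per-shift slope summaries, flat-vs-curved t, binomial test
```

## Command-line wrapper

```sh
Rscript inst/cli/beamext.R experiment --config cfg.yaml --seed 1 --out out/
Rscript inst/cli/beamext.R report --table out/extent_table.csv --out out/
```

Subcommands: `make-mesh`, `simulate`, `scan`, `experiment`, `report`. Each
writes its outputs as CSV/OBJ plus a `run_log.json` with the config hash,
seed and package version.
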