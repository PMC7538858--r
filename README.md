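# tilstrat

Relapse-risk stratification of triple-negative breast cancer (TNBC) from
two-channel immunofluorescence images: pan-cytokeratin (PanCK) marking
cancer-cell islands and CD8 marking tumor-infiltrating cytotoxic T cells.

Classical prognostic metrics — overall CD8 density, CD8 density inside
cancer islands — need a hand-picked threshold that varies between metrics
and cancers. `tilstrat` implements a patch-based machine-learning
alternative for pathologists and computational-biology groups working
with IF cohorts:

1. binarize each channel at its per-image nearest-rank 90th intensity
   percentile (top ~10% of pixels positive);
2. clean the binary masks in physical units: remove connected areas
   < 200 µm² (noise), fill holes < 200 µm² in the PanCK mask (PanCK is a
   surface marker, so cell interiors image dark);
3. resample to a common 10 µm/px grid (PanCK: block-majority; CD8:
   block-presence) and tile into adjacent 64 × 64 px patches, keeping a
   patch iff ≥ 1/4 of its pixels are PanCK⁺ and it has ≥ 1 CD8⁺ pixel;
4. train a small CNN (RMSProp, mini-batch 20, binary cross-entropy;
   minority class balanced by 3 extra copies per patch) to predict
   whether a patch comes from a poor-outcome patient
   (relapse < 3 y; good = relapse-free ≥ 5 y);
5. per patient, compute the fraction R of held-out patches labeled
   "good" and predict poor outcome iff R < Rc, where the cut-off Rc is
   the accuracy-maximizing value scanned exactly (accuracy is piecewise
   constant in Rc) and averaged over repeated split/training
   realizations that achieve the best separation;
6. compare against the manual baselines (CD8-in-island density,
   absolute CD8/PanCK areas with exhaustively scanned best cut-offs) and
   probe robustness under half/quarter-section subsampling.

The signal this pipeline extracts is the *relative infiltration* of CD8⁺
T cells into cancer-cell islands: patches from good-outcome patients
show CD8 signal inside the PanCK islands, poor-outcome patches show CD8
confined to stroma. A synthetic-cohort generator plants exactly this
signal (a per-patient infiltration probability `p_in` drives both the
image structure and the outcome label), so the entire pipeline is
testable end to end without patient data.

## Worked example

```r
library(tilstrat)

# one synthetic patient: islands + infiltrated T cells
p <- generate_patient(synthetic_study_params(p_in = 0.8, seed = 42),
                      patient_id = "PT1", outcome = "good")

# raw intensities -> cleaned binary masks -> 10 um grid -> patches
mp  <- make_mask_pair(p$panck, p$cd8)
pat <- filter_patches(tile_patches(rescale_mask_pair(mp), 64, "PT1"))
nrow(pat)                      # surviving 64x64 patches
cd8_density_in_islands(mp)     # classical density baseline

# the full synthetic validation study: 15 good + 9 poor training
# patients, 5 split/training realizations, 10-patient test cohort
st <- run_synthetic_study(seed = 1)
glance(st)
```

Output of the last call (deterministic given the seed):

```
# A tibble: 1 x 6
   seed training_separation_accuracy rc_final test_accuracy test_recall test_precision
  <dbl>                        <dbl>    <dbl>         <dbl>       <dbl>          <dbl>
1     1                            1    0.583             1           1              1
```

Reading: at least one realization separated the 24 training patients
perfectly (`training_separation_accuracy = 1`); averaging the optimal
cut-off intervals of the perfect realizations gives `Rc ≈ 0.58` (a
patient is called poor when fewer than ~58% of its held-out patches look
"good"); applying the vetted classifier and that cut-off to an
independently generated 10-patient cohort classifies all ten
correctly. `autoplot(st$scans[[1]])` draws the accuracy-vs-Rc scan,
`autoplot(st$model)` the training trace, and
`infiltration_monotonicity()` / `robustness_study()` reproduce the
rank-correlation and half-section stability analyses.

A thin command-line front end is installed with the package
(`system.file("cli", "tilstrat", package = "tilstrat")`) with
subcommands `simulate`, `preprocess`, `run`, `predict`, `baselines` and
`study` over written cohorts (TIFF pairs plus a TSV manifest).

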