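# sacmetry

Automated biometry of the gestational sac (GS) in early-pregnancy
ultrasound, for researchers building or validating GS segmentation
pipelines. Given a binary sac mask and the physical pixel spacing,
`sacmetry` measures the sac the way a sonographer's calipers do and turns
the measurement into a gestational-age estimate; around that core it
provides the segmentation losses, region metrics, agreement statistics,
architecture definitions and synthetic phantoms needed to evaluate the
whole pipeline end to end on a desk.

## The method

From a segmented binary mask the measurement chain is:

1. keep the largest 8-connected foreground component;
2. trace the outer boundary by **Moore neighbor tracing** (clockwise
   neighborhood walk, Jacob's stopping criterion, implicit zero padding at
   the image border);
3. fit the **minimum-area enclosing rectangle** to the boundary by
   rotating calipers over the convex hull;
4. scale the rectangle's sides per axis by the pixel spacing
   (cm/px) to get the maximum length *DM* and short diameter *Dm*:
   for corners c1, c2 (long side) and c1, c3 (short side),

   DM = sqrt((Δcol·PS_col)² + (Δrow·PS_row)²),  and likewise Dm;

5. estimate gestational weeks with the **Hellman mean-sac-diameter
   formula**:

   GW = (0.5·(DM + Dm) + 2.543) / 0.7,   DM, Dm in cm.

At the classical empty-sac threshold (mean sac diameter 25 mm) the formula
gives 7.2 weeks, which the package's tests pin down.

Also included: soft Dice / Jaccard / binary cross-entropy losses; IoU,
Dice, Recall, Precision region scores; annotator-consensus masks;
Bland–Altman agreement with limits of agreement and MAE; UNet, UNet++,
DeepLabV3 and ResUNet built on a ResNet50 encoder with exact
trainable-parameter accounting and a deterministic CPU training loop; a
4× augmentation protocol (45° rotation + flips) and stratified 5-fold CV
splits; and a synthetic sac-phantom generator with analytic ground truth.

## Worked example

```r
library(sacmetry)

# a 512x512 phantom: ellipse with semi-axes 125 x 75 px at 30 deg,
# 0.01 cm/px isotropic spacing
sac <- generate_sac(sac_params(a = 125, b = 75, angle = 30, spacing = 0.01),
                    seed = 1)
bio <- run_biometry(sac$mask, sac$params$spacing)
bio
#> Gestational sac biometry
#>   DM = 2.504 cm, Dm = 1.512 cm (MSD 20.1 mm)
#>   GW = 6.50 weeks (Hellman)
#>   spacing: 0.0100 x 0.0100 cm/px, rect angle 26.6 deg
```

The phantom's analytic truth is DM = 2.5 cm, Dm = 1.5 cm, GW = 6.49
weeks: the digitized measurement lands within half a percent of truth and
about 0.01 weeks of the true gestational age. `tidy(bio)` returns the same
numbers as a one-row tibble, and `autoplot(bio)` draws the traced boundary
with the fitted rectangle.

Comparing automated estimates with a clinician's:

```r
df <- data.frame(doctor = c(7.10, 7.95, 6.52, 8.40, 5.90),
                 auto   = c(7.18, 7.90, 6.55, 8.33, 5.98))
glance(agreement(df, "doctor", "auto"))
#> # A tibble: 1 × 6
#>   mean_diff sd_diff loa_lower loa_upper    mae     n
#>       <dbl>   <dbl>     <dbl>     <dbl>  <dbl> <int>
#> 1    0.0140  0.0709    -0.125     0.153 0.0620     5
```

so the automated reading is biased by +0.014 weeks against this
(toy-sized) reference, with 95% limits of agreement of −0.13 to +0.15
weeks; `autoplot()` on the agreement object gives the Bland–Altman plot.

Architecture bookkeeping:

```r
model_info("resunet")
#> # A tibble: 1 × 3
#>   arch    encoder  trainable_params
#>   <chr>   <chr>               <dbl>
#> 1 resunet resnet50         33435410
```

A command-line front end over the same functions ships in
`inst/cli/sacmetry.R` (`simulate`, `biometry`, `evaluate`, `agreement`,
`model-info`, `pipeline`).

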