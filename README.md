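# vftrain

Headless simulation and evaluation toolkit for adaptive visual-field
training in a virtual-reality headset.

## The problem

Post-chiasmatic brain lesions (stroke, trauma) commonly cause homonymous
visual-field defects — hemianopia or quadrantanopia. Visual restitution
training (VRT) presents bright light stimuli on the *border zone* between the
intact and defect visual field, on the hypothesis that repeated stimulation
drives cortical reorganisation. Whether that works is contested; answering
the question needs a training device that provably puts stimuli where the
investigator intends, on the patient's retina, session after session.

`vftrain` re-implements the computational core of such a device — a
smartphone-in-goggles VR trainer configured from perimetric maps — as an R
library plus CLI, so that its geometry, its adaptive stimulus-placement rule,
and its validation statistics can be studied, simulated, and reproduced
without any hardware. It is aimed at vision scientists and
neurorehabilitation researchers who want to model such training procedures or
audit their evaluation statistics.

## What is inside

* **Geometry** — perimetric data are acquired on a screen at 400 mm; the
  headset shows a phone screen at 44 mm through lenses such that 1 retinal
  degree spans 1.54 device degrees inside a ~90° stereoscopic field. A
  millimetre offset *s* at distance *d* subtends `2·arctan(s/(2d))` degrees;
  `perimeter_to_headset()` applies this per axis and scales by 1.54.
* **Visual fields** — `make_field()` samples parametric scotomata (circle,
  half-plane, quadrant; `blind_spot_scotoma()` gives the anatomical blind
  spot, a 2.5°-radius circle at (±14.5°, −1°)) onto a grid of 0.75° pitch,
  emulating perimeter output; `border_zone()` extracts the training zone.
* **Adaptive trainer** — stimuli (3°, 750 ms, dark background, 2000 ms
  response window plus up to 1500 ms random break) are relocated after every
  response: a *detected* stimulus moves one step (default δ = 0.5°) toward a
  reference point inside the defect, a *missed* one moves one step away,
  so the stimulus set tracks the true border.
* **Simulated observer** — answers presentations from a ground-truth field
  with fixation jitter, lapse and guess rates; a deterministic *quota*
  responder replays subjects known only through summary rates.
* **Validation protocol** — the blind-spot study: monocular runs of 150
  stimuli of 0.33° / 200 ms (25 warm-up, 100 scored = 15 in the blind spot +
  85 detectable, 25 buffer). Since nobody can see a blind-spot stimulus,
  clicks on them measure placement/fixation error.
* **Detection metrics** — the study's (inverted) convention: with TN =
  blind-spot stimulus not clicked, FP = blind-spot stimulus clicked, FN =
  detectable missed, TP = detectable clicked,

  ```
  SEN = TN/(TN+FP)        SPE = TP/(TP+FN)
  PPV = TN/(TN+FN)        NPV = TP/(TP+FP)
  HR  = (TN+TP)/N         RHR = q·D/N + (1−q)·B/N,  q = (TP+FP)/N
  RATZ = (HR−RHR)/(1−RHR) ACC = (TP+TN)/N
  ```

  plus cohort summaries and split-half reliability with the Spearman–Brown
  prophecy `2r/(1+r)`.

## Worked example

Reproduce the 40-subject validation evaluation from the bundled per-subject
rate table:

```r
library(vftrain)
subjects <- read.csv(system.file("extdata", "validation_subjects.csv",
                                 package = "vftrain"),
                     colClasses = c(subject = "character"))
rep <- reproduce_validation(subjects)
head(rep$per_subject, 3)
#>   subject tn fp fn tp   sen   spe   ppv   npv   hr   rhr  ratz  acc
#> 1      01 14  1  1 84 0.933 0.988 0.933 0.988 0.98 0.745 0.922 0.98
#> 2      02 15  0  0 85 1.000 1.000 1.000 1.000 1.00 0.745 1.000 1.00
#> 3      03 14  1  0 85 0.933 1.000 1.000 0.988 0.99 0.752 0.960 0.99
rep$summary[, c("metric", "mean_3", "sd_3")]
#>   metric mean_3  sd_3
#> 1    sen  0.980 0.038
#> 2    spe  0.992 0.016
#> 3    ppv  0.959 0.070
#> 4    npv  0.996 0.007
#> 5     hr  0.990 0.018
#> 6    rhr  0.742 0.008
#> 7   ratz  0.963 0.061
#> 8    acc  0.990 0.018
str(rep$pooled)
#> List of 5
#>  $ tn      : int 588
#>  $ fp      : int 12
#>  $ fn      : int 28
#>  $ tp      : int 3372
#>  $ accuracy: num 0.99
```

Each subject's integer confusion matrix is recovered from their published
rates (`tn = round(15·sen)`, `tp = round(85·spe)`); pooling the 40 matrices
gives 588 correct non-reactions, 12 false reactions, 28 missed detectable
stimuli and 3372 correct reactions out of 4000 scored trials — an overall
placement accuracy of 99.0%. The split-half reliability correction
`spearman_brown(0.547)` returns `0.707`. `rep$discrepancies` lists the
subjects whose published RATZ value the chance-correction formula cannot
reproduce (see the vignette).

Simulate the full study instead of replaying it:

```r
field <- make_field(list(blind_spot_scotoma()), pitch_deg = 0.75, extent_deg = 30)
responder <- make_observer_responder(observer_params(), field)  # ideal observer
res <- run_study(study_config(seed = 1), field, responder)
res$matrix
#> <confusion_matrix: TN=15 FP=0 FN=0 TP=85 (blind-spot 15, detectable 85)>
```

## Command line

An executable wrapper is installed at
`system.file("cli", "vftrain", package = "vftrain")`:

```sh
vftrain make-field --type blindspot --eye right --out field.csv
vftrain convert --x-mm 100 --y-mm 0          # -> 21.945050 0.000000
vftrain train --config config.json --field field.csv --sessions 5 --out-dir out/
vftrain simulate-study --subjects 40 --seed 7 --out study/
vftrain reproduce-validation --out repro/    # pooled accuracy 0.990
```

## Documentation

`vignettes/visual-field-training.Rmd` describes the model, the parameter
choices, what the synthetic data do and do not emulate, and known
limitations.
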