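# clockscore

Automatic, qualitative scoring of digitized Clock Drawing Tests (CDT).

The CDT is a standard cognitive screening task: the subject draws a clock
face with all twelve numbers and sets the hands to a given time (e.g. "10
after 11"). When the test is administered on a touch screen, the device
records a sensor log — time stamp `t[n]` (s), position `x[n]`, `y[n]`
(px), and a touch event `e[n] ∈ {−1 down, 0 move, +1 up}` at 50 Hz on a
2400 × 1200 canvas — alongside the raster drawing. `clockscore` turns that
log into a qualitative score of 13 binary criteria grouped into four
parameters:

| Parameter | Criteria | Points |
|---|---|---|
| Contour | circular (`pfc ≥ θc1`), closed (`dmaxc < θc2`), size (`Ac/Wc ≥ θc3`) | 0–3 |
| Numbers | all present (N = 15 character crops), order (`Rseq ≥ θn`), position (share of anchor distances `dcn ≤ ℓdc` above `θdc`), within contour (`RcN < RcL`) | 0–4 |
| Hands | two/one hand presence (`pfh` vs `θh1`, `θh2`), proportion (`Δℓh > θpr`), hour and minute target indication (hit distance `< ε`) | 0–5 |
| Center | drawn or inferred (hands present, or ink within `εc` of the center) | 0–1 |

The geometry is computed from the sensor trace: the contour is the stroke
with the longest run of move events; its bounding box defines the clock
center and the canonical anchor positions of digits 1–12; `pfc`/`pfh` are
pixel-overlap percentages between the rasterized strokes and segmentation
masks; digit crops come from 8-connected components of the contour-removed
binary image and are classified by a pluggable backend; drawing order is
compared to three habitual reference orders by Ratcliff–Obershelp
similarity; hands are split by line clustering, fitted by total least
squares, and extrapolated to the contour to test the indicated time.

Segmentation and digit classification are **pluggable backends**: the
package ships reproducible U-Net (23 convolutional layers) and CNN
(32@5×5 → pool → 64@5×5×32 → pool → 1024 → 10) builders with a
smoke-scale training harness, and oracle backends driven by the included
synthetic clock generator, so the entire scoring pipeline is testable
without clinical data or trained weights.

## Worked example

```r
library(clockscore)

spec  <- clock_spec(seed = 7)          # a well-executed clock, 10 past 11
clock <- generate_clock(spec)
report <- score_clock(clock$trace,
                      segmenter  = oracle_segmenter(clock$truth),
                      classifier = oracle_classifier(clock$truth))
report
#> <cdt_score_report> total 13/13 (contour 3/3, numbers 4/4, hands 5/5, center 1/1)
```

The report carries every intermediate statistic. For this drawing:
`pfc = 100` (the drawn contour lies on its fitted circle, so it is
circular), `dmaxc = 2.2` px (closed: below the 50 px threshold),
`Ac/Wc = 0.35` (appropriately sized), `N = 15` character crops with five
1s and two 2s (all numbers present), `Rseq = 100` (drawn in ascending
order), anchor distances `dcn` between 54 and 79 px (all within the
100 px limit), `RcN = 355.7 < RcL = 500.1` (numbers inside the contour),
`pfh = 100` with `Δℓh = 98.5` px (two hands, correct proportion), and
hit distances 128.7 px (hour) and 126.4 px (minute), both inside the
200 px radius around the target anchors — total 13/13.

Introducing a defect changes exactly the criteria it should:

```r
bad <- generate_clock(apply_defect(spec, "wrong_time"))
score_clock(bad$trace, oracle_segmenter(bad$truth),
            oracle_classifier(bad$truth))
#> <cdt_score_report> total 11/13 (contour 3/3, numbers 4/4, hands 3/5, center 1/1)
```

A command-line front end is installed with the package:

```sh
Rscript inst/scripts/clockscore.R simulate --seed 7 --out-dir demo/
Rscript inst/scripts/clockscore.R score --trace demo/trace.csv \
    --truth demo/truth.json --out demo/report.json
Rscript inst/scripts/clockscore.R evaluate --pred preds.csv --truth truth.csv
```

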