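# kymotrace

Kymograph-based quantification of motor-protein motility in live-cell
TIRFM time-lapses, with a synthetic movie generator that makes every
stage of the analysis verifiable by parameter recovery.

## The problem

Processive transport by dynein–dynactin (and other cytoskeletal motors)
is measured in living cells by tracing a moving punctum's path on a
microtubule, building a **kymograph** — intensity along the path (one
axis) versus time (the other) — and reading the motility parameters off
the sloped ridge each run leaves behind:

- velocity `v` = slope of the event from start to end (µm/s),
- run time `t` = (end frame − start frame) × frame interval (s),
- run length `L = v · t` (µm),
- directional switches = sign changes of displacement with both flanking
  arms above a minimum length,

plus fluorophore **stoichiometry** of moving puncta: the background-
corrected integrated intensity of each punctum (region-in-region method,
`I = Σ inner − n_inner · mean(outer ring)`) divided by that of a standard
carrying exactly two fluorophores (a kinesin-1-EGFP dimer), so that
`copies = 2 · Ī_test / Ī_standard`. Group comparisons use a
two-sided randomization (permutation) test on the difference of means.

The raw observations behind such measurements are live-cell movies that
cannot be re-measured from a published table. kymotrace therefore ships a
TIRFM scene simulator — diffraction-limited Gaussian puncta with
truncated-normal speeds, exponential run durations (constant detachment
rate), rare directional switches, binomial genetic labeling,
per-fluorophore photobleaching, Poisson shot noise and Gaussian read
noise — whose ground truth is known exactly. Packaged reference
scenarios transcribe the reported study conditions (motile pool:
1.2 µm/s mean velocity, ~2.6 s mean run time, ~3% switches; tip-tracking
comets at one seventh of that speed; heterozygous labeling models), and
the pipeline must recover those numbers blind.

## Worked example

Simulate the motile-pool reference scenario (22 movies, 128×128 px,
60 frames at 5 fps) and run the full kymograph pipeline on it:

```r
library(kymotrace)
res <- run_pipeline("dhc_motile", seed = 7, measure_intensity = FALSE)
res
#> <pipeline_result> dhc_motile
#>   runs scored: 100 / 176 simulated (57%)
#>   velocity:   1.212 +/- 0.043 um/s (mean +/- SEM)
#>   run time:   2.31 +/- 0.18 s
#>   run length: 2.75 +/- 0.23 um
#>   switches:   6.0% of runs
```

100 of 176 simulated runs were scored (the rest carried no fluorophore,
started too late in the stream, bleached, or were too short — the same
censoring real streams impose). The recovered mean velocity (1.212 µm/s),
run time (2.31 s) and run length (2.75 µm) reproduce the scenario's
configured values (1.2 µm/s, 2.6 s, and the implied ~2.8 µm after
censoring) within twice their configured SEMs; the switch percentage is a
small-sample binomial draw around the configured 3%. `res$runs` holds the
per-run table (velocity, run time, run length, switches, frames) and
`res$recovery` joins every simulated particle to what the pipeline
measured for it.

The randomization test's exhaustive branch reproduces the textbook
worked case:

```r
permutation_test(c(1, 2), c(3, 4))
#> Randomization test: observed diff = -2, p = 0.3333 (exhaustive, 6 permutations)
```

A thin command-line front end wraps the same functions:

```sh
./exec/kymotrace pipeline --scenario dhc_motile --seed 7 --out out/
./exec/kymotrace simulate --config sim.yaml --seed 1 --out out/
./exec/kymotrace stats --a a.csv --b b.csv --n-perm 10000 --seed 1
```

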