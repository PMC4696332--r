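# alphaband

Individualized EEG alpha-band anchoring and the alpha3/alpha2 prognostic
power ratio, for clinical neurophysiology researchers studying conversion
from mild cognitive impairment (MCI) to Alzheimer's disease — plus the
cohort statistics that go with it and a synthetic EEG/cohort generator so
the whole pipeline is testable without patient data.

## The science

Fixed band edges (alpha = 8–13 Hz for everyone) blur subject differences
in the alpha rhythm. This package anchors every subject's bands to two
landmarks detected on their own channel-averaged ("collapsed") Welch
spectrum:

- **TF**, the theta/alpha transition frequency — the power minimum between
  theta and alpha activity;
- **IAF**, the individual alpha frequency — the power maximum in the
  extended alpha range 5–14 Hz.

Bands then follow per subject: delta [TF−4, TF−2), theta [TF−2, TF),
alpha1 [TF, mid), alpha2 [mid, IAF), alpha3 [IAF, IAF+2), with `mid` the
TF–IAF midpoint. Relative power is band power over total 2–45 Hz power,
and the biomarker of interest is the **alpha3/alpha2 ratio**: upper-alpha
relative to mid-alpha power. MCI patients with a high ratio (≥ 1.17) are
at elevated risk of converting to Alzheimer's disease; the package
stratifies subjects into low/middle/high groups, computes the companion
theta/gamma ratio, and provides the cohort statistics used around the
marker: Levene-gated ANOVA/ANCOVA with Games–Howell or Bonferroni
post-hocs, Pearson correlations against covariates, chi-square tests, and
SPSS-style stepwise canonical discriminant analysis (tolerance 0.01,
F-to-enter 1.0) with resubstitution classification.

## Worked example

Generate a synthetic 5-minute high-risk subject and run the full pipeline:

```r
library(alphaband)
rec <- generateEEG(highRiskSubject(seed = 7), duration = 300)
res <- subjectPipeline(rec)
res$anchors
#> AnchorFrequencies: TF = 7 Hz, IAF = 10 Hz
res$markers
#> SubjectMarkers:
#>   relative power: delta=0.0531 theta=0.0656 alpha1=0.0401 alpha2=0.3248
#>                   alpha3=0.3840 beta1=0.0145 beta2=0.0459 gamma=0.0296
#>   alpha3/alpha2 = 1.1825   theta/gamma = 2.2180   risk = high
```

The detected anchors sit at the generator's true values (TF 7 Hz, IAF
10 Hz); the alpha3/alpha2 ratio of 1.18 for this realization scatters
around the preset's analytic value of 1.29 (per-subject sampling SD at
5 minutes is about 0.07) and lands the subject in the high-risk group, as
constructed. With the published cohort-mean anchors the band edges
reproduce the published scheme exactly:

```r
bandTable(defineBands(anchorFrequencies(tf = 6.9, iaf = 10.9)))
#>     band   lo   hi
#> 1  delta  2.9  4.9
#> 2  theta  4.9  6.9
#> 3 alpha1  6.9  8.9
#> 4 alpha2  8.9 10.9
#> 5 alpha3 10.9 12.9
#> ...
```

Cohort-level, with the bundled generator defaults (74 subjects in the
published 42/18/14 outcome-group structure):

```r
coh <- generateCohort(cohortSpec(seed = 1))
rep <- followupAnalysis(coh)   # ANOVAs + stepwise discriminant
```

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/alphaband.R`:

```sh
Rscript inst/scripts/alphaband.R subject  --in rec.edf --out report/
Rscript inst/scripts/alphaband.R cohort   --manifest subjects.tsv --out markers.tsv
Rscript inst/scripts/alphaband.R simulate --out sim/ --seed 1
```

Recordings are read from EDF or from a TSV matrix (channels × samples)
with a JSON sidecar declaring `fs`, `channels` and `units`.

## Acceptance script

`scripts/acceptance.R` recomputes the published worked-example band edges
from scratch by running the installed package's band-definition operation
on the published cohort-mean anchors and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/alphaband-methods.Rmd`) documents the
model, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, the numerical edge-case
policies (midpoint snapping, half-open bins, the 1.16/1.17 cut-off gap,
low-TF clipping), and known limitations.
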