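# txcoupler

Quantitative analysis of how promoters couple mRNA synthesis to
cytoplasmic mRNA fate during glucose starvation in budding yeast.

During acute glucose starvation, a set of alternative glucose metabolism
genes (glycogen synthesis, hexose utilization) is strongly transcribed
while its mRNAs are sequestered in cytoplasmic granules and kept
translationally silent; heat-shock genes induced by the same stress stay
diffuse and well translated. The Rvb1/Rvb2 AAA+ ATPases are loaded at the
promoters of the repressed class and travel with the nascent mRNAs,
making the promoter the upstream switch for the mRNA's cytoplasmic fate.
txcoupler implements the measurement layer this biology is quantified
with, exercisable end to end on seeded synthetic data:

* **kinetics** — the first-order induction model `dX/dt = β − αX`
  (closed form `X(t) = X0 + (β/α − X0)(1 − e^{−αt})`, steady state
  `β/α`, half-life `ln2/α`), least-squares inference of `(α, Fss)` from
  fold-induction courses, log2-linear decay fits after transcription
  shut-off, joint-model decay comparison, and a classifier that
  separates a transcription-rate change (constant log-scale offset) from
  a decay-rate change (offset growing in time);
* **qpcr** — ΔΔCt fold changes (`fold = 2^{−ΔΔCt}`) and the three-stage
  RIP-enrichment cascade (reference gene → input → wild-type IP
  control);
* **chip** — RPKM and ChIP/input normalized density from fixed-bin
  bedGraph tracks, strand-aware scaled metagene profiles, promoter-window
  (`[TSS−500, TSS)`) enrichment over a control IP, and Welch tests
  between gene classes;
* **expression** — luciferase protein-synthesis rates with cycloheximide
  background subtraction, translatability
  (`log2 protein_rel − log2 mRNA_rel`), ribosome occupancy (footprint
  RPM / mRNA RPM from AUG+120 to the ORF end), and granule-foci
  fraction comparisons;
* **cotrip** — the CoTrIP proteomics screen: per-protein spectral-count
  fold changes between promoter groups, Welch t-tests, volcano
  coordinates, and background filtering;
* **synthetic** — seeded generators for every input format above.

## Worked example

Does tethering a factor to a reporter mRNA raise its abundance by
boosting transcription or by slowing decay? Simulate a strongly induced
reporter (half-time 25 min, steady-state fold 300) with and without a
2-fold transcription-rate boost, at 5% multiplicative noise and 4
replicates, then classify:

```r
library(txcoupler)

a <- log(2) / 25                                   # 25 min half-time
ctrl_model <- induction_model(alpha = a, beta = a * 300,     x0 = 1)
teth_model <- induction_model(alpha = a, beta = a * 300 * 2, x0 = 1)

ctrl <- gen_timecourse(generator_config(seed = 101), ctrl_model,
                       "induction", "fold_over_t0", "no_tether")
teth <- gen_timecourse(generator_config(seed = 202), teth_model,
                       "induction", "fold_over_t0", "rvb2_tether")

classify_mechanism(ctrl, teth)
#> Mechanism call: transcription_shift (mean shift 0.989 log2, trend slope 0.000262, p = 0.85)

fit_induction(ctrl)
#> Induction fit: alpha = 0.02716 /min (T1/2 = 25.5 min), Fss = 307.2
#>   residual SSE (log2) = 0.118
```

The offset between the curves is flat in time (trend p = 0.85) and its
mean, 0.989 log2, recovers the simulated 2-fold (1 log2) transcription
boost — a transcription shift, not a decay shift. The fit recovers the
simulated rate constant (true α = 0.0277/min) and steady-state fold.

Decay fitting after transcription shut-off, and the translatability of a
reporter whose protein output drops 40% while its mRNA doubles:

```r
fit_decay(simulate_decay(induction_model(a, 0, 1), seq(0, 45, 5)))
#> Decay fit: slope = -0.04 log2/min, half-life = 25 min

translatability(protein_rel = 0.6, mrna_rel = 2.0)
#> Translatability: protein 0.6x, mRNA 2x -> log2 TE = -1.74 (0.3-fold)
```

A −1.74 log2 translatability is a greater-than-3-fold drop in
translational efficiency: the protein deficit is not explained by mRNA
supply.

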