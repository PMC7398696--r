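---
title: "Models and methods: how silest quantifies silencing establishment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: how silest quantifies silencing establishment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silest)
```

## The scientific question

The silent mating-type loci *HML* and *HMR* of budding yeast are kept
transcriptionally off by Sir-protein heterochromatin. When Sir function is
restored to a naive, expressed locus, repression is established over one to
several cell cycles, and S-phase passage is required. Two qualitatively
different single-cell routes are compatible with the same bulk (RT-qPCR)
time course:

* **gradual tune-down** — every cell moves through partially repressed
  intermediate states, so the mean transcript number per cell falls
  steadily while the whole count distribution slides toward zero;
* **discrete switching** — each cell is either fully ON or fully OFF; over
  time an increasing fraction of cells sits at zero transcripts, but the
  cells still expressing keep the *unchanged* ON distribution.

Single-molecule RNA FISH gives exactly the observable that separates these:
the per-cell transcript count distribution at each timepoint. `silest`
implements both generative models, the likelihood machinery to discriminate
them, the chromatin-level kinetics proposed to drive the transition
(replication dilution of H3K79 methylation), the MNase ChIP-seq
normalization used to examine Sir binding, and standard-curve RT-qPCR
quantification — together with a seeded synthetic-data generator so every
stage is testable without external data.

## The count model

Expressing cells carry an overdispersed transcript count distribution
modelled as a negative binomial with mean $\mu$ and dispersion $\alpha$:

$$\mathrm{Var}(X) = \mu + \alpha \mu^2, \qquad \alpha \ge 0,$$

with $\alpha = 0$ degenerating to Poisson. This is the standard
overdispersed model for transcript counts; nothing in the biology pins the
family down further, so the NB is a modelling choice and is documented as
such. The pre-induction ("ON") sample fixes $(\hat\mu_0, \hat\alpha)$ by
maximum likelihood (`fit_on_distribution()`; the mean is profiled out
analytically, leaving a one-dimensional search over $\alpha$).

Each post-induction timepoint then gets **one** free parameter:

* gradual: counts $\sim \mathrm{NB}(s\,\hat\mu_0, \hat\alpha)$ with
  transcription scale $s \in (0, 1]$; over $k$ cycles with per-cycle
  retention $r$ the generator uses $s = r^k$;
* switch: counts $\sim w\,\delta_0 + (1-w)\,\mathrm{NB}(\hat\mu_0,
  \hat\alpha)$ with OFF fraction $w \in [0,1]$; per-cycle OFF probability
  $p$ compounds memorylessly, $w_k = 1-(1-p)^k$. The OFF state defaults to
  exactly zero transcripts; a residual Poisson mean is exposed
  (`off_residual_mean`) for mRNA-decay realism but is 0 by default because
  the observable contrast is zero versus nonzero cells.

Holding $\hat\alpha$ shared across timepoints and models keeps the two
hypotheses at equal per-timepoint parameter count, so their log-likelihoods
(and AICs) are directly comparable and the comparison is not confounded by
flexibility differences.

```{r fit-example}
on <- on_distribution(6, 0.3)
tc <- rbind(
  simulate_counts_gradual(on, 1.0, 0, 300, seed = 1, timepoint = 0),
  simulate_counts_gradual(on, 0.4, 1, 300, seed = 2, timepoint = 2))
fit_g <- fit_establishment(count ~ timepoint_hr, tc, model = "gradual")
fit_s <- fit_establishment(count ~ timepoint_hr, tc, model = "switch")
compare_models(fit_g, fit_s)
```

## Model comparison and its bootstrap

`compare_models()` reports $\Delta = \log L_{\text{gradual}} -
\log L_{\text{switch}}$, the AICs, and the selected model; $|\Delta|$ below
a tolerance (default $10^{-6}$ per cell) is declared a tie, since at full
repression the two models coincide exactly. With `n_bootstrap > 0` it runs
a parametric bootstrap: whole time courses (baseline included, so the ON
fit is re-estimated each time) are simulated under each fitted model, both
models are refit, and the observed $\Delta$ is ranked within each null's
bootstrap distribution using the conservative Monte-Carlo convention
$(1 + \#\{\Delta^* \text{ at least as extreme}\})/(B+1)$.

**Known limitation — calibration of these p-values.** They are *plug-in*
p-values: the same data choose the simulation parameters and supply the
observed statistic, and $\Delta$ is strongly correlated with the fitted
$\hat s$ / $\hat w$ that drive the null simulation. As is well documented
for double-use p-values, their distribution under a true null concentrates
around 0.5 rather than being uniform: they are conservative in the tails
(they under-state evidence both for and against the simulated null). This
is a property of the procedure, not of its implementation: with the
simulation run at the true parameters the same ranking is exactly uniform.
A full double-bootstrap calibration would restore uniformity but multiplies
the cost by the inner bootstrap size. Use the p-values as conservative
plausibility measures; model *selection* rests on $\Delta$ itself, whose
accuracy under the study conditions is verified directly by simulation in
the test suite.

Summary statistics (`summary_stats()`) complete the argument: the zero
fraction, overall and nonzero-cell means, and a two-sample
Kolmogorov–Smirnov distance between the nonzero counts and a reference
sample. Under switching the nonzero cells keep the pre-induction shape;
under tune-down they do not. Counts are treated as continuous with pooled
ECDFs (tie-safe); a permutation p-value is available (`n_perm`) where the
asymptotic approximation is doubtful.

## H3K79 methylation kinetics

H3K79 methylation is deposited by Dot1 and has no demethylase, so a locus
can lose it only by acquiring unmethylated histones. The model
(`step_mark()`, `simulate_marks()`) tracks the methylated fraction $m \in
[0,1]$ of locus nucleosomal H3 through three event types:

* **replication**: replication-coupled incorporation of new histones
  halves the mark, $m' = m/2$ — so $k$ S phases alone give $m_0 2^{-k}$;
* **turnover**: replication-independent exchange over $dt$ relaxes $m$
  toward the free-pool methylated fraction,
  $m' = (1-\lambda dt)m + \lambda dt\, f_{\text{pool}}$. Outside S phase
  about 90% of nuclear H3 is K79-methylated, hence
  `f_pool = 0.9`; during S phase new synthesis roughly doubles the pool
  with unmethylated H3, hence the default `f_pool_s_phase = 0.45` (the
  halved value; any value below `f_pool` preserves the qualitative
  behaviour, and the parameter is exposed);
* **dot1**: re-methylation of resident histones,
  $m' = m + k_{\text{me}} dt (1-m)$, gated by a boolean Sir-protection
  flag — the evidence for protection is binary (mark unchanged in arrested
  cells despite Sir binding), so no Sir-occupancy continuum is modelled.

Cycles are discrete and phase-ordered (G1 turnover → S replication and
S-pool turnover → G2 turnover), not an ODE, because every statement the
model encodes is per-cell-cycle. A non-replicating locus (e.g. an excised
episome) can be simulated with `replicate_locus = FALSE`: it still loses
methylation in S phase through pool exchange, which is the model's
explanation for replication-independent, S-phase-dependent establishment.

The mark-to-transcription map (`repression_map()`,
`transcription_scale()`) is deliberately pluggable. The direction is
constrained — no repression without Sir binding regardless of $m$ (Sir
binding alone achieves none), and repression deepens as $m$ falls when Sir
is bound — but no functional form is identified by data, so the default is
the simplest monotone interpolation $s = s_{\min} + (1-s_{\min})m$, with a
logistic alternative. Only monotonicity and endpoints are ever asserted
about it. The per-cycle retention $r$ of the gradual count model and $m$
are kept as independent parameterizations: the quantitative link between
mark level and transcription rate is unknown, and conflating them would
fake precision.

## MNase ChIP-seq normalization

The ChIP stages mirror a mononucleosome ChIP-seq workflow on interval data
(fragments, not reads — alignment is out of scope):

1. **Size gate** (`filter_fragments()`): keep fragments with length in the
   closed interval [130, 180] bp, the MNase-protected mononucleosome
   window. Both bounds inclusive ("130–180" read as a closed range);
   configurable.
2. **Coverage** (`coverage_track()`): per-base overlap counts, 0-based
   half-open throughout (BED convention); strand is ignored.
3. **Median normalization** (`normalize_to_nonhet_median()`): every value
   is divided by the median per-base coverage over positions *outside* the
   exclusion set — rDNA, subtelomeres, and any fully heterochromatic
   chromosome — so heterochromatin itself cannot distort the scale on
   which its enrichment is read. The median is per-base (the simplest
   faithful definition; a windowed variant would be a different statistic
   and is not silently substituted), and even position counts use the mean
   of the two central values (the `stats::median()` convention). IP and
   input tracks are normalized independently, which is what puts them on
   one displayable scale.
4. **Per-gene densities** (`gene_normalized_coverage()`): summed coverage
   per gene, divided by gene length, then by the mean density over all
   genes — the normalized densities average exactly 1 by construction.

Subtelomere coordinates are not standardized, so
`subtelomere_exclusions()` defaults to the terminal 20 kb of each
chromosome end and is overridable by an explicit exclusion BED; the toy
workflows use 5 kb because their chromosomes are only tens of kb long.
rDNA coordinates are always supplied via the exclusion table, never
hard-coded: the package's toy genomes are not a real genome.

The generator (`toy_genome()`, `simulate_fragments()`) places regularly
spaced nucleosomes, samples dyads uniformly (input) or proportionally to a
per-nucleosome enrichment factor (IP), jitters fragment centres and lengths
normally (defaults 155 ± 10 bp, 10 bp dyad jitter), and mixes in a stated
fraction of sub-130 bp fragments so the size gate has work to do. A
programmed enrichment is therefore an exact ground truth: the test suite
verifies that a 10× locus is recovered within 10% from 50,000 fragments
after gating and normalization.

## RT-qPCR quantification

Quantification is by standard curve, never by the ΔΔCq shortcut:
$C_q = a \log_{10} Q + b$ is fit by least squares to a dilution series
(`fit_standard_curve()`; the simulator's default series is 5 points at
10-fold steps — a design assumption, as dilution designs vary), and
abundances are recovered as $Q = 10^{(C_q - b)/a}$ (`quantify()`). The
amplification efficiency $10^{-1/a} - 1$ equals 1 exactly at
$a = -\log_2 10 \approx -3.3219$; fits outside [0.8, 1.1] warn. Replicates
are aggregated as the mean of the triplicate $C_q$ (the $C_q$ scale is
where the noise is approximately Gaussian); replicate SD above 0.5 cycles
is flagged. Target abundances are normalized to a reference gene (*ALG9*
in the motivating experiments), matched no-RT wells are quantified the same
way and flagged above 1% of the RT signal (the threshold is a config
default, not a measured constant), and non-detects are missing values with
a QC flag — never imputed as zero. `fold_repression()` anchors a time
course to its own pre-induction sample: $\text{fold}_t =
\text{ratio}_{t_0} / \text{ratio}_t$, so the baseline is exactly 1 and
values above 1 mean repression.

```{r qpcr-example}
truth <- rbind(
  data.frame(sample = c("t0", "t2", "t4"), target = "HMRa1",
             quantity = c(0.8, 0.32, 0.128)),
  data.frame(sample = c("t0", "t2", "t4"), target = "ALG9", quantity = 1))
plate <- simulate_qpcr(truth, cq_noise_sd = 0, seed = 3)
ra <- relative_abundance(plate, target = "HMRa1", reference = "ALG9")
fold_repression(ra, "t0")[, c("sample", "ratio", "fold_repression")]
```

## What the generator emulates — and what it does not

The synthetic module reproduces the *statistical* structure of the three
assays: overdispersed per-cell counts evolving under either establishment
model, nucleosome-centred fragment libraries with programmable IP
enrichment and size mixture, and standard-curve Cq tables with triplicates,
dilution standards, and leaky no-RT wells. It deliberately omits: cell
size, cell-cycle position and segmentation errors of real FISH images;
detection efficiency below 1 (available as binomial thinning, default off,
since no efficiency estimate exists to anchor it); sequencing reads,
mappability, duplicates and GC bias; and inter-run qPCR block effects.
Passing tests therefore demonstrate that the *inference machinery* is
correct and well calibrated under its own assumptions — not that those
assumptions exhaust real data.

## Numerical choices and default problem sizes

* One-dimensional likelihood maximization uses `stats::optimize()`
  (tolerance $10^{-9}$), with an explicit boundary check so that boundary
  data yield exact boundary estimates ($\hat s = 1$, $\hat w = 0$) rather
  than near-boundary interior points.
* Confidence intervals invert the likelihood-ratio test by profile
  likelihood (`uniroot`, tolerance $10^{-8}$), truncated at the parameter
  domain.
* Degenerate inputs fail loudly: an all-zero pre-induction sample (ON
  state undefined), a zero non-excluded median (nothing to normalize
  against), all-excluded genomes, zero-length genes, non-positive
  quantities, and sub-three-point dilution series are all errors with
  directed messages, never silent NaNs.
* Generators restore the caller's RNG state; identical arguments and seed
  give byte-identical output. Workflow stages derive child seeds from the
  run seed by a fixed documented map (`child_seed()`), so any stage can be
  re-run in isolation from its manifest.
* The simulation sizes exercised by the test suite — 300 cells per
  timepoint for model selection, 1000 for parameter recovery, 100
  replicate datasets per truth, 50,000 ChIP fragments, 200 calibration
  replicates with 99 bootstrap draws — were chosen as realistic
  desk-scale analogues of the motivating experiments (a few hundred cells
  per FISH condition; tens of thousands of informative fragments per
  library).

## Known limitations

* The bootstrap p-values of `compare_models()` are conservative plug-in
  p-values (see above); the selection decision and its simulated accuracy
  are the load-bearing outputs.
* The NB family and the shared-dispersion assumption are conventions;
  strongly non-NB ON distributions (e.g. bursty bimodality) would require
  a different anchor.
* The mark model has no positional memory: replication dilutes uniformly,
  with no local re-deposition of parental histones, because nothing finer
  than "half" is identified.
* Fragments are intervals, not reads; nothing here touches alignment,
  duplicates, or peak calling.
* H4K16ac / H3K56ac dynamics, Sir spreading, and nucleosome-array
  geometry are out of scope.
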