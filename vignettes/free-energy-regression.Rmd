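---
title: "Free-energy regression for peptide display selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy regression for peptide display selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimfit)
```

## The model

Affinity selection of a displayed random peptide library enriches, round by
round, the sequences that bind a bait domain (for example an SH2 domain
binding phosphotyrosine peptides). `slimfit` models the observed
input/bound sequencing counts with an additive binding free-energy model.
For a peptide $s$ scored in selection round $c$, the predicted enrichment is

$$
\kappa_c(s) \;=\;
\alpha_{c,\mathrm{NS}} \sum_{x=1}^{L-w_\mathrm{NS}+1}
  e^{\vec X_{s,x:x+w_\mathrm{NS}} \cdot \vec\beta_\mathrm{NS} + \gamma_x}
\;+\;
\alpha_{c,\mathrm{S}} \sum_{x=1-f_\mathrm{S}}^{L+f_\mathrm{S}-w_\mathrm{S}+1}
  e^{\vec X_{s,x:x+w_\mathrm{S}} \cdot \vec\beta_\mathrm{S}},
$$

a sum over *all* binding offsets of two log-linear "binding modes": a
non-specific mode (width $w_\mathrm{NS}=3$ by default, with a per-offset
bias $\gamma_x$) that absorbs background capture and sequence biases, and a
specific mode whose coefficient table $\vec\beta_\mathrm{S}$ is the
free-energy matrix $-\Delta\Delta G/RT$ we want to learn. The specific mode
extends its windows up to $f_\mathrm{S}=5$ residues into the constant
displayed flanks (`GQSGQ`/`GGQSG`), because a binding site may straddle the
variable region. Activities $\alpha$ are free per count table, so rounds
with different capture efficiency need no calibration.

Counts are scored with the scaled binomial likelihood

$$
\ell_\mathrm{data} = \sum_{c=1}^{N_C} \frac{1}{k_c} \sum_{i \in S_c}
\left[ k_{c,i,I}\,\ln\frac{1}{1+\rho_c \kappa_c(s_i)}
     + k_{c,i,B}\,\ln\frac{\rho_c \kappa_c(s_i)}{1+\rho_c \kappa_c(s_i)}
\right],
$$

where $k_c$ is the table's total read count and $\rho_c$ a per-table depth
ratio. The sequencing-depth parameters of the input and bound columns enter
only through their ratio, so a single free $\log\rho_c$ per table is fitted
(the separate depths are not identifiable from a count table).

Fitting minimizes $\ell_\mathrm{total} = -\ell_\mathrm{data} +
\ell_\mathrm{reg}$ with L-BFGS-B over all free parameters jointly, using the
analytic gradient (implemented in C++ for speed). $\ell_\mathrm{reg}$
contains an L2 term ($\lambda = 10^{-6}$ per coefficient), a symmetric
exponential barrier $e^{\beta-B}+e^{-\beta-B}$ with cap $B = 8$ that keeps
coefficients in a numerically safe range, and a Dirichlet pseudo-count term
(count 5) on the predicted column probabilities. The barrier and Dirichlet
forms are design choices of this package (the exact forms used elsewhere are
not printed in our sources); both are exposed in
`regularization_config()` and default to weights small enough that they act
only as stabilizers. Because the Dirichlet term depends on the predicted
column probabilities, `penalty()` takes the count tables as an optional
third argument; without tables only the L2 and barrier terms are returned.

For phosphotyrosine-directed domains the central column of the specific mode
is frozen to recognise tyrosine: weight 0 for Y, $-10$ for everything else.
Frozen cells are excluded from the gradient and the regularizer and are
returned bit-exactly. Unconstrained fitting (for target-agnostic libraries)
simply omits the frozen cells; nothing else changes.

## Gauge, energies, and scores

Adding a constant to one column of $\vec\beta_\mathrm{S}$ and rescaling
$\alpha_{c,\mathrm{S}}$ leaves every $\kappa$ unchanged, so the matrix is
only defined up to per-column shifts. `normalize_model()` fixes the gauge by
shifting every column to maximum zero and absorbing the compensating factor
into the activities. After normalization,

* `ddg(peptide, model)` is $\Delta\Delta G/RT \ge 0$ of the single central
  (phosphosite-aligned) register, zero exactly for the per-position-argmax
  peptide;
* `relative_affinity()` is $e^{-\Delta\Delta G/RT} \in (0, 1]$, inversely
  proportional to $K_D$.

The offset *sum* is used only inside $\kappa$ during fitting; downstream
scoring (phosphosite scans, variant ratios) uses the central register, which
is how validation peptides are synthesized and measured. Windows that run
past a protein terminus are padded with `-` and scored at the column mean
over unfrozen cells — a neutral choice; `skip_truncated = TRUE` drops such
sites instead.

## Read processing

`build_count_table()` applies a fixed pipeline per read: locate the 3L-nt
variable region between the two constant DNA anchors (ungapped, at most 5
mismatches per anchor; best placement by fewest total mismatches, ties
leftmost), then require PHRED $\ge 20$ at every position *of the cropped
region* (the stage order follows the processing description the package
implements: crop first, then filter), then require every codon to be NNS
(third base G/C), non-stop, and consistent with the design's fixed residues
before translating. Stop-codon regions are rejected even though NNS admits
the amber codon, because such a sequence cannot be displayed as a peptide;
fixed residues are accepted under any codon that encodes them. Anchor
matching is Hamming-only (no indels): the fixed-length region implies fixed
geometry. Per-stage discard counts are reported and conserve the total.
`merge_pairs()` is a convenience ungapped overlap merger for pre-joined
pipelines, not a re-implementation of a dedicated read-joining tool.

## The synthetic world

`simulate_experiment()` generates the world the inference tests assume:

* `gen_library()` samples peptides residue-wise from the NNS codon
  distribution (31 coding codons; leucine/arginine/serine have 3, tryptophan
  1) and draws log-normal abundances. The default skew
  `abundance_lognormal_sigma = 1.5` produces the heavily right-skewed
  count distributions typical of display libraries; 0 gives a uniform
  library.
* Selection is strictly enrichment-proportional: the bound column is a
  multinomial draw from the law $\propto$ composition $\times \kappa$, with
  the non-specific mode of the ground truth acting as carry-over.
  Bead-capture saturation and kinetics are deliberately not modeled.
* The next round's composition is the expected bound law (re-amplification
  of the bound fraction), which separates selection noise from sequencing
  noise; `resample = TRUE` switches to the harsher finite-read regime.
* The default ground truth (`random_truth_model()`) draws specific
  coefficients from N(0, 1), freezes the central tyrosine column, and sets
  the non-specific activity so that the carry-over floor is comparable to
  the median specific signal — both modes visibly shape the bound column,
  as they do in real selections. Note that at the default library size and
  sequencing depth (1e5 unique peptides, 5e5 reads per column) a single
  round already averages five input reads per clone, which is far more
  informative per clone than a real fully random library; the
  multi-round-versus-single-round contrast that motivates repeated
  selection only emerges when diversity greatly exceeds read depth.
* `phospho_efficiency < 1` downweights tyrosine-containing windows in the
  truth enrichment, emulating incomplete enzymatic phosphorylation; the
  default 1 keeps the core tests simple.

What a green recovery test establishes: that the estimator inverts the
generative model it assumes, at realistic scale, under multinomial
sequencing noise and skewed abundances. What it does not establish: bead
kinetics, PCR jackpotting, codon-usage bias of the host, or any
model-misspecification robustness — real libraries violate additivity in
ways the simulator does not emulate.

## Numerical choices

* Coefficients are initialized N(0, 0.01^2) from the recorded seed; log
  activities start at 0 and each table's depth log-ratio at
  `log(bound reads / input reads)`. Fits with the same seed and inputs are
  bit-identical.
* Convergence is declared at relative loss change `1e-9` (L-BFGS-B
  `factr`); the loss trajectory reported is the running best, hence
  non-increasing.
* `fit_multistart()` reruns from seeds derived from the base seed and keeps
  the best final loss; the default 3 starts guard against the (rare, in
  practice) local optima of the non-convex offset-sum likelihood.
* Enrichment $\kappa$ is clamped below at `1e-300` inside the likelihood
  kernel so that pathological parameter proposals during line search cannot
  produce `-Inf`/`NaN`.
* `aa_log_enrichment()` uses a pseudo-count of 0.5 as a frequency floor
  (`0.5 / column total`), because zero bound counts are common; fixed design
  positions are masked, not dropped, so matrices from different designs stay
  comparable cell-wise.
* Ties in `score_sites()` keep input order (stable sort); model clustering
  uses distance $1-r$ with average linkage, a plain choice for comparing
  coefficient tables.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(design_x5yx5(), n_unique = 2000, rounds = 2,
                  reads_per_round_input = 2e4, reads_per_round_bound = 2e4,
                  truth_sigma = 1, seed = 7)
sim <- simulate_experiment(cfg)
res <- fit(sim$tables, fit_config(seed = 1))
model <- normalize_model(res$model)
recovery_r2(model, sim$truth)
head(score_sites(data.frame(protein_id = "P1", site_position = 6,
                            window = "AAAAAYAAAAA"), model))
```

## Known limitations

* One specific binding mode per model: cooperative, dimeric, or
  multi-motif recognition is out of scope.
* Energies are dimensionless $\Delta\Delta G/RT$; no absolute kcal/mol or
  absolute $K_D$ calibration is attempted.
* The likelihood treats every table as an independent single-round
  experiment; carry-over between rounds is captured only through the shared
  coefficients and per-round activities, not an explicit transfer model.
* The additive model cannot represent epistasis between peptide positions;
  position-pair terms are deliberately not implemented.
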