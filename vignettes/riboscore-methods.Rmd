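---
title: "Scoring rRNA modification stoichiometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring rRNA modification stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscore)
```

## The measurement problem

Ribosomes are not uniformly modified: at many 2′-O-methylation (Nm) and
pseudouridine (Ψ) positions only a fraction of the rRNA molecule population
carries the mark, and that fraction can move with cell state or with the
expression of the guide snoRNA that directs the modification. Both read-outs
used here convert a *chemical protection* into a *local count anomaly* in
sequencing read ends:

* alkaline hydrolysis cleaves every phosphodiester bond at a roughly uniform
  rate, **except** the bond 3′ of a 2′-O-methylated ribose;
* hydrazine/aniline cleaves uridines, **except** pseudouridines.

A modified fraction *f* at a site therefore attenuates the local cleavage
rate to `(1 − f)` of its background, and an estimator of *f* can be built
from the relative depletion of read ends at that one coordinate.

## The estimators

**MethScore.** Cleavage evidence per bond is
`c[j] = counts3[j] + counts5[j+1]` (both ends of a cut contribute, so the
measure tolerates one-sided end losses). For a site on nucleotide *i* the
package uses the symmetric flanking-mean form over `flank = 6` bonds per
side,

`score = clip(1 − 2·c[i] / (L̄ + R̄), 0, 1)`,

which equals `1 − c[i] / mean(12 neighbours)` when both windows are full.
The historical weighted variant of this score exists in the literature but
its weights are not restated here; output metadata labels the form used
(`methscore_form: symmetric-flank-mean`) so runs are comparable.
Three rules matter in practice:

* *Undefined, never zero.* Fewer than 3 usable bonds on either side, or a
  zero flanking background, yields `NA`. Silently reporting 0 would fake an
  "unmethylated" call at molecule ends.
* *Clipping.* Raw values below 0 (hyper-cleavage) are floored at 0, because
  the score is interpreted as a molecule fraction.
* *No masking of neighbouring annotated sites inside the window.* No
  published masking rule exists for this protocol family; for clustered
  sites this is a known bias source (a protected neighbour deflates the
  local background and hence the score).

**NormUcount / PsiScore.** 5′-end counts are normalised to a rolling local
background (`window = 10` nt, plain mean; even windows are centred
center-right, which is provably irrelevant on constant backgrounds and
tested as such). `NormUcount = count / background` is the protection value;
restricting to U residues gives the U profile, and `PsiScore = 1 −
NormUcount`, **unclipped below**. The negative branch is informative:
a strongly negative score marks a residue cleaved well above its local
background — not protected, hence not pseudouridylated. An auxiliary
`scoremean` (the RMS-style local score computed on the U profile over the
nearest 6 U-neighbours per side) is provided as a diagnostic; further
auxiliary scores of the original protocol (its "A" and "B") are not
reproduced because their exact definitions are not restated in the sources
this package follows.

Two switches are shared between scorer and simulator so the pair stays
self-consistent: `end_offset` (integer offset between the cleaved U and the
reported read start; default 0, real-data users may need +1) and
`exclude_self` (leave-one-out background; the default plain mean includes
the queried position, which biases scores at strongly protected sites by at
most `f/window` — the leave-one-out mean is what the calibration tests use).

## The simulator: what it emulates, and what it does not

`simulate_rms()` and `simulate_hydrapsi()` draw independent Poisson cleavage
events per bond/residue with intensity
`depth · base_rate · (1 − f·(1 − residual))` at modifiable coordinates
(`residual` is the cleavage propensity retained at a fully modified site,
default 0 = full protection; non-U residues under HydraPsi cleave at
`bg_rate = 0.01` of the U rate). Replicates differ only by RNG stream;
replicate *r*'s stream is derived arithmetically from the master seed so
adding replicates never perturbs earlier ones, and everything is
bit-reproducible given `(seed, r)`.

Deliberate simplifications, documented rather than hidden:

* **Poisson events, not molecules.** Cleavage events at distinct bonds are
  treated as independent — this matches the scorers' local-ratio assumptions
  and keeps simulations fast. The optional fragment mode (pairs of cuts
  20–40 nt apart, uniform acceptance in the size window) exists only to
  exercise 5′/3′ end-count conservation; its effect on local ratios is
  assumed negligible.
* **Pure Poisson replicate noise.** No overdispersion between biological
  replicates is modelled; real replicate variance is typically larger, so
  power estimates from simulations are optimistic.
* **No end bias, ligation bias or sequencing error model.**
* **U-specific chemistry and the rolling background.** With `bg_rate =
  0.01`, non-U positions carry almost no counts, so on a mixed-composition
  molecule the all-position rolling background is deflated by roughly the
  local U density and NormUcount at an unmodified U lands near
  1 / (U density) rather than 1 — which is exactly how strongly negative
  PsiScores arise on real hyper-reactive or composition-skewed stretches.
  Calibration, recovery and null tests therefore run on
  uridine-homogeneous substrates, where the background is well defined
  under U-specific cleavage; recovered stoichiometries on such substrates
  are accurate to < 0.04 at `depth ≥ 2000`. What passing tests show is that
  the estimator is calibrated *given a representative background*; they do
  not certify absolute PsiScores on sequences whose windows are dominated
  by non-cleavable residues.

Problem sizes used by the test suite were chosen to make Monte-Carlo error
comfortably smaller than the asserted tolerances: recovery grids use 50
simulations per stoichiometry at `depth·base_rate = 2000` (SE of the mean
≈ 0.003), null calibrations 200 simulations, type-I control 1000 site
simulations at n = 3 replicates against a 99% binomial interval, and the
stoichiometry-recovery checks 3 replicates at 5000 events/bond (SE of the
replicate mean ≈ 0.01, against ±0.03/±0.04 bands).

## Differential calling

Per site, replicate-level scores are contrasted between two conditions with
a paired Student's *t*-test implemented from its closed form (pairing is by
replicate/batch label — the only pairing key available; an unpaired Welch
fallback is deliberately not the default). Conventions:

* all within-pair differences exactly zero → p = 1;
* zero variance with nonzero mean difference → p reported as the 0-limit
  with a `degenerate` flag (3 replicates cannot distinguish an exact
  constant shift from noise-free measurement);
* sites need ≥ 2 complete pairs; exactly 2 runs at df = 1 and is flagged
  `low_power`;
* `affected` uses strictly `|Δ| > 0.05` while heatmap eligibility uses
  `|Δ| ≥ 0.1` — two thresholds with two distinct comparison semantics, kept
  as such;
* stars (`*` ≤ 0.05, `**` ≤ 0.01, `***` ≤ 0.001) are computed on **raw**
  p-values, matching the convention of the score tables this mirrors; a
  Benjamini–Hochberg column is emitted for the reader but never drives any
  call.

## Guide concordance

A site's modification change is compared with the expression change of its
annotated guide snoRNA(s), consumed from an external DE export (`snorna`,
`log2fc`, `padj`, `source`). A guide counts as changed when significant
(`padj ≤ 0.05`) with `|log2fc|` above a threshold that defaults to 0 —
direction, not magnitude, is read, since no magnitude cutoff is published
for this call; the threshold is configurable. Verdicts partition sites into
`concordant` (≥ 1 significant co-directional guide, none significantly
opposed — so a two-guide site where only one guide responds is concordant),
`partial` (significant guides disagree), `discordant` (no significant guide
support, including the all-non-significant case), `no_guide` (orphan) and
`site_unchanged`. With both small-RNA-seq and qPCR evidence, any concordant
source suffices by default; `strict = TRUE` requires sign agreement across
sources.

## Degenerate inputs and numerical choices

* Catalog validation is hard: residue mismatches, Ψ on non-U, out-of-range
  positions and duplicate (molecule, position, modality) keys abort with
  the offending site named. Legacy (old-nomenclature) numbers are stored
  data — the old/new offset varies along 28S, so it is never computed.
* Scores are exactly invariant under uniform scaling of counts (pure
  ratios), and local: counts outside the scoring window cannot move a
  score.
* Zero-coverage windows give `NA` backgrounds, which propagate to `NA`
  scores and are excluded from condition means with a warning.
* Exactly-constant difference vectors are detected with an absolute 1e-10
  guard; scores are O(1) quantities, so floating-point dust below that is
  not a real variance.

## Known limitations

* Catalog-driven scoring only; no de-novo site discovery scan (the API
  accepts any position list, so a whole-molecule scan is possible, but no
  discovery statistics are provided).
* MethScore windows do not mask neighbouring annotated sites (see above).
* The Ψ background model is honest only where windows contain cleavable
  positions; terminal ~window/2 positions and non-U-dense contexts yield
  `NA` or composition-biased scores by design.
* No multiple-testing control drives calls; users screening hundreds of
  sites should read the `p_bh` column.
* The simulator's replicate noise floor (pure Poisson) understates
  biological variance; treat simulated power as an upper bound.
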