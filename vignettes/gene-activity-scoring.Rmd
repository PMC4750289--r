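---
title: "Fuzzy-logic gene activity scoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-logic gene activity scoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncofuzz)
```

## The model

`oncofuzz` scores the activity state of a gene in a sample by combining three
molecular measurements — somatic mutation calls, expression level and log2
copy ratio — through Mamdani fuzzy inference. The premise is biological:
oncogenes are activated by recurrent missense or in-frame mutations, usually
reinforced by amplification and over-expression, while tumor suppressors are
inactivated by truncating mutations, deletions and loss of expression. These
statements are qualitative, so they are encoded as IF/THEN rules over *fuzzy
categories* rather than as hard thresholds, and the measurements enter
through membership functions that map each crisp value to degrees of belief
in the categories.

Inference proceeds in four steps for every variant (and for every unmutated
gene/sample pair, via the wild-type rules):

1. **Fuzzification.** Each input is converted to category degrees in [0, 1].
2. **Rule firing.** Antecedents combine leaf degrees with AND = minimum and
   OR = maximum; the antecedent degree is the rule's activation. These are
   the standard IEC 61131-7 FCL operator defaults, and the operator
   declarations in the rule file are validated against them.
3. **Implication and accumulation.** Each rule's output category (one of
   seven spanning the activity axis [-1, 1]) is clipped at the activation;
   clipped curves accumulate by union (pointwise maximum), which also makes
   duplicated rules harmless.
4. **Defuzzification.** The accumulated curve is reduced to its centroid.
   Positive scores read as gain of function (GoF), negative as loss of
   function (LoF).

Per gene and sample, the GoF score is the maximum over the sample's
positively scoring variants (0 if none) and the LoF score the minimum over
negatively scoring ones; sign identifies which variants count for which side.
An unmutated pair has a single wild-type score that is sign-split the same
way. A gene mutated in strictly more than 1% of samples is labeled `GoF`
(`LoF`) when strictly more than 50% of its mutated samples have
`gof > |lof|` (`|lof| > gof`); exact ties count toward neither side, and a
gene where neither fraction clears 50% stays `unclassified` — the two
majority conditions are not exhaustive, and forcing a label would overstate
the evidence.

### Mutation semantics

Eight variant classes are modeled (missense, in-frame insertion/deletion,
nonsense, nonstop, frame-shift insertion/deletion, splice site); they are
integer-coded and matched by singleton membership functions with a +/-0.5
window, so each code matches exactly its own category. Silent and any
unrecognized classifications carry no interpretable signal for the rules and
are mapped to `No_Mutation`, which routes those samples through the
wild-type rules. A variant position is *recurrent* when strictly more than
1% of all cohort samples (not just mutated ones) carry a variant at the same
position; position preferentially means the amino-acid position parsed from
the protein-change string, falling back to genomic coordinates. Duplicate
records of the same (sample, gene, class, position) are collapsed on input —
they would receive identical scores and only inflate logs.

### TP53-style exceptions

For genes such as TP53, recurrent missense mutations inactivate rather than
activate the protein. `apply_special_rules()` handles this by *mirroring the
consequent* of every rule conditioned on an activating mutation class
(`high_GoF <-> high_LoF`, `GoF <-> LoF`, `low_GoF <-> low_LoF`); truncating
and wild-type rules are untouched. Mirroring the consequents rather than
hand-writing extra rules keeps the special-gene base structurally identical
to the default one and, because the default output categories are symmetric
about zero, makes the special-gene score in an activating context exactly
the negative of the default score — a property the test suite checks to
machine precision.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| recurrence threshold | 0.01 (strict) | fraction of cohort | hotspots must stand out above passenger noise; strict “more than” makes exactly-1% non-recurrent |
| classification frequency filter | 0.01 (strict) | fraction of cohort | genes mutated in fewer samples give unstable majority fractions |
| majority threshold | 0.5 (strict) | fraction of mutated samples | a label requires an actual majority |
| CN breakpoints | ±0.2 (inner), ±0.6 (outer) | log2 copy ratio | conventional SNP-array gain/loss cutoffs; configurable in `default_cn_variable()` |
| expression sigmoid slope | `sqrt(8·ln 2)/sd` of each tertile | 1/expression units | matches the sigmoid's transition width to the full width at half maximum of a Gaussian with that tertile's spread |
| output categories | Gaussians (sd 0.15) at 0, ±1/3, ±2/3; sigmoids at ±0.85 | activity score | evenly spaced with near-half-maximum neighbor overlap; see "declared defaults" below |
| centroid resolution | 2001 grid points | — | doubling to 20001 moves scores by < 1e-3 (tested); cost is linear |

The tertile fit splits a gene's samples into three rank groups of nearly
equal size (extras go to the lower groups first; ties keep input order), and
summarizes each group by its own mean and standard deviation: the outer
groups set the sigmoid inflections and slopes, the middle group the medium
Gaussian. Group standard deviations are floored at 1e-3 of the observed
range so a degenerate group yields a steep but valid shape; a fully constant
gene cannot be fitted and is skipped with all-NA scores rather than guessed.

**Declared defaults, not a reconstruction.** The seven output membership
functions and the recurrence category encoding are original to this package:
spacing Gaussians of sd 0.15 at 0, ±1/3 and ±2/3 with boundary sigmoids at
±0.85 gives evenly spaced, symmetric categories whose neighbors overlap near
half maximum. Symmetry is what the mirroring of special genes relies on; all
of it can be overridden by editing the shipped FCL file.

## Numerical choices

- **Grid.** The output domain is sampled uniformly; for symmetric domains
  the grid is built as a mirrored half-grid (and even resolutions bumped to
  the next odd), so it contains 0 and is exactly sign-symmetric. Mirrored
  rule bases therefore produce exactly negated scores instead of
  almost-negated ones.
- **Centroid.** Computed with trapezoidal quadrature weights (endpoints at
  half weight). On this grid that differs from a plain sum only at the two
  domain endpoints, but it matters: the boundary sigmoid categories are
  non-zero at ±1, and plain summation would bias scores there by ~2e-4
  relative to the exact integral.
- **Empty curve.** If no rule fires at all, the score is defined as 0 — the
  neutral no-effect value — avoiding 0/0.
- **Monotonicity is approximate.** Holding the mutation context fixed,
  scores track expression according to the rules' consequent ordering, but
  max-union centroid defuzzification is not exactly monotone: in tertile
  transition zones, where one category's activation falls while the next
  rises, the centroid can dip by about 0.01 before recovering. The property
  tests therefore assert monotonicity up to a 0.02 tolerance on dense grids
  and cleanly (1e-9) deep inside the tertiles where a single rule dominates.
- **Recurrent dominance is exact.** At identical expression and copy number,
  a recurrent activating variant never scores below its non-recurrent
  counterpart, because each recurrent rule's consequent weakly dominates the
  matching non-recurrent rule's.
- **Gaussian-mixture thresholds.** The two-component EM is initialized by a
  median split and iterated to 1e-8 log-likelihood tolerance (max 200
  iterations), making it deterministic without random restarts. The
  intersection point X solves the equality of the two *weighted* component
  densities — the fitted model's decision boundary — via the closed-form
  quadratic, taking the root inside (mu1, mu2); with equal variances this
  degenerates to the single linear solution. Unweighted intersection was
  the plausible alternative; the weighted form was chosen because it is the
  point where posterior class probability actually flips.

## What the synthetic cohorts do and do not show

`generate_cohort()` emulates the structure of a cancer cell-line panel:
log2-microarray-like background expression (per-gene Gaussian means drawn
from 5–11, sds 0.6–1.4), log2 copy-ratio noise (sd 0.15), and planted driver
genes. Oncogenes get a shared missense hotspot in 20% of samples with
expression raised by 1.5 within-gene sds and copy number by 0.8; tumor
suppressors get scattered truncating variants with the mirror-image shifts;
a TP53-like gene gets a recurrent missense hotspot with raised expression
(mutant protein accumulates) but inactivating intent; neutral genes carry
sparse passengers (1% per sample). The simulated drug response couples the
first oncogene's *graded* activity — mutants respond in proportion to how
far their expression sits above background — to an activity-area metric with
Gaussian noise, so a continuous activity score can out-predict the binary
mutation flag, which is the comparison of interest.

Passing tests on these cohorts shows the pipeline recovers planted signal
under its own modeling assumptions with realistic effect sizes and cohort
sizes (the recovery suite uses 20 cohorts of 300 samples by 50 genes). It
does not show performance on real tumors: the generator has no lineage
structure, no correlated copy-number segments, no mutational signatures, no
subclonality, no zygosity, and expression shifts are Gaussian by
construction. Those are exactly the regimes where per-gene tertiles and
fixed CN breakpoints can misfire and should be tuned.

## Open design decisions taken

- *Tertile scope.* Expression tertiles are fitted per gene across **all**
  samples, not per lineage; the fit is a property of the gene's marginal
  distribution.
- *Unmutated pairs are scored*, via the wild-type rules, rather than left at
  0: per-sample activity of an unmutated gene (e.g. an amplified,
  over-expressed oncogene) is exactly what downstream sensitivity analyses
  need. Both the GoF and LoF matrices are returned; their sum is a usable
  net score when one number is wanted.
- *"GoF variants" / "LoF variants"* are identified by score sign when
  aggregating to the gene/sample level — the only reading under which the
  max/min aggregation is well defined.
- *Fixed-threshold compounds.* Sensitivity calls validated by prior studies
  (e.g. the EC50/Amax combination) are applied directly from the shipped
  compound table rather than re-derived via the mixture model.

## Known limitations

- The rule base treats copy number and expression as corroborating evidence;
  it cannot express dosage-specific mechanisms (e.g. one-copy loss with
  retained expression).
- Tertile fitting assumes the cohort mixes low/medium/high states for every
  gene; genes uniformly high (or low) across the cohort get categories that
  describe relative, not absolute, expression.
- The recurrence caller counts shared positions, not functional equivalence;
  adjacent-codon hotspots are separate positions.
- Classification fractions are unweighted sample counts; a gene mutated in
  few samples clears the frequency filter with small denominators, so the
  reported fractions should be read together with `n_mutated_samples`.
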