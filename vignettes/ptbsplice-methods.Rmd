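---
title: "Models and methods in ptbsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ptbsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptbsplice)
```

# The problem

PTBP1 (polypyrimidine tract binding protein) recognizes pyrimidine-rich RNA
through four RRM domains, each contacting roughly a nucleotide triplet. Its
binding sites are degenerate — many different CU-rich sequences, with
guanosines tolerated inside them — so neither a consensus motif nor simple
motif counting predicts binding well. `ptbsplice` implements two linked
models: a **binding model** that scores any RNA sequence for PTBP1 binding
affinity, and a **regulation model** that converts regional binding scores
plus 3' splice-site strength into the probability that a cassette exon is
repressed (or enhanced) by PTBP1.

# The binding model

## Structure

The binding model is a two-hidden-state HMM whose observations are the
**overlapping** nucleotide triplets of a sequence: a sequence of length $L$
yields $L-2$ tokens, token $i$ covering residues $i..i+2$, drawn from the 64
triplets ordered lexicographically over $A<C<G<U$. One hidden state (the
*binding state*, identified after training as the state with the larger
summed emission mass over the eight pyrimidine-only triplets $\{C,U\}^3$)
captures protein-contacted sequence; the other captures background.

The overlap convention is the package's central modelling choice. Disjoint
triplets would give a 3-fold coarser state path; overlapping tokens give a
per-nucleotide Viterbi path, which is what the sliding-window binding-density
maps and crosslink-anchored profiles consume. A consequence worth stating
plainly: overlapping triplets from a real sequence are *not* conditionally
independent given the state path (adjacent tokens share two bases), so the
HMM is a scoring model, not a faithful generative law in nucleotide space.
The synthetic-data module therefore has two cluster generators — a
token-space generator that follows the HMM's law exactly (the estimand of
the Baum–Welch recovery tests) and a nucleotide-space generator that plants
pyrimidine tracts for end-to-end tests.

## Training

Parameters (initial distribution, $2\times2$ transitions, $2\times64$
emissions) are fit by Baum–Welch EM over a set of cluster sequences, with:

* log-space recursions (log-sum-exp) so ten-thousand-token inputs do not
  underflow;
* a pseudocount of $10^{-6}$ on emission counts so no state freezes on an
  exact zero;
* multiple random restarts (default `n_restarts = 10`; initial/transition
  rows uniform on the simplex, emissions Dirichlet(1)), keeping the restart
  with the best total log-likelihood — the standard guard against local
  maxima;
* convergence on relative log-likelihood change (`tol = 1e-6`, `max_iter =
  500`).

The per-iteration total log-likelihood trace is returned and is asserted
non-decreasing (slack $10^{-8}$) in every training run of the test suite.

## Scoring and normalization

The raw binding score of a sequence is the log-odds
$\log_2 P(\text{seq}\mid\text{HMM}) - \log_2 P(\text{seq}\mid\text{background})$,
with a uniform background (every triplet $1/64$) by default — the most
accurate choice among the alternatives (mononucleotide shuffle, dinucleotide
shuffle via an Altschul–Erickson Euler-path shuffle, and a gene-matched
sequence pool), all of which remain available. The log base is configurable;
z-scores are base-invariant.

Raw log-odds grow with sequence length, so two normalizations are provided:

* **Random-sequence nulls** for fixed-length probes: the model scores
  `n = 100000` i.i.d. random sequences of the query's length (default 69 nt —
  four 6-nt RRM elements separated by three 15-nt gaps), and the query is
  expressed as a z-score against that null. Empirical p-values use the
  "equal or greater" counting rule with no pseudocount, so 500 of 100,000
  at-or-above gives exactly $p = 0.005$; a $(k+1)/(n+1)$ mode exists for
  multiple-testing pipelines.
* **Length bins** for genome-scale sets: within each region class (upstream
  intron / exon / downstream intron), sequences are sorted by length and cut
  into bins of 1,000; each sequence is z-scored against its own bin. The
  final partial bin is merged into its predecessor when smaller than 500
  (the bin size is fixed by the protocol; the partial-bin rule is this
  package's choice).

# Binding maps

Viterbi state paths are spread onto per-base tracks (base $i$ takes the
state of the triplet starting at $i$; the last two bases inherit the final
token's state) and summarized as:

* sliding-window densities (24-nt windows, 8-nt overlap, i.e. 16-nt step;
  only full windows are emitted);
* group-averaged RNA maps anchored at the splice sites — intron positions
  are counted from the junctions and exons contribute a fixed number of
  windows from each end rather than being length-scaled, so no
  interpolation is involved; windows absent from shorter sequences are
  dropped from that window's denominator, and denominators are always
  reported;
* per-exon heatmap matrices ordered by hierarchical clustering (Euclidean
  distance, average linkage — a conventional default, chosen here, not
  dictated by the protocol);
* crosslink-anchored state-frequency profiles with per-offset denominators.

# Splice-site strength and the feature vector

Splice-site strength is the min–max-scaled position-weight-matrix score
$100\,(S - S_{\min})/(S_{\max} - S_{\min})$ with $S$ the sum of per-position
frequencies of the observed bases — the per-position consensus scores 100,
the worst sequence 0. Matrices are built from user-supplied junction sets
with a pseudocount (all frequencies positive) and serialized as TSV next to
results. Default windows: 3'ss = last 14 intronic + first exonic base;
5'ss = last 3 exonic + first 6 intronic. These windows are conventional
choices; the original scoring tool's internals are not public.

Each exon's feature vector is then

| feature | meaning |
|---|---|
| $x_1$ | 3' splice-site strength |
| $x_2$ | binding z-score of the 250 nt of upstream intron |
| $x_3$ | binding z-score of the exon |
| $x_4$ | binding z-score of the first 100 nt of downstream intron |

with $x_2..x_4$ length-bin z-scores and all four standardized against a
reference internal-exon population. Regions falling off a contig edge are
truncated and flagged, never silently dropped.

# The regulation model

Exons are labelled from PSI (percent spliced in) tables: repressed if the
minor isoform exceeds 5% in both conditions and $\Delta\mathrm{PSI} =
\mathrm{PSI}_{kd} - \mathrm{PSI}_{ctrl} \ge 30$; enhanced for
$\Delta\mathrm{PSI} \le -30$; non-regulated if the exon is flagged
alternative and $|\Delta\mathrm{PSI}| \le 5$ (the 5% non-regulated ceiling
is this package's concrete choice); everything else is excluded.

The model is a three-class multinomial logistic regression with
non-regulated as the baseline: two g-functions (logits)
$g_c(x) = \beta_{c,0} + \sum_i \beta_{c,i} x_i$ for $c \in
\{\text{repressed}, \text{enhanced}\}$, and

$$p_{\text{repressed}} = \frac{e^{g_R}}{1 + e^{g_R} + e^{g_E}}, \qquad
p_{\text{non-reg}} = \frac{1}{1 + e^{g_R} + e^{g_E}}.$$

Training follows a three-step protocol:

1. **Screening**: a candidate feature is kept if a Welch t-test of either
   regulated class against the baseline gives $p < 0.25$ (strictly) — a
   deliberately permissive filter.
2. **Outlier removal**: exons whose standardized Pearson residual
   $|y_{ic} - \hat p_{ic}|/\sqrt{\hat p_{ic}(1-\hat p_{ic})}$, maximized
   over class indicators, exceeds 3 under an interim fit are removed from
   the final fit. The residual criterion and cutoff are this package's
   instantiation of an otherwise unspecified step; both are configurable
   and all flags are reported.
3. **Stepwise selection**: backward elimination by AIC, refitting at each
   step (again a concrete instantiation of an unspecified "stepwise"
   step; deterministic given the table).

The likelihood is maximized by BFGS with the analytic gradient; standard
errors come from the numeric Hessian at the optimum. Complete or
quasi-complete separation (diverging coefficients or a non-invertible
Hessian) is detected, reported, and refit with a small ridge penalty
($\lambda = 10^{-2}$) — such fits are flagged, never silent.

**Cross-validation** is leave-one-out with screening (and optionally
stepwise selection) re-run *inside every fold*. Whether the original
protocol re-selected per fold is unknowable from the outside; re-selecting
is the unbiased choice and the one implemented. ROC curves are computed per
logit (repressed-vs-rest on $p_{\text{repressed}}$, enhanced-vs-rest on
$p_{\text{enhanced}}$) with trapezoid AUC over unique thresholds, which
equals the concordant-pair fraction with ties counted half.

Decision thresholds: an exon is called predicted-repressed when
$p_{\text{repressed}} > 0.65$ (strict) and predicted-unregulated when
$p_{\text{repressed}} \le 0.20$; in between is reported as intermediate.
Enhanced-class predictions are computed and reported but carry a
low-confidence caveat — the enhanced class is smaller and its binding
signal weaker, and its logit is known to rank worse than the repression
logit.

# What the synthetic world does and does not establish

The generators emulate: (i) token-space clusters drawn exactly from a
planted HMM (for estimation oracles), (ii) nucleotide sequences with planted
CU-rich tracts, G-interspersed, at the ~30-nt scale of CLIP clusters,
(iii) exon feature tables drawn either class-conditionally or from a planted
multinomial logit, (iv) PSI tables with planted per-class
$\Delta\mathrm{PSI}$ (default $\pm40$, noise sd 2) and logged clipping at
the [0, 100] bounds, and (v) a toy genome of cassette exons whose
"repressed" members carry a 200-nt upstream CU tract, a weak 3'ss tail and
a downstream tract.

Two generator choices deserve emphasis:

* **Tract composition is symmetric in C and U** (default: 2% A, 10% G, the
  rest split equally). Canonical binding elements are CU repeats without a
  consistent skew. Empirically this matters: with a skewed tract (e.g.
  C:U = 45:55) Baum–Welch at longer sequence lengths can converge to a
  *C-rich vs U-rich* state split — a higher-likelihood explanation than
  tract-vs-background, precisely because overlapping triplets are
  autocorrelated — and then pyrimidine triplets do not all segregate into
  one state. This is a real property of triplet HMMs worth knowing, not a
  bug.
* **Token-space vs nucleotide-space clusters are different worlds.** Only
  the former matches the HMM's generative law, so only it supports sharp
  parameter-recovery claims (emission total-variation ≤ 0.05, transition
  error ≤ 0.1 at 2,000 clusters × 30 nt).

A green suite therefore establishes algorithmic correctness (oracle
equivalence with brute-force enumeration up to 8 tokens, EM monotonicity,
self-consistent normalization, coefficient recovery within Wald coverage)
and qualitative reproduction of the planted signals. It does *not*
establish the numeric results that depend on real CLIP clusters, a real
genome annotation, or measured dissociation constants (score–$K_d$
correlation, published AUCs, genome-wide exon counts and validation rates);
those are consumed as inputs when available, never asserted.

# Numerical and boundary choices

* Viterbi ties are broken toward the binding state at every backtrack step,
  making decoded paths deterministic.
* An exact tie in pyrimidine emission mass labels state 1 the binding state
  with a warning.
* Empirical p-values use "equal or greater" and no pseudocount by default;
  a raw score above the null maximum gives $p = 0$ (or $1/(n+1)$ in
  pseudocount mode).
* Out-of-bounds genomic regions are truncated with a flag rather than
  rejected: 250-nt upstream windows legitimately fall off contig edges.
* Coordinates are BED-style 0-based half-open everywhere internally.
* EM restart counts in the long-running acceptance tests are reduced (2–4
  restarts instead of the default 10) to keep the suite inside its time
  budget; in the well-separated planted worlds used there, recovery is
  insensitive to the restart count.

# Known limitations

* Two states and first-order transitions only; no posterior-decoding
  alternative to Viterbi.
* The dinucleotide-shuffle background returns the input with a warning for
  pathological short sequences where no distinct Euler path exists.
* Heatmap clustering and RNA-map display spans are conventional defaults,
  not reconstructions of any published figure's exact geometry.
* The regulation model is a single-factor model by design: an exon
  unaffected in one cell type may still be a target elsewhere, so
  predicted probabilities are rankings of sequence-encoded potential, not
  cell-type-specific outcomes.
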