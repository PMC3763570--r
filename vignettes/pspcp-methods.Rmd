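---
title: "Positional specific physicochemical properties for submitochondrial localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional specific physicochemical properties for submitochondrial localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PSPCPloc)
```

# The model

## Problem

Given a mitochondrial protein sequence, predict its submitochondrial
location: inner membrane, matrix, or outer membrane. The representation must
work on small, imbalanced benchmark datasets, so it should be compact,
deterministic and informed by evolutionary conservation where a profile is
available.

## From PSSM to standardized profile

PSI-BLAST produces, for a query of length $L$, a position-specific scoring
matrix of integer log-odds scores $E_{ij}$ ($i = 1..L$, $j = 1..20$ amino
acids in the canonical order A R N D C Q E G H I L K M F P S T W Y V). Each
row is mapped to a probability vector by a softmax,

$$A_{ij} = \frac{e^{E_{ij}}}{\sum_{j'} e^{E_{ij'}}},$$

computed with the usual max-subtraction so arbitrarily large scores cannot
overflow. Row $i$ of $A$ is interpreted as the substitution distribution of
position $i$. Sequences without a PSSM fall back to one-hot rows (a
degenerate residue symbol such as X receives the uniform row $1/20$), in
which case the whole representation reduces exactly to plain amphiphilic
pseudo-amino-acid composition — a property the test suite checks against an
independent oracle implementation.

## PSPCP series and the fused descriptor

Nine AAindex property scales are bundled (two hydrophobicities, one
hydrophilicity, two polarities, rigidity, flexibility, irreplaceability and
side-chain mass). Each scale is z-score normalized across the 20 amino
acids, using the population convention (divisor 20, not 19). The positional
specific physicochemical property of position $i$ under scale $r$ is the
expectation

$$d_{i,r} = \sum_j A_{ij}\, h_{r,j}.$$

The descriptor fuses the profile composition
$f_j = \tfrac1L \sum_i A_{ij}$ with sequence-order correlation factors

$$u_{k,r} = \frac{1}{L-k} \sum_{i=1}^{L-k} d_{i,r}\, d_{i+k,r},
\qquad k = 1..\lambda,$$

into the normalized vector of length $20 + \lambda R$

$$q_n = \frac{f_n}{Z} \;(n \le 20), \qquad
  q_{20 + (r-1)\lambda + k} = \frac{w\, u_{k,r}}{Z}, \qquad
  Z = \sum_j f_j + w \sum_{k,r} u_{k,r}.$$

The pseudo block is laid out property-major, lag-minor; feature names
(`f_A`, …, `u_BULH740101_k1`, …) make the layout explicit.

### A real degeneracy: $Z \le 0$

Unlike classical pseudo-AAC, whose correlation factors are squared
differences and hence nonnegative, the amphiphilic factors $u_{k,r}$ are
signed. For particular sequences and larger $w$ the normalizer $Z$ can
therefore reach zero or become negative, and the descriptor is no longer a
well-defined distribution-like vector. The package refuses to return such a
vector: `descriptorVector()` raises an error naming the degeneracy. The
tests treat that error as part of the contract — whenever an independently
computed $Z$ is nonpositive the pipeline must raise, and only draws with
$Z > 0$ count toward the oracle-agreement comparisons.

## Classifier

A one-vs-one support vector machine with RBF kernel
$K(x, y) = e^{-\gamma \lVert x-y \rVert^2}$ (via e1071/LIBSVM,
`scale = FALSE` since descriptors are already normalized). Package defaults
are $w = 0.15$, $\lambda = 11$ (descriptor length 119), $\gamma = 0.125$,
$C = 8$ — the recommended operating point for the three-class benchmark
setting this method targets.

# Parameters and why

- **$w$ (default 0.15)** balances composition against sequence order.
  Larger $w$ moves descriptor mass into the pseudo block (a monotonicity
  the tests check) but increases the risk of the $Z \le 0$ degeneracy.
- **$\lambda$ (default 11)** is the maximum correlation lag; it must be
  strictly smaller than every sequence length. The synthetic order study
  below shows why $\lambda$ must reach the characteristic period of an
  order signal before it becomes visible.
- **Scales (default: all nine)** — any subset can be selected via
  `featureConfig(accessions = ...)`; user tables can be supplied through
  `readPropertyTable()`.
- **$\gamma$, $C$** — calibrated per dataset. `defaultGrid()` enumerates
  $w \in \{0.05, 0.10, \dots, 1.00\}$ (20 values) and
  $\lambda \in \{2, \dots, 20\}$ (19 values), 380 descriptor combinations,
  crossed with the standard LIBSVM ranges $\gamma \in 2^{-15}..2^3$ and
  $C \in 2^{-5}..2^{15}$. Note one deliberate inconsistency: the published
  enumeration range for $w$ includes 1.00, while the `FeatureConfig`
  validity contract requires $w \in (0, 1)$; the grid therefore evaluates
  $w = 1$ as the one-sided limit ($1 - 10^{-12}$) and reports it as 1.00.
  Ties are broken toward the simplest model: smallest $\lambda$, then $w$,
  then $C$, then $\gamma$. Infeasible $\lambda$ values (not below the
  shortest sequence) are reported, never silently dropped.

# Evaluation protocols

- **Jackknife (leave-one-out)** is the reference protocol: deterministic,
  and the one under which per-class accuracies and MCCs are reported.
  Per-class accuracy is $TP_s/(TP_s+FN_s)$; overall accuracy is
  $\sum_s TP_s / N$.
- **MCC** uses the standard convention of 0 when its denominator vanishes;
  a class with no true members gets accuracy `NA` with a warning rather
  than a silent 0. The implementation is tested against the independent
  definition of MCC as the Pearson correlation of indicator vectors.
- **Repeated hold-out** draws the training set uniformly at random
  *without stratification* — matching how an independent dataset would be
  collected, and keeping the protocol honest on imbalanced data. A draw
  that loses a class entirely is redrawn with a warning (bounded retries).
  The summary reports the mean and the *population* standard deviation
  (divisor $n$) of overall accuracy across repeats; all repeats derive
  from one master seed.

# The synthetic generator

Real PSSMs require PSI-BLAST and a sequence database, so the package ships
a generator (`generateDataset()` / `syntheticSpec()`) that produces FASTA
sequences, parseable ASCII PSSM files and labels with controllable signal:

- **Composition channel.** Each class $c$ has residue usage
  $p_c = \mathrm{softmax}(\text{signal} \cdot z_c)$ for a fixed
  class-specific direction $z_c$; signal 0 gives the uniform distribution
  for every class.
- **Order channel.** A class with motif period $T$ draws residue $i$ by
  *copying* residue $i - T$ with probability $\text{signal}/(1+\text{signal})$
  and sampling from $p_c$ otherwise. The control class is generated by the
  *same* copy process and then randomly permuted: its per-sequence residue
  multiset is preserved exactly, so the two classes differ only in order,
  never in composition. This is what makes the $\lambda$ study meaningful —
  with period 4, descriptors at $\lambda = 3$ carry no class signal while
  $\lambda = 4$ does.
- **PSSMs.** Scores are
  $E_{ij} = \mathrm{clip}(\mathrm{round}(2\log(Q_{ij}/0.05) + \varepsilon), -10, 10)$
  with $Q$ a mixture of the one-hot observed residue and $p_c$, and noise
  shrinking as signal grows.
- **Presets.** `"easy"`: three balanced classes of 20, signal 4 — strongly
  separable. `"null"`: signal 0 — every class identical, so any classifier
  is expected to sit at the majority-class prior. The default class sizes
  (40/11/9) mirror the imbalance typical of curated submitochondrial
  benchmarks.

With signal 0 the construction is fully exchangeable across classes, which
is what justifies the test that jackknife accuracy on the null preset stays
within sampling noise of the prior.

## Kernel width for the synthetic studies

The package default $\gamma = 0.125$ is tuned for the benchmark operating
point. The synthetic studies in the tests and the acceptance script instead
use $\gamma = 32$, chosen by the median heuristic: descriptors are
normalized vectors whose pairwise squared distances on these generators are
of order $0.03$, so $\gamma \approx 1/\text{median}\,\lVert x-y\rVert^2$
lands near $2^5$. With $\gamma = 0.125$ the kernel is nearly constant at
those distances and the SVM cannot express the separation regardless of
how strong the signal is.

# Problem sizes

The shipped studies use 40–60 sequences of length 30–120 with $R = 9$
scales and $\lambda \le 11$ (descriptor length $\le 119$): jackknife over
$N = 60$ trains 60 SVMs in seconds. Grid calibration is the expensive
operation — the full default grid is $380 \times 19 \times 21$ jackknifed
models and should be restricted (`calibrationGrid()`) for exploratory work;
features are cached per $\lambda$ so descriptor assembly is not the
bottleneck.

# Limitations

- The representation discards order information beyond lag $\lambda$ and
  all pairwise property interactions; two sequences with equal composition
  and equal short-lag autocorrelations are indistinguishable.
- The $Z \le 0$ degeneracy means not every (sequence, $w$, $\lambda$)
  combination yields a descriptor; calibration over large $w$ can fail on
  datasets that contain such sequences.
- Synthetic PSSMs are a stylized stand-in for PSI-BLAST output: they
  validate the pipeline's mechanics and its null behavior, not biological
  accuracy. Claims about real submitochondrial benchmarks require real
  profiles.
- The one-hot fallback silently loses all evolutionary information for the
  affected sequences; `extractFeatures()` records per-sequence origins so
  mixed datasets can be audited.
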