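---
title: "Methods: an exact NBP test with thinning normalization, and the pipeline around it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an exact NBP test with thinning normalization, and the pipeline around it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqdge)
```

This vignette records the statistical model, the numerical choices, and the
design decisions behind `seqdge`, in enough detail that every number the
package produces can be re-derived by hand or against an independent
implementation. The companion test suite does exactly that; here we explain
*why* each choice was made.

## 1. The count model

Replicated RNA-Seq gene counts are overdispersed relative to Poisson. The
package models a gene's count $Y$ in one replicate as negative binomial with
mean $\mu$ and variance

$$\operatorname{Var}(Y) = \mu + \phi\,\mu^{\alpha},$$

the *NBP* parameterization. Two genome-wide parameters are shared by all
genes: $\phi > 0$ scales the extra-Poisson noise and $\alpha$ lets the
effective dispersion depend on the mean ($\alpha = 2$ recovers the classical
NB2 model with constant dispersion $\phi$). Equivalently, the NB size
parameter for a gene with mean $\mu$ is

$$r(\mu) = \frac{\mu^{2-\alpha}}{\phi}.$$

Counts are simulated and fitted through the Gamma–Poisson mixture, which is
exactly this distribution.

### Dispersion estimation

`fit_nbp()` maximizes an *adjusted* profile log-likelihood over
$(\phi, \alpha)$:

* For each gene and each treatment group, the group mean is profiled out by
  its sample mean (the NB mean MLE for fixed dispersion is not the sample
  mean in general, but the sample mean is the standard, consistent plug-in
  and keeps the profile closed-form).
* Per-group means matter: profiling a single pooled mean per gene would
  absorb genuine between-group differences into apparent overdispersion,
  biasing $\phi$ upward on differential data and, worse, biasing it
  *downward* after adjustment on typical mixtures. With per-group means the
  fit recovers the generating $(\phi, \alpha)$ on simulated data whether or
  not differential genes are present.
* Plugging in estimated means makes the unadjusted profile likelihood
  underestimate $\phi$ (the classic degrees-of-freedom loss). We apply the
  Cox–Reid adjustment: for every profiled (gene, group) mean $\hat\mu_{gj}$
  estimated from $n_j$ replicates, the objective adds
  $-\tfrac12 \log\!\big(n_j / \operatorname{Var}(\hat\mu_{gj})\big)$,
  the log observed information of the profiled parameter. On 2000 genes
  with 3+3 replicates this moves $\hat\phi$ from roughly $0.06$ to within
  a few percent of the generating $0.1$.

A consequence worth knowing: because the adjustment term does not scale with
the data, mechanically duplicating every replicate moves the estimate back
toward the unadjusted MLE. The test suite asserts this direction rather than
pretending duplication is invariant.

### The exact conditional test

For one gene with group-A replicates summing to $s$ and overall total $S$,
both group sums are NB under the null (sums of i.i.d. NB with common size
$r$ are NB with sizes $n_A r$ and $n_B r$). The test conditions on $S$:

$$P(s \mid S) \propto f_{n_A r}(s)\, f_{n_B r}(S - s),$$

with $f$ the NB pmf and $r$ evaluated at the pooled per-replicate mean
$\hat\mu = S / (n_A + n_B)$ (the null estimate). The two-sided p-value sums
the probabilities of all outcomes no more likely than the observed one:

$$p = \sum_{t\,:\,P(t \mid S)\, \le\, P(s \mid S)\,(1 + 10^{-7})} P(t \mid S).$$

Numerical choices:

* The $(1 + 10^{-7})$ tie tolerance makes "equally likely" robust to
  floating-point noise in the pmf ratios; without it, exactly symmetric
  outcomes are sometimes dropped from the sum and p-values land slightly
  below their enumerated values.
* The weights are computed on the log scale via `lgamma` and normalized
  after subtracting the maximum, so the enumeration is stable for any
  $S$ the package will meet.
* When $r > 10^8$ (for example as $\phi \to 0$) the NB pmf underflows its
  size parameter's useful range; the conditional law converges to
  Binomial$(S, n_A/(n_A+n_B))$ and the implementation switches to the exact
  binomial enumeration. The switch point is far beyond any realistic
  dispersion, so it only replaces values that would otherwise lose
  precision; the suite checks agreement with `binom.test` to $10^{-9}$ in
  the limit.
* $S = 0$ gives $p = 1$ by definition.

### Normalization by random thinning

Instead of scale factors, libraries are made comparable by binomial
thinning: every count $c$ in a replicate with library size $L$ is replaced
by Binomial$(c, N/L)$ draws, where $N$ is the smallest library size. After
thinning, all replicates are at depth $N$ and counts enter the exact test
directly. Thinning is seeded (one derived substream per replicate) and
therefore bit-reproducible; the minimum-size replicate is untouched.

Thinning discards information, and a single thinning draw adds Monte Carlo
noise to the significant set. `thinning_stability()` quantifies this: it
re-thins and re-tests `n_iter` times and reports, per reference-significant
gene, the percentage of iterations in which it is recovered.

**A property the user should know about.** Thinning normalizes *total*
counts. When differential expression is predominantly one-directional, the
affected group's libraries are systematically larger, and equalizing totals
shifts every null gene slightly in the opposite direction. On simulations
with 10% of genes induced 4-fold (and nothing repressed), per-test type-I
error stays nominal under a true null, but the observed false discovery
proportion of the q ≤ 0.05 set inflates well above its nominal level, and an
independent cross-check with a trimmed-mean normalization does not show the
inflation. This is an intrinsic property of total-count normalization under
asymmetric differential expression — not of the exact test — and is
documented honestly in the acceptance suite rather than patched around.
Balanced induction/repression, or spike-in/robust normalization upstream,
removes it.

### Multiple testing

Per-gene p-values get Storey q-values: $\hat\pi_0(\lambda)$ is computed on a
grid $\lambda = 0.05, \dots, 0.95$, smoothed by a natural cubic spline
(3 df) and read at $\lambda = 0.95$, clamped to $(0, 1]$. The q-value is the
monotone step-down minimum of $\hat\pi_0 m p_{(i)} / i$. With $\pi_0 = 1$
this reduces exactly to Benjamini–Hochberg, which the tests verify against
`p.adjust`. Fewer than 100 p-values make the smoother unreliable; the
implementation then fixes $\pi_0 = 1$ (conservative) and warns.

## 2. The pipeline around the test

* **Reference catalog.** GFF3 gene models over a FASTA genome; malformed or
  orphaned records are rejected row-by-row with line numbers rather than
  aborting the parse. Splice-junction sequences are synthesized per isoform
  by concatenating `flank` bases on each side of every exon–exon boundary;
  the default `flank = read_length - 1` is the longest flank that cannot
  produce a junction hit explainable by a contiguous genomic alignment.
* **Read store.** Fixed-position trimming (head/tail) happens *before*
  collapsing to unique sequences, so identical post-trim reads share one
  alignment; occurrence counts per replicate preserve the raw read count
  through an explicit conservation identity (retained + dropped short +
  ambiguous-base = raw) that the tests assert.
* **Aligner.** 2-bit encoded, preamble-container index (12-nt container
  key, 16-nt sorted suffix); candidate placements come from seed lookup
  with substitution-variant enumeration (two seeds with budget
  $\lfloor k/2 \rfloor$ each when the read covers both, one seed with
  budget $k$ otherwise — the pigeonhole principle guarantees no placement
  is missed), then every candidate is verified base-by-base. Windows near a
  sequence's 3' end where a seed has no fully indexed word are verified
  directly. Exhaustiveness (never one missed placement, never a spurious
  one, $k \le 2$) is the property the acceptance suite checks on 1000
  random instances against a brute-force scan.
* **Counting.** A read is *unambiguous* when its best-stratum alignments
  all fall within features of exactly one gene locus (junction hits count
  toward their gene). Gene counts accumulate each unique read's
  per-replicate occurrences in full; isoform counts split them equally
  among the compatible isoforms. The expression filter retains a gene only
  when at least one treatment group has a positive count in *every* one of
  its replicates, so a gene cannot enter testing on the strength of a single
  stray replicate.
* **Replicate QC.** Counts are transformed by $\ln(c \cdot 250000/L + 1)$
  (a log reads-per-quarter-million, stabilized by the +1) and replicate
  agreement is the one-way random-effects ICC,
  $(\mathrm{MSB}-\mathrm{MSW})/(\mathrm{MSB}+(k-1)\mathrm{MSW})$. MA plots
  use thinned counts with +1 offsets so zero counts stay finite.
* **GO enrichment.** Annotations propagate to ancestors via the is_a /
  part_of closure. Term-for-term is the upper-tail hypergeometric test;
  parent–child (intersection variant) conditions each term's universe on
  genes annotated to *all* its parents, with root terms at $p = 1$ by
  convention; the permutation method redraws study sets of equal size and
  uses the add-one estimator $(1 + \#\{m^* \ge m\})/(B + 1)$, which can
  never return 0 and is seeded.

## 3. The synthetic-data generator

All simulation defaults are study conditions chosen once, on scientific
grounds, before the verification suite was run, and are deliberately modest
in scale so the whole suite runs on one CPU in minutes:

* genomes of 5–20 kb with 2–4-exon genes, 0.3–0.5 genes/kb, 30% of genes
  with a second (exon-skipping) isoform — enough structure to exercise
  junctions and isoform ambiguity without inflating runtimes;
* per-gene means log-uniform on [10, 500] (count level) or [20, 200] (read
  level), covering the low-count regime where exact tests matter and the
  moderate regime where dispersion dominates;
* noise at $\phi = 0.1$, $\alpha = 2$ — a typical biological-replicate
  dispersion;
* planted effects: 10% of genes at 4-fold induction for power and
  stability studies; `fold = 1, de_fraction = 0` is the null;
* reads of 25 nt (plus optional padding to exercise trimming), substitution
  errors at 0.002/base capped at two per read to stay within the aligner's
  mismatch allowance.

The generator retains full ground truth (per-read provenance, per-gene
expected means, the planted set), so accuracy statements in the tests are
identities, not estimates.

## 4. Reproducibility

Every stochastic step takes an explicit integer seed and derives independent
substreams from it; re-running any stage, or the whole pipeline, with the
same inputs and seed reproduces every output file byte-for-byte. The
acceptance script (`scripts/acceptance.R`) re-runs the main computations
from a single `--seed` and writes the headline quantities as JSON.
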