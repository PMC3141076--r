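---
title: "choreseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{choreseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choreseq)
```

## The problem this package addresses

ChREBP (carbohydrate response element binding protein) is a glucose-activated
bHLH-ZIP transcription factor that, as a heterodimer with Mlx, binds the
carbohydrate response element (ChoRE): two E-box-like hexamers separated by a
strictly conserved 5-nt spacer (consensus `CAYGNG-n5-CNCRTG`, where the second
half-site is the reverse complement of the first). Studies of such factors
combine ChIP-seq (where does the factor bind?) with two-condition expression
profiling (which genes respond to glucose?) and ask whether the bound genes
are the responding genes — and in which direction.

`choreseq` implements that full analysis chain as small, separately testable
stages, together with a synthetic-data generator that plants known binding
sites and known expression responses, so every stage can be validated against
ground truth. The package is written for analysts who want a transparent,
reproducible desk-scale model of this class of study rather than a
production peak caller.

## Peak calling

Tags (36-nt mapped reads by default) are extended to the sonication fragment
length (default 200 bp) in their strand direction and piled up per base.
A base qualifies as bound when

* ChIP coverage ≥ `min_height` (default 8 overlapping reads), **and**
* ChIP / max(scaled input, pseudocount) ≥ `min_ratio` (default 5), where the
  input track is scaled by the ratio of library sizes and the pseudocount
  (default 1) floors the denominator at empty input bases.

Maximal runs of qualifying bases separated by at most `merge_gap` (default
100 bp; prevents single-base dropouts from splitting one site) become peaks;
the summit is the leftmost base of maximal ChIP coverage. The two thresholds
are the published stringent setting for this experiment type; the
normalization (library-size scaling, pseudocount, per-base conjunction) is
the minimal defensible completion of them, since threshold-style callers do
not document one. The height threshold is applied to *extended-fragment
coverage*, not raw tag starts, which is what pileup figures of such
experiments depict.

Two properties of this caller are worth knowing:

* **Count non-monotonicity.** Raising a threshold can split one peak into
  two (interior bases drop out), so the peak *count* is not monotone in the
  thresholds; the total covered base pairs are. The test suite asserts the
  bp version.
* **Specificity is depth-dependent.** The 8-read floor is calibrated for the
  sparse per-bp coverage of a genome-wide experiment (millions of tags over
  gigabases ≈ 0.4–0.5× fragment coverage), where background almost never
  stacks 8 fragments and null genomes stay peak-free. At the dense default
  of the desk-scale simulation (100k tags on 1 Mb ≈ 20× coverage) every base
  passes the height floor and specificity rests on the ratio alone, which
  admits occasional false positives where the input dips as the ChIP
  fluctuates high (about 1–2 × 10⁻⁵ per base). The null-specificity test
  therefore runs at the sparse, genome-wide-equivalent depth, and users
  applying the caller at high per-bp coverage should raise `min_height`
  toward the coverage scale.

## Peak annotation

The summit (a single base, unambiguous) determines everything. The nearest
gene is the one whose TSS is closest to the summit, if within 20 kb
(strictly); distances are signed in the gene's orientation, negative
upstream. Categories are computed per gene and resolved by precedence:

`proximal_promoter` (≤2 kb upstream, strand-aware) > `distal_promoter`
(2–5 kb) > `utr5` > `utr3` > `exon` (CDS-overlapping) > `intron_1_2` (first
or second intron in transcription order) > `intron_other` > `intergenic`.

Promoters dominate the precedence so the single-label pie behaves like the
published ones; the multi-label set keeps every overlapped feature across
all genes, because summits genuinely sit in, say, the intron of one gene and
the promoter of another — which is why published category percentages can
sum to more than 100. The two promoter windows are arguments
(`proximal_bp`, `distal_bp`) because the literature's "promoter" and "2 kb
upstream" categories overlap without a standard resolution; we expose both
rather than resolve the ambiguity. Minus-strand TSS is `tx_end − 1` (the
last transcribed base), the standard convention for half-open coordinates.

## PWM scoring and exact p-values

Two scores are carried per window:

* the **normalized score** \(\sum_i p_i(b_i) / \sum_i \max_b p_i(b)\),
  which maps every per-column-argmax window to exactly 1 — this is the
  convention under which a perfect E-box "scores 1";
* the **log2-odds score** against the background, used for ranking ChoRE
  half-sites.

P-value thresholds are exact: the full background distribution of the window
score is computed either by enumerating all \(4^w\) windows (width ≤ 10) or
by a column-by-column convolution on a discretized score grid (resolution
`1e-4`; rounding error is at most grid/2 per column, and the two methods are
tested to agree to that resolution). The threshold for level α is the
smallest attainable score whose exact exceedance probability is ≤ α. Windows
containing `N` are skipped. Scanning covers both strands with forward-strand
offsets; overlapping hits are kept.

ChoRE detection is deliberately structural rather than one long PWM: half-
site hits of a width-6 E-box PWM (both strands, best strand per position)
are paired whenever their inner gap is exactly the configured spacer
(default 5 nt) — the spacing the element strictly requires — in either
orientation of the sequence. Because the element is quasi-palindromic
(second half-site = reverse complement of the first), the same physical
element is typically detected in both orientations with identical scores;
such duplicates are collapsed, keeping the higher combined log-odds and "+"
on ties. The orientation label is therefore not meaningful for perfectly
palindromic elements, and no analysis in the package depends on it.

## ZOOPS-EM motif discovery

The de novo stage fits the zero-or-one-occurrence-per-sequence model: each
sequence contains one site (probability γ, estimated) at a uniform offset,
emitted by the PWM; everything else is iid background (mononucleotide
frequencies estimated from the input once, then fixed). E-step: per-offset
posteriors; M-step: pseudocount-smoothed letter probabilities and γ. Each
of `n_starts` (default 10) runs is seeded from a smoothed random data
window, and the best final log-likelihood wins.

Plain EM on this model has a well-known failure mode: it locks onto a
*shifted register* of the true site (a local optimum sharing most columns).
After each run converges we therefore restart EM from column-shifted
versions of the model (±1–3, vacated columns filled with background) and
accept a restart only if its converged likelihood is strictly better. The
reported likelihood trace is that of the final accepted run, which is the
sequence of EM iterations that produced the returned model and is
non-decreasing by the standard EM guarantee. The information content of the
result (relative entropy vs background, in bits) is reported for null
calibration; MEME-style E-values are out of scope.

## Differential expression and PPDE

Per gene, the log2 fold change is the difference of condition means; the
moderated t blends a variance prior into the pooled residual variance,
\( \tilde s^2 = (\nu_0 s_0^2 + d s^2)/(\nu_0 + d) \), with `nu0 = 4` prior
degrees of freedom by default and \(s_0^2\) the median pooled variance when
not supplied. Two-sided p-values use \( \nu_0 + d \) df; with `nu0 = 0` the
statistic reduces exactly to the ordinary pooled two-sample t (a tested
identity). Genes with fewer than two observed replicates in a condition are
dropped.

The posterior probability of differential expression (PPDE) comes from a
beta-uniform mixture \( f(p) = \lambda + (1-\lambda)\,a\,p^{a-1} \) fitted
to all p-values by EM (init λ = 0.5, a = 0.5; stop at log-likelihood change
< 1e−8 or 500 iterations; a constrained to (0, 1], making PPDE monotone
non-increasing in p). One subtlety matters for calibration: under a global
null the likelihood is flat along the a = 1 ridge, so λ itself is not
identified there. The identifiable functional is the mixture density at
p = 1, \( \hat\pi_0 = \lambda + (1-\lambda)a \) — the classical upper-bound
estimate of the null-gene fraction — which `fit_bum()` reports as `pi0` and
which the calibration tests require to sit in [0.9, 1] on null data. PPDE
is used only as a *ranking* (its intended role here); gene lists default to
PPDE ≥ 0.95, with a p-value cutoff exposed as the alternative.

Ranking is fully deterministic: descending key, ties by |log2FC|, then
lexicographic gene id.

## Running-sum KS enrichment

Walking the ranked list, a binding target adds +1/Nh and a non-target
−1/(N−Nh); the running sum ends exactly at zero and its maximum is the
enrichment score ES ∈ [0, 1] (the unweighted, classic form of the
GSEA-style statistic — the minimal model consistent with "increase on a
match, decrease otherwise", and the one that makes the walk a pivot).
ES_min is reported separately for bottom-of-list enrichment. Significance
permutes the *placement of the target set* (equivalently, gene labels), not
expression values, with the add-one estimator to avoid zero p-values; when
\( \binom{N}{N_h} \le 10^6 \) the exact p over all placements is computed
as well. The leading edge is the set of targets at or before the argmax.
Direction is summarized by intersecting targets with the significant DE
genes and splitting on the sign of the fold change — the analysis that
reveals a factor acting as both activator and repressor. Gene-set
over-representation uses the one-sided hypergeometric upper tail with
Benjamini–Hochberg FDR across sets.

## The synthetic experiment: what it emulates, and what it does not

`simulation_config()` defaults define the study conditions:

| parameter | default | emulates |
|---|---|---|
| genome | 1 Mb, 2 chromosomes, iid GC 0.5 | a desk-scale reference |
| genes | 60, non-overlapping, 2–5 exons | annotated gene models |
| planted sites | 20, Normal(−200, 500) bp around linked TSSs, 10% intergenic | TSS-proximal ChoRE loci |
| fragments / reads | 200 bp / 36 nt, random strand | sonication + short-read tags |
| libraries | 100k ChIP, 100k input, 10% of ChIP site-derived | IP enrichment over input |
| expression | 6 replicates per condition, effect 1 log2 unit, noise sd 0.3 | two-condition arrays |
| direction | each bound gene up with probability 0.5 | dual activator/repressor action |
| other regulation | 5% of unbound genes responsive | glucose response not through this factor |

ChIP fragments around a site have midpoints Normal(center, fragment/4) — the
simplest model that produces the peaked pileups such experiments show;
strand is Bernoulli(0.5) because sonication is unstranded. Background
sequence is iid so exact motif p-values are analytic. Replicate noise sd
0.3 and a two-fold (1 log2 unit) effect are typical of array data; six
replicates match the emulated design.

The default 10% ChIP efficiency (fraction of site-derived tags) is a guess —
the real value is unknown. Its effect is easy to bound analytically at the
default depth: a site receives about `eff × 100k / 20` tags whose fragments
nearly all overlap the center, against an input coverage of ~20, so the
expected summit height is ≈ 500·eff·0.95 and the ratio threshold (5×) stops
binding sites from being called once `eff` drops below roughly 2%
(height ≈ 95, ratio ≈ 95/20 < 5). Between 2% and 100% efficiency the
recovery property is insensitive to the value; the default sits comfortably
inside that plateau.

Not modelled: sequencing errors, GC bias, mappability, copy number,
duplicate-read artifacts, probe-level array effects, and correlated
replicate structure. Passing tests therefore demonstrate the *logic* of the
chain — recovery of planted truth under the stated noise model — not
robustness to real-data artifacts.

## Numerical and tie-breaking choices

* Coordinates are 0-based half-open everywhere internally (BED convention);
  1-based appears only in human-readable output.
* Summit ties: leftmost argmax. Ranking ties: |log2FC|, then gene id.
  Equidistant TSSs: lexicographically smaller gene id. ChoRE orientation
  ties: "+".
* Score-grid resolution 1e-4; −∞ log-odds columns are clamped 30 units
  below the finite minimum so zero-probability windows can never cross a
  threshold.
* Tag fragments are clamped inside chromosome bounds; planted sites are
  resampled (up to 200 times) rather than clamped.
* p-values are floored at 1e-12 inside the BUM fit; permutation p-values
  use the add-one estimator.
* EM stops on a log-likelihood improvement below `tol` (1e-6 for motif
  discovery, 1e-8 for the BUM fit) or at `max_iter`.

## Problem sizes used by the test suite

The shipped tests run the chain at the default simulation scale (1 Mb /
100k tags) for recovery, 100 sparse-depth null genomes for specificity, 20
seeded discovery runs of 50 planted sequences for the EM, 50 null and 50
coupled expression simulations of 200 genes for calibration and the
end-to-end causal-vs-decoupled contrast, and 100k permutations for the KS
Monte-Carlo convergence check — sizes chosen so the full suite exercises
every claimed property in a few minutes on one core.

## Known limitations

* The peak caller has no FDR calibration and no local background window;
  it is the stated-threshold model, suitable where those thresholds are the
  object of study.
* One TSS per gene; alternative promoters are out of scope.
* The bipartite ChoRE detector fixes the spacer exactly; biologically
  marginal ±1-nt spacings are deliberately not matched.
* The BUM-based PPDE is a ranking device, not a calibrated posterior for
  individual genes, and inherits the ridge non-identifiability discussed
  above.
* `run_pipeline()` is deterministic given config + seed, but determinism
  across R versions is only as strong as R's RNG stability guarantees.
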