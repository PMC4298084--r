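---
title: "Model-based evaluation of de novo transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based evaluation of de novo transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A de novo transcriptome assembler turns a set of RNA-Seq reads into a set
of contigs without a genome. Because sequencing depth is finite and
transcript abundances span orders of magnitude, the best *achievable*
assembly is not the transcriptome itself but the set of transcript
segments actually supported by reads. `asmeval` evaluates assemblies in
two complementary ways:

* a **reference-free score**: the log joint probability of the assembly
  `A` and the read set `D` under a generative model,
  `score(A) = log P(A, D)`, used to rank assemblies of the *same* reads;
* **reference-based measures** (when a transcript set is available):
  contig- and nucleotide-level recall/precision/F1 and a weighted k-mer
  compression score.

Both revolve around the notion of the **true assembly at minimum overlap
length `w`**: for each transcript, the maximal segments coverable by a
chain of reads whose successive placements overlap by at least `w` bases
(at `w = 0`, abutting reads also merge). `true_contigs()` builds it from
known read origins; `estimate_true_assembly()` estimates it for real
reads by sampling one alignment per read from its posterior.

# The reference-free score

The score decomposes as

```
log P(A, D)  ~  log P(D | A, Lambda_MLE)        (corrected likelihood)
             +  log P(A | Lambda_MLE)           (assembly prior)
             -  (1/2) (M + 1) log N             (BIC penalty)
```

with `M` contigs, `N` reads, natural logarithms throughout, and
`Lambda = {lambda_i}` the expected read coverage of each contig's parent
transcript (reads starting per valid position).

**Likelihood.** Reads are modelled as an `M + 1`-component mixture: a
read picks the noise component (weight `theta_0`, emitting bases from a
background distribution) or contig `i` (weight `theta_i`), then a start
position uniform over the contig's `l_i - L + 1` valid positions, an
orientation (1/2 each unless strand-specific), and independent per-base
substitution errors at rate `epsilon` (the three alternative bases
equiprobable). `em_fit()` finds the maximum-likelihood `theta` by EM over
each read's candidate alignments; `lambda_i = N theta_i / (l_i + L + 1)`
— the denominator is deliberately *not* the contig-level `l_i - L + 1`,
because under minimum overlap 0 no reads can have started within `L`
bases of either side of the contig's read footprint, so the estimate is
referred to the parent transcript. The raw likelihood is divided by
`P(C = 1)`, the probability that the model's reads completely cover every
contig with successive overlaps of at least `w`; this conditions the read
model on producing data consistent with the assembly.

**Assembly prior.** Each contig is treated as an independent draw from a
"bag of contigs": a parent transcript length is drawn from a negative
binomial (fit from a known transcriptome by `estimate_prior_params()`, or
the vertebrate-scale default of mean 1500), Poisson(`lambda`) read starts
land at each valid position, and the true contigs at `w = 0` are thrown
into the bag. The prior of the assembly is the product of each contig
length's bag frequency `P(l_i | lambda_i)` times a uniform sequence term
`(1/4)^(total bases)` that penalises assembly size.

**BIC.** One free parameter per contig's coverage plus one for the noise
component.

The **normalised score** subtracts the score of the empty (null)
assembly, whose likelihood explains every read by the noise model.

## The dynamic programs and their oracles

Both `P(l | lambda)` and `P(C = 1)` reduce to chain statistics of
independently occupied start positions (`q = 1 - exp(-lambda)`), where a
contig is a maximal chain of occupied positions at most `G = L - w`
apart. The interior bridge probability `g(d)` between occupied positions
`d` apart satisfies

```
g(d) = q W(d) + [d <= G] u^d ,   W(d) = sum_{j=1..min(G,d)} u^(j-1) g(d-j)
```

with `u = 1 - q`, maintained in O(1) per step by a sliding window.
Expected chain counts add boundary-clearance factors `u^min(G, .)` at
both ends, whose autocorrelation has a closed form beyond `2G`, making
the negative-binomial marginalisation over transcript lengths O(G) per
contig length. The full-coverage probability of a contig of length `l`
is `q^2 g(l - L)` (or `q` for `l = L`).

The derivations are certified by independent Monte-Carlo oracles in the
test-suite, which simulate the processes literally: transcript draws with
geometric gap jumps for the bag distribution (total variation against
the DP at `lambda` in {0.05, 0.5, 5}), and raw Poisson start counts for
the coverage probability. The oracle fixture uses a compact length prior
(NB mean 150, size 20) so that the Monte-Carlo noise floor at 10^6
replicates (~0.005 TV) sits well below the 0.01 equivalence band; with
the wide default prior the floor itself would exceed the band and the
test would measure noise, not correctness.

## Numerical and boundary choices

* Natural logs everywhere (BIC convention).
* Zero-abundance contigs take the coverage floor
  `lambda_min = 1/(l + L + 1)` (one expected read) in the prior and
  correction terms, so an unsupported contig is penalised heavily but
  finitely — chiefly by the `(1/4)^l` size term.
* Contigs shorter than one read (real assemblers emit them; the bag
  process cannot) are charged the length-prior and correction terms at
  the boundary length `L`; likelihood and size prior see the true
  length. Without this the score of, say, an indel-perturbed assembly
  would be NaN.
* The transcript-length truncation bound (default: NB 0.9999 quantile)
  enlarges automatically when a scored contig exceeds it, so fused
  contigs keep a small finite prior instead of an artificial `-Inf`.
* EM: uniform initialisation over the `M + 1` components, relative
  log-likelihood tolerance `1e-4`, at most 1000 iterations; the
  likelihood trace is checked to be non-decreasing in tests.
* The model's `w` (in prior and correction) defaults to 0; the
  uncorrected likelihood deliberately does not check overlap violations.

## Per-contig impact scores

`contig_impact_scores()` compares, for each contig, the hypothesis that
it is a true contig against the hypothesis that its reads are background
noise: the contig's additive share of the total score (its reads'
corrected-likelihood terms apportioned by posterior weight, its prior
terms, its BIC share) minus the probability of those reads under the
noise model with the contig's mixture weight folded into the noise
fraction. Where a contig shares no reads with the rest of the assembly
this equals the leave-one-out score difference exactly (verified to
1e-6 in tests). `trim_assembly()` removes negative-impact contigs.

# Reference-based measures

* **Contig level**: an assembly and a reference sequence match when
  their best local alignment identically recovers at least 99% of the
  non-N length of *both* and its indel bases are at most 1% of either
  length (the stricter reading: percentages relative to full non-N
  sequence length, minimum of the two for indels). Recall and precision
  are read off the maximum-cardinality matching of the match graph
  (computed by igraph).
* **Nucleotide level**: alignments are selected greedily by marginal
  contribution of newly correct reference positions, each position
  assigned to at most one alignment; ties broken by longer alignment,
  then lexicographic ids (determinism). Precision swaps the roles.
* **KC score** `= WKR - ICR`: weighted k-mer recall
  `WKR = sum_{r in kmers(A)} p(r)` with
  `p(r) = sum_b n(r,b) tau(b) / sum_b n(b) tau(b)`, and inverse
  compression rate `ICR = |A| / (N L)`. Default `k = L`. K-mers are
  counted strand-canonically unless the data are strand-specific;
  duplicate assembly k-mers count once. `tau` may be supplied, set
  uniform, or estimated from reads by `em_fit()` against the reference
  (molar abundances: mixture weights divided by effective length).

Local alignments come either from 21-column PSL files (`read_psl()` +
`psl_to_alignments()`, which re-derives per-position identity from the
sequences) or from the built-in seed-and-extend aligner (12-base exact
seeds — small enough that any 50-base alignment at 95% identity contains
one — greedy collinear chaining within a 40-diagonal band, gap stitching
up to 100 bases, X-drop end extension). Its thresholds are documented
knobs; alignment significance is not modelled.

# The simulators and what the experiments show

`simulate_transcriptome()` / `simulate_reads()` generate i.i.d. uniform
transcript sequences with negative-binomial lengths, Dirichlet relative
abundances, and reads drawn with effective-length-weighted transcript
choice, uniform starts, both orientations (unless strand-specific), and
uniform substitution errors. Defaults (`L = 76`, `epsilon = 0.01`,
Dirichlet 0.3, NB lengths) emulate a strand non-specific single-end
short-read study with a broad expression range. The simulators emulate
*placement and substitution noise only*: no positional or sequence bias,
no quality-score structure, no indel sequencing errors, no homologous
gene families (beyond shared isoform structure the user builds
explicitly). Passing tests therefore certify the mathematics and the
implementation, not robustness to every artefact of real libraries.

The benchmark experiments (also run by `scripts/acceptance.R`):

* **Random perturbation** (`perturbation_experiment()`): substitution,
  fission and indel perturbations of a simulated ground truth at rates
  1e-4..1e-2 degrade the mean normalised score monotonically, with zero
  error rate (no perturbed assembly outscoring the truth) at 1e-2. The
  shared study conditions (`perturbation_sim_config()`: 250 transcripts,
  NB mean 800/size 2, Dirichlet 0.3, 200,000 reads) were chosen once so
  the ground truth exceeds 200 contigs and mixes deep and sparse
  coverage; 50 replicates per class in the test-suite, 15 in the
  acceptance script.
* **Guided perturbation** (`guided_experiment()`): over true assemblies
  at `w` in {0, 1, 2, 5, 10, 25, 75}, the full score is maximised at
  `w <= 2` while the bare likelihood keeps rising to `w = 75`. The
  separation rests on the per-junction balance between the roughly
  `2 log((L + 1 - w)/2)` likelihood gain of splitting a sparse junction
  and its `(1/2) log N` BIC cost: at 200,000 reads the cost wins
  decisively, which is why the experiment is run at that scale.
* **Two-isoform scenario** (`two_isoform_scenario()`): a 1,000-base
  isoform equal to the first half of a 2,000-base isoform, 5,000 reads
  of length 100 at 0.01% error, 90:10 read split. Only an
  abundance-aware, mapping-uncertainty-aware score ranks the two-isoform
  truth above both single-isoform assemblies; the package does, in 20 of
  20 seeds in our runs.
* **Score agreement** (`score_agreement_experiment()`): across a spread
  of variants of one read set (truth, trimmed, perturbed), the
  reference-free total and the reference-based KC score agree in rank
  (Spearman at least 0.8).

# Design choices where the ground was open

* **Aligner seeding**: seeds of length `min(25, floor(L/(mm+1)))` with
  `mm + 1` non-overlapping seeds per read guarantee (pigeonhole) that
  every alignment within the mismatch cap is found; a fixed 25-base seed
  cannot give that guarantee for `L < 75` at the default cap of 2.
  Exhaustive scanning covers degenerate cases (tiny reads/contigs).
* **Noise background**: uniform by default; the model carries no
  quality or position terms (the error model is a flat substitution
  rate), which keeps the likelihood orthogonal to base-calling artefacts.
* **Fission** needs the supporting-read layout, so it operates on the
  `true_assembly` object; junction = any position where two successive
  reads merged, overlap duplicated into both fragments.
* **Fusion** joins head-to-tail in sampled order without
  reverse-complementing, collapsing the longest shared end overlap.
* **Indel lengths**: geometric on {1, 2, ...} with success 1/3 (mean 3);
  insertions and deletions equiprobable; a deletion never removes a
  whole contig and each event stays within one contig.
* **Posterior sampling** in `estimate_true_assembly()` uses inverse-CDF
  sampling over the deterministic alignment order, so results are
  bit-reproducible given a seed; noise-sampled reads are dropped; with
  paired reads, pairs whose mates land on different transcripts are
  excluded from scaffolding.
* A read pair with one unalignable mate contributes its alignable mate
  to contig support (the converse convention would discard usable
  coverage).

# Known limitations

* Single-end scoring only; paired-end data enter through true-assembly
  scaffolding and scaffold-level measures, not the likelihood.
* No indel alignments in the read model; indel-perturbed contigs lose
  their reads to the noise component, which is exactly why the score
  punishes indel perturbations strongly.
* The built-in local aligner is tuned for high-identity synthetic
  comparisons; for diverged references import BLAT PSL alignments.
* Scores of assemblies built with genome guidance, or scored against
  reads other than those assembled, are not meaningful under the model.

# Problem sizes used by the test-suite

Chosen as the package's standing study conditions: the shared
perturbation ground truth uses 200,000 reads and 300-370 contigs with 50
replicates per perturbation class; the guided sweep evaluates 7 values
of `w` on the same data; oracle equivalence uses 10^6 bag replicates and
10^5 coverage replicates; the two-isoform scenario runs 20 seeds; EM
recovery uses 5,000 reads. The acceptance script runs the same
experiments with 15 perturbation replicates per class.
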