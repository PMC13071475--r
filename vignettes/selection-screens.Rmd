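---
title: "Codon-model selection tests and convergent substitution screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-model selection tests and convergent substitution screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonsel)
library(ape)
```

## The analysis

`codonsel` implements the comparative-genomic machinery used to ask whether a
designated set of lineages — for example, ferocious carnivorous fishes within
an otherwise omnivorous/herbivorous clade — shows distinctive molecular
evolution in their protein-coding genes. Three complementary questions are
addressed per gene, on a fixed rooted species tree whose branches are
partitioned into *foreground* (the focal lineages) and *background*:

1. **Positive selection** (branch-site test): is there a class of codon sites
   with dN/dS ratio ω > 1 on the foreground branches only?
2. **Rapid evolution** (branch test): is the gene-wide ω higher on foreground
   branches than on background branches?
3. **Convergence**: are there protein sites where every foreground species
   carries one identical residue that no background species has — especially
   at sites otherwise conserved across the background?

Gene sets emerging from these screens are then tested for functional-category
enrichment with a per-category chi-square test.

## The codon substitution model

All likelihood computations use a Goldman–Yang (GY94) codon model on the 61
sense codons of the standard genetic code (stop codons are excluded from the
state space, the convention of codon-model software). The instantaneous rate
from codon $i$ to codon $j$ is

$$
q_{ij} \propto
\begin{cases}
0 & \text{more than one nucleotide change}\\
\pi_j & \text{synonymous transversion}\\
\kappa\,\pi_j & \text{synonymous transition}\\
\omega\,\pi_j & \text{nonsynonymous transversion}\\
\omega\,\kappa\,\pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

scaled so the mean rate at stationarity is one, i.e. branch lengths are
expected substitutions per codon site. ω > 1 indicates positive selection,
ω < 1 purifying selection, ω = 1 neutrality. The model is reversible, so
likelihoods are invariant to rerooting along the same unrooted topology —
one of the properties the test suite checks.

Four model parameterizations are fitted by `fit_codon_model()`:

* **M0** (one-ratio): a single ω for all branches and sites.
* **M2_branch** (two-ratio): ω~bg~ on background and ω~fg~ on foreground
  branches. The LRT of M2 against M0 (df = 1), combined with the requirement
  ω~fg~ > ω~bg~, defines a *rapidly evolving gene* (REG) via `call_reg()`.
* **MA_branchsite** (branch-site Model A): four site classes — purifying
  (ω~0~ < 1 everywhere), neutral (ω = 1), and two classes that switch to
  ω~2~ ≥ 1 on the foreground — with free proportions p~0~, p~1~.
* **MA0_null**: Model A with ω~2~ fixed at 1. The LRT of MA against MA0
  (df = 1, plain chi-square) is the positive-selection test.

Site likelihoods come from Felsenstein pruning over 61 states, with per-node
rescaling accumulated in log space to prevent underflow, alignment columns
compressed to unique site patterns, and transition matrices obtained from the
symmetric eigendecomposition that reversibility affords. Gaps, ambiguous
codons and (in observed data) stop codons are treated as missing data —
partial likelihood one over all states — matching permissive `cleandata = 0`
behavior.

The df = 1 chi-square for the branch-site LRT (rather than the 50:50
point-mass mixture sometimes advocated) was chosen because the branch-test
p-values in the bundled published table are exactly chi-square df = 1, and a
plain chi-square is the more conservative, more common reporting choice.

## Codon frequencies

By default the stationary distribution π is estimated by **F3x4**: the codon
frequency is the product of position-specific nucleotide frequencies,
renormalized over the 61 sense codons. Position frequencies are floored at
10^-6^ before renormalization so that a base missing from one codon position
in a short alignment cannot zero out codons and disconnect the chain; this is
a numerical guard, not a biological prior. `F61` (observed codon frequencies
with a 0.5 pseudo-count) and `uniform` are available behind the `freq`
argument. The simulator deliberately defaults to *uniform* frequencies while
fitting defaults to F3x4: recovery tests therefore also probe robustness to a
mildly misspecified frequency model.

## Optimization

Fits use bounded L-BFGS-B on log-transformed rates, with bounds
ω ∈ [10^-6^, 50], κ ∈ [10^-3^, 100]; Model A proportions use a
stick-breaking pair so box constraints suffice. One deterministic start is
supplemented by seeded random restarts (`n_starts`, default 3); the reported
`converged` flag is the optimizer's own and is never overridden. Branch
lengths are taken from the input species tree, as in analyses that fix a
genome-wide tree per gene. The convergence tolerance is `factr = 1e4`
(≈10^-8^ relative on the log-likelihood). Nested-model monotonicity
(lnL(M2) ≥ lnL(M0), lnL(MA) ≥ lnL(MA0)) is asserted in tests up to 10^-6^.

## Empirical-Bayes site posteriors

`site_posteriors()` reports, per codon site, the posterior probability of
the positive-selection classes of Model A, computed by naive empirical Bayes
(NEB) at the maximum-likelihood estimates; the output records the flavor so
downstream thresholds are interpretable. Full Bayes-empirical-Bayes
integration over a parameter grid is not implemented; at the alignment sizes
where the screen is applied the MLEs are well informed and NEB is the
standard first-order approximation. A practical limit documented by our
simulations: with only a handful of selected sites in a long gene, per-site
posteriors vary with the substitutions a site happens to draw, so single
sites are not guaranteed to cross a 0.95 threshold even when the gene-level
LRT is strongly significant. The tests therefore assert rank enrichment of
planted sites (plus a top-decile best site) rather than a uniform per-site
guarantee, and gene-level power is assessed at study-scale conditions (12
taxa, 5 foreground, 500–1000 codons, 25% selected sites) where planted genes
are recovered as PSGs with all candidate sites genuinely selected.

## PSG and REG decision rules

`filter_psg()` applies, after the branch-site LRT, the conservative site
filters used in genome-scale screens. A gene is called a **PSG** only when

* LRT p < α (default 0.05, raw — no multiple-testing correction by default,
  `p.adjust` available behind a flag elsewhere in the workflow),
* at least one site has posterior ≥ 0.95,
* candidates do **not** include a run of ≥ 3 consecutive codon positions
  (a signature of alignment error rather than selection),
* no candidate falls on the first or last codon of the coding sequence.

"Start or end" is read literally as the first and last codon position; the
consecutive-run rule counts consecutive candidate codon indices, and
alignment gaps do not reset a run. All triggered rejection reasons are
reported together, so the filters are order-independent by construction.
The rules are applied to candidates at the ≥ 0.95 threshold (not to
sub-threshold sites), which is the reading that makes the low-posterior rule
and the run rule compose coherently.

## The convergence screen

`run_convergence_screen()` chains four stages over per-gene protein
alignments, with per-stage counts that can only narrow:

1. **Detection** (`detect_shared_substitutions()`): columns where all
   foreground (IN_list) taxa share one residue that no background (ON_list)
   taxon carries. Columns with a foreground gap/X are skipped; background
   gaps are flagged but retained. An optional `on_mode = "majority"` relaxes
   the background condition to "differs from the ON majority residue", which
   is the variant under which the next filter has work to do.
2. **Background-sharing filter** (`filter_background_shared()`): any gene in
   which some ON taxon carries the foreground residue at a called column is
   removed *whole* — partial convergence in the background disqualifies the
   gene, not just the site.
3. **Conservative sites (CCs)** (`conservative_site_filter()`): a call
   survives only where the background (ON plus optional outgroup) is
   conserved. The cited conservation statistic is not fully specified in the
   literature this screen descends from, so two explicit modes are provided:
   strict residue identity at a configurable fraction (default 1.0), and a
   property-class mode in which residues of one biochemical class (e.g.,
   lysine and arginine, both basic) count as conserved. The mode used is
   recorded in the output. The property mode exists precisely to admit
   basic→neutral cases such as a K/R background replaced by Q.
4. **Domain annotation** (`annotate_domains()`): 1-based closed-interval
   containment of the site in a supplied domain table; annotation never
   changes the site count. Coordinates are ungapped positions of a reference
   taxon (default: the first IN_list taxon), since published residue numbers
   rarely state their reference alignment.

Property changes are classified with a fixed four-class scheme —
hydrophobic (G A V L I P F M W), polar/uncharged-hydrophilic (S T C Y N Q),
basic (K R H), acidic (D E). The literature's informal labels "hydrophilic"
(for S) and "neutral" (for Q) both denote the polar class here. Glycine is
classed hydrophobic, following the usage in the structural argument this
classification supports.

## The simulator

`simulate_alignment()` evolves codon sequences on the fixed tree: a root
codon per site is drawn from `codon_freqs`, then each branch applies its
GY94 transition matrix (foreground branches use `omega_foreground`).
Per-branch RNG streams are seeded deterministically from the root seed and
the child node id, so subtree draws do not depend on traversal order and a
fixed seed yields byte-identical FASTA. There are no indels, no among-site
rate variation beyond the two-ω/branch-site structure, and no gene-family
birth–death — synthetic alignments are gap-free and cleanly aligned, so
passing screens on them validates the statistics and the decision rules,
*not* robustness to alignment error, which real data would add.

`plant_convergent_substitutions()` creates ground truth for the convergence
screen: at chosen positions where the background is conserved, every
foreground tip is forced to a codon of a chosen different residue. The
planted-truth tests require the full screen to return exactly the planted
sites (precision = recall = 1) for 0, 1 and 5 planted sites.

Default study conditions mirror a genome-scale screen of this kind: a
12-taxon tree with 5 non-monophyletic foreground tips, branch lengths of
0.3–0.4 substitutions per codon site (deep, order-level divergences),
κ = 2, purifying background ω = 0.2. A branch is foreground iff all tip
descendants of its child are foreground, plus foreground terminal branches —
so a non-monophyletic foreground set flags exactly its terminal branches and
any pure-foreground internal branches.

## Worked example

A miniature end-to-end run (sizes kept small for the vignette):

```{r example, eval = FALSE}
tree <- tag_foreground(
  read.tree(text = "((a:0.3,b:0.3):0.2,(c:0.3,d:0.3):0.2):0;"),
  c("a", "b"))

# a gene accelerated on the foreground, and a control
fast <- simulate_alignment(simulation_config(
  tree, 400, omega_background = 0.2, omega_foreground = 4, seed = 51))
flat <- simulate_alignment(simulation_config(
  tree, 400, omega_background = 0.2, seed = 53))

res <- run_selection(list(fast = fast, flat = flat), tree,
                     tests = "branch", n_starts = 1)
res$calls[, c("gene_id", "p", "omega_bg", "omega_fg", "verdict")]
```

The branch screen calls `fast` a REG (LRT p far below 0.05 with
ω~fg~ > ω~bg~) and rejects `flat`. The same orchestration runs the
branch-site screen (`tests = "branch_site"`) and file-based configurations
via `pipeline_config()`.

## Numerical and degenerate-input choices

* Transition-probability matrices are clamped at zero from below after the
  eigendecomposition reconstruction (entries of order −10^-16^ can occur).
* Pattern compression keys include missing states, so gap columns are shared
  correctly.
* A single-sequence "alignment" has likelihood ∏ π(codon); no tree needed.
* An LRT statistic that comes out negative by optimizer tolerance is clamped
  to 0 (p = 1).
* Internal stop codons are fatal in back-translation; one trailing stop is
  trimmed silently. Translation mismatches name the taxon and position and
  abort rather than dropping taxa.
* In enrichment, a degenerate 2×2 table (no contrast) reports χ² = 0, p = 1;
  expected cells < 5 are flagged rather than switched to an exact test, no
  continuity correction by default (Yates behind a flag).

## Problem sizes used in validation

The shipped tests validate: brute-force likelihood equality on ≤ 4-taxon,
≤ 3-codon fixtures (tolerance 10^-8^ in log space); M0 recovery at ω ∈
{0.2, 1, 3} with 2000 codons (±25% relative); branch-LRT power at
ω~fg~ = 4 vs ω~bg~ = 0.2 with 300 codons (≥ 8/10 replicates); branch-site
PSG recovery at 500–1000 codons; and the convergence screen on 100-codon
genes. These sizes were chosen to exercise each statistic in its informative
regime while keeping the default validation run fast on one CPU.

## Known limitations

* NEB (not full BEB) site posteriors; see above.
* No codon models beyond the GY94 family; no site-model suite (M1a/M2a/
  M7/M8), no tree search, no divergence dating, no gene-family dynamics.
* Branch lengths are fixed at the input tree; joint branch-length
  estimation is out of scope.
* The conservation filter is a declared approximation to the cited
  convergence-at-conservative-sites method, with its two modes reported
  explicitly.
* Multiple-testing correction is off by default to match the screening
  convention this package reproduces; for genome-scale use, switch on
  Benjamini–Hochberg via the `adjust` argument of `enrichment_test()` and
  treat per-gene p-values accordingly.
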