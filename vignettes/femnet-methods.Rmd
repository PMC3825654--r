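---
title: "Methods: differential methylation hotspots and functional epigenetic modules"
author: "femnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation hotspots and functional epigenetic modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Cancer methylomes contain thousands of differentially methylated CpGs.
Ranking CpGs one at a time leaves two questions open: which of these events
are *coordinated* — concentrated in an interacting group of gene products —
and which are *functional*, i.e. accompanied by the transcriptional change
that promoter methylation is expected to cause. femnet addresses both with
a two-step network analysis over a user-supplied protein-interaction
network (interactome):

1. **EpiMods** — connected subnetworks whose gene promoters carry unusually
   strong differential methylation between the two phenotype groups.
2. **FEMs** (functional epigenetic modules) — EpiMods whose genes also show
   differential mRNA expression *anti-correlated* with the methylation
   change (promoter hypermethylation with under-expression or the
   reverse). An EpiMod that fails this filter is a methylation hotspot with
   no transcriptional correlate — biologically interesting, but not
   evidence of functional deregulation.

# Per-CpG statistics

For each CpG the binary phenotype is regressed on the beta-value
(`phenotype ~ intercept + beta`, logistic link) and tested with a
likelihood-ratio chi-square on 1 df. The beta-value itself is the
predictor; an M-value transform is deliberately not applied, keeping the
model on the scale the arrays report. The effect size is the median
beta difference (case − control). False discovery rates use Storey
q-values: the null proportion pi0 is estimated by the smoother method over
lambda = 0.05, …, 0.95 with inverse-variance weights `1 − lambda` (the
high-lambda end of the pi0(lambda) curve is the most informative but also
the noisiest; the weights stabilise the spline's extrapolation). With pi0
pinned to 1 the q-values reduce exactly to Benjamini–Hochberg — a test in
the suite asserts bitwise equality.

Complete separation (common at large effect sizes with clean groups) is
detected when the fitted slope passes ±50; the slope is pinned there, the
intercept re-profiled, and the CpG flagged. This keeps the statistic — and
the CpG ranking — finite without introducing a penalised model.

Each CpG/gene receives the signed normal-scale statistic
`z = sign(delta) · Φ⁻¹(1 − p/2)`, which preserves the ranking by p and
gives hyper- and hypomethylation opposite signs. Gene-level statistics take
the CpG *closest to the TSS* (smallest |signed distance|; ties prefer the
upstream CpG, then the lexicographically smaller CpG id, making the mapping
deterministic).

# The weighted network and the search objective

Nodes carry weight `|z|` (0 for genes without array coverage — they stay in
the network so topology is preserved); an edge weighs the mean of its
endpoint node weights. The analysis runs on the largest connected
component.

A module is a connected subgraph S containing a seed gene, scored by a
seeded spin-glass (constant Potts) objective:

    Q(S) = Σ_{edges inside S} w_ij − γ · ŵ · |S|(|S|−1)/2

where ŵ is the network-mean edge weight. Every *pair* inside the module is
charged γ·ŵ — the expected weight of a random edge under degree-preserving
rewiring — so a module must both be densely connected and carry edge
weights above the network's background level. Two properties anchor the
form: with γ = 0 the objective is monotone in edge count (a pure
edge-weight collector), and at γ = 1 a heavy clique attached by one bridge
edge to a quiet path is scored optimally as exactly the clique
(the exhaustive-enumeration oracle test).

Two more familiar candidates were considered and rejected for the seeded
setting. The configuration-model penalty `s_i s_j / 2W` evaluated on
existing edges only is O(1/|E|) of a typical edge weight on a sparse
interactome, so the objective degenerates into edge collecting. The
all-pairs configuration penalty behaves correctly for global partitions,
where boundary genes can defect to competing communities, but a *seeded*
search has no competing community: a background gene adjacent to a strong
module inherits half the module's signal through the edge-weight averaging
and is absorbed, inflating modules with their entire first neighbour ring.
The constant-Potts charge, being proportional to module size, is the
simplest form that resists this absorption; planted-module recovery in the
acceptance suite (F1 ≥ 0.8 required, ≈ 0.95 observed) pins the behaviour.

**Optimisation.** Simulated annealing over add-a-boundary-neighbour /
remove-a-member moves (connectivity through the seed enforced), geometric
cooling from T = 2ŵ to 0.02ŵ at ratio 0.95, 15 proposals per temperature
level per member, 2 restarts, followed by a greedy polish to a local
optimum. Temperatures scale with ŵ so the schedule is invariant to the
statistic scale. The schedule is intentionally light: the permutation null
re-runs the full search hundreds of times per module, so the search budget
multiplies through everything. Its adequacy is pinned by the oracle test —
on 100 random 8–12-node weighted graphs the returned objective reaches at
least 0.99× the exhaustive optimum in ≥ 95% of instances (0.98 observed).

# Significance: two null models

**Statistic permutation (the p-value source).** Node statistics are
shuffled over the nodes, edge weights recomputed, and the *entire*
detection pipeline re-run — seed re-selection, growth, overlap collapse,
ranking — with the observed rank-r modularity (mean internal edge weight)
compared against the null rank-r modularities:
`p = (1 + #{null ≥ observed}) / (B + 1)`. Re-running only the search at the
*same* seed would be anti-conservative at the detection level, because
seeds are chosen as the top-|z| nodes of the observed statistics; under a
same-seed null the observed seed keeps its selection advantage. Matching
the whole selection procedure restores exchangeability, and the
calibration test (200 null networks) checks that the EpiMod rate at
alpha = 0.05 stays inside the 95% binomial band of 0.05. The same-seed
mode remains available as `permutation_pvalue()`, which is calibrated
whenever the seed is fixed a priori rather than data-selected.

**Degree-preserving rewiring (a diagnostic).** Each module also reports the
gap between its observed modularity and the mean modularity obtained by
regrowing from the same seed on double-edge-swap rewirings of the network.
This says how much of the hotspot is carried by the specific wiring rather
than by the statistics; it is reported, not used for the p-value.

Seeds are the top `n_seeds` genes by |z| (default 100). Modules sharing
more than half of the smaller one's members are collapsed, keeping the
higher modularity, so reported hotspot counts are well defined. The
significance level alpha = 0.05 is applied per module without multiplicity
correction across seeds — EpiMod counts are descriptive, not a
family-controlled discovery list.

# Step 2: the expression filter

Per-gene differential expression uses a two-sided Wilcoxon rank-sum test
(a Welch t option exists), converted to a signed `z_expr` like the
methylation statistic. The expression cohort is typically *different* from
the methylation cohort, so integration happens purely at the statistic
level. The integrated node weight is

    w = (|z_dnam| + |z_expr|)/2   if sign(z_dnam)·sign(z_expr) < 0, else 0

— magnitudes average, but only when the directions are anti-correlated;
genes with missing expression weigh 0.

The network is rebuilt with these weights and the search re-run from each
EpiMod seed. The FEM p-value permutes the *expression* statistics over the
measured genes while the methylation layer stays fixed. This conditional
null asks exactly the step-2 question: *given* this methylation hotspot,
is the anti-correlated expression inside it stronger than chance? A
tuple-permutation mode (shuffling paired `(z_dnam, z_expr)` over nodes) is
also provided, but it answers a different question — "is there any
integrated hotspot at all" — and a hotspot with an overwhelming
methylation signal passes it even when its expression is pure noise,
because the sign gate only halves a signal that is many times the
background. The conditional null is the default precisely so that a
methylation-only hotspot (the situation the FEM filter exists to catch) is
*not* called functional; the synthetic contrast test (anti-correlated
expression → FEM; uncorrelated expression → EpiMod-only) checks both arms.

# Gene-set enrichment

Over-representation of the hyper- and hypomethylated gene lists (q < 0.1
calls, collapsed to genes) is tested per gene set with a one-tailed Fisher
exact test inside the universe of genes that have a statistic — not the
whole genome — with BH correction within each direction's table. The odds
ratio is the plain cross-product `a·d/(b·c)` with a Woolf CI
(Haldane-corrected at zero cells). Working at the gene level, after the
closest-to-TSS collapse, prevents genes with many probes from being
counted repeatedly.

# The synthetic benchmark

`simulate_fem_dataset()` generates the three-layer data the method
consumes, with ground truth:

* **Interactome**: preferential attachment (m = 2, started from two
  unlinked founders, so exactly `2(n−2)` edges) or Erdős–Rényi stitched to
  connectivity. The planted module is a random spanning tree over the
  planted genes plus extra internal edges to 50% internal density —
  guaranteed connected, embedded in the ambient topology.
* **Methylome**: per CpG a baseline mean mu ~ U(0.1, 0.9) and beta values
  from a Beta distribution with precision (a+b) = 50, approximating the
  boundary-compressed dispersion of 27K-style array betas. Planted genes'
  promoter CpGs get the case mean shifted by `delta_beta` (clipped into
  (0.01, 0.99)). Defaults: delta_beta = 0.3, 50 cases / 50 controls —
  a strong, clean two-group design of the kind the method was built for.
* **Transcriptome**: log-scale Gaussian N(8, 1), planted genes shifted
  down by `delta_expr` (default 1.5) in cases, in an *independent* cohort
  (default 40/40), mirroring the separate-cohort integration design.

What the generator does *not* emulate: probe chemistry and
cross-hybridisation, batch effects, cell-type mixture, correlated
background methylation, or hub-biased placement of signal. Passing the
recovery tests therefore demonstrates the algorithmic pipeline — not
robustness to the full messiness of real array data.

# Numerical choices and degenerate inputs

* p-values are floored at 1e-300 so downstream `(0, 1]` invariants survive
  underflow; `z` is computed through the upper-tail `qnorm` for precision.
* Modules need ≥ 2 members and ≥ 1 internal edge; inside permutation loops
  a degenerate module scores modularity 0 (the permutation statistic must
  be total).
* A constant-beta CpG returns LRT 0, p 1 rather than an error; CpGs that
  lose a class to missing values return NA statistics and are omitted from
  gene mapping.
* Annealing randomness comes from R's RNG: any run is reproducible from a
  single `set.seed()`, and the CLI records the seed in its manifest.
* Ties in the closest-to-TSS rule and in the overlap collapse are broken
  deterministically (upstream CpG, then id; higher modularity first).

# Problem sizes used by the test-suite

The suite exercises the statistical claims at deliberately desk-scale
sizes: 100 graphs of 8–12 nodes for the exhaustive oracle; 200 null
networks of 300 nodes with B = 200 permutations for calibration; one
500-node scale-free benchmark (10 planted genes, delta_beta 0.3, 50/50)
with 15 seeds and B = 100 for recovery and the FEM contrast; 2,000 null
CpGs at n = 100 for LRT uniformity; 1,000 rewiring trials. The whole suite
runs in well under five minutes on one core. Production runs (e.g.
n_seeds = 100, B = 1000 on a 10^4-node interactome) scale linearly in
seeds × permutations and are an overnight-scale computation.

# Known limitations

* The closest-to-TSS rule uses one CpG per gene; multi-promoter genes and
  probe-sparse promoters are represented by a single, possibly
  unrepresentative probe.
* No covariates by default; confounding (age, cell composition) must be
  handled upstream if present.
* The permutation null treats gene statistics as exchangeable across the
  network; spatially correlated methylation (e.g. long hypomethylated
  blocks) violates this and would inflate hotspot significance.
* The interactome is taken as given; hub bias and literature bias in
  interaction databases propagate directly into which hotspots can be
  found.
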