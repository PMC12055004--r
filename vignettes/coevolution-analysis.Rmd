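---
title: "Mirrortree coevolution analysis: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirrortree coevolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevotree)
```

## The method

The mirrortree idea is that two proteins under shared selective pressure
accumulate substitutions at correlated rates across the branches of the
species phylogeny, so their pairwise distance matrices — each a summary of
one family's tree — correlate strongly over the organisms both families
occupy. `coevotree` implements this as a pipeline with two interchangeable
distance front ends and a common statistical back end.

**Distances.** In genetic-distance mode, the divergence between two aligned
protein sequences is estimated by maximizing the likelihood
$\sum_{\mathrm{sites}} \log\!\big(\pi_a\, [e^{Qd}]_{ab}\big)$ over
$d \ge 0$, where $Q$ is the Jones–Taylor–Thornton (JTT) generator built
from the published exchangeability counts and equilibrium frequencies,
rescaled to one expected substitution per site per unit branch length.
Site rates are uniform: no gamma heterogeneity, no partitioning. In
patristic mode, the distance between two organisms is the sum of branch
lengths on the path connecting their leaves in a supplied tree; the package
parses Newick (tolerating support labels), and can itself build
neighbor-joining trees, but deliberately does not search tree space —
likelihood or Bayesian trees are consumed as Newick input.

**Statistics.** The two matrices are restricted to their common organisms,
sorted alphabetically (C-locale radix order, so the ordering is
platform-independent), and the strict upper triangles are vectorized as the
paired observations entering the Pearson correlation $r$. The Fisher
transform $r' = \tfrac12\ln\frac{1+r}{1-r}$ is approximately normal with
variance $1/(N-3)$ in the number of organisms $N$, so two correlations are
contrasted with $z = (r'_1 - r'_2)\big/\sqrt{1/(N_1-3) + 1/(N_2-3)}$ and a
standard-normal tail. `control_panel_analysis()` applies this target
against a panel of control correlations and flags whether the target $r$
clears the decision cutoff.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `cutoff` | 0.8 | decision threshold on the target $r$; the conventional empirical mirrortree cutoff, see *Baseline inflation* below |
| `max_distance` | 10 | substitutions/site; saturation cap for the ML distance |
| `tol` | 1e-8 | convergence tolerance of the bounded scalar optimizer |
| `n_replicates` | 1000 | bootstrap column resamples for distance standard errors |
| `rho` | — | between-gene branch-rate correlation of the simulator, in [0, 1] |
| `rate_sd` | 0.5 | SD of log branch-rate multipliers in the simulator |
| `birth_rate` | 1 | Yule speciation rate; only sets the overall depth scale |
| `sign_convention` | `"equation"` | `z = (r'_1 - r'_2)/SE`; `"flipped"` negates z so a stronger first correlation is negative |
| `alternative` | `"two.sided"` | normal tail for the p-value; one-sided available by flag |

Bootstrap standard errors are reported alongside the distances but never
propagated into the correlation point estimate: the correlation is computed
from the point distances only.

## What the synthetic generator emulates — and what it does not

Real mirrortree inputs are curated ortholog sets collected per gene family.
No such set ships here; instead `simulate_coevolution_study()` generates
the *statistical structure* the analysis assumes:

- a shared species tree (pure-birth Yule — the simplest process giving
  realistic ultrametric-ish trees; the choice only matters through the
  spread of the true distances);
- per gene and per branch, a lognormal rate multiplier
  $\exp(\epsilon - \sigma^2/2)$ with $\epsilon \sim N(0, \sigma^2)$, mean-
  corrected so the expected branch length is preserved. For the target
  pair the two genes' $\epsilon$ draws are bivariate normal with
  correlation $\rho$ — the explicit, tunable stand-in for "shared
  evolutionary pressure". $\rho = 1$ makes the gene trees identical,
  $\rho = 0$ makes their rate noise independent;
- protein sequences evolved site-independently under JTT, drawn from
  equilibrium at the root. `rate_sd = 0.5` is used as the default noise
  level: rate variation of roughly ±65% per branch (one lognormal sd),
  comparable to the between-lineage rate scatter seen in fungal protein
  families, while leaving the species-tree signal clearly recoverable.

Not emulated: indels and alignment error (alignments are gap-free),
site-rate heterogeneity, domain gain/loss, gene duplication/loss,
horizontal transfer, and ortholog-misassignment noise. Passing the
simulation-based checks therefore demonstrates that the *statistics* behave
as designed under the model's own assumptions — not that a particular real
gene pair coevolves, and not robustness to alignment or orthology errors.

## Baseline inflation and the 0.8 cutoff

Both gene trees descend from the same species tree, so even at $\rho = 0$
their patristic matrices share the deep structure of the phylogeny and the
mirrortree correlation is far above zero. `run_validation_suite()` and
`scripts/acceptance.R` measure this baseline directly (50 species,
`rate_sd = 0.5`, 50 replicates per $\rho$): the mean $r$ at $\rho = 0$ is
large and its confidence interval excludes zero, and the mean $r$ rises
monotonically with $\rho$. This inflation is exactly why a stringent
empirical cutoff (0.8) is used for calling coevolution rather than a test
against $r = 0$, and why the control-panel comparison — is the target's
correlation significantly above those of unrelated conserved genes? —
carries more weight than the absolute value of $r$. The specificity of the
cutoff at a given `rate_sd` is reported by the validation run, not asserted
as a universal constant, since it depends on the noise level.

## Numerical choices

- **Gap handling:** pairwise deletion — a site is dropped for a pair if
  either member has a gap; ambiguity codes (B, Z, X, U, O, J) are treated
  as gaps. A pair with no comparable sites raises an error naming the pair.
- **Saturation:** the ML optimizer runs on $[0, 10]$ substitutions/site;
  an optimum pressed against the cap is clamped to it and flagged
  `saturated` rather than chasing an unbounded maximum. Identical
  sequences short-circuit to exactly 0.
- **Transition matrices** come from the eigendecomposition of the
  symmetrized generator ($\pi^{1/2}$-similarity transform), so the spectrum
  is real and $e^{Qd}$ is stable at any depth; tiny negative entries from
  roundoff are truncated at zero.
- **Degenerate correlations:** a distance vector with zero variance is an
  error; $|r| = 1$ (e.g. identical matrices) is representable, with
  $r' = \pm\infty$ carried rather than raised, while the standalone
  `fisher_transform()` enforces $|r| < 1$.
- **Common-taxa overlap** below 4 organisms is refused: $1/(N-3)$ is
  degenerate there.
- **Neighbor joining** uses the classic Saitou–Nei agglomeration; negative
  inferred branch lengths are clamped to zero with a count reported. On an
  additive matrix the reconstruction reproduces the input patristic matrix
  to numerical precision (the round-trip test asserts 1e-9); the
  minimum-evolution trees of external software are approximated by NJ when
  not supplied as Newick.
- **Taxon matching** is exact string equality; no normalization or fuzzy
  mapping is applied, no imputation of missing organisms.
- **No normalization across tree methods** before correlating (min-max
  rescaling is available but off by default; the Pearson correlation is
  invariant to it anyway).
- **No multiple-testing correction** across a control panel by default;
  the per-control z tests are descriptive. `p.adjust` can be applied to
  the reported column if desired.
- **Seeding:** every stochastic function takes a `seed`; a run-level seed
  fans out deterministically to stage-specific child seeds, and fixed seeds
  give byte-identical FASTA/Newick/JSON outputs.

## Validation problem sizes

The shipped test suite and acceptance script exercise the pipeline at desk
scale, chosen so the whole suite runs in well under a minute of simulation
per check: estimator consistency uses 100 replicate sequence pairs per true
distance at 50,000 sites; the $\rho$ sweep uses 50-species trees with 50
replicates per grid point; the control-panel experiment repeats a
1-target/8-control design 100 times. These sizes give Monte-Carlo errors
comfortably below the asserted margins.

## Known limitations

- Mirrortree without background correction: the shared species-tree signal
  is not subtracted (no tol-mirrortree/ContextMirror variants), which is
  why conclusions rest on control panels and a stringent cutoff.
- Uniform site rates and a single empirical matrix (JTT); families evolving
  under strongly heterogeneous or compositionally biased processes will
  have biased distances.
- The z test treats the two correlations as independent; when both involve
  the same target gene (as in a control panel) this is an approximation.
- Patristic-mode results inherit whatever estimation error the supplied
  trees carry; the package does not re-estimate them.
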