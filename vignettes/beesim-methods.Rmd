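---
title: "Simulating long-term honeybee breeding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating long-term honeybee breeding: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

beesim simulates a closed honeybee breeding program year by year and asks
how predictions of genetic gain, genetic variance, inbreeding and
estimation bias depend on the underlying genetic model. This vignette
documents the model, the tunable parameters, the numerical choices and
the places where the design was genuinely open — and what our choices
were.

## The biological model

A colony consists of one queen and her worker group. The selected trait
has a maternal component expressed by the queen (egg laying, pheromones)
and a direct component expressed collectively by the workers (foraging,
hygienic behaviour). The colony phenotype is

$$ y \;=\; \mathrm{TBV}^m_Q + \mathrm{TBV}^d_W + e, \qquad
   e \sim N(0, \sigma^2_E), $$

and the genetic part $PC = \mathrm{TBV}^m_Q + \mathrm{TBV}^d_W$
("performance criterion") is what selection should improve. Breeding
values are bivariate (direct $d$, maternal $m$) with founder covariance

$$ \Sigma_A = \begin{pmatrix} \sigma^2_{Ad} & \sigma_{Amd} \\
                              \sigma_{Amd} & \sigma^2_{Am} \end{pmatrix}. $$

Defaults (trait units²): $\sigma^2_{Ad} = 2$, $\sigma^2_{Am} = 1$,
$\sigma^2_E = 1$ and $\sigma_{Amd} = -0.25$ (genetic correlation
$r_{md} = -0.18$); the strong-antagonism variant uses
$\sigma_{Amd} = -0.75$ ($r_{md} = -0.53$). These combinations mirror
heritability estimates reported for commercial honeybee traits, where
direct and maternal effects are consistently negatively correlated.

Drones are haploid: they arise from unfertilized eggs, carry one maternal
genome, and transmit it whole. A queen mates once with 12 drones from a
single mating station of 8 sister drone-producing queens (DPQs); the
worker group is the infinite-worker average over that polyandrous mating,

$$ \mathrm{TBV}_W = \tfrac12\!\left(\mathrm{TBV}_Q +
   \overline{\mathrm{TBV}}_D\right). $$

## The two genetic engines

**Infinitesimal (INF).** Founder queens draw
$\mathrm{TBV} \sim N(0, \Sigma_A)$. Inheritance with exact inbreeding
correction:

$$ \mathrm{TBV}_Q = \tfrac12\left(\mathrm{TBV}_B + \mathrm{TBV}_D +
      \sqrt{1 - F_B}\,\Phi\right), \qquad
   \mathrm{TBV}_D = \mathrm{TBV}_Q + \sqrt{1 - F_Q}\,\Phi, $$

with $\Phi \sim N(0, \Sigma_A)$ independently per individual. Because the
sire drone passes his entire genome, only the dam side contributes
Mendelian sampling: a queen's Mendelian variance is
$(1 - F_B)\Sigma_A/4$ and a drone's $(1 - F_Q)\Sigma_A$. These are
exactly the Mendelian terms implied by the haplodiploid relationship
matrix when drones are treated as diploid-but-homozygous (relationship
diagonal 2), which is why no "corrected" variant of the inheritance
formula is needed: simulated TBV variances reproduce the relationship
diagonals (the test suite replays small pedigrees to confirm this).
$\Sigma_A$ itself is never shrunk during a run — selection does not
change the Mendelian sampling variance under the infinitesimal model,
only the $(1-F)$ factors do.

**Finite locus (FL200, FL400).** The trait is controlled by $n = 200$ or
$400$ unlinked biallelic loci, all potentially pleiotropic. Founder
construction:

1. frequencies $p_1 \sim \mathrm{Beta}(0.5, 0.5)$ (U-shaped, most loci
   near fixation, as expected for standing variation);
2. raw bivariate effects
   $e \sim 0.95\,L(0, \Sigma_A) + 0.05\,N(0, \Sigma_A)$ — heavy-tailed,
   so a minority of loci carry large effects. The multivariate Laplace is
   generated as the Gaussian scale mixture $e = \sqrt{W} z$ with
   $W \sim \mathrm{Exp}(1)$, $z \sim N(0, \Sigma_A)$, which has
   covariance exactly $\Sigma_A$ and marginal excess kurtosis 3. The
   original generator's Laplace parameterization is not published beyond
   its covariance; the covariance calibration is the contract we adopt
   and test;
3. preliminary allele effects
   $\tilde E_1 = (p_2 - p_1 + 1)\,e/\sqrt{n}$,
   $\tilde E_2 = (p_2 - p_1 - 1)\,e/\sqrt{n}$, giving zero mean at every
   locus. We read the scaling as $1/\sqrt{n}$: the per-locus diploid
   variance is $2 p_1 p_2 (\tilde E_1 - \tilde E_2)(\cdot)' =
   8 p_1 p_2\, e e'/n$ and $E[8 p_1 p_2] = 1$ under Beta(0.5, 0.5), so
   only $\sqrt{n}$ makes the expected total variance $\Sigma_A$ (a $1/n$
   reading would give $\Sigma_A/n$);
4. post-correction $E_{1,2} = \Sigma_A^{1/2} \tilde\Sigma_A^{-1/2}
   \tilde E_{1,2}$ with symmetric PSD matrix roots via
   eigendecomposition, after which the realized variance equals
   $\Sigma_A$ to 1e-8 for every seed. Inverse roots guard eigenvalues
   below 1e-12 and raise a degenerate-draw error (the caller redraws).

Genomes are stored as per-locus allele counts (0/1/2 for queens, 0/1 for
drones): with unlinked loci the two strands are exchangeable, so counts
are a lossless representation and gamete sampling reduces to a Bernoulli
draw at heterozygous loci. No mutation, dominance, epistasis, linkage or
csd sex locus; drone TBVs are twice the haploid genome sum.

## Pedigree, kinship and inbreeding

All queens, all drones and all worker groups are pedigree nodes with
strictly increasing ids. Coancestry follows the haplodiploid rules
(queen: average over dam and sire drone; drone: his dam, with
$f(D,D) = 1$; worker group: bilinear with weights 1/2 and 1/24), and
inbreeding is the coancestry of a queen's parents. Because drones are
individual nodes, sibling relationships take their exact values — two
daughters of one dam have additive relationship anywhere between 0.25
(different sire drones from unrelated DPQs) and 0.75 (same sire drone) —
rather than field approximations.

Inside the simulation loop, kinship is maintained as a dense matrix over
the queens of the last four cohorts (all possible parents), updated
generation-wise from parent rows with a correction for shared sire
drones. This is exact and avoids recursion; a gene-dropping oracle and an
independent iterative tabular implementation verify it in the tests.

## The yearly BLUP and its solver

Every year from year 2 on, all colony records to date enter

$$ y = \mathbf{1}\mu + Z_d u_d(\text{worker group}) +
       Z_m u_m(\text{queen}) + e, \qquad
   u \sim N(0,\, A \otimes \Sigma_A), \; e \sim N(0, I\sigma^2_E), $$

with fixed $\Sigma_A$, $\sigma^2_E$ (no re-estimation, deliberately — the
bias this induces in the finite-locus engines is one of the phenomena
under study). A single overall mean is the only fixed effect: the
simulation generates no year or apiary environmental effects, so a
richer fixed-effect structure would only absorb genetic trend; this was
an open design point and we chose the minimal model.

$A^{-1}$ is assembled directly from the regression of each node on its
parents ($A^{-1} = U' D^{-1} U$). The mixed-model equations are solved by
sparse Cholesky factorization (CHOLMOD via Matrix) at every problem
size; we chose a direct solver over iterative schemes because the
factorization of these pedigree-structured systems is cheap, exact and
free of convergence diagnostics. Two structural reductions keep the
system small and well conditioned without changing the solution:

* Worker groups are exact linear combinations of their members, which
  makes $A$ singular. In the default *exact* paternity mode, drones that
  have no offspring at evaluation time appear only through their 1/24
  weight in one worker group, so they are marginalized analytically: the
  worker group regresses on the queen, the retained (sire) drones and the
  folded drones' dams, and receives the folded Mendelian variance
  $\sum (1 - F_{\text{dam}})/576$ as its residual diagonal. Their BLUPs
  are recovered afterwards from the worker-group residual. This is the
  $\varepsilon \to 0$ limit of the $\varepsilon$-regularized worker-group
  rows that `build_sparse_A_inverse()` offers (default
  $\varepsilon = 10^{-8}$), and the dense-GLS oracle in the test suite
  confirms agreement to $10^{-6}$ on problems with hundreds of records.
* In the *expected* paternity mode (the default) drones drop out
  entirely: a queen regresses 1/2 on her dam and 1/16 on each DPQ of her
  dam's station, and a worker group receives the drone-sampling diagonal
  $(1 - \bar f_{\text{station}})/24$. The expected-mode kinship table is
  maintained separately so this $A$ is internally consistent and PSD.
  This mode is the default because it is how honeybee breeding-value
  estimation works in the field — individual paternity inside the
  polyandrous mating is unobservable, so the established evaluation
  methodology averages the paternal path over the station — and because
  the choice is not neutral: with realized-drone relationships the
  evaluation is slightly more accurate on the paternal side and the
  simulated program selects measurably harder on the direct component,
  inflating 20-year direct gains by some 20% in the strong-covariance
  finite-locus setting. Inheritance, inbreeding and all reported true
  breeding values always use the exact tracked pedigree regardless of
  mode; `pedigree_mode = "exact"` switches the evaluation to realized
  drones and is the mode pinned against the dense GLS oracle in the
  tests.

The selection criterion of a colony is
$\widehat{\mathrm{SC}} = \hat u_d(W) + \hat u_m(W)$; truncation selection
takes the top 60 two-year-old queens as dams of queens (5 daughters
each) and the top 4 three-year-olds as dams of stations, ties broken by
id for reproducibility.

## Scheme timing and bookkeeping

Years 1–2 create 300 unrelated base BQs each; years 1–3 create 4
unrelated base stations of 8 DPQs (no relationships among or between
base groups). Stations built in year $t$ serve the matings of year $t$ —
with base stations in each of the first three years this covers all
early matings. Full-sister groups go to one uniformly chosen station (no
inbreeding avoidance, none being stated for the field scheme). Colonies
are phenotyped once, at queen age 1; queens live exactly 3 years. A BQ
may serve as dam of BQs at age 2 and as dam of a station at age 3; only
the BQ/DPQ roles are mutually exclusive. DPQs are sired by their dam's
own stored mating drones (uniform with replacement) — the field scheme
specifies only that a station's DPQs share one dam, and using the stored
mates is the only paternity available in a closed program. Drone genomes
are kept only while their queen can still reproduce; pedigree links are
kept forever.

## Reported statistics

Per year and replicate: mean direct/maternal TBV and mean F of the new
BQ cohort; mean and variance of PC; bias as mean estimated over mean
true SC of the tested colonies; accuracies as correlations between
worker-group EBVs and TBVs. Accumulated gains are raw cohort means (the
base expectation is 0). The *corrected* gains divide by the initial
genetic standard deviations — $\sigma_{Am}$, $\sigma_{Ad}$ and
$\sqrt{\sigma^2_{Ad} + \sigma^2_{Am} + \sigma_{Amd}}$ for PC, the
covariance entering once because PC sums one maternal and one direct
component.

One alignment choice deserves a note: published per-year gain tables for
this kind of scheme list the maternal and direct means of the BQs *of
that year* together with a PC value that exceeds their sum by only a few
hundredths — which identifies the PC as belonging to the same cohort's
colonies (the worker groups sit slightly above their queens because the
drone side is under stronger selection). A colony's genetic value is
fixed at mating, one year before its performance test, so `stats$mean_PC`
is computed over the cohort's colonies at mating and aligns with
`mean_d_BQ`/`mean_m_BQ` of the same row, while `mean_PC_tested` carries
the phenotyped-that-year (one cohort older) view. The repetition
analysis `required_repetitions(s, e, alpha)` is
$\lceil (s\, z_{1-\alpha/2} / e)^2 \rceil$, used with a 10% error bound
at 99% confidence.

## Problem sizes, replication and runtime

A 20-year small-program run (300 BQs/year) creates roughly 85,000
pedigree nodes and solves a growing sequence of mixed-model systems, and
takes under a minute on one core; the acceptance analysis runs the
20-year scenarios at the replication the repetition analysis itself
prescribes for a 10% error bound (4–10 replicates, with finite-locus
replicates spread over 2 independent founder locus sets). The full
100-year contrasts at 30+ replicates are available via
`long_horizon_contrasts()` and take hours; the always-on test suite
instead runs a reduced-scale program (100 BQs, 2 stations, 50 years, 3
replicates per engine). The horizon matters: for the first 15 or so
female generations the engines agree (the heavy-tailed locus effects can
even put the finite-locus engines slightly ahead early on); by 50
reduced-scale years the variance contrast is unambiguous — the
infinitesimal engine retains about one and a half times the PC variance
of FL200 and leads in accumulated gain — and those two orderings are
what the suite asserts, along with the invariants (selection response,
inbreeding
accumulation, Bulmer dip, unbiasedness under INF, maternal-over-direct
accuracy). Two published long-run phenomena do not reproduce at reduced
scale and are deliberately left to the full-scale driver: the three-way
gain ordering over FL400, and the growing upward bias of finite-locus
EBVs, which is driven by selection-induced allele-frequency change and
at small population sizes is swamped by drift that pedigree BLUP tracks
without bias.

## What the generator does and does not emulate

The synthetic data are generated under the stated conditions: closed
population, one trait, purely additive bivariate gene action, no
genotype-by-environment interaction, no measurement structure beyond one
Gaussian residual per colony test, no mutation replenishing variance, no
csd-locus viability effects, and exact execution of the selection rules.
Passing tests therefore demonstrate internal consistency of models,
algebra and code — they do not show that real breeding programs will
realize these gains, where parameter misspecification, environmental
trends, non-additive variation and management deviations all intervene.

## Known limitations

* Linkage is not modelled; with a few hundred loci this conservatively
  overstates the effective number of independent loci.
* The expected-paternity BLUP mode is provided for comparison but has no
  field-data approximation formulas behind it; it is the in-silico
  expectation, not a reimplementation of published field estimators.
* Variance components are never re-estimated by design; studying
  re-estimation schedules would require adding an estimation module.
* The reduced-scale test runs cannot exhibit the 100-year contrasts; use
  `long_horizon_contrasts()` at full scale for those.
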