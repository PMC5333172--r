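---
title: "regevo: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regevo: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package simulates

`regevo` simulates the evolution of the regulatory DNA of the four
Drosophila trunk gap genes (*hb*, *Kr*, *gt*, *kni*) in a population
under mutation, truncation selection and free recombination between
loci. Fitness is developmental: each individual's regulatory sequences
are annotated for transcription-factor binding sites (TFBSs) of the
eight canonical gap-gene regulators (Bcd, Cad, Hb, Gt, Kr, Kni, Tll,
Hkb), the annotation drives a thermodynamic/reaction-diffusion model of
gap-gene expression along a row of nuclei on the anterior-posterior
axis, and the root-mean-square deviation of the resulting
spatiotemporal expression from the wild-type solution,

$$F = \sqrt{\frac{1}{N}\sum_{p,a,i,t}\bigl(u^{p}(a,i,t) -
U^{p}(a,i,t)\bigr)^{2}},$$

is the (inverse) fitness: lower $F$ is fitter. Products $p$ are mRNA
and protein, $a$ runs over the four genes, $i$ over nuclei, $t$ over
the observation times, and $N$ is the size of that grid. The founder
population is genetically identical and scores $F = 0$ by construction
against its own wild-type solution.

All real inputs of the original study system — genomic sequence,
empirical motif models, chromatin accessibility and curated CRM /
footprint annotations, and fitted expression-model parameters — are
replaced by a fully seeded synthetic generator with the statistical
structure the downstream analysis assumes.

# The synthetic study conditions

The generator's defaults define the study conditions; they are fixed
once and not tuned per analysis.

* **Loci.** Four loci, one per gap gene, 2 kb each at the desk scale
  (18 kb in the `full` preset). Background sequence is i.i.d. uniform
  over ACGT (a GC-bias knob exists; the field rarely knows the right
  non-uniform background for synthetic work, and uniform makes the
  PWM log-odds interpretable directly).
* **Motifs.** One PWM per TF, 7–10 bp, target information content 1.2
  bits/column (jittered ±10% per column), log2-odds against the
  uniform background. Hb is generated as a repetitive poly-A consensus:
  its hits self-overlap on poly-A/poly-T tracts, reproducing the
  redundancy structure that drives the self-overlap analyses. Hit
  thresholds are calibrated empirically per PWM as the $(1-p)$
  quantile of window scores on random background with $p =
  5\times10^{-4}$ per bp per strand — a standard motif-scan stringency
  that also reproduces a realistic overall site density (about
  0.02 sites/bp after inclusion filtering).
* **Planted sites.** ~15 per locus, drawn from a fixed TF mixture
  weighted towards the broad activators, alternating "strong"
  (consensus) and "weak" (1–2 second-best-base mismatches) tiers,
  placed non-overlapping on random strands. Repetitive (Hb) plantings
  insert a longer homopolymer run (motif length + 6) so that one
  planting yields several mutually overlapping hits. The planted
  excess over the chance-hit equilibrium is what gives the founder
  more sites than mutation–selection balance sustains — the origin of
  the site-count decline the analysis tracks.
* **Interval sets.** The accessibility mask is a union of intervals
  covering ~80% of each locus and always covering all planted sites.
  Two CRM-like 200-bp windows per locus are centred on planted sites
  (curated modules sit where the functional sites are), and footprints
  cover up to three planted-site intervals exactly. These provide the
  three inclusion routes: high score inside open chromatin, CRM
  overlap, footprint overlap.
* **External profiles.** Bcd: anterior-high exponential
  ($\lambda = n/4$ nuclei); Cad: its posterior mirror; Tll and Hkb:
  symmetric terminal peaks ($\lambda = n/12$ and $n/20$). All in
  $[0, c_\max]$, $c_\max = 1$, static in time, 30 nuclei by default.

What the generator does **not** emulate: real base composition and
motif shapes, distances between real modules, maternal-factor temporal
dynamics, nuclear divisions, or any quantitative match to real
expression data. Passing trend tests therefore demonstrates that the
*mechanisms* (redundant weak sites eroding under mutational pressure,
selective retention of functionally important sites) behave as in the
study system, not that real D. melanogaster numbers are reproduced.

# The expression model

The exact equations of the original fitted model are not public; the
package implements a documented surrogate that preserves every
property the analyses depend on, and is versioned so a faithful
replacement could be swapped in.

1. **Site occupancy.** Site $s$ of TF $f$ with binding energy $E_s$
   (its PWM log-odds score) in a nucleus with concentration $c_f$ has
   $\phi_s = q_s/(1+q_s)$, $q_s = K_f\,c_f\,e^{\beta (E_s -
   E^{\mathrm{ref}}_f)}$. $E^{\mathrm{ref}}_f$ is the PWM threshold,
   so the weakest callable site has $q = K_f c_f$. Defaults $K_f = 1$
   (concentrations are order-1), $\beta = 0.3$ per score unit (a
   strong site ~10 units above threshold binds ~20× tighter than a
   threshold site).
2. **Cooperativity.** Same-TF sites within 50 bp edge-to-edge boost
   each other: $q'_s = q_s (1 + \omega \sum_{n} \phi_n)$ in a single
   pass using the *unboosted* neighbour occupancies (one fixed-point
   iteration; iterating to convergence changes little and costs a lot
   in the inner loop). $\omega = 1$ by default.
3. **Activation.** $P_{\mathrm{on},a} = \mathrm{logistic}\bigl(\sum_s
   T_{f(s)\to a}\,\phi_s + \theta_a\bigr)$, with the signed per-site
   weight matrix $T$ wired to the classical gap network (Bcd/Cad
   activate with anterior/posterior weighting; Hb–Kni and Gt–Kr are
   strong mutual repressors; Tll/Hkb are terminal repressors).
   Magnitudes are 0.04–0.2 per site so that tens of sites sum into the
   responsive range of the logistic; $\theta_a = -3$ sets a low basal
   rate. $P_{\mathrm{on}}$ is strictly inside $(0,1)$, monotone in
   activator concentrations and antitone in repressor concentrations.
4. **Dynamics.** Per gene and nucleus,
   $\dot m = R\,P_{\mathrm{on}} - \lambda m + D\,\Delta m$ and
   $\dot p = r\,m - \rho\,p + D'\,\Delta p$ with nearest-neighbour
   Laplacian and zero-flux (mirrored) boundaries. The four gap TFs
   take their concentrations from the protein state at the current
   step, closing the gap–gap feedback; Bcd, Cad, Tll, Hkb come from
   the external profiles. Defaults $R = 2$, $\lambda = \rho = 1.5$,
   $r = 1.5$, $D = D' = 0.2$ (dimensionless time units; the relaxation
   time $1/\lambda$ is the natural unit), integrated to $t = 2$ and
   observed at $t \in \{0.5, 1, 1.5, 2\}$ from a zero initial state
   (expression onset).

## Numerical choices

Explicit Euler with fixed `dt = 0.01` and an upfront stability check
(`dt` must be well below $2/(\lambda + 4D)$). The integrator lives in
compiled code; a simulation of a 2-kb, ~160-site genotype over 200
steps and 30 nuclei takes ~10 ms, which is what makes 300-generation
populations tractable. Closed-form checks (no-diffusion relaxation,
mass conservation under zero decay) are run at much smaller `dt`
(down to $10^{-6}$) where the first-order Euler error is far below
the test tolerances; a convergence test verifies that halving `dt`
moves the rms-score of a fixed genotype by less than $10^{-4}$.
Integration blow-up (non-finite or > $10^8$) aborts with diagnostics;
inside the evolutionary loop such an individual receives $F = \infty$
and is never selected.

# Evolutionary algorithm

Each generation: every accessible base pair of every individual
mutates independently with probability $\mu$ (substitutions only, to
one of the three other bases — indels would break the coordinate
identity the tracking algorithm relies on); genotypes are re-annotated
and re-scored; individuals are ranked by increasing $F$; the eligible
parent set is everyone at least as fit as the rank-`elite_size`
individual (ties included — the only reading of rank truncation
consistent with "at least as good as the 20th best"); parents are
drawn uniformly with replacement and each of the four loci is copied
whole from one parent or the other with probability 1/2 (free
recombination between loci, none within). Mutation is restricted to
the accessibility mask because the genotype is defined as the
accessible sequence. One tracked individual per generation is drawn
uniformly from the elite; summary statistics ("all" and "new" sites)
are averaged across the elite.

# Tracking and analysis conventions

* The vicinity of a site of length $L$ at start $s$ is $[s-L, s+2L)$,
  clipped to the locus.
* Step matching: exact coordinate matches persist; remaining old sites
  are greedily matched nearest-first (ties towards smaller
  coordinates) to unmatched same-TF new sites whose interval overlaps
  the old site's vicinity (interval overlap was chosen over
  start-in-window as the more permissive reading; a flag selects the
  alternative). Unmatched old sites die, unmatched new sites are
  births; a birth overlapping the vicinity of a dead same-TF
  wild-type site is a rebirth, which starts a new trajectory rather
  than resuming the old one (so lifetimes are not spliced).
* Core sites are initial trajectories alive in every generation
  (moves allowed; an `identical_coords` flag reports the stricter
  subset). Cooperative neighbours are non-core sites within 50 bp
  edge-to-edge of a same-TF core site; overlapping neighbours
  intersect a core site and are not cooperative (cooperative takes
  precedence). Classification uses origin coordinates.
* Bin energies sum site $E$ within fixed 180-bp bins (the last bin of
  a locus may be shorter and is normalised by its true width); a site
  straddling a boundary belongs to the bin containing its start. The
  bin count follows locus length / 180 rather than any fixed total.
* Tracked-site statistics (mean $E$, CV, low/high ratio, affinity-set
  correlations) are computed on the tracked individual only; "all" and
  "new" site statistics pool the elite. CV distributions customarily
  drop the first 100 generations (few new sites exist before that).
* The bootstrapped two-sample KS test pools both samples, resamples
  two samples of the original sizes with replacement, and reports
  $p = (1 + \#\{D^\ast \ge D\})/(n_{\mathrm{boot}}+1)$ — the +1
  correction avoids zero p-values.
* Pearson correlation is used throughout; epoch boundaries for
  fitness–energy correlations default to thirds of the run.

# Problem sizes

The desk preset — 4 × 2 kb loci, 30 nuclei, 50 individuals, 20 elite,
$\mu = 10^{-3}$, 300 generations — is the package's reference
configuration for trend analyses and completes in a few minutes on one
CPU; the test suite and the acceptance script both use it. The `full`
preset (18 kb loci, 100 individuals, 3,350 generations) is expressible
but takes hours.

# Known limitations

* At the desk scale the per-individual mutational load on functional
  sequence (~6 substitutions/generation, ~1.5 of them inside sites) is
  an order of magnitude below the full-scale conditions, so selection
  purges most site losses and the quantitative turnover is slower:
  the site-count decline, while statistically significant, is a few
  percent rather than the several-fold drop seen at full scale, and
  the surviving core fraction is correspondingly larger. The trends'
  directions, not their magnitudes, are the reproducible object.
* Surviving tracked sites' mean energy rises through composition (weak
  sites die first); the *per-site* energy drift of survivors is
  slightly negative at desk scale because consensus-planted sites can
  only lose score. Bin energies drift down with site loss, as
  expected.
* The expression surrogate is qualitative: no parameter fitting, no
  mRNA transport delays, no nuclear divisions, no 3D genome effects.
* The greedy step matcher is optimal on the unambiguous cases covered
  by the test suite and maximal (no matchable pair left unmatched) in
  general, but is not guaranteed to minimise total displacement in
  dense ambiguous clusters.
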