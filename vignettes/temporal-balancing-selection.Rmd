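---
title: "Detecting short-term balancing selection from temporal haplotype data"
author: "tempoSel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting short-term balancing selection from temporal haplotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Balancing selection maintains multiple alleles at a locus; its canonical
form, overdominance (heterozygote advantage), drives a de novo allele
toward an intermediate equilibrium frequency. *Long-term* balancing
selection leaves conspicuous footprints (excess diversity, trans-species
polymorphism). *Short-term* balancing selection — an overdominant allele
that arose only thousands of years ago — does not: by the time the allele
reaches intermediate frequency, its footprint in present-day variation is
subtle and heavily confounded by drift. Serial samples (ancient-DNA-like
haplotypes from several past time points alongside a present-day sample)
restore identifiability, because they record the allele's frequency
*trajectory*, not just its endpoint.

`tempoSel` implements the complete simulation-based supervised approach:
a forward Wright–Fisher simulator generates labeled temporal samples under
neutrality and under weak/moderate overdominance; a deterministic encoder
turns them into fixed-shape tensors; a two-branch residual convolutional
network classifies each locus as `N` (neutral), `D0.25` (s = 0.25%) or
`D0.5` (s = 0.5%); repeated training yields confusion matrices with
confidence intervals, and single-branch ablations quantify what the
ancient samples contribute.

## The simulator

The engine is a diploid Wright–Fisher model with discrete generations:

1. **Viability selection** at the focal site with genotype fitnesses
   `1 : 1+s : 1` (ancestral homozygote, heterozygote, derived homozygote).
   Parents are drawn with probability proportional to fitness. The
   implied deterministic frequency update,
   `p' = (p^2 + p(1-p)(1+s)) / (1 + 2p(1-p)s)`,
   has fixed points at 0, 1 and the symmetric equilibrium 1/2, and serves
   as an independent oracle for the stochastic engine
   (`deterministicUpdate()`).
2. **Random mating** of diploids (selfing allowed, standard Wright–Fisher).
3. **Recombination**: each gamete receives `Poisson(rho * L)` crossovers at
   uniform positions.
4. **Infinite-sites mutation**: `Poisson(mu * L)` new mutations per gamete
   at continuous uniform positions; every mutation is a new column with a
   persistent identity.

A run consists of a neutral burn-in of `burninFactor * N_ancestral`
generations at the ancestral size (default 10N, enough for S and pi to
equilibrate to their Watterson expectations within Monte-Carlo error),
the piecewise demographic epochs, injection of the focal mutation on one
random haplotype at the onset generation, and non-destructive sampling of
haplotypes without replacement at each requested age. Lost and fixed
non-focal columns are pruned; the focal column is always retained. The
emitted site set is the set of sites segregating in the present-day
population; ancient blocks are projected onto it (sites not yet born at an
ancient sampling time are ancestral there).

**Conditioning.** Selected replicates are retained only if the focal
allele segregates (population frequency strictly in (0, 1)) at the
present-day sampling. The population state at the onset generation is
checkpointed and failures rewind to it, redrawing only the post-onset
phase — the standard idiom for conditioning on a de novo mutation in
forward simulation, and the reason the per-replicate cost is dominated by
the burn-in rather than by the retry count. Attempt counts are recorded in
each sample's provenance.

**Rescaling.** Forward simulation at human scale is expensive, so the
configuration carries a factor `lambda`: sizes are divided by it, `s`,
`mu`, `rho` and growth rates multiplied, and times in generations divided,
preserving `N*s`, `N*mu*L`, `N*rho*L` and times in coalescent units.
One caveat is inherent and worth stating precisely: the initial frequency
of a de novo mutant is `1/(2N)`, which rescaling cannot preserve. The
conditioned *early-phase* frequency distribution (and the conditioning
acceptance rate) therefore differ between `lambda` values; once the allele
reaches its balanced equilibrium the stationary distribution depends only
on the preserved compound `Ns` and invariance is restored. The validation
suite tests rescaling invariance of (S, pi, focal frequency) in that
equilibrated regime; S and pi are invariant throughout.

## Study designs shipped with the package

`defaultConfig()` mirrors the full-scale design: 50 kbp loci,
`mu = rho = 1.25e-8`, a European-like piecewise demography (ancestral size
10,000; bottleneck to 1,500 between 2,000 and 1,000 generations ago;
recovery; exponential growth over the last 400 generations — a documented
stand-in, not a reproduction of any published fit), generation time 25
years, overdominant de novo mutation at the locus center arising 10,000
years ago with s of 0.25% or 0.5%, and sampling of 40 present-day plus
10 haplotypes at each of 8, 4, 2 and 1 kya; 2,000 loci per class; 64
filters; 10 training repeats.

`deskConfig()` is the desk-scale scenario used by the validation suite and
the acceptance script. It keeps the selection compound parameters at
`2Ns = 50` (weak) and `100` (moderate) but rescales by `lambda = 40`
(scaled sizes 250 growing to 500) and lengthens selection to 100 scaled
generations, i.e. 0.2 coalescent units, with ancient samples at 80, 60,
40 and 20 scaled generations. Two considerations fix these numbers:

* the weak allele needs roughly `log(2N)/s ~ 60` scaled generations to
  approach its equilibrium, so 100 generations leaves both selected
  classes at intermediate frequency at present while their *trajectories*
  through the four ancient time points differ strongly — that is exactly
  the signal the time-series branch is supposed to capture;
* the onset must stay a small fraction of the coalescent timescale
  (here 0.2) or the selected haplotype class is no younger than neutral
  clusters and the present-day signature dissolves. An earlier desk
  parameterization with `N_scaled = 200` and onset at half a coalescent
  unit was verified (by an independent random-forest baseline on summary
  features) to be near-inseparable, and was replaced by this design.

Desk problem sizes — 380 loci per class (300 train / 30 validation / 50
test), window width 32, 16 filters, 20 epochs, 3 repeats, burn-in 5N —
are the package's choice of a one-CPU-scale experiment; all are plain
config fields.

## Encoding

Within each sampling block, haplotypes are grouped by identity and groups
ordered by descending multiplicity, ties broken by descending
lexicographic order of the row bits. This canonical sort makes the
encoding invariant to haplotype input order (the rows of a sample are
exchangeable) while presenting frequency-organized structure to the 2-D
convolutions. SNP columns are *not* additionally sorted by frequency:
column order is genomic position, preserving linkage structure around the
focal site. The window is *anchored*: the focal site (for neutral samples,
the segregating site nearest the locus center — a label-independent rule,
since in application one always tests a named candidate site) always lands
at the same column, with the nearest flanking sites on either side and
zero-padding where a flank runs short. Anchoring matters: with a floating
window the classifier must first localize the candidate column, and at
desk scale that localization — not the trajectory signal — was the
accuracy bottleneck (a six-feature logit given the true column outperformed
the network by 30 points until the window was anchored). The present-day matrix
(40 x W) feeds one branch; the four ancient blocks are stacked as
channels, oldest first, into a 4 x 10 x W tensor for the other. Derived
alleles are 1, ancestral 0; for unpolarized user data the reader can fall
back to minor-allele coding.

## The classifier

Each branch applies an input 3x3 convolution (64 filters at full scale;
all sizes configurable), then residual blocks `x + relu(conv(x))` with 2x2
max-pooling between consecutive blocks (2 blocks by default), a mean
reduction over the haplotype axis, and a dense ReLU embedding. The
haplotype-axis mean respects the exchangeability of sampled haplotypes;
invariance to the *original* haplotype ordering is supplied exactly by the
canonical sort in the encoder, which the test suite verifies end-to-end at
bit precision. Branch embeddings are concatenated, passed through dropout
(0.25) and a single dense layer to three logits and a softmax. Inputs are
centered (allele values ±1/2) before the first convolution. Ablation
modes `present_only` and `ancient_only` are independently trained
single-branch models, not zero-masked two-branch models; zero-masking is
additionally available (`predictProb(..., silence =)`) as a structural
check.

An alternative branch architecture is available as
`NetworkSpec(variant = "exchangeable")` (YAML: `network.variant`):
row-shared 1-D convolutions followed by a mean over the haplotype axis and
residual 1-D convolutions over the resulting per-column frequency map. It
encodes haplotype exchangeability architecturally, trains about three
times faster at desk scale, and reaches accuracy comparable to the default
2-D residual network; the bundled configurations keep the default.

Training minimizes multiclass cross-entropy with Adam (learning rate
1e-3, batch 32 by default), tracks validation accuracy per epoch, returns
the best-validation parameters, and optionally early-stops. Convolution
and pooling forward/backward passes are compiled (im2col plus BLAS);
everything is driven by R's RNG, so one (config, seed) pair yields a
byte-identical model, history and evaluation report. Gradients were
verified against central finite differences (median relative error
~5e-11; isolated larger deviations occur only at exact ReLU kinks).

## Evaluation protocol

The dataset is split once, stratified by label (per-class counts within
one sample of the requested fractions). The repeat protocol trains
`nRepeats` models (default 10) that differ only in initialization, batch
order and dropout — isolating training variance, which is what the
confidence interval is meant to capture — and reports per-repeat 3x3
confusion matrices (rows true, columns predicted; a transposed rendering
is a display option), per-repeat accuracies, their mean and a t-based 95%
interval (n = 10 is too small for a percentile bootstrap), and the
element-wise mean of row-normalized matrices. The weak-vs-moderate
pairwise accuracy restricts the matrix to the two selected classes. The
ablation comparison runs the three modes on identical splits and seed
streams.

## What the synthetic data do and do not show

The generator reproduces the sampling design, demography and selection
model of the study scenario, so passing tests demonstrate that the method
recovers the signal it was designed for under its own generative
assumptions. Real ancient-DNA data violate several of them: sequencing
and damage errors, low coverage and pseudo-haploid calls, missingness,
population structure and gene flow across time points, and uncertainty in
sample ages. None of these are modeled here (deliberately, as in the
study design); classifier accuracies reported by this package are
therefore upper bounds on what identical architectures would achieve on
real data.

## Numerical choices and degenerate inputs

* Positions are continuous fractions of the locus, rounded to the
  6-decimal precision of the ms-style dialect at emission; rounding
  collisions are resolved by nudging to preserve strictly increasing
  positions.
* When a flank of the anchored window runs out of segregating sites it is
  zero-padded on that side; zero-site samples encode to all-zero tensors
  of the declared shape.
* `predict` probabilities are softmax outputs and sum to 1 within 1e-6;
  confusion matrices are integer counts and normalized rows sum to 1
  within 1e-9.
* Training aborts with a dedicated error on non-finite loss; a learning
  rate of 0 provably freezes the parameters.
* The conditioning retry cap (default 100) turns pathological
  configurations (e.g. an allele that cannot survive) into a clean
  conditioning-failure error carrying the attempt count.

## Known limitations

No coalescent engine or tree-sequence recording; no aDNA error model; no
population structure; ablation conclusions at desk scale rest on 3
repeats and 150 test loci, so only differences beyond a few percent are
meaningful; and the bundled European-like demography is a stand-in whose
parameters should be replaced with a fitted model for any real
application.
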