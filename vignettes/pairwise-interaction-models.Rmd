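---
title: "Pairwise interaction models of transcription factor binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise interaction models of transcription factor binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A transcription factor binding site (TFBS) is modeled as an L-mer over
{A,C,G,T} (L = 12 by default). The classical position weight matrix (PWM)
assigns each site the probability `prod_i p_i(s_i)`, i.e. it assumes
positions contribute independently. The pairwise interaction model (PIM)
generalizes this: it is the maximum-entropy distribution over L-mers that
reproduces the observed single-nucleotide frequencies at every position
*and* the observed dinucleotide frequencies for a selected set of position
pairs. Solving the constrained entropy maximization gives a Boltzmann form

    P(s) = exp(-E(s)) / Z,
    E(s) = sum_i h_i(s_i) + sum_{(i,j) active} J_ij(s_i, s_j),

so that more frequent sites have lower binding energy. The fields `h_i(a)`
play the role of per-nucleotide binding energies and the couplings
`J_ij(a,b)` of interaction energies between nucleotides at two positions.
The PWM is exactly the `J = 0` special case. `Z` is the partition function,
the sum of `exp(-E)` over all `4^L` sites.

Everything here is exact: no mean-field or pseudo-likelihood approximation
is used anywhere. The one computational identity we exploit is that `Z`,
the model marginals and exact sampling all factorize over the connected
components of the coupling graph, so full enumeration is only ever needed
over a component's `4^m` states (capped at 14 positions per component, 12
where a probability vector must be materialized). For the sparse coupling
sets selected in practice the components are small and all operations are
fast even at L = 12.

### Gauge fixing

The split of `E` between fields and couplings is not unique: adding a
constant to a field row, or moving a row/column profile of a coupling block
into the fields, leaves every probability unchanged. `fix_gauge()` resolves
this with the minimum-square-norm convention: coupling blocks are made
doubly centered (zero row and column sums) with the removed profiles
absorbed into the fields, and field rows are then centered to zero sum.
This leaves 3 free field parameters per position and 9 free coupling
parameters per pair, which is also the parameter counting used in the BIC
(`3L + 9 * n_couplings`). The counting is a documented choice — it counts
gauge-independent degrees of freedom rather than raw matrix entries.

## Fitting

`fit_pim()` performs marginal matching: starting from any initialization it
updates

    h_i(a) <- h_i(a) - eta * (f_i^data(a) - f_i^model(a))

and analogously for the active coupling blocks, recomputing the exact model
marginals each sweep, until the largest absolute marginal residual falls
below `tol` (1e-4 by default; `eta = 0.1`). The negative log-likelihood is
convex in `(h, J)`, so the fitted distribution is unique and independent of
the initialization (the test suite verifies two distant initializations
agree).

Two numerical choices matter here:

* **Adaptive gain (default `adapt = TRUE`).** The plain fixed-step update
  converges at a rate governed by the smallest marginal variances; on sharp
  motifs (`f -> 0 or 1`) it needs tens of thousands of sweeps. We therefore
  scale `eta` per parameter by a gain that grows by 1.1 while the gradient
  sign persists and halves on a sign flip. The fixed point is identical
  (convexity); `adapt = FALSE` restores the plain schedule, and a test
  confirms both reach the same distribution.
* **Consistent pseudo-counts.** Single frequencies use `beta1 = 1` per cell
  (Laplace's rule); pairwise frequencies use `beta2 = beta1 / 4` per cell.
  With this ratio the pseudo-counted pair tables marginalize *exactly* onto
  the pseudo-counted single table, so the constraint set handed to the
  maximum-entropy fit is internally consistent and the fit can actually
  reach `tol`. Any other ratio leaves an O(1/N) contradiction between the
  single and pair constraints which places a floor on the achievable
  residual. Both values are configurable; at the sample sizes involved the
  choice has no visible effect on the fitted models.

## Greedy coupling selection with BIC

`build_pim()` starts from the coupling-free fit and repeatedly adds the
pair whose dinucleotide table deviates most from the current model. The
deviation score of a pair is the minimum, over its 16 cells, of the exact
two-sided binomial tail probability of the observed cell count out of N
given the model cell probability (two-sided in the minimum-likelihood
sense; ties between pairs go to the lexicographically first). Each addition
is followed by a full refit, warm-started from the previous parameters, and
scored by

    BIC = -log L + (k/2) log N,        k = 3L + 9 * n_couplings .

The loop stops after the BIC fails to improve for 3 consecutive additions
(a patience rule; the stopping criterion itself is BIC minimization) and
the BIC-minimal model is returned with the full trace. Restricting the
candidate pairs to adjacent positions gives the nearest-neighbor model
(NNM), the maximum-entropy equivalent of a first-order Markov chain.

The per-cell binomial aggregation (rather than, say, a chi-square over the
table) and the two-sided convention are documented choices; the selection
statistic only orders candidate pairs, and the BIC decides what stays.

## The PWM-mixture baseline

`select_mixture()` fits mixtures of K PWMs for K = 1..K_max and keeps the
BIC argmin, with `K*3L + (K-1)` parameters. Components are estimated by
K-means on the sites under the Hamming metric: the centroid of a cluster is
its per-position modal nucleotide (ties to the alphabetically first
letter), assignment ties go to the lowest cluster index, empty clusters are
re-seeded from the farthest point, and the best of 10 restarts by total
weighted Hamming cost is kept. Hard clustering is only the estimation
device: the mixture likelihood entering the BIC is the full
`sum_k pi_k prod_i p_i^k(s_i)` probability of the sample.

## Binding-site refinement on fragments

`iterate_refinement()` implements the self-consistent workflow that couples
a model to its training set. Each round scans both strands of every
fragment, scores each L-window as `log2(P_model / P_background)`, sets the
cutoff at the `ceiling(0.5 * M)`-th largest per-fragment best score (so at
least half the fragments retain a predicted site; ties can only push the
fraction up), selects above-cutoff windows greedily without overlap within
each fragment (by descending score), relearns the model on the selected
sites, and repeats until the selected multiset of (fragment, offset,
strand) is exactly unchanged. Windows containing N are skipped rather than
dropping the fragment; minus-strand sites are recorded as the L-mer they
match on their strand.

The background defaults to the position-independent model built from all
windows of both strands (strand symmetry is automatic); a background PIM
can be requested when dinucleotide structure in the background itself is of
interest.

The PWM stage re-centers the learned matrix each round: per-column
information content is computed relative to the background frequencies, its
center of mass is rounded half-up, and that column is placed at position
`floor(L/2) + 1`, padding with background columns where the input does not
cover. One caveat is worth knowing: a motif whose information profile is
exactly symmetric has its center of mass midway between two columns, and
sampling noise then decides between two self-consistent windows that differ
by one column. Site coordinates are only defined up to that convention for
such motifs; the synthetic sharp model used in the package's end-to-end
studies is deliberately composition-skewed so its center is unambiguous.

## Energy landscape

With couplings the energy landscape over the `4^L` sites can have several
local minima. `descend()` lowers the energy by single-nucleotide
substitutions until none improves strictly (plateaus therefore terminate);
deterministic mode takes the steepest step with ties broken by position
then alphabet order, random mode picks uniformly among improving moves.
`find_basins()` descends every observed site once and weights each basin by
its member fraction; `basin_pwms()` learns one PWM per basin, and
`match_basins_to_mixture()` assigns each basin PWM to the mixture component
with the smallest position-summed Kullback-Leibler divergence (in bits; for
independent-position models the position sum is the exact
sequence-distribution divergence). Agreement between the two descent modes
is a property of well-separated basins — near a shallow ridge the random
path genuinely decides the attractor — and the mode-consistency test
accordingly uses a deep two-well model.

## Information-theoretic summaries

* `dkl()` and `dkl_data_model()` report divergences in bits; `self_dkl()`
  draws repeated exact samples of size N from a model and returns the mean
  and SD of the sample-to-model divergence — the finite-sampling floor
  against which an observed data-model divergence should be judged (values
  within two SDs of the mean are indistinguishable from sampling noise).
* **Direct information.** For a pair with coupling block J, the direct
  two-site distribution `P_dir(a,b) ∝ exp(-J(a,b) - ht_i(a) - ht_j(b))` is
  solved (Levenberg-Marquardt, residual tolerance 1e-10, fields anchored to
  vanish at T) so that its marginals equal the observed single-site
  frequencies; DI is then the mutual information of `P_dir`. It isolates
  the dependence carried by the direct coupling from correlation that
  merely propagates along interaction paths.
* **Normalization.** NDI = DI / min(H_i, H_j) and likewise NMI, with
  entropies in bits; a deterministic copy of a position scores 1,
  independence scores 0, and the bound NDI <= 1 holds because the MI of any
  joint with the given marginals is at most the smaller marginal entropy.
  When both entropies vanish the value is defined as 0. The denominator is
  a documented choice (exposed as `normalized_information()`).
* **Participation ratio.** `R = (sum w)^2 / (N_pairs * sum w^2)` over the
  off-diagonal entries of a pairwise weight matrix, `N_pairs = L(L-1)`
  counting both orientations: 1 for uniform weights, `2/N_pairs` for a
  single interacting pair. The default weight is NDI^2 per pair (squaring
  emphasizes dominant interactions; the weight is a configurable choice).
* **Distance profile.** Weights at separation d are summed and divided by
  the number `L - d` of pairs at that distance — without this correction
  uniformly random interactions would fake a nearest-neighbor excess — then
  normalized to sum to one.

## Hopfield-pattern decomposition

The sparse couplings extend to a symmetric `4L x 4L` matrix with zero
within-position blocks, so the coupling energy is `(1/2) x' Jhat x` with x
the one-hot site indicator. Its eigendecomposition gives orthonormal
patterns with real eigenvalues summing to zero (zero trace); the coupling
energy decomposes as `(1/2) sum_k lambda_k (xi_k . x)^2`, the same algebra
as a Hopfield network with the patterns as memories. Patterns are ranked by
|lambda| (ties: larger lambda first, then index) and signed so their
largest-magnitude coordinate is positive. `truncate_spectrum()` rebuilds
the coupling matrix from the top p patterns; truncation leaks small values
into the within-position diagonal blocks, which have no meaning as
couplings and are re-zeroed before any energy or NDI evaluation (a
documented choice). `p = 4L` reproduces the full matrix exactly.

## The synthetic-data generator

The generator exists so that every analysis above can be validated against
a known ground truth without any external download.

* `sample_sites()` draws i.i.d. sites *exactly* from a PIM or PWM
  (enumerated categorical sampling per coupling component; no Gibbs chain,
  hence no mixing question).
* `sample_background()` emulates ChIP fragment background: a first-order
  Markov chain whose stationary single-nucleotide distribution equals the
  requested composition exactly while the C→G transition is suppressed by a
  bias factor (the CpG depletion typical of mammalian genomes), built by
  scaling the CG cell of the product dinucleotide table and restoring both
  marginals by iterative proportional fitting.
* `plant_sites()` writes model-drawn sites at non-overlapping uniform
  offsets on uniformly chosen strands and returns the truth table.
* `planted_pim()` provides the two reference models used in the studies: a
  *sharp* model (~0.97 of the probability mass on one composition-skewed
  consensus, one mild adjacent coupling, information content far above 8
  bits) for site-recovery studies, and a *two-basin* model (a field-favored
  word plus a second word held together by three mutual couplings among the
  positions where the words differ, basin weights roughly 60/40) for
  landscape, mixture and model-comparison studies.

What the generator does **not** emulate: genomic repeats and masking,
read-level coverage and peak shape, variable-length spacers inside motifs,
and higher-than-first-order background correlations. Passing the planted
studies therefore demonstrates the correctness of the machinery under the
stated generative assumptions, not performance on any particular genome.

## Problem sizes and study conditions

The shipped tests and studies use: exhaustive checks at L <= 6 (all 4^L
states), distributional checks at L = 2..4, parameter recovery at L = 8
with 5 couplings and N = 50,000 exact samples (the recovery study uses
balanced, doubly-centered coupling blocks with entries up to 0.75 — the
identifiable regime; blocks saturating ±1 in single rare cells push the
per-parameter sampling error itself above the 0.05 comparison bound), and
an end-to-end run with 1,000 fragments of 300 bp, CpG-depleted background
and one planted L = 12 site per fragment, where the refinement loop
recovers the planted coordinates and the Kullback-Leibler divergence to the
data at the BIC optima orders PIM <= mixture <= PWM on the two-basin model.

## Known limitations

* Coupled components larger than 14 positions exceed the enumeration cap;
  densely coupled models at L = 12 (e.g. a full NNM chain) enumerate 4^12
  states per sweep and are slow, though exact.
* The greedy pair addition is sequential; it does not revisit or remove a
  coupling once added (the BIC trace makes such cases visible).
* Binding sites are fixed-length L-mers; motifs with variable spacers are
  only captured implicitly through couplings among flanking positions.
* The refinement fixed point is defined up to the window-centering
  convention for information-symmetric motifs (see above).
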