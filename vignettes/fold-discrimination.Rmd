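---
title: "Discriminating the folds of near-identical protein sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating the folds of near-identical protein sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchfold)
```

## The problem

Engineered variants of the albumin-binding GA domain and the IgG-binding
GB domain can share up to 98% sequence identity — a single substitution
in 56 residues — yet fold into entirely different topologies: a
three-helix bundle (3α) versus a four-stranded β-sheet packed against
one helix (4β+α). Such *chameleon* pairs defeat ordinary
homology reasoning, which assumes that near-identical sequences share a
fold. `switchfold` implements a sequence-and-structure analysis battery
for this regime:

1. **Average-distance statistics** — a knowledge-based table of mean
   Cα–Cα distances per residue-type pair and sequence-separation bin,
   compiled from reference structures.
2. **Coil Monte Carlo + F profile** — Metropolis sampling of random
   Cα chains under the distance potential; residues with excess contact
   frequency (F-value peaks) mark putative folding-initiation sites.
3. **Sequence tendency** — a smoothed ±1 track showing which parent a
   chimeric sequence locally descends from.
4. **Conservation analysis** — `*`/`+` marks on multiple alignments,
   conserved-hydrophobic site extraction, and a fold classifier that
   weighs conservation evidence near F peaks.
5. **An orientation-dependent Cα Gō model** — folding simulations with
   Q-value tracking and transition-state contact maps.

## The coil potential and its sampler

For residues $i, j$ of types $A, B$ at sequence separation
$k = |i-j|$, the separation bin is $M = 1$ for $1 \le k \le 8$,
$M = 2$ for $9 \le k \le 20$, then one bin per decade (21–30, 31–40,
…). The table stores the mean $\bar r_{AB}^M$ and spread
$\sigma_{AB}^M$ of the Cα distance over all reference-structure pairs in
that cell. The pair energy is a Gaussian-well log-likelihood with a hard
core:

$$
E_{ij}(r) =
\begin{cases}
\varepsilon_{HC} & r < r_{cut} \\
kT \, \dfrac{(r - \bar r_{AB}^M)^2}{2 \, (\sigma_{AB}^M)^2} & r \ge r_{cut},
\end{cases}
$$

with $r_{cut} = 1.9$ Å and $\varepsilon_{HC} = 50$ kcal/mol. Constant
terms are the zero point. Because the quadratic term carries the $kT$
factor, the Metropolis ratio for it is temperature-independent; the
temperature only softens the hard core, and the acceptance ratio is
tuned mainly through the move amplitude γ (`autotune()` targets
0.4–0.6, aiming at ≈0.5).

The chain is a bead model with exact 3.8 Å virtual bonds. A sweep visits
residues sequentially; at each residue the bond angle θ and then the
dihedral ϕ are perturbed uniformly within ±γπ, each followed by its own
Metropolis judgment. Moves are pivots: the downstream segment rotates
rigidly, so bond lengths are preserved exactly and the energy delta
involves only pairs spanning the pivot. θ proposals reflect at the
(0, π) boundary — a symmetric proposal, so detailed balance holds and a
flat potential accepts every move. Ten Gly residues pad each terminus to
absorb nonspecific end effects; padding participates in the energy but
never in reported profiles. Ensembles default to ten independent runs of
60000 sweeps each, started from uniformly random internal coordinates
and relaxed for 100 sweeps before a 10% burn-in (starting recipe and
recording schedule are package choices).

## The F profile

Two residues are in contact when their Cα atoms are within 10 Å. Per
run, contact counts over sampled conformations give $g(i,j)$, the
contact probability; matrices are averaged across runs. The profile
subtracts the separation-dependent baseline:

$$
D(m) = \langle g \rangle_{|i-j|=m}, \qquad
q(\mu,\nu) = \max(0,\; g(\mu,\nu) - D(|\mu-\nu|)), \qquad
F(\mu) = \frac{1}{N-1} \sum_{\nu \ne \mu} q(\mu,\nu).
$$

This functional form is one of several consistent with the verbal
contract ("a peak corresponds to a residue forming many inter-residue
contacts", with values on a ϕ-value-like scale); it is isolated behind
one function so an alternative baseline is a one-function swap. A
uniform $g$ yields $F \equiv 0$ by construction. Error bars are the
standard deviation of per-run F values. Peaks are local maxima above the
profile mean with prominence at least half the profile standard
deviation (a package default; by-eye peak marking has no single
formalisation),
plateaus count once at their centre, and shoulder positions — above the
mean and above the mean of their neighbours without being strict
maxima — are flagged separately.

Packing analysis uses the complementary structural rule: residues
$|i-j| \ge 3$ whose closest heavy atoms are within 5 Å. Hydrophobic
residues default to A, V, L, I, M, F, W, Y, C (configurable). The
peak–packing correspondence table asks, both ways, whether packing
residues lie within ±3 residues of an F peak.

## Sequence tendency

Each site of a chimera is attributed to the parents by exact matching
(`A`, `B`, `both`, `neither`), scored +1 for the 3α parent, −1 for the
4β+α parent, 0 otherwise, and smoothed with a normalised
(Nadaraya–Watson) Gaussian kernel of bandwidth $h = 3.5$ residues. Both
sign conventions are seen in practice; the default takes positive =
GA/3α parent, with a `flip` switch for the opposite reading. $h$ is
interpreted as the kernel
standard deviation in residue units, the kernel support is untruncated,
and the normalisation makes homogeneous blocks read exactly ±1,
including at the edges.

## Conservation and the classifier

Per alignment column the consensus is the modal residue; gaps count as
mismatches and never as consensus. `*` marks perfect conservation;
`+` marks columns with consensus fraction ≥ 0.85 whose every variant is
hydrophobic (one substitution among seven rows gives 6/7 ≈ 0.857, i.e.
"85% conserved"; the threshold is configurable).

`classify_fold()` formalises the prose discrimination recipe, and is the
one genuinely composite rule in the package: per fold, the score is the
weighted fraction of its conserved sites matched by the query
(hydrophobic-class sites accept any hydrophobic residue), sites within
±3 residues of an F-value peak carry double weight, and a mismatch at a
perfectly conserved site vetoes the fold. The per-site evidence table
sums to the reported score.

## The Gō model

A native contact joins residues $|i-j| \ge 3$ with any heavy-atom pair
closer than 4 Å; its *contact number* is the count of such atom pairs,
and $C_{ij}$ is that count scaled to unit mean over all contacts. The
energy of conformation Γ is

$$
E(\Gamma) = \sum_i K_\theta (\theta_i - \theta_{0,i})^2
 + \sum_i \left[ K_{\phi 1}(1 - \cos \Delta\phi_i)
   + K_{\phi 3}(1 - \cos 3\Delta\phi_i) \right]
 + \sum_{\text{native}} \varepsilon \, C_{ij} B_{ij}\, u(r_{ij}/r_{0,ij})
 + \sum_{\text{non-native}} \varepsilon_{rep} \left( \sigma_{rep}/r \right)^{12},
$$

with $u(x) = 5x^{-12} - 6x^{-10}$ (minimum −1 at the native distance)
and $K_\theta = 20$, $a_\Theta = 0.6\pi$. $K_{\phi1} = 1$,
$K_{\phi3} = 0.5$, $\varepsilon = 1$ are package defaults (they set the
energy unit), as are the 12-10 well and the purely repulsive
$\sigma_{rep} = 4$ Å wall, truncated where it falls below ~10⁻⁶.

The orientation factor compares the angle $\Theta_{ij}$ between the
h-vectors $\mathbf h_i = \mathbf r_{i,i-1} + \mathbf r_{i,i+1}$ with its
native value:
$B_{ij} = \tfrac12\left[1 + \cos\left(\pi \min(|\Theta_{ij}-\Theta_{0,ij}|,\, a_\Theta)/a_\Theta\right)\right]$,
a raised cosine equal to 1 at the native orientation and 0 beyond
$a_\Theta$ — the simplest form satisfying the stated range and limits,
again isolated behind one function. Terminal residues have no h-vector,
so $B = 1$ there, as do degenerate (collinear) interior residues.

A native contact counts as *formed* when $r < 1.2\, r_0$ — the standard
convention in structure-based modelling — and $Q$ is the formed
fraction. Folding simulations are Metropolis Monte
Carlo with the same pivot moves as the coil sampler, keeping the two
engines consistent. The folding temperature is found by bisection until runs
started from the native state split their samples roughly evenly between
basins. The transition-state ensemble collects samples within one bin of
the interior free-energy maximum $Q^*$ of $-\ln P(Q)$, where the two
basins are the pair of well-separated local minima (≥ 0.3 apart in Q)
with the largest combined occupancy. Histogram bins are centred on
multiples of the bin width so the discrete Q levels of small topologies
(multiples of 1/`n_contacts`) never sit on a bin edge, and the barrier
is located on a three-bin moving average because small zipper-like
topologies produce parity-striped histograms (contacts forming in
correlated pairs); the reported free-energy profile is always raw.

## The synthetic generator and what the tests show

`make_structure()` builds ideal helices (1.5 Å rise, radius solved so
virtual bonds are exactly 3.8 Å), planar zigzag hairpins, three-helix
bundles and hairpin+helix hybrids, decorating each residue with two
pseudo-heavy atoms along the outward side-chain direction — the minimal,
deliberately non-physical decoration that lets the 4 Å and 5 Å
heavy-atom rules run. `make_chimera()` composes parent segments with
crossovers and point mutations; `make_alignment()` realises planned
per-column conservation fractions exactly for fractions of the form
k/rows.

The reference set behind the packaged statistics table mixes the four
kinds with the longest members helical, so the pooled mean distance
grows with the separation bin as it does in statistics compiled from
real globular proteins; early drafts that let the longest member fold
back on itself inverted the long-range trend and gave the coil
potential an unphysical long-range attraction.

What passing tests show — and do not show. The synthetic system
exercises every contract: exact bond geometry, Metropolis correctness
(flat-potential acceptance, Boltzmann occupancies against quadrature),
the F formula against brute force, conservation marks against planned
alignments, Gō invariants (unit-mean $C_{ij}$, native minimum, folding
at low temperature). It does not show where F-value peaks of real GA/GB
variants land: that depends on which reference structure set the
statistics were compiled from, so peak positions on real sequences are
explicitly outside the test gates. Likewise the
transition-state $Q^*$ of the real NMR structures requires PDB downloads
and long simulations; `inst/scripts/reproduce_go_ts.R` documents that
computation.

## Numerical choices and problem sizes

* σ floor of 0.5 Å in the statistics table; empty cells imputed from the
  residue-type-pooled mean for the same bin; separations beyond the last
  populated bin reuse it.
* Identity percentages round to the nearest integer (55/56 → 98); gap
  columns are excluded from the denominator (a declared convention).
* NMR multi-model files default to model 1, and the chosen model is
  recorded on every structure-derived object.
* Nonstandard residues map to the nearest standard letter where known,
  else `X`; `X` is excluded from type-pair statistics and takes pooled
  values in the potential.
* The test suite and the acceptance script run desk-scale problems —
  56-residue queries with 5 runs × 1500 sweeps for the pipeline stages,
  a 16-residue hairpin with 8 × 30000 sweeps for the transition-state
  analysis, 10⁵ sweeps for the Boltzmann check — sizes chosen so the
  whole battery runs in minutes on one core while every statistical
  check retains adequate power. Production analyses should use the
  defaults (10 × 60000 sweeps).

## Limitations

* The coil model knows nothing of secondary-structure propensity beyond
  what the distance statistics encode; with the packaged synthetic table
  the F profile is a demonstration of machinery, not biology.
* The Gō energy follows the stated contract in modulating the whole
  12-10 well by $B_{ij}$, so a native pair at a wrong orientation also
  loses its core repulsion; the non-native wall does not apply to native
  pairs. At $a_\Theta = 0.6\pi$ the effect is minor for compact states.
* `classify_fold()` needs the query pre-aligned to the profiles'
  coordinate system; no alignment is computed internally.
* Pseudo-heavy atoms are not rotamers: contact numbers on synthetic
  structures are stylised.
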