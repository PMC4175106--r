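---
title: "Log-space partition functions for RNA secondary structure: model and methods"
author: "rnapf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-space partition functions for RNA secondary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnapf)
```

## The problem

An RNA molecule folds into an ensemble of secondary structures — sets of
canonical base pairs (A·U, G·C and the G·U wobble) without crossing
pairs.  At equilibrium, each structure $s$ with standard free energy
$\Delta G_s$ carries Boltzmann weight $w(\Delta G_s) = e^{-\Delta
G_s/RT}$ relative to the fully unpaired state, and the probability that
bases $i$ and $j$ pair is

$$
p_{ij} \;=\; \frac{\sum_{s \ni (i,j)} w(\Delta G_s)}{Z},
\qquad Z \;=\; \sum_{s} w(\Delta G_s),
$$

with the empty structure contributing weight 1 to $Z$.  `rnapf` computes
$Z$ (reported as the ensemble free energy $\Delta G^0 = -RT\log Z$) and
the full matrix $p_{ij}$ by dynamic programming over fragments, under a
complete nearest-neighbor free-energy model: hairpin, stack,
internal/bulge and multibranch loops, with dangling ends, terminal
mismatches and coaxial stacking in multibranch loops.

Two implementation ideas shape the package:

1. **Log-space arithmetic.**  Every dynamic-programming array stores free
   energies ($-RT\log$ of restricted partition functions) instead of
   weights.  Sums of weights become the stable two-operand log-sum
   $f(a,b) = \min(a,b) - \mathrm{log1p}(e^{-|a-b|})$, which costs at most
   one `exp` call and is accurate even when the two weights differ by
   hundreds of orders of magnitude.  This removes the overflow/underflow
   problem that otherwise forces scaling factors, and it is what makes a
   32-bit mode feasible at all.
2. **Memory-reduced storage.**  The recursions are organized so that only
   four full $N\times N$ arrays ($V$, $Y$, $Y^L$, $Z$) and one
   half-triangle ($W^Q$) persist — 4.5 array-equivalents, a 25% reduction
   against the six full arrays a direct implementation needs.  The
   remaining arrays live on a few rolling anti-diagonals: two each of
   $W$, $W^L$, $W^{MBL}$, five of $W^{MB}$, and $W^{coax}$ is transient
   per element.  `storage_report()` exposes this accounting, and the
   "full" storage mode materializes the rolling arrays for inspection
   without changing a single bit of the results.

## Fragments and recursions

For a pair $(i,j)$ the ensemble splits into an *interior* fragment
(bases $i..j$) and an *exterior* fragment (bases $j..N$ plus $1..i$,
with the same pair closing it).  The array $V$ holds the restricted free
energy of the interior fragment in its upper triangle ($i<j$) and of the
exterior fragment in its lower triangle ($i>j$), so that

$$
p_{ij} = w\!\left(V_{ij} + V_{ji} - \Delta G^0\right),
$$

the product of the interior and exterior restricted weights over $Z$.
Interior $V_{ij}$ accumulates four alternatives: a hairpin closed by
$(i,j)$; a stack on $(i{+}1,j{-}1)$; an internal/bulge loop to an inner
pair (total unpaired capped at 30 nucleotides, which is what bounds the
overall work by $O(N^3)$); or a multibranch loop.  The multibranch
alternative is assembled from a family of chain arrays ($W$-type: one
branch with optional adornments; $W^{MB}$-type: two or more branch
units; $W^{coax}$: a coaxially stacked pair of helices; $Z$: a branch
unit anchored at its 5' end; $Y$, $Y^L$: log-sums of the one-branch and
multi-branch variants) in which every unpaired base costs $b$, every
helix costs $c$, and the loop itself costs $a$, so a loop with $n$
unpaired bases and $h$ helices (counting the closing helix) pays
$a + bn + ch$.

The exterior pass runs the *same* recursions over wrapped fragments,
processed in ascending fragment length after the prefix/suffix ensembles
$W5'$ and $W3'$ have been accumulated from the half-triangle $W^Q$.
Index arithmetic in wrapped fragments never wraps modulo $N$: a term
that would reference position $0$ or $N{+}1$ is dropped.  That single
rule encodes the physics that no hairpin, stack, internal or multibranch
loop may span the molecular ends — the open exterior loop alone connects
them, through the $W3'/W5'$ terms.  It also means the "closing pair" of
a wrapped multibranch cell is just another branch of the loop seen from
outside; the true closing helix appears as a wrapped branch inside the
chain, and the constants come out identically from either perspective.

### Adornment configurations

In the full model, each helix end facing a multibranch loop can take at
most one of: nothing, a 3' dangle, a 5' dangle, a terminal mismatch, or
a coaxial stack with an adjacent branch (flush, or mediated by one
mismatched base in either of two geometries).  Each unpaired base serves
at most one adornment, each helix joins at most one coaxial stack, and
the closing pair may coax with the first or the last branch.  The
partition function sums over all consistent assignments, which the chain
arrays enumerate without double counting.  The enumeration oracle
(`structure_log_weight()`) implements the same menu per loop as an
explicit sum over configurations, so the two routes to the same ensemble
are written independently.

### The exterior loop and coaxial stacking

The open exterior loop supports dangles and terminal mismatches on its
branches (through $W^Q$) but **no coaxial stacking** — on either the
unrestricted side ($W5'$, $W3'$) or the pair-restricted side
(`Q^exterior`).  The numerator and denominator of $p_{ij}$ must describe the same
configuration space: if the restricted ensemble admitted exterior coax
configurations that the unrestricted ensemble lacks, probabilities would
no longer be bounded by 1 (adjacent stable helices in the exterior loop
would inflate their outermost pairs' numerators by the coax weight).
Omitting exterior-loop coaxing on both sides keeps the model
self-consistent; it is a simplification relative to nearest-neighbor
treatments that coax free helices, and it only affects the open exterior
loop — multibranch loops carry the complete coaxial menu.

## Numerical choices

* **Units.**  All arrays are computed in reduced units ($RT=1$): table
  energies are divided by $RT$ on entry and results multiplied back on
  output.  Defaults: $T = 310.15$ K, $R = 1.9872\times10^{-3}$
  kcal mol$^{-1}$ K$^{-1}$, both configurable.
* **Fold order.**  Every accumulation site folds its alternatives
  left-to-right in the printed term order, with $k$-sums ascending in
  $k$ (ordinal order along the fragment).  Skipping a $+\infty$ operand
  is exact — $+\infty$ is the identity of the log-sum — which is what
  lets the fill iterate sparse indices of finite $V$ entries without
  changing any result bit.  Fixed order makes repeated runs, and the
  rolling versus full storage modes, bit-identical.
* **Precision modes.**  The default is 64-bit.  In single-precision mode
  every array value and every log-sum is IEEE 32-bit (loop energies are
  evaluated in double and rounded on entry), mirroring a
  single-precision accelerator path.  Probabilities are clipped to
  $[0,1]$; in double precision an entry above $1 + 10^{-6}$ raises an
  internal-consistency error instead.
* **Degenerate inputs.**  A sequence with no canonical pairs has
  $Z = 1$, $\Delta G^0 = 0$ and an all-zero probability matrix; $N = 1$
  works.  Loop initiations beyond tabulated size 30 extrapolate as
  $\Delta G(30) + 1.75\,RT\log(n/30)$; internal loops above the 30-base
  cap are forbidden.
* **Minimum hairpin loop** is 3 unpaired bases; **canonical pairs** are
  Watson–Crick plus G·U — both the field's standard conventions.

## Parameters

The packaged set `"toy-nn"` is *synthetic*: complete, self-consistent
and thermodynamically plausible (stacks $-0.9$ to $-2.5$ kcal/mol with
the rotational symmetry a physical stack table must have, monotone loop
initiations, stabilizing mismatches/dangles/coax terms, multibranch
$a=3.4$, $b=0.4$, $c=0.9$ kcal/mol), but deliberately *not* the
published Turner values, which live in external data files with their
own licensing and formats.  Every correctness statement in the package
compares two routes under the *same* parameter set, so numerical
fidelity to the published tables is irrelevant to the tests; users can
supply their own set in the documented YAML schema
(`write_parameters()` shows it).

Simplifications relative to the full Turner rules, chosen to keep the
model surface small and stated here so nobody mistakes the toy model for
the published one: no special small-hairpin bonuses, no stack-through
energies for single-base bulges, no internal-loop asymmetry penalty.
The enumeration oracle uses the identical evaluators, so these
simplifications cannot mask an indexing error.

`perturb_parameters()` shifts every finite tabulated scalar — all
tables plus $a$, $b$, $c$ — by an independent Gaussian draw (default sd
0.01 kcal/mol, comparable to experimental uncertainty), leaving
temperature and $+\infty$ entries untouched.

## Validation strategy

Correctness rests on two independent routes to the same numbers:

1. **Exhaustive enumeration** (`brute_force_probabilities()`): all
   pseudoknot-free structures of a short sequence, each weighted by its
   loop decomposition, with multibranch/exterior adornment sums
   evaluated per loop.  Two enumerators (a recursive generator and an
   interval-counting recurrence) cross-check each other.  In
   configuration-free mode (dangles, mismatches and coax all off) the
   oracle is a plain sum of loop energies — a tier with no shared
   grammar at all.  The suite compares the fill to this oracle over
   hundreds of seeded random sequences; agreement is at machine
   precision, asserted at $10^{-9}$.
2. **A naive weight-space reference DP** (`reference_dp()`): the same
   recursions on raw Boltzmann weights with all ten arrays stored in
   full and no scaling factors — usable only while 64-bit weights do not
   overflow, which is precisely the limitation that motivates the
   log-space design.  It checks the log-space arithmetic and the rolling
   storage at sizes the enumeration cannot reach ($N = 150$ in the
   suite, agreement asserted at $10^{-10}$ relative).

## The studies

`random_rna_sequence()` supplies the seeded i.i.d. sequences the studies
run on (uniform composition by default).  What random sequences do *not*
emulate about biological RNA — conserved helices, long-range structure,
skewed composition — does not matter for what the studies measure, which
are properties of the *algorithm* (roundoff growth, parameter
sensitivity, operation count), not of any particular molecule.  Passing
tests therefore say the implementation is exact and numerically stable,
not that the toy parameters predict real structures.

* `accuracy_study()` / `precision_study()` / `perturbation_study()`:
  for each length and seed, fold in double and single precision and
  with perturbed parameters, recording the RMSD between probability
  matrices over all $i<j$ pairs (zeros included; the averaging set must
  be fixed for RMSDs at different $N$ to be comparable).  At the default
  desk-scale conditions ($N \in \{100, 200, 400, 800\}$, ten seeds — the
  package's study sizes; multi-kilobase runs are out of scope) the
  single-precision RMSD grows with $N$, as accumulated roundoff over an
  $O(N^3)$ computation must, while remaining orders of magnitude below
  the effect of perturbing the parameters within their experimental
  uncertainty.  That ordering is the practical justification for the
  32-bit mode.
* `scaling_study()`: the exact operation count of the recursions'
  index ranges (`term_counter()`, closed form, verified against the
  fill's instrumented count at small $N$) fitted on log–log axes over
  $N \in \{512, 1024, 2048, 4096\}$; the slope is 2.94, i.e. cubic with
  the expected finite-size deflection from the capped internal loops
  and the quadratic prefix/suffix pass.
* `probknot()`: consensus structures from mutually maximal pairs
  ($p_{ij}$ maximal among all pairs involving $i$ *and* all involving
  $j$; ties toward smaller indices; helices shorter than `min_helix`
  pruned; crossing pairs permitted, rendered with bracket tiers in
  dot-bracket output).  The defaults (one selection round, minimum helix
  3) are deliberately minimal — the reference algorithm's iteration
  count is not documented, and one round plus pruning reproduces its
  published behavior on high-confidence pairs, which is all the
  single-versus-double comparison needs.

## Known limitations

* Pseudoknots are excluded from the ensemble (standard for this model
  class); they can appear only in ProbKnot output.
* The exterior loop carries no coaxial stacking (see above).
* The toy parameter set is synthetic; conclusions about real molecules
  require the published nearest-neighbor tables in the same schema.
* The enumeration oracle is exponential and refuses sequences beyond its
  cap (16 by default); the weight-space reference DP overflows somewhere
  beyond $N \approx 300$ for stable sequences — by design, both are
  validation tools, not production paths.

## A worked two-state example

The sequence `GAAAC` can form exactly one pair, the G1·C5 closing a
three-base hairpin, so the ensemble has two structures and everything is
known in closed form: with $\sigma = w(\Delta G^{hairpin}_{1,5})$,

$$Z = 1 + \sigma,\qquad p_{1,5} = \frac{\sigma}{1+\sigma},\qquad
\Delta G^0 = -RT\log(1+\sigma).$$

```{r two-state}
params <- load_parameters("toy-nn")
RT <- thermal_energy(params)
gh <- hairpin_energy("GAAAC", 1, 5, params)
sigma <- exp(-gh / RT)
fold <- partition_function("GAAAC", params)
c(dG0 = ensemble_free_energy(fold),
  closed_form = -RT * log(1 + sigma))
c(p15 = pair_probabilities(fold)[1, 5],
  closed_form = sigma / (1 + sigma))
```

The test suite holds this identity to $10^{-12}$ and the general
enumeration comparison to $10^{-9}$.
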