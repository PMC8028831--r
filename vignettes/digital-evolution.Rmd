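---
title: "Digital evolution of metabolic signaling: model and methods"
author: "avidula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital evolution of metabolic signaling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avidula)
```

# The model

`avidula` simulates populations of self-replicating computer programs
("digital organisms") evolving on a small toroidal lattice.  Each organism
is a genome of exactly 120 instruction sites, each holding one of 32
single-character instruction codes (`instructionTable()`); a virtual CPU
with three 32-bit registers (AX, BX, CX), two stacks, four heads
(instruction pointer, read, write, flow) and a 3-deep input buffer
executes the genome cycle by cycle.  Organisms replicate by allocating a
240-site memory image (`h-alloc`), copying their genome site by site
(`h-copy`) and splitting off the offspring region (`h-divide`); the
canonical copy-loop uses `h-search` to set the flow head, `if-label` to
detect that the terminal nop label has just been copied, and `mov-head`
to close the loop.  Template matching is by cyclic nop complement
(nop-A→nop-B→nop-C→nop-A).

## Metabolism and merit

The environment supplies uniformly random 5-bit integers whenever an
organism executes an IO instruction.  An output is checked against every
unary application (NOT) and every ordered pair of distinct entries of the
recent-input buffer for the nine logic tasks (NOT, NAND, AND, ORN, OR,
ANDN, NOR, XOR, EQU), all in 5-bit arithmetic; the reward weights
(1, 1, 2, 2, 4, 4, 8, 8, 16) double with rough circuit complexity
(`taskTable()`, `taskComplexity()`).

Each task has its own chemostat resource held near a target level $R^*$
per lattice site: per update each cell's level relaxes as
$L \leftarrow L + \delta (R^* - L)$ (default $\delta = 0.01$) and then
diffuses toward its 8-neighborhood mean with coefficient 0.5, which
conserves totals and erases spatial heterogeneity quickly.  A task
performance consumes $\min(f L, c_{\max})$ with uptake fraction
$f = 0.0025$ and cap $c_{\max} = 1$, and accrues a pending merit bonus of
(task value × consumed).  Merit — the organism's execution-speed
weight — is applied at divide:

$$\mathrm{merit} = 120 \times \Bigl(1 + \sum \mathrm{value} \times
\mathrm{consumed}\Bigr),$$

with 120 (the genome length) as the basal floor, inherited by the
offspring.  No reference source fixes the functional form of the reward;
this linear, resource-limited form preserves the relative task weights,
keeps merit finite per gestation, and lets rewards be earned repeatedly
within one gestation.  A consequence worth knowing: because the
scheduler normalizes total execution per update, merit is a *relative*
advantage — in a world where every organism's merit rises by the same
factor, births per update do not change.

## The world and the scheduler

The world is a width × height torus (near-square factorization of the
requested site count, `worldDims()`), one organism per cell.  Per update,
$30 \times N$ CPU cycles ($N$ = organisms alive at the start of the
update) are allocated proportionally to merit with largest-remainder
rounding, so the total is exact and an equal-merit population receives
exactly 30 cycles per organism.  The per-update quota belongs to the
*cell*: an offspring that replaces an occupant mid-update inherits its
victim's unspent cycles (an offspring born into an empty cell starts at
the next update).  This makes the cycle-conservation identity
`cycles = 30 * population` exact in the event log.  Organisms die only by
replacement: a divide places the offspring in the cell the parent faces,
killing any occupant.  Messages — register pairs (BX, CX) sent with
`send-msg` or broadcast with `bcast1` — are collected during the update
and delivered to the recipients' 32-deep FIFO queues at its end; messages
into empty cells are discarded.

Mutation acts at divide as a whole-genome pass: each of the 120 sites is
independently selected with the configured probability (study rates
7.5e-4 and 7.5e-3) and rewritten by a uniform draw over all 32 codes.
The configured rate is therefore a substitution *event* rate
(self-substitutions are allowed), and insertions/deletions do not exist,
so genome length is invariant.  The VM's `h-copy` also supports a
per-copy substitution probability; the evolutionary loop keeps it at
zero so that mutation is never double-counted.

## Conventions the instruction set needed but no source fixes

* `h-search` with a label places the flow head at the *start* of the
  first complement occurrence (scanning forward with wraparound), sets
  BX to the distance and CX to the label size; with an empty label it
  places the flow head immediately after the instruction and zeroes
  BX/CX; with no match it leaves the flow head at the instruction.
* `h-alloc` extends memory to 240 nop-X-filled sites and places the
  write head at site 120.  With the flow-head-at-label-start convention
  above, the classic trick of searching for the end label to position
  the write head past it is unavailable, so allocation itself
  establishes the offspring region.
* `if-label` with an empty template never matches; the skipped
  instruction costs no cycle.  The copied-label register tracks the most
  recent run of consecutively copied nops (capacity 10) and is cleared
  whenever a non-nop is copied.
* A nop immediately following an instruction selects its operand
  (nop-A: AX/instruction pointer; nop-B: BX/read head; nop-C: CX/write
  head) and is consumed in the same cycle.  nop-X is never a modifier
  or label symbol.
* Registers are 32-bit unsigned; task checking masks outputs to 5 bits.
* Unknown characters in serialized genomes decode as nop-X.

# The ancestor and the archetype fixtures

`buildAncestor()` is pinned at `inst/extdata/ancestor.txt`: prologue
`w E`, a NOT segment `y o p c u y` (load input, duplicate into CX via
the stack, NAND it with itself, output the complement), a nop-X barrier
so the filler cannot act as an operand modifier, nop-C filler, and the
terminal loop `z v f c a x g` with end label `a b`.  Its gestation is
471 cycles (7 prologue + 1 barrier + 102 filler + 1 search + 120 × 3
loop cycles), it performs NOT exactly once per gestation, and it
replicates faithfully.

`makeFixtures()` constructs the archetypes that stand in for evolved
genotypes when exercising the assays.  The multi-copy replicators
(`loop-2x-*`, `loop-4x`) copy 2 or 4 sites per loop pass; the variants
without `if-label` gate division by comparing the write-head position
with its origin (`get-head` + `if-n-equ`), so they lack label-based
validation yet still divide exactly on completion.  `loop-no-iflabel`
shows what removing the guard really costs: division fires on the first
pass and the offspring is a partial copy.

The `messenger` archetype is the signaling-positive model organism.  It
broadcasts a constant jump hint (CX = 32) early in its gestation;
receivers zero BX/CX, retrieve a message, and execute `jmp-head`, which
skips a countdown burn-loop that otherwise costs them roughly 115
cycles.  Messaging thus shortens realized gestation — the only channel
by which a process can raise births/update in a monoclonal world — and
knocking out `send-msg`/`retrieve-msg`/`bcast1` removes about 20% of its
assayed fitness.  The `messenger-pair-A/B` fixtures implement the
cooperative division of labor instead: A computes and outputs OR and
broadcasts the result; B (which performs no task alone) NOTs any
received value and broadcasts it back; A then outputs the returned
value, which is NOR of *its own* inputs and passes task checking.
Jointly they perform a task neither performs alone.

What the fixtures do *not* emulate: evolved genomes are mosaic,
carry duplicated copy elements outside the terminal loop, and mix
strategies; the fixtures isolate one mechanism each with deterministic
layouts.  Passing fixture tests therefore validates the assay
machinery and the existence of each strategy, not the evolutionary
frequency of any of them.

# Assays

* `fitnessAssay()`: 200 copies of one genotype in a 225-cell world
  (seeded uniform placement and facings), mutation zero, 100 updates of
  stabilization, fitness = mean births/update over the next 400.  The
  world size is the smallest near-square lattice comfortably holding
  200 organisms; the resource level defaults to saturating (10,000) and
  should be set to the treatment level when comparing against evolved
  conditions.
* `isolationAssay()`: one organism, no neighbors, saturating resources;
  merit at first divide, gestation in cycles, and merit/gestation as
  the platform-internal fitness.  Budget: 10 × the ancestor gestation.
* `viability()`: the fraction of genomes that divide in isolation with
  an offspring *identical* to the parent within the budget.  Requiring
  faithfulness makes "able to replicate" decidable in one gestation:
  with mutation off, a faithful divider renews itself indefinitely,
  while premature dividers produce nop-X-padded junk.
* `phenotypeProfile()`: one scripted-input execution through gestation;
  task counts and the 512-class phenotype index.
* `marginalUtility()`: (F − F_knockout)/F under one shared seed; 0 by
  contract when the process is absent, NA when F = 0.
* `jointPhenotype()`: two genotypes seeded adjacent and facing each
  other; per-genotype task totals accumulated over faithful
  descendants.

# Population statistics

Fitness distributions are summarized by a Gaussian KDE with Silverman's
rule-of-thumb bandwidth on a 512-point grid spanning the data ± 3
bandwidths; peaks are strict local maxima of the evaluated density and
each peak's genotype sample is all values within ± 2 bandwidths.
Unimodality is tested with the Hartigan dip statistic, implemented from
the convex-minorant/concave-majorant characterization: for each
candidate mode the best convex fit left of it deviates from the
empirical cdf by half the largest gap between the upper step corners
and the greatest convex minorant of the lower corners (mirrored on the
right); the dip is half the minimax over modes, floored at $1/(2n)$.
P-values come from a seeded bootstrap under the uniform null, which
calibrates the test against the same implementation.

Genotypic heterogeneity is the sum over the 120 sites of the per-site
Shannon entropy of instruction frequencies (natural log, $0 \ln 0 = 0$);
phenotypic heterogeneity is the entropy of the population's distribution
over the 512 phenotype classes.  Signaling classification pools marginal
utilities of messaging over genotypes, locates the utility peak nearest
zero and the densest positive-shifted peak, takes their midpoint as the
threshold, and labels a population signaling-positive when its *median*
utility exceeds it (medians, not means, because utility distributions
within a population are skewed by occasional lethal knockouts).  When
the pooled distribution does not separate into two peaks the fallback
threshold 0.05 is used, with a warning.

# Problem sizes and reproducibility

The desk-scale preset (`conditionGrid()`) uses world sizes {50, 200},
resource levels {0.1, 100, 10000}, 10 replicates and 20,000 updates;
`paperGrid()` exposes the full grid (decade resources 0.1–10,000, sizes
50–500, 100 replicates, 100,000 updates) for cluster-scale use.  These
desk sizes were chosen so that a full grid cell runs in minutes while
still showing the qualitative phenomena: fitness gain over the ancestor
in a minority of high-mutation-rate replicates, and nonzero
mutation–selection-balance heterogeneity.  Every source of randomness
runs through R's RNG, so a `seed` makes any run, assay or grid
bit-reproducible; `deriveSeed()` maps (condition cell, replicate) pairs
injectively to seeds below $2^{31}$.

# Known limitations

* The instruction set is one concrete 32-code choice; evolved outcomes
  (peak positions, incidence curves) depend on it quantitatively, so
  only qualitative regeneration of those phenomena is in scope.
* Organisms never die of age or starvation — only by replacement — so
  populations cannot go extinct after seeding; extinction bookkeeping
  exists but reports zeros.
* The linear, repeatable merit reward makes task-spamming a strong
  evolutionary attractor at abundant resources; evolved genotypes often
  trade longer gestation for enormous merit, which raises in-world
  competitiveness but lowers monoclonal births/update.  This is the
  package's chosen economy, stated here so that fitness comparisons are
  read correctly.
* The dip statistic cannot be cross-checked against an external
  reference implementation in this environment; its tests rest on
  hand-derivable exact values, invariances, and the self-calibrated
  bootstrap.
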