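---
title: "Motif-constrained RNA library design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-constrained RNA library design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamotiflib)
```

## The design problem

Classical inverse RNA folding asks for a sequence $\phi \in \{A,C,G,U\}^n$
whose predicted secondary structure equals a fixed, fully specified
dot-bracket target. Practical design campaigns rarely start from such a
target: they start from *motifs* — fragments of sequence and structure that
must appear somewhere in the construct — with everything in between left
open, including the total length.

`rnamotiflib` expresses this as a constraint satisfaction problem over pairs
of constraint strings. The sequence channel uses the alphabet
$\{A, C, G, U, ?\}$ and the structure channel $\{., (, ), ?\}$, where `?`
leaves a single position unconstrained. A second wildcard, `?*`, marks a
region of arbitrary (bounded) length that is unconstrained in both channels.
A *design space* is the pair of aligned constraint lines together with total
length bounds; splitting the lines at `?*` yields its motif sequence. For
example

```
sequence:  ?*?GUAA??*
structure: ?*(....)?*
```

is the space of all RNAs, of any length inside the configured bounds, that
contain a GNRA-type tetraloop hairpin (here with the concrete loop `GUAA`)
anywhere. Structure constraint lines may contain unbalanced brackets; a
bracket constrains only its own position, which is what permits "this
position is paired" statements without naming the partner.

Two relations connect candidates to a design space. The *hard-constraint
relation* demands that every concrete sequence symbol is matched by the
candidate and every concrete structure symbol by the candidate's folded
structure, position by position. The *folding relation* applies a folding
engine $F$ to the designed sequence and evaluates the structure channel on
$F(\phi)$. Objectives (structure satisfaction, GC content, plug-in scores)
are deliberately separated from the space definition.

## Sampling fixed-length tasks

A `?*`-containing space is an infinite family of fixed-length *tasks*. The
sampler first draws the total length uniformly from the feasible interval,
then distributes the surplus beyond the fixed tokens over the `?*` regions
uniformly at random over weak compositions (stars and bars). Neither choice
is canonical — no distribution over lengths or compositions is prescribed by
the problem — but uniform-by-length first matches the goal of libraries
spread evenly across lengths, and uniform compositions maximise positional
diversity of the motifs. Both draws use R's RNG, so `set.seed()` governs
reproducibility end to end. A space without `?*` must carry length bounds
equal to its fixed length; a space with `?*` and no bounds is rejected,
because the CSP would be infinite.

## The decision process

Each task is solved by a sequential decision process. Unconstrained sequence
positions are visited left to right. The observation at step $t$ is the
$(2\kappa + 1)$-gram of the jointly encoded task centred on the $t$-th
unconstrained position; each position maps to the index $4s + t$ of its
(sequence symbol, structure symbol) pair, with a dedicated pad symbol (index
20) filling $\kappa$ positions at both ends. The *state radius* $\kappa$
(default 16 for the policy network, 8 in the desk-scale protocols) trades
context against model size. A flag controls whether already-placed
nucleotides replace their wildcard in later observations; it is implemented
by re-encoding the partially filled task, so observations are a pure
function of (task, fills).

Actions 0–3 place A, G, C, U. With *action semantics* enabled, an action at
a matched opening bracket whose partner is also unconstrained places the
Watson–Crick complement at the partner position and removes it from the
visit order; unmatched brackets (legal, since bracket composition is free)
receive a single nucleotide. Episode length is therefore the number of
unconstrained positions minus the auto-filled partners. The reward is
computed only at the terminal step: the full sequence is folded and the
configured objective evaluated.

## Objectives

The structure loss counts violated concrete structure symbols (a Hamming
distance restricted to constrained sites). The terminal reward is
$(1 - L_{\omega}/|\omega|)^{\alpha}$; with a GC-content target the weighted
sum $\beta L_{\omega}/|\omega| + \gamma L_{GC}$ replaces the normalised
loss, clipped to reward 0 when it exceeds 1. Defaults are
$\alpha = \beta = \gamma = 1$ and a GC tolerance $\epsilon = 0.01$; the
exponent is exposed because reward shaping is the usual tuning knob for this
family of agents.

Two plug-in transforms adapt external scorers: a covariance-model bitscore
passes through unchanged with $-200$ substituted for "no match", and an
RNA–RNA interaction energy $E$ becomes $(-E)^3$ so that lower energies give
steeply larger rewards. The scorers themselves (e.g. Infernal, IntaRNA) are
adapters supplied by the user; the package ships the contracts and
transforms only.

As an alternative structure distance, a Weisfeiler–Lehman kernel on
structure graphs is provided: positions are nodes labelled by their
dot-bracket symbol, edges are backbone adjacencies plus matched base pairs,
labels are refined for $h$ rounds (default 2) by hashing each node's label
with the sorted multiset of its neighbours' labels, and structures are
compared by the cosine of their label-count vectors. The cosine
normalisation is a deliberate choice: a plain dot product grows with
sequence length and would leave the distance unbounded, whereas
$d_{WL} = 1 - \cos$ lies in $[0, 1]$, is symmetric, and is zero exactly on
label-isomorphic graphs.

## Local refinement

Two refinement steps post-process candidates that are close to valid. The
*local improvement step* activates when at most `max_mismatches` (default 5)
constrained positions disagree; it exhaustively re-enumerates the
unconstrained positions within radius 1 of a mismatch and keeps the
assignment with minimal structure loss, ties resolved by enumeration order.
The enumeration is capped (default 256 assignments, folded in one batch)
because the gate alone would admit $4^{15}$ folds in the worst case. The
*GC improvement step* runs whenever the improvement step is active and a GC
target is set: it greedily swaps unconstrained A/U positions to G/C (or vice
versa), one position per step, choosing the swap with the smallest
structure-loss increase, and stops inside the tolerance band or when a swap
can no longer reduce the deviation (each swap moves the GC content by
exactly $1/n$, so the loop provably terminates). Neither step ever touches a
constrained sequence position; both can at most improve the structure loss
relative to their own search neighbourhood, and the greedy GC walk accepts
the documented risk of a locally suboptimal structure loss in exchange for
hitting the GC band.

## The agent

The policy maps an observation window to action probabilities through a
symbol embedding (dimension 8), dense ReLU layers (default one layer of 32
units) and a softmax. Training is episodic REINFORCE with a running-mean
baseline, an entropy bonus (default $10^{-3}$), global gradient-norm
clipping and Adam. Updates are synchronous minibatches of 8 episodes —
asynchronous updates would introduce scheduler-dependent nondeterminism,
and exact reproducibility from a seed was weighted higher here. The wider
architecture family for this agent class also includes convolutional and
recurrent layers; this implementation commits to the compact dense policy
(the configuration surface rejects other settings explicitly) because it
keeps the whole learner dependency-free, exactly reproducible and fast
enough for desk-scale experiments. The default Adam step size is 0.01: on
the four-armed bandit reduction (one free position, reward 1 for a single
nucleotide) the policy then concentrates more than 0.9 probability on the
rewarded action within 1000 episodes, which is the calibration used for all
defaults.

The design loop repeatedly samples a task, runs one episode, applies the
refinement steps, and emits the candidate with its scores and a solved flag
(hard constraints plus objective satisfaction). With adaptation on, policy
updates continue between episodes; a restart timer (default 1800 s) resets
the parameters to their exact initial values, which guards against
objective-specific overfitting during long runs. A uniform random agent
with the identical stream contract serves as the baseline.

## Synthetic training corpus and masking

Training tasks are manufactured from a synthetic corpus: uniform-random
sequences with lengths drawn from one of three ranges (50–200 nt, 200–350
nt, or mixed 50–350 nt), folded by the configured engine. The corpus
emulates only the *shape* of a curated RNA family collection — sequence
lengths and fold-consistent structures — not its homology structure,
conservation patterns or base composition biases; a two-column file of real
(sequence, structure) pairs can be substituted for fidelity runs.

Masking proceeds in three steps: (1) a part count is drawn uniformly from
{0, …, 5} and that many non-overlapping structure intervals are masked, each
of length at most 20% of the sequence (positions and lengths uniform); (2)
the sequence is masked on the complement of the structure mask, producing
alternating constraints, and a drawn part count of zero yields a pure
inverse-folding task (the count includes zero precisely so such tasks arise
naturally); (3) with probability 0.2 a sample instead receives independent
Bernoulli(0.5) sequence masking, emulating design from arbitrary mixed
motifs. The per-position density 0.5 in step (3) is this package's choice;
published task-mix proportions cannot be derived unambiguously from the
procedure's description, so no claim is made to reproduce them exactly.

## Folding engines

A bundled Nussinov folder (maximum base pairing with Watson–Crick and GU
wobble pairs, minimum hairpin loop 3, deterministic tie-breaks preferring
the unpaired 3' end and then the earliest partner) makes the entire toolkit
runnable without external software; it is a test and teaching engine, not a
thermodynamic predictor. For realistic work the `RNAfold` interface
provides MFE and MEA structures (batched through a single process call;
temperature and dangle options follow RNAfold's defaults). Engine identity
is recorded in every report and manifest. A known asymmetry is documented:
the episode's pair action places only Watson–Crick pairs, while both bundled
and external engines may predict GU pairs — biologically sensible, and the
agent can still discover GU pairs through single placements.

## The riboswitch protocol

The transcriptional theophylline riboswitch experiment uses a design space
reconstructed from the published construction protocol: the 42-nt TCT8-4
aptamer, a 6–20 nt spacer, a 10–21 nt region complementary to the aptamer's
3' end, and an 8-U tail, giving total lengths 66–91 nt. The first 10
complement nucleotides are common to all constructs and therefore fixed in
the space; the structure line constrains a 10-bp terminator stem core and
the unpaired U-stretch, leaving the aptamer body free (in the
terminator-formed state its 3' end is sequestered, so constraining the full
aptamer fold would contradict the terminator). The packaged definition is
labelled synthetic because the original machine-readable record is not
bundled; the reconstruction is pinned down by two independent published
quantities that it reproduces exactly — the total length bounds and the
achievable GC margins (0.29–0.63 after rounding).

The baseline sampler mirrors the original library construction (random
spacer, exact reverse-complement region, fixed tail). Validity of a
candidate is, by default, the hard-constraint relation of its instantiated
task evaluated on the MFE fold; the criteria object is pluggable because
published screening pipelines apply additional, partly unpublished filters.
Library reports count distinct folded structures over all candidates, with
the valid-only count reported alongside, since either convention is
defensible. Note that the design space carries only total-length bounds:
a sampled task may allocate the variable regions differently from the
per-component ranges of the construction protocol, which only the baseline
sampler enforces.

## Problem sizes and numerical choices

The bundled experiments use desk-scale sizes chosen once: riboswitch
libraries of 50,000 candidates per seed (two seeds in the acceptance
script) for the baseline statistics, 2,000 candidates for the agent versus
random comparison with a 300-episode pretraining phase on 60 masked
synthetic tasks, 1,000 episodes for the bandit calibration, and
brute-force cross-checks on sequences of at most 12 nt. Degenerate inputs
are handled explicitly: a task with no unconstrained position is a
zero-step episode evaluated immediately; empty pending sets, zero-length
surpluses and all-`?` constraint channels are all legal. All tie-breaks
(folding traceback, refinement enumeration order) are deterministic, and
every stochastic component draws from R's RNG only.

## Known limitations

Pseudoknots, IUPAC ambiguity codes beyond `?`, multi-target structures and
partition-function objectives are out of scope. The dense policy is far
smaller than tuned architectures from large-scale hyperparameter searches;
it demonstrates the learning dynamics and beats the random baseline at desk
scale, but published large-budget solved-rate numbers should not be expected
from it. The synthetic corpus does not model homology or composition bias,
so passing tests show correctness of the pipeline, not performance on any
real RNA family. Covariance-model and interaction-energy scorers are
adapter contracts; the corresponding external tools are not bundled.
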