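# rnamotiflib

Motif-constrained RNA library design with reinforcement learning.

## The problem

Most RNA design tools solve inverse folding: given one fully specified
dot-bracket target of fixed length, find a sequence that folds into it. Real
design campaigns — riboswitches, scaffolds with tertiary-contact loops,
interaction partners — start instead from *motifs*: fragments of sequence
and/or structure that must occur somewhere in the construct, with the rest
(including the total length) left open.

`rnamotiflib` is for computational RNA designers who want *libraries* of
candidates from such partially constrained spaces. A design space is a pair
of aligned constraint strings over `{A,C,G,U,?}` and `{.,(,),?}`, plus the
variable-length wildcard `?*` (unconstrained region of any length within
configured bounds):

```
sequence:  ?*?GUAA??*        # any construct containing a GNRA-type tetraloop
structure: ?*(....)?*
```

Brackets may be unbalanced — a bracket constrains only its own position, so
"this position is paired" never requires naming the partner.

## The method

Fixed-length tasks are sampled from the space (uniform over lengths, then
uniform over weak compositions of the surplus across `?*` regions). Each
task becomes an episode of a Markov decision process: the agent scans the
unconstrained sequence positions left to right, observing a `(2κ+1)`-gram of
the jointly encoded sequence/structure constraints, and places nucleotides
(Watson–Crick pairs at matched bracket pairs). At the terminal step the
sequence is folded and rewarded with

    R_T = (1 − L_ω/|ω|)^α,

where `L_ω` is the number of violated structure constraints; with a GC
target, `β·L_ω/|ω| + γ·L_GC` replaces the normalised loss (reward 0 when the
sum exceeds 1, tolerance ε = 0.01 on the GC deviation). The policy
(embedding + dense softmax network) is trained by policy gradient on masked
synthetic folding tasks and can keep adapting while designing, with periodic
restarts to its initial weights. Local and GC improvement steps refine
near-miss candidates. Folding goes through a uniform engine contract: a
bundled, dependency-free Nussinov maximum-pairing folder, or ViennaRNA's
`RNAfold` (MFE or MEA). A Weisfeiler–Lehman graph distance between
structures and plug-in reward transforms (covariance-model bitscores with a
−200 no-match floor; cubed negated interaction energies) support alternative
objectives.

## Worked example

```r
library(rnamotiflib)
set.seed(7)
sp  <- parse_design_space("?*?GUAA??*", "?*(....)?*", min_len = 12, max_len = 30)
pol <- build_policy(policy_config(), kappa = 8)
cfg <- env_config(state_radius = 8, engine = viennarna_engine("MFE"))
lib <- design(pol, sp, structure_objective(), n_candidates = 5,
              env_cfg = cfg, seed = 7)
lib[, c("length", "sequence", "structure", "gc", "reward", "solved")]
```

```
 length                   sequence                  structure        gc    reward solved
     21      GGCGUAAAAGAUCUUCCGGCC      (((...............)))  0.571429 0.9523810  FALSE
     23    CCGCUCGCGUAAGUUGGCAAAUU    ..(((.((....)).))).....  0.521739 1.0000000   TRUE
     19        UAGGCCAUUUGCGUAAGCG        ..........((....)).  0.526316 1.0000000   TRUE
     26 GGUCCUAUGGUAACCGUGCGUCCCUA ((.(.(((((...))))).).))...  0.576923 0.9615385  FALSE
     20       GGCGGUGAUUAUCAGUAAGC       .((..(((...)))....))  0.500000 0.9500000  FALSE
```

Each row is one sampled task solved in one shot: `reward` is the structure
objective on the MFE fold of the designed sequence, and `solved` flags
candidates whose fold satisfies every constrained position of their task —
here the hairpin `(....)` enclosing the `GUAA` loop (see rows 2 and 3).
Candidates can be written as FASTA plus a TSV sidecar with
`write_candidates()`.

The packaged riboswitch protocol designs transcriptional theophylline
riboswitches (TCT8-4 aptamer, variable spacer, terminator-forming
complement, 8-U tail; 66–91 nt):

```r
rs <- riboswitch_space()
round(gc_bounds(rs), 2)
#> [1] 0.29 0.63
set.seed(1)
library_report(wachsmuth_sample(5000), engine = viennarna_engine("MFE"))
#> Candidate library report (engine: RNAfold-MFE)
#>   candidates:             5000
#>   valid candidates (%):   59
#>   unique structures:     2933 (valid only: 1697)
#>   length range:           66-91 nt
```

A command-line interface with `design`, `fold`, `gen-data`, `riboswitch`
and `train` subcommands lives at
`system.file("cli", "rnamotiflib.R", package = "rnamotiflib")`; every run
writes a JSON manifest (configuration, seed, engine identity, version).

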