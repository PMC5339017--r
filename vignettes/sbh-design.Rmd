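---
title: "Designing spacer-blocking-hairpin and inducible sgRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing spacer-blocking-hairpin and inducible sgRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbhdesign)
```

## The design problem

An SpCas9 single guide RNA (sgRNA) starts with a 20-nt spacer that base-pairs
the DNA target; everything downstream is the ~80-nt tracrRNA scaffold. Because
targeting is Watson–Crick pairing, a 5′ extension complementary to the spacer
folds the guide back on itself into a *spacer-blocking hairpin* (SBH): the
spacer is sequestered in a stem and the guide is silenced. Cutting the
connecting loop releases the back-fold and restores activity, which turns the
hairpin into a conditional switch (an inducible SBH, iSBH): the loop can be an
endoribonuclease recognition motif (Csy4, Cas6A), an antisense-oligonucleotide
(ASO) sensing loop cleaved by RNase H on ASO binding, or a self-cleaving
ribozyme.

`sbhdesign` implements the design side of this system: assembling the
constructs, predicting whether they fold as designed, enumerating design
series, evolving sensing loops shared across several guides, and emitting the
DNA oligos to clone them.

## Construct grammar

A construct is `back-fold + loop unit + spacer (+ scaffold)`, with 0-based
half-open region coordinates and the 5′-most nucleotide at position 0.
`SBH(x)` leaves the x *scaffold-proximal* (3′) spacer nucleotides unpaired;
the back-fold covers the loop-proximal 5′ segment. This placement is forced by
the topology: the loop joins the back-fold 3′ end to the spacer 5′ end, so
uncovered nucleotides can only accumulate at the spacer 3′ end.

Bulges destabilize the stem so that cleavage-mediated strand separation is
thermodynamically easier while OFF-state silencing is retained. The default
two-bulge (0B) pattern places 2-nt bulges on the *spacer strand* at paired-stem
indices 5 and 12 from the loop (the back-fold simply skips their complements,
leaving the spacer sequence untouched for DNA targeting). The exact published
positions are supplementary-only, so these are configurable defaults.

```{r}
sp <- spacer_record("demo", "GGTCGACCTCGAGTCAGTCA")
cons <- assemble_sbh(sp, cleaving_units()$basic_loop,
                     bulge_pattern = default_bulge_pattern())
cons
```

**The basal (0B\*) bulge.** The destabilizing third bulge of the 0B\* variant
is realized as 2 spacer nucleotides left unpaired at the very base of the stem
(stem index 14). Of the realizations we evaluated, this is the only one with a
*guaranteed* direction of effect: the 0B\* guide is a suffix of the 0B guide,
so every structure available to 0B\* is available to 0B at the same or lower
energy, and the free-energy ordering ΔG(0) ≤ ΔG(0B) ≤ ΔG(0B\*) holds for every
sequence rather than statistically. An internal basal bulge (index 13) leaves
a lone terminal pair and occasionally *stabilizes* the hairpin through
alternative alignments of the altered back-fold; a back-fold-strand insertion
stabilizes roughly half of random cases because the inserted bases find
partners. Both were rejected on those grounds.

**Graft geometries.** A cleaving unit grafts at the apex (replacing the loop;
"full"), at the loop-proximal bulge ("medium") or at the scaffold-proximal
bulge ("nano"). For the bulge modes the stem between the apex and the chosen
bulge is deleted on *both* strands and the unit bridges the cut points; the
chosen bulge's unpaired nucleotides are kept at the junction. Whether the
published designs delete one strand or both is not stated in the main text;
both-strand deletion is implemented because it is the only variant that keeps
the stem a proper duplex, and it reproduces the shortened effective spacers
(15 and ~8 nt) consistent with the observation that spacers down to 10 nt
still direct activation.

**Residual 5′ nucleotides.** After in-silico cleavage at the unit's cut site,
we count the nucleotides left 5′ of the targeting spacer *net of the guide
segment the Cas protein accommodates*:

    residual = max(0, unit_tail + spacer_region_length − native_spacer_length)

The rationale: dCas9 buries a ~20-nt 5′ guide segment; when the bulge-graft
geometries shorten the retained spacer, the shortfall absorbs part or all of
the cleavage tail. With the 28-nt Csy4 unit (cut after position 20, 8-nt tail)
this yields residuals of 8 / 3 / 0 nt for full / medium / nano — the ordering
that motivates the nano design. For a full-length spacer the formula reduces
to the plain "tail plus junction" count.

## The folding engine

No thermodynamic folding backend is assumed to exist on the host system, so
the package ships its own engine (`fold_engine()`, "nnfold") behind the same
pluggable interface an external engine would use. It is a standard Zuker-style
minimum-free-energy dynamic program with a McCaskill-style partition function
for pair probabilities, at 37 °C, with a nearest-neighbour model:

* Watson–Crick + GU wobble pairs; Turner-2004-style 6×6 stacking table;
* hairpin / bulge / internal-loop initiation by length with
  Jacobson–Stockmayer (1.75 RT ln) extrapolation; minimum hairpin loop 3 nt;
* internal-loop asymmetry at 0.6 kcal/nt capped at 3.0 kcal;
* 0.5 kcal terminal penalty for AU/GU helix-closing pairs;
* affine multiloop model (3.4 close, 0.4 per branch, free unpaired bases);
* no dangling ends or terminal-mismatch bonuses; interior loops capped at 30
  unpaired nucleotides; pseudoknots not modelled.

Omitting mismatch/dangle terms makes absolute energies ~1–1.5 kcal/mol less
negative per loop than mismatch-aware engines, but preserves orderings, which
is what every design decision in this package rests on. The dynamic program
and the partition function are validated in the test suite against exhaustive
structure enumeration with an independently written energy evaluator; pair
probabilities are checked against the brute-force Boltzmann ensemble.
Published stem free energies computed with other engine families should be
compared with a cross-engine tolerance of roughly ±1.5 kcal/mol; with this
engine's reduced loop model, ordering comparisons are meaningful, absolute
reproduction of another engine's printed values is not guaranteed.

`stem_free_energy()` folds the hairpin region only (back-fold + loop +
spacer); the scaffold is excluded by default since its own strong
self-structure would dominate the statistic. Whether published stem energies
are whole-hairpin MFEs or duplex-only energies is unstated; whole-hairpin is
the default and `with_scaffold = TRUE` folds the complete guide.

## Folding scores

The per-spacer folding score FS ∈ [0, 1] measures agreement between the
predicted and the designed fold. The expected fold asserts: back-fold
positions paired to their designed spacer partners, bulged/free/loop positions
unpaired (units with internal structure of their own, like Csy4, are left
unconstrained), scaffold unconstrained.

Two modes are provided because "similarity between predicted and expected
fold" admits two natural readings:

* `"mfe"` (default): the fraction of constrained positions whose pairing
  state in the MFE structure matches the target, where paired positions must
  have the *identical* partner. Deterministic, cheap, and exactly 1 iff the
  designed fold is the MFE fold at every constrained position.
* `"probability"`: the mean, over constrained positions, of the equilibrium
  probability of the target state (pair probability for designed pairs,
  unpaired probability for designed dots). Softer and ensemble-aware, at
  roughly an order of magnitude more compute.

The fitness of a sensing loop across p spacers is the product FS₁·…·FSₚ —
multiplicative, so one badly folding hairpin vetoes the candidate.

## The ASO-sensing loop and its flanks

An ASL is 20 nt: a 14-nt single-stranded core (the RNase-H/ASO landing pad)
flanked by three "stem-complementary" nucleotides on each side. The flanks
are implemented as a 3-bp apex clamp: `flank3 = revcomp(flank5)`, stacking on
top of the stem and closing exactly the 14-nt loop. The alternative reading —
flanks complementary to each spacer's own stem — would make the flanks
spacer-specific and a *shared* loop across spacers impossible, which is the
entire point of the evolution procedure; hence the clamp is a construct-level
constant (`stem_context`, default `GGC`/`GCC`, chosen G/C-rich so the clamp
survives in A/U-rich loop contexts), identical across all spacers in a run.
After crossover or mutation the flanks are re-imposed ("repair"), so the
evolvable genotype is effectively the 14-nt core.

ASOs are emitted at the three published footprints: 14 nt (core only), 20 nt
(full loop), and 25 nt extended 3 nt into the back-fold-side stem and 2 nt
into the spacer-side stem to favour strand invasion.

## Evolving shared loops

`exhaustive_evolve()` enumerates all 4^len sequences of a short variable
region (guarded at len ≤ 8) and is the global-optimum oracle.
`ga_evolve()` is the elitist genetic algorithm for the real problem:

1. every pool member is recombined (single-point crossover, uniform position)
   with a uniformly drawn partner; both offspring join the pool;
2. mutated copies (per-base rate 0.05 on the core) are appended;
3. fresh random loops are appended;
4. everything is scored by the product fitness and the best N survive.

Defaults follow the published run where stated: N = 150, iteration threshold
20, stop once the generation count exceeds the threshold *and* the top score
has been constant for 2 consecutive generations (a hard cap of 5× the
threshold guarantees termination). The per-generation addition counts (N/2
mutants, N/2 randoms), the 5% mutation rate, and single-point crossover are
package defaults where the original description is silent; multi-point
crossover was not implemented because single-point already satisfies the
columnwise-conservation property the tests check. Offspring are scored after
pooling with their parents (score-then-truncate), which is the simplest
reading consistent with elitism. Ties are broken by GC content closest to
50%, then smallest maximum homopolymer run (a total-order quantification of
"devoid of consecutive repeats"), then lexicographically, so ranked output is
deterministic. Scoring is memoised per loop sequence; this accelerates
converged pools without affecting results.

```{r, eval = FALSE}
spacers <- synth_spacers(2, gc_target = 0.6)
res <- ga_evolve(spacers, ga_config(seed = 1))
head(res, 3)
```

## What the synthetic generators emulate

`synth_spacers()` draws i.i.d. bases at a chosen GC content — it emulates the
*composition* of guide libraries, not genomic context: no PAM logic, no
off-target structure, no positional biases. `synth_planted_instance()` draws
GC-rich (70%) spacers and verifies by folding that a designated A/U-rich loop
scores exactly 1 on every hairpin, redrawing until it does; it emulates the
favourable regime where a perfect shared loop exists. A green planted-recovery
test therefore establishes that the GA finds an existing global optimum — not
that real gene-targeting spacer pairs always admit a perfect loop (they need
not; the GA then returns the best compromise).

## Numerical and degenerate-input choices

* Energies are integer centi-kcal internally; reported MFEs are exact to
  0.01 kcal/mol and runs are bit-reproducible for a fixed engine version.
* A sequence with no stable pair returns the all-dot structure with MFE
  exactly 0; MFE is never reported positive.
* `free_count_x = len(spacer)` with no loop degenerates to the native guide;
  empty back-folds, empty reports (non-fitting bulge patterns) and
  non-cleavable loops are handled explicitly rather than by crash.
* All randomness flows through R's RNG; `ga_evolve()` seeds locally and
  restores the caller's RNG state.

## Known limitations

* The energy model omits terminal mismatches, dangles and special-case loop
  tables; absolute ΔG values differ from NUPACK/ViennaRNA by roughly the
  per-loop mismatch terms. Orderings used by the design logic are preserved
  and oracle-tested, but do not quote this engine's absolute energies against
  another engine's without the cross-engine tolerance above.
* The bundled Cas6A and hammerhead units are clearly-labelled synthetic
  stand-ins (the published motifs are supplementary-only); substitute real
  motifs via `cleaving_unit()` before designing wet-lab constructs.
* No off-target scanning, PAM validation, or cleavage-kinetics modelling;
  designs are structural only.
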