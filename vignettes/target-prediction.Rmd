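---
title: "Two-step thermodynamic prediction of bacterial sRNA targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step thermodynamic prediction of bacterial sRNA targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starpick)
```

## The model

Bacterial small regulatory RNAs (sRNAs, roughly 40–500 nt) act mainly by
base-pairing with mRNAs, most often near the ribosome binding site.
`starpick` models the formation of an sRNA–mRNA interaction as a
two-step process:

1. **Seed matching.** A short stretch of perfect, consecutive
   inter-molecular base pairs (Watson–Crick plus G–U wobble) nucleates
   the interaction. Because both molecules are structured, a productive
   seed must be both thermodynamically stable *and* accessible — the
   bases it occupies must be liberated from intra-molecular structure on
   both molecules.
2. **Elongation.** The initial helix extends outward into the full
   binding site, limited by the surrounding intra-molecular structure.

Prediction follows the same two steps, followed by supervised scoring:
candidate seeds are enumerated and screened; survivors are extended by
constrained co-folding; each resulting site is described by 22
structural and energetic features; and a voting ensemble of 1000 base
classifiers converts the feature vector into an interaction probability
(the fraction of positive votes). A pair is called interacting when the
probability strictly exceeds 0.5.

## Energies

Three quantities drive the screening, all in kcal/mol at 37 °C:

* **ΔG_hybrid** — the free energy of the inter-molecular duplex formed
  by the two regions, considered in isolation (only inter-molecular
  pairs).
* **ΔG_open = ΔG_unpaired − ΔG_paired** — the cost of making a region
  single-stranded: the difference between the ensemble free energy
  (−RT ln Z) of the molecule with the region constrained unpaired and
  its unconstrained ensemble free energy. Because the constrained
  ensemble is a subset of the unconstrained one, ΔG_open ≥ 0 always.
* **ΔΔG = ΔG_hybrid + ΔG_open(sRNA region) + ΔG_open(target region)** —
  the accessibility-corrected interaction energy used to screen seeds
  and to score binding sites (features f19 and f21).

Two flanking policies control which sequence is folded for ΔG_open:
sRNAs are folded **full length** (they are short); target regions are
folded together with up to **100 nt of flanking sequence** on each side
(base pairs spanning more than ~100 nt are rare, and the truncation
keeps the partition functions cheap). Flanks are truncated at molecule
ends, never padded.

## Folding engines

All thermodynamics go through a small behavioral contract (an "energy
engine"), so the pipeline is independent of any particular folding
implementation:

* `vienna_engine()` adapts the ViennaRNA command-line programs:
  `RNAduplex` for ΔG_hybrid, `RNAfold -p0` (with `-C` and an
  `x`-constraint for the unpaired region) for ensemble free energies,
  and `RNAcofold -C --noLP --noClosingGU` for the constrained co-fold
  of the extension step. Dangling-end and terminal-AU options stay at
  the suite's defaults; the engine identifier (with the suite version)
  is recorded in trained models. The co-fold constraint is expressed as
  matched brackets; since constraint folding does not hard-guarantee
  the pairs, the adapter verifies that every seed pair is present in
  the returned structure and otherwise aborts the extension for that
  seed with a warning.
* `toy_engine()` is a self-contained deterministic nearest-neighbour
  toy model: pair free energies G-C −3, A-U −2, G-U −1 kcal/mol, no
  loop terms, minimum hairpin loop 3 nt. Duplex optimisation is a
  maximum-weight non-crossing antiparallel matching; ensemble free
  energies are exact partition functions evaluated in log space (so
  both structure-rich and structure-free molecules stay in numeric
  range); the constrained co-fold is a Nussinov-style dynamic program
  with the seed pairs driven into the optimum. The toy co-fold does not
  emulate the lonely-pair and G-U-closure exclusions of the production
  engine — those are properties of the Vienna adapter only.

The toy engine exists because published interaction energies depend on
a specific thermodynamic parameter set that cannot be pinned here; the
contract isolates that dependency, and the toy model makes the entire
test suite and synthetic study exactly reproducible with no external
binaries. Energies from the two engines are *not* comparable on an
absolute scale; a trained model records which engine produced its
features, and `predict_pair()` warns on a mismatch.

## Seed selection

Candidate helices are all maximal antiparallel runs of consecutive
complementary pairs between the sRNA and the target window
(`enumerate_helices()`). Terminal G–U pairs are trimmed from both ends
before anything else; runs shorter than 5 nt after trimming are
discarded. Each survivor must then pass a length-specific composition
rule (`passes_composition_rules()`):

| length | G-U pairs | G-C pairs |
|--------|-----------|-----------|
| 5      | none      | ≥ 4, or 3 consecutive |
| 6–7    | ≤ 1       | ≥ 3 |
| 8–9    | ≤ 1       | ≥ 2 |
| ≥ 10   | ≤ 4       | ≥ 2 |

Finally the seed's ΔΔG (duplex energy of the two seed subsequences plus
both opening costs) must be **strictly below −2 kcal/mol**
(`select_seeds()`; the threshold is exposed as a parameter). Sub-runs
of a maximal run are not emitted separately, and surviving seeds are
extended independently.

## Extension and binding sites

For each selected seed, the sRNA is co-folded with the target context
(seed region ± 100 nt) with every seed pair imposed. From each seed
boundary the scan walks outward over positions that are inter-molecularly
paired *or unpaired*; a side halts at the first position engaged in an
intra-molecular pair. Unpaired positions between inter-molecular pairs
belong to the site (interior loops and bulges are part of the hybrid),
but the site is clipped to the outermost inter-molecular pair on each
side, so a site never starts or ends unpaired and never contains an
intra-molecular pair. When the context is truncated by a window edge,
extension simply stops there. If two seeds extend to the identical site,
the duplicate with the larger seed ΔΔG is dropped at reporting time.

## Features

The hybrid is the concatenation of the sRNA-site and target-site
nucleotides with the inter-molecular pairing found during extension.
Percentages use the total nucleotide count of both strands, which makes
the identity f8 + f17 = 100 exact. f1–f7: percent A, C, G, U, G+C, A+U,
A+C; f8/f17: percent paired/unpaired; f9, f10: pairing in duplexes of
≥ 3 bp (percent of nucleotides, and fraction of base pairs); f11:
maximum consecutive base pairs; f12–f16: interior-loop and bulge counts
and their nucleotide percentages (an interior loop has unpaired bases on
both strands between two pairs, a bulge on exactly one); f18/f19: ΔG
and ΔΔG of the binding region; f20/f21: ΔG and ΔΔG of the seed; f22:
seed length. The published final model projects onto
{f1, f4, f18, f19, f22} (`project_final_subset()`).

## Training the voting ensemble

Training tables are built from candidate sites
(`build_training_samples()`): per pair, among candidates overlapping an
experimentally validated site only the one with the smallest seed ΔΔG
becomes the positive sample; candidates overlapping the chosen positive
are excluded, and mutually overlapping negatives are greedily
deduplicated keeping the smallest seed ΔΔG.

Feature selection is a forward beam search scored by leave-one-out
cross-validation: for each subset size 1–10, the ten best subsets are
recorded and seed the next size. Every recorded candidate then undergoes
**stability analysis**: 1000 random 75/25 train/test partitions, one
base classifier fitted per partition, and the mean test accuracy is the
subset's stability index. All candidates see the same sequence of
partitions, so subsets are compared on common splits and ties are exact.
The subset with the highest stability index wins (ties: smaller subset,
then lexicographic order), and the 1000 classifiers trained during its
stability rounds *are* the final ensemble. Prediction is unweighted
voting: the probability is the fraction of positive votes, and the
decision threshold 0.5 is strict.

### The base classifier

Each base classifier is a **shrinkage-regularized linear discriminant**
with empirical class priors: w = (S + λ·tr(S)/p·I)⁻¹(μ₊ − μ₋) with
λ = 0.05, and a sample votes positive when
w·x − w·(μ₊+μ₋)/2 + log(n₊/n₋) > 0. This choice is deliberate on three
grounds. First, it is closed-form and deterministic, so the whole
training path is exactly reproducible from one master seed. Second,
binding-site descriptors are strongly collinear (composition, stem
length and duplex energy are nearly functions of one another on clean
sites); the shrinkage term keeps the weights bounded, where a bare
inverse produces thousand-fold weights that misclassify sites lying
slightly off the training manifold. Third, the log-prior term shifts the
decision boundary toward the majority class, so training with more
negatives than positives (the 102:31 imbalance of curated interaction
collections) yields conservative base rules — specificity is bought at
the cost of sensitivity, the appropriate trade-off for genome-wide
screens where every reported candidate costs wet-lab validation. A
depth-limited decision tree was evaluated for this role first and
rejected: on ~130-row tables its axis-wise overfit variance exceeds the
marginal signal of a second informative feature at every effect size,
so stability selection collapses to single-feature subsets and cannot
recover a planted two-feature signal.

Per-round random splits are derived deterministically from the master
seed and the round index; a degenerate split leaving one class absent
from the training portion is resampled, again deterministically. Models
serialize to a versioned JSON container at full numeric precision, so a
write/read round trip reproduces predictions exactly.

## Target windows and genome-wide mode

The putative binding region of an annotated gene is the sub-sequence
from 150 nt upstream of the first base of the start codon to 100 nt
downstream of (and including) it — 250 nt in mRNA sense, with up to
100 nt of genomic flank kept on each side as accessibility context.
Relative coordinates skip zero: +1 is the first base of the start codon
and −1 the base upstream of it. Minus-strand genes use the
forward-strand coordinate of the start codon's first base (the CDS end)
and are reverse-complemented to sense. Windows truncated by contig ends
are processed, not skipped; overlapping genes get independent windows;
annotated starts are trusted as given. Genome-wide prediction runs the
pair cascade over every annotated CDS, ranks all candidates by the
three-key order (probability descending, then binding-region ΔΔG, then
seed ΔΔG, with gene identifier as a deterministic final tie-break), and
reports those whose probability strictly exceeds the threshold.

## The synthetic data generators

Every stage is testable offline against label-known inputs. The
generators emulate the *interaction geometry* of real sRNA-target
pairs — a complementary helix of controlled length and composition
planted in molecules whose accessibility is known by construction —
not the sequence statistics of real genomes.

The letter scheme is the load-bearing design. Two constraints drive it:
a planted helix must be *uniquely recoverable* (a repetitive plant
admits shifted off-diagonal helices), and its accessibility must be
*controlled* (no molecule may contain a letter that pairs with its own
background, or the planted region is combinatorially occluded — under a
loop-free energy model a single planted U over a poly-A background
costs several kcal/mol of opening energy). Mixed helices therefore put
G (G-C pairs), A (A-U pairs) and G (wobbles) on the sRNA side over a
poly-A background, and C/U on the target side over a poly-C background;
all-Watson-Crick G-C helices alternate G and C over poly-A backgrounds
(with a doubled C from length 7 so no 5-mer repeats at any lag). G-C
runs are broken into blocks of at most four so that sRNA G-blocks
against the target's C background stay below seed length, and guard
letters at the plant boundaries stop shifted alignments from running
into the backgrounds. With at most two A-U pairs these invariants are
exact; A-U-richer plants can carry shifted duplicates, which the
generators surface through a self-audit rather than hide.

Synthetic genomes place non-overlapping CDSs on alternating strands of
a contig whose background is C *in mRNA sense* for every window
(forward-strand C with G patches across minus-strand windows). This
matters twice: a poly-A contig would make minus-strand windows poly-U
in sense, and the sRNA's poly-A background would then form a spurious
window-wide duplex with them; and the C background matches the training
pairs, so genome-mode feature vectors live on the same manifold the
model was trained on. Planted targets carry the complement of a stated
sRNA stretch inside their window; decoy genes carry nothing, and the
generator re-scans its own output for accidental rule-passing seeds.

`generate_training_table()` draws abstract feature tables with class
signal planted only on f19 (positives 4 kcal/mol lower, ~2 SD) and f22
(positives 3 nt longer, over a Binomial(8, 0.25) length noise), all
other features iid and shared between classes, at the 31:102 class
ratio. The effect sizes make the planted pair clearly separable while
leaving a few percent of class overlap, so that a wrapper selection can
recover the informative features against twenty chance-correlated noise
features and the class imbalance still expresses itself as a
specificity/sensitivity asymmetry. What these fixtures do *not* emulate:
real compositional biases, Hfq-mediated pairing, multi-site regulation,
and real thermodynamic parameters — passing tests demonstrate that the
machinery is correct, not that the toy world's accuracies transfer to
real genomes.

## Numerical choices and degenerate inputs

* Strict inequalities at both decision points: seeds at exactly
  −2 kcal/mol are dropped; probability exactly 0.5 is non-interacting.
* ΔG_open is clamped at 0 against the production engine's printed
  rounding (mathematically it cannot be negative).
* Partition functions run in log space with pairwise log-sum-exp; the
  toy engines are bit-deterministic, and two calls with identical
  inputs compare identical.
* Deterministic tie-breaks everywhere: candidate subsets by accuracy
  then lexicographic order; equal-stability subsets by size then order;
  ranked records by gene identifier after the three sort keys.
* A pair with no surviving seed returns an empty record set — it is
  non-interacting by construction, not an error. Per-gene failures in
  genome mode are logged and skipped.
* Sequences are validated on ingest (DNA transliterated, lowercase
  uppercased, anything outside the alphabet rejected with the offending
  line); `N` is accepted in genomic contigs and never pairs.

## Problem sizes

The shipped tests and the acceptance script run entirely on the toy
engine at deliberately modest scales — oracle-equivalence sweeps over
hundreds of random instances (duplexes to 24 nt, partition functions to
20 nt, seed scans at 60×260 nt), training-path studies on 133-row
tables with 20 repetitions and 200 stability rounds (the full 1000
rounds are used for the single headline model), and a 20-gene synthetic
genome with two planted targets. These sizes were chosen so the entire
evidence base regenerates from scratch in minutes on one CPU while
still exercising every code path at the sample sizes the training
procedure was designed around.

## Known limitations

* The toy model's energies are not ViennaRNA energies; absolute ΔΔG
  values are engine-specific, and models do not transfer across
  engines.
* Reproducing the published model's exact weights would require the
  original training sequences (external databases) and the exact
  folding parameter set; the training *procedure* is what this package
  provides.
* Seeds shorter than 5 nt are outside the model by design, so pairs
  that interact through 4-nt seeds are invisible to it.
* No conservation, Hfq, or expression evidence enters the score; the
  model is purely thermodynamic and structural.
* The GenBank reader covers single-interval CDS locations
  (`start..end`, `complement(...)`); joins and partial starts are
  skipped with warnings.
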