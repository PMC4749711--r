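---
title: "Methods: typing bacterial 16S-23S intergenic spacers with ribospacer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: typing bacterial 16S-23S intergenic spacers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribospacer)
```

## The problem

In bacteria the rRNA genes sit in an operon ordered 5'-16S-23S-5S-3', with an
intergenic spacer (ITS) between the 16S and 23S genes. The spacer is under
far weaker selection than the flanking rRNA genes, so closely related strains
that are indistinguishable by 16S sequence often differ markedly in spacer
length, G+C content, tRNA gene content and internal sequence. ribospacer
implements the full comparative workflow used to exploit that signal in
sphingomonads (Gram-negative, glycosphingolipid-enveloped
alpha-proteobacteria common in oligotrophic water): excise the spacer from an
operon fragment with the conserved flanking primers, find the tRNA genes
inside it, type the spacer by their content and order, partition it into
ITS-1/ITS-2/ITS-3, quantify conservation and indels across a panel, build a
bootstrap phylogeny, and fold ITS-2 into its hairpin.

Because real survey panels are not redistributable, the package also ships a
first-class synthetic operon generator with known ground truth; every
pipeline stage is validated against that truth and against independent
oracles (exhaustive enumeration, closed forms, an external likelihood
engine).

## Spacer excision (in-silico PCR)

Primer sites are matched ungapped under IUPAC-intersection semantics
(`R` matches `A` and `G`, and so on), with up to `max_mismatch = 2`
mismatches per site - a tolerance typical of the Sanger-era assays the
primer set derives from. Products are all forward/reverse site pairs whose
length falls inside `[200, 2000]` bp, bracketing the 415-849 bp spacer range
the defaults emulate. The spacer itself is the sub-sequence strictly
*between* the primer footprints: the forward primer sits in the conserved
16S tail and the reverse primer at the 23S start, so excluding the
footprints makes spacer lengths comparable across assays. Only the forward
strand is scanned for forward primers (reverse primers as reverse
complements); templates are assumed in 16S-to-23S orientation, which the
generator guarantees.

Coordinates are 1-based inclusive throughout, both internally and in every
output - the native R convention, and the convention of the field's reports
(a deletion "at position 672-681" spans ten bases).

## tRNA gene detection

tRNA genes are found with a rule-based cloverleaf scanner rather than a
covariance model. A candidate window is decomposed as acceptor stem (6-7
bp, pairing the gene termini, discriminator base last), D-arm (3-4 bp stem,
4-12 nt loop), a 5-bp anticodon stem with a 7-nt loop (anticodon at
cloverleaf positions 34-36), a variable loop, and a 5-bp T-stem whose 6-9
nt loop carries the TTC signature. Stems score GC = 3, AT = 2, GT = 1 per
pair, plus a +2 bonus for the T-loop motif. The scanner enumerates all arm
placements at every offset; the acceptor gate depends only on the window
ends, so it is applied first and prunes almost the entire search space.

A decomposition is a *candidate* when the acceptor, D and T stems are each
at least 80% paired. Candidates at or above `min_score` are then judged
against two hard constraints: an intact anticodon stem (at least 4 of 5
pairs) and the T-loop motif. Both satisfied: a tRNA gene. Exactly one
violated: reported with `pseudo = TRUE` - an operational definition chosen
because pseudo-tRNAs are named but never defined in the source material for
this workflow. Both violated: discarded. Overlaps are resolved by score,
ties to the leftmost. Isotypes come from the anticodon (TGC = Ala,
GAT = Ile, anything else = other).

`min_score = 52` is a one-time calibration against the generator
(`scripts/calibrate_its2.R` reproduces the evidence): canonical genes score
65 (21 fully paired GC-rich stem positions plus the motif bonus), the
generator's pseudo genes 56, while the best gated decomposition on hundreds
of composition-matched random spacers never exceeded 45. The threshold sits
in the wide gap, far more than the "90% of shuffles fail" the detector
promises. The scanner recovers canonical genes exactly; it is *not*
equivalent to a covariance-model search on real genomic edge cases
(group-I introns, unusual D-loops), which is a documented limitation.

## Typing, partition, size groups

Five arrangements are named: no gene, Ala alone, Ala+Ile, Ile+Ala, and Ile
followed by a pseudo gene; anything else is reported as `ITS_other`, never
coerced. With two gene-like features (pseudo genes count - they divide the
spacer like real ones) the spacer partitions into ITS-1 / ITS-2 / ITS-3;
with one gene the flanks are labelled `spacer-a`/`spacer-b` and excluded
from ITS-2 statistics, since the three-part nomenclature is defined only
for the two-gene case. ITS-2 lengths are binned into the observed size
groups 16-19, 60-61 and 122-138 nt; other lengths report themselves
(`other(90)`).

## Alignment and conservation

The package carries its own aligner (global Needleman-Wunsch with affine
gaps via Gotoh's three matrices; match +1, mismatch -1, gap open -5, extend
-1, a gap of length k costing open + (k-1)·extend) and a progressive MSA:
guide tree by UPGMA on 4-mer distances, profiles merged by profile-profile
NW. It fills the role of an external MSA program in this workflow but makes
no attempt to reproduce any particular program's columns; pairwise scores
are verified against exhaustive path enumeration on short sequences, and
every output row strips back to its input sequence bit-exactly.

Percent identity between two rows is matches over columns where at least
one row is non-gap, so indels count as differences; the alternative
(`denominator = "ungapped"`) is available because published "percent
conservation" figures rarely state their denominator. Conservation
summaries are mean/SD (n-1) over upper-triangle pairwise identities.
Conserved blocks are maximal runs of gap-free columns whose majority
residue reaches a threshold, with ties encoded as IUPAC union symbols.
Indel events are maximal gap runs of a focus row versus the rest;
group-level length stretches are maximal column runs present in one group
and gapped in the other.

## Phylogeny

Distances are Jukes-Cantor, d = -(3/4)·ln(1 - 4p/3), saturated pairs
(p >= 3/4) capped at 5.0 substitutions/site and flagged. Trees come from
neighbour joining (via ape; negative branches clamped to zero with the
deficit moved to the sibling). The likelihood engine is Felsenstein pruning
under JC69 with gaps and ambiguity as missing data; it matches the
two-taxon closed form analytically and phangorn's `pml` numerically.
Branch lengths are optimised by coordinate ascent - per-branch bounded
scalar optimisation on conditional messages from a down/up pass over
site-pattern-compressed data, sweeping until the log-likelihood gains less
than 1e-6 (at most 20 sweeps). There is no topology search: the study
design this emulates specifies NJ starting trees, and the bootstrap
consensus topology is what is interpreted.

The bootstrap resamples alignment columns with replacement under a single
integer seed, builds a JC/NJ tree per replicate, and takes the strict
majority-rule consensus with bipartition supports in percent. ML branch
lengths are fitted once, on the consensus against the input alignment -
per-replicate branch optimisation cannot change any bipartition, so the
consensus and its supports are identical either way and the work is saved.
Strict complete deletion (drop every column with a gap or ambiguity) is
applied before distance computation when enough columns survive; on panels
whose spacers differ greatly in length the common gap-free core can vanish,
and the pipeline then falls back to pairwise deletion per sequence pair and
records that in the run metadata. The default replicate count is 1000; the
shipped validation and acceptance runs use 100, a scale chosen to keep the
whole suite interactive while leaving support estimates stable to a few
percent.

## ITS-2 hairpin folding

Folding is a Nussinov-style dynamic program over nested structures with at
least 3 unpaired bases inside any pair, maximising a unitless stability
score: pair weights GC -3, AT -2, GT -1 and -1 per stacked adjacent pair
(two tables, "paired" and "not paired together", make the stacking term
exact). The traceback prefers pairing, then the leftmost split, so results
are deterministic. The score is *only ordering-comparable* - it stands in
for free energy in long-stem versus short-hairpin comparisons but predicts
no kcal/mol. Structures whose longest helix reaches 8 bp are classed
`long_stem`; 3-7 bp helices are `short_hairpin` and flagged as putative
RNase III processing targets; weaker folds are `unstructured`. One subtlety
the property suite documents: with GT wobble admitted, the stability score
is invariant under sequence *reversal* but not under reverse complement
(the complement of a G:T pair is A:C, which cannot pair); reverse-complement
symmetry holds exactly for the Watson-Crick-only parameterisation.

## The synthetic panel generator

The generator emulates the statistical shape of a 37-sequence survey: 14
reference operons (clade templates) plus 23 isolates distributed over them.
Each operon is a fixed 200-nt 16S-tail scaffold carrying the forward primer
site, the spacer, and a fixed 200-nt 23S-head scaffold carrying the reverse
sites. Defaults pin the published envelopes: spacer lengths drawn in
415-849 bp, spacer G+C targets in 42.2-57.9 mol% (flanking fillers are
built with exact G/C counts to land the whole spacer on target), an
Ala+Ile-dominant type mix over all five arrangements, ITS-2 size groups at
16-19 / 60-61 / 122-138 nt plus an unbinned remainder, and the conserved
CCAACCAT / TGGT blocks planted at the ITS-2 termini. Canonical genes are
built to the blueprint the detector expects - 73 nt (Ala) and 74 nt (Ile),
fully paired GC-rich stems, loops drawn from A/C so they cannot pair -
and pseudo genes disrupt exactly the anticodon stem (three substitutions on
its 3' strand), leaving the score above threshold.

Within a size group, template ITS-2 sequences descend from a common group
ancestor - mirroring the observation that same-sized spacers share an
origin - and isolates descend from their template under JC substitutions
plus indels (Poisson counts, geometric lengths capped at 12 nt, placed only
in unconstrained filler). Planted gene stems, anticodons, T-loop motifs and
the ITS-2 terminal blocks are substitution-protected, modelling the length
and structural conservation of real spacer tRNA genes. Descendants are
rejection-resampled (bounded) until their spacer stays inside the length
and G+C envelopes, so the generator's contract holds for every emitted
sequence. A single integer seed reproduces a panel byte-for-byte.

`its2_divergence = 0.50` is the one calibrated constant: the JC distance
from template to isolate (templates sit at 3x that from their group
ancestor). It was fixed once, with `scripts/calibrate_its2.R`, so that the
mean pairwise ITS-2 identity of default panels reproduces the 22.5%
conservation headline; the sweep shows the statistic is dominated by
between-group length mismatch and saturates near chance identity, so
values in 0.4-0.6 all land within a few points and the calibrated default
reads as "ITS-2 effectively free-running within clades", which is the
biological claim the statistic encodes. It is a calibration artifact, not
an estimate of real within-species divergence.

What the generator does *not* emulate - and hence what passing tests do not
show about real data: realistic rRNA secondary structure in the scaffolds,
compositional heterogeneity along the spacer, recombination between
operons, within-genome operon copy variation, and tRNA genes that deviate
from the canonical blueprint. Results on real spacers depend on the
detector's structural rules holding, which the covariance-model caveat
above qualifies.

## Validation scale and determinism

The shipped test suite runs the whole pipeline at study scale (37 operons,
100 bootstrap replicates), checks detector lengths over 20 independent
panels, spacer envelopes over 1000 generated operons, ITS-2 conservation
over 5 panel seeds, and the oracle suites (alignment scores vs exhaustive
enumeration at lengths <= 6, folding vs enumeration at lengths <= 10, NJ
recovery from additive matrices up to 8 leaves, likelihood closed forms).
End-to-end runs are byte-deterministic given the configuration seeds; the
report JSON omits only the timestamp when byte-reproducibility is
requested.

## Known limitations

* The detector is rule-based: isotypes other than Ala/Ile are labelled
  `other` rather than classified, and non-canonical gene structures are
  missed by design.
* The aligner is a teaching-grade progressive MSA: no iterative refinement,
  no consistency scoring; column-level agreement with production aligners
  is not a goal.
* The ML stage optimises branch lengths only; there is no topology search.
* Folding ignores thermodynamic nearest-neighbour effects, pseudoknots and
  suboptimal ensembles.
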