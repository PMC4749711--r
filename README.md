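# ribospacer

Typing and comparative analysis of bacterial 16S–23S rRNA intergenic
spacers (ITS), with defaults tuned to sphingomonads.

## The problem

Bacterial rRNA genes sit in an operon ordered 5′-16S–23S-5S-3′, separated by
intergenic spacers. The 16S–23S spacer evolves under far weaker selection
than the rRNA genes around it, so closely related strains that look
identical by 16S sequence often differ in spacer length, G+C content, tRNA
gene content and internal sequence — exactly the resolution needed to
separate, say, drinking-water sphingomonad isolates at the sub-species
level. `ribospacer` implements that workflow end to end:

* **in-silico PCR** — degenerate-primer site search (IUPAC semantics,
  mismatch tolerance) and excision of the spacer from between the primer
  footprints of an operon fragment;
* **tRNA detection** — a rule-based cloverleaf scanner that locates tRNA
  genes inside the spacer, assigns isotypes from the anticodon
  (TGC → Ala, GAT → Ile) and flags structurally broken "pseudo" genes;
* **spacer typing** — classification into the five observed arrangements
  (`ITS_none`, `ITS_Ala`, `ITS_AlaIle`, `ITS_IleAla`, `ITS_IlePseudo`),
  partition into ITS-1/ITS-2/ITS-3 and ITS-2 size-group binning
  (16–19 / 60–61 / 122–138 nt);
* **alignment & conservation** — in-package Needleman–Wunsch and
  progressive MSA, pairwise percent-identity summaries, conserved-block
  discovery (e.g. the CCAACCAT / TGGT blocks at the ITS-2 termini), indel
  events and group-specific length stretches;
* **phylogeny** — Jukes–Cantor distances (d = −¾ ln(1 − 4p/3)),
  neighbour joining, Felsenstein-pruning JC likelihood with ML branch
  lengths, and seeded bootstrap majority-rule consensus with supports;
* **ITS-2 structure** — Nussinov-style hairpin folding with a stacking
  bonus, long-stem vs short-hairpin classification (putative RNase III
  targets);
* **synthetic panels** — a seeded generator of operon panels with known
  ground truth emulating a 37-sequence (14 reference + 23 isolate) survey,
  used to validate every stage.

## Worked example

```r
library(ribospacer)

# simulate the default 37-operon study design and run the whole pipeline
cfg <- pipeline_config(simulate = panel_config(seed = 42),
                       n_boot = 100, seed = 1)
rep <- run_pipeline(cfg)
print(rep)
```

```
ITS pipeline report: 37 of 37 sequences analysed
       its_type count percent
1      ITS_none     3     8.1
2       ITS_Ala     1     2.7
3    ITS_AlaIle    27    73.0
4    ITS_IleAla     6    16.2
5 ITS_IlePseudo     0     0.0
6     ITS_other     0     0.0
ITS-2 pairwise identity over 528 pairs: mean 22.7% +/- 14.0 (range 7.4-100.0)
tree: 37 leaves, 100 bootstrap replicates
```

Reading the output: all 37 operons amplified and were annotated; the
Ala+Ile arrangement dominates (73%), as it does in the survey the defaults
emulate; mean pairwise ITS-2 identity across the panel is ~23% — the
spacer's hypervariable core — with a handful of near-identical same-clade
pairs at the top of the range; and the bootstrap consensus tree carries all
37 operons as leaves, with supports (percent of 100 replicates) as node
labels in `rep$tree_newick`.

Single-sequence annotation works the same way from FASTA:

```r
ops <- read_fasta("operons.fasta")
amp <- amplify(ops[1, ], "16S-1511f", "23S-23r")
its <- extract_its(amp[1, ], "16S-1511f", "23S-23r")
annotate_its(its$seq, seq_id = ops$id[1])
```

```
spacer REF01: 436 nt, G+C 53.2 mol%, type ITS_AlaIle
  tRNA-Ala(TGC) 136-208 score 65
  tRNA-Ile(GAT) 225-298 score 65
  ITS-2: 16 nt, group short(16-19)
```

A thin command-line wrapper over the same functions ships at
`inst/scripts/run_pipeline.R` (see `--help`).

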