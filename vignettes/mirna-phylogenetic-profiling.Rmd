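---
title: "Phylogenetic profiling of miRNA presence and absence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic profiling of miRNA presence and absence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socmir)
```

## The question and the method

Eusociality — reproductive division of labor, cooperative brood care,
overlapping generations — arose repeatedly within the aculeate
Hymenoptera (ants, bees, stinging wasps) while remaining rare
elsewhere. One family of hypotheses holds that lineage-specific
microRNAs contributed to this convergence, either as repeatedly gained
regulators in eusocial lineages, or as an ancestral aculeate toolkit
that "primed" the clade. Both hypotheses make claims about *where in
the genome panel a miRNA is present*, so both can be screened with
phylogenetic profiling: score every annotated mature miRNA as present
or absent in every genome of a panel, lay the resulting binary matrix
along the species tree, and ask which rows track the trait rather than
the phylogeny.

`socmir` implements this pipeline end to end:

1. **Catalog** (`load_mature_fasta`, `dedup_catalog`): mature miRNA
   queries from miRBase-style FASTA, converted RNA→DNA, validated, and
   collapsed to unique sequences.
2. **Scan** (`scan_genome`, `call_presence`): strand-aware exact
   multi-pattern search; a miRNA is *present* in a genome iff the full
   mature sequence occurs exactly, on either strand.
3. **Matrix** (`filter_informative`, `order_by_tree`,
   `restrict_panel`): assembly, informativeness filtering, and
   deterministic phylogenetic ordering.
4. **Reconstruction** (`fitch_min_changes`, `dollo_reconstruct`,
   `count_independent_gains`): parsimony gain/loss histories per row.
5. **Screens** (`trait_exclusive`, `clade_exclusive`,
   `clade_universal`, `convergence_summary`): the two candidate
   screens plus a descriptive convergence summary.
6. **Synthetic data** (`simulation_config`,
   `simulate_presence_evolution`, `generate_genomes`) and the packaged
   worked-example panel (`make_paper_fixture`).

## The presence criterion and the scanner

The presence call is deliberately austere: *full-length exact match of
the mature sequence*. Mature miRNAs are short (~18–24 nt) and often
perfectly conserved, so an exact-substring criterion is both
biologically defensible and trivially reproducible, where a heuristic
local aligner would import cutoff and word-size choices without adding
sensitivity for full-length matches. `scan_genome` therefore uses
exact string search over both strands (Biostrings; a preprocessed
multi-pattern dictionary on large workloads, per-query matching on
small ones — the two paths are exact and interchangeable, and the test
suite holds both to a naive character-by-character oracle).

Decisions worth knowing:

* **Soft-masking is ignored.** Lowercase in assemblies marks repeats,
  not absence; contigs are uppercased at load.
* **Ambiguity codes never match**, even when nominally compatible
  (R vs A): an "exact match" criterion is read literally. With a
  mismatch budget (`max_mismatches > 0`, off by default; intended for
  sensitivity analyses only) hit regions containing any non-ACGT
  character are discarded rather than absorbed as mismatches.
* **All occurrences are reported**, including overlapping and
  self-overlapping ones; coordinates are 0-based half-open, minus-
  strand hits in forward coordinates. Presence is the binarization
  `hits ≥ 1`, with counts kept as provenance.
* **Queries are deduplicated by sequence, not by name.** Identical
  matures from paralogous loci collapse to one query; genomic
  multiplicity comes back through hit counts. The canonical name
  follows a species-prefix precedence (`ame` > `nvi` > `dme` by
  default) because candidates are conventionally reported under
  honey-bee names. The source of every merged record is preserved in
  `source_ids`.

## Matrix conventions

`filter_informative` drops rows present everywhere or in at most one
genome: neither pattern can discriminate placements on the tree. The
filter is applied *per panel* — a row uninformative on a small panel
can be informative on a larger one.

"Clustered by phylogeny" is operationalized as a deterministic
convention, not a clustering algorithm: columns take the tree's
left-to-right leaf order, rows sort lexicographically by their
presence pattern in that column order, ties by name. This makes every
figure and TSV reproducible byte-for-byte; it makes no claim about how
any published figure was produced.

## Parsimony reconstruction

Three reconstructions are offered per binary character:

* **Fitch (minimum change)** — gains and losses both cost 1, regain
  after loss allowed. Polytomies are handled natively by a
  dynamic program over node states (no arbitrary binarization). No
  cost attaches to the root state itself, so a constant character
  costs 0. Among co-optimal assignments the reported event list keeps
  the parent's state at ties, pushing events toward the tips
  (delayed-transformation flavor); nodes that remain free are flagged
  `ambiguous_nodes`.
* **Dollo** — exactly one gain, placed on the branch entering the MRCA
  of all present leaves (the root stem when all are present), plus the
  minimal loss set below it. Cost `1 + losses`. Dollo cost always
  dominates Fitch cost; the gap measures how much the single-origin
  constraint hurts.
* **Minimum independent gains** (`count_independent_gains`) — under
  weighted parsimony (defaults 1/1) with the state *prior to the root
  fixed at absent*, the smallest number of gain events over all
  minimum-cost assignments. The root prior reflects what the queries
  are: lineage-annotated miRNAs whose presence at the panel root is
  itself an origin worth counting — an all-present character counts
  one gain, on the root stem. The count is computed by a
  lexicographic (cost, gains) dynamic program and is independent of
  event-list tie-breaking. Note one consequence: for constant-present
  characters the gain count (1) exceeds the Fitch cost (0); the two
  quantities answer different questions.

All three are validated, over every character on small trees
(including polytomies), against exhaustive enumeration of all
ancestral assignments.

`convergence_summary` reports, per row, the minimum independent gains
and how many inferred gain branches lead to subtrees whose labeled
leaves are all trait-positive-or-neutral. It is a descriptive
parsimony summary; no significance test is computed, because
presence/absence counts on a handful of deeply split lineages do not
support one honestly.

## The screens and the neutral label

`trait_exclusive` keeps rows with zero presences in trait-negative
genomes and at least `min_positive` (default 1; the informativeness
filter already removes singletons) presences in positive genomes.
Facultatively eusocial species get a third, *neutral* label: a gene
present in a species that is both social and solitary is evidence for
neither state, so neutral presences neither qualify nor disqualify.
This is not a technicality — in the worked example two candidate genes
(miR-281, miR-6065) are present in the facultative sweat bee
*Lasioglossum albipes* and survive the screen precisely because of the
neutral contract. The suite tests the contract directly by randomizing
neutral-column cells.

`clade_exclusive` (absent outside, ≥ `min_inside` inside) expresses
"unique to clade X"; `clade_universal` (absent outside, present in at
least `|clade| − tolerance` members) expresses "already present in the
clade ancestor". `tolerance` (default 0) exists because incomplete
assemblies produce false absences; it is surfaced rather than baked
in.

## The worked-example panel

`make_paper_fixture()` ships a 21-miRNA × 24-genome panel encoding the
reported presence/absence facts of the hymenopteran eusociality
analysis: a species tree over four non-hymenopteran outgroup orders
plus ticks, the sawfly, four parasitoid wasps, and thirteen Aculeata
(eight bees, five ants in the broad sense, one vespid); trait labels
(11 eusocial, 1 facultative, 12 negative); clade handles for
Hymenoptera, Aculeata, and Vespidae; and two nested panels — the
*initial* seven-genome panel (fruit-fly outgroup) and the *extended*
24-genome panel.

Every cell is either **sourced** (fixed by a reported fact, tagged in
`provenance.tsv`) or **interpolated** (filled phylogeny-concordantly
to complete the grid); `fixture_cell_status()` distinguishes them.
Two design decisions deserve flagging:

* The five-candidate eusociality screen is evaluated on the *initial*
  panel. On the extended panel it cannot come out five: miR-279d is
  conserved in the non-dipteran outgroups (tick, aphid, beetle,
  silkworm), which are negative-labeled there, and is excluded by any
  exclusivity screen — consistent with the original analysis, whose
  candidate set was produced with the fruit fly as the only outgroup.
* One cell is interpolated with consequence: miR-6065 is marked
  present in one non-hymenopteran outgroup so that exactly three of
  the five candidates are Hymenoptera-exclusive on the extended
  panel, matching the reported three-out-of-five arithmetic. The
  underlying reports are ambiguous on this point (a gene called
  "possibly unique to Aculeata" would otherwise also be unique to
  Hymenoptera, making four); the fixture resolves the ambiguity in
  favor of the printed count and flags the cell as interpolated, not
  sourced.
* Internal tree resolution beyond the clades the screens use is
  cosmetic: the screens depend only on clade membership, and the
  reconstruction narratives only on the major splits.

The exclusion chain of the clade-universality screen then reproduces
the reported arithmetic computationally: six Hymenoptera-specific
genes on the initial panel, minus two shared with the sawfly, minus
three absent from the vespid (post-Vespidae origin), leaves one
Aculeata-universal candidate (miR-6001).

## The simulator: what it emulates, and what it does not

`simulate_presence_evolution` draws each character's root state with
probability `root_presence_prob`, then runs a two-state
continuous-time Markov chain (gain rate `gain_rate`, loss rate
`loss_rate`, per unit branch length) down the tree, using the closed-
form transition probabilities at each branch length. Defaults:
`gain_rate = 0.1`, `loss_rate = 0.3` (novel miRNA families arise
rarely and are lost more readily than gained, so losses outpace
gains), `root_presence_prob = 0.5`, 50 characters. No quantitative
rates exist for hymenopteran miRNA turnover; these defaults are for
exercising the pipeline, not for biological inference, and the suite
checks the simulator's leaf-state frequencies against the analytic
two-state formula rather than against any empirical value.

`generate_genomes` plants each truly-present mature once, at a uniform
position and strand, into i.i.d. background at `gc_content = 0.35`
(hymenopteran genomes are AT-rich) and `genome_length = 200000` nt.
Planted panels are verified by a full scan and resampled if any
catalog sequence occurs by chance (or a planting junction creates
one), so with `fn_rate = 0` the scan of a generated panel equals the
simulated truth *exactly*, by construction — the pipeline's core
correctness property is testable as an identity rather than a
probability. The random catalog itself is collision-checked across
strands so queries cannot cross-match. `fn_rate` vetoes cells (not
occurrences): it models the assembly-gap false negative, where a
genome simply lacks the locus, which acts at the miRNA-by-genome
level.

What the simulator does *not* emulate: repeats and isochore structure
(backgrounds are i.i.d.), sequence evolution of the matures themselves
(presence/absence only), heterogeneous assembly quality across the
panel, and rate variation across miRNA families. Passing recovery
tests therefore show the pipeline is exact on clean inputs and
degrades as binomial theory predicts under cell-level dropout — they
do not show robustness to real assembly artifacts.

## Numerical and procedural choices

* Problem sizes in the shipped test suite: scanner-oracle equivalence
  on 1,000 randomized catalog/contig pairs; parsimony-oracle
  equivalence on all 256 characters of a fixed 8-leaf tree plus 100
  random polytomous trees; Dollo-vs-Fitch domination on 10,000 random
  characters; recovery on 20 seeds of a 50-miRNA, 10-leaf, 200-kb
  panel at `fn_rate` 0 and 0.2. These sizes were chosen to exercise
  every code path at desk scale.
* Seeds are mandatory in simulation configs; there is no hidden global
  randomness, and equal seeds give byte-identical panels.
* Degenerate inputs fail loudly: empty catalogs, genomes with zero
  contigs, all-absent characters under Dollo, unlabeled matrix
  columns, unbound clade handles, non-monophyletic clade bindings, and
  unparsable miRNA-name dialects are all errors, not warnings.
* Tie-breaks are documented conventions: event lists delay changes
  toward tips; row ordering breaks pattern ties by name; dedup breaks
  equal-precedence name ties alphabetically.

## Limitations

The analysis inherits the limits of its presence criterion: a single
substitution in a mature sequence, a sequencing error, or an assembly
gap scores as absence. The false-negative direction is therefore the
dangerous one, which is why `clade_universal` exposes `tolerance`, the
simulator models `fn_rate` explicitly, and absences in low-coverage
genomes should be read with care. A three-state (present / absent /
unknown) matrix would be the principled extension; the current core
keeps the binary matrix of the original analysis. Likelihood-based
gain/loss models (rate estimation, branch-length-aware reconstruction)
are out of scope by design — the reconstructions here are parsimony
summaries of the profile, matching the descriptive character of the
screens.
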