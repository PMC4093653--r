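---
title: "Methods: transposable-element annotation with beanTE"
author: "beanTE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposable-element annotation with beanTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

beanTE reconstructs, as a tested R workflow, the combined
homology-and-structure strategy used to build the common bean
(*Phaseolus vulgaris*) transposon database: de novo structural discovery of
LTR retrotransposons, translated homology search for the coding superfamilies
(LINE, CACTA, hAT, MULE, PIF/Harbinger, Helitron), structural classification
by terminal motifs, terminal inverted repeats (TIRs), target-site
duplications (TSDs) and polyA tails, single-linkage clustering into families
with one representative each, EST-based expression summaries, ORF-layout
screening of LTR-element internal regions, and neighbor-joining phylogenetics
of reverse-transcriptase (RT) domains.

The package deliberately does not re-annotate the real 521-Mb assembly: the
published genome-wide counts depend on external data. Instead, a
truth-tracked synthetic genome generator plants intact elements with known
coordinates, TSDs, terminal structures, family memberships and ORF layouts,
so that every stage can be scored against ground truth, and the published
worked-example arithmetic (EST percentages, layout census, library totals)
is recomputed from the printed per-category counts.

All coordinates are 0-based half-open internally; GFF3 export converts to
1-based closed. Every threshold that matters is a visible default:
50 bp minimum LTR length and minimum inter-LTR distance, translated-search
cutoff E < 1e-20 with 10-kb flanks, family identity > 70% (with an added 80%
coverage requirement), EST cutoff E < 1e-5, 150-aa minimum ORF, 100-kb
distribution windows.

# The synthetic genome generator

`sim_config()` / `simulate_genome()` build an i.i.d. background at a fixed GC
content (default 0.40, a plant-like value) and plant per-family consensus
elements mutated per copy by substitutions only. Defaults describe the study
conditions used throughout the tests and scripts: a 1-Mb genome; 10 Ty1-copia
and 10 Ty3-gypsy elements (so at least 20 intact LTR elements), 4 each of
CACTA, hAT, MULE and PIF/Harbinger, 3 Helitrons, 4 LINEs, 3 SINEs and 3
non-coding MITEs; LTR lengths 150-400 bp; per-copy divergence drawn from
0-10%; about 3 members per family; at least 1 kb of background between
insertions; 600 ESTs of 200-500 bp at 30% TE fraction with 1-2% read error.
The per-superfamily copy numbers are not taken from any published table
(none exists at this scale); they were chosen once so that every superfamily
is represented with enough copies to measure recovery, and are not tuned.

Element anatomy follows the field's textbook structure. LTR retroelements
are `TSD | TG..CA LTR | internal | TG..CA LTR | TSD` with a 4-6 bp TSD; the
internal region carries an ATG-initiated retrotransposase ORF whose middle
is a bundled 180-aa "domain core" peptide (synthetic stand-ins shipped in
`inst/extdata/domain_cores_synthetic.fa`, one per superfamily — they are
random sequences, not real proteins, which keeps the homology stage fully
self-contained and dependency-free). Envelope-like families add a sense ORF
between the retrotransposase and the 3' LTR; ORF2 families add the same ORF
reverse-complemented (antisense). CACTA elements carry the literal
`CACTA...ATGTG` terminal motifs (the published motif pair; the
reverse-complement-consistent `TAGTG` is available as a config switch — the
two are mutually inconsistent and we do not guess which was intended); hAT,
MULE and PIF/Harbinger carry TIRs of 15, 60 and 14 bp with 8, 9-11 and 3 bp
TSDs; LINEs end in a protected polyA tract with 5-29 bp TSDs; SINEs are
short, non-coding, polyA-tailed; Helitrons have no TSD.

Three mutation-model choices matter and are deliberate:

* substitutions only (no indels), so boundary-exact recovery is a fair test;
* within planted ORFs, substitutions that would create a premature stop are
  reverted — a selection-style constraint that keeps planted coding capacity
  intact at the divergence levels the recovery properties quantify over;
* terminal motifs, TIRs and polyA tails are protected, mirroring the strong
  cis-sequence conservation transposition machinery imposes; and the two
  LTRs of one copy receive mirrored element-level mutations plus an
  independent LTR-to-LTR divergence, so that `ltr_divergence = 0` plants
  exactly identical LTRs (the recent-insertion signature) regardless of the
  copy's overall divergence.

What the generator does **not** emulate: nested or fragmented insertions,
solo LTRs, indels, isochore structure, tandem-repeat fields, or low-copy
segmental duplications. Passing recovery tests therefore demonstrates
correctness of the detection logic under clean insertions, not performance
on a real, rearrangement-riddled genome.

# LTR detection

`find_direct_repeat_pairs()` seeds on exact 15-mers repeated on one diagonal
within the allowed element span (the two copies of a substitution-only
repeat share a diagonal exactly), clusters seeds, and extends each cluster
with an X-drop walk (match +1, mismatch -2, drop 40) that settles at the
maximum-score point. Repeats shorter than 50 bp, pairs closer than 50 bp or
spanning more than 15 kb (a maximum chosen to cover the largest described
element, 13.6 kb, with margin), and identities below 80% are discarded. When
the identity threshold is set to 100 the extension reduces to the maximal
exact run, which is what the brute-force all-diagonal oracle in the test
suite enumerates. Tandem-array overlap is resolved by trimming the repeat so
that an internal region of at least the minimum distance remains; redundant
variants of one repeat pair (both copies overlapping a better-scoring
candidate's) are collapsed keeping the highest (identity, length), ties
leftmost. Whole-span containment alone does not discard a candidate: a
chimeric pair bridging two neighbouring same-family insertions can contain
a true element, and it is inspection, not containment, that kills chimeras.

`inspect_candidate()` automates the manual boundary inspection: boundary
shifts of up to 10 bp are searched (both repeat copies move together,
preserving the diagonal), scored by TG...CA termini plus TSD evidence with
longer TSDs preferred and the smallest shift winning ties. Shifts up to
10 bp — rather than a smaller window — are needed because a
substitution-dense terminal stretch can stall the extension several bases
short of the true boundary. A TSD found at shifted boundaries only counts
when the shift also restores TG...CA; otherwise a wide search would dredge
chance 4-6-mers out of the flanks of structureless candidates. A candidate
is accepted only when a TSD is found and it is not a tandem (internal region
shorter than the minimum distance, or sharing at least 50% identity with the
LTR); otherwise the status records the reason (`rejected_tandem`,
`rejected_no_tsd`, `rejected_structure`). Accepted candidates overlapping a
better accepted candidate are demoted: chimeric pairs between neighbouring
identical insertions occasionally survive inspection by a chance TSD, and
true elements never overlap each other in the simulation model.

# Translated homology search

`translated_search()` translates all six frames, indexes 4-aa words once per
frame, and requires two seed words in a narrow diagonal band before aligning
(the classic two-hit policy; isolated random words never trigger an
alignment). Alignment is Smith-Waterman under BLOSUM62 (gap 11/1) against
stop-free segments of the seeded window, so hits never cross stop codons and
frameshifted coding regions surface as multiple fragment hits, which the
downstream layout logic unions. E-values use the deterministic bound
`E = m * n * 2^(-bits)` with `bits = score/2` (BLOSUM62 half-bits), `m` the
total translated residues, `n` the query length — a conservative,
reproducible alternative to fitted Karlin-Altschul statistics; the cutoff
stays user-configurable. The exhaustive full-DP score over whole frames is
the test oracle for the seeded heuristic.

# Structural classification

`superfamily_rules()` is the single rule table: CACTA `CACTA...ATGTG` with
2-3 bp TSD; hAT TIR >= 10 with 8 bp TSD; MULE TIR >= 40 with 9-11 bp; PIF/
Harbinger 3 bp; LINE polyA with 5-29 bp; SINE polyA, at most 700 bp, 5-20 bp;
LTR retroelements TG...CA with 4-6 bp; Helitron has no structural rule and is
classified from domain homology alone (no TSD exists to anchor its
boundaries, so Helitron spans stay approximate — a documented limitation).
`find_tsd()` returns the longest exact duplication anchored at both
boundaries. TSD matching is exact: the TSD is treated as diagnostic, and a
mismatch allowance stays off by default.

`classify_candidate()` slides each boundary up to 50 bp to maximise the
joint structural evidence of each rule on both strands. When several rules
fit, the fit with the longest exact TSD wins — a short-TSD rule (PIF's 3 bp)
always fires spuriously on the prefix of a longer duplication (hAT's 8 bp),
so TSD length is the specificity order; a residual tie falls back to domain
homology, and an unresolvable tie is logged and left unclassified, never
silently picked. LINE is preferred over SINE when domain homology supports
coding capacity; a polyA+TSD region of at most 700 bp without domain
evidence classifies as SINE. In the pipeline, the 10-kb homology flanks are
first narrowed by an anchored search (`CACTA` motif pairs validated by their
TSD, innermost pair first, because chance motif occurrences accumulate in
wide flanks; inverted-repeat seeds validated by TIR arm and TSD; polyA runs
plus TSD anchoring for LINEs) before the 50-bp refinement. LINE boundaries
on the TSD-less side are the least reliable call: when the true TSD is
short, a chance duplication elsewhere in the flank can win, and boundary
errors of tens of bp result; superfamily assignment is unaffected.

SINEs are classified when a candidate region is supplied but are not
discovered de novo by the pipeline (the original workflow found them by
BLASTN against known SINEs, an external resource); the MITE scan
(`find_mite_like()`) covers short TIR elements instead, seeding on exact
reverse-complement 12-mers within 2 kb and demanding a TIR arm of at least
14 bp plus an exact TSD, which keeps the false-positive rate at roughly one
spurious short element per megabase.

# Families, library, expression, layout, phylogeny

`cluster_families()` aligns all element pairs that share at least three
exact 12-mers (either orientation), scores identity over the aligned region
and coverage against the shorter sequence, and joins pairs above 70%
identity and 80% coverage; families are single-linkage components — the
published criterion states only the similarity threshold, and single
linkage matches the 80-80-80 tradition; the coverage requirement prevents a
short shared domain from welding unrelated families. Representatives prefer
intactness, then length, then the smallest identifier, so adding a shorter
fragment never changes a family's representative. The library summary
recomputes class subtotals and the grand total from the per-category counts
— totals are never stored.

`map_ests()` assigns each EST its best local-alignment hit (nucleotide
+1/-2, gaps 2/1, both strands, same E-value bound with `bits = score`)
below E < 1e-5; best-hit-only, because the published per-category counts
are unique assignments. Percentages round half-up to one decimal, matching
the printed precision of the source tables.

`find_orfs()` is stop-to-stop, ATG-initiated ORF calling in six frames (TE
coding regions are treated as intronless, replacing external gene
predictors); within a stop-bounded segment the first ATG gives the longest
ORF. Extra ORFs must be ATG-initiated — whether the original analysis
required this is unstated; we require it and note the alternative. The
150-aa default floor sits safely below the smallest published extra ORF
(211 aa) while suppressing random open frames. `classify_layout()` takes
the retrotransposase to be any ORF overlapping an RT-domain hit (or,
lacking domain evidence, the longest ORF), unions frameshifted fragments,
and calls an extra ORF envelope-like when it is on the retrotransposase
strand with its midpoint downstream of the retrotransposase 3' end, or ORF2
when it is antisense in the same position — "between the retrotransposase
ORF and the 3' LTR" operationalised as the midpoint criterion. Stop-gain
under divergence can demote an element to `no_coding`; the synthetic
generator's no-premature-stop constraint keeps this rare, and the recovery
tests count rather than hide such demotions.

`rt_distances()` uses global-alignment p-distances with terminal-gap
columns excluded (internal gaps count as differences) — a deliberate,
documented replacement for progressive MSA plus manual removal of ambiguous
regions; its effect on clade composition is not asserted.
`neighbor_joining()` is the standard Q-criterion agglomeration with a
deterministic tie-break (lexicographically smallest label pair, internal
nodes identified by their smallest leaf), negative branch estimates clamped
to zero with the clamped total reported. `ape::nj` serves as an independent
cross-check in the tests, never as the implementation. No bootstrap is
computed. `clade_report()` asks whether annotated leaves form an
edge-bounded cluster of the unrooted tree (the rooting-free notion of
monophyly).

# Numerical and degenerate-input conventions

Ties are never silent: candidate variants rank by (identity, length,
leftmost); structural-rule ties resolve by TSD length, then domain backing,
then a logged `unclassified`; EST best-hit ties keep library order with a
message; NJ ties use the label order. Empty inputs return empty, typed
results (an empty genome region, an EST pool of zero reads, a zero-element
configuration); contract violations (a candidate span outside its sequence,
ORFs outside the internal region, a genome too small for its elements) stop
with explicit errors rather than truncating. Homopolymer TSDs whose
flanking host base happens to extend them are reported one base longer than
planted — an inherent ambiguity of the longest-duplication definition,
visible in the recovery rate at well under one percent of elements.

# Problem sizes

The bundled analysis workflow and the acceptance script run on a 1-Mb
genome with 46 planted elements (20 of them LTR retroelements), a 1-Mb
element-free control, a 300-kb undiverged-layout genome and a 300-kb
family-structure genome; the test suite uses a 200-kb shared simulation
plus many constructed micro-fixtures. These sizes give every stage several
dozen positive and negative cases while keeping a complete run in the
minutes range on one CPU.

# Known limitations

* Helitron boundaries are approximate (homology span only); the rolling-
  circle 5'TC/3'CTRR-hairpin structural criterion is deliberately omitted.
* SINEs are not discovered de novo.
* LINE 5' boundaries (3' on the minus strand) depend entirely on the TSD
  anchor and degrade when the TSD is short.
* No nested-insertion resolution, no solo-LTR discovery, no PBS/PPT
  detection, no indel-aware boundary recovery.
* The E-value bound is conservative rather than calibrated; absolute
  E-values are not comparable to BLAST's, though thresholds play the same
  role.
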