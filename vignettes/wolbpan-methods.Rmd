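---
title: "Methods: comparative genomics of endosymbiont strain sets with wolbpan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of endosymbiont strain sets with wolbpan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbpan)
```

# Scope and model

wolbpan analyses panels of closely related bacterial endosymbiont genomes —
the *Wolbachia*-style setting of a handful of circular ~1.3 Mb chromosomes
from congeneric host species — and asks the comparative questions such
panels support: which gene families are present in which strains
(presence–absence variation, PAV), which proteins are exported or membrane
anchored (the secretome), which protein families carry many variable sites
(candidate host-interaction effectors), how strongly genome architecture has
been reshuffled (synteny breakpoints), and what the GC landscape of each
chromosome looks like. A simulation module generates strain sets with fully
known ground truth so that every one of these stages is testable offline,
end to end, without reference databases or external predictors.

This vignette documents the statistical and algorithmic choices, the
tunable parameters with their defaults and units, what the simulator does
and does not emulate, and the known limitations. It states no empirical
result that the package's test suite and acceptance script do not
themselves compute.

# Read hygiene: the gap-compressed mismatch-ratio filter

Short reads re-aligned to a draft assembly before polishing carry
mismapping noise. The filter removes a read when its **gap-compressed
divergence** exceeds a threshold (default `0.04`):

$$ r = \frac{n_\text{mismatch} + n_\text{gap opens}}
           {n_\text{match} + n_\text{mismatch} + n_\text{gap opens}} $$

where every insertion or deletion *run* counts as one event regardless of
its length — the convention modern long-read aligners use for their
per-base divergence estimate. The boundary is strict: a read at exactly the
threshold is retained, only reads *exceeding* it are removed. Because
aligners emit several encodings, `gap_compressed_divergence()` resolves
mismatches in a fixed precedence: explicit `X` runs from `=`/`X` CIGARs;
then mismatches implied by an `NM` edit distance beyond the gap bases and
explicit `X` runs (carved out of ambiguous `M` runs when those exist);
a parsed `cs:Z:` difference string resolves `M` runs and must agree with
`NM` when both are present. A record with none of these is
*divergence-indeterminate* and is dropped with a warning rather than
assumed perfect — failing safe, since an unverifiable read adds no
polishing signal. Each read is judged by its primary alignment only;
secondary and supplementary lines are ignored.

`dedup_reads()` removes duplicate reads (by id or by full sequence),
keeping first occurrences, mirroring the duplicate-removal step sequencing
artifacts make necessary before assembly.

# Genome statistics

`gc_content()` is $(G{+}C)/(A{+}C{+}G{+}T)$ with IUPAC ambiguity codes
excluded from numerator and denominator — exclusion is unbiased, while
counting ambiguous bases as half would shrink extreme windows toward 0.5.
`gc_skew()` is $(G-C)/(G+C)$; its sign structure tracks replication strand
asymmetry and flips at the origin and terminus of replication.
`windowed_profile()` slides a window (default 10,000 bp, step 1,000 bp —
smooth at the ~1.3 Mb scale of these chromosomes; both are configuration,
not claims about any upstream viewer's settings) over the chromosome,
wrapping across the origin of circular genomes. With `deviation = TRUE`
the genome-wide value is subtracted from every window, the convention of
circular genome viewers. A window with no informative bases records `NA`,
never zero. Each window carries its informative-base count as a weight, so
the count-weighted window mean reconciles exactly with the genome-wide
value — an invariant the tests check to `1e-12`. GC percentages are
reported rounded half-up to two decimals, the precision of
genome-announcement tables.

# Orthogroups and presence–absence variation

Full orthology inference (all-vs-all alignment, MCL graph clustering) is
out of proportion for a desk-scale panel, and the downstream statistics
need only a strain→gene partition. `infer_orthogroups()` therefore uses
reciprocal best hits (RBH): each protein is fingerprinted as the multiset
of its amino-acid 4-mers; similarity is the multiset Jaccard index; for
each ordered strain pair each gene's best hit with similarity at least
`min_score` (default 0.2 — permissive at congeneric divergence, where
within-family similarity stays well above 0.5) is recorded; reciprocal
edges are kept and orthogroups are the connected components. Ties break on
the lexicographically smallest gene id, and group ids are assigned by each
group's smallest member, so output is independent of strain enumeration
order. Externally computed orthogroup tables can be ingested instead via
`read_orthogroup_table()` (the `Orthogroup<TAB>strain…` dialect) when
fidelity to a specific external tool matters.

The multiset Jaccard is computed exactly at scale by an occurrence-indexing
trick: the *i*-th copy of a k-mer within one protein becomes the key
`kmer#i`, so a sparse binary gene-by-key incidence matrix cross-product
yields all pairwise multiset intersection sizes in one step.

`build_pav()` emits copy counts per orthogroup and strain in a fixed
column order; `extract_scos()` selects single-copy orthologs (exactly one
gene in every strain), the basis for strain phylogenies;
`export_supermatrix()` concatenates SCO alignments with a 0-based
half-open partition table for downstream phylogenetics tools (tree
inference itself is out of scope).

Orthogroup alignments use the center-star method: the member with maximal
summed k-mer similarity is the center; every other member is globally
aligned to it (match +1, mismatch −1, affine gaps costing 2 + L for a gap
of length L) and the pairwise alignments are merged under
once-a-gap-always-a-gap. Center-star has bounded error relative to an
optimal multiple alignment and is exactly checkable on small cases against
an exhaustive dynamic program, which the test suite does. At the ≤10%
divergence of these panels the members differ essentially by
substitutions, so the pairwise optima are gap-free and the merged columns
are the homologous sites.

# Secretome classification

The classification rule is fixed and total: a protein with a signal
peptide and at least one transmembrane segment is **membrane-bound**; with
a signal peptide and no transmembrane segment, **secreted**; without a
signal peptide, **other**. The evidence for the two flags comes either
from external predictor tables (`read_predictor_tables()` accepts
classic short formats and generic TSVs; external evidence always overrides
the heuristics and is recorded per protein in `evidence_source`) or from
built-in hydropathy heuristics:

* `hydropathy_profile()` — centered moving average of Kyte–Doolittle
  residue hydropathy (window 19, the canonical transmembrane scan width).
* `predict_signal_peptide()` — positively charged residue (K/R) in
  positions 1–5, followed by ≥7 consecutive positions within 3–25 whose
  window-7 mean hydropathy exceeds 1.6; cleavage at the first small
  residue (A/G/S) in positions 18–35 after the hydrophobic stretch.
  Proteins shorter than 25 residues are negative with a `too-short` note.
* `predict_tm_segments()` — maximal runs of ≥15 residues with window-19
  mean hydropathy > 1.6, runs separated by <5 residues merged. Segments
  overlapping the predicted signal peptide are discarded: signal peptides
  are themselves hydrophobic and would otherwise push every secreted
  protein into the membrane-bound class.

These heuristics are deliberately simple stand-ins for neural-network and
HMM predictors, which are outside this package's scope; the external-table
path is the fidelity route. The thresholds (1.6 on the Kyte–Doolittle
scale, run lengths 7 and 15) are package defaults tuned to the simulator's
planted features, and every one is a visible argument.

Orthogroup-level classes aggregate member classes by majority vote with
ties broken by the fixed precedence membrane-bound > secreted > other —
an aggregation rule is needed to label orthogroup-level PAV displays, the
choice is conservative toward the rarer, more interesting classes, and it
is configurable in the sense that the per-member table is always returned.

# Variability: per-column Shannon entropy

For each orthogroup alignment, `column_entropy()` computes
$H = -\sum_a p_a \log_2 p_a$ in bits over the residues observed in the
column. Gaps, `X` and `*` are excluded from the frequencies, and a column
with fewer than `min_coverage = 2` informative residues is undefined and
never variable — otherwise indel-rich columns represented by a single
residue would be called "variable" on no evidence. Base 2 is the sequence
conservation convention; since the default variable-site threshold is 0
(any column with ≥2 observed states), the base affects only the scale of a
non-default threshold. Whether an upstream analysis would have included
gap columns or used a stricter "high-entropy" cutoff cannot be settled
from the outside, so both the gap policy and the threshold are first-class
parameters rather than baked-in assertions.

`summarize_variability()` reports per-class orthogroup counts and medians
of the variable-site count, computing even-count medians as the mean of
the two central order statistics — so half-integer medians (e.g. `{13,14}
→ 13.5`, the form such analyses print) are representable. Zero-variable
orthogroups enter the medians but are excluded from the histogram table
and counted separately, the usual display convention.
`effector_report()` matches named effector families (TomO-, WalE1-,
Cif-style labels) by regular expression and reports each matched
orthogroup's variable-site count and percentage, with the full alignment
length (including gap-containing columns) as the denominator and the
percentage rounded to a whole percent.

# Synteny

`kmer_anchors()` finds exact shared k-mers (default k = 15 bp) between
genome *a* and both strands of genome *b*, discards k-mers occurring more
than `max_occurrence = 4` times in either genome (endosymbiont genomes are
IS-element rich; the cap keeps the unique backbone while preventing a
quadratic repeat blowup), and merges overlapping consecutive matches into
maximal exact anchors. Reverse-strand anchors report forward-strand
coordinates of the reverse-complemented interval, so one convention serves
dotplots and block logic. All genomic coordinates package-wide are
0-based, half-open.

`chain_anchors()` chains strand-consistent, monotone anchors with
inter-anchor gaps ≤ `max_gap` (default 5,000 bp) into collinear blocks,
scoring each block by its constituent seed k-mers and dropping blocks with
fewer than `min_anchors = 3` seeds. Three guards make the greedy chain
robust to chance k-mer matches, which occur by the hundreds between
AT-rich megabase genomes: (i) an anchor may only extend a chain whose
(anti-)diagonal it continues to within `max_diag_drift = 1000` bp — about
the local indel scale of a gained or lost gene, far below the offset of a
random match; (ii) weak terminal anchors far from a chain's body are
trimmed at flush, so a chance anchor near the block diagonal cannot
stretch a boundary past the true breakpoint; (iii) blocks spanning less
than `min_length = 200` bp of genome *a* — reachable by chance matches,
never by genuine collinear runs — are dropped. Remaining small overlaps
between blocks (up to k bp of boundary-anchor wobble at rearrangement
breakpoints) are trimmed in favor of the stronger block. On circular
genomes the first and last blocks are merged across the origin when
mutually extendable, so wrap-spanning blocks are not split artificially;
the merged block is represented with `end > length`.

`breakpoint_report()` emits the boundaries between adjacent blocks in
genome-a order, including the circular adjacency, each flagged for strand
change (an inversion signature). A single block covering the chromosome
yields no breakpoints. On simulated data the planted inversion boundaries
are recovered to within k−1 bp — the resolution limit of exact k-mer
anchoring, since no anchor can cross a breakpoint.

# The simulator and its ground truth

`simulate_strain_set()` draws every stage's input from one integer seed.
Sub-streams are derived per strain/family/read by stable string hashing of
identifiers, so output is independent of iteration order and
byte-reproducible; intergenic spacer streams are keyed by flanking
families rather than by strain, so strains with identical gene content
assemble identical chromosomes apart from planted rearrangements — the
property the synteny closed loop measures against.

The defaults define the simulated study conditions: 8 strains in 2 clades
("supergroups"), 300 gene families (240 core + 60 accessory), protein
bodies of 120 residues, 0–12 planted variable columns per family, class
probabilities 0.7/0.15/0.15 for other/secreted/membrane-bound (secretome
classes are minorities in real proteomes), 400 reads with divergences
0.005–0.1 straddling the 0.04 filter threshold, genes of 600 bp with
~300 bp intergenic spacers at GC 0.35 (the AT-rich composition typical of
these endosymbionts), skew amplitude 0.6 with the origin at a quarter of
the chromosome, and one planted 10 kb inversion. These sizes keep a full
two-run determinism check within a few minutes on one core while leaving
every recovery statistic far from its decision boundary.

Component models, chosen for controllability over realism:

* **Tree** — random bifurcations within and between clades, branch
  lengths uniform on [0.02, 0.15] substitutions/site; clades are
  monophyletic by construction.
* **Gene content** — at most one state flip per family per branch: gain
  probability $1-e^{-g\ell}$ when absent, loss probability
  $1-e^{-l\ell}$ when present, root presence of accessory families with
  probability `accessory_root_prob` (default 0.5). Every event is logged;
  the truth PAV table is exact and the limiting cases (no events → all
  present; a single stem-branch gain → exactly one clade) are analytic.
* **Alignments** — substitutions uniform over the 20 amino acids, placed
  only in designated columns; with forced-variability mode a designated
  column that drifts monomorphic receives a second state in one leaf, so
  recovered variable-site counts equal the planted counts exactly.
  Realism (rate heterogeneity, exchangeability matrices) is deliberately
  sacrificed for exact truth recovery.
* **Protein features** — bodies are drawn from a polar alphabet, so
  planted features are the only hydrophobic signal. The signal segment is
  22 residues from {A,L,I,V,F} with a charged residue at position 2. The
  planted internal hydrophobic segment is 28 residues from {L,I,V,F}: a
  19-residue segment flanked by polar sequence cannot sustain the
  detector's required 15-position run of window-19 means above 1.6 (the
  attainable run tops out near 11–13 positions), while 28 strongly
  hydrophobic residues guarantee it with margin; the segment still
  contains the canonical 19-residue transmembrane core.
* **Genomes** — shared per-family gene sequences concatenated in family
  order with intergenic spacers whose per-strand G probability is
  $p(1+A)$ on the half-chromosome approaching the origin and $p(1-A)$
  leaving it, so the windowed skew flips sign at the origin and terminus.
  Gene interiors are unskewed; with ~40% intergenic sequence and
  amplitude 0.6 the windowed signal is an order of magnitude above
  sampling noise at 4 kb windows. Inversions are applied per strain with
  breakpoints recorded.
* **Reads** — each record realizes a requested divergence as
  `round(d * n_events)` difference events (mismatches and 1–3 bp indel
  runs, each separated by at least one match), so the realized divergence
  recorded in the truth table is within `0.5/n_events` of the request and
  the filter closed loop is exact. Requested divergences must not exceed
  0.5, where the separating-match construction runs out of room.

What the simulator does **not** emulate — and what passing tests
therefore do not show about real data: sequencing error profiles and
basecalling artifacts; codon structure and selection (nucleotide genes and
protein sequences are generated independently); recombination and lateral
transfer; repeat families and mobile elements beyond what the
`max_occurrence` cap guards against; paralogy (no within-strain gene
duplications, so RBH clustering is never stressed by out-paralogs); and
realistic amino-acid substitution processes. Results on real panels
depend on upstream annotation and predictor quality in ways no closed
loop here can certify.

# Numerical and degenerate-input conventions

Alphabet validation is strict and non-repairing; malformed input is an
error naming the offender. Undefined values propagate as `NA` (windows
with no informative bases) or typed conditions (`wolbpan_undefined`,
`wolbpan_indeterminate`, `wolbpan_too_short`) rather than silent zeros.
Ties break lexicographically everywhere (best hits, center selection,
orthogroup ids) so every output is deterministic. TSV writers emit fixed
six-decimal numeric formatting; the wrap-around window of a circular
track is written as two lines sharing a window id, with the line format
keeping seqid/start/end/value as the first four columns. The run report's
wall-clock timings are the only non-deterministic output and live only in
`report.json`.

# Known limitations

RBH with connected components can chain two families through a promiscuous
hub gene at low `min_score`; the default 0.2 avoids this at congeneric
divergence but is not safe for inter-genus panels. Center-star alignment
degrades when members differ by large indels. The hydropathy heuristics
have no notion of Tat signals, lipoprotein anchors, or T4SS effector
signals and should not be read as predictions of secretion mechanism. The
synteny module detects rearrangements between two genomes at a time; it
does not compute multi-genome collinear block decompositions, gapped
alignments within blocks, or nucleotide identity statistics.
`replicate_online()` exists for convenience against deposited assemblies
and degrades to a skipped report whenever the network or the accession is
unavailable.
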