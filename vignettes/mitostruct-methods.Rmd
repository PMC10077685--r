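---
title: "Methods: structural evolution of fungal mitogenomes in mitostruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural evolution of fungal mitogenomes in mitostruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Within a fungal species, mitochondrial genomes diverge far more by
structural turnover than by point mutation: mobile group I and group II
introns are gained and lost; a pair of inverted repeats (here called IRS)
can flank a segment (the MIR, carrying *nad2*, *nad3*, *rrnL*, *rps3* and
several tRNAs) whose orientation differs between lineages; and fragments of
a plasmid-derived DNA polymerase gene (*dpo*) are integrated at various
positions in clade-specific combinations. `mitostruct` turns each of these
observations into a reproducible computation over annotated circular
genomes, and adds a Dollo-parsimony event count that answers "how few
gain/loss events explain the observed intron distribution on this tree?"

# Coordinate conventions

All in-memory coordinates are 0-based half-open intervals on the forward
strand; GenBank I/O converts to and from the 1-based inclusive dialect
(`join()`/`complement()` locations become multi-segment features with an
explicit strand, rows ordered 5'→3' in gene orientation). Unambiguous
interval arithmetic is the sole reason for this choice. Sequences are
restricted to A/C/G/T/N; other ambiguity codes are rejected at parse time
because every identity computation downstream assumes a 4-letter alphabet.

Circular genomes are compared after `normalize_orientation()`: the genome
is rotated so the anchor gene (default *cox1* — the longest, reliably
single-copy mitochondrial gene) starts at position 0 on the plus strand,
reverse-complementing first if needed. Composition statistics are then
strand- and rotation-stable: AT content is computed over non-N bases and GC
skew as (G−C)/(G+C) over the whole forward strand. No convention for the
strand or origin used in published per-clade GC-skew tables is universal,
so exact reproduction of any specific published table is not promised; the
definition here is self-consistent and sign-flips under reverse
complement, which the tests assert.

# Inverted repeats and MIR orientation

`detect_inverted_repeats()` is a seed-and-extend detector: exact 21-mer
matches between the sequence and its reverse complement lie on
anti-diagonals (constant sum of the two start coordinates) when they come
from an ungapped inverted repeat. Seeds are grouped by anti-diagonal
(±16 nt band, chaining gaps up to 200 nt), extended outward base by base —
extension stops once 5 of the last 12 positions mismatch, then trims back
so the repeat ends on a clean run of 6 matches, which keeps chance
base-pairing in the flanks from inflating the repeat — and scored by global
alignment of copy A against the reverse complement of copy B. Circularity
is handled by searching the doubled sequence and canonicalizing the
images. Defaults `min_len = 500`, `min_identity = 0.95`: the IRS modeled
here consists of eight tRNA genes, hence ≳500 nt, and within-genome copies
are near-identical. Pairs are ranked by length × identity with ties broken
by the smaller start; nested pairs are suppressed.

`call_mir()` takes the dominant (longest) pair, considers the two arcs
strictly between the copies, and picks the arc containing more marker
genes (ties: the shorter arc). Orientation is defined *within* the genome:
the strand of *rps3* relative to the strand of the anchor gene — same
strand is `forward`, opposite is `reverse`. This makes the call independent
of any external reference; published per-clade forward/reverse labels
correspond after normalizing the reference genome the same way. If a
marker is annotated twice on opposite strands the genome carries both MIR
orientations (`duplicated_both`), a configuration observed in a small
number of real strains. The call is invariant under rotation and under
whole-genome reverse complement (both the marker and the anchor flip).

# The intron site registry

A homologous intron insertion site is defined by its **spliced
coordinate**: the number of exonic bases of the host gene 5' of the intron,
i.e. the insertion point in the intron-less transcript. This is robust to
intron turnover and to exon substitutions, which never move the insertion
point. `build_site_registry()` walks the reference annotation and records
one site per intron, with ordinals assigned 5'→3' within each gene.
`map_introns()` computes each query intron's spliced position *in the
query's own coordinates* and assigns it to the registry site of the same
gene within `tol = 6` nt. The tolerance is a design choice (no published
convention exists); exon micro-indels within a genus are rare and small,
and 6 nt separates any two real sites in practice while absorbing
annotation jitter. Two query introns mapping to one site indicate an
annotation fault and raise an error. Unmatched introns become novel sites
with fractional ordinals (inserted between their neighbors), so existing
ordinals never renumber; novel sites are excluded from IDP classification
by default because the classification frame is registry-defined.

**Types and subtypes.** Distinct intron types at one site are recognized by
global-alignment identity to per-site exemplars, threshold 0.90: reported
same-site foreign types show ≤88% identity while conspecific copies are
near-identical, so 0.90 separates the two regimes with margin on both
sides. Identity is matches / alignment length (gap columns count against).
Below-threshold sequences register a new type. Subtypes are called only at
*declared variant columns* of a type (e.g. one SNP plus one 2-bp deletion
distinguishing subtypes A and B), mirroring how such subtypes are defined
in practice and staying robust to sequencing noise elsewhere in the
intron. `detect_intron_anomalies()` reports query-only alignment segments
≥ `insert_min = 15` nt as internal inserts (real examples span 18–1238 nt;
15 ignores alignment slippage) and flags exemplar coverage < 0.80 as
degenerate (partial deletion).

# dpo fragments

`build_dpo_catalog()` single-links all dpo-annotated segments at
`merge_id = 0.90` identity (diverged fragments stay split; conspecific
copies merge), takes the longest member of each cluster as exemplar, and
names fragments `dpo1..dpoN` by genomic position in a designated naming
genome — ideally a basal-clade representative — then discovery order.
`profile_genome_dpo()` searches every exemplar on both strands
(12-mer seeding to candidate windows, then pattern-global/subject-local
alignment) and keeps hits at ≥ 0.75 identity over ≥ 0.60 of the exemplar;
these looser thresholds tolerate between-clade fragment divergence while
the 0.90 merge threshold keeps the catalog split. Hits inside the inverted
repeats are flagged and excluded from the per-clade summaries by default,
since only the fragments between the repeat and the MIR are
clade-diagnostic. The consensus call per clade is presence fraction ≥ 0.5.

# IDP classes and congruence

An IDP (intron distribution pattern) class is an equivalence class of
strains with identical **categorical** states over all variable intronic
sites — type, subtype and insert signature, not bare presence, because
some patterns differ only by a subtype at a single site. Labels follow
first-member occurrence in the post-order leaf sequence of a supplied tree
(else matrix order), so the partition itself is invariant to strain input
order. Congruence with a clade partition is summarized both as the count
of single-clade classes and as the adjusted Rand index (permutation-model
form); the ARI gives a single comparable number while the count matches
how such results are usually reported. Outgroup strains can be excluded
via `scope`, matching the convention that IDP classes are defined within
the focal species.

Haplotype collapsing (`collapse_haplotypes()`) groups identical rows of a
SNP matrix; the default `drop_columns` policy removes every column with a
missing state first (common population-genetics practice), `strict` treats
missingness as its own state — provided because published tool settings
for such counts are rarely stated.

# Minimum-event inference

Intron gains are rare horizontal transfers; losses (e.g. by reverse
transcription of spliced mRNA followed by reintegration) are common and
can delete several neighboring introns at once. Dollo parsimony encodes
exactly this asymmetry: per site, one gain on the stem of the MRCA of all
carriers, plus the minimal set of loss branches (the stems of the maximal
all-absent subtrees below it). A gain placed on the root stem means the
intron was ancestrally present; it is state, not an event — without this
convention the count for ancestrally present introns would include
uninformative root gains.

Loss events on one branch within one gene merge into a single block event
when they are **block-adjacent in the ancestral context**: no site of that
gene strictly between them is present in the branch's parent state. This
is what makes introns separated only by empty sites "neighboring" (the
*cox2* 1 + 6 case) while an intervening ancestrally present intron keeps
two losses distinct. Merging never crosses gene boundaries — the
reprocessed-segment mechanism operates within one transcript. Sub-root
gains merge under the same rule. A Fitch mode (`model = "fitch"`, per-site
change counts, no merging) is provided for sensitivity checks only.

Correctness is checked against exhaustive oracles: loss sets against
enumeration of all edge subsets on 6-leaf trees, and merged counts against
an independently coded reconstruction, over dozens of random instances.

# The simulator

`simulate_evolution()` is first-class, tested code that defines the study
conditions for every end-to-end check. The reduced-scale scaffold
(~40–55 kb once intron presence varies) carries the full gene inventory —
15 protein-coding genes, 2 rRNAs, 20 tRNAs, an IRS pair of 8 tRNAs
flanking a MIR with *nad2*/*nad3*/*rrnL*/*rps3* plus 9 tRNAs, and up to 8
dpo fragment slots between the first repeat and the MIR — with 21 intron
sites spread over the 7 intron-hosting genes (*cox1* the largest reservoir
with 8). Reduced scale keeps a full test battery fast while preserving
every structural element; the code contains no full-scale constants that
tests depend on.

Defaults, chosen once: AT content 0.71 (the observed mitogenome
composition in this group); loss rate 0.15 and gain rate 0.05 per site per
unit branch length (loss-dominated turnover, several events per data set
on a unit-height tree); block extension probability 0.4 per additional
neighboring site; dpo gain/loss 0.1/0.2 per fragment; MIR inversion rate
0.1 (rare enough to be clade-consistent, frequent enough to appear).
Trees are seeded coalescents scaled to unit height; branch lengths are
arbitrary units, with no attempt at absolute dating. The root carries all
registry introns (type 1, subtype A), the basal-style dpo set {1,2,4,5,6},
and reverse MIR orientation, so the simulated ancestor resembles the
deep-branching genomes in this group.

Sequence realization: one deterministic backbone (exons, tRNAs, spacers,
intron type exemplars, dpo exemplars) per seed; further types at a site
are generated at ~35% substitution divergence so the 0.90 type threshold
is exercised from both sides; per-leaf substitution noise (1% in exons,
0.3% in introns) never touches declared subtype variant columns. Emission
writes GenBank + FASTA per leaf, a noise-free reference genome, the
metadata table, a registry JSON (exemplars + declared variant columns —
the reference-side knowledge a real analysis also starts from), the tree,
and a truth JSON; identical seeds give byte-identical files.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: realistic nucleotide substitution processes and
phylogenetic signal in sequences, recombination between mitogenomes,
annotation error beyond coordinate jitter, selection, and genome-size
evolution of intergenic DNA. Truth-recovery results certify the pipeline's
internal consistency under the stated generative model, not annotation
quality of real assemblies.

# Numerical choices and degenerate inputs

* Alignment scoring: match +1 / mismatch −1, gap opening 12, extension
  0.5 — low extension cost keeps a long foreign insert in one gap instead
  of fragmenting it.
* Ties in type assignment go to the lexicographically smaller label;
  equal-length repeat pairs rank by smaller start; both make outputs
  deterministic.
* GC skew of a G+C-free sequence is defined as 0 with a warning.
* Empty inputs fail loudly: no genomes, empty dpo catalog, zero haplotype
  columns after filtering, a tree missing strains — each raises a specific
  error naming the offender.
* Problem sizes used by the test battery: 6-leaf simulations (20 seeds in
  the end-to-end battery), 50 kb sequences for planted-repeat checks,
  6-leaf/4-site exhaustive oracles, 200–400 replicate Monte-Carlo bands.

# Known limitations

* The IRS boundary convention is operational (seed coverage plus clean-run
  trimming); published analyses rarely state theirs, so cross-tool
  boundary agreement is only expected to ±25 nt.
* Intron class (group I vs II) is taken from annotation when present and
  otherwise left `unknown`; no secondary-structure inference is attempted.
* `infer_min_events()` assumes the supplied tree is correct and rooted;
  uncertainty in the tree propagates directly into the event count.
* The type threshold (0.90) and site tolerance (6 nt) are operational
  definitions of "same type" and "same site"; data sets with much higher
  intra-type divergence or micro-rearranged exons would need them revisited.
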