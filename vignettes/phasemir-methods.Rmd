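---
title: "Methods: phased MIR159/319 stem-loop analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phased MIR159/319 stem-loop analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`phasemir` implements the computational chain used to study plant
MIR159/319 genes — an ancient microRNA family whose long stem-loop
precursors are diced from the terminal loop toward the base, releasing
three phased ~21-nt duplexes. The chain runs: mature-miRNA homolog
scanning and hairpin filtering; five-type precursor classification and
the nine-partition scheme (`sp1, miR*, sp2, ACR5, sp3, ACR3, sp4, miR,
sp5`); partitioned small-RNA quantification; PARE (degradome) cleavage
profiling; structural-alignment consensus with covariation-classified
base pairs; Bayesian phylogenetics under a partitioned GTR + 16-state
doublet model; and duplication/loss reconciliation. Every input class
has a seeded generator with machine-readable ground truth, so the whole
pipeline is validated end to end on synthetic data without external
databases.

All coordinates in the package are 0-based, half-open intervals on the
5'→3' strand of the sequence at hand. All thresholds mentioned below
are arguments of the corresponding parameter constructors
(`scan_params()`, `mircheck_params()`, `quant_params()`,
`consensus_params()`, `acr_consensus()`, `mcmc_config()`); the values
quoted are the defaults.

# Hairpins and the built-in folder

A `hairpin` couples a sequence with a non-crossing secondary structure
and the span of the terminal loop of its main stem (the loop enclosed
by the most pairs, ties 5'-most). Structures can be supplied as
dot-bracket text — the native output format of thermodynamic folders —
so the package never requires an external folding binary. For inputs
without a structure, `fold_rna()` runs a deterministic stacking-aware
dynamic program: canonical pairs (Watson–Crick plus GU wobble) score
GC = 3, AU = 2, GU = 1, each stacked pair earns +1, minimum loop 3, and
ties are broken by pairing the 5'-most position to its smallest
admissible partner. This folder is not a free-energy minimizer (no
nearest-neighbour parameters, no ensembles, no pseudoknots); it exists
to make the pipeline self-contained and reproducible. Downstream rules
are parameterized so that structures from a thermodynamic folder can be
substituted everywhere.

# Homolog scanning and the seven hairpin rules

"Mismatches or indels" between a candidate site and a mature reference
is formalized as unit-cost Levenshtein distance over the best-matching
window. The scanner finds, on both strands, every cluster of windows
within `max_edits` of the query (a banded semi-global DP proposes end
positions; each cluster is reported once, keeping the window with the
smallest distance, ties to the leftmost start then the shortest
interval). `N` bases never match. Hits are extracted with 350-nt flanks
("as long as possible" at sequence ends) and folded.

The seven filtering rules are evaluated on the miR interval and its
located miR*: (1) miR and miR* each lie within a single arm; (2) at
most 6 unpaired miR bases; (3) at most 3 bulges, defined as maximal
runs of consecutive unpaired miR bases; (4) miR/miR* length difference
at most 3; (5) at most 3 asymmetrically unpaired miR bases — for each
interior unpaired run, the surplus of the run length over the number of
unpaired miR*-side bases between the same flanking pairs; (6) longest
unpaired run at most 3; (7) the loop-spanning distance between the
loop-proximal ends of miR and miR* within [5, 300]. The miR* is the
minimal interval containing the pairing partners of the miR (excluding
the miR's own 3'-terminal two bases) extended two bases at its 3' end —
the standard 2-nt 3'-overhang convention; on a perfect duplex this
returns exactly the 21-nt star with symmetric overhangs. When no miR
position is paired, or the miR straddles the loop, rules 1, 4, 5 and 7
fail and the miR-local rules 2, 3 and 6 are still reported.

Status calling: all seven rules must pass; then edit distance ≤ 3 is a
homolog, exactly 4 a candidate homolog, more is rejected. The published
workflow additionally discarded "loose and unstable structures" by
manual inspection; the package replaces that step with a deterministic
screen — at least 50% of miR ∪ miR* positions must be paired
(`stability_min`, configurable). Family naming follows the reference
mature sequence with the smallest Levenshtein distance, ties broken by
lexicographic reference id.

# Five types and nine partitions

The classifier reduces to a decision table over three quantities. `D`
is the number of nucleotides strictly between the loop-proximal ends of
miR and miR* — the same quantity bounded by rule 7. `D ≤ 60` (boundary
inclusive) is the short form, type 2: no elongated loop-proximal stem
exists. For `D > 60`, sequence conservation (`seq`) holds when
ungapped sliding windows in the loop-proximal gap match the supplied
ACR5 and ACR3 consensus sequences at identity ≥ 0.6 (window lengths
within ±2 of the consensus length, ACR5 window 5' of the ACR3 window);
structure conservation (`str`) holds, when the consensus windows were
found, if they pair with each other at a pairing fraction ≥ 0.6 with no
multiloop in the connecting stem (no position between the ACR duplex
and the miR duplex pairs outside that span). When sequence evidence is
absent, `str` falls back to elongated-stem integrity: the fraction of
gap positions pairing within the gap must reach the same threshold —
this is what separates a maintained stem (type 4) from one opened up or
broken into multiloops (type 5). The mapping is then (yes, yes) → 1,
(yes, no) → 3, (no, yes) → 4, (no, no) → 5. The 0.6 thresholds are
design choices (the source material never quantifies "conserved");
they separate the planted synthetic cases cleanly and are exposed as
`acr_consensus()` arguments. The ACR consensus sequences themselves are
caller input — typically derived from `consensus_sequence()` on a
type-1 alignment — keeping the classifier family-agnostic.

Identity searches run over the whole loop-proximal gap rather than
relative to the structure-derived terminal loop, because in type-3
precursors the disrupted second duplex inflates the apparent loop; this
also makes `detect_acr()` invariant to unpaired flanking sequence.

`build_partitions()` requires a type-1 record: the four conserved
partitions are the located miR, miR*, ACR5 and ACR3 intervals and the
five space partitions fill the gaps in 5'→3' order (sp3 spans the
terminal loop; zero-length space partitions are allowed; the mirrored
order with an orientation flag covers miR on the 5' arm). A type-2
stem-loop is refused — with no elongated region there is nothing to
partition.

# Small-RNA quantification

Reads map to precursors by exact substring match only. Distinct
sequences are the unit of accounting ("unique small RNAs"); a read
matching several precursors is `shared` and excluded from the `unique`
abundances but counted at full weight in every matching precursor's
`max_possible` abundance; a read matching one precursor at several
positions splits its abundance equally (a mass-conserving choice for a
case that is vanishingly rare on hairpins). Across samples, counts are
scaled to the mean total: `factor = mean(total_reads) / total_reads`;
libraries flagged as pre-normalized keep factor 1.

A placement is assigned to the partition holding at least 80% of its
nucleotides (for a 21-nt read, 17 nt = `ceiling(0.8 × 21)`); with
disjoint partitions and any threshold above one half at most one
partition can qualify, which the tests verify by scanning every
placement. Unassignable placements accumulate as `leak`, the proxy for
reads inconsistent with the phased register. Per precursor and sample,
partition abundances plus leak equal the mapped normalized abundance
exactly.

Mutant-to-wild-type ratios average replicates first and divide
`max_possible` abundances. When both sides fall below `ratio_floor`
(default 1 normalized unit) the ratio is reported as 1 with an
`absent` flag; when only the denominator is below the floor it is
replaced by the floor and flagged `floored`. The same conventions apply
to read-length-class ratios (e.g. 20–21 nt vs 24 nt), which give the
overall size-class enrichment against which per-partition changes are
judged. Paralogs whose reads cannot be told apart can be quantified as
a named group whose expression counts each read once per group.

# PARE profiling

PARE tags are uncapped transcript 5' ends, so they map sense-strand
only, exact match over the tag's full length, minimum 18 nt. Abundances
are normalized to TP10M (`raw × 1e7 / total_reads`). The cleavage
between nucleotides `i−1` and `i` is recorded at 0-based position `i`
by summing the abundances of all tags whose 5' end maps there;
`max_possible` profiles count tags that also match close homologs in
every matching target. Profiles aggregate across samples by positionwise
summation, and the modal (most frequently cleaved) site per target is
reported with ties broken 5'-most. Mass is conserved exactly, and a
profile restricted to a sub-interval equals the whole-context profile
shifted by the offset.

# Alignment consensus and covariation

Columns with a gap fraction strictly above 75% are removed (a column at
exactly 75% is kept). A column's consensus residue requires 80% of the
non-gap entries; information content is `(2 − H) ×` (non-gap fraction)
bits, so an invariant gap-free column scores exactly 2.

Consensus base pairs are detected in one covariation-scored dynamic
program rather than by reproducing the four separate consensus tools of
the original workflow. For each column pair, support is the fraction of
gap-free rows forming a canonical pair (rows with a gap in either
column are excluded; a pair of columns is eligible only if at least
half the rows are gap-free). Candidates need support ≥ 0.75 and at
least 4 columns of separation (minimum loop 3). The selection score of
a candidate adds a covariation term — the expected Hamming distance
between the doublets of two random supporting rows, 0 for an invariant
pair and approaching 2 under full compensatory variation — and the
selected set is the maximum-total-score non-crossing subset by interval
DP, with a stacking bonus (default 1) for a pair directly enclosing
another selected pair. The covariation term and stacking bonus matter:
in a conserved family many columns are nearly invariant, and any two
invariant complementary columns reach high support by accident; real
helices distinguish themselves by compensatory variation and
contiguity. A selected pair with at least 2 distinct canonical types
among its supporting rows is classed `covarying`, else `consensus`.
The canonical structure line is emitted as Stockholm `#=GC SS_cons`.

# The partitioned substitution model

Unpaired columns follow GTR; paired columns follow the 16-state doublet
model in which exactly one position may change per event:
`rate(xy → x'y) = r(x, x') π₁₆(x'y)` and simultaneous two-position
changes have rate 0. Both matrices share the six exchangeabilities by
default (a flag-free design choice; the original configuration is
unstated), are reversible by construction, and are rescaled to unit
mean rate at stationarity — one unit of branch length is one expected
substitution per site, where a doublet column is one site. Rate
heterogeneity uses 4 discrete gamma categories with exact mean-of-bin
rates (the conditional bin means via the incomplete-gamma identity), so
the category rates average exactly 1 for every shape.

Likelihoods are computed by Felsenstein pruning per column (4-state)
and per column pair (16-state), averaged over categories, with gaps as
missing data and per-node rescaling against underflow. The pruning core
is compiled (C++/Armadillo) with transition probabilities from the
spectral decomposition of the symmetrized generator. Two analytic
limits anchor the implementation: at uniform base frequencies with
doublet frequencies equal to the outer product, the normalized doublet
chain is two independent GTR coordinates at half speed, so a doublet
column's likelihood at branch length *t* equals the sum of two
single-column likelihoods at *t*/2 (verified to 1e-8); and the pruning
likelihood equals exhaustive summation over internal states on 4-taxon
data (to 1e-10).

# MCMC, consensus trees and duplicate taxa

The sampler is Metropolis–Hastings over unrooted topologies
(nearest-neighbour interchange), branch lengths (multipliers,
exponential(10) prior), the gamma shape (multiplier, exponential(1)
prior) and the simplex parameters (Dirichlet proposals, flat priors);
move weights 0.45/0.35/0.08/0.04/0.04/0.04. Desk-scale defaults are
100,000 generations, two independently seeded runs, samples every 100
generations, 25% burn-in; the original analysis ran 20 million
generations — explicitly out of desk scope, and the configuration can
raise the limits. Convergence is always reported as the average
standard deviation of split frequencies between runs, never silently
ignored. A prior-only mode samples the topology prior, which on 4 taxa
must give each of the three splits frequency 1/3 — a sampler
correctness check. Dirichlet proposals whose smallest component falls
below 1e-5 are rejected outright as a numerical guard for the spectral
decomposition.

The majority-rule consensus contains exactly the splits above the 0.5
threshold (all mutually compatible), annotated with their sample
frequencies as percentage node labels. Identical alignment rows are
collapsed to one representative before inference and reinserted
afterwards as a clade of the original taxa with posterior probability
100 and branch lengths 0.001 exactly.

Rooting for reconciliation is the caller's responsibility (an outgroup
such as the moss clade); no automatic rooting is attempted. Each gene
node maps to the last common ancestor of its descendants' species; a
node is a duplication iff it maps to the same species node as one of
its children, and losses are counted along the compressed species
paths (`d` losses below a duplication, `d − 1` below a speciation at
species distance `d`). For the LCA map these counts are the parsimony
minimum, which the tests confirm against an independent complete search
over all ancestrally consistent placements.

# Synthetic data: what it emulates, and what it does not

The generators define the study conditions:

* `gen_hairpin()` builds precursors from the canonical geometry
  sp1(15), miR*(21), sp2(20), ACR5(21), loop(8), ACR3(21), sp4(20),
  miR(21), sp5(15) — D = 90 — with reverse-complement miR:miR* and
  ACR5:ACR3 duplexes, a 70%-paired connecting stem, and a lower stem
  continuing past the duplex so the miR's 3' overhang is paired within
  the hairpin (as in real precursors). Violation presets plant exactly
  one rule failure each; rule 1's preset (a miR straddling the loop)
  necessarily drags down the duplex-dependent rules 4, 5 and 7, since
  no miR* exists — the concordance oracle shares that convention.
* `gen_library()` draws multinomial read counts over the planted
  partition proportions at 21 ± 1 nt, placing each read to overlap its
  partition by ≥ 80% (leak reads straddle boundaries below the
  threshold) and adding 5% unmappable noise. Planted proportions are
  recovered within multinomial error — binomial 3σ per partition at
  depth 1e5.
* `gen_pare()` samples tag 5' ends from a planted site distribution at
  tag lengths 20–21.
* `evolve_alignment()` simulates substitutions only (the alignment is
  the frame, mirroring post-alignment analyses; no indels) with exact
  spectral transition probabilities; planted pairs form a nested helix
  separated by a ≥3-column terminal loop so every pair is structurally
  legal, and ancestral pair states are drawn from the canonical doublet
  states — the planted structure exists in the ancestor, which is what
  "planting" a consensus helix means. The simulation model for the
  recovery studies uses a mild transition bias (exchangeabilities
  1,4,1,1,4,1), doublet frequencies with 88% Watson–Crick and 8% wobble
  mass, and branch lengths scaled so alignments sit near 55–60% mean
  pairwise identity — the divergence regime of a deeply conserved RNA
  family that is still confidently alignable.
* `gen_family()` runs birth–death on the species tree (Poisson
  duplications, exponential loss probability per branch) with a full
  event log; reconciliation counts are a lower bound on the logged
  truth because events without surviving descendants are invisible.

None of the generators model sequencing error, adapter artifacts,
alignment error, or indel evolution, so green tests demonstrate the
correctness of the computations under the stated models — not
robustness of the pipeline to the technical noise of real libraries.

# Problem sizes and numerical choices

The validation studies run at: 1000 synthetic hairpins for rule
concordance; 50 libraries at depth 1e5 for quantification; 20 PARE
libraries at depth 5000; 20 alignments of 30 rows × 150 columns for
pair detection, with exhaustive-optimum checks on ≤ 20 columns; 200
random 4-taxon instances for the likelihood oracle; 20 seeds of the
6-taxon topology-recovery study at 2000 columns (100 doublet pairs +
1800 unpaired — consensus structures annotate only a minority of
columns as pairs) and 100,000 generations × 2 runs; and 200 random
instances for reconciliation. The fixed 6-taxon recovery tree has tip
branches 0.09–0.13 and internal branches 0.06–0.08 expected
substitutions per site.

Tie-breaking is deterministic throughout (documented per function);
degenerate inputs raise errors rather than guesses (empty sequences,
all-gap alignments, unpaired miRs, type-2 partitioning, zero library
totals). Floating-point tolerances: conservation identities hold to
1e-9; reversibility and unit mean rate to 1e-10; the pruning oracle to
1e-10; the factorization limit to 1e-8.

# Known limitations

The folder is a scoring heuristic, not a thermodynamic model; boundary
behaviour (isolated pairs, coaxial stacks) differs from free-energy
folders, which is why external structures are accepted everywhere. The
five-type classifier depends on caller-supplied ACR consensus
sequences and two conservation thresholds with no claim of matching any
particular curation by hand. The homolog scanner is exact rather than
heuristic and is not tuned for genome-scale throughput. The MCMC
implements single-chain Metropolis–Hastings (no Metropolis coupling)
and desk-scale run lengths; it is a faithful small-scale instrument,
not a replacement for long production runs. Reconciliation assumes a
correctly rooted, binary gene tree and uniform event costs.
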