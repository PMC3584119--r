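---
title: "Methods and design choices in mitosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in mitosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package automates

The processionary moths (*Thaumetopoea*) fall into three clades with
distinct life histories: Angiosperm feeders with fast spring development
(clade A), winter pine processionary moths (clade B), and summer
pine/cedar processionary moths (clade C).  Three mitogenome segments per
taxon (spanning *cox1*–*cox3*, *nad5*–*nad4*, and *cob*–control region)
plus three nuclear genes carry the phylogenetic information; beyond the
trees themselves, the mitochondrial tRNA loops and the intergenic spacers
(isps) between genes carry clade-diagnostic sequence signatures, and a set
of categorical life-history traits can be mapped onto the phylogeny to ask
which characters are ancestral, derived or convergent.

`mitosig` implements this workflow as seeded, testable code: a synthetic
generator that produces such data with known ground truth, a rule-based
annotator, alignment builders, a quartet likelihood-mapping signal
analysis, p-distance clade summaries, spacer/loop signature detection, and
unordered-parsimony trait mapping, orchestrated by `run_pipeline()`.

# The substitution model

All sequence evolution and all likelihood computation use a reversible
nucleotide model with discrete-gamma rate heterogeneity
(`subst_model()`).  The default is HKY with κ = 4 and AT-rich stationary
frequencies (A, C, G, T) = (0.40, 0.10, 0.10, 0.40), mimicking insect
mitochondrial composition; a full GTR parameterisation is available.  The
rate matrix is scaled to one expected substitution per site per unit
branch length.  Rate heterogeneity uses four equal-probability gamma
categories with the category means computed from the incomplete gamma
function (mean exactly 1); the default shape α = 0.4 gives the strong
heterogeneity typical of mitochondrial protein-coding data.  No proportion
of invariable sites is estimated: mixing I with Γ is redundant at this
data scale and can be statistically unstable.

# The synthetic generator defines the study conditions

`sim_config()` fixes the simulated system to the design of the real study:

* 10 ingroup taxa in clades of 3/3/4 plus 3 outgroups (13 taxa);
* branch lengths uniform on 0.01–0.04 substitutions/site, which yields
  ingroup pairwise p-distances of roughly 0.05–0.15 on protein-coding
  genes, the observed range for the genus;
* the lepidopteran gene order of the three segments, with *nad5*, *trnH*,
  *nad4*, *nad1*, *trnL1*, *rrnL*, *trnV* and *rrnS* on the minus strand;
* two truncated-stop genes (*cox2* ends in `T` before *trnK* on the plus
  strand; *nad4* ends in `TA` before *trnH* on the minus strand), so both
  truncation forms and both strands are exercised;
* the canonical 7-nt *atp8*/*atp6* overlap (`...CCA TGA TAA` overlapping
  `ATG ATA A...`); the seven shared bases are held fixed so the junction
  remains annotatable on every lineage;
* a ubiquitous spacer between *trnS2* and *nad1*, plus branch-addressed
  gain events: ingroup stem (*trnK*–*trnD*), clade B+C stem
  (*atp6*–*cox3*), the clade-A cherry (*cox1*–*trnL2*, the 2-nt `CT`
  spacer), and a lineage-specific spacer on the first outgroup;
* clade-specific tRNA loop replacements (TΨC of *trnD* on the clade C
  stem, DHU of *trnD* on the clade A stem, TΨC of *trnH* on one clade-B
  terminal), mirroring the loop motifs that distinguish real clades;
* three categorical traits with known ancestral assignments: a single
  host-plant shift on the B+C stem, a twice-gained morphological character,
  and a twice-derived foraging type.

Two deliberate departures from a neutral i.i.d. model make the generator
biologically faithful rather than convenient:

* **tRNA stems evolve slower than loops** (`stem_rate_scale = 0.1`).
  Pairing in cloverleaf stems is under strong purifying selection in real
  mitochondrial tRNAs of congeneric taxa; without this constraint the
  simulated stems accumulate mismatches far faster than any real
  within-genus alignment shows.  Anticodons are invariant.
* **Loop replacements are fixed below their event branch.**  The loop
  motifs act as clade signatures precisely because they are maintained;
  letting them drift would simulate a different biological claim.

Reading frames are preserved during evolution by codon repair: a
substitution that would create an internal stop, destroy the legitimate
start, or break the (possibly truncated) terminal stop is reverted on that
codon.  Indels occur only in rRNA and the AT-rich control region
(`indel_rate = 0.02` per site per substitution unit, lengths 1–4 nt), so
coding truth remains exactly recoverable.  The gained *atp6*–*cox3* spacer
uses a C-heavy sequence in which no single substitution can create a
legitimate in-frame start codon; AT-rich spacer sequences upstream of a
protein gene would otherwise mimic alternative 5' starts, which is a real
annotation hazard the default conditions should not be dominated by.

Root tRNA templates are additionally certified *in segment context*: a
drawn tRNA is accepted only when, embedded in its segment, its canonical
cloverleaf is the best-scoring fold and beats every alternative-span fold
by a clear score margin (>= 5), otherwise the tRNA is redrawn.  A
template whose optimal fold were a different geometry, or only barely the
intended one, would not be the structure it claims to be, and a couple of
substitutions on some lineage would make its boundaries intrinsically
ambiguous.  Junctions with truncated-stop genes are further constrained
(and held fixed) so that a `T`/`TA` remainder can never combine with the
neighbouring tRNA's first bases into a complete in-frame stop, which
would make the truncation unannotatable by construction.  A residual
(well under 1%) boundary ambiguity remains possible when mutations make
an off-by-one fold genuinely tie with the true one; the recovery
invariants are therefore stated as rates, not as exactness.

What the generator does **not** emulate: codon usage bias, selection on
amino acids, recombination, heteroplasmy, sequencing error, or
compensatory stem co-substitution.  Passing the recovery tests therefore
shows that the rules are implemented correctly and are robust at realistic
divergence — not that they would be error-free on arbitrary real genomes.

# Annotation rules and thresholds

Protein-coding 5' ends: first legitimate start codon (ATN, GTG, TTG, GTT)
in the search window not located within the upstream same-strand feature;
*atp6* may start up to 7 nt inside *atp8* (the canonical overlap).  A
candidate start is accepted only if its open reading frame reaches
`min_orf_frac` (default 0.5) of the template gene length — the analogue of
confirming gene identity against orthologous proteins, which suppresses
spurious short ORFs in wrong frames.  3' ends: first in-frame stop
(TAA/TAG under the invertebrate mitochondrial code); a stop falling at or
beyond the downstream same-strand feature yields a truncated `T`
(remainder 1) or `TA` (remainder 2) stop abutting that feature.
Minus-strand genes are processed on the reverse complement and mapped
back.  Coordinates are 0-based half-open internally and converted at I/O
(GFF3 is 1-based closed).

tRNAs: every occurrence of the expected anticodon in a window centred on
the template position (± 150 nt) seeds candidate cloverleaf folds over the
allowed geometries (acceptor 7 bp; D stem 3–4 bp; anticodon stem 5 bp;
T stem 4–5 bp; loops 3–11 nt, anticodon centred).  A fold's score is the
number of paired stem positions minus a penalty (default 1) per
mismatching position, with G·T counted as a pair; a fold is acceptable
when at least 80% of its pairable positions pair.  Ties prefer more paired
positions, then the geometry closest to the canonical cloverleaf.  The
search is made O(1) per fold by precomputing the pairing indicator matrix
and its anti-diagonal cumulative sums (a stem lies on one anti-diagonal);
anchors are prefiltered on the anticodon stem, with a weaker fallback
when a mutated stem defeats the fast filter.  Because a drifted fold can
occasionally outscore the true one, `annotate_genomes()` adds a
comparative curation pass — the in-silico analogue of checking a tRNA
against its orthologous counterparts: a fold whose geometry deviates from
the across-taxa modal geometry is re-folded under that geometry near its
original position; a *marginal* fold (under 90% of stem positions
paired) sitting away from the across-taxa median position is re-folded
pinned to that consensus interval with a relaxed threshold (confident
folds are trusted even when positionally deviant — genuine shifts such
as lineage-specific spacers move tRNAs); and a tRNA missing from one
taxon but found in most others is re-searched near the consensus
position with the modal geometry and a relaxed threshold.  Every
candidate correction is pre-validated by a direct constrained fold
search before the segment is re-annotated.

rRNA: *rrnL* is the interval between *trnL1* and *trnV*; the *rrnS* 3' end
abuts *trnV* and its 5' end is placed a configurable reference length
(default 780 nt) downstream.  A consequence of the tRNA-delimited rule is
that any spacer adjacent to an rRNA is absorbed into the rRNA interval;
the generator's default events avoid such loci.

Spacers: one record per adjacent feature pair, including zero-length
records (absence is data); a spacer is *present* when its length is at
least 1 nt.  Overlapping features other than *atp8*/*atp6* are a
structural error.

# Alignment choices

Codon-aware alignment translates each CDS (truncated stops first completed
to `TAA`; terminal stops then excluded so frames stay comparable), aligns
the proteins with MAFFT (`--auto`, deterministic), and back-translates so
every amino-acid column is one intact codon triple.  Internal stops reject
the sequence with a diagnostic rather than silently shifting frames.

Structure-guided RNA alignment runs MAFFT on the nucleotide sequences and
then applies a deterministic correction that operationalises manual
curation: a gap run lying in stem columns is relocated to the nearest
position entirely in non-stem columns whenever the realigned characters
agree with the (frozen) column majorities at least as well — loop columns
absorb length variation, stems stay intact.  Rows and runs are processed
left-to-right with fixed tie-breaking, so the result is reproducible.

`concatenate()` builds named supermatrices with one partition block per
gene and optional p1/p2/p3 codon sub-blocks; partition schemes are
validated to be disjoint covers and written in RAxML-style text.  Taxa
missing a block are dropped by default (as when a nuclear gene is
unavailable for some outgroups); gap-filling is explicit opt-in.

# Quartet likelihood mapping

For each quartet the three resolved topologies are fitted by maximising
the pruning likelihood over the five branch lengths (coordinate-wise Brent
search, relative tolerance 1e-6, at most 100 sweeps; site patterns are
compressed first).  Likelihoods become barycentric weights
$w_i = L_i / \sum_j L_j$.  The simplex is divided into seven regions with
boundaries at weight 1/3 in each pairwise competition: with sorted weights
$w_{(1)} \ge w_{(2)} \ge w_{(3)}$, the quartet is *fully resolved* when
$w_{(2)}/(w_{(1)}+w_{(2)}) < 1/3$ (the best topology at least doubles the
runner-up), *partly unresolved* when the runner-up competes but
$w_{(3)}/(w_{(2)}+w_{(3)}) < 1/3$, and *fully unresolved* otherwise; ties
on a boundary go to the less resolved region.  Under this geometry equal
likelihoods land in the centre (identical sequences give 100% QFU) and a
dominant topology in a corner, and the three percentages always sum
to 100.  Exhaustive enumeration is used up to 20,000 quartets, above which
a seeded uniform sample is drawn.  Because the original signal tables were
produced by an external program whose settings are not published,
per-alignment percentages are expected to reproduce approximately, not
exactly; the validated properties are the table structure, the simplex
closure, and the monotone growth of %QFR with alignment length.

# Distances and clade summaries

p-distances use pairwise deletion by default (any non-ACGT symbol excludes
the site for that pair), matching the convention of the distance software
used for such tables; complete deletion is available and equal in the
gap-free case.  Within-clade means average unordered ingroup pairs inside
a clade; among-clade means average all cross-clade pairs; outgroups are
excluded.  Values are reported at full precision and rounded half-up at
the third decimal (plain `round()` is banker's rounding and would turn
0.0795 into 0.079).  Because the "±" in published tables of this kind is
rarely defined, both the sample SD over pairs and a seeded bootstrap SE
(1,000 resamples over pairs) are reported.  Note that published among-clade
means recomputed from rounded printed cells can differ by 0.001 from the
printed means (which were presumably computed from unrounded distances);
the summaries here are exact functions of their input matrix.

# Parsimony mapping

`parsimony_reconstruct()` is Sankoff dynamic programming with unit costs
(equal to Fitch on binary trees), native over polytomies, with `?` as
missing data.  A down-pass computes subtree costs, an up-pass the
rest-of-tree costs; their sum gives, per node, the set of states attained
in *some* most-parsimonious reconstruction (the MPR union — the ambiguity
display of classical character-mapping software, avoiding an arbitrary
ACCTRAN/DELTRAN choice).  A branch is reported as a change only when *no*
MPR keeps the state constant across it; the from/to sets enumerate the
optimal assignments of that branch.  `count_origins()` counts such
branches whose destination is exactly one state, a lower bound on
independent origins; `map_all_traits()` flags traits where any state
arises at least twice (convergence).  Spacer presence/absence uses the
same engine with gain cost 1001 and loss cost 1000: the primary objective
is still the change count, and ties between equally parsimonious solutions
break towards fewer gains (independent identical gains of the same spacer
being the less plausible event).

The packaged trait matrix (`traits.tsv`) is an encoding of published
life-history descriptions of these species (host plant class, foliage
age, foraging type, tent, pupation site, overwintering stage, adult front,
tibia spine, egg-scale size, urticating setae); cells not established in
the literature are `?`.

# Signature detection

Orthologous spacers are grouped by locus; members of equal length are
compared columnwise directly, length-variable groups are aligned
progressively.  A group's shared motif is the strict IUPAC consensus of
its members when their mean pairwise identity reaches 0.6 (the published
"exclusive long motif" notion is qualitative; this makes it explicit).
A clade-diagnostic loop motif is the position-wise IUPAC union of the
clade members' loops, reported only if it has at most 2 degenerate
positions, matches every member, and matches no non-member — exclusivity
is checked by re-matching, so reported motifs cannot be false positives by
construction; loops of unequal length admit no consensus.

# Numerical and degenerate-input choices

* Brent branch-length optimisation on [1e-8, 5] substitutions/site,
  relative tolerance 1e-6, max 100 sweeps; a sweep is kept only when it
  improves the log-likelihood.
* Transition probabilities through the symmetrised eigendecomposition of
  the rate matrix; tiny negative entries are clipped and rows
  renormalised.
* Gaps/ambiguities in likelihoods are missing data (partial likelihood 1);
  `N` never counts as a stem pair and translates to `X`, never to a stop.
* A pair with zero comparable sites gets an `NA` distance with a warning;
  a singleton clade gets an `NA` within-mean with a message.
* Negative neighbor-joining branch lengths are clamped to zero.
* Zero-length spacers are retained; empty spacer sets give an empty group
  list; a tRNA without an acceptable fold is reported missing, not forced.

# Validation scale

The test suite validates: parsimony against exhaustive enumeration on 500
seeded random trees of 4–10 leaves and 2–4 states (plus 40 smaller cases
with missing data); pruning likelihoods against brute-force state
enumeration on 200 instances of 3–5 leaves and up to 10 columns across
HKY and GTR parameterisations, and against an independent likelihood
implementation on a 6-taxon alignment; quartet resolution growing to 100%
QFR across alignment lengths 100/1,000/10,000 with 20 replicates each; and
annotation/signature recovery on 20 seeded 13-taxon truth bundles
(boundary recovery, every truncated-stop case, all anticodons, all
injected spacer events, zero diagnostic-motif false positives).  These
sizes were chosen so the full suite runs on a laptop in minutes while the
enumeration oracles remain exact.

# Known limitations

* The real-sequence benchmark of the annotation-alignment-distance chain
  requires the archived accession sequences; offline, the chain is
  validated against the generator's truth instead.
* The *rrnS* 5' boundary is a configured reference length, not a homology
  model; full rRNA secondary-structure modelling is out of scope.
* Only the three study segments' gene order ships as a template; other
  mitogenome arrangements would need their own template tables.
* MAFFT is treated as a deterministic black box; its gap parameters are
  not re-exposed.
* The likelihood-mapping percentages of the original analysis are not
  bit-reproducible (unpublished settings of the original program); the
  package documents and validates its own, fully specified, geometry.
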