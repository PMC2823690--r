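---
title: "regenEST: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regenEST: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

regenEST re-implements, as tested reusable components, the analysis of a
classical non-normalized EST (expressed sequence tag) survey of a
regenerating tissue: single-pass 5' cDNA reads are cleaned, assembled
into contigs, annotated by homology against protein and nucleotide
databases, mapped onto the Gene Ontology, screened for functional
enrichment against an unbiased baseline corpus, linked to a comparator
species' deregulated gene set, and complemented by RT-PCR densitometry
statistics. The wet-lab stages (library construction, sequencing,
database searches themselves) are out of scope: the pipeline consumes
reads and hit tables and produces accounting tables, annotation sets and
statistics. A synthetic-data module generates all inputs with complete
ground truth so that every stage can be validated against a known
answer.

# Read cleanup

Cleanup follows a fixed stage order — quality filter, vector clipping,
polyA trimming, empty/short filtering — and keeps exact accounting: the
input count always equals low-quality + empty + short + kept. All
coordinates are 1-based inclusive positions on the raw read.

**Quality.** "Minor quality" traces are not defined quantitatively in
classical EST protocols; we use the simplest defensible criterion, mean
Phred score below 20 (configurable). Reads without quality strings are
kept.

**Vector clipping.** Each cloning-vector flank is located by exact
k-mer seeding followed by ungapped extension across the whole flank,
accepting a placement with at least 90% identity. The seed size default
is 12 nt: with a ~40 nt flank and a substitution error model, two
errors can destroy every 16-mer but almost never every 12-mer, and at
read scale (<1 kb) 12-mer false matches are negligible. The insert is
everything between the matched flank regions; an empty-vector clone
yields a zero-length interval with both flanks flagged.

**polyA trimming.** The tail rule is shared verbatim between read
trimming and contig polyA detection. It has two stages: (1) a maximal
terminal run of pure A of at least 10 nt is removed exactly — this
handles the error-free case without ever eating into the insert; (2)
otherwise, within the last 50 nt, the leftmost suffix of at least 10 nt
that is at least 90% adenine is removed (error-tolerant). The rule is
iterated to a fixed point, because a substitution inside a tail splits
it into fragments removable only one at a time; iteration is what makes
the whole cleanup idempotent. Because a transcript that itself ends in
adenines makes the insert/polyA boundary unidentifiable, the synthetic
truth table defines the boundary canonically as the start of the
maximal terminal A-run; trimming then recovers the truth exactly on
error-free reads.

Inserts shorter than 100 nt are discarded as short; the threshold is the
classical EST submission cutoff.

# Assembly

The assembler is a deterministic greedy overlap-layout-consensus
procedure intended for desk-scale EST sets, not a re-implementation of
any commercial assembler. Overlaps are ungapped (the dominant error
mode downstream of trace processing is substitution); candidate
placements come from an exact 16-mer index; a placement is accepted at
a minimum overlap of 40 nt and 95% identity, both configurable. Reads
are placed longest-first (ties by id) onto growing contigs, then whole
contigs are merged best-overlap-first (longest overlap, then highest
identity) until a fixed point. Reverse-complement placements are
allowed by default because cloning orientation is not guaranteed.

The consensus is the column-majority base over a per-contig base-count
matrix; ties are resolved by the fixed base order A < C < G < T, which
keeps the output deterministic without per-column history. Contig ids
are assigned after assembly by decreasing EST count, then consensus
length, then first member id, so two runs on the same input are
byte-identical.

Redundancy statistics (singleton fraction, two-member fraction, mean
ESTs per contig, contigs with more than 20 ESTs) are computed directly
from the membership table; the singleton fraction is singleton contigs
over all contigs. The mean ESTs per contig is reported as the exact
quotient of totals.

# Homology classes and best hits

Hit tables use the standard 12-column BLAST tabular layout plus three
sidecar columns (algorithm, subject description, taxon class); taxon
classes are an input column, not a live taxonomy lookup, so the package
has no external database dependency. Similarity classes follow the
printed inequalities: e < 1e-20 is significant, 1e-20 <= e <= 1e-05 is
weak, anything larger is none. Ranking is by ascending e-value with
ties broken by higher bitscore, then lexicographic subject id; the
global best hit of a query is its rank-1 hit across all algorithms
merged.

# Full-length calling and ORF scanning

A contig is called full length when its best protein alignment starts
early in the homolog and the consensus carries a polyA tail. The start
window is "before amino-acid position 10" (positions 1..9), which is
the reading under which the cumulative table is internally consistent;
the window is configurable. The cumulative table reports, per start
position, contig counts and polyA-bearing contig counts with running
totals.

Contigs without any hit at the weak cutoff are scanned in all six
frames for ATG-to-stop ORFs of at least 22 amino acids (length counted
without the stop). The scanner is a deterministic replacement for
HMM-based EST ORF finders: it covers the reported statistics (longest
ORF per contig, fraction of ORFs of at least 150 aa), not probabilistic
coding-region scoring. ORFs truncated by the contig end are flagged and
excluded from the long-ORF fraction by default. A no-hit contig with a
polyA tail and no qualifying ORF is the operational "3'UTR-like" case.

# GO annotation and true-path propagation

Protein identifiers are assigned from protein-database hits when the
e-value passes 1e-20 or a normalized significance score passes a sigma
threshold; identifiers are kept in hit-rank order, at most 50 per
query. The literature gives two sigma thresholds (15 and 8) and no
formula, so the score is pluggable: the default is a z-like heuristic,
(bitscore − log2(qlen × slen)) / 4, and the threshold defaults to the
stricter 15. The e-value gate is primary; the score only rescues
strong alignments with mediocre e-values.

Annotations propagate along is_a edges only (part_of and regulates are
not modelled), implementing the true-path rule: a protein annotated to
a term is implicitly annotated to every ancestor up to its namespace
root. Counts are of distinct proteins, which makes the enrichment
ratios well defined when several contigs share an identifier. The
propagation is validated in the test suite against a brute-force
"union over descendants" oracle on DAGs of up to 200 terms.

# Enrichment

Fold accumulation of a term is (k_ds/N_ds)/(k_base/N_base): k counts
distinct proteins under the term, N counts proteins under the
biological_process root (other namespaces use their own root on
request). Significance is the plain Pearson chi-square on the 2x2
table (in-term vs not-in-term) x (dataset vs baseline), df = 1, no
continuity correction — the continuity-corrected variant is
deliberately not used, and the choice is backed by a type-I-error
simulation that shows the plain statistic calibrated at the 5% level
at the study's problem sizes. Degenerate margins yield a
not-computable flag rather than an error. No multiple-testing
correction is applied by default (per-term p-values are the primary
output); Bonferroni/BH columns are available as an option.

The enrichment screen combines a fold threshold (default 10) with
per-dataset minimum protein counts (defaults 8 and 3 for the primary
and comparator datasets). Note a statistical subtlety the tests
respect: when the true fold equals the threshold exactly, the
fold-threshold flag fires in only about half of replicates by sampling
symmetry; detection power is therefore assessed on the chi-square
p-value together with the count screen.

# Cross-species mapping

Two routes link the dataset to a comparator species' deregulated
sequences: direct nucleotide hits below 1e-05 (deduplicated per pair,
best e-value kept as evidence) and shared protein identifiers (exact
identifier equality; no orthology inference). Pairs already covered by
direct hits can be excluded from the identifier route, matching the
reading that the two published routes were disjoint. Union coverage is
counted over distinct comparator proteins with identifiers — the
published denominator — not over probes.

# Expression statistics

Densitometry intensities are normalized to a non-modulated control
gene within the same timepoint and pool, and folds are means over
pools relative to day 0. The paired t-test pairs by pool index — the
only pairing structure the design provides — and is two-sided, since
both up- and down-regulation are reported. The two-fold flag is
symmetric on the ratio scale (fold >= 2 or <= 0.5). Degenerate pairs
(zero-variance differences) give p = 1 when the difference is zero.
Whether the original analysis normalized to the control before fold
computation is not documented; we normalize, and the alternative is a
one-line change (skip the control division).

# The synthetic-data module

The generators emulate the statistical structure of the study's
deposited data: reads of median 500-700 nt built as 5' vector flank +
insert + polyA + 3' flank; inserts are 3'-anchored transcript
fragments, as oligo-dT-primed cDNA produces; a Zipf-like abundance law
(exponent default 1.2) reproduces the few-huge-contigs,
mostly-singletons shape of a non-normalized library; configurable
fractions of empty-vector, short-insert (<100 nt) and low-quality
clones; a substitution-only error model (indels are excluded by design
so that clipping and overlap logic stay exactly testable); a two-level
quality model (Q40/Q10), since trace-quality criteria were never
published. Hit tables are simulated from the truth mapping rather than
computed by an aligner — the best hit of a contig is its source
transcript's planted protein — because database search itself is out
of scope. The GO world is a random layered is_a DAG with the three
namespaces, and enrichment scenarios plant a requested fold by
importance-sampling baseline annotation profiles, so the expected fold
of a planted term equals the request and non-planted terms stay near 1.

What the generators do not emulate — chromatograms, chimeric clones,
indel errors, database-version effects, real GO topology — bounds what
passing tests show: they validate the algorithms and their statistics,
not the historical dataset-scale numbers, which depend on 2008-era
database snapshots and are explicitly not reproduction targets.

All generators are pure functions of (spec, seed): one global seed
fans out to per-stage child seeds by fixed offsets, and two runs with
the same configuration are byte-identical end to end.

# Problem sizes and numerical choices

The validation suite uses desk-scale simulations chosen to make every
statistical check well-powered: clone libraries of 150-2000 reads for
cleanup accounting; a 50-transcript, ~330-read library (about 5x
coverage, 0.5% error) for assembly recovery; GO worlds of 120-200
terms and 400 baseline proteins; 100-replicate power runs at 600
dataset proteins and 1000-replicate null calibrations for the
chi-square and paired t-test; densitometry with 3 pools x 5
timepoints. The relational store round-trips a complete pipeline run.
Tolerances: exact equality for integer accounting and identifiers;
1e-10..1e-12 relative for closed-form statistics; calibration bands of
0.05 +/- 0.02 for type-I error and >= 90-95% for planted-effect power.

# Known limitations

- The assembler is ungapped and greedy; it is adequate for
  substitution-error EST data but will fragment around true indels.
- The consensus is unweighted by quality.
- GO propagation ignores part_of/regulates, as the enrichment
  definition requires only parental is_a propagation.
- The relational store is file-backed TSV with integrity checks, not a
  server database; it targets reproducibility and inspection, not
  concurrent access.
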