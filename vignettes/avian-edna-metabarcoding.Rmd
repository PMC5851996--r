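---
title: "Methods: universal-primer evaluation and avian eDNA metabarcoding with aviDNA"
author: "aviDNA authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Environmental DNA (eDNA) metabarcoding detects species from genetic
material suspended in water: a universal primer pair amplifies a short,
taxonomically informative marker from mixed-template DNA, the amplicons
are sequenced in bulk, and reads are assigned back to species by
similarity search against a reference panel. For birds, the marker is a
hypervariable insert of roughly 171 bp in the mitochondrial 12S rRNA
gene, flanked by conserved regions in which the MiBird-U primer pair
anneals. aviDNA implements the computational side of such a survey:

1. **primer evaluation** — how well a primer core matches a panel of
   reference binding sites, position by position;
2. **in-silico PCR** — extracting the insert every reference would yield,
   and quantifying how distinguishable the inserts are;
3. **read processing** — from raw paired FASTQ to dereplicated,
   count-weighted representative sequences;
4. **taxonomic assignment** — species calls with reliability and ratio
   scores from similarity-search hits;
5. **survey summary** — per-sample detection tables, percent-target
   arithmetic and negative-control screening;
6. **simulation** — a seeded generator of reference panels and surveys
   with known truth, against which every other module is validated.

# Primer-template model

## Wobble pairing and the strand convention

The primer cores avoid degenerate bases. Instead they exploit the
non-Watson-Crick but thermodynamically stable G:T pair: where the
template varies, the primer uses G rather than A (tolerating template C
*or* T) and T rather than C (tolerating template A *or* G). With wobble
pairing accepted, a primer G opposite a template T, or a primer T
opposite a template G, is scored `wobble_match` rather than `mismatch`.

All comparisons are performed in *primer orientation*: the site string is
written in the reading where a perfectly matched site is identical to the
core (the sense strand for a forward primer, the reverse complement of
the sense segment for a reverse primer; `siteFromReference()` converts).
In these coordinates the wobble rule becomes: primer G matches site A,
primer T matches site C. This is exactly the template-level G:T rule —
the site base A corresponds to a template T, the site base C to a
template G.

IUPAC ambiguity codes in references are treated leniently by default: a
code counts as a match when the primer base (or, with wobble on, its
wobble partner) lies in the code's base set, and N matches everything.
This avoids inflating mismatch counts on low-quality references;
`ambig = "strict"` treats any non-ACGT base as a mismatch.

The 3'-terminal mismatch flag inspects exactly the last base by default
(`terminalWindow = 1`), because annealing failure at the extension end is
the classical kill criterion; the window is configurable since no
standard width exists.

## Mismatch histograms and base profiles

`mismatchHistogram()` bins per-site mismatch counts at 0, 1, 2, 3, 4 and
>=5 — the conventional summary of universal-primer coverage. Panel
members in which no binding site can be located are reported *separately*
by default rather than silently folded into the >=5 bin; whether such
species should count against the primer is a judgement call, so
`unlocated = "ge5"` provides the other behaviour explicitly.
`positionalBaseProfile()` produces the per-position A/C/G/T counts and
primer-match counts used to judge conservation of each primer position.

## GC content and melting temperature

Design practice keeps primer GC content between 40 and 60% with nearly
identical melting temperatures across the pair. `meltingTemperature()`
implements the nearest-neighbour duplex model with the unified 1998
parameter set (SantaLucia), an entropic salt correction of
`0.368 (L-1) ln[Na+]` cal/(mol K), and
`Tm = dH / (dS + R ln(Ct/4)) - 273.15` for a non-self-complementary
oligo. Defaults are 50 mM monovalent salt and 0.5 uM total oligo — a
standard PCR-like condition — and the whole parameter bundle is
injectable through `thermoParams()`. Published Tm calculators differ in
parameter tables and salt corrections, so numeric agreement with any
particular external tool is not asserted; the tests instead verify the
model against an independent reimplementation, duplex symmetry
(`Tm(s) == Tm(revcomp(s))`) and GC-stability monotonicity.

# In-silico PCR and taxonomic resolution

`locatePrimerSite()` scans every window of the appropriate strand
exhaustively (primer cores are <= 30 nt and references desk-scale, so the
O(L k) scan is cheap and has no heuristic failure modes). Windows are
substitution-only: a binding site disrupted by an indel is reported
*absent* rather than approximately located, which mirrors the exclusion
of deletion-bearing references from in-silico evaluation. The
best-scoring window wins, ties going to the leftmost on the scanned
strand.

`extractInserts()` excises the sequence strictly *between* the two primer
regions — the ~171 bp insert, primers excluded — and records the reason
for every exclusion (`fwd_site_absent`, `rev_site_absent`,
`inverted_sites`) so that "n of N extracted" is an auditable count, never
a silent drop.

Resolution is quantified with the Levenshtein edit distance
(`editDistance()`, backed by `utils::adist`): pairwise distances between
inserts are binned at 0..4 and >=5 for all species pairs, and separately
at genus level. The genus-level statistic is stated as "pairs of species
belonging to different genera", and that literal definition is the
default (`genusMode = "different-genus"`). On realistic panels that
definition produces nearly as many pairs as the species-level one, which
is hard to reconcile with published genus-level row totals; since the
intended statistic cannot be pinned down, two alternatives are offered
without any fidelity claim: `"within-genus"` (congeneric pairs — the
pairs a barcode is most likely to confuse) and `"genus-pair-min"` (the
minimum distance per genus pair). Duplicate species within a panel are
collapsed to their first record with a warning before pairwise analysis.

# Read processing

Stage order and defaults follow the standard amplicon pipeline: quality
tail trimming at Phred 10, pair merging with a minimum 10 bp overlap,
ambiguity/length filtering, primer removal with at most three
substitutions per primer, and two-tier dereplication (>=10 identical
reads to found a representative; 99% identity to rescue the rest). All
thresholds live in `processingParams()`.

Choices where the upstream tools' exact behaviour is unspecified:

* **Trimming rule.** `qualityTrim()` keeps the longest contiguous
  segment in which every base is at or above the cutoff, ties leftmost —
  deterministic and easy to verify against exhaustive enumeration. A
  `method = "first"` alternative cuts at the first below-cutoff base.
* **Merge offset selection.** Candidate overlaps run from `minOverlap`
  up to the shorter read; among them the smallest mismatch fraction wins,
  ties to the longest overlap, and the merge succeeds when that fraction
  is at most 0.25 (the classical merger's default ceiling). Offsets
  *below* the minimum are never candidates: a random 1–3 nt "perfect"
  overlap would otherwise outscore any genuine overlap containing a
  single sequencing error and veto the merge. At disagreeing overlap
  positions the higher-quality base is taken and the per-position maximum
  quality retained (the forward base wins quality ties).
* **Length window.** "Unusual length" is undefined upstream; the default
  window is the expected full amplicon length (primer cores plus the
  expected 171 bp insert) ± 20%, and an explicit window can be supplied.
* **Rescue identity.** Identity between an under-represented sequence
  and a representative is `1 - d/max(len)` with `d` the edit distance —
  consistent with "one or two nucleotide differences" on a ~171 bp
  insert being ~99%. A substitution-only Hamming mode is available for
  strictly equal-length variants. Under-represented sequences that no
  representative rescues are discarded from downstream analysis but
  counted, so every stage conserves the read budget
  (`input = kept + removed`, by reason).
* **Random-base spacers.** Library construction inserts six random bases
  between adapter and primer; standard demultiplexing removes them, so
  the anchored primer match allows 0 leading bases by default
  (`leadingRandom` raises it, e.g. to 6).

Dereplication is order-invariant by construction: exact duplicates are
tabulated first, representatives are ranked by count then sequence, and
rescue ties break to the higher-count representative, then
lexicographically.

# Taxonomic assignment

Hits arrive either from a standard 12-column tabular file
(`parseHitTable()`) or from the built-in Smith–Waterman aligner
(`alignLocal()`, both strands, match +2 / mismatch −3, affine gaps
5 + 2k). E-values for the built-in aligner use Karlin–Altschul
statistics with lambda solved numerically for the configured scores and
K = 0.621; E-values in externally supplied tables are taken as-is.

Per query, records are collapsed to the best hit per species (bit score,
then reliability score, then accession — deterministic throughout), and
the top species is accepted when its best hit has >= 97% identity and
E-value <= 1e-5. The **reliability score** is `L/(m+1)`: alignment
length over one plus the mismatch count, the added one avoiding a zero
divisor (a 150 bp alignment with one mismatch scores 150/(1+1) = 75).
The **ratio score** divides the top species' reliability by that of the
best hit to any *other* species ("second-highest species", not the
second record overall — multiple records of the winning species do not
masquerade as a runner-up). The ratio is reported as a separation
indicator and imposes no threshold by default; `assignParams(minRatio=)`
makes it a veto. Different species tied on both bit score and
reliability at the top give status `ambiguous` with the candidates
listed — an explicit extension, since upstream behaviour for exact ties
is unstated.

# Survey summary

`detectionTable()` accumulates assigned unit read counts into a
sample-by-species matrix; unassigned and ambiguous reads go to a
per-sample unassigned pool. Every assigned-but-unexpected species keeps
its own column *and* counts against the percent-target denominator:
`percent_target = 100 * (reads of expected species) / (total reads of
the sample)`, with totals being assigned plus unassigned reads —
matching the printed-table convention where per-row totals are the reads
that reached assignment, not the raw read counts discarded earlier in
the pipeline. Percentages are reported to one decimal; raw fractions are
kept alongside. `controlCheck()` lists any species detected in a
negative control; an empty report is a pass.

# The simulator

`simulatePanel()` builds mitogenome-like references —
`pad + forward site + insert + revcomp(reverse site) + pad` — with three
planted features driving the validation suite: per-species primer-site
substitution counts (wobble-compatible or not), optional whole-site
deletions, and a minimum pairwise insert distance (default 6 edits, the
resolution criterion). The truth sidecar records the realised site plan
and the full pairwise distance matrix, recomputed from the emitted
inserts so truth and data cannot drift apart. `simulateSurvey()` draws
150 bp paired reads from the two ends of each species' amplicon
(amplicons carry clean primer sequence, as real PCR products do), with
seeded per-base substitution errors, a flat Q35 body and a Q2 10-nt
tail (below the Q10 trimming cutoff, so tail trimming has something to
do). Negative controls receive zero biological reads. Abundances are
realised exactly by default, which makes end-to-end read-count
assertions exact; a multinomial mode sits behind the same seed.

What the simulator deliberately does *not* model: PCR amplification
bias, chimeras, indel sequencing errors (substitution-only by default so
identity arithmetic is exact), eDNA shedding/degradation, or
cross-sample index bleed. Passing the end-to-end suites therefore
demonstrates the pipeline's correctness on its own terms — conservation,
recovery of planted truth, clean controls — not field performance on
real water samples, where reference-database gaps and shared haplotypes
dominate the error budget.

All simulator randomness flows through R's RNG from the single integer
seed in `simulationConfig()`; identical configurations give
byte-identical FASTA/FASTQ output.

# Validation problem sizes

The shipped suites exercise, among others: a 410-reference panel with
three planted forward-site deletions (407 extracts; and
`choose(407, 2) = 82,621` inter-species pairs over the extracted
inserts); mismatch-histogram recovery of planted site plans on 60–100
species panels; oracle equivalence for edit distance (200 random pairs
against a DP reimplementation), trimming, merging and dereplication; and
a 13-cage zoo-like survey (12 single-resident cages, one five-species
walk-through cage at 100 reads per resident unit, three field negative
controls) processed end to end with error-free reads, recovering every
per-sample species set and read count with clean controls. These sizes
were chosen as the smallest instances that still exercise every rule
branch of the corresponding module.

# Known limitations

* Site location is substitution-only; a primer site split by a genuine
  insertion is reported absent rather than gapped-aligned.
* The built-in aligner is quadratic-time and intended for desk-scale
  panels (hundreds of references), not database-scale search; its
  E-values use ungapped Karlin–Altschul parameters as an approximation.
* Tm values depend on the chosen nearest-neighbour table and salt
  correction; comparisons across calculators require matching both.
* The genus-level distance statistic is ambiguous in its classical
  presentation; all three implemented readings are documented above and
  none is claimed to reproduce any particular published genus-row total.
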