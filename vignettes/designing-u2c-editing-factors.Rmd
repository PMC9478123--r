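---
title: "Designing and evaluating synthetic PPR DYW:KP U-to-C editing factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating synthetic PPR DYW:KP U-to-C editing factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprkp)
```

# Scope and model

pprkp implements the computational workflow around synthetic PLS-class PPR
proteins carrying a DYW:KP deaminase domain — programmable U-to-C RNA editing
factors. The package's units are:

* a **motif catalog** model: a protein is an ordered array of typed repeats
  (P1, L1, S1, P2, L2, S2, E1, E2, rarely SS), optionally followed by a DYW
  domain;
* a **recognition model**: the 13 motifs (P1L1S1)×3–P2L2S2–E1 each bind one
  nucleotide; motif *k* (1-based) binds target position *k* − 16, so the array
  covers −15..−3 and the edited base sits at position 0, three nucleotides
  downstream of E1. E2 and DYW are not part of the recognition model; whether
  E2 contributes to recognition is deliberately left unmodelled.
* a **code table**: `(motif type, residue pair) → (wA, wC, wG, wU)` with the
  residue pair read at motif position 5 and the motif's last residue. This
  "5 and last" convention is a package parameter (`pos5`), since annotation
  pipelines differ in how they index the pair.

All positions are integers relative to the edited base (negative upstream);
RNA is handled internally as {A, C, G, U} with DNA transcribed on read.

# Motif catalog

`classify_triplets()` labels each exact P1-L1-S1 run: *N-term* when it is the
protein's first motif triplet and the protein starts with P1; *Central* when
at least three motifs precede it and another P1L1S1 immediately follows;
*C-term* when a P2L2S2 triplet immediately follows. The labels are
**non-exclusive** sets: a short protein can satisfy two predicates at once,
and nothing in the selection logic requires exclusivity, so we do not impose
it. Labels depend only on types and positions, never on sequence content.

`detect_deaminase_signature()` finds the deaminase active-site signature
HxE(x)<sub>n</sub>CxxC: an H, E two residues later, then a downstream CxxC.
The spacer length *n* is not tightly specified by the domain family, so the
H-to-first-C span is bounded by a configurable `max_span` (default 80
residues) — wide enough to span the catalytic core of a ~130-residue domain,
tight enough not to bridge two domains. The leftmost match wins (smallest H,
then smallest first C).

`filter_dyw_domains()` retains a domain iff the signature is present, at most
34 unannotated residues precede the domain, and the domain is at least 116
residues long (115 aa or shorter is removed). The upstream gap is taken from
the annotation table, not recomputed: profile-HMM motif discovery is upstream
of this package. Rejection reasons are reported as the first failed rule in
the fixed order signature → upstream → length, which makes rejection reports
deterministic when several rules fail at once.

# Consensus design

`consensus()` implements a plurality-0 consensus: every column emits its most
frequent residue regardless of absolute count. Two numerical choices are ours,
because plurality consensus alone does not fix them:

* **ties** break towards the lexicographically smallest residue, and the
  column is flagged (`tie`); determinism matters more than any particular
  choice here;
* **gaps** are counted but can never win a column: motifs are length-selected
  before consensus, so a gap-majority column indicates an upstream problem and
  is flagged (`gap_majority`) while the most frequent non-gap residue is
  emitted.

`assemble_designer()` validates the (P1L1S1)×3–P2L2S2–E1E2–DYW order, applies
the length policy (35/35/31 for P1/L1/S1; C-terminal motif and domain lengths
are free — designer DYW:KP domains of 133 and 136 residues are both real
cases) and keeps a residue-level boundary map. The deaminase-signature
positions are located once, at assembly, and **frozen** on the object:
`apply_catalytic_mutant()` edits those stored coordinates, which keeps the
HAA, AxxA and HSE mutants idempotent even though a mutated active site no
longer matches the signature pattern. HSE replaces the residue between the
signature H and E with serine and warns when that residue is not the expected
alanine.

# Retargeting and binding prediction

`retarget()` reprograms the ten canonical-code motifs (three P1, three L1,
three S1, P2): for each, it selects the code entry of that type whose weight
vector is maximised at the site's base at the motif's position — requiring
that the needed base attains the entry's row maximum — and writes the entry's
residue pair into the motif. Among equally good entries the first in table
order wins (deterministic). The L2, S2 and E1 motifs follow a non-canonical
code that is not reliably known; their pairs are **configuration**, supplied
verbatim via `overrides` (e.g. residues taken from a donor editing factor),
never computed. A missing override is an error, not a default.

`predict_binding()` returns per-position weight vectors; unknown pairs yield
the uniform vector and a flag rather than an error, so partially characterised
proteins can still be scanned. `mismatch_count()` compares a 13-nt window to
the model's argmax bases, counting a position as a match when the window base
is among the tied maxima.

The shipped `default_code_table()` seeds the classic P/S-family preferences
(TD → G, TN → A, ND → U, NS → C and relatives) for P1/L1/S1/P2 only, and is
labelled literature-derived: it is an editable starting point. Every test that
needs exact inversion uses synthetic bijective tables instead, so no test
outcome depends on the literature weights.

# Off-target scanning and neighbour preference

`scan_transcripts()` slides the 13-nt binding window over the sense strand of
each transcript (targets are mRNA; no reverse-complement scanning) and reports
windows within `max_mm` mismatches whose base at site position 0 equals
`require_edit_base` (default U, configurable — whether C-rooted windows should
also be scanned is left to the caller). The comparison is a mismatch count
against the model's preferred bases, not a PWM score: the off-target analyses
this supports are defined by mismatch thresholds such as "fewer than four
mismatches". Windows never span record boundaries, and results are returned in
canonical (transcript, offset) order so the scan is invariant to input order.

`build_logo()` computes the empirical position frequency matrix of aligned
site contexts; the default window is −16..+5 around the edited base, a
parameter because logo spans are a display choice. Frequencies are the
contract; information-content scaling is display-only and out of scope.

`neighbor_preference()` reproduces the usual mutate-one-position experiment
summary: per position, a one-way ANOVA of editing efficiency across the four
nucleotide groups, Tukey HSD pairwise comparisons at α = 0.05, and a compact
letter display (groups share a letter iff their adjusted p ≥ α). The CLD uses
the insert-and-absorb algorithm with deterministic group ordering, so letters
are reproducible. When the within-group variance is numerically zero the
pairwise p degenerates to 0/1 on mean equality, which keeps the
all-values-identical case well-defined. Groups with fewer than two replicates
are excluded with a warning. ANOVA and Tukey come from `stats::aov()` /
`stats::TukeyHSD()`; only the letter assignment is implemented here.

# Chromatogram quantification

The quantifier operates at peak-area level: a trace is, per called position,
the base call and the four channel areas (the TSV dialect written by the
simulator and by base-caller exports; binary AB1 parsing is not implemented —
convert to the dialect upstream). The U-to-C editing ratio is
%C/(%C + %T) of percent areas at the site, and symmetrically %T/(%C + %T) for
C-to-U.

Channels that are not significantly above background are zeroed before the
ratio. The noise test is empirical: for each channel, the background is that
channel's percent areas over the flanking window (default 10 positions each
side) restricted to positions where the channel is not the called base,
trimmed of its largest 5 %; the channel is zeroed when
`mean(background >= observed) >= 0.01`. The 0.01 cutoff is the standard
chromatogram-noise cutoff; the flank width and trimming fraction are our
defaults, configurable and recorded per run, because published descriptions of
the procedure state the cutoff but not the window. Zeroing does **not**
renormalise the surviving percents — "the percent area was 0" semantics.
Channels with fewer than 5 per-channel background values fall back to the
pooled non-call background, which keeps degenerate traces (all channels equal)
well-defined: everything is zeroed and the ratio is flagged undefined rather
than invented.

`locate_edit_position()` anchors the site in the read with a ≥15-nt exact
anchor search (one base-call error tolerated when no exact match exists;
multiple matches are an ambiguity error). `summarize_replicates()` reports the
arithmetic mean and n−1 standard deviation, preserving replicate values; a
single replicate reports sd 0 with a flag rather than NA so downstream tables
stay numeric.

# Editing-site calling

`call_editing_sites()` applies, in order: mean base quality ≥ 20 at load;
candidate gating (coverage strictly above 10, dominant non-reference base
forming one of the transition classes AG/TC/CT/GA with the reference on the
reported strand, frequency ≥ 0.05, frequency < 1 — an all-variant site is a
homozygous SNP-like change, not editing); a two-sided Fisher exact test of
treated vs control variant/reference counts; Benjamini–Hochberg correction
with significance at q < 0.05; and removal of control-significant and known
SNP positions with recorded reasons.

Two readings of the read-count gate circulate ("coverage above 10" vs "at
least 10 variant reads"); both are implemented (`count_mode = "coverage"`,
the default, or `"variant"`) and the choice is recorded in provenance. Strand
is taken from the pileup rows; the caller does not re-infer it, and read-level
filters (duplicates, trimming, positional filters) belong to pileup
construction upstream of the package's TSV contract.

The Fisher p-value is computed exactly from the hypergeometric distribution
over the table support (the same two-sided definition and tie buffer as
`stats::fisher.test()`), vectorised by grouping tables with equal margins so
that genome-scale candidate lists are cheap; it is verified in the tests
against both `stats::fisher.test()` and an independent binomial-coefficient
enumeration. Note the test is two-sided, so variant depletion can also reach
small p; depleted sites never pass the candidate frequency gate, so this does
not affect calling.

# The synthetic-data generators

The generators define the package's reference study conditions; they are
first-class, tested code, and every stage's recovery properties are stated
against them.

* `gen_motif_library()`: per-type column distributions put probability 0.6 on
  a randomly drawn plurality residue and spread the rest uniformly; n = 200
  proteins. At these settings the per-column winner is recovered with
  overwhelming margin, which is exactly what the consensus-recovery check
  asserts.
* `gen_transcriptome()`: uniform random RNA with planted copies of a 16-nt
  reference site (positions −15..0) altered at exactly the requested number of
  window positions; the edited base is never mutated. When sites are planted,
  the background is scrubbed of incidental near-matches (within 4 mismatches,
  carrying the edit base) by deterministic resampling, so the manifest is the
  complete hit set at the scan thresholds; the no-plant mode leaves the
  background as drawn and is checked against a brute-force oracle instead.
* `gen_trace()`: peak-area-level traces — the quantification consumes percent
  areas, so simulating areas is sufficient and directly testable, and raw
  electropherogram curves are out of scope. The called channel carries the
  signal, dark channels a 1 % baseline, and the edit position splits the C+T
  signal by the planted fraction. Channel noise is **multiplicative**
  log-normal (`exp(N(0, sd))`, default sd 0.05): peak-area fluctuations scale
  with the signal, and under this model the recovered ratio is unbiased with
  a per-trace sd of roughly `f(1-f)·√2·sd` (~0.015 at f = 0.3), so the
  50-seed mean recovers the planted fraction to well within ±0.02.
* `gen_pileups()`: planted positions draw edited reads from a binomial at the
  planned frequency; every read then passes a uniform per-base error channel
  (default 0.001, spread over the three non-template bases) — the simplest
  null consistent with a treated-vs-control Fisher design. Controls and
  background positions carry errors only. Planned frequencies must be below
  1: frequency 1 is the SNP regime the caller is required to exclude.

Each generator re-seeds from the spec's single integer seed at entry, so every
generator is independently bit-reproducible from one `sim_spec`.

What the simulations do **not** emulate: alignment and base-calling artefacts,
strand-biased or position-dependent error, overdispersed coverage, linked
errors within reads, mixed isoforms, and chromatogram dye blobs or mobility
shifts. Passing the recovery checks therefore demonstrates the correctness of
the statistics and bookkeeping under the stated models, not robustness to
every artefact of real data.

# Sensitivity, as tested

One definitional choice deserves emphasis. A site planted *at* the 5 %
frequency threshold yields an empirical binomial frequency below 5 % in about
half of simulations (coverage 1000), so no caller can recover every *planted*
site while honouring the frequency gate. The caller's sensitivity property is
therefore stated over **gated** planted sites — planted sites whose observed
counts pass the coverage/class/frequency gates must all be called at q < 0.05
— and that property holds exactly at the reference conditions (coverage 1000,
error 0.001, planted frequencies 0.05/0.1/0.3, 20 seeds), with false calls at
unplanted positions bounded by the Benjamini–Hochberg expectation (in
practice: zero, since error-rate background cannot reach the 5 % gate at
coverage 1000).

# Problem sizes and determinism

The shipped checks use 20 seeds × 200 proteins for consensus recovery, 100
random targets for the code round trip, 100 random 150-nt transcripts ×
mismatch thresholds 0..4 for the scanner oracle, all 2×2 tables with margins
≤ 50 (≈1.76 million tables) for the Fisher enumeration, 50 seeds for trace
recovery and 20 seeds × 203 pileup positions for the caller — sizes chosen so
the full property suite runs in well under a minute on one core while leaving
the statistical margins wide. All randomness flows through explicit seeds;
re-running any check with the same seed is bit-identical.

# Known limitations

* The PPR code is consumed, not learned; contributions of residues 2, 9 and
  13, and of L-motif context, are not modelled.
* L2/S2/E1 retargeting requires donor-derived residue pairs; the package never
  guesses them.
* Off-target scanning is transcript-space and sense-strand only; spliced
  genome-coordinate scanning is out of scope.
* AB1 traces must be exported to the TSV peak-area dialect upstream.
* The caller consumes pileups; alignment, duplicate marking and splice-aware
  pileup construction are upstream contracts.
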