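---
title: "Methods: from protein boundaries to primers, constructs and plasmid maps"
author: "ConstructDesigner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from protein boundaries to primers, constructs and plasmid maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConstructDesigner)
```

This vignette explains the models and procedures behind the package, the
parameters that matter, and the design choices made where several
reasonable options existed.

## Coordinate model

All user-visible coordinates are 1-based and inclusive: residue *i* of a
protein corresponds to bases 3*i*−2..3*i* of its coding sequence, ORF and
feature spans are printed as `start..end`, and a construct from start *s*
to stop *t* contains both boundary residues. Internally no half-open
representation leaks to any interface. `residueToCodonSpan()` is the single
source of this arithmetic.

Sequences travel as plain character strings validated by
`validateSequence()` against one of three alphabets. Strict DNA (A/C/G/T)
is required everywhere a sequence is annealed to or translated; IUPAC
degenerate codes are legal **only** in primer overhangs, which never anneal
to the template; proteins use the 20 one-letter codes with no internal stop
symbol.

## ORF scanning and isoform matching

`findOrfs()` scans all six frames (both strands by default). An ORF runs
from the first start codon after the previous in-frame stop to the next
in-frame stop; the stop codon is excluded from the stored coding sequence,
so translation length is exactly length/3. The start-codon set defaults to
the common bacterial set {ATG, GTG, TTG} and the minimum reported length to
50 codons — both chosen because the multicistronic/genomic use case is
bacterial, and both configurable. Input is capped at 1 Mb of sequence, a
deterministic, network-free proxy for a record-size limit. The scanner is
tested against an independent brute-force enumeration that groups start
codons per stop, on random sequences up to 3 kb.

Isoform matching is deliberately substitution-only: an ORF translation
matches an isoform perfectly when identical, imperfectly when equal in
length with a Hamming distance of at most three, and not at all otherwise.
Indels are out of scope — tolerating them would silently change what "three
differences" means. Imperfect matches are reported only when an isoform has
no perfect match, each with its full difference list. DNA is never
compared, so silent polymorphisms are invisible by design. Where several
perfect matches exist all are reported, sorted lexicographically by source
id, to keep output deterministic.

## Melting-temperature model

The original choice of Tm formula for this kind of tool is rarely
documented, so the package defaults to the community-standard unified
nearest-neighbor model: Allawi–SantaLucia dinucleotide stacks with the
unified initiation terms, the entropic salt correction
ΔS′ = ΔS + 0.368·(N−1)·ln[Na⁺], and

Tm = 1000·ΔH / (ΔS′ + R·ln(Cₜ/4)) − 273.15

with R = 1.987 cal mol⁻¹ K⁻¹. Defaults are 50 mM Na⁺ and 500 nM total
primer (Cₜ) — ordinary PCR conditions. The test-suite pins this
implementation to an independent nearest-neighbor implementation
(Biopython's, with the same parameter table and corrections) within
0.1 °C. Two closed-form alternatives, the Wallace rule 2(A+T)+4(G+C) and a
GC-fraction formula, are available for quick estimates and give exactly
computable test values. Degenerate bases make Tm undefined, hence strict
DNA is enforced in annealing regions.

In Tm mode a primer grows one base at a time from 15 nt until its annealing
Tm reaches the target (default 65 °C) or 60 nt is hit, in which case the
primer carries a `tm-unreachable` notice rather than failing: the user
decides. The growth contract makes primers *minimal* — dropping the last
base always falls below the target — which the tests verify against an
exhaustive scan over all lengths. Fixed-length mode bypasses the search.
When fewer bases remain in the CDS than the minimum length, design errors
out; when the CDS truncates the search early, the same notice applies.

## Overhang semantics

Overhangs are prepended 5′ of the annealing region, shown lower-case in all
tables (annealing upper-case), and never considered in the Tm. Each
overhang carries a `frameOffset` (0–2) describing the reading frame of the
insert's first codon relative to the overhang's 3′ end; start-codon
scanning (forward: ATG) and stop-codon scanning (reverse: stop codons on
the encoded sense strand, i.e. reverse-complemented in the primer) are
frame-aware. A plain substring scan was the alternative; frame-aware was
chosen because an out-of-frame ATG is harmless and flagging it would train
users to ignore the notice.

## Physicochemical properties

Properties follow the ProtParam conventions: molecular weight as the sum of
average residue masses plus one water (18.01524 Da); isoelectric point by
bisection of the net Henderson–Hasselbalch charge under the Bjellqvist pKa
set, including the residue-specific terminal pKa values, over pH 0–14 until
|charge| < 10⁻⁴ (at most 100 iterations — the charge is monotone in pH, so
the bracket always converges); ε₂₈₀ by the Gill–von Hippel coefficients,
reporting both the reduced value 5500·nW + 1490·nY and a cystine value
adding 125 per ⌊nC/2⌋ pairs. Both extinction values are always reported
because the oxidation state of a future protein prep is unknown at design
time. The choices (average rather than monoisotopic masses, this exact pKa
set, the floor-pairing convention) are pinned by frozen oracle fixtures
computed once with an independent ProtParam implementation; the recorded
tolerances are 0.01 % on MW, 0.01 pH on pI, and exactness on ε₂₈₀. The
oracle's own bisection only covers pH 4.05–12, so the fixture set contains
only peptides inside that bracket.

Tag fusion prepends the vector's tag protein (and appends an optional
C-terminal tag); cleavage keeps the configured number of C-terminal tag
residues on the insert (e.g. the glycine of an ENLYFQ↓G TEV site). A
vector without a protease site simply has no cleaved form.

## Vectors, plasmid maps and the GenBank dialect

Vector definitions load from YAML. The schema requires the two overhangs to
match the backbone immediately flanking the insertion placeholder
(IUPAC-aware comparison), which catches the most common config error —
overhangs copied from the wrong strand. Real ligation-independent-cloning
vector sequences are proprietary to their distributors and are not shipped;
the included `vectors_synthetic.yaml` is a randomly generated but
schema-complete stand-in, clearly labelled synthetic, and real vectors are
expected as user data.

`buildPlasmidMap()` splices the insert over the placeholder: upstream
features keep their coordinates, downstream features shift by the length
difference, features overlapping the placeholder are dropped, and a CDS
feature with the insert's translation is added. Record length is always
backbone − placeholder + insert. The GenBank writer emits the NCBI
sample-record layout — LOCUS with the length right-justified to column 40
and a `circular` topology flag, a FEATURES table with 1-based inclusive
spans, ORIGIN with 60 bases per line in 10-base groups — and is pinned by a
golden-file test plus a round-trip through an independent parser. Features
never wrap the origin; the insertion point in all shipped and generated
fixtures is chosen accordingly.

## Annotation filters and tracks

Homolog display keeps hits with E-value ≤ 0.001 and per-hit query coverage
(qend − qstart + 1)/query length ≥ 75 %. The significance direction is
worth a note: descriptions of such filters sometimes print "E-value of
> 0.001", but a lower-is-better statistic filtered for *display of true
orthologues* can only mean a cutoff from above; the threshold is
configurable for users who disagree. Coverage is computed per hit, not on
merged spans: a protein sharing one domain should not pass by accumulating
fragments. Mapping-candidate selection takes at most five hits with
identity strictly above 95 %, identity-descending, E-value as tie-break.

Structure-database tiers partition identity: ≥95 (PDB_95), [50, 95),
[30, 50), below 30 none — half-open downward so every hit lands in exactly
one tier, verified by an exhaustive sweep. PDB_95 tracks additionally mark
deposited-construct boundaries with `>`/`<` at the hit's query start/end,
carrying the structure id and chain as metadata; these are experimentally
validated truncation points and the single most useful prior for boundary
choice.

Per-residue tracks (PTMs with their single-letter legend and `+` for
multiply modified residues, domain/disorder spans, predictor outputs read
from documented two-column TSVs) render in 60-column blocks under the query
with a residue ruler; 60 columns matches the conventional alignment width
and is fixed by a golden test. PTM tracks are disabled (all blank, flagged
in metadata) for non-canonical isoforms because recorded modification
coordinates refer to the canonical sequence.

## What the synthetic generator does and does not emulate

`generateFixture()` produces the study inputs: clean ORFs (ATG + sense
codons + TAA), isoform sets derived from a base protein by parameterized
substitutions/indels, genomic sequences with ORFs embedded on either
strand, schema-complete vector definitions, and hit tables spanning the
filter thresholds (coverages 60–95 %, identities across all tiers). All
output is deterministic per seed. It does **not** emulate codon-usage bias,
GC skew, repetitive or low-complexity DNA, sequencing errors, splice
structure, or realistic BLAST score/E-value coupling — so passing tests
demonstrate the correctness of the algorithms on well-formed input, not
robustness to pathological real-world records. Primer specificity
(off-target annealing, hairpins, dimers) is explicitly out of scope, and
the in-silico PCR used in testing requires unique annealing sites.

## Problem sizes

The shipped tests use ORFs of 60–120 codons, genomic fixtures up to 3 kb
against the brute-force ORF oracle, 200 random (CDS, start, stop) triples
for the PCR round-trip property with minimality spot-checks every tenth
triple, 10 frozen property-oracle peptides, and plasmid backbones of
1.5–6 kb; the full suite and the acceptance script each run in well under a
minute on a laptop-class machine.

## Known limitations

* Substitution-only isoform matching cannot pair isoforms that differ by
  splicing from their encoding ORFs; such isoforms are reported unmatched.
* The GenBank reader is a minimal dialect parser (simple, `join`, and
  `complement` locations); fuzzy and remote locations are unsupported.
* Only the standard genetic code is exercised, though the translation table
  id is a parameter.
* The melting-temperature model ignores Mg²⁺, dNTPs and mismatches.
* No network access anywhere: UniProt/Ensembl-style records must be
  provided as local files.
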