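# ConstructDesigner

Structural-biology and protein-biochemistry projects rarely succeed with the
full-length gene: most proteins are modular, and obtaining soluble,
well-behaved material means designing *truncation constructs* that cut
between domains, then turning each chosen boundary into PCR primers with the
right cloning adaptors. Doing this by hand — mapping protein residues onto
codons, tuning primer melting temperatures, tracking dozens of
start/stop combinations and their tags — is trivial but error-prone.
ConstructDesigner automates the whole loop for R users:

* **Finding the coding DNA.** Validate and translate coding sequences, scan
  multicistronic/genomic DNA (up to 1 Mb) for open reading frames on both
  strands, extract CDS features from local GenBank records, and match
  candidate ORFs to protein isoforms at the protein level — exactly, or
  tolerating up to three single amino-acid substitutions when no perfect
  match exists (never comparing raw DNA, so silent SNPs are ignored).
* **Primer design.** A start residue *s* maps to CDS bases 3*s*−2..3*s*; the
  forward primer anneals from base 3*s*−2, the reverse primer is the reverse
  complement of the segment ending at base 3*t*. Annealing regions grow one
  base at a time (15–60 nt) until they reach the target melting temperature
  (default 65 °C), computed with the unified nearest-neighbor model

  > Tm = 1000·ΔH / (ΔS + 0.368·(N−1)·ln[Na⁺] + R·ln(Cₜ/4)) − 273.15

  (Wallace rule and GC-fraction formulas are available as alternatives).
  Cloning overhangs — ligation-independent-cloning vector adaptors,
  restriction sites from a shipped enzyme table, or arbitrary custom
  sequences including IUPAC degenerate codes — are prepended without ever
  affecting the Tm, and scanned in the insert's reading frame for stray
  start/stop codons.
* **Construct bookkeeping.** All start×stop combinations are enumerated and
  characterized with the ProtParam algorithms: molecular weight from average
  residue masses, isoelectric point by bisection on the Bjellqvist-pKa net
  charge, and ε₂₈₀ = 5500·nTrp + 1490·nTyr (+125 per cystine pair) — for the
  bare insert and, when a vector is configured, the tagged and
  protease-cleaved fusions.
* **Plasmid maps.** Vector definitions (overhangs, tag, protease site,
  backbone with an insertion placeholder) load from a documented YAML
  config; inserting a construct produces an annotated, circular GenBank
  flat file with recalculated feature coordinates.
* **Annotation filters.** BLAST-style tabular hits are filtered for homolog
  display (E ≤ 0.001 and ≥75 % query coverage), capped at five >95 %-identity
  mapping candidates, and classified into PDB-similarity tiers (≥95,
  50–95, 30–50 % identity) with deposited-construct boundary markers; PTM
  and domain tracks render vertically aligned under the query sequence.

Everything is plain R objects (S4 classes with accessors) plus CSV/TSV/FASTA/
GenBank files, so results drop straight into lab notebooks and spreadsheets.

## Worked example

Design primers and constructs for boundaries 1/48 (starts) and 48/58
(stops) on a synthetic 100-residue protein:

```r
library(ConstructDesigner)

fx  <- generateFixture("orf", nCodons = 100, seed = 42)
cds <- fx$dna

primers <- c(lapply(c(1, 48),  function(s) designForwardPrimer(cds, s)),
             lapply(c(48, 58), function(t) designReversePrimer(cds, t)))
primers <- lapply(primers, attachOverhang,
                  overhang = Overhang("cacc", origin = "vector"))
primerTable(primers, "RBX5")
#>         name direction boundary                                  sequence length    tm
#> 1  RBX5_Fw_1        Fw        1 caccATGTTTGCTTTAGAAGTAACGCGTCACGAGTTTCAGT     41 65.18
#> 2 RBX5_Fw_48        Fw       48          caccGGCTTAATATTTGCCACCCACGAGCCCC     32 65.75
#> 3 RBX5_Rv_48        Rv       48                caccGCCGCAGTCGTAACAACCGCCC     26 65.86
#> 4 RBX5_Rv_58        Rv       58     caccCTTAAGGGGCTCGTGGGTGGCAAATATTAAGCC     37 66.05
```

Primer names follow `prefix_Fw/Rv_position`; the lower-case prefix of each
sequence is the overhang, the upper-case part the annealing region, and
every annealing Tm meets the 65 °C default. The same boundaries yield four
constructs (note the single-residue 48–48 construct from a position marked
both start and stop):

```r
cons <- enumerateConstructs(c(1, 48), c(48, 58), fx$protein, cds)
constructTable(cons)[, c("start", "stop", "length", "mw", "pi", "eps280_reduced")]
#>   start stop length         mw       pi eps280_reduced
#> 1     1   48     48 5673.47994 4.313957           4470
#> 2     1   58     58 6823.86604 4.562561           4470
#> 3    48   48      1   75.06714 5.523438              0
#> 4    48   58     11 1225.45324 6.748779              0
```

A molecular weight of 5673.5 Da and pI 4.3 for construct 1–48 are exactly
what the Expasy-style algorithms predict for that 48-mer; ε₂₈₀ = 4470 means
three tyrosines and no tryptophan. Finally, clone construct 1–58 into the
shipped (synthetic) example vector and write the plasmid map:

```r
vec <- loadVectorConfig(system.file("extdata", "vectors_synthetic.yaml",
                                    package = "ConstructDesigner"))[[1]]
rec <- buildPlasmidMap(vec, constructDna(cons[[2]]), "RBX5_1-58")
rec
#> PlasmidRecord RBX5_1-58: 715 bp circular, 5 feature(s)
writeGenBank(rec, "RBX5_1-58.gb")
```

A command-line front end over the same functions ships at
`inst/scripts/construct-design.R` (subcommands `fixtures`, `primers`,
`constructs`, `map`, `annotate`).

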