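# pegforge

Design prime-editing reagents in R: from a wild-type DNA sequence and a
desired edit, pegforge produces ranked pegRNA designs (spacer, primer
binding site, RT template), PE3/PE3b secondary nicking guides, and
golden-gate-ready cloning oligos — each verified in silico by
reconstructing the edited locus from the RT template and by simulating the
Type IIS digestion/ligation of the emitted fragment.

It is written for molecular biologists building knock-in constructs (point
mutations, small insertions/deletions) with the PE2/PE3/PE3b prime-editing
strategies, and for pipeline authors who want a deterministic, scriptable
designer with structured (JSON/TSV/FASTA/GenBank) outputs.

## The design rules at its core

A prime editor (nCas9–RT fusion) nicks the PAM strand 3 nt 5' of the PAM.
The pegRNA is `spacer + scaffold + RTT + PBS` (5'→3'), where the PBS
(reverse complement of the nucleotides 5' of the nick) primes reverse
transcription and the RTT (reverse complement of the *edited* strand 3' of
the nick) templates the flap that installs the edit. pegforge:

* enumerates every 20-nt protospacer abutting an `NGG` PAM on both strands
  and ranks candidates by ascending nick-to-edit distance (edit must lie 3'
  of the nick);
* emits PBS options of 8–17 nt anchored at **12 nt**, warning at **≤ 30%
  GC**, and RTT options of 8–31 nt anchored at **14 nt** that span the edit
  with ≥ 5 nt of post-edit homology;
* classifies secondary nicking guides on the opposite strand of the
  *edited* sequence: **PE3b** guides overlap the edit and match only the
  edited allele (≥ 1 mismatch to wild type), **PE3** guides match both
  alleles within a signed 40–90 nt nick-to-nick window;
* emits a BbsI-flanked synthesized fragment for the pegRNA cassette and
  CACC/AAAC duplex oligos for nicking guides, and verifies assembly with a
  Type IIS golden-gate simulator (BbsI and BsaI geometries).

## Worked example

The edit is written inline — wild type with the region to replace in
parentheses, plus the replacement text:

```r
library(pegforge)

demo <- demo_target()   # 120-nt synthetic locus, central T>A substitution
report <- run_design(demo$wt_notation, replacement = demo$replacement)
print(report)
```

```
<design_report> status: ok; 1 spacer candidate(s), 9 emitted design(s)
  top design:
<pegrna_design> PE2 | spacer +:39 (20 nt) | PBS 12 nt | RTT 14 nt
  full pegRNA (122 nt): GACGTGACGTGACGTGACGTGTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGCCGTCACGTCCTTCGTCACGTCACGTC
  warnings: first_base_c
  verified: locus TRUE, assembly TRUE
  note: no PE3 candidate for spacer +:39
  note: no PE3b candidate for spacer +:39
```

The top design uses the only candidate spacer (a 20-mer on the `+` strand,
protospacer `[39,59)`, nick at inter-base position 56, two nucleotides 5'
of the edit), the preferred 12-nt PBS (`TCACGTCACGTC`, 58.3% GC, no
warning) and the preferred 14-nt RTT (`CGTCACGTCCTTCG`, 11 nt of homology
3' of the edit; flagged `first_base_c` because the scaffold-adjacent
template base is a C). `verified: locus TRUE` means the RT template
reconstructs exactly the requested edited sequence; `assembly TRUE` means
the emitted BbsI fragment releases the cassette with the configured
overhangs and circularizes into a product whose transcription unit is
`spacer + scaffold + RTT + PBS + TTTTTTT`. At this synthetic locus the
opposite strand offers no protospacer site at all, so the report records
the absence of PE3/PE3b options as structured notes and the designs are
PE2.

```r
write_report(report, "out/")   # report.json, designs.tsv, oligos.tsv/.fasta,
                               # pegrnas.fasta, construct.gb, ...
```

A thin command-line front end with the same capabilities lives at
`inst/cli/pegforge.R` (`design`, `fixtures`, `check` subcommands; logs on
stderr, machine output in files).

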