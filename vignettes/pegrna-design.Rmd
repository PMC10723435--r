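---
title: "Designing prime-editing reagents with pegforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing prime-editing reagents with pegforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegforge)
```

## The design problem

A prime editor is a Cas9 nickase (nCas9) fused to a reverse transcriptase
(RT), delivered with a prime-editing guide RNA (pegRNA). The pegRNA carries
three functional segments, 5' to 3': a **spacer** that directs nCas9 to the
target protospacer, the constant sgRNA **scaffold**, and a 3' extension made
of the **RT template (RTT)** followed by the **primer binding site (PBS)**.
nCas9 nicks the PAM-containing strand 3 nt 5' of the PAM; the freed 3' end
hybridizes with the PBS, and the RT copies the RTT into a new 3' DNA flap
that carries the edit. Cellular flap resolution then installs the edit. In
the PE3 strategy a second, conventional guide nicks the unedited strand to
bias repair toward the edited strand; in PE3b the second guide is chosen so
its protospacer or PAM overlaps the edit and therefore matches **only the
edited allele**, which delays the second nick until the edit is installed
and markedly reduces indels.

pegforge turns a wild-type sequence plus a desired edit into ranked pegRNA
designs, PE3/PE3b nicking guides and golden-gate-ready cloning oligos, and
verifies each design twice in silico: the RT template must reconstruct
exactly the requested edited locus, and the emitted fragment must survive a
simulated Type IIS digestion/ligation with the intended transcription unit.

## Input notation and coordinates

The edit is written inline: the wild-type sequence with the region to
replace wrapped in one pair of parentheses, plus the replacement text
(`AC(GT)AC` + `""` is a deletion, `ACGT()ACGT` + `TT` an insertion).
Alternatively `parse_edit_pair()` accepts the full edited sequence and
infers the interval from the longest common prefix/suffix. The parser
normalizes every edit to the *minimal differing interval* by trimming the
common prefix and suffix of region vs replacement, so distance-to-edit
metrics do not depend on how generously the user bracketed the edit. All
coordinates in the package are 0-based and half-open on the top (input)
strand; nicks are inter-base indices, which makes arithmetic identical on
both strands. Targets must be plain A/C/G/T; IUPAC degeneracy codes are
allowed only in PAM patterns, because a degenerate target would make edit
placement ill-defined.

```{r}
spec <- parse_edit_input("AC(GTG)AC", "GAG")  # trimmed to a 1-nt substitution
spec
```

## Spacer search and ranking

`enumerate_spacers()` scans both strands for every position where a 20-nt
protospacer abuts a PAM match (default `NGG`), using `Biostrings` pattern
matching with a fixed subject. The nick is placed 3 nt 5' of the PAM on the
protospacer strand — the standard SpCas9 H840A nickase geometry, which the
prime-editing literature assumes rather than restates. A candidate is
**valid for PE** only when the whole edit lies 3' of its nick on the
protospacer strand, since reverse transcription extends the nicked strand
across the edit; candidates are ranked by ascending nick-to-edit distance.
Ties are broken deterministically: candidates whose PAM or 10-nt seed is
disrupted by the edit come first (the edited allele resists re-cutting),
then `+` strand, then leftmost start. The tie-break order is this package's
contract — a deterministic, documented choice where the field has no single
convention. User-supplied spacers are validated by `validate_custom_spacer()`,
which requires a unique occurrence adjacent to a PAM and reports not-found,
ambiguous and PAM-less failures as distinct error classes.

## PBS and RTT options

For each valid spacer, one PBS option is emitted per feasible length in
8–17 nt and one RTT option per feasible length in 8–31 nt. The preferred
anchors are 12 nt (PBS) and 14 nt (RTT), reflecting current generalizable
design guidance for mammalian prime editing; the ranges bracket those
anchors generously since published guidance names anchors, not bounds.
Ranking is by distance from the anchor, warned options last among ties,
shorter first as the final tie-break — a total, deterministic order.

Warnings are advisory, never hard filters:

* `low_gc` — a PBS at or below 30% GC (the pass condition is *strictly
  above* 30%).
* `first_base_c` — the scaffold-adjacent first nucleotide of the RT
  template is C. This base is the last one incorporated into the flap, and
  a C here can pair with the scaffold's terminal G and impair editing; it is
  surfaced as a warning because the evidence is a tendency, not a rule.
* `polyT` — a TTTT run in the spacer or 3' extension, which a Pol III
  promoter would read as a terminator.
* `pam_not_disrupted` — the edit leaves PAM and seed intact, so the edited
  allele remains cleavable.

RTT options must span the full edit **and** leave at least 5 nt of homology
3' of the edit (default `min_post_edit_homology`), because the new flap
must re-anneal beyond the edit to be resolved in its favor; published
guidance is silent on a number, and 5 nt is a deliberately conservative
floor that still admits a 14-nt template for edits up to ~8 nt from the
nick. Non-spanning lengths are suppressed entirely rather than warned: a
template that does not encode the edit is not a design.

## The round-trip verifier

`predict_edited_locus()` models flap resolution directly: the
reverse-transcribed flap replaces the corresponding window 3' of the nick
on the protospacer strand, and the resulting top strand is compared with the
requested edited sequence. Every design the pipeline emits must satisfy
this equality — it is the package's hard guarantee, checked for 100% of
emitted designs over the synthetic fixture suite, on both strands and for
substitutions, insertions and deletions.

## PE3 / PE3b nicking guides

`enumerate_nick_guides()` scans the strand *opposite* the pegRNA spacer of
the **edited** sequence. A site is PE3b when its protospacer+PAM interval
intersects the edit and the aligned wild-type window differs at one or more
positions — the wild-type comparison window is anchored on the left flank
for sites starting 5' of the edit and on the right flank otherwise, which
keeps the comparison well-defined for insertions and deletions. A site
identical in both alleles is PE3 and is kept only when its signed
nick-to-nick offset falls in 40–90 nt (positive meaning 3' of the pegRNA
nick on the pegRNA protospacer strand). The window is the conventional PE3
guidance band, configurable, and deliberately not applied to PE3b: PE3b is
defined by allele-specific matching, not distance. PE3b guides are listed
first, reflecting the strategy's superior precision in neuronal editing
screens.

## Cloning kit and assembly simulation

The cassette (spacer + scaffold + RTT + PBS) is emitted as a synthesized
double-stranded fragment flanked by convergent BbsI sites positioned so
digestion releases the cassette with configurable 4-nt overhangs (defaults
CACC / AAAC, the ubiquitous hU6 convention; the original plasmid set's
exact overhangs are not published, so these are configuration, not claim).
Nicking guides are emitted as classic annealed sense/antisense duplex
oligos. `simulate_golden_gate()` implements the Type IIS geometry exactly
(BbsI `GAAGAC` with a 2-nt spacer, BsaI `GGTCTC` with a 1-nt spacer, both
leaving 4-nt 5' overhangs), rejects duplicate or palindromic junction
overhangs, chains inserts by unique overhang complementarity into a single
circular product, and requires the promoter to be immediately followed by
the cassette with no residual recognition site. The backbone is modeled as
a descriptor — junction overhangs plus annotated promoter and an optional
polyT terminator — with short synthetic stand-in sequences, because the
simulator needs junction structure, not a full plasmid. A design whose
cassette happens to contain an internal BbsI site cannot be released
cleanly; the pipeline drops it with a structured note instead of emitting
an unbuildable reagent.

Two policies are config-only because the source protocols leave them open:
the hU6 5'-G policy (default: prepend a G to spacers that lack one, giving
21-nt spacers; substitute-first-base and no-op are available) and the polyT
terminator appended to the transcription-unit model (default on).

## What the synthetic generator emulates — and what it does not

`generate_fixtures()` builds random 150–300-nt loci with a planted
protospacer+NGG site, places the edit 0–20 nt 3' of the planted nick, mixes
substitutions (1–3 nt), insertions (1–5 nt) and deletions (1–5 nt), and
mirrors half the targets onto the minus strand. These conditions guarantee
that every fixture admits at least one valid design, which is what the
round-trip and contract properties quantify. The generator emulates
sequence geometry only: uniform base composition, no repeats beyond chance,
no chromatin, no off-target landscape, no cell-type efficiency effects.
Passing tests therefore demonstrate correctness of the design arithmetic
and the simulators, not wet-lab editing efficiency; the efficiency
heuristics (PBS ~12 nt, >30% GC, RTT ~14 nt) are encoded as ranking
preferences and warnings, exactly as a designer would apply them, and are
not themselves validated by this package.

## Numerical and degenerate-input choices

* Ranking keys are total orders; permuting input order never changes
  output order, and repeated runs serialize to byte-identical JSON.
* Zero-width (insertion) edit intervals count as disrupting a window only
  when the insertion point falls strictly inside it.
* A target with no usable site returns a structured `no_valid_spacer`
  report (and a distinct CLI exit status), never a crash; an infeasible RTT
  request reports the minimal feasible length.
* Problem sizes in the test-suite properties (1000 fixtures for oracle
  equivalence, 50 for full-pipeline round-trips, 150 for the PE3b contract,
  100 for mirror symmetry) were chosen to exercise both strands and all
  three edit types many times over while keeping the suite quick to run.

## Known limitations

* No off-target scoring, thermodynamic folding, or machine-learned
  efficiency prediction; ranking encodes the published rule-based
  heuristics only.
* Single-edit inputs only; no RNA alphabets or degenerate targets.
* The golden-gate simulator models junction logic and site geometry, not
  ligation kinetics or fidelity; the backbone is a descriptor, not a
  replicon.
* epegRNA 3' structural motifs and chemical modifications are out of scope.
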