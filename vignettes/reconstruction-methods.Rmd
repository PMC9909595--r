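---
title: "Methods: simulating overlap-directed reconstruction of an adenoviral genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating overlap-directed reconstruction of an adenoviral genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adenoforge)
```

## The procedure being modelled

`adenoforge` simulates a partition-and-reassemble strategy for cloning a
large linear viral genome into a circular plasmid. The genome's two
ITR-bearing arms (left arm: positions 1–2,566; right arm: the last 161
bases, for the default 34,776-bp scale) are carried by an acceptor plasmid;
the internal genome is amplified as six fragments whose neighbouring termini
share 30–40 bp; fragment pairs are joined with a linearized backbone into
three intermediates; the E3-carrying fragment is additionally subcloned on
its own so the E3 interval can be excised by inverse PCR and replaced
base-exactly by a reporter cassette; the merged inserts are released by
NotI/EcoRI, NotI/EcoRV and NotI/ClaI digests and reassembled with the
SapI-linearized acceptor in one isothermal reaction; finally two PmeI sites
flanking the genome release it for rescue.

Every step is simulated at single-base resolution, and the end-to-end
correctness criterion is exact: the rescued genome must equal the wildtype
with the E3 interval excised and the cassette spliced in, up to documented
terminal scars.

## Sequence model and coordinates

External coordinates are 1-based and inclusive; internally spans convert
locally, and on circular sequences `start > end` denotes an origin-wrapping
span. Construct sequences are restricted to `{A,C,G,T}` — ambiguity codes
are allowed only in enzyme recognition patterns, because overlap detection
and digestion on ambiguous construct sequence would be ill-defined. Circular
molecules have no meaningful origin: assembly products are reported in
*canonical rotation* (the lexicographically smallest sequence over all
rotations of both strands, ties broken toward the forward strand, computed
with Booth's least-rotation algorithm), and circular identity is defined as
equality of canonical rotations.

## Restriction model

An enzyme is a recognition pattern plus two cut offsets counted from the
recognition start; `cut_bottom - cut_top` fixes the end chemistry (0 blunt,
positive a 5′ overhang, negative a 3′ overhang), and type IIS offsets run
past the recognition (SapI `GCTCTTC(1/4)` is stored as 8/11). Fragment bases
are the top strand read left to right, so fragment lengths always sum to the
parent length; each end stores the protruding single-stranded bases written
5′→3′, which reduces ligation compatibility to a reverse-complement equality
test. Digestion refuses two configurations rather than guessing: coincident
cut positions, and overlapping cut windows (a partial-digest situation the
model deliberately does not represent). A cut whose window falls off a
linear molecule simply does not happen. Note that the top-strand convention
is strand-asymmetric on purpose: digesting the reverse complement of a
carrier yields fragments whose top-strand boundaries are the old
bottom-strand boundaries.

## Primer grammar and partition planning

A vector-adjacent primer is `25-bp anchor + restriction tail + genomic
anneal`. In the packaged forward primers the NotI recognition overlaps the
anchor's terminal `GC` (`...AATTGC` + `GGCCGC` ⇒ `GCGGCCGC`), so the parser
allows the recognition span to overlap the anchor span by up to 2 nt and the
designer reproduces the fusion. Internal-junction primers are fully genomic;
the genomic overlap implied by an adjacent rev/fwd pair is
`|rev| + |fwd| − s` with `s` the longest suffix of the forward primer equal
to a prefix of the reverse complement of the reverse primer. `s` must reach
a seed of 10 — the smallest value that uniquely recovers all three packaged
junctions while rejecting shuffled controls.

The planner divides the inter-arm region into near-equal fragments (spread
≤ 10%), assigns every junction the midpoint overlap of the allowed window
(35 bp of 30–40), and then searches ±200 bp around each ideal boundary for a
position satisfying four constraints: both 25-mer anneal windows unique in
the genome on either strand; no release enzyme cutting inside its own
released insert; the engineered tail context creating exactly the intended
release site and no extra one; and the genome base adjacent to the anneal
not extending the tail's terminal base (otherwise the parser's
longest-3′-match would out-run the designed anneal and the design→parse
round trip would not be exact). Arm-side junction overlaps may take any
value in the window, scanned outward from 35, under the same cleanliness
rules. Anneals default to 25 nt and extend up to 35 nt to reach a Tm floor
of 58 °C under the documented two-regime rule (Wallace `2(A+T)+4(G+C)`
below 14 nt, else `64.9 + 41(GC − 16.4)/N`); the rule is a deterministic
engineering heuristic, not a thermodynamic claim, so validation reports the
Tm spread for inspection without failing on it.

## Reaction simulators

**PCR** requires each primer's 3′-terminal 18 bases to match the template
exactly and uniquely; unmatched 5′ portions become tails. Both template
strands exist in a real reaction, so primer roles are resolved against
either orientation; on circular templates a divergent pair automatically
performs inverse PCR across the origin. Polymerase error is out of scope
(amplification is treated as error-free).

**Ligation** joins ends whose overhang classes match and whose protruding
bases are reverse complements; blunt–blunt joins require an explicit
permissive flag. Internally fragments are handled in a blunt-filled
representation (the top strand extended over any overhang protruding on the
bottom strand) so that flipping a fragment is reverse-complement-symmetric
and every join drops exactly the duplicated overhang bases.

**Isothermal assembly** computes, for every ordered pair of fragments and
orientation, the longest exact terminal overlap in `[15, 80]` bp and builds
a junction graph; assembly succeeds iff exactly one Hamiltonian cycle
(circular) or path (linear) exists, enumerated exhaustively (inputs are
capped at 12 fragments) with the start fragment's orientation fixed to break
the global strand symmetry. Two design choices matter here:

* *Exact matching only.* The enzymatic chew-back/anneal mechanism tolerates
  no mismatches at junction scale, and mismatch tolerance would introduce
  ambiguity with no ground truth to resolve it.
* *End slack.* The exact overlap may sit up to 8 nt inside either terminus,
  and the unmatched flaps are trimmed at the splice. This models the 5′
  exonuclease resecting restriction scars: released inserts carry 1–6 nt of
  enzyme remnant at their termini (`GGCCGC` from NotI, `G` from EcoRI,
  `GAT` from EcoRV, `AT` from ClaI), yet the recombined genome must be
  seamless. A strict suffix–prefix rule cannot join such fragments at all;
  with slack 8 every scar in the workflow (maximum 6 nt) is resected while
  spurious matches remain improbable, since 15 exact bases are still
  required. Flapless inputs reduce to plain suffix–prefix matching.
  Competing equal-length maximal overlaps between the same ordered pair are
  an explicit ambiguity error.

## Workflow engineering choices

The acceptor plasmid's synthesized interval is
`NotI — PmeI — left arm — SapI› (stuffer) ‹SapI — right arm — PmeI — SrfI`.
The SapI sites face outward into a 20-nt stuffer with a 4-nt spacer on the
left and 1-nt on the right, placed so both SapI top-strand cuts fall exactly
at the arm boundaries: linearization drops the stuffer and exposes the arm
termini scar-free for assembly. The spacer constants were chosen so that no
proper suffix of any workflow recognition pattern is a prefix of the
spacer-side sequence — otherwise an unlucky arm terminus could complete a
recognition site across the junction (the package's tests enumerate this
property). The PmeI sites abut the arms directly, so rescue linearization
leaves 4-nt scars (`AAAC...GTTT`); the two scars are reverse complements,
preserving the rescued genome's ITR property, and verification treats up to
4 nt per terminus as documented scars.

The E3 deletion primers are `4-nt pad + SapI + 1-nt spacer + 24-nt
cassette-matching tail + genomic anneal`; the inverse-PCR amplicon is cut
with SapI (releasing the pads precisely at the cut offset) before overlap
assembly with the cassette, which is why the product carries the cassette
with no remnant: the product length law `|plasmid| − |E3| + |cassette|` is
asserted at run time.

## What the synthetic generator emulates — and what it does not

`synth_genome()` produces a 34,776-bp linear genome with 137-bp ITRs
(a realistic adenovirus ITR scale; the true lengths vary by serotype), a
200-bp packaging placeholder, and an E3-like interval. Defaults are study
conditions, fixed once:

* *Forbidden enzymes.* The whole workflow set (PmeI, NotI, SbfI, SrfI, SapI,
  EcoRI, EcoRV, ClaI, SwaI) is scrubbed genome-wide by local patching
  (minimal substitutions, mirrored into both ITRs; a site and its ITR mirror
  are one physical site and are patched once per pass). The method itself
  presupposes this property — the terminal enzyme must be absent from the
  genome and each release enzyme from its own insert; a uniformly random
  35-kb sequence would violate it, whereas the real workflow would simply
  choose different enzymes.
* *E3 interval.* 2,762 bp at 25,000–27,761 — the length of a real E3
  deletion, positioned inside fragment 5 of a near-equal six-way partition
  (serotype coordinates of E3 do not fit a near-equal partition at this
  genome length, so the synthetic frame keeps the biology — an interval
  wholly inside one fragment — rather than the literal coordinates).
* *Junction guards.* The released cassette always has blunt `ATC…GAT`
  termini (EcoRV release), so the generator additionally forbids the two
  genome contexts (`ATCG` immediately before the interval, `CGAT`
  immediately after) that would complete a ClaI site across a splice
  junction.

The generator does not emulate adenovirus gene content, codon structure,
GC skew, repeats, or any sequence bias; passing tests therefore demonstrate
the correctness of the simulated chemistry and bookkeeping on
realistic-scale inputs, not performance on real genomes. Real genomes can be
supplied directly (FASTA/GenBank) with their own E3 coordinates, where the
same planner constraints apply and may legitimately fail if a release
enzyme saturates the sequence.

The packaged pBR322-analog backbone is likewise synthetic: a seeded
4,361-bp circle carrying the two printed 25-nt anchors exactly where the
MCS swap and the assembly junctions need them, with the workflow enzyme set
excluded from the retained backbone region. It is labelled synthetic
everywhere; it is not the natural plasmid sequence.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on the
default 34,776-bp genome; one end-to-end reconstruction takes a few seconds,
and the identity property is exercised over twenty consecutive seeds.
Every step is deterministic given the configuration seed: generators use
scoped RNG, assembly enumeration is sorted, and repeated runs are
byte-identical.

## Known limitations

* No thermodynamics: primer quality is a deterministic formula; hairpins,
  dimers, and mismatch-tolerant annealing are out of scope.
* No partial digestion, methylation sensitivity or star activity.
* Assembly ambiguity detection is exact-sequence-based; two junctions
  sharing an overlap by biological repetition would be reported as an
  ambiguity error rather than resolved probabilistically.
* The wet-lab stages downstream of sequence operations (transfection,
  rescue kinetics, reporter readouts) are intentionally not modelled.
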