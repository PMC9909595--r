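# adenoforge

In-silico planning and simulation of adenoviral genome reconstruction by
isothermal (Gibson) assembly.

## The problem

Adenovirus genomes are linear double-stranded DNA molecules of roughly 26-45
kb whose native restriction-site landscape rarely supports direct cloning.
A practical route to building recombinant adenoviral vectors is to partition
the genome: synthesize the two inverted-terminal-repeat (ITR) arms into a
low-copy plasmid, amplify the internal genome as six ~6-kb fragments whose
adjacent termini share 30-40 bp of sequence, subclone fragment pairs into
intermediate plasmids (where any fragment can be engineered, e.g. replacing
the dispensable E3 region with a reporter cassette), release the merged
inserts by restriction digestion, and reassemble everything in a one-pot
isothermal reaction. The full plasmid is then linearized at terminal sites
absent from the viral genome (PmeI) to liberate the genome for transfection.

`adenoforge` models every sequence-level step of that strategy so a design
can be checked before any DNA is ordered:

* **seqcore** — dsDNA sequences with linear/circular topology, 1-based
  inclusive coordinates, canonical rotation for comparing circles, FASTA and
  GenBank I/O.
* **restriction** — enzyme model with explicit cut offsets and end chemistry
  (blunt, 5'/3' overhangs, type IIS offsets such as SapI's 1/4), site
  scanning with origin wrap, digestion, absent-site discovery.
* **design** — genome partitioning under junction-overlap, uniqueness and
  release-site constraints; the tailed-primer grammar
  (25-bp vector anchor + restriction tail + genomic anneal), primer parsing,
  and junction-overlap arithmetic: for adjacent fully genomic primers the
  implied amplicon overlap is `|rev| + |fwd| - s`, with `s` the longest
  suffix of the forward primer equal to a prefix of the reverse complement
  of the reverse primer.
* **insilico** — PCR (convergent and inverse), sticky/blunt ligation, and
  overlap-directed assembly with an exact-match junction graph solved for a
  unique Hamiltonian cycle or path.
* **workflow** — the full reconstruction: MCS swap, arm acceptor plasmid,
  three paired intermediates, E3 replacement, release digests, final
  reassembly, rescue linearization, verification against the directly
  spliced expectation.
* **synthfix** — a seeded synthetic genome/cassette generator (ITRs, E3-like
  interval, forbidden-site scrubbing) plus packaged fixtures: the twelve
  fragment primers, the eight subcloning/deletion primers, the two 25-nt
  anchors, the 64-nt MCS, the enzyme table, and a synthetic pBR322-analog
  backbone.

## Worked example

```r
library(adenoforge)

# junction arithmetic on the packaged fragment-primer set
p <- setNames(fixtures()$table1, sapply(fixtures()$table1, `[[`, "name"))
junction_overlap(p[["ADV-1-R"]], p[["ADV-2-F"]])  # 40
junction_overlap(p[["ADV-3-R"]], p[["ADV-4-F"]])  # 40
junction_overlap(p[["ADV-5-R"]], p[["ADV-6-F"]])  # 35

parse_primer(p[["ADV-1-F"]])$re
#> $name        "NotI"
#> $span        24 31        # recognition fused over the anchor's terminal GC

# a complete seeded reconstruction on synthetic inputs
run <- reconstruct(reconstruction_config(seed = 1))
run$report
#> Reconstruction verification: PASS
#>   orientation: reverse; terminal scars: 4 / 4 nt
#>   cassette at 25004..27981
run$final$junctions
#>              left           right overlap_bp position
#> 1 pBR322LR_linear        insert_1         35     3510
#> 2        insert_1        insert_2         40    31263
#> 3        insert_2        insert_3         37    20559
#> 4        insert_3 pBR322LR_linear         35     9638
```

The verification PASS means the rescued linear genome is base-identical to
the synthetic wildtype with its E3-like interval excised and the reporter
cassette spliced in, up to the documented 4-nt terminal scars left by the
blunt PmeI cuts; because the two scars are reverse complements, the ITR
property of the rescued genome is preserved. The junction report lists the
exact overlap each isothermal joint used and where it sits in the final
plasmid.

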