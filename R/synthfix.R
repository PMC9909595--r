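# Seeded synthetic-data generator and packaged fixtures. The generator
# produces adenovirus-scale study material: a linear ~35-kb genome with
# inverted terminal repeats, an E3-like dispensable interval, and the whole
# workflow enzyme set scrubbed from the sequence (the method itself requires
# the terminal enzyme to be absent from the genome and each release enzyme to
# be absent from its own insert; a random genome is scrubbed genome-wide).

.WORKFLOW_ENZYMES <- c("PmeI", "NotI", "SbfI", "SrfI", "SapI", "EcoRI",
                       "EcoRV", "ClaI", "SwaI")

.MCS <- "GCGGCCGCACTAGTGAATTCGGCCGGCCATTTAAATCGAATAGCCCGGGCATCGAACCTGCAGG"

#' Specification for a synthetic genome
#'
#' @param length Genome length (default 34,776 bp, an adenovirus-scale value).
#' @param itr_len Inverted-terminal-repeat length (default 137 bp, a realistic
#'   adenovirus ITR scale; configurable).
#' @param e3_span E3-like dispensable interval; the default 2,762-bp interval
#'   is placed inside fragment 5 of a near-equal 6-way partition.
#' @param forbidden Enzymes scrubbed from the genome (default: the workflow
#'   set).
#' @param unique_windows Optional list of [span()]s whose 25-mer windows are
#'   forced unique.
#' @param seed Integer seed; fixes the output exactly.
#' @return A list of class `synth_genome_spec`.
#' @export
synth_genome_spec <- function(length = 34776L, itr_len = 137L,
                              e3_span = span(25000L, 27761L),
                              forbidden = .WORKFLOW_ENZYMES,
                              unique_windows = list(), seed = 1L) {
  length <- as.integer(length); itr_len <- as.integer(itr_len)
  if (length <= 2L * itr_len + (e3_span$end - e3_span$start + 1L))
    stop("generation error: genome too short for ITRs plus E3 interval")
  if (e3_span$start <= itr_len || e3_span$end > length - itr_len)
    stop("generation error: E3 interval must not touch the ITRs")
  structure(list(length = length, itr_len = itr_len, e3_span = e3_span,
                 forbidden = forbidden, unique_windows = unique_windows,
                 seed = as.integer(seed)),
            class = "synth_genome_spec")
}

# substitute one base inside a recognition match, deterministically
.patch_base <- function(chars, pos) {
  cycle <- c(A = "C", C = "G", G = "T", T = "A")
  chars[pos] <- cycle[[chars[pos]]]
  chars
}

#' Generate a seeded synthetic genome
#'
#' The genome satisfies, by construction and verified by re-scanning: the
#' first `itr_len` bases equal the reverse complement of the last `itr_len`
#' (inverted terminal repeats), every forbidden enzyme has zero sites on
#' either strand, the E3-boundary contexts cannot recreate a release site once
#' the reporter cassette (with its blunt `ATC`/`GAT` termini) is spliced in,
#' and any requested windows are unique. Forbidden sites are removed by local
#' patching (minimal substitutions mirrored into both ITRs when needed) rather
#' than whole-genome rejection.
#'
#' @param spec A [synth_genome_spec()].
#' @return A linear `nucseq` with ITR, packaging and E3 features.
#' @export
synth_genome <- function(spec = synth_genome_spec()) {
  stopifnot(inherits(spec, "synth_genome_spec"))
  L <- spec$length; itr <- spec$itr_len
  enzymes <- .as_enzymes(spec$forbidden)
  chars <- .with_seed(spec$seed, sample(c("A", "C", "G", "T"), L, replace = TRUE))
  mirror_itr <- function(ch) {
    left <- ch[seq_len(itr)]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ch[(L - itr + 1L):L] <- rev(comp[left])
    ch
  }
  e3s <- spec$e3_span$start; e3e <- spec$e3_span$end
  guard <- function(ch) {
    # cassette splices in with ATC.../...GAT blunt termini; forbid the genome
    # contexts that would complete a ClaI site across either junction
    if (paste(ch[(e3s - 4L):(e3s - 1L)], collapse = "") == "ATCG")
      ch[e3s - 1L] <- "T"
    if (paste(ch[(e3e + 1L):(e3e + 4L)], collapse = "") == "CGAT")
      ch[e3e + 1L] <- "A"
    ch
  }
  for (iter in 1:60) {
    chars <- guard(mirror_itr(chars))
    g <- nuc_seq("synth_genome", paste(chars, collapse = ""), "linear")
    dirty <- FALSE
    touched <- integer(0)  # a site and its ITR mirror are the same site:
                           # patch each physical position at most once per pass
    for (enz in enzymes) {
      sites <- find_sites(g, enz)
      if (nrow(sites) == 0L) next
      dirty <- TRUE
      for (i in seq_len(nrow(sites))) {
        l <- nchar(enz$recognition)
        s0 <- sites$position[i]
        covered <- s0:(s0 + l - 1L)
        mirrored <- (L - covered + 1L)
        if (any(c(covered, mirrored[covered <= itr | covered > L - itr])
                %in% touched)) next
        p <- s0 + l %/% 2L
        chars <- .patch_base(chars, p)
        touched <- c(touched, covered)
        if (p <= itr) {
          chars <- mirror_itr(chars)
          touched <- c(touched, mirrored)
        }
        if (p > L - itr) {  # mirror the patch into the left ITR instead
          comp <- c(A = "T", C = "G", G = "C", T = "A")
          chars[L - p + 1L] <- comp[[chars[p]]]
          chars <- mirror_itr(chars)
          touched <- c(touched, mirrored)
        }
      }
    }
    for (w in spec$unique_windows) {
      win <- paste(chars[w$start:w$end], collapse = "")
      g2 <- paste(chars, collapse = "")
      hits <- c(.match_starts(win, g2),
                if (revcomp(win) != win) .match_starts(revcomp(win), g2))
      extra <- setdiff(hits, w$start)
      if (length(extra) > 0L) {
        dirty <- TRUE
        for (h in extra) chars <- .patch_base(chars, h + (w$end - w$start) %/% 2L)
      }
    }
    if (!dirty) break
    if (iter == 60L) stop("generation error: constraints not satisfiable")
  }
  bases <- paste(chars, collapse = "")
  # self-verification
  if (substr(bases, 1L, itr) != revcomp(substr(bases, L - itr + 1L, L)))
    stop("generation error: ITR mirror violated")
  g <- nuc_seq("synth_genome", bases, "linear", features = list(
    feature("ITR_left", span(1L, itr), "ITR"),
    feature("packaging", span(itr + 1L, itr + 200L), "packaging"),
    feature("E3", spec$e3_span, "E3"),
    feature("ITR_right", span(L - itr + 1L, L), "ITR")))
  for (enz in enzymes) {
    if (nrow(find_sites(g, enz)) != 0L)
      stop("generation error: ", enzyme(enz)$name, " still present after patching")
  }
  g
}

#' Generate a seeded synthetic reporter cassette donor
#'
#' A linear donor whose cassette is flanked by EcoRV-releasable context:
#' digestion with the end enzyme cuts the flanks only, releasing a blunt
#' cassette (`ATC`...`GAT` termini) free of every workflow enzyme internally.
#'
#' @param length Total donor length (default 3,000 bp; >= 200).
#' @param end_enzyme Blunt cutter providing the releasable flanks.
#' @param forbidden Enzymes excluded from the released cassette.
#' @param seed Integer seed.
#' @return A linear `nucseq`; the released cassette is its central digest
#'   fragment.
#' @export
synth_cassette <- function(length = 3000L, end_enzyme = "EcoRV",
                           forbidden = .WORKFLOW_ENZYMES, seed = 1L) {
  length <- as.integer(length)
  if (length < 200L) stop("generation error: cassette length must be >= 200")
  enz <- enzyme(end_enzyme)
  pad <- 8L
  core_len <- length - 2L * pad - 2L * nchar(enz$recognition)
  chars <- .with_seed(seed + 7L,
                      sample(c("A", "C", "G", "T"), length, replace = TRUE))
  rec <- strsplit(enz$recognition, "")[[1]]
  set_flanks <- function(ch) {
    ch[(pad + 1L):(pad + 6L)] <- rec
    ch[(length - pad - 5L):(length - pad)] <- rec
    ch
  }
  core_lo <- pad + 7L; core_hi <- length - pad - 6L
  released_span <- c(pad + 4L, length - pad - 3L)  # blunt cut GAT^ATC
  enzymes <- .as_enzymes(unique(c(forbidden, end_enzyme)))
  for (iter in 1:60) {
    chars <- set_flanks(chars)
    rel <- paste(chars[released_span[1]:released_span[2]], collapse = "")
    dirty <- FALSE
    for (e in enzymes) {
      sites <- find_sites(nuc_seq("rel", rel, "linear"), e)
      if (nrow(sites) == 0L) next
      dirty <- TRUE
      for (i in seq_len(nrow(sites))) {
        p <- released_span[1] - 1L + sites$position[i] +
          nchar(e$recognition) %/% 2L
        p <- min(max(p, core_lo), core_hi)  # keep the flank sites intact
        chars <- .patch_base(chars, p)
      }
    }
    if (!dirty) break
    if (iter == 60L) stop("generation error: cassette constraints not satisfiable")
  }
  donor <- nuc_seq("cassette_donor", paste(chars, collapse = ""), "linear",
                   features = list(feature("cassette",
                                           span(released_span[1], released_span[2]),
                                           "cassette")))
  if (nrow(find_sites(donor, enz)) != 2L)
    stop("generation error: cassette flanks malformed")
  donor
}

#' Release the cassette from its donor
#'
#' @param donor Output of [synth_cassette()] (or any donor whose end enzyme
#'   cuts the flanks only).
#' @param end_enzyme The flank enzyme.
#' @return Linear `nucseq`: the released cassette.
#' @export
release_cassette <- function(donor, end_enzyme = "EcoRV") {
  frags <- digest(donor, list(end_enzyme))
  f <- select_fragment(frags, "largest")
  nuc_seq("cassette", f$bases, "linear")
}

#' Synthetic pBR322-analog backbone
#'
#' A seeded 4,361-bp circular stand-in for the low-copy cloning vector: it
#' carries the two 25-nt anchor sequences at the positions the cloning-site
#' swap and the assembly junctions require, and the retained backbone region
#' is free of the workflow enzyme set. It is a synthetic analog, not the
#' natural plasmid sequence.
#'
#' @param seed Integer seed (default 322).
#' @return A circular `nucseq` of length 4,361.
#' @export
synth_pbr322 <- function(seed = 322L) {
  L <- 4361L
  chars <- .with_seed(seed, sample(c("A", "C", "G", "T"), L, replace = TRUE))
  up <- .UP_ANCHOR; down <- .DOWN_ANCHOR
  set_anchors <- function(ch) {
    # upstream anchor = [4341..4361] + [1..2] + the MCS's leading GC;
    # downstream anchor = the MCS's trailing GG + [974..996]
    ch[4341:4361] <- strsplit(substr(up, 1, 21), "")[[1]]
    ch[1:2] <- strsplit(substr(up, 22, 23), "")[[1]]
    ch[974:996] <- strsplit(substr(down, 3, 25), "")[[1]]
    ch
  }
  protected <- c(1:2, 974:996, 4341:4361)
  enzymes <- .as_enzymes(.WORKFLOW_ENZYMES)
  for (iter in 1:60) {
    chars <- set_anchors(chars)
    raw <- paste(chars, collapse = "")
    # scan the virtual swapped product (what build_backbone will retain)
    product <- paste0(substr(raw, 1, 2), .MCS, substr(raw, 974, L))
    pseq <- nuc_seq("bb", product, "circular")
    dirty <- FALSE
    mcs_zone <- c(3L, 66L)
    for (e in enzymes) {
      sites <- find_sites(pseq, e)
      for (i in seq_len(nrow(sites))) {
        p <- sites$position[i]
        if (p >= mcs_zone[1] && p + nchar(e$recognition) - 1L <= mcs_zone[2])
          next  # the multiple-cloning-site's own sites
        # map a patchable product position back to the raw plasmid
        cand <- (p + 0:(nchar(e$recognition) - 1L))
        cand <- ((cand - 1L) %% nchar(product)) + 1L
        raw_pos <- vapply(cand, function(q) {
          if (q <= 2L) q else if (q <= 66L) NA_integer_ else q - 66L + 973L
        }, integer(1))
        raw_pos <- raw_pos[!is.na(raw_pos) & !(raw_pos %in% protected)]
        if (length(raw_pos) == 0L)
          stop("generation error: unpatchable site in engineered region")
        chars <- .patch_base(chars, raw_pos[(length(raw_pos) + 1L) %/% 2L])
        dirty <- TRUE
      }
    }
    # the anchors must be unique on the product for unambiguous assembly
    Lp <- nchar(product)
    dd <- paste0(product, substr(product, 1L, 40L))
    map_to_raw <- function(q) {
      q <- ((q - 1L) %% Lp) + 1L
      if (q <= 2L) q else if (q <= 66L) NA_integer_ else q - 66L + 973L
    }
    expected_at <- c(Lp - 20L, 65L)   # upstream anchor wraps the origin
    anchor_seqs <- c(up, down)
    for (ai in 1:2) {
      a <- anchor_seqs[ai]
      hits <- .match_starts(a, dd)
      hits <- hits[hits <= Lp]
      extras <- c(setdiff(hits, expected_at[ai]),
                  Filter(function(h) h <= Lp, .match_starts(revcomp(a), dd)))
      for (h in extras) {
        dirty <- TRUE
        for (off in 12:0) {
          rp <- map_to_raw(h + off)
          if (!is.na(rp) && !(rp %in% protected)) {
            chars <- .patch_base(chars, rp)
            break
          }
        }
      }
    }
    if (!dirty) break
    if (iter == 60L) stop("generation error: backbone constraints not satisfiable")
  }
  nuc_seq("pBR322_synthetic", paste(chars, collapse = ""), "circular")
}

#' Packaged fixtures
#'
#' Returns, byte-exact as packaged: the twelve fragment-amplification primers,
#' the eight subcloning/deletion primers, the two 25-nt vector anchors, the
#' 64-nt multiple cloning site, the enzyme table, and the synthetic
#' pBR322-analog backbone.
#'
#' @return A list: `table1`, `table2` (primer lists), `anchors`, `mcs`,
#'   `enzymes`, `pbr322`.
#' @export
fixtures <- function() {
  t1 <- read_primers(system.file("extdata", "table1_primers.tsv",
                                 package = "adenoforge"))
  t2 <- read_primers(system.file("extdata", "table2_primers.tsv",
                                 package = "adenoforge"))
  pb_path <- system.file("extdata", "pbr322_synthetic.fa", package = "adenoforge")
  pb <- if (nzchar(pb_path) && file.exists(pb_path)) read_fasta(pb_path)[[1]]
        else synth_pbr322()
  pb$topology <- "circular"
  list(table1 = t1, table2 = t2, anchors = default_anchors(), mcs = .MCS,
       enzymes = load_enzymes(), pbr322 = pb)
}
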