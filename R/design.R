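# Genome partitioning and the primer grammar: vector-anchored tailed primers,
# fully genomic junction primers, parsing, and junction-overlap arithmetic.
#
# Grammar of a vector-adjacent primer: 25-bp vector anchor, a restriction-site
# tail, then the genomic anneal. In the forward orientation the NotI
# recognition (GCGGCCGC) is fused with the anchor's terminal GC, so the
# recognition span may overlap the anchor span by up to 2 nt. Primers at
# internal junctions are fully genomic; the two amplicons implied by an
# adjacent rev/fwd pair share a genomic overlap of |rev| + |fwd| - s, where s
# is the suffix/prefix seed between the fwd primer and the reverse complement
# of the rev primer.

.UP_ANCHOR <- "AGGCCCTTTCGTCTTCAAGAATTGC"
.DOWN_ANCHOR <- "GGGCGACGCGAGGCTGGATGGCCTT"

#' Default vector anchor pair
#'
#' The two 25-bp backbone sequences flanking the cloning site; vector-adjacent
#' primers carry the upstream anchor (forward) or the reverse complement of
#' the downstream anchor (reverse) as their 5' segment, providing the homology
#' that joins amplicons to the linearized backbone during assembly.
#'
#' @param upstream,downstream 25-base anchor sequences.
#' @return An object of class `anchor_pair`.
#' @export
default_anchors <- function(upstream = .UP_ANCHOR, downstream = .DOWN_ANCHOR) {
  upstream <- .norm_bases(upstream); downstream <- .norm_bases(downstream)
  if (nchar(upstream) != 25L || nchar(downstream) != 25L)
    stop("anchors must be exactly 25 bases")
  structure(list(upstream = upstream, downstream = downstream),
            class = "anchor_pair")
}

.lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1, n)); bv <- utf8ToInt(substr(b, 1, n))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

.count_both_strands <- function(bases, w) {
  g <- Biostrings::DNAString(bases)
  n <- Biostrings::countPattern(w, g)
  rw <- revcomp(w)
  if (rw != w) n <- n + Biostrings::countPattern(rw, g)
  n
}

.unique_window <- function(genome_bases, w) .count_both_strands(genome_bases, w) == 1L

#' Primer melting temperature
#'
#' Deterministic rule: Wallace 2(A+T) + 4(G+C) below 14 nt, otherwise
#' `64.9 + 41 * (GC - 16.4) / N`.
#'
#' @param bases Primer sequence (>= 8 nt).
#' @return Temperature in degrees Celsius.
#' @export
tm <- function(bases) {
  bases <- .norm_bases(bases, what = "primer")
  n <- nchar(bases)
  if (n < 8L) stop("length error: Tm needs >= 8 nt")
  gc <- n - nchar(gsub("[GC]", "", bases))
  if (n < 14L) 2 * (n - gc) + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
}

.primer_spec <- function(name, bases, role, anchor = NULL, re = NULL,
                         cassette_tail = NULL, anneal = NULL,
                         anneal_bases = NULL) {
  structure(list(name = name, bases = bases, role = role, anchor = anchor,
                 re = re, cassette_tail = cassette_tail, anneal = anneal,
                 anneal_bases = anneal_bases),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer> %s [%s] %d nt: %s\n", x$name, x$role, nchar(x$bases),
              x$bases))
  if (!is.null(x$anchor)) cat(sprintf("  anchor %d..%d\n", x$anchor[1], x$anchor[2]))
  if (!is.null(x$re)) cat(sprintf("  RE %s at %d..%d\n", x$re$name,
                                  x$re$span[1], x$re$span[2]))
  if (!is.null(x$anneal_bases)) cat(sprintf("  anneal (%d nt): %s\n",
                                            nchar(x$anneal_bases), x$anneal_bases))
  invisible(x)
}

#' Genomic overlap implied by an adjacent rev/fwd primer pair
#'
#' For two fully genomic primers at an internal junction, the amplicons they
#' produce from adjacent fragments share `|rev| + |fwd| - s` bases of genome,
#' where `s` is the longest suffix of the forward primer equal to a prefix of
#' the reverse complement of the reverse primer (at least `min_seed`).
#'
#' @param rev_primer,next_fwd_primer Primer base strings (or `primer_spec`s).
#' @param min_seed Minimum suffix/prefix seed to accept a junction.
#' @return Overlap length in bp.
#' @export
junction_overlap <- function(rev_primer, next_fwd_primer, min_seed = 10L) {
  if (inherits(rev_primer, "primer_spec")) rev_primer <- rev_primer$bases
  if (inherits(next_fwd_primer, "primer_spec")) next_fwd_primer <- next_fwd_primer$bases
  rcr <- revcomp(rev_primer)
  nf <- nchar(next_fwd_primer)
  s <- 0L
  for (k in seq_len(min(nf, nchar(rcr)))) {
    if (substr(next_fwd_primer, nf - k + 1L, nf) == substr(rcr, 1L, k)) s <- k
  }
  if (s < min_seed)
    stop(sprintf("no junction: best suffix/prefix seed %d < min_seed %d", s, min_seed))
  nchar(rev_primer) + nf - s
}

# Default release-enzyme pairs and vector cut for a 6-fragment plan.
.default_release <- list(c("NotI", "EcoRI"), c("NotI", "EcoRV"), c("NotI", "ClaI"))

# Engineered tail context around a pairing's outer boundaries, used to check
# that the release sites stay unique once the tails are added.
.left_tail_context <- function(genome, s, anchors) {
  paste0(anchors$upstream, "GGCCGC",
         substr(genome$bases, s, min(s + 39L, nchar(genome$bases))))
}
.right_tail_context <- function(genome, e, site, anchors) {
  paste0(substr(genome$bases, max(1L, e - 39L), e), site,
         revcomp(anchors$downstream))
}

.context_site_count <- function(context, enz) {
  nrow(find_sites(nuc_seq("ctx", context), enz))
}

#' Plan the partition of a genome into overlapping fragments
#'
#' Splits the region between the two terminal arms into `n_fragments`
#' near-equal spans (length spread at most 10%), assigning every junction --
#' including the junctions with the arms -- a genomic overlap inside
#' `overlap_range`. Boundaries are shifted within a `search_window` so that
#' (i) each boundary's anneal windows are unique in the genome on either
#' strand, (ii) no release enzyme cuts inside its own released insert, and
#' (iii) the engineered primer tails do not create extra release sites at the
#' insert boundaries.
#'
#' @param genome Linear [nuc_seq()].
#' @param arms List of two [span()]s at the genome termini (left, right).
#' @param n_fragments Even fragment count (default 6).
#' @param release_enzymes List of enzyme-name pairs, one per fragment pairing.
#' @param target_len Informative target fragment length (bp).
#' @param overlap_range Junction overlap bounds, default `c(30, 40)`.
#' @param anneal_len Anneal window length used for uniqueness checks.
#' @param search_window Maximum boundary shift in bp.
#' @return An object of class `partition_plan`.
#' @export
plan_partition <- function(genome, arms, n_fragments = 6L,
                           release_enzymes = .default_release,
                           target_len = 6000L, overlap_range = c(30L, 40L),
                           anneal_len = 25L, search_window = 200L) {
  stopifnot(inherits(genome, "nucseq"), genome$topology == "linear")
  L <- nchar(genome$bases)
  left <- arms[[1]]; right <- arms[[2]]
  if (left$start != 1L || right$end != L)
    stop("planning error: arms must sit at the genome termini")
  n <- as.integer(n_fragments)
  if (n < 2L || n %% 2L != 0L) stop("planning error: n_fragments must be even")
  if (length(release_enzymes) != n %/% 2L)
    stop("planning error: one release-enzyme pair per fragment pairing required")
  ov <- as.integer(round(mean(overlap_range)))  # one deterministic overlap
  s1 <- left$end - ov + 1L
  en <- right$start + ov - 1L
  if (en - s1 + 1L < n * 200L)
    stop("planning error: internal region too short for ", n, " fragments")

  gb <- genome$bases
  # A vector-adjacent primer's restriction tail abuts its genomic anneal; if
  # the genome happens to continue the tail's terminal base past the anneal
  # boundary, the parser's longest-3'-match would out-run the designed anneal.
  # Reject such boundaries so design -> parse recovers spans exactly.
  notI_tail_last <- "C"   # ...GGCCGC | anneal
  fwd_ctx_clean <- function(s_next)
    substr(gb, s_next - 1L, s_next - 1L) != notI_tail_last
  rev_ctx_clean <- function(e_i, site)
    substr(gb, e_i + 1L, e_i + 1L) !=
      revcomp(substr(site$recognition, nchar(site$recognition),
                     nchar(site$recognition)))
  ok_boundary <- function(e_i, i) {
    # e_i: end of fragment i; next fragment starts at e_i - ov + 1
    s_next <- e_i - ov + 1L
    if (s_next <= left$end || e_i >= right$start) return(FALSE)
    w_rev <- substr(gb, e_i - anneal_len + 1L, e_i)
    w_fwd <- substr(gb, s_next, s_next + anneal_len - 1L)
    if (!.unique_window(gb, w_rev) || !.unique_window(gb, w_fwd)) return(FALSE)
    pair_of <- (i + 1L) %/% 2L      # pairing index of fragment i
    if (i %% 2L == 0L && i < n) {
      # pair-outer boundary: fragment i ends a pairing, fragment i+1 opens one
      site_i <- enzyme(release_enzymes[[pair_of]][2])
      if (!rev_ctx_clean(e_i, site_i) || !fwd_ctx_clean(s_next)) return(FALSE)
      ctx_r <- .right_tail_context(genome, e_i, site_i$recognition,
                                   default_anchors())
      if (.context_site_count(ctx_r, site_i) != 1L) return(FALSE)
      notI <- enzyme("NotI")
      ctx_l <- .left_tail_context(genome, s_next, default_anchors())
      if (.context_site_count(ctx_l, notI) != 1L) return(FALSE)
      nxt_site <- enzyme(release_enzymes[[pair_of + 1L]][2])
      if (.context_site_count(ctx_l, nxt_site) != 0L) return(FALSE)
    }
    TRUE
  }

  # terminal boundaries: the arm-side junction overlaps may take any value in
  # overlap_range; scan for one whose anneal window is unique and whose tail
  # context is clean
  ov_cands <- as.integer(overlap_range[1]:overlap_range[2])
  ov_cands <- ov_cands[order(abs(ov_cands - ov))]
  bad <- integer(0)
  s1 <- NA_integer_; ov_left <- NA_integer_
  for (o in ov_cands) {
    cand <- left$end - o + 1L
    w1 <- substr(gb, cand, cand + anneal_len - 1L)
    if (.unique_window(gb, w1) && fwd_ctx_clean(cand) &&
        .context_site_count(.left_tail_context(genome, cand, default_anchors()),
                            enzyme("NotI")) == 1L) {
      s1 <- cand; ov_left <- o; break
    }
  }
  if (is.na(s1)) bad <- c(bad, 0L)
  en <- NA_integer_; ov_right <- NA_integer_
  last_site <- enzyme(release_enzymes[[n %/% 2L]][2])
  for (o in ov_cands) {
    cand <- right$start + o - 1L
    wn <- substr(gb, cand - anneal_len + 1L, cand)
    if (.unique_window(gb, wn) && rev_ctx_clean(cand, last_site) &&
        .context_site_count(.right_tail_context(genome, cand,
                                                last_site$recognition,
                                                default_anchors()),
                            last_site) == 1L) {
      en <- cand; ov_right <- o; break
    }
  }
  if (is.na(en)) bad <- c(bad, n)
  if (length(bad) > 0L)
    stop("planning error: no feasible boundary near junction(s) ",
         paste(sort(unique(bad)), collapse = ", "))

  total <- en - s1 + 1L
  ends <- integer(n)
  starts <- integer(n)
  starts[1] <- s1
  for (i in seq_len(n)) {
    ideal <- if (i == n) en else s1 - 1L + as.integer(round(i * total / n))
    if (i == n) {
      ends[i] <- en
    } else {
      found <- NA_integer_
      for (delta in order(abs(seq(-search_window, search_window)))) {
        cand <- ideal + seq(-search_window, search_window)[delta]
        if (ok_boundary(cand, i)) { found <- cand; break }
      }
      if (is.na(found)) { bad <- c(bad, i); ends[i] <- ideal }
      else ends[i] <- found
    }
    if (i < n) starts[i + 1L] <- ends[i] - ov + 1L
  }
  if (length(bad) > 0L)
    stop("planning error: no feasible boundary near junction(s) ",
         paste(sort(unique(bad)), collapse = ", "))

  pairings <- lapply(seq_len(n %/% 2L), function(k) c(2L * k - 1L, 2L * k))
  # no release enzyme may cut inside its own released insert
  offenders <- character(0)
  for (k in seq_along(pairings)) {
    ins <- substr(gb, starts[pairings[[k]][1]], ends[pairings[[k]][2]])
    for (en_name in release_enzymes[[k]]) {
      if (nrow(find_sites(nuc_seq("ins", ins), en_name)) > 0L)
        offenders <- c(offenders, sprintf("pairing %d: %s cuts inside insert",
                                          k, en_name))
    }
  }
  if (length(offenders) > 0L)
    stop("planning error: ", paste(offenders, collapse = "; "))

  lens <- ends - starts + 1L
  if ((max(lens) - min(lens)) / max(lens) > 0.10)
    stop("planning error: fragment length spread exceeds 10%")

  structure(list(
    left_arm = left, right_arm = right,
    fragments = lapply(seq_len(n), function(i) span(starts[i], ends[i])),
    pairings = pairings,
    release_enzymes = release_enzymes,
    junction_overlaps = rep(ov, n - 1L),
    arm_overlaps = c(ov_left, ov_right),
    junction_overlap_range = as.integer(overlap_range),
    vector_cut_enzymes = c("NotI", "SbfI"),
    target_len = target_len,
    anneal_len = as.integer(anneal_len),
    genome_id = genome$id, genome_length = L),
    class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("<partition_plan> %s (%d bp): %d fragments\n", x$genome_id,
              x$genome_length, length(x$fragments)))
  for (i in seq_along(x$fragments)) {
    f <- x$fragments[[i]]
    cat(sprintf("  fragment %d: %d..%d (%d bp)\n", i, f$start, f$end,
                f$end - f$start + 1L))
  }
  cat("  junction overlaps:", paste(x$junction_overlaps, collapse = ", "), "bp\n")
  invisible(x)
}

.extend_for_tm <- function(window_fn, min_len, max_len, tm_floor) {
  k <- min_len
  while (k < max_len && tm(window_fn(k)) < tm_floor) k <- k + 1L
  k
}

#' Design the primer set for a partition plan
#'
#' Vector-adjacent primers (outer ends of each fragment pairing) are
#' anchor + restriction-site tail + genomic anneal; the forward tail is the
#' NotI recognition fused with the anchor's terminal GC, the reverse tail is
#' the pairing's release enzyme. Internal-junction primers are fully genomic.
#' Anneal length starts at `anneal_len` and extends (up to `max_anneal`) until
#' the anneal Tm reaches `tm_floor`. Every anneal window must match the genome
#' uniquely.
#'
#' @param genome Linear [nuc_seq()].
#' @param plan A [plan_partition()] result.
#' @param anchors An [default_anchors()] pair.
#' @param anneal_len,max_anneal Anneal length bounds.
#' @param tm_floor Anneal Tm floor (deg C) under [tm()].
#' @param prefix Primer name prefix.
#' @return List of `primer_spec` objects (fwd/rev per fragment, in order).
#' @export
design_primer_pairs <- function(genome, plan, anchors = default_anchors(),
                                anneal_len = NULL, max_anneal = 35L,
                                tm_floor = 58, prefix = "ADV") {
  stopifnot(inherits(plan, "partition_plan"))
  if (is.null(anneal_len)) anneal_len <- plan$anneal_len
  gb <- genome$bases
  n <- length(plan$fragments)
  out <- list()
  for (i in seq_len(n)) {
    f <- plan$fragments[[i]]
    pair_of <- (i + 1L) %/% 2L
    # forward primer
    fwd_win <- function(k) substr(gb, f$start, f$start + k - 1L)
    kf <- .extend_for_tm(fwd_win, anneal_len, max_anneal, tm_floor)
    fwd_anneal <- fwd_win(kf)
    if (!.unique_window(gb, fwd_anneal))
      stop("design error: non-unique forward anneal at junction ", i - 1L)
    if (i %% 2L == 1L) {
      bases <- paste0(anchors$upstream, "GGCCGC", fwd_anneal)
      fwd <- .primer_spec(sprintf("%s-%d-F", prefix, i), bases,
                          "vector_adjacent_fwd",
                          anchor = c(1L, 25L),
                          re = list(name = "NotI", span = c(24L, 31L)),
                          anneal = span(f$start, f$start + kf - 1L, "+"),
                          anneal_bases = fwd_anneal)
    } else {
      fwd <- .primer_spec(sprintf("%s-%d-F", prefix, i), fwd_anneal,
                          "internal_fwd",
                          anneal = span(f$start, f$start + kf - 1L, "+"),
                          anneal_bases = fwd_anneal)
    }
    # reverse primer
    rev_win <- function(k) substr(gb, f$end - k + 1L, f$end)
    kr <- .extend_for_tm(rev_win, anneal_len, max_anneal, tm_floor)
    rev_anneal_top <- rev_win(kr)
    if (!.unique_window(gb, rev_anneal_top))
      stop("design error: non-unique reverse anneal at junction ", i)
    if (i %% 2L == 0L) {
      site <- enzyme(plan$release_enzymes[[pair_of]][2])
      bases <- paste0(revcomp(anchors$downstream), site$recognition,
                      revcomp(rev_anneal_top))
      rev <- .primer_spec(sprintf("%s-%d-R", prefix, i), bases,
                          "vector_adjacent_rev",
                          anchor = c(1L, 25L),
                          re = list(name = site$name,
                                    span = c(26L, 25L + nchar(site$recognition))),
                          anneal = span(f$end - kr + 1L, f$end, "-"),
                          anneal_bases = revcomp(rev_anneal_top))
    } else {
      rev <- .primer_spec(sprintf("%s-%d-R", prefix, i), revcomp(rev_anneal_top),
                          "internal_rev",
                          anneal = span(f$end - kr + 1L, f$end, "-"),
                          anneal_bases = revcomp(rev_anneal_top))
    }
    out[[length(out) + 1L]] <- fwd
    out[[length(out) + 1L]] <- rev
  }
  # verify implied junction overlaps land in range
  rng <- plan$junction_overlap_range
  for (i in seq_len(n - 1L)) {
    if (i %% 2L == 1L) {  # internal (within-pair) junction: both primers genomic
      got <- junction_overlap(out[[2L * i]], out[[2L * i + 1L]])
      if (got < rng[1] || got > rng[2])
        stop("design error: junction ", i, " overlap ", got, " outside range")
    }
  }
  out
}

#' Parse a primer into its grammar components
#'
#' Identifies (in order) a 25-nt vector anchor (upstream anchor or reverse
#' complement of the downstream anchor), a restriction recognition at or
#' overlapping the anchor boundary (fusion overlap of up to 2 nt allowed), an
#' optional pad + type IIS tail for anchor-free tailed primers, and the
#' remaining 3' portion as the anneal. Given a genome, the anneal is located
#' by the longest unique exact 3'-terminal match (minimum `min_anneal`).
#'
#' @param primer Base string or `primer_spec`.
#' @param anchors An [default_anchors()] pair.
#' @param enzymes Enzyme table (data.frame) to consider for the tail.
#' @param genome Optional [nuc_seq()] for anneal resolution.
#' @param min_anneal Minimum 3'-terminal match length.
#' @return A list decomposition: `anchor_side`, `anchor_span`, `re`,
#'   `anneal_start` (position in primer), plus `anneal_span`/`anneal_strand`
#'   when a genome is given.
#' @export
parse_primer <- function(primer, anchors = default_anchors(),
                         enzymes = load_enzymes(), genome = NULL,
                         min_anneal = 15L) {
  bases <- if (inherits(primer, "primer_spec")) primer$bases else .norm_bases(primer)
  if (nchar(bases) < 15L) stop("primer too short to parse (< 15 nt)")
  anchor_side <- NULL; anchor_span <- NULL
  if (.lcp(bases, anchors$upstream) == 25L) {
    anchor_side <- "upstream"; anchor_span <- c(1L, 25L)
  } else if (.lcp(bases, revcomp(anchors$downstream)) == 25L) {
    anchor_side <- "downstream_rc"; anchor_span <- c(1L, 25L)
  }
  re <- NULL
  lo <- if (is.null(anchor_span)) 1L else anchor_span[2] - 1L
  hi <- if (is.null(anchor_span)) 8L else anchor_span[2] + 1L
  for (i in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[i]
    m <- regexpr(rec, bases, fixed = TRUE)[1]
    if (m >= lo && m <= hi) {
      cand <- list(name = enzymes$name[i], span = c(m, m + nchar(rec) - 1L))
      if (is.null(re) || cand$span[1] < re$span[1] ||
          (cand$span[1] == re$span[1] && diff(cand$span) > diff(re$span)))
        re <- cand
      }
  }
  anneal_start <- if (!is.null(re)) re$span[2] + 1L
                  else if (!is.null(anchor_span)) anchor_span[2] + 1L else 1L
  role <- if (!is.null(anchor_side) && identical(re$name, "NotI")) "vector_adjacent_fwd"
    else if (identical(anchor_side, "downstream_rc")) "vector_adjacent_rev"
    else if (!is.null(anchor_side)) "vector_adjacent_fwd"
    else if (identical(re$name, "SapI")) "deletion"
    else if (!is.null(re)) "subclone"
    else "internal"
  out <- list(bases = bases, anchor_side = anchor_side,
              anchor_span = anchor_span, re = re,
              anneal_start = anneal_start,
              anneal_len = nchar(bases) - anneal_start + 1L, role = role)
  if (!is.null(genome)) {
    gb <- genome$bases
    np <- nchar(bases)
    best_k <- 0L; best_n <- 0L; best_strand <- NA; best_pos <- NA_integer_
    for (k in seq(np, min_anneal)) {
      w <- substr(bases, np - k + 1L, np)
      nf <- .match_starts(w, gb); nr <- .match_starts(revcomp(w), gb)
      tot <- length(nf) + length(nr)
      if (tot >= 1L) {
        best_k <- k; best_n <- tot
        if (length(nf) == 1L && length(nr) == 0L) {
          best_strand <- "+"; best_pos <- nf[1]
        } else if (length(nr) == 1L && length(nf) == 0L) {
          best_strand <- "-"; best_pos <- nr[1]
        }
        break
      }
    }
    if (best_k < min_anneal || best_n == 0L)
      stop("resolution error: no 3'-terminal genome match of >= ", min_anneal, " nt")
    if (best_n > 1L)
      stop("resolution error: 3'-terminal match is not unique (", best_n, " hits)")
    out$anneal_span <- if (best_strand == "+")
      span(best_pos, best_pos + best_k - 1L, "+")
    else span(best_pos, best_pos + best_k - 1L, "-")
    out$anneal_match_len <- best_k
  }
  out
}

#' Design outward-facing deletion/replacement primers
#'
#' Builds the inverse-PCR primer pair that deletes `delete_span` from a
#' circular plasmid and leaves cassette-matching tails for overlap assembly.
#' Each primer is a 4-nt pad, the type IIS recognition (default SapI), one
#' spacer base (so the type IIS cut releases the pad exactly at the tail
#' start), a cassette-end-matching tail, and a genomic anneal.
#'
#' @param plasmid Circular [nuc_seq()].
#' @param delete_span [span()] to remove.
#' @param cassette_ends Length-2 character: the cassette's leading and
#'   trailing terminal sequences (>= 15 nt each, typically 24).
#' @param tail_enzyme Type IIS enzyme for the tails (default `"SapI"`).
#' @param pad 4-nt pad 5' of the recognition.
#' @param anneal_len,max_anneal,tm_floor Anneal sizing as in
#'   [design_primer_pairs()].
#' @return List of two `primer_spec`s (`deletion_fwd`, `deletion_rev`).
#' @export
design_deletion_primers <- function(plasmid, delete_span, cassette_ends,
                                    tail_enzyme = "SapI", pad = "ATCG",
                                    anneal_len = 25L, max_anneal = 35L,
                                    tm_floor = 58) {
  stopifnot(inherits(plasmid, "nucseq"), plasmid$topology == "circular")
  .check_span(delete_span, plasmid)
  head_tail <- .norm_bases(cassette_ends[[1]]); tail_tail <- .norm_bases(cassette_ends[[2]])
  if (nchar(head_tail) < 15L || nchar(tail_tail) < 15L)
    stop("cassette end tails must be >= 15 nt")
  enz <- enzyme(tail_enzyme)
  L <- nchar(plasmid$bases)
  gsub_idx <- function(p) ((p - 1L) %% L) + 1L
  # forward primer anneals immediately downstream of the deletion
  f_start <- gsub_idx(delete_span$end + 1L)
  fwd_win <- function(k) subseq(plasmid, span(f_start, gsub_idx(f_start + k - 1L), "+"))
  kf <- .extend_for_tm(fwd_win, anneal_len, max_anneal, tm_floor)
  f_anneal <- fwd_win(kf)
  # reverse primer anneals immediately upstream, on the bottom strand
  r_end <- gsub_idx(delete_span$start - 1L)
  rev_win <- function(k) subseq(plasmid, span(gsub_idx(r_end - k + 1L), r_end, "+"))
  kr <- .extend_for_tm(rev_win, anneal_len, max_anneal, tm_floor)
  r_anneal_top <- rev_win(kr)
  if (!.unique_window(plasmid$bases, f_anneal) ||
      !.unique_window(plasmid$bases, r_anneal_top))
    stop("design error: deletion-primer anneal not unique on plasmid")
  spacer <- "A"
  fwd <- .primer_spec("DEL-F",
                      paste0(pad, enz$recognition, spacer, tail_tail, f_anneal),
                      "deletion_fwd",
                      re = list(name = enz$name,
                                span = c(nchar(pad) + 1L,
                                         nchar(pad) + nchar(enz$recognition))),
                      cassette_tail = tail_tail,
                      anneal = span(f_start, gsub_idx(f_start + kf - 1L), "+"),
                      anneal_bases = f_anneal)
  rev <- .primer_spec("DEL-R",
                      paste0(pad, enz$recognition, spacer, revcomp(head_tail),
                             revcomp(r_anneal_top)),
                      "deletion_rev",
                      re = list(name = enz$name,
                                span = c(nchar(pad) + 1L,
                                         nchar(pad) + nchar(enz$recognition))),
                      cassette_tail = revcomp(head_tail),
                      anneal = span(gsub_idx(r_end - kr + 1L), r_end, "-"),
                      anneal_bases = revcomp(r_anneal_top))
  list(fwd, rev)
}

#' Pad + site + anneal subcloning primers for a single fragment
#'
#' Used when one genomic fragment is cloned on its own through restriction
#' digestion and ligation rather than overlap assembly: a short pad, the full
#' recognition sequence, then the genomic anneal.
#'
#' @param genome Linear [nuc_seq()].
#' @param frag A [span()] for the fragment.
#' @param fwd_enzyme,rev_enzyme Recognition carried by each primer.
#' @param fwd_pad,rev_pad 6-nt pads.
#' @param anneal_len,max_anneal,tm_floor Anneal sizing.
#' @return List of two `primer_spec`s (`subclone_fwd`, `subclone_rev`).
#' @export
design_subclone_primers <- function(genome, frag, fwd_enzyme = "NotI",
                                    rev_enzyme = "SrfI", fwd_pad = "CGATAA",
                                    rev_pad = "AATAGC", anneal_len = 25L,
                                    max_anneal = 35L, tm_floor = 58) {
  gb <- genome$bases
  fe <- enzyme(fwd_enzyme); re_ <- enzyme(rev_enzyme)
  fwd_win <- function(k) substr(gb, frag$start, frag$start + k - 1L)
  kf <- .extend_for_tm(fwd_win, anneal_len, max_anneal, tm_floor)
  rev_win <- function(k) substr(gb, frag$end - k + 1L, frag$end)
  kr <- .extend_for_tm(rev_win, anneal_len, max_anneal, tm_floor)
  if (!.unique_window(gb, fwd_win(kf)) || !.unique_window(gb, rev_win(kr)))
    stop("design error: subclone anneal not unique")
  list(
    .primer_spec("SUB-F", paste0(fwd_pad, fe$recognition, fwd_win(kf)),
                 "subclone_fwd",
                 re = list(name = fe$name,
                           span = c(nchar(fwd_pad) + 1L,
                                    nchar(fwd_pad) + nchar(fe$recognition))),
                 anneal = span(frag$start, frag$start + kf - 1L, "+"),
                 anneal_bases = fwd_win(kf)),
    .primer_spec("SUB-R", paste0(rev_pad, re_$recognition, revcomp(rev_win(kr))),
                 "subclone_rev",
                 re = list(name = re_$name,
                           span = c(nchar(rev_pad) + 1L,
                                    nchar(rev_pad) + nchar(re_$recognition))),
                 anneal = span(frag$end - kr + 1L, frag$end, "-"),
                 anneal_bases = revcomp(rev_win(kr))))
}

#' Validate a primer set against its plan and genome
#'
#' Pre-flight QC: per-junction overlap inside the plan's window, anchor
#' integrity (LCP exactly 25), expected restriction tails present, anneal
#' uniqueness on the genome, and the Tm spread across anneals. Overall PASS
#' iff every check passes.
#'
#' @param genome Linear [nuc_seq()].
#' @param primers Primer list from [design_primer_pairs()] (or parsed
#'   equivalents; fwd/rev per fragment in order).
#' @param plan A [plan_partition()] result.
#' @param anchors An [default_anchors()] pair.
#' @return data.frame of checks with attribute `pass`; class `plan_validation`.
#' @export
validate_plan <- function(genome, primers, plan, anchors = default_anchors()) {
  n <- length(plan$fragments)
  stopifnot(length(primers) == 2L * n)
  rows <- list()
  add <- function(check, subject, value, pass)
    rows[[length(rows) + 1L]] <<- data.frame(check = check, subject = subject,
                                             value = as.character(value),
                                             pass = pass, stringsAsFactors = FALSE)
  bases_of <- function(p) if (inherits(p, "primer_spec")) p$bases else p
  name_of <- function(p, d) if (inherits(p, "primer_spec")) p$name else d
  rng <- plan$junction_overlap_range
  for (i in seq_len(n - 1L)) {
    if (i %% 2L == 1L) {
      ovl <- tryCatch(junction_overlap(bases_of(primers[[2L * i]]),
                                       bases_of(primers[[2L * i + 1L]])),
                      error = function(e) NA_integer_)
      add("junction_overlap", sprintf("junction %d-%d", i, i + 1L), ovl,
          !is.na(ovl) && ovl >= rng[1] && ovl <= rng[2])
    }
  }
  for (i in seq_len(n)) {
    fwd <- primers[[2L * i - 1L]]; rev <- primers[[2L * i]]
    if (i %% 2L == 1L) {
      lcp <- .lcp(bases_of(fwd), anchors$upstream)
      add("anchor", name_of(fwd, sprintf("fwd %d", i)), lcp, lcp == 25L)
      has_site <- grepl("GCGGCCGC", bases_of(fwd), fixed = TRUE)
      add("re_site", name_of(fwd, sprintf("fwd %d", i)), "NotI", has_site)
    } else {
      lcp <- .lcp(bases_of(rev), revcomp(anchors$downstream))
      add("anchor", name_of(rev, sprintf("rev %d", i)), lcp, lcp == 25L)
      site <- enzyme(plan$release_enzymes[[i %/% 2L]][2])
      has_site <- grepl(site$recognition, bases_of(rev), fixed = TRUE)
      add("re_site", name_of(rev, sprintf("rev %d", i)), site$name, has_site)
    }
    for (p in list(fwd, rev)) {
      dec <- tryCatch(parse_primer(bases_of(p), anchors, genome = genome),
                      error = function(e) NULL)
      add("anneal_unique", name_of(p, sprintf("primer %d", i)),
          if (is.null(dec)) "unresolved" else dec$anneal_match_len,
          !is.null(dec))
    }
  }
  tms <- vapply(primers, function(p) {
    dec <- parse_primer(bases_of(p), anchors)
    tm(substr(bases_of(p), dec$anneal_start, nchar(bases_of(p))))
  }, numeric(1))
  # reported for inspection; the grammar defines no hard spread bound, and
  # extension already pushes each anneal toward the Tm floor
  spread <- max(tms) - min(tms)
  add("tm_spread", "all anneals", sprintf("%.1f", spread), TRUE)
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("plan_validation", "data.frame")
  out
}

#' @export
print.plan_validation <- function(x, ...) {
  cat(sprintf("Plan validation: %s\n",
              if (attr(x, "pass")) "PASS" else "FAIL"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read / write primers as TSV
#'
#' @param path TSV with columns `name`, `sequence`, and optionally `role`.
#' @return List of `primer_spec`s.
#' @export
read_primers <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "sequence") %in% names(tab)))
    stop("primer TSV needs columns: name, sequence")
  lapply(seq_len(nrow(tab)), function(i)
    .primer_spec(tab$name[i], .norm_bases(tab$sequence[i]),
                 if ("role" %in% names(tab)) tab$role[i] else "internal"))
}

#' @rdname read_primers
#' @param primers List of `primer_spec`s.
#' @export
write_primers <- function(primers, path) {
  tab <- data.frame(name = vapply(primers, `[[`, character(1), "name"),
                    sequence = vapply(primers, `[[`, character(1), "bases"),
                    role = vapply(primers, `[[`, character(1), "role"),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
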