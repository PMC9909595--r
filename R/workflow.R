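# Full reconstruction workflow: backbone engineering, the arm-carrying
# acceptor plasmid, paired-fragment intermediates, E3 replacement by a
# reporter cassette, release digests, final isothermal reassembly, rescue
# linearization and verification.

#' Swap a backbone interval for a multiple cloning site
#'
#' Replaces `replace_span` of a circular backbone with the 64-nt MCS so the
#' product carries single NotI and SbfI sites (plus a single SrfI site) for
#' the downstream cloning steps.
#'
#' @param pbr322 Circular `nucseq` backbone.
#' @param replace_span [span()] to replace (default 3..973).
#' @param mcs Replacement sequence (default: the packaged 64-mer).
#' @return Circular `nucseq` with an annotated MCS.
#' @export
build_backbone <- function(pbr322, replace_span = span(3L, 973L), mcs = .MCS) {
  stopifnot(inherits(pbr322, "nucseq"), pbr322$topology == "circular")
  if (replace_span$start > replace_span$end)
    stop("coordinate error: reversed replace_span")
  .check_span(replace_span, pbr322)
  b <- pbr322$bases
  out <- paste0(substr(b, 1L, replace_span$start - 1L), mcs,
                substr(b, replace_span$end + 1L, nchar(b)))
  res <- nuc_seq("backbone", out, "circular", features = list(
    feature("MCS", span(replace_span$start,
                        replace_span$start + nchar(mcs) - 1L), "MCS")))
  for (nm in c("NotI", "SbfI", "SrfI")) {
    k <- nrow(find_sites(res, nm))
    if (k != 1L)
      stop("conflict error: ", nm, " cuts the backbone ", k, " times (need 1)")
  }
  res
}

# Fixed spacers of the arm-carrying plasmid; constants validated in the
# package's own tests against the whole workflow enzyme set. The spacer after
# the left arm must not begin with any proper suffix of a workflow recognition
# pattern, or an unlucky arm terminus could complete a site across the
# junction ("GTGT" extends no such suffix).
.LR_SP4 <- "GTGT"    # between left-arm end and the left type IIS site
.LR_SP1 <- "A"       # between the right type IIS site and the right arm
.LR_STUFFER <- "TGACCTAGACCTGAACCAGT"

#' Build the arm-carrying acceptor plasmid
#'
#' Inserts, between the backbone's NotI and SrfI cut positions:
#' `NotI -- PmeI -- left arm -- SapI> (stuffer) <SapI -- right arm -- PmeI --
#' SrfI`. The two SapI sites point outward into the stuffer so that SapI
#' linearization drops the stuffer and exposes the arm termini scar-free on
#' the top strand; the two PmeI sites later release the reassembled genome
#' with 4-nt terminal scars.
#'
#' @param backbone Product of [build_backbone()].
#' @param left_arm,right_arm Arm base strings (or `nucseq`).
#' @param stuffer Stuffer core between the two SapI sites.
#' @return Circular `nucseq` (the acceptor, analogous to an LR plasmid) with
#'   annotated features.
#' @export
build_pbr322lr <- function(backbone, left_arm, right_arm,
                           stuffer = .LR_STUFFER) {
  la <- .norm_bases(.bases_of(left_arm), what = "left arm")
  ra <- .norm_bases(.bases_of(right_arm), what = "right arm")
  for (nm in c("SapI", "PmeI", "NotI", "SrfI")) {
    for (arm in c(la, ra)) {
      if (nrow(find_sites(nuc_seq("arm", arm), nm)) > 0L)
        stop("conflict error: arm sequence contains a ", nm, " site")
    }
  }
  np <- find_sites(backbone, "NotI")$position[1]
  sp <- find_sites(backbone, "SrfI")$position[1]
  not_cut <- np + 1L   # GC^GGCCGC
  srf_cut <- sp + 3L   # GCCC^GGGC
  if (not_cut >= srf_cut) stop("conflict error: unexpected backbone layout")
  sap <- enzyme("SapI")$recognition            # GCTCTTC
  insert <- paste0("GGCCGC", "GTTTAAAC", la, .LR_SP4, revcomp(sap),
                   stuffer, sap, .LR_SP1, ra, "GTTTAAAC", "GCCC")
  b <- backbone$bases
  out <- paste0(substr(b, 1L, not_cut), insert,
                substr(b, srf_cut + 1L, nchar(b)))
  la_start <- not_cut + 6L + 8L + 1L
  ra_start <- la_start + nchar(la) + nchar(.LR_SP4) + 7L + nchar(stuffer) +
    7L + nchar(.LR_SP1)
  res <- nuc_seq("pBR322LR", out, "circular", features = list(
    feature("left_arm", span(la_start, la_start + nchar(la) - 1L), "arm"),
    feature("stuffer",
            span(la_start + nchar(la), ra_start - 1L), "stuffer"),
    feature("right_arm", span(ra_start, ra_start + nchar(ra) - 1L), "arm")))
  if (nrow(find_sites(res, "SapI")) != 2L)
    stop("conflict error: acceptor must carry exactly 2 SapI sites")
  if (nrow(find_sites(res, "PmeI")) != 2L)
    stop("conflict error: acceptor must carry exactly 2 PmeI sites")
  res
}

#' Amplify fragment pairs and assemble the intermediate plasmids
#'
#' For each fragment pairing: PCR both fragments with their designed primers,
#' then assemble the two amplicons with the NotI/SbfI-linearized backbone into
#' a circular intermediate. Each intermediate must be cut exactly once by each
#' of its release enzymes.
#'
#' @param genome Linear `nucseq`.
#' @param plan A [plan_partition()] result.
#' @param primers Primer list from [design_primer_pairs()].
#' @param backbone Product of [build_backbone()].
#' @param amplicon_overrides Named list (fragment index as name) of
#'   pre-made amplicons substituted for the plain genomic amplicon (used for
#'   the cassette-carrying fragment).
#' @return List with `intermediates` (assembly products) and `amplicons`.
#' @export
build_intermediates <- function(genome, plan, primers, backbone,
                                amplicon_overrides = list()) {
  frags <- digest(backbone, plan$vector_cut_enzymes)
  if (length(frags) != 2L)
    stop("release-site multiplicity error: backbone linearization yielded ",
         length(frags), " fragments")
  vec <- select_fragment(frags, "largest")
  vec_seq <- nuc_seq("backbone_linear", vec$bases, "linear")
  amplicons <- list()
  intermediates <- list()
  for (k in seq_along(plan$pairings)) {
    idx <- plan$pairings[[k]]
    amps <- lapply(idx, function(i) {
      ov <- amplicon_overrides[[as.character(i)]]
      if (!is.null(ov)) return(ov)
      pcr(genome, primers[[2L * i - 1L]], primers[[2L * i]],
          id = sprintf("amplicon_%d", i))
    })
    amplicons[c(idx)] <- amps
    prod <- gibson(c(list(vec_seq), amps), expect = "circular",
                   id = sprintf("intermediate_%d_%d", idx[1], idx[2]))
    for (nm in plan$release_enzymes[[k]]) {
      cnt <- nrow(find_sites(prod$seq, nm))
      if (cnt != 1L)
        stop("release-site multiplicity error: ", nm, " cuts intermediate ",
             k, " ", cnt, " times")
    }
    intermediates[[k]] <- prod
  }
  list(intermediates = intermediates, amplicons = amplicons)
}

#' Clone a single fragment by restriction digestion and ligation
#'
#' Amplifies one fragment with pad + site + anneal subcloning primers, digests
#' the amplicon with both enzymes, and ligates the released insert into the
#' backbone cut with the same enzymes (asymmetric ends force the
#' orientation).
#'
#' @param genome Linear `nucseq`.
#' @param frag [span()] of the fragment.
#' @param backbone Product of [build_backbone()].
#' @param sub_primers Optional primer pair (defaults to
#'   [design_subclone_primers()] with NotI/SrfI).
#' @param id Product id.
#' @return Circular `nucseq` (the single-fragment clone) re-oriented so the
#'   genomic insert runs forward.
#' @export
subclone_fragment <- function(genome, frag, backbone, sub_primers = NULL,
                              id = "pBR322-5") {
  if (is.null(sub_primers))
    sub_primers <- design_subclone_primers(genome, frag)
  amp <- pcr(genome, sub_primers[[1]], sub_primers[[2]], id = paste0(id, "_amp"))
  enzs <- c(sub_primers[[1]]$re$name, sub_primers[[2]]$re$name)
  ins <- select_fragment(digest(amp, enzs), "largest")
  vec <- select_fragment(digest(backbone, enzs), "largest")
  prod <- ligate(list(vec, ins), circularize = TRUE, allow_blunt = TRUE,
                 id = id)[[1]]
  .orient_forward(prod, subseq(genome, span(frag$start,
                                            min(frag$start + 49L, frag$end))))
}

# rotate/flip a circular plasmid so `probe` appears on the forward strand
.orient_forward <- function(plasmid, probe) {
  dd <- paste0(plasmid$bases, substr(plasmid$bases, 1L, nchar(probe)))
  if (length(.match_starts(probe, dd)) > 0L) return(plasmid)
  flipped <- nuc_seq(plasmid$id, revcomp(plasmid$bases), plasmid$topology)
  dd <- paste0(flipped$bases, substr(flipped$bases, 1L, nchar(probe)))
  if (length(.match_starts(probe, dd)) == 0L)
    stop("orientation probe not found on either strand")
  flipped
}

#' Replace a deleted interval with a reporter cassette
#'
#' Inverse PCR with the outward deletion primers removes the interval; the
#' type IIS tails are then cut off the amplicon so its termini begin exactly
#' at the cassette-matching tails, and the released cassette is assembled in
#' by overlap. The product is the input plasmid with the interval replaced
#' base-exactly by the cassette.
#'
#' @param plasmid Circular `nucseq` carrying the interval (e.g. the
#'   fragment-5 clone).
#' @param cassette Released cassette (linear `nucseq`, e.g. from
#'   [release_cassette()]).
#' @param deletion_primers Pair from [design_deletion_primers()].
#' @param id Product id.
#' @return Circular `nucseq` (e.g. the 5LG plasmid).
#' @export
replace_e3 <- function(plasmid, cassette, deletion_primers, id = "pBR322-5LG") {
  amp <- pcr(plasmid, deletion_primers[[1]], deletion_primers[[2]],
             id = "inverse_pcr")
  tail_enz <- deletion_primers[[1]]$re$name
  if (!is.null(tail_enz) && nrow(find_sites(amp, tail_enz)) > 0L) {
    amp <- select_fragment(digest(amp, tail_enz), "largest")
  }
  prod <- gibson(list(amp, cassette), expect = "circular", id = id)
  .orient_forward(nuc_seq(id, prod$seq$bases, "circular"),
                  substr(cassette$bases, 1L, 50L))
}

#' Release the inserts and reassemble the full genome plasmid
#'
#' Digests each intermediate with its release-enzyme pair (keeping the
#' insert), linearizes the acceptor with SapI (dropping the stuffer), and
#' assembles the four pieces into the single circular genome plasmid.
#'
#' @param pbr322lr Product of [build_pbr322lr()].
#' @param intermediates List of intermediate assembly products (or plasmids).
#' @param release_enzymes List of enzyme-name pairs, one per intermediate.
#' @param min_overlap Assembly overlap floor.
#' @return An `assembly_product` with exactly `length(intermediates) + 1`
#'   participants.
#' @export
final_assembly <- function(pbr322lr, intermediates, release_enzymes,
                           min_overlap = 15L) {
  inserts <- lapply(seq_along(intermediates), function(k) {
    pl <- intermediates[[k]]
    if (inherits(pl, "assembly_product")) pl <- pl$seq
    frags <- digest(pl, release_enzymes[[k]])
    if (length(frags) != 2L)
      stop("release digest of intermediate ", k, " yielded ", length(frags),
           " fragments (need 2)")
    ins <- select_fragment(frags, "largest")
    nuc_seq(sprintf("insert_%d", k), ins$bases, "linear")
  })
  lr_piece <- linearize(pbr322lr, "SapI", keep = "largest")
  lr_seq <- nuc_seq("pBR322LR_linear", lr_piece$bases, "linear")
  prod <- gibson(c(list(lr_seq), inserts), expect = "circular",
                 min_overlap = min_overlap, id = "pBR322-rAdV")
  if (any(prod$junctions$overlap_bp < min_overlap))
    stop("assembly junction below the overlap floor")
  prod
}

#' Rescue-linearize the final plasmid
#'
#' Cuts at the two terminal-enzyme sites flanking the genome and keeps the
#' genome fragment (the one containing the cassette probe). The released
#' genome retains at most 4 nt of enzyme scar outside each terminus; with the
#' blunt terminal cutter the two scars are reverse complements, so the
#' inverted-terminal-repeat property survives.
#'
#' @param final_plasmid Circular `nucseq` (or `assembly_product`).
#' @param terminal_enzyme The terminal cutter (default PmeI).
#' @param cassette_probe Subsequence identifying the genome fragment.
#' @return Linear `nucseq`: the rescued genome.
#' @export
rescue_linearize <- function(final_plasmid, terminal_enzyme = "PmeI",
                             cassette_probe) {
  if (inherits(final_plasmid, "assembly_product")) final_plasmid <- final_plasmid$seq
  k <- nrow(find_sites(final_plasmid, terminal_enzyme))
  if (k != 2L)
    stop("configuration error: ", enzyme(terminal_enzyme)$name, " cuts ", k,
         " times (need exactly 2)")
  frags <- digest(final_plasmid, list(terminal_enzyme))
  gf <- select_fragment(frags, list(contains = cassette_probe))
  nuc_seq("rescued_genome", gf$bases, "linear")
}

#' Verify a reconstructed genome against its wildtype
#'
#' PASS iff the rescued linear genome equals the wildtype with `e3_span`
#' excised and the cassette inserted, allowing at most `max_scar` documented
#' scar bases outside each terminus; either strand orientation is accepted.
#' On failure the report carries the first-divergence coordinate and, when
#' the mismatch is explained by a flipped cassette, an orientation diagnostic.
#'
#' @param linear_genome Rescued linear `nucseq`.
#' @param wildtype Wildtype linear `nucseq`.
#' @param e3_span Deleted [span()] in wildtype coordinates.
#' @param cassette Released cassette (`nucseq` or bases).
#' @param max_scar Maximum terminal scar (nt).
#' @param digest_enzymes Optional enzyme names for a diagnostic digest table.
#' @return A `reconstruction_report`.
#' @export
verify_reconstruction <- function(linear_genome, wildtype, e3_span, cassette,
                                  max_scar = 4L, digest_enzymes = NULL) {
  cas <- .bases_of(cassette)
  wt <- wildtype$bases
  expected <- paste0(substr(wt, 1L, e3_span$start - 1L), cas,
                     substr(wt, e3_span$end + 1L, nchar(wt)))
  test_one <- function(g) {
    diffn <- nchar(g) - nchar(expected)
    if (diffn < 0L || diffn > 2L * max_scar) return(NULL)
    for (i in max(0L, diffn - max_scar):min(max_scar, diffn)) {
      if (substr(g, i + 1L, i + nchar(expected)) == expected)
        return(list(left_scar = i, right_scar = diffn - i))
    }
    NULL
  }
  hit <- test_one(linear_genome$bases)
  orientation <- "forward"
  if (is.null(hit)) {
    hit <- test_one(revcomp(linear_genome$bases))
    orientation <- "reverse"
  }
  pass <- !is.null(hit)
  first_div <- NA_integer_
  cassette_flip <- FALSE
  if (!pass) {
    g <- linear_genome$bases
    n <- min(nchar(g), nchar(expected))
    first_div <- .lcp(g, expected) + 1L
    alt <- paste0(substr(wt, 1L, e3_span$start - 1L), revcomp(cas),
                  substr(wt, e3_span$end + 1L, nchar(wt)))
    cassette_flip <- grepl(alt, g, fixed = TRUE) ||
      grepl(alt, revcomp(g), fixed = TRUE)
    if (first_div > n) first_div <- n
  }
  cassette_at <- if (pass)
    regexpr(cas, if (orientation == "forward") linear_genome$bases
            else revcomp(linear_genome$bases), fixed = TRUE)[1]
  else NA_integer_
  regions <- data.frame(
    region = c("upstream_of_E3", "cassette", "downstream_of_E3"),
    identical = if (pass) c(TRUE, TRUE, TRUE) else rep(NA, 3))
  dt <- if (!is.null(digest_enzymes)) digest_report(linear_genome, digest_enzymes)
  structure(list(pass = pass,
                 orientation = orientation,
                 scars = if (pass) c(hit$left_scar, hit$right_scar) else NULL,
                 cassette_span = if (pass)
                   span(cassette_at, cassette_at + nchar(cas) - 1L) else NULL,
                 first_divergence = first_div,
                 cassette_orientation_flipped = cassette_flip,
                 regions = regions, digest_table = dt),
            class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf("Reconstruction verification: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  if (x$pass) {
    cat(sprintf("  orientation: %s; terminal scars: %d / %d nt\n",
                x$orientation, x$scars[1], x$scars[2]))
    cat(sprintf("  cassette at %d..%d\n", x$cassette_span$start,
                x$cassette_span$end))
  } else {
    cat(sprintf("  first divergence at %d\n", x$first_divergence))
    if (x$cassette_orientation_flipped)
      cat("  diagnostic: cassette orientation reversed\n")
  }
  if (!is.null(x$digest_table)) print(x$digest_table, row.names = FALSE)
  invisible(x)
}

#' Configuration for an end-to-end reconstruction
#'
#' @param genome Linear `nucseq`, or `NULL` to generate a synthetic genome.
#' @param cassette_donor Donor `nucseq`, or `NULL` for a synthetic donor.
#' @param pbr322 Backbone source plasmid (default: the packaged synthetic
#'   analog).
#' @param arms List of two arm [span()]s; defaults to 1..2566 and the last
#'   161 bases, the arm layout of a 34,776-bp genome.
#' @param n_fragments Even fragment count (default 6).
#' @param release_enzymes One enzyme pair per pairing.
#' @param e3_span E3 interval in genome coordinates (default: the synthetic
#'   spec's interval).
#' @param overlap_range Junction overlap window.
#' @param terminal_enzyme,stuffer_enzyme Terminal and stuffer cutters.
#' @param seed Integer seed for the synthetic inputs.
#' @return A list of class `reconstruction_config`.
#' @export
reconstruction_config <- function(genome = NULL, cassette_donor = NULL,
                                  pbr322 = NULL, arms = NULL,
                                  n_fragments = 6L,
                                  release_enzymes = .default_release,
                                  e3_span = NULL,
                                  overlap_range = c(30L, 40L),
                                  terminal_enzyme = "PmeI",
                                  stuffer_enzyme = "SapI", seed = 1L) {
  structure(list(genome = genome, cassette_donor = cassette_donor,
                 pbr322 = pbr322, arms = arms, n_fragments = n_fragments,
                 release_enzymes = release_enzymes, e3_span = e3_span,
                 overlap_range = overlap_range,
                 terminal_enzyme = terminal_enzyme,
                 stuffer_enzyme = stuffer_enzyme, seed = as.integer(seed)),
            class = "reconstruction_config")
}

#' Run the full reconstruction end-to-end
#'
#' Orchestrates every step: synthetic inputs (unless provided), backbone MCS
#' swap, arm acceptor, partition plan and primer design with validation,
#' single-fragment subclone of the E3-carrying fragment, E3 replacement by
#' the cassette, re-amplification, the three paired intermediates, release
#' digests, final isothermal reassembly, rescue linearization, and
#' verification against the directly spliced expectation.
#'
#' @param config A [reconstruction_config()].
#' @return A list of class `reconstruction`: inputs, all intermediates, the
#'   final plasmid, the rescued genome, the verification report, and a
#'   `record` data.frame of the steps.
#' @export
reconstruct <- function(config = reconstruction_config()) {
  stopifnot(inherits(config, "reconstruction_config"))
  record <- list()
  note <- function(step, operation, inputs, output, check = TRUE)
    record[[length(record) + 1L]] <<- data.frame(
      step = step, operation = operation, inputs = paste(inputs, collapse = "+"),
      output = output, check_passed = check, stringsAsFactors = FALSE)

  genome <- config$genome
  if (is.null(genome)) {
    spec <- synth_genome_spec(seed = config$seed)
    genome <- synth_genome(spec)
    if (is.null(config$e3_span)) config$e3_span <- spec$e3_span
  }
  if (is.null(config$e3_span)) stop("e3_span required for a supplied genome")
  L <- nchar(genome$bases)
  arms <- config$arms
  if (is.null(arms)) arms <- list(span(1L, 2566L), span(L - 160L, L))
  donor <- config$cassette_donor
  if (is.null(donor)) donor <- synth_cassette(seed = config$seed)
  cassette <- release_cassette(donor)
  note(1, "synth/load inputs", c("seed"), "genome+cassette")

  pb <- config$pbr322
  if (is.null(pb)) pb <- fixtures()$pbr322
  backbone <- build_backbone(pb)
  note(2, "build_backbone", pb$id, backbone$id)
  lr <- build_pbr322lr(backbone,
                       subseq(genome, arms[[1]]), subseq(genome, arms[[2]]))
  note(3, "build_pbr322lr", c(backbone$id, "arms"), lr$id)

  plan <- plan_partition(genome, arms, config$n_fragments,
                         config$release_enzymes,
                         overlap_range = config$overlap_range)
  primers <- design_primer_pairs(genome, plan)
  val <- validate_plan(genome, primers, plan)
  if (!attr(val, "pass")) stop("primer validation failed")
  note(4, "plan+design+validate", genome$id, "primer set", attr(val, "pass"))

  # E3 replacement in the fragment that carries it
  e3 <- config$e3_span
  frag_carrier <- which(vapply(plan$fragments, function(f)
    f$start <= e3$start && f$end >= e3$end, logical(1)))
  if (length(frag_carrier) != 1L)
    stop("configuration error: E3 interval must lie inside exactly one fragment")
  f5 <- plan$fragments[[frag_carrier]]
  pb5 <- subclone_fragment(genome, f5, backbone,
                           id = sprintf("pBR322-%d", frag_carrier))
  note(5, "subclone_fragment", genome$id, pb5$id)
  e3_bases <- subseq(genome, e3)
  p <- regexpr(e3_bases, paste0(pb5$bases, substr(pb5$bases, 1L, nchar(e3_bases))),
               fixed = TRUE)[1]
  if (p < 1L) stop("configuration error: E3 interval not found in the subclone")
  e3_on_plasmid <- span(p, ((p + nchar(e3_bases) - 2L) %% nchar(pb5$bases)) + 1L)
  del <- design_deletion_primers(
    pb5, e3_on_plasmid,
    cassette_ends = c(substr(cassette$bases, 1L, 24L),
                      substr(cassette$bases, nchar(cassette$bases) - 23L,
                             nchar(cassette$bases))))
  pb5lg <- replace_e3(pb5, cassette, del)
  exp_len <- nchar(pb5$bases) - nchar(e3_bases) + nchar(cassette$bases)
  if (nchar(pb5lg$bases) != exp_len)
    stop("E3 replacement length law violated")
  note(6, "replace_e3", c(pb5$id, cassette$id), pb5lg$id)

  amp5lg <- pcr(pb5lg, primers[[2L * frag_carrier - 1L]],
                primers[[2L * frag_carrier]],
                id = sprintf("amplicon_%d", frag_carrier))
  note(7, "reamplify 5LG", pb5lg$id, amp5lg$id)

  overrides <- stats::setNames(list(amp5lg), as.character(frag_carrier))
  bi <- build_intermediates(genome, plan, primers, backbone,
                            amplicon_overrides = overrides)
  note(8, "build_intermediates", "amplicons",
       paste(vapply(bi$intermediates, function(x) x$seq$id, character(1)),
             collapse = "+"))

  final <- final_assembly(lr, bi$intermediates, plan$release_enzymes)
  note(9, "final_assembly", "4 pieces", final$seq$id)
  rescued <- rescue_linearize(final, config$terminal_enzyme,
                              cassette_probe = substr(cassette$bases, 1L, 50L))
  note(10, "rescue_linearize", final$seq$id, rescued$id)
  report <- verify_reconstruction(rescued, genome, e3, cassette)
  note(11, "verify_reconstruction", rescued$id,
       if (report$pass) "PASS" else "FAIL", report$pass)

  structure(list(genome = genome, cassette = cassette, backbone = backbone,
                 pbr322lr = lr, plan = plan, primers = primers,
                 validation = val, pb5 = pb5, pb5lg = pb5lg,
                 amplicons = bi$amplicons, intermediates = bi$intermediates,
                 final = final, rescued = rescued, report = report,
                 record = do.call(rbind, record)),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction>\n")
  print(x$record, row.names = FALSE)
  print(x$report)
  invisible(x)
}
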