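# One cached end-to-end run (seed 1) backs most of these checks.

test_that("backbone swap yields the expected length and single cloning sites", {
  pb <- fixtures()$pbr322
  bb <- build_backbone(pb)
  expect_equal(nchar(pb$bases), 4361L)
  expect_equal(nchar(bb$bases), 4361L - 971L + 64L)
  for (nm in c("NotI", "SbfI", "SrfI"))
    expect_equal(nrow(find_sites(bb, nm)), 1L)
  expect_error(build_backbone(pb, span(973, 3)), "coordinate")
  # an MCS that duplicates a workflow site elsewhere is refused
  expect_error(build_backbone(pb, span(3, 973),
                              mcs = paste0(fixtures()$mcs, "GCGGCCGC")),
               "conflict")
})

test_that("the arm acceptor has the engineered layout and scar-free SapI release", {
  run <- demo_run()
  lr <- run$pbr322lr
  expect_equal(nrow(find_sites(lr, "SapI")), 2L)
  expect_equal(nrow(find_sites(lr, "PmeI")), 2L)
  la <- subseq(run$genome, span(1, 2566))
  ra <- subseq(run$genome, span(nchar(run$genome$bases) - 160,
                                nchar(run$genome$bases)))
  kept <- linearize(lr, "SapI", keep = "largest")
  # top strand opens exactly at the right arm and closes at the left arm end
  expect_equal(substr(kept$bases, 1, nchar(ra)), ra)
  expect_equal(substr(kept$bases, nchar(kept$bases) - nchar(la) + 1,
                      nchar(kept$bases)), la)
  # arms carrying a terminal-enzyme site are refused
  bad_arm <- paste0(substr(la, 1, 100), "GTTTAAAC", substr(la, 109, 200))
  expect_error(build_pbr322lr(run$backbone, bad_arm, ra), "conflict")
})

test_that("fixed spacer constants cannot seed workflow sites at arm junctions", {
  # worst case: the arm terminus supplies any prefix/suffix the spacer could
  # extend into a recognition site
  ctx_left <- paste0("GTGT", "GAAGAGC", "TGACCTAGACCTGAACCAGT", "GCTCTTC", "A")
  for (nm in c("PmeI", "SapI", "NotI", "SrfI")) {
    rec <- enzyme(nm)$recognition
    pats <- unique(c(rec, revcomp(rec)))
    for (pat in pats) {
      l <- nchar(pat)
      for (j in 1:(l - 1)) {
        # arm ends with pat[1..j]; spacer side must not continue the site
        expect_false(startsWith(ctx_left, substr(pat, j + 1, l)),
                     info = paste(nm, pat, j))
      }
    }
  }
})

test_that("the seeded run produces 6 amplicons, 3 intermediates, 4 final pieces", {
  run <- demo_run()
  expect_equal(length(run$amplicons), 6L)
  expect_equal(length(run$intermediates), 3L)
  expect_equal(run$final$n_fragments, 4L)
  expect_equal(nrow(run$final$junctions), 4L)
  expect_true(all(run$final$junctions$overlap_bp >= 15L))
  # every release digest yields exactly two fragments, and each intermediate
  # joins its two fragments at the planned junction overlap
  for (k in 1:3) {
    pl <- run$intermediates[[k]]$seq
    for (nm in run$plan$release_enzymes[[k]])
      expect_equal(nrow(find_sites(pl, nm)), 1L)
    juncs <- run$intermediates[[k]]$junctions
    planned <- run$plan$junction_overlaps[2 * k - 1]
    expect_true(planned %in% juncs$overlap_bp)
  }
})

test_that("E3 replacement obeys the length law and swaps the features", {
  run <- demo_run()
  e3_len <- 27761L - 25000L + 1L   # the synthetic spec's E3-like interval
  expect_equal(nchar(run$pb5lg$bases),
               nchar(run$pb5$bases) - e3_len + nchar(run$cassette$bases))
  e3_bases <- subseq(run$genome, span(25000, 27761))
  expect_false(grepl(substr(e3_bases, 100, 200), run$pb5lg$bases, fixed = TRUE))
  expect_true(grepl(substr(run$cassette$bases, 100, 200), run$pb5lg$bases,
                    fixed = TRUE))
})

test_that("rescue linearization preserves the inverted-terminal-repeat property", {
  run <- demo_run()
  g <- run$rescued$bases
  k <- 100L
  expect_equal(substr(g, 1, k), revcomp(substr(g, nchar(g) - k + 1, nchar(g))))
  # the backbone piece is rejected by the cassette-content criterion
  frags <- digest(run$final$seq, "PmeI")
  expect_equal(length(frags), 2L)
  probe <- substr(run$cassette$bases, 1, 50)
  chosen <- select_fragment(frags, list(contains = probe))
  expect_equal(nchar(chosen$bases), nchar(g))
})

test_that("verification passes honestly and fails on injected faults", {
  run <- demo_run()
  expect_true(run$report$pass)
  expect_true(all(run$report$scars <= 4L))
  e3 <- span(25000, 27761)
  # single substituted base -> FAIL at that coordinate
  mut <- run$rescued
  pos <- 15000L
  b <- mut$bases
  substr(b, pos, pos) <- if (substr(b, pos, pos) == "A") "C" else "A"
  mut$bases <- b
  rep2 <- verify_reconstruction(mut, run$genome, e3, run$cassette)
  expect_false(rep2$pass)
  expect_false(is.na(rep2$first_divergence))
  # flipped cassette -> FAIL with orientation diagnostic
  flipped_expect <- paste0(
    "AAAC", substr(run$genome$bases, 1, e3$start - 1),
    revcomp(run$cassette$bases),
    substr(run$genome$bases, e3$end + 1, nchar(run$genome$bases)), "GTTT")
  rep3 <- verify_reconstruction(nuc_seq("flip", flipped_expect), run$genome,
                                e3, run$cassette)
  expect_false(rep3$pass)
  expect_true(rep3$cassette_orientation_flipped)
})

test_that("the build record is complete and the digest report is conservative", {
  run <- demo_run()
  expect_equal(nrow(run$record), 11L)
  expect_true(all(run$record$check_passed))
  dr <- digest_report(run$final$seq, c("NheI", "ClaI", "EcoRI"))
  expect_equal(sum(dr$size_bp), nchar(run$final$seq$bases))
  expect_equal(dr$topology[1], "circular")
})
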