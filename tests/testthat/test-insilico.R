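test_that("pcr amplifies the region between primers and carries 5' tails", {
  set.seed(101)
  core <- rand_bases(300)
  fwd_a <- substr(core, 21, 45)            # anneals at 21..45
  rev_a <- rc_oracle(substr(core, 231, 255))
  tmpl <- nuc_seq("t", core)
  # tail-free primers matching the chosen windows
  amp <- pcr(tmpl, fwd_a, rev_a)
  expect_equal(amp$bases, substr(core, 21, 255))
  # tails are prepended / rc-appended
  amp2 <- pcr(tmpl, paste0("GGCCGCAA", fwd_a), paste0("TTTTGG", rev_a))
  expect_equal(amp2$bases,
               paste0("GGCCGCAA", substr(core, 21, 255), rc_oracle("TTTTGG")))
  # tail-free primers at the template termini reproduce the template
  amp3 <- pcr(tmpl, substr(core, 1, 25), rc_oracle(substr(core, 276, 300)))
  expect_equal(amp3$bases, core)
})

test_that("pcr errors distinguish no-amplification, mispriming and orientation", {
  set.seed(111)
  core <- rand_bases(200)
  tmpl <- nuc_seq("t", core)
  expect_error(pcr(tmpl, rand_bases(25), rc_oracle(substr(core, 150, 174))),
               "no amplification")
  dup <- nuc_seq("d", paste0(core, core))
  expect_error(pcr(dup, substr(core, 21, 45), rc_oracle(substr(core, 150, 174))),
               "mispriming")
  # both primers priming the same strand cannot converge
  expect_error(pcr(tmpl, substr(core, 21, 45), substr(core, 150, 174)),
               "orientation|no amplification")
  # divergent (outward-facing) primers on a linear template have no product
  expect_error(pcr(tmpl, substr(core, 150, 174), rc_oracle(substr(core, 21, 45))),
               "orientation")
})

test_that("inverse pcr on a circular template deletes the interval between 5' ends", {
  set.seed(121)
  b <- rand_bases(800)
  pl <- nuc_seq("p", b, "circular")
  # divergent primers flanking the marked interval 301..500
  fwd <- substr(b, 501, 525)
  rev <- rc_oracle(substr(b, 276, 300))
  amp <- pcr(pl, fwd, rev)
  expect_equal(amp$bases, paste0(substr(b, 501, 800), substr(b, 1, 300)))
  # rotation of the template does not change the product
  amp2 <- pcr(rotate(pl, 123), fwd, rev)
  expect_equal(amp2$bases, amp$bases)
})

test_that("ligation joins compatible overhangs and refuses mismatched chemistry", {
  set.seed(131)
  # NotI/SrfI vector + insert: asymmetric ends force the orientation
  vec_b <- paste0("GCGGCCGC", rand_bases(120), "GCCCGGGC")
  ins_b <- paste0("GCGGCCGC", rand_bases(60), "GCCCGGGC")
  pl <- nuc_seq("v", paste0(vec_b, rand_bases(40)), "circular")
  vec <- select_fragment(digest(pl, c("NotI", "SrfI")), "largest")
  ins <- select_fragment(digest(nuc_seq("i", ins_b), c("NotI", "SrfI")),
                         "largest")
  prods <- ligate(list(vec, ins), allow_blunt = TRUE)
  expect_equal(length(prods), 1L)
  # orientation was forced: the insert appears in its forward sense
  expect_true(grepl(substr(ins_b, 20, 50), paste0(prods[[1]]$bases,
                                                  prods[[1]]$bases),
                    fixed = TRUE) ||
              grepl(substr(ins_b, 20, 50),
                    paste0(rc_oracle(prods[[1]]$bases),
                           rc_oracle(prods[[1]]$bases)), fixed = TRUE))
  # a NotI end cannot join a blunt SrfI end under strict chemistry
  notI_ends <- digest(nuc_seq("a", paste0("AA", "GCGGCCGC", rand_bases(40))),
                      "NotI")
  blunt_ends <- digest(nuc_seq("b", paste0(rand_bases(40), "GCCCGGGC", "TT")),
                       "SrfI")
  expect_error(ligate(list(notI_ends[[2]], blunt_ends[[1]]),
                      circularize = TRUE, allow_blunt = FALSE),
               "ligation failure")
})

test_that("gibson assembles two overlapping fragments into the expected circle", {
  set.seed(141)
  a_core <- rand_bases(60); b_core <- rand_bases(60)
  ov1 <- rand_bases(20); ov2 <- rand_bases(20)
  fragA <- paste0(ov2, a_core, ov1)
  fragB <- paste0(ov1, b_core, ov2)
  prod <- gibson(list(fragA, fragB), expect = "circular")
  expect_equal(nchar(prod$seq$bases), 160L)
  expect_equal(sort(prod$junctions$overlap_bp), c(20L, 20L))
  expected <- canonical_oracle(paste0(ov2, a_core, ov1, b_core))
  expect_equal(prod$seq$bases, expected)
})

test_that("gibson reassembly identity holds for 2-6 random splits of a circle", {
  set.seed(151)
  for (trial in 1:6) {
    n <- sample(800:1500, 1)
    b <- rand_bases(n)
    k <- sample(2:6, 1)
    cuts <- pick_cuts(n, k)
    overlaps <- sample(15:60, k, replace = TRUE)
    pieces <- split_circle(b, cuts, overlaps)
    # order/orientation invariance: shuffle and flip a random subset
    ord <- sample(k)
    pieces <- pieces[ord]
    flip <- runif(k) < 0.5
    pieces[flip] <- vapply(pieces[flip], rc_oracle, character(1))
    prod <- gibson(as.list(pieces), expect = "circular")
    expect_equal(prod$seq$bases, canonical_oracle(b))
    expect_equal(nchar(prod$seq$bases),
                 sum(nchar(pieces)) - sum(prod$junctions$overlap_bp))
  }
})

test_that("gibson reports ambiguity when one overlap occurs at two termini", {
  set.seed(161)
  ov <- rand_bases(25)
  # the same overlap closes fragment A onto both B and C
  fragA <- paste0(rand_bases(50), ov)
  fragB <- paste0(ov, rand_bases(50), ov)
  fragC <- paste0(ov, rand_bases(50), ov)
  expect_error(gibson(list(fragA, fragB, fragC), expect = "circular"),
               "ambiguity|failure")
  # disconnected fragments report a near-miss hint
  expect_error(gibson(list(rand_bases(80), rand_bases(80)),
                      expect = "circular"),
               "assembly failure")
})

test_that("linearize keeps the selected piece and discards the stuffer", {
  set.seed(171)
  # two SapI sites pointing into a central stuffer
  left <- rand_bases(150); right <- rand_bases(150); stuffer <- rand_bases(30)
  pl <- nuc_seq("p", paste0(left, "GTGT", "GAAGAGC", stuffer, "GCTCTTC", "A",
                            right), "circular")
  kept <- linearize(pl, "SapI", keep = "largest")
  expect_equal(substr(kept$bases, 1, 150), right)
  expect_equal(substr(kept$bases, nchar(kept$bases) - 149, nchar(kept$bases)),
               left)
  expect_error(linearize(pl, "PmeI"), "uncut")
  single <- nuc_seq("s", paste0(rand_bases(100), "GTTTAAAC", rand_bases(50)),
                    "circular")
  expect_equal(nchar(linearize(single, "PmeI")$bases), 158L)
})
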