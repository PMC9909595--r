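mcs_seq <- nuc_seq("MCS", fixtures()$mcs)

test_that("site scanning finds the cloning-site positions and wrapped sites", {
  expect_equal(find_sites(mcs_seq, "NotI")$position, 1L)
  expect_equal(find_sites(mcs_seq, "EcoRI")$position, 15L)
  expect_equal(find_sites(mcs_seq, "SbfI")$position, 57L)
  # palindromic site spanning the origin of a circle
  wrap <- nuc_seq("w", "AAACGTTT", "circular")
  expect_equal(nrow(find_sites(wrap, "PmeI")), 1L)
  expect_equal(nrow(find_sites(nuc_seq("w", "AAACGTTT"), "PmeI")), 0L)
  # non-palindromic enzymes report both strands
  both <- nuc_seq("s", "AAGCTCTTCAAAAGAAGAGCTT")
  s <- find_sites(both, "SapI")
  expect_equal(s$strand, c("+", "-"))
})

test_that("absent_enzymes returns the zero-site subset in order", {
  s <- nuc_seq("s", "GAATTCAAATTTGGGCCC")
  out <- absent_enzymes(s, c("PmeI", "EcoRI", "NotI"))
  expect_equal(vapply(out, `[[`, character(1), "name"), c("PmeI", "NotI"))
  expect_equal(absent_enzymes(s, list()), list())
  expect_equal(length(absent_enzymes(nuc_seq("p", "GTTTAAAC"), c("PmeI"))), 0L)
})

test_that("digestion conserves length and obeys the fragment-count law", {
  set.seed(31)
  for (i in 1:8) {
    n_sites <- sample(1:4, 1)
    parts <- replicate(n_sites + 1, rand_bases(sample(30:80, 1)))
    enz <- sample(c("EcoRI", "EcoRV", "PmeI", "NheI"), 1)
    rec <- enzyme(enz)$recognition
    bases <- paste0(paste(parts[-length(parts)], collapse = rec), rec,
                    parts[length(parts)])
    circ <- nuc_seq("c", bases, "circular")
    lin <- nuc_seq("l", bases, "linear")
    n_cut <- nrow(find_sites(circ, enz))
    fc <- digest(circ, enz)
    fl <- digest(lin, enz)
    expect_equal(length(fc), n_cut)
    expect_equal(length(fl), nrow(find_sites(lin, enz)) + 1L)
    expect_equal(sum(vapply(fc, function(f) nchar(f$bases), integer(1))),
                 nchar(bases))
    expect_equal(sum(vapply(fl, function(f) nchar(f$bases), integer(1))),
                 nchar(bases))
  }
  expect_error(digest(nuc_seq("u", "ACGTACGTAC", "circular"), "EcoRI"), "uncut")
})

test_that("cut offsets produce the documented end chemistry", {
  fr <- digest(nuc_seq("l", "AAAAGAATTCTTTT"), "EcoRI")
  expect_equal(fr[[1]]$bases, "AAAAG")
  expect_equal(fr[[2]]$bases, "AATTCTTTT")
  expect_equal(fr[[1]]$right_end$class, "five_prime")
  expect_equal(fr[[1]]$right_end$bases, "AATT")
  expect_equal(fr[[2]]$left_end$bases, "AATT")
  # SapI cuts 1 nt (top) / 4 nt (bottom) downstream: 3-nt 5' overhang
  fs <- digest(nuc_seq("s", "AAAAGCTCTTCTACGTACGTACG"), "SapI")
  expect_equal(fs[[1]]$bases, "AAAAGCTCTTCT")
  expect_equal(fs[[1]]$right_end$class, "five_prime")
  expect_equal(nchar(fs[[1]]$right_end$bases), 3L)
  # and respects orientation on the bottom strand: the top-strand cut of the
  # flipped carrier falls 5 nt before the (reverse) recognition start
  fs2 <- digest(nuc_seq("s", rc_oracle("AAAAGCTCTTCTACGTACGTACG")), "SapI")
  expect_equal(fs2[[1]]$bases, "CGTACGTA")
  expect_equal(fs2[[2]]$bases, "CGTAGAAGAGCTTTT")
  expect_equal(fs2[[1]]$right_end$class, "five_prime")
  expect_equal(nchar(fs2[[1]]$right_end$bases), 3L)
  # the two cuts describe the same duplex: overhang bases are rc-compatible
  expect_equal(fs2[[1]]$right_end$bases, revcomp(fs2[[2]]$left_end$bases))
  # 3' overhang enzyme
  fb <- digest(nuc_seq("b", "AAACCTGCAGGTTT"), "SbfI")
  expect_equal(fb[[1]]$right_end$class, "three_prime")
  expect_equal(fb[[1]]$right_end$bases, "TGCA")
})

test_that("band sizes sort descending and respect rotation invariance", {
  expect_equal(band_sizes(list(list(bases = strrep("A", 3)),
                               list(bases = strrep("A", 10)),
                               list(bases = strrep("A", 7)))), c(10L, 7L, 3L))
  set.seed(41)
  b <- paste0("GAATTC", rand_bases(50), "GATATC", rand_bases(70), "GAATTC",
              rand_bases(30))
  pl <- nuc_seq("p", b, "circular")
  ref <- band_sizes(digest(pl, c("EcoRI", "EcoRV")))
  for (k in c(13, 77, 100))
    expect_equal(band_sizes(digest(rotate(pl, k), c("EcoRI", "EcoRV"))), ref)
  expect_equal(sum(ref), nchar(b))
})

test_that("re-ligation of a digested circle reproduces the plasmid", {
  set.seed(51)
  b <- paste0("GAATTC", rand_bases(60), "GAATTC", rand_bases(40))
  pl <- nuc_seq("p", b, "circular")
  prods <- ligate(digest(pl, "EcoRI"), all = TRUE)
  expect_true(any(vapply(prods, function(p) seq_equal(p, pl), logical(1))))
})

test_that("select_fragment enforces a unique match", {
  f <- function(n) list(bases = strrep("A", n), span = span(1, n))
  frs <- list(f(10), f(25), f(7))
  expect_equal(nchar(select_fragment(frs, "largest")$bases), 25L)
  expect_error(select_fragment(list(f(9), f(9)), "largest"), "ambiguity")
  set.seed(61)
  probe <- rand_bases(20)
  frs2 <- list(list(bases = paste0("AAA", probe, "TTT"), span = span(1, 26)),
               list(bases = rand_bases(30), span = span(27, 56)))
  expect_equal(select_fragment(frs2, list(contains = probe))$bases,
               frs2[[1]]$bases)
})

test_that("overlapping cut windows raise an unsupported-configuration error", {
  # two SbfI-style cuts cannot interleave, but a type IIS window overlapping
  # another site's window must be refused rather than silently part-digested
  s <- nuc_seq("x", "AAAGCTCTTCGGAATTCAAACCC")
  expect_error(digest(s, c("SapI", "EcoRI")), "unsupported configuration")
})
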