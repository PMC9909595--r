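test_that("revcomp is a length-preserving involution and complements correctly", {
  expect_equal(revcomp("GGGCGACGCGAGGCTGGATGGCCTT"), "AAGGCCATCCAGCCTCGCGTCGCCC")
  set.seed(11)
  for (i in 1:20) {
    s <- rand_bases(sample(1:200, 1))
    expect_equal(revcomp(revcomp(s)), s)
    expect_equal(nchar(revcomp(s)), nchar(s))
    expect_equal(revcomp(s), rc_oracle(s))
  }
  expect_error(revcomp(""), "empty")
  expect_error(revcomp("ACGU"), "U")
  expect_error(nuc_seq("x", "ACFG"), "alphabet")
})

test_that("subseq extracts linear, minus-strand and origin-wrapping spans", {
  lin <- nuc_seq("l", "ACGTACGT")
  expect_equal(subseq(lin, span(3, 6)), "GTAC")
  expect_equal(subseq(lin, span(3, 6, "-")), rc_oracle("GTAC"))
  circ <- nuc_seq("c", "ACGTACGT", "circular")
  expect_equal(subseq(circ, span(7, 2)), "GTAC")
  expect_error(subseq(lin, span(5, 12)), "coordinate")
  expect_error(subseq(lin, span(7, 2)), "coordinate")
})

test_that("subseq on circles is rotation-equivariant", {
  set.seed(5)
  b <- rand_bases(60)
  x <- nuc_seq("x", b, "circular")
  sp <- span(10, 30)
  for (k in c(1, 7, 35, 59)) {
    shifted <- span(((sp$start - 1 - k) %% 60) + 1, ((sp$end - 1 - k) %% 60) + 1)
    expect_equal(subseq(rotate(x, k), shifted), subseq(x, sp))
  }
})

test_that("canonical rotation matches the brute-force enumeration oracle", {
  expect_equal(canonical_rotation(nuc_seq("t", "GTAC", "circular"))$bases, "ACGT")
  set.seed(21)
  for (i in 1:12) {
    b <- rand_bases(sample(4:40, 1))
    x <- nuc_seq("x", b, "circular")
    can <- canonical_rotation(x)$bases
    expect_equal(can, canonical_oracle(b))
    expect_equal(canonical_rotation(canonical_rotation(x))$bases, can)
    k <- sample(nchar(b), 1)
    expect_equal(canonical_rotation(rotate(x, k))$bases, can)
    expect_equal(canonical_rotation(nuc_seq("x", rc_oracle(b), "circular"))$bases, can)
  }
  expect_error(canonical_rotation(nuc_seq("x", "ACGT")), "topology")
})

test_that("FASTA round trip preserves ids, bases and topology", {
  path <- withr::local_tempfile(fileext = ".fa")
  recs <- list(nuc_seq("alpha", rand_bases(133, seed = 2)),
               nuc_seq("beta", rand_bases(77), "circular"))
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$id, "alpha")
  expect_equal(back[[1]]$bases, recs[[1]]$bases)
  expect_equal(back[[2]]$topology, "circular")
  expect_equal(back[[2]]$bases, recs[[2]]$bases)
  lc <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgtacgt"), lc)
  expect_equal(read_fasta(lc)[[1]]$bases, "ACGTACGT")
})

test_that("GenBank round trip preserves bases, topology and features", {
  path <- withr::local_tempfile(fileext = ".gb")
  x <- nuc_seq("plasmidX", rand_bases(321, seed = 9), "circular",
               features = list(
                 feature("leftITR", span(1, 40), "ITR"),
                 feature("ins", span(300, 10), "cassette"),
                 feature("rev_el", span(50, 80, "-"), "RE_site")))
  write_genbank(x, path)
  back <- read_genbank(path)[[1]]
  expect_equal(back$bases, x$bases)
  expect_equal(back$topology, "circular")
  expect_equal(length(back$features), 3L)
  expect_equal(back$features[[1]]$kind, "ITR")
  expect_equal(back$features[[2]]$span$start, 300)
  expect_equal(back$features[[2]]$span$end, 10)
  expect_equal(back$features[[3]]$span$strand, "-")
  # linear token
  path2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(nuc_seq("lin", "ACGTACGTAA"), path2)
  expect_equal(read_genbank(path2)[[1]]$topology, "linear")
  # truncated record
  lines <- readLines(path)
  writeLines(lines[1:5], path2)
  expect_error(read_genbank(path2), "parse error")
})
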