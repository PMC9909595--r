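test_that("synthetic genomes honor ITRs, forbidden sites and determinism", {
  spec <- synth_genome_spec(seed = 2)
  g <- synth_genome(spec)
  L <- nchar(g$bases)
  expect_equal(L, 34776L)
  expect_equal(substr(g$bases, 1, 137),
               revcomp(substr(g$bases, L - 136, L)))
  for (nm in c("PmeI", "NotI", "EcoRI", "EcoRV", "ClaI", "SapI"))
    expect_equal(nrow(find_sites(g, nm)), 0L)
  expect_identical(synth_genome(spec)$bases, g$bases)
  expect_false(identical(synth_genome(synth_genome_spec(seed = 3))$bases,
                         g$bases))
  expect_true(any(vapply(g$features, function(f) f$kind == "E3", logical(1))))
  # scrubbed genomes appear in the absent set by construction
  abs <- absent_enzymes(g, c("PmeI", "NheI"))
  expect_true("PmeI" %in% vapply(abs, `[[`, character(1), "name"))
})

test_that("cassette donors release a clean blunt cassette", {
  d <- synth_cassette(seed = 5)
  expect_equal(nchar(d$bases), 3000L)
  expect_equal(nrow(find_sites(d, "EcoRV")), 2L)
  cas <- release_cassette(d)
  expect_equal(substr(cas$bases, 1, 3), "ATC")
  expect_equal(substr(cas$bases, nchar(cas$bases) - 2, nchar(cas$bases)), "GAT")
  for (nm in c("PmeI", "NotI", "EcoRI", "EcoRV", "ClaI", "SapI"))
    expect_equal(nrow(find_sites(cas, nm)), 0L)
  expect_identical(release_cassette(synth_cassette(seed = 5))$bases, cas$bases)
})

test_that("fixtures are byte-exact and internally consistent", {
  fx <- fixtures()
  t1 <- table1()
  expect_equal(length(fx$table1), 12L)
  expect_equal(t1[["ADV-1-F"]]$bases,
    "AGGCCCTTTCGTCTTCAAGAATTGCGGCCGCTGAGGTGGTAATAGATACTCCAGACAAGACA")
  expect_equal(nchar(fx$mcs), 64L)
  expect_equal(nchar(fx$anchors$upstream), 25L)
  expect_equal(nchar(fx$anchors$downstream), 25L)
  expect_equal(nrow(fx$enzymes), 15L)
  # the packaged backbone analog equals its seeded generator output
  expect_identical(fx$pbr322$bases, synth_pbr322()$bases)
  expect_equal(fx$pbr322$topology, "circular")
})

test_that("the pipeline verifies end-to-end across multiple fresh seeds", {
  for (s in c(2, 3)) {
    run <- reconstruct(reconstruction_config(seed = s))
    expect_true(run$report$pass)
    expected <- paste0("AAAC",
                       substr(run$genome$bases, 1, 24999),
                       run$cassette$bases,
                       substr(run$genome$bases, 27762, nchar(run$genome$bases)),
                       "GTTT")
    # either strand of the rescued molecule may be reported as top
    expect_true(run$rescued$bases %in% c(expected, revcomp(expected)),
                info = paste("seed", s))
  }
})
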