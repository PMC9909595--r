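# The printed primer set is the reference input for the grammar arithmetic.
p <- table1()

test_that("junction overlaps implied by the printed primers are 40, 40, 35", {
  expect_equal(junction_overlap(p[["ADV-1-R"]], p[["ADV-2-F"]]), 40L)
  expect_equal(junction_overlap(p[["ADV-3-R"]], p[["ADV-4-F"]]), 40L)
  expect_equal(junction_overlap(p[["ADV-5-R"]], p[["ADV-6-F"]]), 35L)
  # shuffled controls do not reach the seed
  set.seed(71)
  expect_error(junction_overlap(rand_bases(28), rand_bases(31)), "no junction")
})

test_that("vector anchors align with the printed primers at exactly 25 nt", {
  anchors <- default_anchors()
  for (nm in c("ADV-1-F", "ADV-3-F", "ADV-5-F")) {
    d <- parse_primer(p[[nm]])
    expect_equal(d$anchor_side, "upstream")
    expect_equal(d$anchor_span, c(1L, 25L))
  }
  for (nm in c("ADV-2-R", "ADV-4-R", "ADV-6-R")) {
    d <- parse_primer(p[[nm]])
    expect_equal(d$anchor_side, "downstream_rc")
    expect_equal(d$anchor_span, c(1L, 25L))
  }
})

test_that("parse_primer decomposes tailed, internal and type IIS primers", {
  d1 <- parse_primer(p[["ADV-1-F"]])
  expect_equal(d1$re$name, "NotI")
  expect_equal(d1$re$span[1], 24L)   # recognition fused over the anchor's GC
  expect_equal(d1$anneal_len, 31L)
  d2 <- parse_primer(p[["ADV-2-R"]])
  expect_equal(d2$re$name, "EcoRI")
  expect_equal(d2$re$span[1], 26L)
  d3 <- parse_primer(p[["ADV-2-F"]])
  expect_null(d3$anchor_side)
  expect_null(d3$re)
  expect_equal(d3$role, "internal")
  t2 <- fixtures()$table2
  names(t2) <- vapply(t2, `[[`, character(1), "name")
  dl <- parse_primer(t2[["ADV14forLG-F"]]$bases)
  expect_equal(dl$re$name, "SapI")
  expect_equal(dl$re$span[1], 4L)
  expect_equal(dl$role, "deletion")
})

test_that("the melting-temperature rule is the documented two-regime formula", {
  expect_equal(tm(strrep("ACGT", 3)), 36)
  expect_equal(tm(strrep("G", 20)), 64.9 + 41 * (20 - 16.4) / 20)
  expect_error(tm("ACGTAC"), "length")
})

test_that("partition planning emits near-equal covered spans with in-range overlaps", {
  g <- synth_genome(synth_genome_spec(seed = 3))
  L <- nchar(g$bases)
  arms <- list(span(1, 2566), span(L - 160, L))
  plan <- plan_partition(g, arms)
  expect_equal(length(plan$fragments), 6L)
  expect_true(all(plan$junction_overlaps >= 30 & plan$junction_overlaps <= 40))
  lens <- vapply(plan$fragments, function(f) f$end - f$start + 1L, integer(1))
  expect_lt((max(lens) - min(lens)) / max(lens), 0.10)
  # fragments tile the region between the arms with the declared overlaps
  expect_equal(plan$fragments[[1]]$start, 2566 - plan$arm_overlaps[1] + 1L)
  for (i in 1:5)
    expect_equal(plan$fragments[[i + 1]]$start,
                 plan$fragments[[i]]$end - plan$junction_overlaps[i] + 1L)
  expect_equal(plan$fragments[[6]]$end, (L - 160) + plan$arm_overlaps[2] - 1L)
  # a 1-kb toy with no constraints splits near the midpoint
  toy <- nuc_seq("toy", rand_bases(1000, seed = 5))
  tp <- plan_partition(toy, list(span(1, 100), span(901, 1000)), 2,
                       release_enzymes = list(c("NotI", "EcoRI")))
  expect_equal(length(tp$fragments), 2L)
  mid <- (tp$fragments[[1]]$end + tp$fragments[[2]]$start) / 2
  expect_lt(abs(mid - 500), 250)
})

test_that("planning fails loudly when a release enzyme saturates the genome", {
  set.seed(81)
  chunks <- replicate(60, rand_bases(120))
  b <- paste(chunks, collapse = "GAATTC")   # EcoRI everywhere
  g <- nuc_seq("bad", b)
  L <- nchar(g$bases)
  expect_error(
    plan_partition(g, list(span(1, 600), span(L - 160, L)), 2,
                   release_enzymes = list(c("NotI", "EcoRI"))),
    "planning error")
})

test_that("designed primers re-parse to their own decomposition and validate PASS", {
  g <- synth_genome(synth_genome_spec(seed = 4))
  L <- nchar(g$bases)
  plan <- plan_partition(g, list(span(1, 2566), span(L - 160, L)))
  primers <- design_primer_pairs(g, plan)
  expect_equal(length(primers), 12L)
  for (i in seq_along(primers)) {
    pr <- primers[[i]]
    d <- parse_primer(pr$bases, genome = g)
    if (pr$role == "vector_adjacent_fwd") {
      expect_equal(d$anchor_span, c(1L, 25L))
      expect_equal(d$re$name, "NotI")
    }
    if (pr$role == "vector_adjacent_rev")
      expect_equal(d$anchor_span, c(1L, 25L))
    # resolved anneal matches the designed span
    expect_equal(d$anneal_span$start, pr$anneal$start)
    expect_equal(d$anneal_span$end, pr$anneal$end)
    expect_equal(d$anneal_span$strand, pr$anneal$strand)
  }
  for (i in c(1, 3, 5))
    expect_equal(junction_overlap(primers[[2 * i]], primers[[2 * i + 1]]),
                 plan$junction_overlaps[i])
  val <- validate_plan(g, primers, plan)
  expect_true(attr(val, "pass"))
  # corrupting one anchor base flips the corresponding check to FAIL
  broken <- primers
  b1 <- broken[[1]]$bases
  substr(b1, 3, 3) <- if (substr(b1, 3, 3) == "A") "C" else "A"
  broken[[1]]$bases <- b1
  val2 <- validate_plan(g, broken, plan)
  expect_false(attr(val2, "pass"))
  expect_false(val2$pass[val2$check == "anchor" &
                           val2$subject == broken[[1]]$name][1])
})

test_that("deletion primers carry the type IIS tail and unique anneals", {
  set.seed(91)
  b <- rand_bases(6000)
  pl <- nuc_seq("pl", b, "circular")
  del <- span(2000, 3500)
  cas_head <- rand_bases(24); cas_tail <- rand_bases(24)
  dp <- design_deletion_primers(pl, del, cassette_ends = c(cas_head, cas_tail))
  expect_equal(dp[[1]]$role, "deletion_fwd")
  expect_equal(regexpr("GCTCTTC", dp[[1]]$bases, fixed = TRUE)[1], 5L)
  expect_equal(dp[[1]]$cassette_tail, cas_tail)
  expect_equal(dp[[2]]$cassette_tail, rc_oracle(cas_head))
  # inverse-PCR with these primers deletes exactly the span
  amp <- pcr(pl, dp[[1]], dp[[2]])
  expect_equal(nchar(amp$bases),
               nchar(b) - (del$end - del$start + 1) + 2 * (4 + 7 + 1 + 24))
})
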