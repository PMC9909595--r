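# Shared helpers: independent mini-oracles and cached expensive objects.

rand_bases <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent reverse complement (no Biostrings)
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# independent rotate-then-slice oracle for circular subsequences
rot_oracle <- function(bases, k) {
  n <- nchar(bases)
  k <- ((k %% n) + n) %% n
  paste0(substr(bases, k + 1, n), substr(bases, 1, k))
}

# enumerate all rotations of both strands; the lexicographic minimum
canonical_oracle <- function(bases) {
  n <- nchar(bases)
  cands <- character(0)
  for (s in c(bases, rc_oracle(bases)))
    for (k in 0:(n - 1)) cands <- c(cands, rot_oracle(s, k))
  sort(cands)[1]
}

# pick k cut points around a circle with enough spacing that no piece is
# engulfed by its neighbour's overlap
pick_cuts <- function(n, k, min_gap = 100L) {
  repeat {
    cuts <- sort(sample(n, k))
    gaps <- diff(c(cuts, cuts[1] + n))
    if (min(gaps) >= min_gap) return(cuts)
  }
}

# split a circular sequence into k linear pieces with given terminal overlaps
split_circle <- function(bases, cuts, overlaps) {
  n <- nchar(bases)
  k <- length(cuts)
  dd <- paste0(bases, bases)
  vapply(seq_len(k), function(i) {
    from <- cuts[i]
    to <- cuts[if (i == k) 1L else i + 1L]
    if (to <= from) to <- to + n
    substr(dd, from, to + overlaps[if (i == k) 1L else i + 1L] - 1L)
  }, character(1))
}

table1 <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- fixtures()$table1
    stats::setNames(fx, vapply(fx, `[[`, character(1), "name"))
  }
})

# one cached end-to-end reconstruction shared across test files
demo_run <- local({
  run <- NULL
  function() {
    if (is.null(run)) run <<- reconstruct(reconstruction_config(seed = 1L))
    run
  }
})
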