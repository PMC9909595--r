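# Core dsDNA sequence model: NucSeq objects, 1-based inclusive spans with
# origin-wrap on circular topology, strand arithmetic, canonical rotation,
# and FASTA/GenBank readers/writers.

.IUPAC <- "ACGTRYSWKMBDHVN"

.norm_bases <- function(bases, strict = TRUE, what = "sequence") {
  if (length(bases) != 1L || is.na(bases)) stop("bases must be a single string")
  bases <- toupper(bases)
  if (!nzchar(bases)) stop("alphabet error: empty ", what)
  if (grepl("U", bases, fixed = TRUE))
    stop("alphabet error: RNA base 'U' not accepted")
  alphabet <- if (strict) "ACGT" else .IUPAC
  bad <- gsub(sprintf("[%s]", alphabet), "", bases)
  if (nzchar(bad))
    stop(sprintf("alphabet error: invalid character(s) '%s' in %s",
                 substr(bad, 1, 10), what))
  bases
}

#' Construct a NucSeq
#'
#' A `nucseq` is a named double-stranded DNA sequence with declared topology.
#' Construct sequences are restricted to the unambiguous alphabet `{A,C,G,T}`;
#' IUPAC ambiguity codes are reserved for enzyme recognition patterns, where
#' overlap and digestion semantics stay well defined. Circular sequences carry
#' no meaningful origin: every operation on circular inputs is either
#' rotation-invariant or explicitly canonicalizing.
#'
#' @param id Sequence label.
#' @param bases Character scalar over `{A,C,G,T}` (lowercase is uppercased).
#' @param topology `"linear"` or `"circular"`.
#' @param features List of [feature()] annotations.
#' @return An object of class `nucseq`.
#' @examples
#' nuc_seq("toy", "acgtACGT", "circular")
#' @export
nuc_seq <- function(id, bases, topology = c("linear", "circular"),
                    features = list()) {
  topology <- match.arg(topology)
  bases <- .norm_bases(bases)
  structure(list(id = as.character(id), bases = bases, topology = topology,
                 features = features),
            class = "nucseq")
}

#' @export
print.nucseq <- function(x, ...) {
  cat(sprintf("<nucseq> %s: %s bp, %s, %d feature(s)\n", x$id,
              format(nchar(x$bases), big.mark = ","), x$topology,
              length(x$features)))
  n <- nchar(x$bases)
  shown <- if (n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(" ", shown, "\n")
  invisible(x)
}

#' @export
length.nucseq <- function(x) nchar(x$bases)

#' Genomic span (1-based, inclusive)
#'
#' External coordinates are 1-based and inclusive on both ends, so the span
#' `(1, 2566)` covers the first 2,566 bases. On circular sequences
#' `start > end` denotes a span wrapping the origin.
#'
#' @param start,end 1-based inclusive bounds.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `span`.
#' @export
span <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, strand %in% c("+", "-"))
  if (is.na(start) || is.na(end) || start < 1L || end < 1L)
    stop("coordinate error: span bounds must be >= 1")
  structure(list(start = start, end = end, strand = strand), class = "span")
}

#' @export
print.span <- function(x, ...) {
  cat(sprintf("<span> %d..%d (%s)\n", x$start, x$end, x$strand))
  invisible(x)
}

#' Sequence feature annotation
#'
#' @param label Feature label.
#' @param span A [span()].
#' @param kind One of `ITR`, `arm`, `packaging`, `E3`, `cassette`, `RE_site`,
#'   `anneal`, `MCS`, `backbone`, `junction`, `stuffer`.
#' @return An object of class `feature`.
#' @export
feature <- function(label, span, kind = "backbone") {
  kinds <- c("ITR", "arm", "packaging", "E3", "cassette", "RE_site", "anneal",
             "MCS", "backbone", "junction", "stuffer")
  kind <- match.arg(kind, kinds)
  stopifnot(inherits(span, "span"))
  structure(list(label = as.character(label), span = span, kind = kind),
            class = "feature")
}

.span_length <- function(sp, L) {
  if (sp$start <= sp$end) sp$end - sp$start + 1L else L - sp$start + 1L + sp$end
}

.check_span <- function(sp, seq) {
  L <- nchar(seq$bases)
  if (sp$start > L || sp$end > L)
    stop(sprintf("coordinate error: span %d..%d out of range for '%s' (%d bp)",
                 sp$start, sp$end, seq$id, L))
  if (sp$start > sp$end && seq$topology == "linear")
    stop(sprintf("coordinate error: wrapped span %d..%d on linear '%s'",
                 sp$start, sp$end, seq$id))
  invisible(sp)
}

#' Reverse complement
#'
#' Length-preserving involution over the IUPAC alphabet.
#'
#' @param bases Character scalar (or a `nucseq`, whose bases are taken).
#' @return The reverse-complemented character sequence.
#' @examples
#' revcomp("GGGCGACGCGAGGCTGGATGGCCTT")
#' @export
revcomp <- function(bases) {
  if (inherits(bases, "nucseq")) bases <- bases$bases
  bases <- .norm_bases(bases, strict = FALSE, what = "revcomp input")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(bases)))
}

#' Extract a subsequence
#'
#' Extracts the bases covered by `span`. Minus-strand spans return the reverse
#' complement of the extracted region; wrapped spans (`start > end`, circular
#' only) concatenate tail and head.
#'
#' @param seq A [nuc_seq()].
#' @param sp A [span()].
#' @return Character sequence.
#' @export
subseq <- function(seq, sp) {
  stopifnot(inherits(seq, "nucseq"), inherits(sp, "span"))
  .check_span(sp, seq)
  out <- if (sp$start <= sp$end) {
    substr(seq$bases, sp$start, sp$end)
  } else {
    paste0(substr(seq$bases, sp$start, nchar(seq$bases)),
           substr(seq$bases, 1L, sp$end))
  }
  if (sp$strand == "-") revcomp(out) else out
}

#' Rotate a circular sequence
#'
#' Returns the same circle with its origin moved `k` bases forward, i.e. the
#' new sequence starts at old position `k + 1`. Features are shifted
#' accordingly.
#'
#' @param seq A circular [nuc_seq()].
#' @param k Rotation offset (any integer; reduced modulo length).
#' @return A `nucseq`.
#' @export
rotate <- function(seq, k) {
  stopifnot(inherits(seq, "nucseq"))
  if (seq$topology != "circular") stop("topology error: rotate needs a circular sequence")
  L <- nchar(seq$bases)
  k <- ((as.integer(k) %% L) + L) %% L
  if (k == 0L) return(seq)
  bases <- paste0(substr(seq$bases, k + 1L, L), substr(seq$bases, 1L, k))
  shift <- function(p) ((p - 1L - k) %% L) + 1L
  feats <- lapply(seq$features, function(f) {
    f$span$start <- shift(f$span$start); f$span$end <- shift(f$span$end); f
  })
  nuc_seq(seq$id, bases, "circular", feats)
}

# Booth's algorithm: index (0-based) of the lexicographically least rotation.
.least_rotation <- function(s) {
  v <- utf8ToInt(s)
  n <- length(v)
  if (n == 1L) return(0L)
  vv <- c(v, v)
  f <- rep.int(-1L, 2L * n)
  k <- 0L
  for (j in 1L:(2L * n - 1L)) {
    sj <- vv[j + 1L]
    i <- f[j - k]
    while (i != -1L && sj != vv[k + i + 2L]) {
      if (sj < vv[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != vv[k + i + 2L]) {
      if (sj < vv[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  k %% n
}

#' Canonical rotation of a circular sequence
#'
#' Deterministic representative of a circle: the lexicographically smallest
#' character sequence over all rotations of both strands, ties broken toward
#' the forward strand. Idempotent, and invariant under rotation and strand
#' flip, so two assembled circles are identical molecules iff their canonical
#' rotations have equal bases.
#'
#' @param seq A circular [nuc_seq()].
#' @return A `nucseq` (features dropped; the representative is a bare circle).
#' @export
canonical_rotation <- function(seq) {
  stopifnot(inherits(seq, "nucseq"))
  if (seq$topology != "circular")
    stop("topology error: canonical_rotation needs a circular sequence")
  fwd <- seq$bases
  rev <- revcomp(fwd)
  L <- nchar(fwd)
  rot <- function(s, k) if (k == 0L) s else paste0(substr(s, k + 1L, L), substr(s, 1L, k))
  cf <- rot(fwd, .least_rotation(fwd))
  cr <- rot(rev, .least_rotation(rev))
  best <- if (cr < cf) cr else cf   # tie -> forward strand
  nuc_seq(seq$id, best, "circular")
}

#' Topology-aware sequence identity
#'
#' Linear sequences compare base-for-base; circular sequences compare via
#' [canonical_rotation()], so rotation and strand flip do not matter.
#'
#' @param a,b `nucseq` objects.
#' @return Logical scalar.
#' @export
seq_equal <- function(a, b) {
  stopifnot(inherits(a, "nucseq"), inherits(b, "nucseq"))
  if (a$topology != b$topology) return(FALSE)
  if (a$topology == "linear") return(a$bases == b$bases)
  canonical_rotation(a)$bases == canonical_rotation(b)$bases
}

# ---- FASTA ------------------------------------------------------------------

#' Read a (multi-record) FASTA file
#'
#' Lowercase input is uppercased; a `topology=circular` token in the header
#' sets circular topology (FASTA carries no features by contract).
#'
#' @param path File path.
#' @return List of `nucseq` records.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("parse error: no such file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("parse error in FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("parse error: no records in FASTA '", path, "'")
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    circ <- grepl("topology=circular", header, fixed = TRUE)
    id <- strsplit(header, "[ \t]")[[1]][1]
    nuc_seq(id, as.character(set[[i]]),
            topology = if (circ) "circular" else "linear")
  })
}

#' Write records to FASTA
#'
#' @param records A `nucseq` or list of them.
#' @param path Output path.
#' @param width Line width for wrapped sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "nucseq")) records <- list(records)
  headers <- vapply(records, function(r) {
    if (r$topology == "circular") paste0(r$id, " topology=circular") else r$id
  }, character(1))
  set <- Biostrings::DNAStringSet(vapply(records, function(r) r$bases, character(1)))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# ---- GenBank (minimal flat-file dialect) ------------------------------------

.gb_kind_key <- c(ITR = "repeat_region", arm = "misc_feature",
                  packaging = "misc_signal", E3 = "misc_feature",
                  cassette = "misc_feature", RE_site = "misc_feature",
                  anneal = "primer_bind", MCS = "misc_feature",
                  backbone = "misc_feature", junction = "misc_feature",
                  stuffer = "misc_feature")

#' Write records as minimal GenBank flat files
#'
#' Emits LOCUS (with the circular/linear topology token), DEFINITION, a
#' FEATURES table carrying each feature's kind and label, and ORIGIN. The
#' dialect is deliberately minimal but round-trips through [read_genbank()].
#'
#' @param records A `nucseq` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "nucseq")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    L <- nchar(r$bases)
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN",
                       substr(r$id, 1, 16), L,
                       if (r$topology == "circular") "circular" else "linear"), con)
    writeLines(sprintf("DEFINITION  %s.", r$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    for (f in r$features) {
      loc <- if (f$span$start <= f$span$end)
        sprintf("%d..%d", f$span$start, f$span$end)
      else sprintf("join(%d..%d,1..%d)", f$span$start, L, f$span$end)
      if (f$span$strand == "-") loc <- sprintf("complement(%s)", loc)
      key <- .gb_kind_key[[f$kind]]
      writeLines(sprintf("     %-15s %s", key, loc), con)
      writeLines(sprintf("                     /label=\"%s\"", f$label), con)
      writeLines(sprintf("                     /note=\"kind:%s\"", f$kind), con)
    }
    writeLines("ORIGIN", con)
    b <- tolower(r$bases)
    starts <- seq(1L, L, by = 60L)
    for (s in starts) {
      chunk <- substr(b, s, min(s + 59L, L))
      tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", s, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Read a minimal GenBank flat file
#'
#' Honors the LOCUS circular/linear token and recovers features written by
#' [write_genbank()] (location, strand, label, kind). Malformed records raise
#' a parse error naming the offending line.
#'
#' @param path File path.
#' @return List of `nucseq` records.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("parse error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !grepl("^LOCUS", lines[i])) i <- i + 1L
    if (i > n) break
    locus <- lines[i]
    toks <- strsplit(trimws(locus), "[ \t]+")[[1]]
    if (length(toks) < 3L)
      stop("parse error at line ", i, ": malformed LOCUS line")
    id <- toks[2]
    topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"
    feats <- list()
    bases <- NULL
    j <- i + 1L
    pend_key <- NULL; pend_loc <- NULL; pend_label <- NA; pend_kind <- NA
    flush_feat <- function() {
      if (is.null(pend_key)) return()
      loc <- pend_loc
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("^join\\(", loc)) {
        inner <- sub("^join\\((.*)\\)$", "\\1", loc)
        parts <- strsplit(inner, ",")[[1]]
        a <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
        b <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
        sp <- span(a[1], b[2], strand)
      } else {
        ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        if (length(ab) == 1L) ab <- c(ab, ab)
        sp <- span(ab[1], ab[2], strand)
      }
      kind <- if (!is.na(pend_kind)) pend_kind else "backbone"
      lab <- if (!is.na(pend_label)) pend_label else kind
      feats[[length(feats) + 1L]] <<- feature(lab, sp, kind)
    }
    while (j <= n && !grepl("^ORIGIN", lines[j]) && !grepl("^//", lines[j])) {
      ln <- lines[j]
      if (grepl("^     [A-Za-z_']", ln)) {
        key <- trimws(substr(ln, 1, 20))
        loc <- trimws(substr(ln, 21, nchar(ln)))
        if (key != "source") {
          flush_feat()
          pend_key <- key; pend_loc <- loc; pend_label <- NA; pend_kind <- NA
        }
      } else if (grepl("/label=", ln, fixed = TRUE)) {
        pend_label <- sub('.*?/label="([^"]*)".*', "\\1", ln)
      } else if (grepl("/note=\"kind:", ln, fixed = TRUE)) {
        pend_kind <- sub('.*?/note="kind:([^"]*)".*', "\\1", ln)
      }
      j <- j + 1L
    }
    flush_feat()
    if (j > n || !grepl("^ORIGIN", lines[j]))
      stop("parse error at line ", min(j, n),
           ": expected ORIGIN before end of record '", id, "'")
    j <- j + 1L
    chunks <- character()
    while (j <= n && !grepl("^//", lines[j])) {
      seqpart <- gsub("[ 0-9]", "", lines[j])
      if (nzchar(seqpart)) chunks[length(chunks) + 1L] <- seqpart
      j <- j + 1L
    }
    if (j > n) stop("parse error at line ", n, ": truncated record '", id,
                    "' (missing //)")
    bases <- toupper(paste(chunks, collapse = ""))
    if (!nzchar(bases))
      stop("parse error at line ", j, ": record '", id, "' has no sequence")
    recs[[length(recs) + 1L]] <- nuc_seq(id, bases, topology, feats)
    i <- j + 1L
  }
  if (length(recs) == 0L) stop("parse error: no GenBank records in '", path, "'")
  recs
}

# Seeded RNG scoped to a call; leaves the caller's RNG state untouched.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.random_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                   collapse = "")
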