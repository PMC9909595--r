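# Restriction-enzyme model: site scanning on both strands (with origin wrap on
# circles), digestion producing fragments with explicit end chemistry, and
# absent-site discovery.
#
# Cut offsets are stored as strand boundaries counted from the recognition
# start: cut_top = n means the top strand is cut after the n-th base of (or
# past) the recognition sequence. overhang = cut_bottom - cut_top: 0 blunt,
# > 0 a 5' overhang, < 0 a 3' overhang. Type IIS offsets run past the
# recognition end (SapI GCTCTTC(1/4) has cut_top 8, cut_bottom 11).

#' Built-in restriction enzyme table
#'
#' The packaged table (`inst/extdata/enzymes.tsv`) covers every enzyme the
#' reconstruction workflow uses; users may load an extended table from any TSV
#' with columns `name`, `recognition`, `cut_top`, `cut_bottom`.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return A data.frame of enzyme definitions.
#' @export
load_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                            package = "adenoforge")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_top", "cut_bottom")
  if (!all(need %in% names(tab)))
    stop("enzyme table must have columns: ", paste(need, collapse = ", "))
  if (any(nchar(tab$recognition) < 4L))
    stop("enzyme recognition patterns must be at least 4 nt")
  tab$recognition <- toupper(tab$recognition)
  tab
}

#' Look up an enzyme by name
#'
#' @param name Enzyme name, e.g. `"NotI"`.
#' @param table Enzyme table from [load_enzymes()].
#' @return An object of class `enzyme`.
#' @export
enzyme <- function(name, table = load_enzymes()) {
  if (inherits(name, "enzyme")) return(name)
  i <- match(name, table$name)
  if (is.na(i)) stop("unknown enzyme: ", name)
  structure(list(name = table$name[i],
                 recognition = .norm_bases(table$recognition[i], strict = FALSE,
                                           what = "recognition pattern"),
                 cut_top = as.integer(table$cut_top[i]),
                 cut_bottom = as.integer(table$cut_bottom[i])),
            class = "enzyme")
}

.as_enzymes <- function(x) {
  if (inherits(x, "enzyme")) return(list(x))
  lapply(x, enzyme)
}

.is_palindromic <- function(enz) enz$recognition == revcomp(enz$recognition)

#' @export
print.enzyme <- function(x, ...) {
  ov <- x$cut_bottom - x$cut_top
  kind <- if (ov == 0L) "blunt" else if (ov > 0L) sprintf("5' overhang (%d nt)", ov)
          else sprintf("3' overhang (%d nt)", -ov)
  cat(sprintf("<enzyme> %s %s (%d/%d), %s\n", x$name, x$recognition,
              x$cut_top, x$cut_bottom, kind))
  invisible(x)
}

.match_starts <- function(pattern, subject) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                fixed = FALSE)
  Biostrings::start(methods::as(m, "IRanges"))
}

#' Find restriction sites
#'
#' Reports every recognition match; for non-palindromic patterns the bottom
#' strand is scanned too and reported with strand `-` at the 1-based forward
#' position of the matched window. Circular inputs include origin-spanning
#' matches.
#'
#' @param seq A [nuc_seq()].
#' @param enz An [enzyme()] or name.
#' @return data.frame with columns `position`, `strand`, sorted by position.
#' @export
find_sites <- function(seq, enz) {
  enz <- enzyme(enz)
  l <- nchar(enz$recognition)
  L <- nchar(seq$bases)
  subject <- if (seq$topology == "circular" && L > 1L)
    paste0(seq$bases, substr(seq$bases, 1L, min(l - 1L, L))) else seq$bases
  pos <- .match_starts(enz$recognition, subject)
  strand <- rep("+", length(pos))
  if (!.is_palindromic(enz)) {
    rp <- .match_starts(revcomp(enz$recognition), subject)
    pos <- c(pos, rp)
    strand <- c(strand, rep("-", length(rp)))
  }
  keep <- pos <= L
  pos <- pos[keep]; strand <- strand[keep]
  o <- order(pos, strand)
  data.frame(position = as.integer(pos[o]), strand = strand[o],
             stringsAsFactors = FALSE)
}

#' Enzymes with zero sites in a sequence
#'
#' @param seq A [nuc_seq()].
#' @param enzymes List of enzymes (or names); order preserved.
#' @return The subset with no site in `seq`.
#' @export
absent_enzymes <- function(seq, enzymes) {
  enzymes <- .as_enzymes(enzymes)
  keep <- vapply(enzymes, function(e) nrow(find_sites(seq, e)) == 0L, logical(1))
  enzymes[keep]
}

# Resolve all cut boundaries for a set of enzymes on a sequence.
# A boundary b (0-based, "after position b") cuts between positions b and b+1;
# on circles boundaries are taken modulo L. Returns a data.frame with top/bottom
# boundaries and the producing enzyme.
.resolve_cuts <- function(seq, enzymes) {
  enzymes <- .as_enzymes(enzymes)
  L <- nchar(seq$bases)
  rows <- list()
  for (enz in enzymes) {
    l <- nchar(enz$recognition)
    sites <- find_sites(seq, enz)
    if (nrow(sites) == 0L) next
    for (i in seq_len(nrow(sites))) {
      s <- sites$position[i]
      if (sites$strand[i] == "+") {
        t <- s - 1L + enz$cut_top; b <- s - 1L + enz$cut_bottom
      } else {
        t <- s - 1L + l - enz$cut_bottom; b <- s - 1L + l - enz$cut_top
      }
      if (seq$topology == "circular") {
        t <- ((t %% L) + L) %% L; b <- ((b %% L) + L) %% L
      } else if (t < 1L || t >= L || b < 1L || b >= L) {
        next  # cut window falls off a linear molecule: no cut
      }
      rows[[length(rows) + 1L]] <- data.frame(
        top = t, bottom = b, enzyme = enz$name, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(top = integer(), bottom = integer(), enzyme = character()))
  cuts <- do.call(rbind, rows)
  cuts <- cuts[order(cuts$top), , drop = FALSE]
  if (anyDuplicated(cuts$top))
    stop("unsupported configuration: coincident cut positions")
  # overhang windows (between top and bottom boundary) must not interleave
  lo <- pmin(cuts$top, cuts$bottom); hi <- pmax(cuts$top, cuts$bottom)
  if (nrow(cuts) > 1L) {
    for (i in seq_len(nrow(cuts) - 1L)) {
      if (hi[i] > lo[i + 1L])
        stop("unsupported configuration: overlapping cut windows (",
             cuts$enzyme[i], " / ", cuts$enzyme[i + 1L], ")")
    }
    if (seq$topology == "circular" && hi[nrow(cuts)] > L + lo[1L] &&
        lo[1L] != lo[nrow(cuts)])
      stop("unsupported configuration: overlapping cut windows at origin")
  }
  cuts
}

.end_chem <- function(class, bases = "") {
  stopifnot(class %in% c("blunt", "five_prime", "three_prime"))
  structure(list(class = class, bases = bases), class = "end_chem")
}

#' @export
print.end_chem <- function(x, ...) {
  cat(if (x$class == "blunt") "blunt" else sprintf("%s(%s)", x$class, x$bases), "\n")
  invisible(x)
}

.cut_ends <- function(seq, t, b) {
  # chemistry of the two new ends created by one cut (top boundary t, bottom b)
  L <- nchar(seq$bases)
  d <- b - t
  if (seq$topology == "circular")  # signed minimal difference across the origin
    d <- ((d + L %/% 2L) %% L) - L %/% 2L
  if (d == 0L) {
    return(list(left = .end_chem("blunt"), right = .end_chem("blunt")))
  }
  start <- if (d > 0L) t else ((b %% L) + L) %% L
  k <- abs(d)
  x <- if (start + k <= L) substr(seq$bases, start + 1L, start + k)
       else paste0(substr(seq$bases, start + 1L, L),
                   substr(seq$bases, 1L, start + k - L))
  if (d > 0L) {  # 5' overhang
    list(left = .end_chem("five_prime", revcomp(x)),
         right = .end_chem("five_prime", x))
  } else {       # 3' overhang
    list(left = .end_chem("three_prime", x),
         right = .end_chem("three_prime", revcomp(x)))
  }
}

.digest_fragment <- function(bases, left_end, right_end, source_id, sp,
                             left_enzyme = NA_character_,
                             right_enzyme = NA_character_) {
  structure(list(bases = bases, left_end = left_end, right_end = right_end,
                 source_id = source_id, span = sp,
                 left_enzyme = left_enzyme, right_enzyme = right_enzyme),
            class = "digest_fragment")
}

#' @export
print.digest_fragment <- function(x, ...) {
  fmt <- function(e) if (e$class == "blunt") "blunt" else
    sprintf("%s(%s)", sub("_prime", "'", e$class), e$bases)
  cat(sprintf("<digest_fragment> %d bp from %s [%d..%d], ends: %s | %s\n",
              nchar(x$bases), x$source_id, x$span$start, x$span$end,
              fmt(x$left_end), fmt(x$right_end)))
  invisible(x)
}

#' Digest a sequence with one or more enzymes
#'
#' Produces fragments ordered by source position. A circular molecule with `n`
#' cuts yields `n` fragments; a linear one yields `n + 1`. Fragment bases are
#' the top strand left-to-right, so lengths always sum to the input length
#' (overhang bases counted once). Each new end records its chemistry: blunt,
#' or the protruding single-stranded bases written 5' to 3', which makes
#' ligation compatibility a reverse-complement equality test.
#'
#' @param seq A [nuc_seq()].
#' @param enzymes Enzyme(s) or name(s).
#' @return List of `digest_fragment` objects.
#' @export
digest <- function(seq, enzymes) {
  stopifnot(inherits(seq, "nucseq"))
  cuts <- .resolve_cuts(seq, enzymes)
  L <- nchar(seq$bases)
  n <- nrow(cuts)
  if (seq$topology == "circular") {
    if (n == 0L) stop("uncut: no site for the given enzyme(s) in '", seq$id, "'")
    ends <- lapply(seq_len(n), function(i) .cut_ends(seq, cuts$top[i], cuts$bottom[i]))
    frags <- vector("list", n)
    for (i in seq_len(n)) {
      nxt <- if (i == n) 1L else i + 1L
      from <- cuts$top[i] + 1L
      to <- cuts$top[nxt]
      sp <- span(((from - 1L) %% L) + 1L, ((to - 1L) %% L) + 1L)
      bases <- subseq(seq, sp)
      frags[[i]] <- .digest_fragment(bases, ends[[i]]$right, ends[[nxt]]$left,
                                     seq$id, sp, cuts$enzyme[i], cuts$enzyme[nxt])
    }
    # deterministic source order: start from the fragment beginning earliest
    starts <- vapply(frags, function(f) f$span$start, integer(1))
    frags <- frags[order(starts)]
  } else {
    bounds <- c(0L, cuts$top, L)
    frags <- vector("list", n + 1L)
    for (i in seq_len(n + 1L)) {
      sp <- span(bounds[i] + 1L, bounds[i + 1L])
      left <- if (i == 1L) .end_chem("blunt")
              else .cut_ends(seq, cuts$top[i - 1L], cuts$bottom[i - 1L])$right
      right <- if (i == n + 1L) .end_chem("blunt")
               else .cut_ends(seq, cuts$top[i], cuts$bottom[i])$left
      frags[[i]] <- .digest_fragment(subseq(seq, sp), left, right, seq$id, sp,
                                     if (i == 1L) NA_character_ else cuts$enzyme[i - 1L],
                                     if (i == n + 1L) NA_character_ else cuts$enzyme[i])
    }
  }
  frags
}

#' Simulated gel band sizes
#'
#' @param fragments List of `digest_fragment` (or `nucseq`) objects.
#' @return Integer vector of top-strand lengths, descending.
#' @export
band_sizes <- function(fragments) {
  sizes <- vapply(fragments, function(f) nchar(f$bases), integer(1))
  sort(sizes, decreasing = TRUE)
}

#' Select exactly one fragment by criterion
#'
#' @param fragments List of `digest_fragment` objects.
#' @param criterion `"largest"`, `list(contains = x)` where `x` is a base
#'   string (matched on either strand) or a source-coordinate [span()], or
#'   `list(excludes = enzyme)`.
#' @return The unique matching fragment; selection-ambiguity error otherwise.
#' @export
select_fragment <- function(fragments, criterion = "largest") {
  if (length(fragments) == 0L) stop("selection ambiguity: no fragments")
  if (identical(criterion, "largest")) {
    sizes <- vapply(fragments, function(f) nchar(f$bases), integer(1))
    hit <- which(sizes == max(sizes))
  } else if (is.list(criterion) && !is.null(criterion$contains)) {
    x <- criterion$contains
    if (inherits(x, "span")) {
      hit <- which(vapply(fragments, function(f) {
        f$span$start <= f$span$end &&
          f$span$start <= x$start && f$span$end >= x$end
      }, logical(1)))
    } else {
      x <- toupper(x)
      hit <- which(vapply(fragments, function(f) {
        grepl(x, f$bases, fixed = TRUE) || grepl(revcomp(x), f$bases, fixed = TRUE)
      }, logical(1)))
    }
  } else if (is.list(criterion) && !is.null(criterion$excludes)) {
    enz <- enzyme(criterion$excludes)
    hit <- which(vapply(fragments, function(f) {
      nrow(find_sites(nuc_seq("f", f$bases), enz)) == 0L
    }, logical(1)))
  } else stop("unknown selection criterion")
  if (length(hit) != 1L)
    stop(sprintf("selection ambiguity: criterion matches %d fragments", length(hit)))
  fragments[[hit]]
}

#' Tabulate a simulated diagnostic digest
#'
#' Runs [digest()] and reports the band pattern the corresponding gel lane
#' would show, labelled with the input's topology (the same plasmid digested
#' as a circle or after prior linearization gives different patterns).
#'
#' @param seq A [nuc_seq()].
#' @param enzymes Enzyme(s) or name(s).
#' @return data.frame with the construct id, topology, enzymes and band sizes.
#' @export
digest_report <- function(seq, enzymes) {
  enzymes <- .as_enzymes(enzymes)
  frags <- digest(seq, enzymes)
  data.frame(
    id = seq$id,
    topology = seq$topology,
    enzymes = paste(vapply(enzymes, `[[`, character(1), "name"), collapse = "/"),
    band = seq_along(frags),
    size_bp = band_sizes(frags),
    stringsAsFactors = FALSE)
}
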