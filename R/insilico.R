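# Reaction simulators: PCR (convergent and inverse), sticky/blunt ligation,
# and isothermal overlap-directed (Gibson) assembly.

.bases_of <- function(x) {
  if (inherits(x, "nucseq")) x$bases
  else if (inherits(x, "digest_fragment")) x$bases
  else if (inherits(x, "primer_spec")) x$bases
  else .norm_bases(x)
}

.id_of <- function(x, default) {
  if (inherits(x, "nucseq")) x$id
  else if (inherits(x, "digest_fragment")) x$source_id
  else default
}

# ---- PCR --------------------------------------------------------------------

.find_anneal_fwd <- function(template, primer, min_anneal) {
  # returns list(start, end, matched) for the primer's anneal on the top strand
  tb <- template$bases
  L <- nchar(tb)
  circ <- template$topology == "circular"
  subject <- if (circ) paste0(tb, substr(tb, 1L, min(L, 200L))) else tb
  np <- nchar(primer)
  seed <- substr(primer, np - min_anneal + 1L, np)
  hits <- .match_starts(seed, subject)
  hits <- hits[hits <= L]
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) return("multiple")
  p <- hits[1]
  # extend 5'-ward while the primer keeps matching the template
  m <- min_anneal
  while (m < np) {
    tpos <- p - (m - min_anneal) - 1L
    if (circ) tpos <- ((tpos - 1L) %% L) + 1L
    if (tpos < 1L) break
    if (substr(primer, np - m, np - m) != substr(tb, tpos, tpos)) break
    m <- m + 1L
  }
  start <- p - (m - min_anneal)
  if (circ) start <- ((start - 1L) %% L) + 1L
  end <- ((p + min_anneal - 2L) %% L) + 1L
  list(start = start, end = end, matched = m)
}

#' Simulate PCR on a linear or circular template
#'
#' The 3'-terminal `min_anneal` bases of each primer must match the template
#' exactly and uniquely (forward primer on the top strand, reverse primer on
#' the bottom). Any unmatched 5' portion becomes a tail carried into the
#' amplicon. On circular templates a divergent pair performs inverse PCR: the
#' amplicon is the retained arc across the origin, i.e. the plasmid minus the
#' interval between the primers' 5' ends.
#'
#' @param template A [nuc_seq()].
#' @param fwd,rev Primers (`primer_spec` or base strings).
#' @param min_anneal Required exact unique 3'-terminal match length.
#' @param id Amplicon id.
#' @return A linear `nucseq` of class `amplicon` with a `provenance` field.
#' @export
pcr <- function(template, fwd, rev, min_anneal = 18L, id = NULL) {
  stopifnot(inherits(template, "nucseq"))
  fb <- .bases_of(fwd); rb <- .bases_of(rev)
  if (nchar(fb) < min_anneal || nchar(rb) < min_anneal)
    stop("primer shorter than min_anneal")
  L <- nchar(template$bases)
  # both template strands are present in the reaction: count each primer's
  # seed on both, then orient the template so fwd primes the top strand
  circ <- template$topology == "circular"
  subj <- if (circ) paste0(template$bases, substr(template$bases, 1L, min(L, 200L)))
          else template$bases
  fs <- substr(fb, nchar(fb) - min_anneal + 1L, nchar(fb))
  rs <- substr(rb, nchar(rb) - min_anneal + 1L, nchar(rb))
  count <- function(w) { h <- .match_starts(w, subj); length(h[h <= L]) }
  f_plus <- count(fs); f_minus <- count(revcomp(fs))
  r_plus <- count(revcomp(rs)); r_minus <- count(rs)
  if (f_plus + f_minus == 0L) stop("no amplification: forward primer does not anneal")
  if (f_plus + f_minus > 1L) stop("mispriming: forward primer anneals at multiple sites")
  if (r_plus + r_minus == 0L) stop("no amplification: reverse primer does not anneal")
  if (r_plus + r_minus > 1L) stop("mispriming: reverse primer anneals at multiple sites")
  if (f_minus == 1L && r_minus == 1L) {
    flipped <- nuc_seq(template$id, revcomp(template$bases), template$topology)
    return(pcr(flipped, fwd, rev, min_anneal = min_anneal, id = id))
  }
  if (f_plus != 1L || r_plus != 1L)
    stop("orientation error: primers prime the same strand; no product")
  fa <- .find_anneal_fwd(template, fb, min_anneal)
  if (is.null(fa)) stop("no amplification: forward primer does not anneal")
  if (identical(fa, "multiple")) stop("mispriming: forward primer anneals at multiple sites")
  # reverse primer anneals to the bottom strand where its rc appears on top
  rt <- revcomp(rb)
  ra <- local({
    tb <- template$bases
    circ <- template$topology == "circular"
    subject <- if (circ) paste0(tb, substr(tb, 1L, min(L, 200L))) else tb
    seed <- substr(rt, 1L, min_anneal)   # rc of the rev primer's 3' end
    hits <- .match_starts(seed, subject)
    hits <- hits[hits <= L]
    if (length(hits) == 0L) return(NULL)
    if (length(hits) > 1L) return("multiple")
    q <- hits[1]
    m <- min_anneal
    while (m < nchar(rt)) {
      tpos <- q + m
      if (circ) tpos <- ((tpos - 1L) %% L) + 1L
      if (tpos > L && !circ) break
      if (substr(rt, m + 1L, m + 1L) != substr(tb, tpos, tpos)) break
      m <- m + 1L
    }
    list(start = q, end = ((q + m - 2L) %% L) + 1L, matched = m)
  })
  if (is.null(ra)) stop("no amplification: reverse primer does not anneal")
  if (identical(ra, "multiple")) stop("mispriming: reverse primer anneals at multiple sites")
  fwd_tail <- substr(fb, 1L, nchar(fb) - fa$matched)
  rev_tail <- substr(rb, 1L, nchar(rb) - ra$matched)
  if (template$topology == "linear") {
    if (ra$end < fa$start)
      stop("orientation error: primers do not converge on the linear template")
    core <- substr(template$bases, fa$start, ra$end)
  } else {
    sp <- if (fa$start <= ra$end) span(fa$start, ra$end) else span(fa$start, ra$end)
    core <- subseq(template, sp)   # wraps when fa$start > ra$end
    if (fa$start == ra$end) stop("orientation error: degenerate arc")
  }
  bases <- paste0(fwd_tail, core,
                  if (nzchar(rev_tail)) revcomp(rev_tail) else "")
  structure(list(id = if (is.null(id)) paste0(template$id, "_amplicon") else id,
                 bases = bases, topology = "linear", features = list(),
                 provenance = list(template = template$id,
                                   fwd_anneal = span(fa$start, fa$end, "+"),
                                   rev_anneal = span(ra$start, ra$end, "-"),
                                   fwd_tail_len = nchar(fwd_tail),
                                   rev_tail_len = nchar(rev_tail))),
            class = c("amplicon", "nucseq"))
}

# ---- Ligation ---------------------------------------------------------------

# Blunt-filled representation: the top strand extended over any overhang whose
# protruding strand is the bottom, so that flipping is rc-symmetric and joins
# drop exactly the duplicated overhang bases.
.fill_rep <- function(frag) {
  stopifnot(inherits(frag, "digest_fragment"))
  top <- frag$bases
  lefts <- frag$left_end; rights <- frag$right_end
  lext <- 0L; rext <- 0L
  if (lefts$class != "blunt" && .protrudes_bottom(lefts, "left")) {
    top <- paste0(revcomp(lefts$bases), top); lext <- nchar(lefts$bases)
  }
  if (rights$class != "blunt" && .protrudes_bottom(rights, "right")) {
    top <- paste0(top, revcomp(rights$bases)); rext <- nchar(rights$bases)
  }
  list(fill = top, left = lefts, right = rights)
}

# Which strand protrudes: a LEFT end protrudes on top for 5' overhangs and on
# the bottom for 3'; a RIGHT end is the mirror image.
.protrudes_bottom <- function(end, side) {
  if (end$class == "five_prime") side == "right" else side == "left"
}

.flip_rep <- function(rep) {
  list(fill = revcomp(rep$fill), left = rep$right, right = rep$left)
}

.ends_compatible <- function(right_end, left_end, allow_blunt) {
  if (right_end$class == "blunt" && left_end$class == "blunt") return(allow_blunt)
  right_end$class == left_end$class &&
    right_end$bases == revcomp(left_end$bases)
}

#' Simulate ligation of digest fragments
#'
#' Joins ends whose single-stranded overhangs are reverse-complement
#' compatible (same overhang class). Blunt-blunt joins are allowed only with
#' `allow_blunt = TRUE`. Enumerates the distinct products that use every
#' fragment exactly once, in either orientation.
#'
#' @param fragments List of `digest_fragment`s.
#' @param circularize If `TRUE` (default), only closed circles are products;
#'   otherwise open chains with unjoined outer ends.
#' @param allow_blunt Permit blunt-blunt joins.
#' @param all If `FALSE` (default), more than one distinct product is an
#'   ambiguity error; if `TRUE`, all products are returned.
#' @param id Product id prefix.
#' @return List of `nucseq` products (circular products canonicalized).
#' @export
ligate <- function(fragments, circularize = TRUE, allow_blunt = FALSE,
                   all = FALSE, id = "ligation") {
  stopifnot(length(fragments) >= 1L)
  reps <- lapply(fragments, .fill_rep)
  n <- length(reps)
  products <- list()
  ov_len <- function(e) if (e$class == "blunt") 0L else nchar(e$bases)
  emit <- function(order_idx, orient) {
    segs <- lapply(seq_along(order_idx), function(k) {
      r <- reps[[order_idx[k]]]
      if (orient[k]) .flip_rep(r) else r
    })
    bases <- segs[[1]]$fill
    for (k in seq_along(segs)[-1]) {
      drop <- ov_len(segs[[k]]$left)
      bases <- paste0(bases, substr(segs[[k]]$fill, drop + 1L,
                                    nchar(segs[[k]]$fill)))
    }
    if (circularize) {
      drop <- ov_len(segs[[1]]$left)
      if (drop > 0L) bases <- substr(bases, 1L, nchar(bases) - drop)
      canonical_rotation(nuc_seq(id, bases, "circular"))
    } else nuc_seq(id, bases, "linear")
  }
  dfs <- function(order_idx, orient, used) {
    k <- length(order_idx)
    if (k == n) {
      last <- if (orient[k]) .flip_rep(reps[[order_idx[k]]]) else reps[[order_idx[k]]]
      first <- if (orient[1]) .flip_rep(reps[[order_idx[1]]]) else reps[[order_idx[1]]]
      if (!circularize || .ends_compatible(last$right, first$left, allow_blunt))
        products[[length(products) + 1L]] <<- emit(order_idx, orient)
      return(invisible())
    }
    cur <- if (orient[k]) .flip_rep(reps[[order_idx[k]]]) else reps[[order_idx[k]]]
    for (j in seq_len(n)[!used]) {
      for (fl in c(FALSE, TRUE)) {
        nxt <- if (fl) .flip_rep(reps[[j]]) else reps[[j]]
        if (.ends_compatible(cur$right, nxt$left, allow_blunt)) {
          used2 <- used; used2[j] <- TRUE
          dfs(c(order_idx, j), c(orient, fl), used2)
        }
      }
    }
  }
  used <- rep(FALSE, n); used[1] <- TRUE
  dfs(1L, FALSE, used)   # fragment 1 fixed forward: global flips are duplicates
  if (n == 1L && !circularize) products <- list(emit(1L, FALSE))
  if (length(products) == 0L) stop("ligation failure: no compatible joins")
  key <- vapply(products, function(p) {
    if (p$topology == "circular") p$bases
    else min(p$bases, revcomp(p$bases))
  }, character(1))
  products <- products[!duplicated(key)]
  products <- products[order(vapply(products, `[[`, character(1), "bases"))]
  if (!all && length(products) > 1L)
    stop("ligation ambiguity: ", length(products),
         " distinct products (set all = TRUE to enumerate)")
  products
}

# ---- Isothermal (Gibson) assembly -------------------------------------------

# Best overlap-directed junction from the end of A onto the start of B.
# Models chew-back with flap trimming: the exact match of length
# [min_overlap, max_overlap] may sit up to end_slack bases inside either
# terminus; the flaps outside it are discarded at the splice.
.best_junction <- function(A, B, min_overlap, max_overlap, end_slack) {
  nA <- nchar(A); nB <- nchar(B)
  if (nA < min_overlap || nB < min_overlap) return(NULL)
  tail_len <- min(nA, max_overlap + end_slack)
  tail <- substr(A, nA - tail_len + 1L, nA)
  cands <- list()
  for (b in 0:min(end_slack, nB - min_overlap)) {
    seed <- substr(B, b + 1L, b + min_overlap)
    hits <- gregexpr(seed, tail, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in hits) {
      pA <- nA - tail_len + h          # seed start in A
      # extend the exact match beyond the seed
      ext <- 0L
      while (pA + min_overlap + ext <= nA && b + min_overlap + ext < nB &&
             min_overlap + ext < max_overlap &&
             substr(A, pA + min_overlap + ext, pA + min_overlap + ext) ==
             substr(B, b + min_overlap + ext + 1L, b + min_overlap + ext + 1L))
        ext <- ext + 1L
      ovl <- min_overlap + ext
      flapA <- nA - (pA + ovl - 1L)
      if (flapA > end_slack) next
      cands[[length(cands) + 1L]] <- list(
        overlap = ovl, flapA = flapA, flapB = b,
        a_end = pA + ovl - 1L,          # last A position kept
        b_cont = b + ovl + 1L)          # first B position appended
    }
  }
  if (length(cands) == 0L) return(NULL)
  best <- max(vapply(cands, `[[`, integer(1), "overlap"))
  cands <- cands[vapply(cands, `[[`, integer(1), "overlap") == best]
  keys <- vapply(cands, function(c) paste(c$a_end, c$b_cont - c$flapB - best),
                 character(1))
  cands <- cands[!duplicated(keys)]
  if (length(cands) > 1L) return("ambiguous")
  cands[[1]]
}

#' Isothermal overlap-directed assembly
#'
#' For every ordered pair of fragments and orientation, finds the longest
#' exact terminal overlap within `[min_overlap, max_overlap]`; the overlap
#' may sit up to `end_slack` bases inside either terminus, modelling
#' exonuclease chew-back of restriction scars, and the unmatched flaps are
#' trimmed at the splice. The assembly succeeds iff exactly one Hamiltonian
#' cycle (`expect = "circular"`) or path (`"linear"`) exists over the junction
#' graph; the assembled product is returned with a per-junction report.
#'
#' @param fragments List of linear sequences (`nucseq`, `amplicon`,
#'   `digest_fragment` or strings); 1--12 fragments.
#' @param min_overlap,max_overlap Acceptable exact-overlap bounds (bp).
#' @param expect `"circular"`, `"linear"`, or `"any"`.
#' @param end_slack Maximum trimmed flap per terminus (bp).
#' @param id Product id.
#' @return An `assembly_product`: `$seq` (canonicalized if circular) and
#'   `$junctions` (data.frame: left, right, overlap_bp, position).
#' @export
gibson <- function(fragments, min_overlap = 15L, max_overlap = 80L,
                   expect = c("circular", "linear", "any"), end_slack = 8L,
                   id = "assembly") {
  expect <- match.arg(expect)
  n <- length(fragments)
  if (n < 1L || n > 12L) stop("gibson supports 1-12 fragments")
  seqs <- lapply(fragments, .bases_of)
  for (s in seqs) .norm_bases(s)
  ids <- vapply(seq_len(n), function(i) .id_of(fragments[[i]], paste0("frag", i)),
                character(1))
  ids <- make.unique(ids)
  orient <- function(i, o) if (o == 1L) seqs[[i]] else revcomp(seqs[[i]])
  # junction table: edges[[key]] for (i,oi) -> (j,oj)
  edges <- list()
  ambiguous <- character(0)
  for (i in seq_len(n)) for (oi in 1:2) for (j in seq_len(n)) for (oj in 1:2) {
    if (i == j && n > 1L) next
    jn <- .best_junction(orient(i, oi), orient(j, oj),
                         min_overlap, max_overlap, end_slack)
    if (identical(jn, "ambiguous")) {
      ambiguous <- c(ambiguous, sprintf("%s(%s) -> %s(%s)", ids[i],
                                        c("+", "-")[oi], ids[j], c("+", "-")[oj]))
    } else if (!is.null(jn)) {
      edges[[paste(i, oi, j, oj)]] <- jn
    }
  }
  get_edge <- function(i, oi, j, oj) edges[[paste(i, oi, j, oj)]]
  solutions <- list()
  dfs <- function(path, orients, used) {
    k <- length(path)
    if (k == n) {
      if (expect %in% c("circular", "any")) {
        close <- get_edge(path[k], orients[k], path[1], orients[1])
        if (!is.null(close) && (n > 1L || TRUE))
          solutions[[length(solutions) + 1L]] <<-
            list(path = path, orients = orients, circular = TRUE)
      }
      if (expect %in% c("linear", "any") && n >= 1L)
        solutions[[length(solutions) + 1L]] <<-
          list(path = path, orients = orients, circular = FALSE)
      return(invisible())
    }
    for (j in seq_len(n)[!used]) for (oj in 1:2) {
      if (!is.null(get_edge(path[k], orients[k], j, oj))) {
        used2 <- used; used2[j] <- TRUE
        dfs(c(path, j), c(orients, oj), used2)
      }
    }
  }
  if (expect == "linear" || expect == "any") {
    for (s in seq_len(n)) for (os in 1:2) {
      used <- rep(FALSE, n); used[s] <- TRUE
      dfs(s, os, used)
    }
  } else {
    used <- rep(FALSE, n); used[1] <- TRUE
    dfs(1L, 1L, used)     # cycles can start anywhere; flipped cycles duplicate
  }
  build <- function(sol) {
    path <- sol$path; ors <- sol$orients
    m <- length(path)
    # Each fragment contributes the slice between its incoming junction's
    # continuation point and its outgoing junction's overlap end; the overlap
    # bases therefore appear exactly once, in the upstream contribution.
    contrib <- character(m)
    for (k in seq_len(m)) {
      s <- orient(path[k], ors[k])
      eL <- if (k > 1L) get_edge(path[k - 1L], ors[k - 1L], path[k], ors[k])
            else if (sol$circular) get_edge(path[m], ors[m], path[1], ors[1])
            else NULL
      eR <- if (k < m) get_edge(path[k], ors[k], path[k + 1L], ors[k + 1L])
            else if (sol$circular) get_edge(path[m], ors[m], path[1], ors[1])
            else NULL
      from <- if (is.null(eL)) 1L else eL$b_cont
      to <- if (is.null(eR)) nchar(s) else eR$a_end
      if (to < from) stop("degenerate fragment contribution")
      contrib[k] <- substr(s, from, to)
    }
    out <- paste(contrib, collapse = "")
    cum <- cumsum(nchar(contrib))
    left_id <- ids[path]
    right_id <- ids[c(path[-1], path[1])]
    ovl <- vapply(seq_len(m), function(k) {
      e <- get_edge(path[k], ors[k], path[(k %% m) + 1L], ors[(k %% m) + 1L])
      if (is.null(e)) NA_integer_ else e$overlap
    }, integer(1))
    pos <- cum - ovl + 1L   # junction k sits at the end of contribution k
    juncs <- data.frame(left = left_id, right = right_id, overlap_bp = ovl,
                        position = pos, stringsAsFactors = FALSE)
    if (!sol$circular) juncs <- juncs[-m, , drop = FALSE]
    topo <- if (sol$circular) "circular" else "linear"
    sq <- nuc_seq(id, out, topo)
    list(seq = sq, junctions = juncs, circular = sol$circular)
  }
  built <- lapply(solutions, function(s) tryCatch(build(s), error = function(e) NULL))
  built <- Filter(Negate(is.null), built)
  if (expect == "any" && any(vapply(built, `[[`, logical(1), "circular")))
    built <- Filter(function(b) b$circular, built)
  if (length(built) == 0L) {
    hint <- if (length(ambiguous) > 0L)
      paste0("; ambiguous equal-length overlaps at: ",
             paste(ambiguous, collapse = ", "))
    else {
      near <- .near_miss(seqs, min_overlap, max_overlap, end_slack)
      if (is.null(near)) "" else sprintf(
        "; best overlap found was %d bp (< min_overlap %d)", near, min_overlap)
    }
    stop("assembly failure: no fragment ordering closes the ", expect,
         " product", hint)
  }
  keys <- vapply(built, function(b) {
    if (b$circular) canonical_rotation(b$seq)$bases
    else min(b$seq$bases, revcomp(b$seq$bases))
  }, character(1))
  uniq <- !duplicated(keys)
  if (sum(uniq) > 1L)
    stop("assembly ambiguity: ", sum(uniq), " distinct products; junctions: ",
         paste(unique(unlist(lapply(built[uniq], function(b)
       paste(b$junctions$left, b$junctions$right, sep = "->")))), collapse = ", "))
  res <- built[[which(uniq)[1]]]
  if (res$circular) {
    can <- canonical_rotation(res$seq)
    res$junctions$position <- .remap_positions(res$seq$bases, can$bases,
                                               res$junctions$position,
                                               res$junctions$overlap_bp)
    res$seq <- can
  }
  structure(list(seq = res$seq, junctions = res$junctions,
                 n_fragments = n, min_overlap = min_overlap),
            class = "assembly_product")
}

.near_miss <- function(seqs, min_overlap, max_overlap, end_slack) {
  best <- 0L
  for (lo in seq(min_overlap - 1L, 8L)) {
    for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
      if (i == j) next
      for (A in c(seqs[[i]], revcomp(seqs[[i]])))
        for (B in c(seqs[[j]], revcomp(seqs[[j]]))) {
          jn <- .best_junction(A, B, lo, max_overlap, end_slack)
          if (!is.null(jn) && !identical(jn, "ambiguous"))
            best <- max(best, jn$overlap)
        }
    }
    if (best > 0L) break
  }
  if (best == 0L) NULL else best
}

# map junction positions from the raw circular product onto its canonical form
.remap_positions <- function(raw, canon, positions, overlaps) {
  L <- nchar(raw)
  dd <- paste0(raw, raw)
  k <- regexpr(canon, dd, fixed = TRUE)[1]
  if (k >= 1L) {  # canonical is a rotation of the forward strand
    return(((positions - 1L - (k - 1L)) %% L) + 1L)
  }
  rr <- revcomp(raw)
  dd <- paste0(rr, rr)
  k <- regexpr(canon, dd, fixed = TRUE)[1]
  # overlap [p, p+l-1] maps to [L - p - l + 2, ...] on the flipped strand
  flipped <- L - positions - overlaps + 2L
  (((flipped - 1L - (k - 1L)) %% L) + 1L)
}

#' @export
print.assembly_product <- function(x, ...) {
  cat(sprintf("<assembly_product> %s: %d bp (%s), %d fragment(s)\n",
              x$seq$id, nchar(x$seq$bases), x$seq$topology, x$n_fragments))
  print.data.frame(x$junctions, row.names = FALSE)
  invisible(x)
}

#' Linearize a plasmid with one enzyme
#'
#' A single cut returns the opened molecule; with two or more cuts the
#' fragments are produced by [digest()] and the retained piece is chosen by
#' `keep` (see [select_fragment()]), discarding stuffers.
#'
#' @param plasmid Circular [nuc_seq()].
#' @param enz Enzyme or name.
#' @param keep Selection criterion for multi-cut digests.
#' @return A `digest_fragment`.
#' @export
linearize <- function(plasmid, enz, keep = "largest") {
  stopifnot(inherits(plasmid, "nucseq"))
  if (plasmid$topology != "circular")
    stop("topology error: linearize needs a circular plasmid")
  sites <- find_sites(plasmid, enz)
  if (nrow(sites) == 0L)
    stop("uncut: ", enzyme(enz)$name, " does not cut '", plasmid$id, "'")
  frags <- digest(plasmid, list(enz))
  if (length(frags) == 1L) frags[[1]] else select_fragment(frags, keep)
}
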