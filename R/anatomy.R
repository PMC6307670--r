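## Element anatomy: reconstruct a species-specific consensus from genomic
## copies (majority rule over a center-star alignment), locate open reading
## frames and terminal inverted repeats, and scan the transposase for the
## mariner catalytic DD34D motif and the C-terminal YSPDLAP motif.

ALN_MATCH <- 2; ALN_MISMATCH <- -3; ALN_GAP_OPEN <- 5; ALN_GAP_EXT <- 2

#' @noRd
dna_submat <- function() {
  if (is.null(.ate_env$dna_mat)) {
    .ate_env$dna_mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = ALN_MATCH, mismatch = ALN_MISMATCH, baseOnly = FALSE)
  }
  .ate_env$dna_mat
}

#' Majority-rule consensus over a center-star alignment of genomic copies
#'
#' Fragments shorter than `min_fragment_bp` are dropped (the paper-style
#' length filter).  The longest fragment (ties: lexicographically smallest,
#' canonical strand) anchors the alignment; every other fragment is oriented
#' to it and aligned; columns supported by fewer than two fragments emit N;
#' base ties break by fixed order A < C < G < T.  Invariant to input order
#' and to strand flips of individual fragments.
#'
#' @param copies character vector of copy sequences (uppercase DNA, N ok).
#' @param min_fragment_bp minimum fragment length retained (default 100).
#' @param max_fragments cap on fragments entering the alignment (longest
#'   first, deterministic; default 60).
#' @return list with `consensus` (string or NA), `status`
#'   (`"ok"`/`"remnant_only"`), `n_fragments`, `support` (per-column
#'   fragment counts).
#' @export
build_consensus <- function(copies, min_fragment_bp = 100,
                            max_fragments = 60) {
  copies <- toupper(copies[!is.na(copies)])
  copies <- copies[nchar(copies) >= min_fragment_bp]
  if (length(copies) < 2) {
    return(list(consensus = NA_character_, status = "remnant_only",
                n_fragments = length(copies), support = integer(0)))
  }
  ## deterministic center: longest, ties by canonical-strand lexicographic
  canon <- vapply(copies, function(s) min(s, revcomp(s)), character(1),
                  USE.NAMES = FALSE)
  ord <- order(-nchar(copies), canon)
  copies <- copies[ord]; canon <- canon[ord]
  if (length(copies) > max_fragments) {
    copies <- copies[seq_len(max_fragments)]
    canon <- canon[seq_len(max_fragments)]
  }
  center <- canon[1]
  L <- nchar(center)
  counts <- matrix(0L, nrow = 4, ncol = L, dimnames = list(BASES, NULL))
  tally <- function(seqchars, poschars) {
    hit <- match(seqchars, BASES)
    ok <- !is.na(hit)
    ## positions are unique within one fragment, so plain indexed
    ## increment is safe
    idx <- cbind(hit[ok], poschars[ok])
    counts[idx] <<- counts[idx] + 1L
  }
  tally(strsplit(center, "")[[1]], seq_len(L))
  subj <- Biostrings::DNAString(center)
  for (i in seq_along(copies)[-1]) {
    fr <- copies[i]
    if (nchar(fr) == L) {
      ## full-length twin: orient by p-distance, map positionally
      pf <- p_distance(fr, center)
      pr <- p_distance(revcomp(fr), center)
      if (!is.na(pf) && !is.na(pr) && min(pf, pr) <= 0.25) {
        use <- if (pr < pf) revcomp(fr) else fr
        tally(strsplit(use, "")[[1]], seq_len(L))
        next
      }
    }
    fwd <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(fr), subj, type = "global-local",
      substitutionMatrix = dna_submat(),
      gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
    rev <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(revcomp(fr)), subj, type = "global-local",
      substitutionMatrix = dna_submat(),
      gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
    aln <- if (Biostrings::score(fwd) >= Biostrings::score(rev)) fwd else rev
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    sub_gap <- sa == "-"
    spos_all <- cumsum(!sub_gap) +
      (Biostrings::start(Biostrings::subject(aln)) - 1L)
    keep <- !sub_gap & pa != "-"
    tally(pa[keep], spos_all[keep])
  }
  support <- colSums(counts)
  cons <- rep("N", L)
  has <- support >= 2
  if (any(has)) {
    ## max.col ties.method "first" implements the A<C<G<T tie-break
    best <- max.col(t(counts[, has, drop = FALSE]), ties.method = "first")
    cons[has] <- BASES[best]
  }
  list(consensus = paste(cons, collapse = ""), status = "ok",
       n_fragments = length(copies), support = as.integer(support))
}

#' Find stop-to-stop open reading frames on both strands
#'
#' Reports every region between stop codons (or a sequence end) of at least
#' `min_len_nt` nt in all six frames, with the offset of the first internal
#' ATG.  Coordinates are 0-based half-open on the input sequence.
#'
#' @param seq DNA string.
#' @param min_len_nt minimum ORF length in nt (default 300).
#' @return data.frame sorted by length descending: strand, frame (1-3),
#'   start, end, length_nt, atg_offset (nt from ORF start to first ATG, NA
#'   if none), translation.
#' @export
find_orfs <- function(seq, min_len_nt = 300) {
  seq <- toupper(seq)
  L <- nchar(seq)
  tb <- codon_tables()
  rows <- list()
  for (strand in c("+", "-")) {
    work <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      if (L - f < 3) next
      cods <- seq_to_codons(substr(work, f + 1, L))
      if (!length(cods)) next
      idx <- match(cods, tb$codons)
      stop_at <- which(is.na(idx) | tb$is_stop[idx])
      bounds <- c(0L, stop_at, length(cods) + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        c0 <- bounds[b] + 1L; c1 <- bounds[b + 1L] - 1L
        if (c1 < c0) next
        len <- (c1 - c0 + 1L) * 3L
        if (len < min_len_nt) next
        s_work <- f + (c0 - 1L) * 3L          # 0-based on working strand
        e_work <- s_work + len
        if (strand == "+") {
          s0 <- s_work; e0 <- e_work
        } else {
          s0 <- L - e_work; e0 <- L - s_work
        }
        atg <- which(cods[c0:c1] == "ATG")
        rows[[length(rows) + 1L]] <- data.frame(
          strand = strand, frame = f + 1L, start = s0, end = e0,
          length_nt = len,
          atg_offset = if (length(atg)) (atg[1] - 1L) * 3L else NA_integer_,
          translation = paste(tb$aa[idx[c0:c1]], collapse = ""))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      length_nt = integer(0), atg_offset = integer(0),
                      translation = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$length_nt, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate terminal inverted repeats
#'
#' Best local alignment between the 5' terminal region and the reverse
#' complement of the 3' terminal region; reported when the aligned block
#' reaches `min_len` and `min_identity`.
#'
#' @param seq DNA string (length >= 2 * min_len).
#' @param min_len minimum TIR length (default 10).
#' @param min_identity minimum identity over the aligned block (default 0.8).
#' @param term_bp how much of each terminus to search (default 100;
#'   terminal inverted repeats sit at the element ends, and a narrow
#'   window keeps the chance of a spurious inverted match low).
#' @return list with 0-based half-open `left` and `right` intervals,
#'   `identity` and `length`, or `NULL` when no TIR qualifies (element
#'   flagged non-intact by callers).
#' @export
find_tirs <- function(seq, min_len = 10, min_identity = 0.80,
                      term_bp = 100) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 2 * min_len) stop("validation error: sequence shorter than 2*min_len")
  w <- min(term_bp, L %/% 2)
  head_s <- substr(seq, 1, w)
  tail_s <- substr(seq, L - w + 1, L)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(head_s),
    Biostrings::DNAString(revcomp(tail_s)), type = "local",
    substitutionMatrix = dna_submat(),
    gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
  alen <- Biostrings::nchar(aln)
  if (alen == 0) return(NULL)
  ident <- Biostrings::nmatch(aln) / alen
  if (alen < min_len || ident < min_identity) return(NULL)
  ps <- Biostrings::start(Biostrings::pattern(aln))
  pe <- Biostrings::end(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  se <- Biostrings::end(Biostrings::subject(aln))
  list(left = c(ps - 1L, pe), right = c(L - se, L - ss + 1L),
       identity = ident, length = alen)
}

#' Scan a transposase for mariner signature motifs
#'
#' Reports (a) DD34D spacing hits: an aspartate pair `(i, j)` preceded by an
#' earlier acidic D, with exactly 34 residues between the second and third D
#' (`protein[j]` and `protein[j + 35]` both D), and (b) the C-terminal
#' YSPDLAP heptapeptide at up to one mismatch.
#'
#' @param protein amino-acid string.
#' @return list with data.frames `dd34d` (d1, d2, d3; 1-based positions)
#'   and `yspdlap` (start, mismatches).
#' @export
scan_mariner_motifs <- function(protein) {
  p <- strsplit(toupper(protein), "")[[1]]
  n <- length(p)
  d_pos <- which(p == "D")
  dd <- data.frame(d1 = integer(0), d2 = integer(0), d3 = integer(0))
  for (j in d_pos) {
    if (j + 35L <= n && p[j + 35L] == "D") {
      earlier <- d_pos[d_pos < j]
      if (length(earlier)) {
        dd <- rbind(dd, data.frame(d1 = max(earlier), d2 = j,
                                   d3 = j + 35L))
      }
    }
  }
  motif <- strsplit("YSPDLAP", "")[[1]]
  ys <- data.frame(start = integer(0), mismatches = integer(0))
  if (n >= 7) {
    for (s in seq_len(n - 6L)) {
      mm <- sum(p[s:(s + 6L)] != motif)
      if (mm <= 1L) ys <- rbind(ys, data.frame(start = s, mismatches = mm))
    }
  }
  list(dd34d = dd, yspdlap = ys)
}

#' Autonomy flag: intact ORF, a TIR pair, and a DD34D catalytic motif
#'
#' @param seq element (consensus) DNA sequence.
#' @param min_orf_nt minimum intact ORF length (default 1059, the
#'   transposase convention).
#' @return list with `autonomous` flag and the underlying evidence.
#' @export
element_autonomy <- function(seq, min_orf_nt = 1059) {
  orfs <- find_orfs(seq, min_len_nt = min_orf_nt)
  tir <- find_tirs(seq)
  motifs <- if (nrow(orfs)) scan_mariner_motifs(orfs$translation[1]) else
    list(dd34d = data.frame(), yspdlap = data.frame())
  list(autonomous = nrow(orfs) > 0 && !is.null(tir) && nrow(motifs$dd34d) > 0,
       orfs = orfs, tir = tir, motifs = motifs)
}
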