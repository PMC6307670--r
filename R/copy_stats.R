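## Copy statistics: conservative copy counting at a consensus-coverage
## threshold (with merging of overlapping loci to avoid double counting),
## strand-normalized dereplication of identical copies, and nucleotide
## diversity (pi) as the mean pairwise model-corrected distance with a
## column bootstrap.

#' Count genomic copies at a coverage threshold
#'
#' Hits covering at least `min_coverage` of the consensus are counted
#' (inclusive, "at least").  Same-strand hits overlapping more than 50%
#' reciprocally are merged into one locus first, so a large internal
#' deletion cannot be double counted.
#'
#' @param hits data.frame with `coverage` in `[0,1]`; optional `subject`,
#'   `sstart`, `send`, `strand` columns enable the locus merge.
#' @param min_coverage coverage threshold (0.60 within-genome counting,
#'   0.40 for cross-species counts).
#' @return integer copy count.
#' @export
count_copies <- function(hits, min_coverage = 0.60) {
  if (is.null(hits) || nrow(hits) == 0) return(0L)
  if (any(hits$coverage < 0 | hits$coverage > 1, na.rm = TRUE)) {
    stop("validation error: coverage outside [0,1]")
  }
  keep <- hits[!is.na(hits$coverage) & hits$coverage >= min_coverage, ,
               drop = FALSE]
  if (nrow(keep) == 0) return(0L)
  if (!all(c("subject", "sstart", "send") %in% names(keep))) {
    return(nrow(keep))
  }
  if (!"strand" %in% names(keep)) keep$strand <- "+"
  n <- 0L
  for (grp in split(keep, paste(keep$subject, keep$strand))) {
    grp <- grp[order(grp$sstart), , drop = FALSE]
    last_s <- NA_real_; last_e <- NA_real_
    for (i in seq_len(nrow(grp))) {
      s <- grp$sstart[i]; e <- grp$send[i]
      ov <- if (is.na(last_e)) -Inf else min(e, last_e) - max(s, last_s)
      if (!is.na(last_e) && ov > 0.5 * min(e - s, last_e - last_s)) {
        last_e <- max(last_e, e)              # same locus, extend
      } else {
        n <- n + 1L
        last_s <- s; last_e <- e
      }
    }
  }
  n
}

#' Group identical copies after strand normalization
#'
#' Each sequence is keyed by the lexicographic minimum of itself and its
#' reverse complement, so a copy and its flipped twin land in one group.
#'
#' @param sequences character vector of copy sequences.
#' @return list with `groups` (list of index vectors, multi-copy groups
#'   first), `n_variants_multi` (variants with >= 2 identical copies) and
#'   `n_copies_multi` (total copies in such groups).
#' @export
dereplicate_identical <- function(sequences) {
  if (!length(sequences)) {
    return(list(groups = list(), n_variants_multi = 0L,
                n_copies_multi = 0L))
  }
  key <- vapply(toupper(sequences), function(s) min(s, revcomp(s)),
                character(1), USE.NAMES = FALSE)
  groups <- split(seq_along(sequences), key)
  names(groups) <- NULL
  groups <- groups[order(-lengths(groups),
                         vapply(groups, `[`, integer(1), 1))]
  multi <- lengths(groups) >= 2
  list(groups = groups,
       n_variants_multi = sum(multi),
       n_copies_multi = sum(lengths(groups)[multi]))
}

#' Vectorized corrected distances from per-pair difference counts
#' @noRd
correct_dist <- function(n_ok, n_diff, n_ts, model, strict = TRUE) {
  p <- n_diff / n_ok
  if (model == "p") return(p)
  if (model == "JC") {
    bad <- p >= 0.75
    if (any(bad, na.rm = TRUE) && strict) {
      stop("distance correction undefined: p >= 3/4 for ",
           sum(bad, na.rm = TRUE), " pair(s)")
    }
    out <- -0.75 * log(1 - 4 * p / 3)
    out[bad] <- NA_real_
    return(out)
  }
  ts <- n_ts / n_ok
  tv <- p - ts
  w1 <- 1 - 2 * ts - tv
  w2 <- 1 - 2 * tv
  bad <- w1 <= 0 | w2 <= 0
  if (any(bad, na.rm = TRUE) && strict) {
    stop("distance correction undefined: saturation for ",
         sum(bad, na.rm = TRUE), " pair(s)")
  }
  out <- -0.5 * log(w1) - 0.25 * log(w2)
  out[bad] <- NA_real_
  out
}

#' Nucleotide diversity among aligned copies
#'
#' pi is the mean over all sequence pairs of the model-corrected distance
#' (pairwise deletion of gap/N sites); the standard error comes from a
#' bootstrap over alignment columns.
#'
#' @param aligned character vector of equal-length aligned sequences
#'   (length >= 2).
#' @param model `"p"`, `"JC"` or `"K2P"` (default).
#' @param n_bootstrap bootstrap replications (default 1000).
#' @param seed seed for the bootstrap resampling.
#' @return object of class `diversity_estimate`: `pi`, `se`, `n`, `model`.
#' @export
nucleotide_diversity <- function(aligned, model = c("K2P", "JC", "p"),
                                 n_bootstrap = 1000, seed = 1L) {
  model <- match.arg(model)
  aligned <- toupper(aligned)
  if (length(aligned) < 2) stop("validation error: need >= 2 sequences")
  if (length(unique(nchar(aligned))) != 1) {
    stop("validation error: sequences must be aligned to equal length")
  }
  mat <- do.call(rbind, strsplit(aligned, ""))
  n <- nrow(mat); L <- ncol(mat)
  pr <- utils::combn(n, 2)
  is_base <- matrix(mat %in% BASES, n, L)
  ## per-pair x per-column indicators; matrix products give weighted counts
  OK <- (is_base[pr[1, ], , drop = FALSE] &
           is_base[pr[2, ], , drop = FALSE]) * 1
  DF <- (mat[pr[1, ], , drop = FALSE] !=
           mat[pr[2, ], , drop = FALSE]) * OK
  TS <- NULL
  if (model == "K2P") {
    pur <- matrix(mat %in% c("A", "G"), n, L)
    same_class <- (pur[pr[1, ], , drop = FALSE] ==
                     pur[pr[2, ], , drop = FALSE]) * 1
    TS <- DF * same_class
  }
  w1 <- rep(1, L)
  d <- correct_dist(OK %*% w1, DF %*% w1,
                    if (is.null(TS)) NULL else TS %*% w1, model)
  pi_hat <- mean(d)
  se <- 0
  if (pi_hat > 0 && n_bootstrap > 0) {
    set.seed(seed)
    reps <- vapply(seq_len(n_bootstrap), function(b) {
      w <- tabulate(sample.int(L, L, replace = TRUE), L)
      db <- correct_dist(OK %*% w, DF %*% w,
                         if (is.null(TS)) NULL else TS %*% w, model,
                         strict = FALSE)
      mean(db, na.rm = TRUE)
    }, numeric(1))
    se <- stats::sd(reps)
  }
  structure(list(pi = pi_hat, se = se, n = length(aligned), model = model),
            class = "diversity_estimate")
}
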