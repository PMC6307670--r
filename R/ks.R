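## Synonymous/nonsynonymous divergence, Nei-Gojobori (1986) counting:
## amino-acid-guided codon alignment, fractional site counts averaged over
## the two sequences, pathway-averaged difference counts for
## multi-substitution codons, and Jukes-Cantor correction
## d = -(3/4) ln(1 - (4/3) p).  This single estimator is applied identically
## to element copies and to nuclear genes, which is what the divergence
## contrast requires.

#' Amino-acid-guided pairwise codon alignment
#'
#' Sequences are trimmed to complete codons, translated, globally aligned at
#' the protein level (BLOSUM62, affine gaps) and the alignment is threaded
#' back to codons; every codon column containing a gap is removed.
#' Equal-length pairs whose translations are directly comparable skip the
#' aligner (gap-free global alignment is optimal for them).
#'
#' @param nuc_a,nuc_b in-frame coding DNA strings, no internal stop codons.
#' @param conserved_block apply the sliding-window conserved-block filter
#'   (15-column windows, >= 50% conserved) after gap removal.  Off by
#'   default; recommended for cross-species element comparisons.
#' @return object of class `codon_alignment`: `codons_a`, `codons_b`
#'   (equal-length codon vectors), `n_removed_gap`, `n_removed_block`.
#' @export
codon_align <- function(nuc_a, nuc_b, conserved_block = FALSE) {
  prep <- function(s, label) {
    cods <- seq_to_codons(s)
    if (length(cods) == 0) stop("validation error: empty sequence ", label)
    idx <- codon_index(cods)
    tb <- codon_tables()
    stops <- which(tb$is_stop[idx])
    stops <- stops[stops < length(idx)]
    if (length(stops)) {
      stop("validation error: internal stop codon in ", label,
           " at codon ", stops[1])
    }
    ## drop a terminal stop so it cannot enter the comparison
    if (tb$is_stop[idx[length(idx)]]) cods <- cods[-length(cods)]
    cods
  }
  ca <- prep(nuc_a, "a")
  cb <- prep(nuc_b, "b")
  tb <- codon_tables()
  aa_a <- tb$aa[codon_index(ca)]
  aa_b <- tb$aa[codon_index(cb)]
  if (length(ca) == length(cb)) {
    keep_a <- seq_along(ca); keep_b <- seq_along(cb)
    n_gap <- 0L
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(paste(aa_a, collapse = "")),
      Biostrings::AAString(paste(aa_b, collapse = "")),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ia <- cumsum(pa != "-")
    ib <- cumsum(sa != "-")
    both <- pa != "-" & sa != "-"
    keep_a <- ia[both]; keep_b <- ib[both]
    n_gap <- sum(!both)
  }
  codons_a <- ca[keep_a]
  codons_b <- cb[keep_b]
  n_block <- 0L
  if (conserved_block && length(codons_a) >= 15) {
    cons <- tb$aa[codon_index(codons_a)] == tb$aa[codon_index(codons_b)]
    w <- 15L
    frac <- stats::filter(as.numeric(cons), rep(1 / w, w), sides = 2)
    drop <- logical(length(cons))
    bad_centers <- which(!is.na(frac) & frac < 0.5)
    for (ctr in bad_centers) {
      lo <- max(1L, ctr - w %/% 2L)
      hi <- min(length(cons), ctr + w %/% 2L)
      drop[lo:hi] <- TRUE
    }
    n_block <- sum(drop)
    codons_a <- codons_a[!drop]
    codons_b <- codons_b[!drop]
  }
  structure(list(codons_a = codons_a, codons_b = codons_b,
                 n_removed_gap = n_gap, n_removed_block = n_block,
                 conserved_block = conserved_block),
            class = "codon_alignment")
}

#' NG86 synonymous/nonsynonymous divergence for one codon alignment
#'
#' Fractional synonymous site counts per codon (changes to stop codons count
#' as nonsynonymous) are averaged over the two sequences; differences in
#' codons differing at several positions are averaged over all substitution
#' pathways not passing through a stop codon; proportions are corrected
#' with the Jukes-Cantor formula.  `p >= 3/4` is flagged `saturated`,
#' `S = 0` is flagged `S_zero`; both leave the corresponding rate `NA`.
#'
#' @param alignment a [codon_align()] result.
#' @param min_codons minimum codons compared (default 10).
#' @return one-row data.frame (`ks_record`): ks, ka, S, N, Sd, Nd, pS, pN,
#'   codons, method, flag.
#' @export
ks_ng86 <- function(alignment, min_codons = 10) {
  stopifnot(inherits(alignment, "codon_alignment"))
  ia <- codon_index(alignment$codons_a)
  ib <- codon_index(alignment$codons_b)
  nc <- length(ia)
  if (nc < min_codons) {
    stop("validation error: fewer than ", min_codons, " codons compared")
  }
  tb <- codon_tables()
  ng <- ng86_tables()
  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  N <- 3 * nc - S
  Sd <- sum(ng$sd[cbind(ia, ib)])
  Nd <- sum(ng$nd[cbind(ia, ib)])
  flag <- "ok"
  ks <- ka <- NA_real_
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  if (S == 0) {
    flag <- "S_zero"
  } else if (pS >= 0.75 || (!is.na(pN) && pN >= 0.75)) {
    flag <- "saturated"
  } else {
    ks <- -0.75 * log(1 - 4 * pS / 3)
    ka <- if (!is.na(pN)) -0.75 * log(1 - 4 * pN / 3) else NA_real_
  }
  out <- data.frame(ks = ks, ka = ka, S = S, N = N, Sd = Sd, Nd = Nd,
                    pS = pS, pN = pN, codons = nc, method = "NG86-JC",
                    flag = flag)
  class(out) <- c("ks_record", class(out))
  out
}

#' All-against-all Ks between two copy sets
#'
#' Attempts exactly `length(set_a) * length(set_b)` comparisons; per-pair
#' failures (alignment or estimation errors) are collected, not fatal.
#'
#' @param set_a,set_b named or unnamed character vectors of coding
#'   sequences.
#' @param conserved_block passed to [codon_align()].
#' @param min_codons passed to [ks_ng86()].
#' @return list with `records` (data.frame, columns id_a, id_b + ks_record
#'   fields), `failures` (id_a, id_b, error), `n_attempted`.
#' @export
cross_set_ks <- function(set_a, set_b, conserved_block = FALSE,
                         min_codons = 10) {
  if (!length(set_a) || !length(set_b)) {
    stop("validation error: both sets must be non-empty")
  }
  ids_a <- if (is.null(names(set_a))) paste0("a", seq_along(set_a)) else names(set_a)
  ids_b <- if (is.null(names(set_b))) paste0("b", seq_along(set_b)) else names(set_b)
  recs <- list(); fails <- list()
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      res <- tryCatch({
        aln <- codon_align(set_a[[i]], set_b[[j]],
                           conserved_block = conserved_block)
        cbind(data.frame(id_a = ids_a[i], id_b = ids_b[j]),
              ks_ng86(aln, min_codons = min_codons))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          id_a = ids_a[i], id_b = ids_b[j], error = conditionMessage(res))
      } else {
        recs[[length(recs) + 1L]] <- res
      }
    }
  }
  list(records = if (length(recs)) do.call(rbind, recs) else NULL,
       failures = if (length(fails)) do.call(rbind, fails) else NULL,
       n_attempted = length(set_a) * length(set_b))
}

#' Codon-based Z-test for purifying selection
#'
#' Z = (dS - dN) / sqrt(Var(dS) + Var(dN)) with variances from a bootstrap
#' over codon columns; the one-tailed p-value addresses H1: dN < dS.
#' Degenerate variance (all replicates equal) yields p = 1 with a flag.
#'
#' @param alignment a [codon_align()] result.
#' @param n_bootstrap codon bootstrap replications (default 1000).
#' @param seed bootstrap seed.
#' @return list: `z`, `p`, `dS`, `dN`, `var_dS`, `var_dN`, `flag`.
#' @export
codon_z_test <- function(alignment, n_bootstrap = 1000, seed = 1L) {
  stopifnot(inherits(alignment, "codon_alignment"))
  ia <- codon_index(alignment$codons_a)
  ib <- codon_index(alignment$codons_b)
  nc <- length(ia)
  tb <- codon_tables()
  ng <- ng86_tables()
  ## per-codon contributions; the bootstrap only resamples these
  s_sites <- (tb$syn_sites[ia] + tb$syn_sites[ib]) / 2
  n_sites <- 3 - s_sites
  sd_i <- ng$sd[cbind(ia, ib)]
  nd_i <- ng$nd[cbind(ia, ib)]
  d_from <- function(idx) {
    S <- sum(s_sites[idx]); N <- sum(n_sites[idx])
    pS <- if (S > 0) sum(sd_i[idx]) / S else NA_real_
    pN <- if (N > 0) sum(nd_i[idx]) / N else NA_real_
    c(dS = if (!is.na(pS) && pS < 0.75) -0.75 * log(1 - 4 * pS / 3) else NA_real_,
      dN = if (!is.na(pN) && pN < 0.75) -0.75 * log(1 - 4 * pN / 3) else NA_real_)
  }
  pt <- d_from(seq_len(nc))
  set.seed(seed)
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    d_from(sample.int(nc, nc, replace = TRUE))
  }, numeric(2))
  v_s <- stats::var(boot["dS", ], na.rm = TRUE)
  v_n <- stats::var(boot["dN", ], na.rm = TRUE)
  if (!is.finite(v_s)) v_s <- 0
  if (!is.finite(v_n)) v_n <- 0
  if (v_s + v_n == 0 || is.na(pt["dS"]) || is.na(pt["dN"])) {
    return(list(z = 0, p = 1, dS = unname(pt["dS"]), dN = unname(pt["dN"]),
                var_dS = v_s, var_dN = v_n, flag = "degenerate"))
  }
  z <- (pt["dS"] - pt["dN"]) / sqrt(v_s + v_n)
  list(z = unname(z), p = stats::pnorm(z, lower.tail = FALSE),
       dS = unname(pt["dS"]), dN = unname(pt["dN"]),
       var_dS = v_s, var_dN = v_n, flag = "ok")
}

#' Benjamini-Hochberg adjustment across elements
#'
#' @param pvals numeric p-values.
#' @return adjusted p-values (monotone, bounded by 1).
#' @export
bh_fdr <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}
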