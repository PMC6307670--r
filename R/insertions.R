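## Insertion polymorphism between haploid brothers: IBD-window discovery
## from SNP density, non-reference insertion calling from junction reads
## with target-site-duplication evidence, family-occupancy classification,
## and the de novo insertion-rate bound over the IBD-informative genome.

#' Classify 10 kb windows as IBD / non-IBD from SNP density
#'
#' Windows tile `[0, genome_length)`; per-window SNP counts are classified
#' by a two-component Poisson mixture (EM), falling back to a fixed count
#' threshold when the mixture is degenerate.  Input SNPs are assumed to be
#' heterozygous-between-brothers calls (homozygous-vs-reference removed
#' upstream).
#'
#' @param snp_table data.frame with `chrom`, `pos` (1-based) and optionally
#'   `family`; each family is classified separately.
#' @param genome_length pseudochromosome length in nt.
#' @param window_bp window size (default 10000).
#' @param method `"mixture"` (default) or `"threshold"`.
#' @param threshold fallback/fixed IBD threshold: window is IBD when its
#'   SNP count is <= `threshold` (default 2).
#' @return list with `windows` (family, chrom, start, end, snp_count,
#'   state) and `ibd_fraction` (named per family).
#' @export
ibd_windows <- function(snp_table, genome_length, window_bp = 10000,
                        method = c("mixture", "threshold"), threshold = 2) {
  method <- match.arg(method)
  n_win <- max(1L, as.integer(ceiling(genome_length / window_bp)))
  if (is.null(snp_table) || nrow(snp_table) == 0) {
    warning("empty SNP table: all windows called IBD")
    win <- data.frame(family = "all", chrom = "chr1",
                      start = (seq_len(n_win) - 1L) * window_bp,
                      end = pmin(seq_len(n_win) * window_bp, genome_length),
                      snp_count = 0L, state = "IBD")
    return(list(windows = win, ibd_fraction = c(all = 1)))
  }
  if (!"family" %in% names(snp_table)) snp_table$family <- "all"
  fams <- unique(snp_table$family)
  all_counts <- lapply(fams, function(fam) {
    sub <- snp_table[snp_table$family == fam, , drop = FALSE]
    w <- pmin((sub$pos - 1L) %/% window_bp + 1L, n_win)
    tabulate(w, n_win)
  })
  names(all_counts) <- fams
  classify <- function(counts) {
    if (method == "mixture") {
      fit <- poisson_mixture2(counts)
      if (!is.null(fit)) return(fit$ibd)
    }
    counts <= threshold
  }
  rows <- list(); frac <- numeric(length(fams)); names(frac) <- fams
  for (fam in fams) {
    ibd <- classify(all_counts[[fam]])
    chrom <- snp_table$chrom[snp_table$family == fam][1]
    rows[[fam]] <- data.frame(
      family = fam, chrom = chrom,
      start = (seq_len(n_win) - 1L) * window_bp,
      end = pmin(seq_len(n_win) * window_bp, as.integer(genome_length)),
      snp_count = all_counts[[fam]],
      state = ifelse(ibd, "IBD", "non-IBD"))
    frac[fam] <- mean(ibd)
  }
  win <- do.call(rbind, rows)
  rownames(win) <- NULL
  list(windows = win, ibd_fraction = frac)
}

#' Two-component Poisson mixture via EM; returns NULL when degenerate
#' @noRd
poisson_mixture2 <- function(counts, max_iter = 200, tol = 1e-8) {
  med <- stats::median(counts)
  l0 <- mean(counts[counts <= med]); l1 <- mean(counts[counts > med])
  if (!is.finite(l1) || l1 - l0 < 1) return(NULL)
  w <- 0.5
  l0 <- max(l0, 1e-3)
  for (it in seq_len(max_iter)) {
    d0 <- w * stats::dpois(counts, l0)
    d1 <- (1 - w) * stats::dpois(counts, l1)
    g <- d0 / (d0 + d1)
    g[!is.finite(g)] <- 0.5
    w_new <- mean(g)
    l0_new <- max(sum(g * counts) / sum(g), 1e-3)
    l1_new <- max(sum((1 - g) * counts) / sum(1 - g), 1e-3)
    delta <- abs(w_new - w) + abs(l0_new - l0) + abs(l1_new - l1)
    w <- w_new; l0 <- l0_new; l1 <- l1_new
    if (delta < tol) break
  }
  if (l1 - l0 < 1 || w < 1e-3 || w > 1 - 1e-3) return(NULL)
  d0 <- w * stats::dpois(counts, l0)
  d1 <- (1 - w) * stats::dpois(counts, l1)
  list(ibd = d0 >= d1, lambda_ibd = l0, lambda_non = l1, weight_ibd = w)
}

#' Call non-reference insertions from junction reads
#'
#' Reads below `min_mapq` (never below 10) are dropped.  Left-side reads
#' end at the right edge of the target-site duplication, right-side reads
#' start at its left edge; a left cluster and a right cluster whose
#' breakpoints overlap by a length inside `tsd_range` produce a call with
#' that overlap as the TSD.  A locus where a carrier individual also shows
#' TE-absent spanning reads is flagged `excised`.
#'
#' @param junction_reads data.frame: chrom, start, end (0-based half-open),
#'   mapq, side (`"left"`/`"right"`/`"absent"`), family, individual.
#' @param reference optional reference sequence for TSD sequence lookup.
#' @param min_mapq mapping-quality floor (default 10; lower values are
#'   raised to 10).
#' @param tsd_range allowed TSD lengths, inclusive (default c(2, 10)).
#' @param min_support minimum reads per side (default 2).
#' @param cluster_tol breakpoint clustering tolerance in bp (default 2).
#' @return list with `calls` and `low_confidence` data.frames.
#' @export
call_insertions <- function(junction_reads, reference = NULL,
                            min_mapq = 10, tsd_range = c(2, 10),
                            min_support = 2, cluster_tol = 2) {
  min_mapq <- max(min_mapq, 10)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), tsd_len = integer(0),
                      tsd_seq = character(0), n_left = integer(0),
                      n_right = integer(0), min_mapq = integer(0),
                      families = character(0), individuals = character(0),
                      excised = logical(0))
  if (is.null(junction_reads) || nrow(junction_reads) == 0) {
    return(list(calls = empty, low_confidence = empty))
  }
  jr <- junction_reads[junction_reads$mapq >= min_mapq, , drop = FALSE]
  if (nrow(jr) == 0) return(list(calls = empty, low_confidence = empty))
  cluster_pos <- function(pos) {
    o <- order(pos)
    brk <- c(TRUE, diff(pos[o]) > cluster_tol)
    grp <- cumsum(brk)
    split(o, grp)
  }
  calls <- list(); lowconf <- list()
  for (chrom in unique(jr$chrom)) {
    sub <- jr[jr$chrom == chrom, , drop = FALSE]
    left <- sub[sub$side == "left", , drop = FALSE]
    right <- sub[sub$side == "right", , drop = FALSE]
    absent <- sub[sub$side == "absent", , drop = FALSE]
    if (!nrow(left) || !nrow(right)) next
    lcl <- cluster_pos(left$end)
    rcl <- cluster_pos(right$start)
    r_bp <- vapply(rcl, function(ix) as.integer(round(stats::median(
      right$start[ix]))), integer(1))
    for (li in lcl) {
      if (length(li) < min_support) next
      e <- as.integer(round(stats::median(left$end[li])))
      ov <- e - r_bp
      cand <- which(ov >= 1 & ov <= max(tsd_range) + 5 &
                      lengths(rcl) >= min_support)
      if (!length(cand)) next
      best <- cand[which.max(lengths(rcl)[cand])]
      ri <- rcl[[best]]
      s <- r_bp[best]
      tsd_len <- e - s
      inds <- unique(c(left$individual[li], right$individual[ri]))
      fams <- unique(c(left$family[li], right$family[ri]))
      exc <- nrow(absent) > 0 &&
        any(absent$start < e & absent$end > s &
              absent$individual %in% inds)
      row <- data.frame(
        chrom = chrom, start = s, end = e, tsd_len = tsd_len,
        tsd_seq = if (!is.null(reference))
          substr(reference, s + 1, e) else NA_character_,
        n_left = length(li), n_right = length(ri),
        min_mapq = min(c(left$mapq[li], right$mapq[ri])),
        families = paste(sort(fams), collapse = ","),
        individuals = paste(sort(inds), collapse = ","),
        excised = exc)
      if (tsd_len >= tsd_range[1] && tsd_len <= tsd_range[2]) {
        calls[[length(calls) + 1L]] <- row
      } else {
        lowconf[[length(lowconf) + 1L]] <- row
      }
    }
  }
  bindr <- function(x) if (length(x)) {
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  } else empty
  list(calls = bindr(calls), low_confidence = bindr(lowconf))
}

#' Classify calls as family-specific or common and summarize occupancy
#'
#' Calls within `merge_tol` bp are treated as one locus (their family sets
#' are unioned); a locus found in >= 2 families is `common`.  An optional
#' BED-style exclusion mask (chrom, start, end) is applied first.
#'
#' @param calls a `calls` data.frame from [call_insertions()].
#' @param merge_tol merge tolerance in bp (default 10, the maximum TSD).
#' @param exclusion_mask optional data.frame (chrom, start, end).
#' @return list with `calls` (one row per locus, `class` column) and
#'   `summary` (n_total, n_common, n_family_specific, per_family_unique).
#' @export
classify_family_occupancy <- function(calls, merge_tol = 10,
                                      exclusion_mask = NULL) {
  if (!is.null(exclusion_mask) && nrow(calls)) {
    keep <- vapply(seq_len(nrow(calls)), function(i) {
      m <- exclusion_mask[exclusion_mask$chrom == calls$chrom[i], ,
                          drop = FALSE]
      !any(calls$start[i] < m$end & calls$end[i] > m$start)
    }, logical(1))
    calls <- calls[keep, , drop = FALSE]
  }
  if (!nrow(calls)) {
    return(list(calls = calls,
                summary = list(n_total = 0L, n_common = 0L,
                               n_family_specific = 0L,
                               per_family_unique = integer(0))))
  }
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  grp <- integer(nrow(calls))
  g <- 1L; grp[1] <- g
  if (nrow(calls) > 1) {
    for (i in 2:nrow(calls)) {
      if (calls$chrom[i] == calls$chrom[i - 1] &&
          calls$start[i] - calls$start[i - 1] <= merge_tol) {
        grp[i] <- g
      } else {
        g <- g + 1L; grp[i] <- g
      }
    }
  }
  merged <- lapply(split(seq_len(nrow(calls)), grp), function(ix) {
    fams <- sort(unique(unlist(strsplit(calls$families[ix], ","))))
    row <- calls[ix[1], , drop = FALSE]
    row$families <- paste(fams, collapse = ",")
    row$n_families <- length(fams)
    row$class <- if (length(fams) >= 2) "common" else "family_specific"
    row$excised <- any(calls$excised[ix])
    row
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  fs <- out[out$class == "family_specific", , drop = FALSE]
  per_fam <- table(fs$families)
  list(calls = out,
       summary = list(
         n_total = nrow(out),
         n_common = sum(out$class == "common"),
         n_family_specific = nrow(fs),
         per_family_unique = stats::setNames(as.integer(per_fam),
                                             names(per_fam))))
}

#' De novo insertion-rate bound over the IBD-informative genome
#'
#' The informative sample is `g = n_individuals * mean_ibd_fraction`
#' effective genomes.  With zero new insertions observed the rate is
#' bounded above by 1/g per genome per generation; otherwise the point
#' estimate n/g is returned.
#'
#' @param n_individuals haploid individuals surveyed (>= 1).
#' @param mean_ibd_fraction mean IBD fraction per brother pair (0 < f <= 1).
#' @param n_new_insertions_observed de novo insertions seen in IBD regions.
#' @return list: `effective_genomes`, `rate`, `type`
#'   (`"upper_bound"`/`"point_estimate"`).
#' @export
insertion_rate_bound <- function(n_individuals, mean_ibd_fraction,
                                 n_new_insertions_observed) {
  if (n_individuals < 1) stop("validation error: n_individuals >= 1")
  if (mean_ibd_fraction <= 0 || mean_ibd_fraction > 1) {
    stop("validation error: mean_ibd_fraction must lie in (0, 1]")
  }
  g <- n_individuals * mean_ibd_fraction
  if (n_new_insertions_observed == 0) {
    list(effective_genomes = g, rate = 1 / g, type = "upper_bound")
  } else {
    list(effective_genomes = g, rate = n_new_insertions_observed / g,
         type = "point_estimate")
  }
}
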