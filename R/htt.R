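## Horizontal-transfer inference: presence/absence scanning across genome
## assemblies (patchy distribution), the Games-Howell unequal-variance
## contrast of element Ks versus nuclear-gene Ks, and phylogenetic
## incongruence via neighbor-joining trees and Robinson-Foulds distance.

#' Scan a genome for an element; call presence by the established criterion
#'
#' Seeded k-mer matching (both strands) followed by local alignment of the
#' consensus against each candidate region.  Presence requires at least one
#' hit with alignment length strictly greater than `min_hit_len` and
#' identity strictly greater than `min_identity`.
#'
#' @param consensus element consensus sequence.
#' @param genome genome sequence (single string) or named character vector
#'   of contigs.
#' @param min_hit_len presence length threshold, exclusive (default 100).
#' @param min_identity presence identity threshold, exclusive (default 0.90).
#' @param k seed k-mer length (default 12).
#' @return object of class `presence_call`: `present`, `best_len`,
#'   `best_identity`, `n_copies_40` (hits covering >= 40% of the consensus),
#'   `hits` (data.frame, 0-based half-open genomic intervals).
#' @export
presence_scan <- function(consensus, genome, min_hit_len = 100,
                          min_identity = 0.90, k = 12L) {
  empty <- data.frame(sstart = integer(0), send = integer(0),
                      strand = character(0), identity = numeric(0),
                      aln_len = integer(0), coverage = numeric(0),
                      score = numeric(0))
  absent <- structure(list(present = FALSE, best_len = 0L,
                           best_identity = NA_real_, n_copies_40 = 0L,
                           hits = empty), class = "presence_call")
  if (is.null(genome) || !length(genome) || all(nchar(genome) == 0)) {
    return(absent)
  }
  if (is.null(names(genome))) {
    names(genome) <- paste0("contig", seq_along(genome))
  }
  consensus <- toupper(consensus)
  Lc <- nchar(consensus)
  hit_rows <- list()
  for (ctg in names(genome)) {
    gseq <- Biostrings::DNAString(toupper(genome[[ctg]]))
    Lg <- length(gseq)
    for (strand in c("+", "-")) {
      qry <- if (strand == "+") consensus else revcomp(consensus)
      if (Lc < k) next
      starts <- seq(1L, Lc - k + 1L, by = max(1L, k %/% 3L))
      kmers <- substring(qry, starts, starts + k - 1L)
      keep <- !grepl("[^ACGT]", kmers)
      if (!any(keep)) next
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
      m <- Biostrings::matchPDict(pd, gseq)
      gpos <- unlist(Biostrings::startIndex(m))
      if (is.null(gpos) || !length(gpos)) next
      qpos <- rep(starts[keep], lengths(Biostrings::startIndex(m)))
      ord <- order(gpos)
      gpos <- gpos[ord]; qpos <- qpos[ord]
      ## cluster seeds into candidate loci by genomic proximity
      brk <- c(TRUE, diff(gpos) > Lc)
      cl <- cumsum(brk)
      for (ci in unique(cl)) {
        gs <- gpos[cl == ci]; qs <- qpos[cl == ci]
        lo <- max(1L, min(gs) - min(qs) - 20L)
        hi <- min(Lg, max(gs) + (Lc - min(qs)) + 20L)
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(qry), gseq[lo:hi], type = "local",
          substitutionMatrix = dna_submat(),
          gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
        alen <- Biostrings::nchar(aln)
        if (alen < k) next
        ident <- Biostrings::nmatch(aln) / alen
        ss <- lo + Biostrings::start(Biostrings::subject(aln)) - 2L
        se <- lo + Biostrings::end(Biostrings::subject(aln)) - 1L
        pw <- Biostrings::end(Biostrings::pattern(aln)) -
          Biostrings::start(Biostrings::pattern(aln)) + 1L
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          subject = ctg, sstart = ss, send = se, strand = strand,
          identity = ident, aln_len = alen, coverage = pw / Lc,
          score = Biostrings::score(aln))
      }
    }
  }
  if (!length(hit_rows)) return(absent)
  hits <- do.call(rbind, hit_rows)
  ## a plus and minus scan of the same locus: keep the better-scoring one
  hits <- hits[order(hits$subject, hits$sstart, -hits$score), , drop = FALSE]
  drop <- logical(nrow(hits))
  if (nrow(hits) > 1) {
    for (i in 2:nrow(hits)) {
      prev <- i - 1L
      same <- hits$subject[i] == hits$subject[prev] &&
        min(hits$send[i], hits$send[prev]) -
          max(hits$sstart[i], hits$sstart[prev]) >
          0.5 * min(hits$send[i] - hits$sstart[i],
                    hits$send[prev] - hits$sstart[prev])
      if (same) drop[i] <- TRUE
    }
  }
  hits <- hits[!drop, , drop = FALSE]
  rownames(hits) <- NULL
  best <- hits[which.max(hits$score), ]
  structure(list(
    present = any(hits$aln_len > min_hit_len & hits$identity > min_identity),
    best_len = best$aln_len, best_identity = best$identity,
    n_copies_40 = count_copies(hits, 0.40), hits = hits),
    class = "presence_call")
}

#' Games-Howell pairwise post-hoc test
#'
#' For groups with unequal variances and sizes:
#' q = |m_i - m_j| / sqrt((s_i^2/n_i + s_j^2/n_j)/2), Welch-Satterthwaite
#' degrees of freedom, p from the studentized-range distribution with
#' `k = length(groups)`.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @return data.frame: group_i, group_j, mean_i, mean_j, n_i, n_j, q, df,
#'   p, flag.
#' @export
games_howell <- function(groups) {
  if (length(groups) < 2) stop("validation error: need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("validation error: each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  n <- lengths(groups)
  if (any(!is.finite(v))) stop("validation error: non-finite variance")
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    vi <- v[i] / n[i]; vj <- v[j] / n[j]
    flag <- "ok"
    if (vi + vj == 0) {
      if (m[i] == m[j]) {
        q <- 0; df <- Inf; p <- 1
      } else {
        q <- Inf; df <- Inf; p <- 0; flag <- "degenerate"
      }
    } else {
      q <- abs(m[i] - m[j]) / sqrt((vi + vj) / 2)
      df <- (vi + vj)^2 / (vi^2 / (n[i] - 1) + vj^2 / (n[j] - 1))
      p <- suppressWarnings(
        stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
      if (is.nan(p)) {
        ## ptukey underflows for extreme q at low df; for two groups the
        ## range statistic is sqrt(2)|t|, which gives an exact fallback
        p <- if (k == 2) {
          2 * stats::pt(q / sqrt(2), df, lower.tail = FALSE)
        } else if (q > 50) 0 else NA_real_
        flag <- "underflow"
      }
    }
    data.frame(group_i = names(groups)[i], group_j = names(groups)[j],
               mean_i = m[i], mean_j = m[j], n_i = n[i], n_j = n[j],
               q = q, df = df, p = p, flag = flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Element-vs-gene Ks contrast per species pair
#'
#' One Games-Howell two-group contrast per species pair; the decision is
#' "HTT-consistent" iff the element mean Ks is below the gene mean AND the
#' p-value is below `alpha`.
#'
#' @param te_ks_by_pair,gene_ks_by_pair named lists (species-pair label ->
#'   numeric Ks values); pairs missing from either side are skipped with a
#'   warning.
#' @param alpha significance threshold (default 1e-4).
#' @return data.frame: pair, n_te, mean_te, var_te, n_gene, mean_gene,
#'   var_gene, q, df, p, decision.
#' @export
ks_contrast_report <- function(te_ks_by_pair, gene_ks_by_pair,
                               alpha = 1e-4) {
  common <- intersect(names(te_ks_by_pair), names(gene_ks_by_pair))
  missing <- setdiff(union(names(te_ks_by_pair), names(gene_ks_by_pair)),
                     common)
  if (length(missing)) {
    warning("pairs missing one group skipped: ",
            paste(missing, collapse = ", "))
  }
  rows <- lapply(common, function(pp) {
    te <- te_ks_by_pair[[pp]]; ge <- gene_ks_by_pair[[pp]]
    te <- te[is.finite(te)]; ge <- ge[is.finite(ge)]
    if (length(te) < 2 || length(ge) < 2) return(NULL)
    gh <- games_howell(list(te = te, gene = ge))
    data.frame(pair = pp, n_te = length(te), mean_te = mean(te),
               var_te = stats::var(te), n_gene = length(ge),
               mean_gene = mean(ge), var_gene = stats::var(ge),
               q = gh$q, df = gh$df, p = gh$p,
               decision = if (mean(te) < mean(ge) && gh$p < alpha)
                 "HTT-consistent" else "not-supported")
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(pair = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Taxa are ordered by label before the NJ pass so ties break
#' deterministically.
#'
#' @param d symmetric matrix with zero diagonal (n >= 3), labeled.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("validation error: need >= 3 taxa")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("validation error: non-symmetric distance matrix")
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop("validation error: non-zero diagonal")
  }
  ord <- order(rownames(d))
  ape::nj(stats::as.dist(d[ord, ord]))
}

#' Robinson-Foulds distance between two trees on the same leaves
#'
#' @param tree_a,tree_b `phylo` objects or Newick strings.
#' @return integer count of bipartitions present in exactly one tree.
#' @export
robinson_foulds <- function(tree_a, tree_b) {
  as_tree <- function(x) {
    if (inherits(x, "phylo")) x else ape::read.tree(text = x)
  }
  ta <- as_tree(tree_a); tb <- as_tree(tree_b)
  if (!setequal(ta$tip.label, tb$tip.label)) {
    stop("validation error: leaf sets differ")
  }
  as.integer(phangorn::RF.dist(ape::unroot(ta), ape::unroot(tb),
                               check.labels = TRUE))
}

#' K2P neighbor-joining tree straight from unaligned equal-length sequences
#' @param seqs named character vector of aligned (equal-length) sequences.
#' @param model distance model for [ape::dist.dna] (default "K80").
#' @return `phylo` tree.
#' @export
nj_tree_from_sequences <- function(seqs, model = "K80") {
  stopifnot(length(seqs) >= 3, length(unique(nchar(seqs))) == 1)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  rownames(bin) <- names(seqs)
  d <- as.matrix(ape::dist.dna(bin, model = model,
                               pairwise.deletion = TRUE))
  nj_tree(d)
}
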