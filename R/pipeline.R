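## Orchestration of the two workflows: "find the active element"
## (expression triage -> anatomy -> copy statistics -> insertion
## polymorphism) and "prove horizontal transfer and date it" (presence ->
## Ks contrast -> trees -> dating).

#' Orient a copy to the consensus strand
#' @noRd
orient_to <- function(copy, consensus) {
  if (nchar(copy) == nchar(consensus)) {
    fwd <- p_distance(copy, consensus)
    rev <- p_distance(revcomp(copy), consensus)
    if (!is.na(fwd) && !is.na(rev) && rev < fwd) revcomp(copy) else copy
  } else {
    sc <- function(s) Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(consensus),
      type = "global-local", substitutionMatrix = dna_submat(),
      gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT))
    if (sc(revcomp(copy)) > sc(copy)) revcomp(copy) else copy
  }
}

#' Extract the transposase ORF from full-length copies via the consensus
#' @noRd
copy_orfs_via_consensus <- function(copies, consensus, min_orf_nt = 300) {
  orfs <- find_orfs(consensus, min_len_nt = min_orf_nt)
  if (!nrow(orfs)) return(NULL)
  o <- orfs[1, ]
  full <- copies[nchar(copies) == nchar(consensus)]
  if (!length(full)) return(NULL)
  full <- vapply(full, orient_to, character(1), consensus = consensus,
                 USE.NAMES = FALSE)
  seqs <- substr(full, o$start + 1, o$end)
  if (o$strand == "-") seqs <- vapply(seqs, revcomp, character(1),
                                      USE.NAMES = FALSE)
  stats::setNames(seqs, paste0("copy", seq_along(seqs)))
}

#' Finite Ks values from a cross-set result, optionally per-copy means
#' @noRd
contrast_values <- function(cross, mode) {
  rec <- cross$records
  if (is.null(rec)) return(numeric(0))
  rec <- rec[is.finite(rec$ks), , drop = FALSE]
  if (!nrow(rec)) return(numeric(0))
  if (mode == "all_pairs") return(rec$ks)
  c(tapply(rec$ks, rec$id_a, mean), tapply(rec$ks, rec$id_b, mean))
}

#' Screen candidate elements for current activity
#'
#' Combines the evidence lines of the activity argument: high germline
#' expression relative to the reference third quartile in every sample,
#' an autonomous consensus (intact ORF + TIR pair + DD34D), identical-copy
#' variants, copy count, low nucleotide diversity, and non-reference
#' insertion support.  Candidates are ranked by the number of evidence
#' lines met, ties broken by pi ascending.
#'
#' @param te_transcripts named list (sample -> TE transcript data.frame
#'   with `te_name`, `masked_bp`, `divergence`, `tpm`).
#' @param reference_tpms named list (sample -> numeric reference TPM).
#' @param copy_sets named list (TE -> character vector of genomic copies).
#' @param hits named list (TE -> hit data.frame with `coverage`).
#' @param insertion_calls optional calls data.frame with a `te` column.
#' @param max_pi_seqs cap on sequences entering the pi estimate
#'   (default 40).
#' @param pi_bootstrap bootstrap replications for pi (default 100).
#' @param seed subsampling / bootstrap seed.
#' @return data.frame ranked by evidence (one row per element).
#' @export
run_active_te_screen <- function(te_transcripts, reference_tpms,
                                 copy_sets = list(), hits = list(),
                                 insertion_calls = NULL,
                                 max_pi_seqs = 40, pi_bootstrap = 100,
                                 seed = 1L) {
  samples <- names(te_transcripts)
  if (!length(samples) || !nrow(do.call(rbind, te_transcripts))) {
    warning("no TE transcript evidence available: empty report")
    return(data.frame(te = character(0)))
  }
  per_sample <- lapply(samples, function(s) {
    tab <- filter_te_transcripts(te_transcripts[[s]])
    if (!nrow(tab)) return(NULL)
    tiers <- expression_tiers(reference_tpms[[s]])
    tpm <- tapply(tab$tpm, tab$te_name, max)
    data.frame(sample = s, te = names(tpm), tpm = as.numeric(tpm),
               tier = classify_expression(as.numeric(tpm), tiers))
  })
  expr <- do.call(rbind, Filter(Negate(is.null), per_sample))
  if (is.null(expr) || !nrow(expr)) {
    warning("no transcripts survive the filter: empty report")
    return(data.frame(te = character(0)))
  }
  tes <- sort(unique(expr$te))
  rows <- lapply(tes, function(te) {
    e <- expr[expr$te == te, , drop = FALSE]
    n_high <- sum(e$tier == "high")
    cps <- copy_sets[[te]]
    autonomous <- NA; has_tir <- NA; intact_orf <- NA
    n_ident <- NA_integer_; pi_val <- NA_real_
    if (!is.null(cps) && length(cps) >= 2) {
      cons <- build_consensus(cps)
      if (cons$status == "ok") {
        an <- element_autonomy(cons$consensus)
        autonomous <- an$autonomous
        has_tir <- !is.null(an$tir)
        intact_orf <- nrow(an$orfs) > 0
      }
      full <- cps[nchar(cps) == max(nchar(cps))]
      dr <- dereplicate_identical(full)
      n_ident <- dr$n_variants_multi
      if (length(full) >= 2) {
        set.seed(seed)
        sub <- if (length(full) > max_pi_seqs)
          sample(full, max_pi_seqs) else full
        pi_val <- tryCatch(
          nucleotide_diversity(sub, n_bootstrap = pi_bootstrap,
                               seed = seed)$pi,
          error = function(e) NA_real_)
      }
    }
    n_copies <- if (!is.null(hits[[te]])) count_copies(hits[[te]], 0.60)
      else NA_integer_
    n_nonref <- if (!is.null(insertion_calls) && nrow(insertion_calls))
      sum(insertion_calls$te == te) else NA_integer_
    data.frame(te = te, n_samples_high = n_high,
               n_samples = length(samples),
               autonomous = autonomous, intact_orf = intact_orf,
               tir = has_tir, n_identical_variants = n_ident,
               copy_count_60 = n_copies, pi = pi_val,
               n_nonref_insertions = n_nonref)
  })
  rep <- do.call(rbind, rows)
  top_copies <- !is.na(rep$copy_count_60) &
    rep$copy_count_60 == max(rep$copy_count_60, na.rm = TRUE)
  lowest_pi <- !is.na(rep$pi) & rep$pi == min(rep$pi, na.rm = TRUE)
  zero_na <- function(x) ifelse(is.na(x), 0L, as.integer(x))
  rep$evidence <- as.integer(rep$n_samples_high == rep$n_samples) +
    zero_na(rep$autonomous) +
    zero_na(rep$n_identical_variants > 0) +
    zero_na(rep$n_nonref_insertions > 0) +
    as.integer(top_copies) + as.integer(lowest_pi)
  rep <- rep[order(-rep$evidence, rep$pi, rep$te), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Run the horizontal-transfer analysis across species
#'
#' Per species: consensus reconstruction and ORF extraction.  Per species
#' pair: element Ks versus ortholog Ks, contrasted with Games-Howell.
#' Across species: neighbor-joining gene and element trees, compared with
#' the reference species tree by Robinson-Foulds distance.  Per lineage:
#' neutral-rate calibration and copy dating with an entry-time estimate and
#' burst profile.
#'
#' @param copy_sets named list (species -> character vector of element
#'   copies).
#' @param gene_sets named list (species -> character vector of orthologous
#'   genes, index-matched across species).
#' @param species_tree reference species tree (`phylo` or Newick, branch
#'   lengths in My).
#' @param calibration data.frame (lineage, counterpart, time_my) naming,
#'   per lineage, the species pair and divergence time used for the
#'   neutral-rate calibration; defaults to each species' closest relative
#'   in the tree.
#' @param te_sample element copies sampled per species for the Ks contrast
#'   (default 12).
#' @param n_genes_ks ortholog pairs used per species pair (default 100).
#' @param contrast_mode `"disjoint_pairs"` (default: each copy enters at
#'   most one cross-species pair, giving independent Ks observations),
#'   `"per_copy_mean"` (one value per copy) or `"all_pairs"` (every copy
#'   pair; pseudo-replicated, matching the historical practice).
#' @param alpha contrast significance threshold (default 1e-4).
#' @param min_te_group smallest element Ks group entering a contrast
#'   (default 5): with only 2-3 observations the Welch degrees of freedom
#'   collapse toward 1 and no effect size can reach small p-values, so
#'   such pairs are reported as untestable rather than non-significant.
#' @param n_tree_genes genes concatenated for the gene tree (default 10).
#' @param gap_threshold_my burst-profile gap threshold (default 0.1).
#' @param entry_method `"p95"` or `"max"` (see [estimate_entry_time()]).
#' @param genomes optional named list (species -> genome sequence) for the
#'   presence scan.
#' @param seed subsampling seed.
#' @return list: `consensus`, `presence`, `contrasts`, `te_ks`, `gene_ks`,
#'   `trees` (gene, te, rf_gene, rf_te), `rates`, `dating`.
#' @export
run_htt_analysis <- function(copy_sets, gene_sets, species_tree,
                             calibration = NULL, te_sample = 12,
                             n_genes_ks = 100,
                             contrast_mode = c("disjoint_pairs",
                                               "per_copy_mean",
                                               "all_pairs"),
                             alpha = 1e-4, min_te_group = 5,
                             n_tree_genes = 10,
                             gap_threshold_my = 0.1,
                             entry_method = "p95", genomes = NULL,
                             seed = 1L) {
  contrast_mode <- match.arg(contrast_mode)
  tree <- if (inherits(species_tree, "phylo")) species_tree else
    ape::read.tree(text = species_tree)
  species <- names(copy_sets)[vapply(copy_sets, length, integer(1)) > 0]

  consensus <- lapply(copy_sets[species], build_consensus)
  with_cons <- species[vapply(consensus[species], function(x)
    x$status == "ok", logical(1))]

  presence <- NULL
  if (!is.null(genomes) && length(with_cons)) {
    ref_cons <- consensus[[with_cons[1]]]$consensus
    presence <- lapply(genomes, function(g) presence_scan(ref_cons, g))
  }

  set.seed(child_seed(seed, "orfs"))
  orfs <- lapply(with_cons, function(sp) {
    copy_orfs_via_consensus(copy_sets[[sp]], consensus[[sp]]$consensus,
                            min_orf_nt = 300)
  })
  names(orfs) <- with_cons
  with_orf <- with_cons[!vapply(orfs, is.null, logical(1))]

  te_ks <- list(); gene_ks <- list()
  gene_sp <- names(gene_sets)
  if (length(with_orf) >= 2) {
    prs <- utils::combn(with_orf, 2)
    for (c0 in seq_len(ncol(prs))) {
      a <- prs[1, c0]; b <- prs[2, c0]
      lab <- paste(a, b, sep = "x")
      set.seed(child_seed(seed, paste0("tesample_", lab)))
      sa <- orfs[[a]]
      sb <- orfs[[b]]
      if (contrast_mode == "disjoint_pairs") {
        n <- min(length(sa), length(sb), te_sample)
        ia <- sample(seq_along(sa), n)
        ib <- sample(seq_along(sb), n)
        vals <- vapply(seq_len(n), function(i) {
          tryCatch({
            rec <- ks_ng86(codon_align(sa[[ia[i]]], sb[[ib[i]]]))
            if (rec$flag == "ok") rec$ks else NA_real_
          }, error = function(e) NA_real_)
        }, numeric(1))
        te_ks[[lab]] <- vals[is.finite(vals)]
      } else {
        if (length(sa) > te_sample) sa <- sample(sa, te_sample)
        if (length(sb) > te_sample) sb <- sample(sb, te_sample)
        te_ks[[lab]] <- contrast_values(cross_set_ks(sa, sb),
                                        contrast_mode)
      }
    }
  }
  if (length(gene_sp) >= 2) {
    prs <- utils::combn(sort(gene_sp), 2)
    for (c0 in seq_len(ncol(prs))) {
      a <- prs[1, c0]; b <- prs[2, c0]
      lab <- paste(a, b, sep = "x")
      n_avail <- min(length(gene_sets[[a]]), length(gene_sets[[b]]))
      set.seed(child_seed(seed, paste0("genesample_", lab)))
      idx <- if (n_avail > n_genes_ks) sample.int(n_avail, n_genes_ks)
        else seq_len(n_avail)
      vals <- vapply(idx, function(i) {
        tryCatch({
          rec <- ks_ng86(codon_align(gene_sets[[a]][i],
                                     gene_sets[[b]][i]))
          if (rec$flag == "ok") rec$ks else NA_real_
        }, error = function(e) NA_real_)
      }, numeric(1))
      gene_ks[[lab]] <- vals[is.finite(vals)]
    }
  }
  small <- lengths(te_ks) < min_te_group
  if (any(small)) {
    warning("element Ks groups below min_te_group dropped as untestable: ",
            paste(names(te_ks)[small], collapse = ", "))
    te_ks <- te_ks[!small]
  }
  contrasts <- if (length(te_ks) && length(gene_ks)) {
    ks_contrast_report(te_ks, gene_ks, alpha = alpha)
  } else NULL

  trees <- list(species = tree)
  if (length(gene_sp) >= 3) {
    n_avail <- min(vapply(gene_sets, length, integer(1)))
    set.seed(child_seed(seed, "treegenes"))
    idx <- if (n_avail > n_tree_genes) sample.int(n_avail, n_tree_genes)
      else seq_len(n_avail)
    concat <- vapply(gene_sets, function(g) paste(g[idx], collapse = ""),
                     character(1))
    if (length(unique(nchar(concat))) == 1) {
      trees$gene <- nj_tree_from_sequences(concat)
      trees$rf_gene <- robinson_foulds(
        ape::keep.tip(tree, names(concat)), trees$gene)
    }
  }
  if (length(with_cons) >= 3) {
    ## element tree from genomic copies (not consensi): the distance
    ## between species then includes within-host divergence since entry,
    ## which carries the transfer-order signal
    ref_cons <- consensus[[with_cons[1]]]$consensus
    set.seed(child_seed(seed, "tetree"))
    copy_samp <- lapply(with_cons, function(sp) {
      cs <- consensus[[sp]]$consensus
      full <- copy_sets[[sp]][nchar(copy_sets[[sp]]) == nchar(cs)]
      if (!length(full)) return(NULL)
      full <- vapply(full, orient_to, character(1), consensus = cs,
                     USE.NAMES = FALSE)
      ## put every species on the reference species' strand
      pf <- p_distance(substr(cs, 1, min(nchar(cs), nchar(ref_cons))),
                       substr(ref_cons, 1, min(nchar(cs),
                                               nchar(ref_cons))))
      pr <- p_distance(substr(revcomp(cs), 1,
                              min(nchar(cs), nchar(ref_cons))),
                       substr(ref_cons, 1, min(nchar(cs),
                                               nchar(ref_cons))))
      if (!is.na(pf) && !is.na(pr) && pr < pf) {
        full <- vapply(full, revcomp, character(1), USE.NAMES = FALSE)
      }
      if (length(full) > 8) full <- sample(full, 8)
      full
    })
    names(copy_samp) <- with_cons
    te_sp <- with_cons[!vapply(copy_samp, is.null, logical(1))]
    if (length(te_sp) >= 3) {
      d <- matrix(0, length(te_sp), length(te_sp),
                  dimnames = list(te_sp, te_sp))
      for (i in seq_along(te_sp)) {
        for (j in seq_along(te_sp)) {
          if (j <= i) next
          pairs_d <- outer(copy_samp[[te_sp[i]]], copy_samp[[te_sp[j]]],
                           Vectorize(function(a, b) nt_divergence(a, b)))
          d[i, j] <- d[j, i] <- mean(pairs_d, na.rm = TRUE)
        }
      }
      if (all(is.finite(d))) {
        trees$te <- nj_tree(d)
        trees$rf_te <- robinson_foulds(ape::keep.tip(tree, te_sp),
                                       trees$te)
      }
    }
  }

  if (is.null(calibration) && length(gene_sp) >= 2) {
    ct <- ape::cophenetic.phylo(tree) / 2
    calibration <- do.call(rbind, lapply(gene_sp, function(sp) {
      others <- setdiff(gene_sp, sp)
      cp <- others[which.min(ct[sp, others])]
      data.frame(lineage = sp, counterpart = cp, time_my = ct[sp, cp])
    }))
  }
  rates <- list()
  if (!is.null(calibration)) {
    for (i in seq_len(nrow(calibration))) {
      sp <- calibration$lineage[i]; cp <- calibration$counterpart[i]
      lab <- paste(sort(c(sp, cp)), collapse = "x")
      vals <- gene_ks[[lab]]
      if (is.null(vals) || !length(vals)) next
      rates[[sp]] <- neutral_rate(mean(vals), calibration$time_my[i],
                                  lineage = sp)
    }
  }

  dating <- list()
  for (sp in with_cons) {
    if (is.null(rates[[sp]])) next
    full <- copy_sets[[sp]][nchar(copy_sets[[sp]]) ==
                              nchar(consensus[[sp]]$consensus)]
    if (length(full) < 2) next
    full <- vapply(full, orient_to, character(1),
                   consensus = consensus[[sp]]$consensus,
                   USE.NAMES = FALSE)
    ages <- copy_ages(full, consensus[[sp]]$consensus, rates[[sp]],
                      mode = "nucleotide")
    entry <- estimate_entry_time(ages, rates[[sp]], method = entry_method)
    single_branch_my <- ages$k / rates[[sp]]$r / 1e6
    prof <- if (sum(is.finite(single_branch_my)) >= 5) {
      proliferation_profile(single_branch_my,
                            gap_threshold_my = gap_threshold_my)
    } else NULL
    dating[[sp]] <- list(ages = ages, entry_my = entry, profile = prof)
  }

  list(consensus = consensus, presence = presence, te_ks = te_ks,
       gene_ks = gene_ks, contrasts = contrasts, trees = trees,
       rates = rates, dating = dating)
}
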