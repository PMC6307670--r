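test_that("zero substitution rates give identical copies, zero pi and Ks", {
  cfg <- simulation_config(
    seed = 3, species_tree = "(A:10,B:10);", rates = c(A = 0, B = 0),
    n_nuclear_genes = 5, gene_length_codons = 60,
    htt_events = data.frame(recipient = "A", time_my = 1.5, lambda = 2),
    donor_rate = 0, genome_length = 1e5, max_copies = 20,
    fragment_prob = 0, n_reference_genes = 20)
  w <- simulate_world(cfg)
  expect_true(all(w$te$A$copies == w$te$A$entry_seq))
  expect_true(all(w$te$A$copies == w$te$A$copies[1]))
  pi_est <- nucleotide_diversity(w$te$A$copies, n_bootstrap = 10)
  expect_identical(pi_est$pi, 0)
  rec <- ks_ng86(codon_align(w$genes$A[1], w$genes$B[1]))
  expect_identical(rec$ks, 0)
})

test_that("copy number stays inside the birth-process 99% envelope", {
  ## linear (Yule) birth process: N(t) ~ Geometric(p = exp(-lambda t)),
  ## mean exp(lambda t); closed-form quantiles give the envelope
  lam <- log(40) / 1.5
  p_geo <- exp(-lam * 1.5)
  lo <- stats::qgeom(0.005, p_geo) + 1
  hi <- stats::qgeom(0.995, p_geo) + 1
  counts <- vapply(1:8, function(s) {
    cfg <- simulation_config(
      seed = s, species_tree = "(A:10,B:10);", rates = c(A = 1e-9, B = 1e-9),
      n_nuclear_genes = 2, gene_length_codons = 30,
      htt_events = data.frame(recipient = "A", time_my = 1.5, lambda = lam),
      genome_length = 3e5, max_copies = 5000, fragment_prob = 0,
      n_reference_genes = 20)
    length(simulate_world(cfg)$te$A$copies)
  }, integer(1))
  expect_true(all(counts >= lo & counts <= hi))
  ## at least one draw away from the mean shows these are not constant
  expect_gt(length(unique(counts)), 1)
})

test_that("nuclear-gene divergence matches 2rt at the printed rate", {
  ## two species split 50 My ago at r = 5.17e-9/site/year:
  ## expected JC-corrected divergence 2rt = 0.517 per site
  cfg <- simulation_config(
    seed = 11, species_tree = "(A:50,B:50);",
    rates = c(A = 5.17e-9, B = 5.17e-9),
    n_nuclear_genes = 40, gene_length_codons = 200,
    htt_events = data.frame(recipient = character(0),
                            time_my = numeric(0), lambda = numeric(0)),
    genome_length = 5e4, n_reference_genes = 20)
  w <- simulate_world(cfg)
  d <- vapply(seq_len(40), function(i) {
    p <- activeTE:::p_distance(w$genes$A[i], w$genes$B[i])
    -0.75 * log(1 - 4 * p / 3)
  }, numeric(1))
  ## 40 genes x 600 sites; allow 3 sigma of the mean plus the small bias
  ## from the intact-ORF (stop-avoiding) constraint
  expect_lt(abs(mean(d) - 0.517), 0.03)
})

test_that("copy divergence tracks r x age and ages never exceed entry time", {
  sw <- small_world()
  w <- sw$world
  for (sp in c("Sinv", "Dgri", "Aech")) {
    t_h <- w$truth$events[[sp]]$t_h
    expect_true(all(w$te[[sp]]$ages <= t_h + 1e-12))
    full <- which(!w$te[[sp]]$fragmented)
    p_obs <- vapply(full, function(i) {
      activeTE:::p_distance(w$te[[sp]]$copies[i], w$te[[sp]]$entry_seq)
    }, numeric(1))
    d_exp <- 3.5e-9 * w$te[[sp]]$ages[full] * 1e6
    p_exp <- 0.75 * (1 - exp(-4 * d_exp / 3))
    L <- nchar(w$te[[sp]]$entry_seq)
    sig <- sqrt(pmax(p_exp, 1e-6) * (1 - p_exp) / L)
    expect_true(all(abs(p_obs - p_exp) <= 4 * sig + 2 / L))
  }
})

test_that("the element is absent from lineages without a transfer event", {
  sw <- small_world()
  w <- sw$world
  expect_null(w$te$Dfic)
  expect_identical(nrow(w$hits$Dfic), 0L)
})

test_that("an entry time older than the recipient terminal branch is rejected", {
  expect_error(simulation_config(
    seed = 1, species_tree = "((A:5,B:5):5,C:10);",
    rates = c(A = 1e-9, B = 1e-9, C = 1e-9),
    htt_events = data.frame(recipient = "A", time_my = 7, lambda = 1)),
    "older than recipient lineage root")
})

test_that("identical config and seed reproduce the world bit-identically", {
  cfg <- simulation_config(
    seed = 99, species_tree = "(A:10,B:10);",
    rates = c(A = 3e-9, B = 3e-9), n_nuclear_genes = 5,
    gene_length_codons = 50,
    htt_events = data.frame(recipient = "A", time_my = 1, lambda = 2),
    genome_length = 1e5, max_copies = 30, n_reference_genes = 20)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$genes, w2$genes)
  expect_identical(w1$te$A$copies, w2$te$A$copies)
  expect_identical(w1$genomes, w2$genomes)
  p1 <- simulate_brother_pairs(cfg)
  p2 <- simulate_brother_pairs(cfg)
  expect_identical(p1$snps, p2$snps)
  expect_identical(p1$reads, p2$reads)
})

test_that("brother pairs report the configured effective genome count", {
  cfg <- simulation_config(
    seed = 5, species_tree = "(A:10,B:10);",
    rates = c(A = 3e-9, B = 3e-9), n_families = 7, ibd_fraction = 0.62,
    genome_length = 4e5, n_reference_genes = 20)
  p <- simulate_brother_pairs(cfg)
  expect_equal(p$truth$n_individuals, 14L)
  expect_equal(p$truth$effective_genomes, 14 * 0.62)
  expect_equal(p$truth$effective_genomes, 8.68)
  ## every planted locus has the configured TSD length
  expect_true(all(p$truth$insertions$tsd_len == cfg$tsd_len))
})

test_that("full IBD yields no high-density windows and warns", {
  cfg <- simulation_config(
    seed = 6, species_tree = "(A:10,B:10);",
    rates = c(A = 3e-9, B = 3e-9), n_families = 2, ibd_fraction = 1,
    genome_length = 2e5, n_reference_genes = 20)
  expect_warning(p <- simulate_brother_pairs(cfg), "no non-IBD SNPs")
  expect_true(all(vapply(p$ibd_states, all, logical(1))))
  counts <- table(cut(p$snps$pos, seq(0, 2e5, by = 1e4)))
  expect_true(all(counts <= 5))   # residual error-rate SNPs only
})

test_that("fixtures are written deterministically with all file classes", {
  cfg <- simulation_config(
    seed = 21, species_tree = "(A:10,B:10);",
    rates = c(A = 3e-9, B = 3e-9), n_nuclear_genes = 4,
    gene_length_codons = 40,
    htt_events = data.frame(recipient = "A", time_my = 1, lambda = 2),
    genome_length = 1e5, max_copies = 20, n_families = 2,
    n_reference_genes = 20)
  w <- simulate_world(cfg)
  p <- simulate_brother_pairs(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixtures(w, d1, pairs = p)
  m2 <- write_fixtures(w, d2, pairs = p)
  expect_identical(m1$md5, m2$md5)
  expect_setequal(unique(m1$class),
                  c("fasta", "hits_tsv", "expression_tsv", "vcf", "bed",
                    "json"))
  ## junction reads survive the BED round trip
  rt <- read_junction_bed(file.path(d1, "junction_reads.bed"))
  expect_equal(nrow(rt), nrow(p$reads))
  expect_equal(rt$start, p$reads$start)
  expect_equal(rt$side, p$reads$side)
})

test_that("an empty world still yields a valid, empty manifest", {
  d <- withr::local_tempdir()
  m <- write_fixtures(NULL, d)
  expect_identical(nrow(m), 0L)
  expect_named(m, c("file", "class", "md5"))
})
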