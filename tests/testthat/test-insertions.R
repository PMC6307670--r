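test_that("IBD windows handle empty and perfectly separated input", {
  expect_warning(res <- ibd_windows(data.frame(chrom = character(0),
                                               pos = integer(0)),
                                    genome_length = 1e5),
                 "empty SNP table")
  expect_equal(unname(res$ibd_fraction), 1)
  ## planted alternating blocks: 0 vs 40 SNPs per 10 kb
  set.seed(60)
  n_win <- 40
  state <- rep(c(TRUE, FALSE), each = 5, length.out = n_win)  # TRUE = IBD
  pos <- unlist(lapply(which(!state), function(w) {
    (w - 1) * 10000 + sample.int(10000, 40)
  }))
  snp <- data.frame(chrom = "chr1", pos = sort(pos))
  res <- ibd_windows(snp, genome_length = n_win * 10000)
  expect_identical(res$windows$state == "IBD", state)
  expect_equal(unname(res$ibd_fraction), mean(state))
  ## threshold fallback gives the same answer here
  res_t <- ibd_windows(snp, genome_length = n_win * 10000,
                       method = "threshold")
  expect_identical(res_t$windows$state, res$windows$state)
})

test_that("IBD fraction is recovered on simulated brother pairs", {
  ## enough windows that the realized per-family IBD fraction
  ## concentrates near the target (mean block length is 30 windows)
  cfg <- simulation_config(
    seed = 61, species_tree = "(A:10,B:10);",
    rates = c(A = 3e-9, B = 3e-9), n_families = 7, ibd_fraction = 0.62,
    genome_length = 8e6, n_reference_genes = 20)
  p <- simulate_brother_pairs(cfg)
  res <- ibd_windows(p$snps, genome_length = cfg$genome_length)
  est <- mean(res$ibd_fraction)
  expect_lt(abs(est - 0.62), 0.05)
  ## window-level accuracy when the density separation is large
  acc <- mean(vapply(names(p$ibd_states), function(fam) {
    called <- res$windows$state[res$windows$family == fam] == "IBD"
    mean(called == p$ibd_states[[fam]])
  }, numeric(1)))
  expect_gte(acc, 0.99)
})

test_that("a planted insertion with a 4-bp TSD is called at its breakpoint", {
  set.seed(62)
  ref <- paste(sample(c("A", "C", "G", "T"), 5e4, replace = TRUE),
               collapse = "")
  pos <- 20000L; tsd <- 4L
  mk_reads <- function(side, n) {
    anchor <- round(runif(n, 30, 60))
    if (side == "left") {
      data.frame(chrom = "chr1", start = pos + tsd - anchor,
                 end = pos + tsd, mapq = 50, side = "left",
                 family = "F1", individual = "F1_a")
    } else {
      data.frame(chrom = "chr1", start = pos, end = pos + anchor,
                 mapq = 50, side = "right", family = "F1",
                 individual = "F1_a")
    }
  }
  reads <- rbind(mk_reads("left", 10), mk_reads("right", 10))
  res <- call_insertions(reads, reference = ref)
  expect_identical(nrow(res$calls), 1L)
  expect_identical(res$calls$start, pos)
  expect_identical(res$calls$tsd_len, tsd)
  expect_identical(res$calls$tsd_seq,
                   substr(ref, pos + 1, pos + tsd))
  expect_false(res$calls$excised)
  ## no reads at all -> empty
  expect_identical(nrow(call_insertions(reads[0, ])$calls), 0L)
})

test_that("low-mapq support never reaches a call", {
  pos <- 500L
  reads <- data.frame(
    chrom = "chr1",
    start = c(pos + 2 - 40, pos + 2 - 45, pos, pos),
    end = c(pos + 2, pos + 2, pos + 40, pos + 45),
    mapq = c(9, 8, 9, 5),
    side = c("left", "left", "right", "right"),
    family = "F1", individual = "F1_a")
  res <- call_insertions(reads)
  expect_identical(nrow(res$calls), 0L)
  ## and the floor cannot be lowered below 10
  res2 <- call_insertions(reads, min_mapq = 0)
  expect_identical(nrow(res2$calls), 0L)
})

test_that("TSD overlaps outside the allowed range become low-confidence", {
  pos <- 800L; tsd <- 14L
  reads <- rbind(
    data.frame(chrom = "chr1", start = pos + tsd - c(40, 44, 50),
               end = pos + tsd, mapq = 50, side = "left", family = "F1",
               individual = "F1_a"),
    data.frame(chrom = "chr1", start = pos, end = pos + c(40, 44, 50),
               mapq = 50, side = "right", family = "F1",
               individual = "F1_a"))
  res <- call_insertions(reads, tsd_range = c(2, 10))
  expect_identical(nrow(res$calls), 0L)
  expect_identical(nrow(res$low_confidence), 1L)
  expect_identical(res$low_confidence$tsd_len, tsd)
})

test_that("somatic excision is flagged when TE-absent reads coexist", {
  pos <- 3000L; tsd <- 2L
  reads <- rbind(
    data.frame(chrom = "chr1", start = pos + tsd - c(35, 40, 45),
               end = pos + tsd, mapq = 50, side = "left", family = "F7",
               individual = "F7_b"),
    data.frame(chrom = "chr1", start = pos, end = pos + c(35, 40, 45),
               mapq = 50, side = "right", family = "F7",
               individual = "F7_b"),
    data.frame(chrom = "chr1", start = pos - 50, end = pos + 50,
               mapq = 50, side = "absent", family = "F7",
               individual = "F7_b"))
  res <- call_insertions(reads)
  expect_identical(nrow(res$calls), 1L)
  expect_true(res$calls$excised)
})

test_that("family occupancy classification matches the published fractions", {
  ## 70 loci, 42 carried by >= 2 families -> 60% common
  set.seed(63)
  mk_call <- function(i, fams) {
    data.frame(chrom = "chr1", start = i * 1000L, end = i * 1000L + 2L,
               tsd_len = 2L, tsd_seq = "TA", n_left = 5L, n_right = 5L,
               min_mapq = 30L, families = paste(fams, collapse = ","),
               individuals = "x", excised = FALSE)
  }
  fams <- paste0("F", 1:7)
  calls <- do.call(rbind, lapply(1:70, function(i) {
    if (i <= 42) mk_call(i, sample(fams, 2)) else mk_call(i, sample(fams, 1))
  }))
  res <- classify_family_occupancy(calls)
  expect_identical(res$summary$n_total, 70L)
  expect_identical(res$summary$n_common, 42L)
  expect_identical(res$summary$n_family_specific, 28L)
  expect_equal(res$summary$n_common / res$summary$n_total, 0.60)
  expect_identical(res$summary$n_common + res$summary$n_family_specific,
                   res$summary$n_total)
})

test_that("single-family calls are family-specific; masks exclude loci", {
  calls <- data.frame(chrom = "chr1", start = c(100L, 5000L),
                      end = c(102L, 5002L), tsd_len = 2L, tsd_seq = "TA",
                      n_left = 3L, n_right = 3L, min_mapq = 30L,
                      families = "F1", individuals = "F1_a",
                      excised = FALSE)
  res <- classify_family_occupancy(calls)
  expect_true(all(res$calls$class == "family_specific"))
  masked <- classify_family_occupancy(
    calls, exclusion_mask = data.frame(chrom = "chr1", start = 0L,
                                       end = 200L))
  expect_identical(masked$summary$n_total, 1L)
})

test_that("nearby calls from different families merge into one common locus", {
  mk <- function(start, fam) {
    data.frame(chrom = "chr1", start = start, end = start + 2L,
               tsd_len = 2L, tsd_seq = "TA", n_left = 3L, n_right = 3L,
               min_mapq = 30L, families = fam, individuals = "x",
               excised = FALSE)
  }
  res <- classify_family_occupancy(rbind(mk(1000L, "F1"), mk(1004L, "F2")))
  expect_identical(res$summary$n_total, 1L)
  expect_identical(res$calls$class, "common")
})

test_that("the insertion-rate bound reproduces the published arithmetic", {
  b <- insertion_rate_bound(14, 0.62, 0)
  expect_equal(b$effective_genomes, 8.68)
  expect_equal(b$rate, 1 / 8.68)
  expect_equal(b$rate, 0.115, tolerance = 0.01)
  expect_identical(b$type, "upper_bound")
  expect_equal(insertion_rate_bound(1, 1, 0)$rate, 1)
  e <- insertion_rate_bound(10, 0.5, 2)
  expect_equal(e$rate, 0.4)
  expect_identical(e$type, "point_estimate")
  expect_error(insertion_rate_bound(10, 0, 0), "mean_ibd_fraction")
})
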