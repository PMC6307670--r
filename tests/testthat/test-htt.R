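test_that("presence calls follow the length/identity rule on planted genomes", {
  set.seed(40)
  cons <- paste(sample(c("A", "C", "G", "T"), 1300, replace = TRUE),
                collapse = "")
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  ## exact full-length copy (reverse strand) -> present, identity ~ 1
  g1 <- paste0(bg(4000), activeTE:::revcomp(cons), bg(3000))
  call1 <- presence_scan(cons, g1)
  expect_true(call1$present)
  expect_gte(call1$best_identity, 0.99)
  expect_gte(call1$best_len, 1200)
  expect_identical(call1$n_copies_40, 1L)
  ## short high-identity fragment -> absent (length rule is strict >);
  ## 80 bp leaves no room for chance extension past the 100-bp threshold
  g2 <- paste0(bg(3000), substr(cons, 100, 179), bg(3000))
  call2 <- presence_scan(cons, g2)
  expect_false(call2$present)
  ## a 150-bp exact fragment clears both rules
  g3 <- paste0(bg(3000), substr(cons, 100, 249), bg(3000))
  expect_true(presence_scan(cons, g3)$present)
  ## empty genome -> absent
  expect_false(presence_scan(cons, "")$present)
})

test_that("a 52-genome panel recovers exactly the planted carriers", {
  set.seed(41)
  cons <- paste(sample(c("A", "C", "G", "T"), 1300, replace = TRUE),
                collapse = "")
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  mutate_frac <- function(s, f) {
    ch <- strsplit(s, "")[[1]]
    mut <- sample(length(ch), round(f * length(ch)))
    ch[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
    paste(ch, collapse = "")
  }
  carriers <- sort(sample(52, 8))
  genomes <- lapply(1:52, function(i) {
    if (i %in% carriers) {
      paste0(bg(2500), mutate_frac(cons, 0.04), bg(2500))
    } else {
      bg(6500)
    }
  })
  found <- which(vapply(genomes, function(g) {
    presence_scan(cons, g)$present
  }, logical(1)))
  expect_identical(found, carriers)
})

test_that("Games-Howell matches the textbook two-group hand computation", {
  gh0 <- games_howell(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(gh0$q, 0)
  expect_equal(gh0$p, 1)
  set.seed(42)
  x <- scale(rnorm(30))[, 1] + 10   # mean 10, var 1 exactly
  y <- scale(rnorm(30))[, 1] + 12   # mean 12, var 1 exactly
  gh <- games_howell(list(x = x, y = y))
  q_hand <- abs(10 - 12) / sqrt((1 / 30 + 1 / 30) / 2)
  df_hand <- (1 / 30 + 1 / 30)^2 /
    ((1 / 30)^2 / 29 + (1 / 30)^2 / 29)
  expect_equal(gh$q, q_hand, tolerance = 1e-10)
  expect_equal(gh$df, df_hand, tolerance = 1e-10)
  p_oracle <- 1 - oracle_tukey_cdf(q_hand, 2, df_hand)
  expect_equal(gh$p, p_oracle, tolerance = 1e-4)
})

test_that("Games-Howell p-values agree with the integration oracle on a grid", {
  grid <- expand.grid(q = c(0.8, 2, 3.5, 5), k = c(2, 3, 4),
                      df = c(6, 20, 60))
  for (i in seq_len(nrow(grid))) {
    p_impl <- stats::ptukey(grid$q[i], grid$k[i], grid$df[i],
                            lower.tail = FALSE)
    p_orc <- 1 - oracle_tukey_cdf(grid$q[i], grid$k[i], grid$df[i])
    expect_equal(p_impl, p_orc, tolerance = 5e-4)
  }
})

test_that("degenerate variance cases are handled explicitly", {
  gh_eq <- games_howell(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(gh_eq$p, 1)
  gh_ne <- games_howell(list(a = c(2, 2, 2), b = c(3, 3, 3)))
  expect_equal(gh_ne$p, 0)
  expect_identical(gh_ne$flag, "degenerate")
  expect_error(games_howell(list(a = 1:3)), ">= 2 groups")
  expect_error(games_howell(list(a = 1:3, b = 2)), "n >= 2")
})

test_that("the Ks contrast separates transferred elements from genes", {
  ## distributions shaped like the observed histograms: element Ks tight
  ## and low, gene Ks broad and high
  set.seed(43)
  hits <- vapply(1:30, function(r) {
    te <- abs(rnorm(50, 0.01, 0.005))
    gene <- rnorm(50, 0.35, 0.08)
    gh <- games_howell(list(te = te, gene = gene))
    gh$p < 1e-4
  }, logical(1))
  expect_gte(sum(hits), 29)
})

test_that("contrast decisions control type I error on equal distributions", {
  set.seed(44)
  false_pos <- vapply(1:60, function(r) {
    te <- rnorm(40, 0.3, 0.05)
    gene <- rnorm(60, 0.3, 0.05)
    rep <- ks_contrast_report(list(p1 = te), list(p1 = gene),
                              alpha = 1e-4)
    rep$decision == "HTT-consistent"
  }, logical(1))
  expect_lte(sum(false_pos), 1)
  ## trivial separation decides HTT-consistent
  rep <- ks_contrast_report(list(p1 = rep(0, 30) + rnorm(30, 0, 1e-6)),
                            list(p1 = rnorm(30, 1, 0.1)))
  expect_identical(rep$decision, "HTT-consistent")
})

test_that("neighbor joining recovers additive trees exactly", {
  ## three taxa: closed-form branch lengths
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  ## closed form: la = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(2, 3, 7))
  ## four-taxon additive matrix from a known topology
  tr4 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:3):1);")
  d4 <- ape::cophenetic.phylo(tr4)
  rec <- nj_tree(d4)
  expect_identical(robinson_foulds(rec, tr4), 0L)
  expect_equal(sum(rec$edge.length), sum(tr4$edge.length))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3 taxa")
  dbad <- d; dbad[1, 2] <- 99
  expect_error(nj_tree(dbad), "non-symmetric")
})

test_that("NJ reproduces the generating topology for random additive matrices", {
  set.seed(45)
  for (r in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    tr$tip.label <- paste0("t", seq_len(n))
    d <- ape::cophenetic.phylo(tr)
    expect_identical(robinson_foulds(nj_tree(d), tr), 0L)
  }
})

test_that("Robinson-Foulds counts disagreeing bipartitions", {
  t1 <- "((a:1,b:1):1,(c:1,d:1):1);"
  expect_identical(robinson_foulds(t1, t1), 0L)
  t2 <- "((a:1,c:1):1,(b:1,d:1):1);"
  expect_identical(robinson_foulds(t1, t2), 2L)
  t3 <- "((a:1,x:1):1,(b:1,d:1):1);"
  expect_error(robinson_foulds(t1, t3), "leaf sets")
})
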