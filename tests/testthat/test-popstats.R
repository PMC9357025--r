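test_that("theta is 1 for complete fixation and ~0 for a split population", {
  fixA <- ss_from_strings(rep(list(paste(rep("11", 3), collapse = " ")), 20),
                          collection = "A")
  fixB <- ss_from_strings(rep(list(paste(rep("22", 3), collapse = " ")), 20),
                          collection = "B", ids = sprintf("t%02d", 1:20))
  s <- sample_set(rbind(fixA$samples, fixB$samples),
                  rbind(fixA$a1, fixB$a1), rbind(fixA$a2, fixB$a2),
                  loci = fixA$loci)
  expect_equal(wc_fst(s, c("A", "B"))$theta, 1)

  # one HWE population split into two arbitrary halves: expectation 0
  set.seed(31)
  n <- 100; p <- 0.4
  a1 <- matrix(ifelse(runif(n * 5) < p, 1L, 2L), n, 5)
  a2 <- matrix(ifelse(runif(n * 5) < p, 1L, 2L), n, 5)
  colnames(a1) <- colnames(a2) <- paste0("L", 1:5)
  meta <- data.frame(sample_id = sprintf("i%03d", 1:n), role = "reference",
                     collection = rep(c("A", "B"), each = n / 2),
                     reporting_group = "G", stringsAsFactors = FALSE)
  null_s <- sample_set(meta, a1, a2)
  expect_lt(abs(wc_fst(null_s, c("A", "B"))$theta), 0.05)
})

test_that("theta matches the independent ANOVA sums-of-squares oracle to 1e-12", {
  set.seed(32)
  for (rep in 1:20) {
    s <- random_ss(n = sample(6:25, 1), L = sample(1:6, 1),
                   miss = sample(c(0, 0.2), 1), n_coll = 2)
    # ensure both collections present with >= 2 members
    if (min(table(s$samples$collection)) < 2) next
    pops <- sort(unique(s$samples$collection))
    got <- tryCatch(wc_fst(s, pops)$theta, error = function(e) NULL)
    if (is.null(got)) next
    dos <- (s$a1 == 1L) + (s$a2 == 1L)
    oracle <- wc_anova_theta(list(dos[s$samples$collection == pops[1], , drop = FALSE],
                                  dos[s$samples$collection == pops[2], , drop = FALSE]))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("theta is invariant to allele relabeling and sample order", {
  set.seed(33)
  s <- random_ss(n = 30, L = 5, miss = 0.1, n_coll = 2)
  pops <- sort(unique(s$samples$collection))
  t0 <- wc_fst(s, pops)$theta
  # swap allele labels 1 <-> 2
  sw <- sample_set(s$samples, 3L - s$a2, 3L - s$a1, loci = s$loci)
  expect_equal(wc_fst(sw, pops)$theta, t0, tolerance = 1e-12)
  # permute sample order
  perm <- sample(n_samples(s))
  expect_equal(wc_fst(ss_subset(s, perm), pops)$theta, t0, tolerance = 1e-12)
})

test_that("permutation p-values behave at the extremes and are reproducible", {
  fixA <- ss_from_strings(rep(list("11 11"), 15), collection = "A")
  fixB <- ss_from_strings(rep(list("22 22"), 15), collection = "B",
                          ids = sprintf("t%02d", 1:15))
  s <- sample_set(rbind(fixA$samples, fixB$samples),
                  rbind(fixA$a1, fixB$a1), rbind(fixA$a2, fixB$a2),
                  loci = fixA$loci)
  pt <- fst_permutation(s, c("A", "B"), n_perm = 200, seed = 5)
  expect_equal(pt$p_value, 1 / 201)  # no permutation can exceed theta = 1

  # identical collections: p typically far from significant
  set.seed(34)
  null_s <- random_ss(n = 60, L = 5, miss = 0, n_coll = 2)
  p0 <- fst_permutation(null_s, sort(unique(null_s$samples$collection)),
                        n_perm = 300, seed = 6)$p_value
  expect_gt(p0, 0.05)

  # determinism under a fixed seed
  pa <- fst_permutation(s, c("A", "B"), n_perm = 100, seed = 99)
  pb <- fst_permutation(s, c("A", "B"), n_perm = 100, seed = 99)
  expect_identical(pa, pb)
})

test_that("pairwise_fst returns a symmetric labeled matrix", {
  set.seed(35)
  s <- random_ss(n = 45, L = 5, miss = 0.05, n_coll = 3)
  pf <- pairwise_fst(s)
  m <- attr(pf, "theta_matrix")
  expect_true(isSymmetric(m))
  expect_equal(nrow(pf), 3)
  expect_true(all(pf$theta <= 1))
})

test_that("HWE exact test matches the allele-pairing enumeration oracle", {
  # all-heterozygote configuration with equal allele counts, n = 4
  expect_equal(hwe_exact(0, 4, 0), hwe_enum_oracle(0, 4, 0))
  # assorted small configurations
  for (cfg in list(c(1, 2, 1), c(3, 0, 1), c(2, 2, 2), c(0, 1, 3),
                   c(4, 1, 0))) {
    expect_equal(hwe_exact(cfg[1], cfg[2], cfg[3]),
                 hwe_enum_oracle(cfg[1], cfg[2], cfg[3]),
                 tolerance = 1e-10,
                 label = paste(cfg, collapse = ","))
  }
  # monomorphic input
  expect_equal(hwe_exact(5, 0, 0), 1)
  # mid-p variant is smaller but positive
  expect_lt(hwe_exact(1, 2, 1, midp = TRUE), hwe_exact(1, 2, 1))
})

test_that("HWE exact test is conservative under the null", {
  set.seed(36)
  n <- 40; p <- 0.5
  reps <- 10000
  gt <- rmultinom(reps, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))
  pv <- vapply(seq_len(reps),
               function(i) hwe_exact(gt[1, i], gt[2, i], gt[3, i]),
               numeric(1))
  expect_lte(mean(pv < 0.05), 0.05)
  # super-uniform at other thresholds too
  for (t in c(0.01, 0.1, 0.25)) expect_lte(mean(pv < t), t + 0.005)
  expect_true(all(pv > 0 & pv <= 1))
})

test_that("LD test flags correlated loci and respects monomorphic input", {
  set.seed(37)
  # perfectly correlated genotypes at two loci
  d <- sample(0:2, 30, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  gstr <- c("22", "12", "11")[d + 1]
  s <- ss_from_strings(as.list(paste(gstr, gstr)))
  expect_lt(ld_exact(s, "loc1", "loc2", B = 5000, seed = 1), 0.001)

  # monomorphic locus -> 1
  m <- ss_from_strings(list("11 12", "11 22", "11 12", "11 11"))
  expect_equal(ld_exact(m, "loc1", "loc2"), 1)

  # independent loci: close-to-nominal rejection rate
  rej <- 0; nrep <- 100
  for (i in seq_len(nrep)) {
    s0 <- random_ss(n = 40, L = 2, miss = 0, n_coll = 1)
    if (ld_exact(s0, "loc1", "loc2", B = 500) < 0.05) rej <- rej + 1
  }
  expect_lte(rej / nrep, 0.1)
})

test_that("PCA separates fixed clusters, centers scores, is order-invariant", {
  fixA <- ss_from_strings(rep(list("11 11 11"), 10), collection = "A")
  fixB <- ss_from_strings(rep(list("22 22 22"), 10), collection = "B",
                          ids = sprintf("t%02d", 1:10))
  s <- sample_set(rbind(fixA$samples, fixB$samples),
                  rbind(fixA$a1, fixB$a1), rbind(fixA$a2, fixB$a2),
                  loci = fixA$loci)
  p <- pca_genotypes(s)
  expect_gt(p$explained[1], 0.999)
  ga <- p$scores[1:10, 1]; gb <- p$scores[11:20, 1]
  expect_true(max(ga) < min(gb) || max(gb) < min(ga))
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)

  # permutation of sample order permutes scores identically
  set.seed(38)
  s2 <- random_ss(n = 25, L = 6, miss = 0.1, n_coll = 2)
  perm <- sample(25)
  p1 <- pca_genotypes(s2)
  p2 <- pca_genotypes(ss_subset(s2, perm))
  expect_equal(unname(p2$scores), unname(p1$scores[perm, ]), tolerance = 1e-9)

  mono <- ss_from_strings(list("11 11", "11 11", "11 11"))
  expect_error(pca_genotypes(mono), "monomorphic")
})

test_that("mixture individuals project nearest their own group centroid", {
  set.seed(39)
  scn <- make_scenario(seed = 40)
  ref <- sample_reference(scn, seed = 41)
  mix <- sample_mixture(scn, "burton_early", seed = 42, n = 200)
  mixf <- filter_missing(mix$samples)
  comb <- sample_set(rbind(ref$samples, mixf$samples),
                     rbind(ref$a1, mixf$a1),
                     rbind(ref$a2, mixf$a2), loci = ref$loci)
  p <- pca_genotypes(comb)
  sc <- p$scores[, 1:2]
  refrows <- p$meta$role == "reference"
  cent <- sapply(unique(scn$groups), function(g)
    colMeans(sc[refrows & p$meta$reporting_group == g, , drop = FALSE]))
  mixrows <- which(!refrows)
  nearest <- sapply(mixrows, function(i) {
    d <- colSums((cent - sc[i, ])^2)
    colnames(cent)[which.min(d)]
  })
  truth <- mix$truth$true_group[match(p$meta$sample_id[mixrows],
                                      mix$truth$sample_id)]
  expect_gte(mean(nearest == truth), 0.9)
})
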