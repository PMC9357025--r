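test_that("baseline tallies allele counts from called genotypes only", {
  s <- ss_from_strings(list("11", "12"), collection = "A")
  b <- build_baseline(s)
  expect_equal(unname(b$x[1, 1, ]), c(3, 1))

  # a missing genotype contributes nothing
  s2 <- ss_from_strings(list("11 --", "12 12"), collection = "A")
  b2 <- build_baseline(s2)
  expect_equal(unname(b2$x[1, 2, ]), c(1, 1))

  # conservation at study scale: total counts = 2 x called genotypes
  scn <- make_scenario(seed = 51)
  ref <- sample_reference(scn, seed = 52)
  b3 <- build_baseline(ref)
  expect_equal(sum(b3$x), 2 * sum(!is.na(ref$a1)))
  expect_equal(nrow(b3$collections), 8)
})

test_that("genotype log-likelihood matches hand computation", {
  # empty-count baseline with lambda = 0.5: posterior-predictive p = 0.5
  b0 <- build_baseline(ss_from_strings(list("11"), collection = "A"))
  b0$x[] <- 0
  hom <- ss_from_strings(list("11"), collection = "M", role = "mixture")
  het <- ss_from_strings(list("12"), collection = "M", role = "mixture")
  expect_equal(unname(genotype_loglik(hom, b0)[1, 1]), log(0.25))
  expect_equal(unname(genotype_loglik(het, b0)[1, 1]), log(0.5))

  # all loci missing -> loglik 0 against every collection
  blank <- ss_from_strings(list("--"), collection = "M", role = "mixture")
  expect_equal(unname(genotype_loglik(blank, b0)[1, 1]), 0)

  # two-collection toy with counts written out (lambda = 0.5):
  # collection A: genotypes 11, 11 -> x = (4, 0); pA = 4.5/5 = 0.9
  # collection B: genotypes 22, 12 -> x = (1, 3); pB = 1.5/5 = 0.3
  ref <- ss_from_strings(list("11 11", "11 12", "22 11", "12 22"),
                         collection = c("A", "A", "B", "B"),
                         group = c("G1", "G1", "G2", "G2"))
  b <- build_baseline(ref)
  q <- ss_from_strings(list("12 11"), collection = "M", role = "mixture")
  pA1 <- (b$x[1, 1, 1] + 0.5) / (sum(b$x[1, 1, ]) + 1)
  pA2 <- (b$x[1, 2, 1] + 0.5) / (sum(b$x[1, 2, ]) + 1)
  expected_A <- log(2) + log(pA1) + log(1 - pA1) + 2 * log(pA2)
  expect_equal(unname(genotype_loglik(q, b)[1, "A"]), expected_A)
})

test_that("single-collection baseline gives rho = 1 with zero-width CI", {
  ref <- ss_from_strings(list("11 12", "12 22", "11 11"), collection = "A")
  mix <- ss_from_strings(list("11 12", "12 12"), collection = "M",
                         role = "mixture")
  fit <- infer_mixture(build_baseline(ref), mix, n_iter = 500, burn_in = 100,
                       seed = 1)
  sm <- summary(fit)
  expect_equal(sm$mean, 1)
  expect_equal(sm$lo, 1)
  expect_equal(sm$hi, 1)
})

test_that("a near-diagnostic mixture concentrates on the right collection", {
  # two collections fixed for opposite alleles; 20 A-type homozygotes
  refA <- ss_from_strings(rep(list("11 11 11"), 20), collection = "A",
                          group = "G1")
  refB <- ss_from_strings(rep(list("22 22 22"), 20), collection = "B",
                          group = "G2", ids = sprintf("b%02d", 1:20))
  ref <- sample_set(rbind(refA$samples, refB$samples),
                    rbind(refA$a1, refB$a1), rbind(refA$a2, refB$a2),
                    loci = refA$loci)
  mix <- ss_from_strings(rep(list("11 11 11"), 20), collection = "M",
                         role = "mixture", ids = sprintf("m%02d", 1:20))
  fit <- infer_mixture(build_baseline(ref), mix, n_iter = 4000, burn_in = 500,
                       seed = 2)
  sm <- summary(fit)
  expect_gt(sm$mean[sm$unit == "G1"], 0.95)
  # every retained draw is on the simplex
  expect_true(all(abs(rowSums(fit$pi_draws) - 1) < 1e-12))
  expect_true(all(abs(rowSums(fit$rho_draws) - 1) < 1e-12))
})

test_that("Gibbs posterior matches exact enumeration on a tiny instance", {
  # 2 collections, 2 loci, 3 mixture individuals
  ref <- ss_from_strings(list("11 12", "11 11", "22 12", "22 22"),
                         collection = c("A", "A", "B", "B"),
                         group = c("G1", "G1", "G2", "G2"))
  b <- build_baseline(ref)
  mix <- ss_from_strings(list("11 11", "22 12", "12 12"),
                         collection = "M", role = "mixture")
  zeta <- rep(0.5, 2)
  fit <- infer_mixture(b, mix, n_iter = 22000, burn_in = 2000, zeta = zeta,
                       seed = 3)
  ll <- genotype_loglik(mix, b)
  exact <- gsi_exact_posterior_mean(exp(ll), zeta)
  for (k in 1:2) {
    got <- mean(fit$pi_draws[, k])
    se <- mcse_batch(fit$pi_draws[, k])
    expect_lt(abs(got - exact[k]), 3 * se + 1e-8)
  }
})

test_that("fixed seeds reproduce draws bitwise; collection order only permutes", {
  set.seed(54)
  scn <- make_scenario(seed = 55)
  ref <- sample_reference(scn, seed = 56)
  mix <- sample_mixture(scn, "bay_late", seed = 57)$samples
  b <- build_baseline(ref)
  f1 <- infer_mixture(b, mix, n_iter = 1500, burn_in = 300, seed = 9)
  f2 <- infer_mixture(b, mix, n_iter = 1500, burn_in = 300, seed = 9)
  expect_identical(f1$pi_draws, f2$pi_draws)
  expect_identical(f1$z_freq, f2$z_freq)

  # permuting collection order permutes the posterior (within MC error)
  perm <- c(5:8, 1:4)
  ord <- order(match(ref$samples$collection,
                     b$collections$collection[perm]))
  bp <- build_baseline(ss_subset(ref, ord))
  f3 <- infer_mixture(bp, mix, n_iter = 6000, burn_in = 1000, seed = 10)
  f1b <- infer_mixture(b, mix, n_iter = 6000, burn_in = 1000, seed = 11)
  m1 <- colMeans(f1b$pi_draws)[bp$collections$collection]
  m3 <- colMeans(f3$pi_draws)
  expect_equal(unname(m3), unname(m1), tolerance = 0.03)
})

test_that("summaries are order statistics of the retained draws", {
  draws <- matrix(c(seq(0, 1, length.out = 101),
                    rev(seq(0, 1, length.out = 101))), ncol = 2)
  draws <- draws / rowSums(draws)
  fake <- structure(list(pi_draws = draws, rho_draws = draws,
                         z_freq = NULL,
                         collections = data.frame(collection = c("A", "B"),
                                                  reporting_group = c("A", "B")),
                         groups = c("A", "B")),
                    class = "mixture_result")
  colnames(fake$rho_draws) <- c("A", "B")
  colnames(fake$pi_draws) <- c("A", "B")
  sm <- summary(fake)
  expect_equal(sm$mean, c(0.5, 0.5))
  expect_equal(sm$lo, unname(apply(draws, 2, quantile, 0.025)))
  expect_equal(sm$hi, unname(apply(draws, 2, quantile, 0.975)))
  expect_true(all(sm$lo <= sm$mean & sm$mean <= sm$hi))
})

test_that("input validation: empty mixture and bad iteration counts error", {
  ref <- ss_from_strings(list("11", "12"), collection = "A")
  b <- build_baseline(ref)
  mix <- ss_from_strings(list("11"), collection = "M", role = "mixture")
  expect_error(infer_mixture(b, ss_subset(mix, logical(0)), seed = 1),
               "empty mixture")
  expect_error(infer_mixture(b, mix, n_iter = 100, burn_in = 100),
               "burn_in")
})
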