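# Shared fixtures and independent oracles.

# Build a sample_set from a list of genotype-string vectors, one element per
# sample: e.g. c("11", "12", "--") for three loci ("--" = missing).
ss_from_strings <- function(genos, collection = "A", role = "reference",
                            group = collection, ids = NULL,
                            loci = NULL) {
  n <- length(genos)
  parse1 <- function(g) {
    cells <- strsplit(g, " ")[[1]]
    cells[cells == "--"] <- NA_character_
    rbind(as.integer(substr(cells, 1, 1)), as.integer(substr(cells, 2, 2)))
  }
  mats <- lapply(genos, parse1)
  a1 <- do.call(rbind, lapply(mats, function(m) m[1, , drop = FALSE]))
  a2 <- do.call(rbind, lapply(mats, function(m) m[2, , drop = FALSE]))
  if (is.null(loci)) loci <- paste0("loc", seq_len(ncol(a1)))
  colnames(a1) <- colnames(a2) <- loci
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  collection <- rep_len(collection, n)
  group <- rep_len(group, n)
  role <- rep_len(role, n)
  meta <- data.frame(sample_id = ids, role = role, collection = collection,
                     reporting_group = ifelse(role == "reference", group,
                                              NA_character_),
                     stringsAsFactors = FALSE)
  sample_set(meta, a1, a2, loci = loci)
}

# random sample_set for property tests (may contain missing genotypes)
random_ss <- function(n = 10, L = 5, miss = 0.1, n_coll = 2,
                      role = "reference") {
  coll <- sample(paste0("c", seq_len(n_coll)), n, replace = TRUE)
  a1 <- matrix(sample(1:2, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample(1:2, n * L, replace = TRUE), n, L)
  drop <- matrix(runif(n * L) < miss, n, L)
  a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  colnames(a1) <- colnames(a2) <- paste0("loc", seq_len(L))
  meta <- data.frame(sample_id = sprintf("s%03d", seq_len(n)), role = role,
                     collection = coll,
                     reporting_group = if (role[1] == "reference") toupper(coll)
                                       else NA_character_,
                     stringsAsFactors = FALSE)
  sample_set(meta, a1, a2)
}

# two sample_sets compare equal?
expect_same_ss <- function(a, b) {
  expect_identical(a$samples, b$samples)
  expect_identical(a$loci, b$loci)
  expect_identical(unname(a$a1), unname(b$a1))
  expect_identical(unname(a$a2), unname(b$a2))
}

# ---------------------------------------------------------------------------
# Independent oracle for Weir-Cockerham theta: the ANOVA sums-of-squares
# route. dos_by_pop: list of per-population dosage matrices (0/1/2/NA).
# Works per locus on allele-1 indicators; loci unusable are dropped.
wc_anova_theta <- function(dos_by_pop) {
  r <- length(dos_by_pop)
  L <- ncol(dos_by_pop[[1]])
  A <- B <- C <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    d <- lapply(dos_by_pop, function(m) m[!is.na(m[, l]), l])
    ni <- vapply(d, length, numeric(1))
    if (any(ni < 1) || sum(ni) <= 2) next
    pi_ <- vapply(d, function(v) sum(v) / (2 * length(v)), numeric(1))
    pbar <- sum(vapply(d, sum, numeric(1))) / (2 * sum(ni))
    # sums of squares over gene copies nested in individuals in populations
    SSG <- sum(vapply(d, function(v) sum(v == 1) * 0.5, numeric(1)))
    SSI <- sum(unlist(mapply(function(v, p) 2 * (v / 2 - p)^2, d, pi_,
                             SIMPLIFY = FALSE)))
    SSP <- sum(2 * ni * (pi_ - pbar)^2)
    MSP <- SSP / (r - 1)
    MSI <- SSI / (sum(ni) - r)
    MSG <- SSG / sum(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    C[l] <- MSG
    B[l] <- (MSI - MSG) / 2
    A[l] <- (MSP - MSI) / (2 * nc)
  }
  sum(A, na.rm = TRUE) / sum(A + B + C, na.rm = TRUE)
}

# ---------------------------------------------------------------------------
# Independent oracle for the biallelic HWE exact test: enumerate every way of
# placing the nA allele-1 gene copies into the 2n ordered gene-copy slots of
# n individuals, count heterozygous pairings, and sum the probabilities of
# configurations no more probable than the observed heterozygote count.
hwe_enum_oracle <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  nA <- 2 * n11 + n12
  if (nA == 0 || nA == 2 * n) return(1)
  slots <- 2 * n
  combs <- utils::combn(slots, nA)
  hets <- apply(combs, 2, function(pos) {
    ind <- ceiling(pos / 2)
    sum(table(ind) == 1)
  })
  tab <- table(hets) / ncol(combs)
  p_obs <- tab[as.character(n12)]
  sum(tab[tab <= p_obs * (1 + 1e-12)])
}

# ---------------------------------------------------------------------------
# Exact posterior for a tiny GSI instance by enumeration over latent origins.
# expL: N x K likelihood matrix; zeta: Dirichlet prior. Returns exact
# posterior mean of pi.
gsi_exact_posterior_mean <- function(expL, zeta) {
  N <- nrow(expL); K <- ncol(expL)
  zs <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logw <- apply(zs, 1, function(z) {
    counts <- tabulate(z, nbins = K)
    sum(log(expL[cbind(seq_len(N), z)])) +
      sum(lgamma(zeta + counts)) - lgamma(sum(zeta) + N)
  })
  w <- exp(logw - max(logw)); w <- w / sum(w)
  means <- sapply(seq_len(K), function(k) {
    sum(w * sapply(seq_len(nrow(zs)), function(i) {
      counts <- tabulate(zs[i, ], nbins = K)
      (zeta[k] + counts[k]) / (sum(zeta) + N)
    }))
  })
  means
}

# Monte-Carlo standard error of a chain mean by batch means
mcse_batch <- function(x, n_batch = 50) {
  m <- floor(length(x) / n_batch)
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], nrow = m))
  stats::sd(bm) / sqrt(n_batch)
}
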