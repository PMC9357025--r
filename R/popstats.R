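# Pairwise Weir-Cockerham (1984) F_ST, permutation significance, exact
# Hardy-Weinberg and linkage-disequilibrium tests, and dosage PCA.

# Weir-Cockerham variance components for a pair of populations, vectorized
# over loci and (optionally) permutations. All arguments are L x P matrices
# (or vectors) of per-locus summaries: number of called genotypes, summed
# allele-1 dosage, and heterozygote counts for group A and group B.
# Returns a, b, c on the same shape; loci unusable in a column are NA.
# For a biallelic locus the components are identical for the two alleles, so
# summing over alleles rescales numerator and denominator of theta equally;
# components are therefore computed once per locus.
wc_components <- function(nA, sdA, shA, nB, sdB, shB) {
  r <- 2
  nT <- nA + nB
  valid <- nA >= 1 & nB >= 1 & nT > 2
  nbar <- nT / r
  nc <- nT - (nA^2 + nB^2) / nT
  pA <- sdA / (2 * nA); pB <- sdB / (2 * nB)
  pbar <- (sdA + sdB) / (2 * nT)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (shA + shB) / nT
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!valid] <- NA_real_; b[!valid] <- NA_real_; cc[!valid] <- NA_real_
  list(a = a, b = b, c = cc)
}

# per-group, per-locus summaries for a logical membership vector
group_locus_summaries <- function(called, dos0, het0, members) {
  m <- as.numeric(members)
  list(n = drop(crossprod(called, m)),
       sd = drop(crossprod(dos0, m)),
       sh = drop(crossprod(het0, m)))
}

#' Weir-Cockerham F_ST between two collections
#'
#' Computes the per-locus variance components `a` (among populations),
#' `b` (among individuals within populations) and `c` (within individuals)
#' of the Weir-Cockerham (1984) theta estimator, and the multilocus estimate
#' `theta = sum(a) / sum(a + b + c)` (ratio of sums across loci, the WC84
#' recommendation). Loci with no called genotypes in either collection, or
#' too few genotypes to estimate the components, are skipped. Negative
#' estimates are reported as computed, never clamped.
#'
#' @param s a [sample_set].
#' @param pops character vector of two collection labels.
#' @param group_by metadata column holding the labels (default
#'   `"collection"`).
#' @return list with `theta`, `per_locus` (data.frame `locus, n_a, n_b, a, b,
#'   c`), and `pair`.
#' @export
wc_fst <- function(s, pops, group_by = "collection") {
  stopifnot(length(pops) == 2L)
  groups <- s$samples[[group_by]]
  if (!all(pops %in% groups)) stop("unknown collection label(s)")
  idx <- groups %in% pops
  sub <- ss_subset(s, idx)
  g <- s$samples[[group_by]][idx]
  dos <- dosage_matrix(sub)
  called <- !is.na(dos) + 0
  dos0 <- ifelse(is.na(dos), 0, dos)
  het0 <- ifelse(is.na(dos), 0, het_matrix(sub) + 0)
  A <- group_locus_summaries(called, dos0, het0, g == pops[1])
  B <- group_locus_summaries(called, dos0, het0, g == pops[2])
  if (all(A$n < 2) || all(B$n < 2)) {
    stop("a collection has <2 genotyped individuals at every locus")
  }
  comp <- wc_components(A$n, A$sd, A$sh, B$n, B$sd, B$sh)
  theta <- sum(comp$a, na.rm = TRUE) /
    sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  list(theta = theta,
       per_locus = data.frame(locus = sub$loci, n_a = A$n, n_b = B$n,
                              a = comp$a, b = comp$b, c = comp$c,
                              row.names = NULL, stringsAsFactors = FALSE),
       pair = pops)
}

#' Permutation test for pairwise F_ST
#'
#' Shuffles individuals between the two collections (keeping sizes fixed)
#' and recomputes multilocus theta for each permutation;
#' `p = (1 + #[theta_perm >= theta_obs]) / (n_perm + 1)`.
#'
#' @inheritParams wc_fst
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for reproducible permutations.
#' @return list with `theta`, `p_value`, `n_perm`.
#' @export
fst_permutation <- function(s, pops, n_perm = 1000L, group_by = "collection",
                            seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  groups <- s$samples[[group_by]]
  idx <- groups %in% pops
  sub <- ss_subset(s, idx)
  g <- groups[idx]
  dos <- dosage_matrix(sub)
  called <- (!is.na(dos)) + 0
  dos0 <- ifelse(is.na(dos), 0, dos)
  het0 <- ifelse(is.na(dos), 0, het_matrix(sub) + 0)

  theta_from_M <- function(M) {
    # M: n x P matrix of group-A membership indicators
    nAm <- crossprod(called, M); sdAm <- crossprod(dos0, M)
    shAm <- crossprod(het0, M)
    nTv <- colSums(called); sdTv <- colSums(dos0); shTv <- colSums(het0)
    comp <- wc_components(nAm, sdAm, shAm,
                          nTv - nAm, sdTv - sdAm, shTv - shAm)
    num <- colSums(comp$a, na.rm = TRUE)
    den <- colSums(comp$a + comp$b + comp$c, na.rm = TRUE)
    num / den
  }
  n <- nrow(dos)
  nA0 <- sum(g == pops[1])
  obs <- theta_from_M(matrix(as.numeric(g == pops[1]), ncol = 1))
  M <- matrix(0, n, n_perm)
  for (j in seq_len(n_perm)) M[sample.int(n, nA0), j] <- 1
  perm <- theta_from_M(M)
  list(theta = obs,
       p_value = (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1),
       n_perm = n_perm)
}

#' All pairwise F_ST values between collections
#'
#' @param s a [sample_set].
#' @param group_by metadata column defining the populations.
#' @param n_perm permutations per pair for significance (0 = skip the test).
#' @param seed optional seed governing all permutation tests.
#' @return data.frame `pop_a, pop_b, theta, p_value` with the square theta
#'   matrix in attribute `"theta_matrix"`.
#' @export
pairwise_fst <- function(s, group_by = "collection", n_perm = 0L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- unique(s$samples[[group_by]])
  if (length(pops) < 2L) stop("need at least two collections")
  pairs <- utils::combn(pops, 2)
  res <- vector("list", ncol(pairs))
  mat <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  diag(mat) <- 0
  for (j in seq_len(ncol(pairs))) {
    pr <- pairs[, j]
    if (n_perm > 0) {
      pt <- fst_permutation(s, pr, n_perm = n_perm, group_by = group_by)
      th <- pt$theta; pv <- pt$p_value
    } else {
      th <- wc_fst(s, pr, group_by = group_by)$theta; pv <- NA_real_
    }
    mat[pr[1], pr[2]] <- mat[pr[2], pr[1]] <- th
    res[[j]] <- data.frame(pop_a = pr[1], pop_b = pr[2], theta = th,
                           p_value = pv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "theta_matrix") <- mat
  out
}

#' Biallelic Hardy-Weinberg exact test
#'
#' Full-enumeration exact test conditional on the observed allele counts:
#' with `n` individuals and `nA` copies of one allele, every heterozygote
#' count `h` compatible with `nA` has probability
#' `P(h) = n! / (n11! h! n22!) * 2^h * nA! nB! / (2n)!`, and the p-value is
#' the sum of `P(h)` over configurations no more probable than the observed
#' one (standard exact tail; set `midp = TRUE` to subtract half of the
#' observed configuration's probability).
#'
#' @param n11,n12,n22 genotype counts (allele-1 homozygote, heterozygote,
#'   allele-2 homozygote).
#' @param midp use the mid-p variant (default off).
#' @return the exact p-value; 1 for monomorphic input.
#' @export
hwe_exact <- function(n11, n12, n22, midp = FALSE) {
  stopifnot(n11 >= 0, n12 >= 0, n22 >= 0)
  n <- n11 + n12 + n22
  if (n < 1) stop("need at least one genotyped individual")
  nA <- 2 * n11 + n12
  nB <- 2 * n22 + n12
  if (nA == 0 || nB == 0) return(1)
  hs <- seq.int(nA %% 2L, min(nA, nB), by = 2L)
  logp <- lfactorial(n) -
    (lfactorial((nA - hs) / 2) + lfactorial(hs) + lfactorial((nB - hs) / 2)) +
    hs * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[match(n12, hs)]
  tail_sum <- sum(p[p <= p_obs * (1 + 1e-12)])
  if (midp) tail_sum <- tail_sum - p_obs / 2
  min(1, tail_sum)
}

#' Hardy-Weinberg exact tests across collections and loci
#'
#' @param s a [sample_set].
#' @param group_by metadata column defining the populations.
#' @param midp passed to [hwe_exact()].
#' @return data.frame `collection, locus, n, het_obs, p_value`; cells with no
#'   called genotypes are omitted.
#' @export
hwe_test <- function(s, group_by = "collection", midp = FALSE) {
  groups <- s$samples[[group_by]]
  dos <- dosage_matrix(s)
  out <- list()
  for (g in unique(groups)) {
    d <- dos[groups == g, , drop = FALSE]
    for (j in seq_along(s$loci)) {
      v <- d[, j]; v <- v[!is.na(v)]
      if (length(v) == 0L) next
      n11 <- sum(v == 2L); n12 <- sum(v == 1L); n22 <- sum(v == 0L)
      out[[length(out) + 1L]] <-
        data.frame(collection = g, locus = s$loci[j], n = length(v),
                   het_obs = n12, p_value = hwe_exact(n11, n12, n22, midp),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Genotypic linkage-disequilibrium test for one locus pair
#'
#' Tests independence of the genotype categories at two loci within one
#' collection with a Monte-Carlo exact contingency-table test
#' ([stats::fisher.test] with simulated p-value; for 2x2 tables the p-value
#' is fully exact). Only individuals called at both loci enter the table.
#'
#' @param s a [sample_set].
#' @param locus_a,locus_b locus names.
#' @param collection optional collection label to restrict to.
#' @param B Monte-Carlo replicates (default 2000).
#' @param seed optional seed.
#' @return the p-value; 1 when either locus is monomorphic in the collection.
#' @export
ld_exact <- function(s, locus_a, locus_b, collection = NULL, B = 2000L,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(collection)) s <- ss_subset(s, s$samples$collection == collection)
  dos <- dosage_matrix(s)
  ja <- match(locus_a, s$loci); jb <- match(locus_b, s$loci)
  if (is.na(ja) || is.na(jb)) stop("unknown locus name")
  ok <- !is.na(dos[, ja]) & !is.na(dos[, jb])
  if (sum(ok) < 2L) stop("need at least two individuals called at both loci")
  ga <- dos[ok, ja]; gb <- dos[ok, jb]
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L) return(1)
  tab <- table(ga, gb)
  fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value
}

#' Linkage-disequilibrium tests for all locus pairs in every collection
#'
#' @inheritParams ld_exact
#' @param group_by metadata column defining the populations.
#' @return data.frame `collection, locus_a, locus_b, n, p_value`.
#' @export
ld_test <- function(s, group_by = "collection", B = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- s$samples[[group_by]]
  prs <- utils::combn(s$loci, 2)
  out <- list()
  for (g in unique(groups)) {
    sub <- ss_subset(s, groups == g)
    dos <- dosage_matrix(sub)
    for (j in seq_len(ncol(prs))) {
      ja <- match(prs[1, j], sub$loci); jb <- match(prs[2, j], sub$loci)
      ok <- !is.na(dos[, ja]) & !is.na(dos[, jb])
      if (sum(ok) < 2L) next
      pv <- ld_exact(sub, prs[1, j], prs[2, j], B = B)
      out[[length(out) + 1L]] <-
        data.frame(collection = g, locus_a = prs[1, j], locus_b = prs[2, j],
                   n = sum(ok), p_value = pv, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' PCA of allele dosages
#'
#' Genotypes are coded as allele-1 dosage (0/1/2); missing cells are imputed
#' with the per-locus mean dosage; columns are centered (and optionally
#' scaled) before eigendecomposition of the covariance. Component signs are
#' fixed by making the largest-magnitude loading of each component positive,
#' so scores are reproducible across sample orderings.
#'
#' @param s a [sample_set].
#' @param scale scale columns to unit variance (default off).
#' @return object of class `gsi_pca`: `scores` (samples x components,
#'   rownames = sample ids), `explained` (variance fractions), `loadings`,
#'   and the sample metadata in `meta`.
#' @export
pca_genotypes <- function(s, scale = FALSE) {
  if (n_samples(s) < 2L) stop("need at least two samples")
  dos <- dosage_matrix(s)
  mu <- colMeans(dos, na.rm = TRUE)
  for (j in seq_len(ncol(dos))) dos[is.na(dos[, j]), j] <- mu[j]
  v <- apply(dos, 2, stats::var)
  if (all(v < .Machine$double.eps)) stop("all loci are monomorphic")
  if (scale) dos <- dos[, v > 0, drop = FALSE]
  pc <- prcomp(dos, center = TRUE, scale. = scale)
  # deterministic sign: largest |loading| positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  rownames(pc$x) <- s$samples$sample_id
  structure(list(scores = pc$x,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 loadings = pc$rotation,
                 meta = s$samples),
            class = "gsi_pca")
}

#' @export
print.gsi_pca <- function(x, ...) {
  cat(sprintf("gsi_pca: %d samples, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$explained[1],
              if (length(x$explained) > 1) 100 * x$explained[2] else 0))
  invisible(x)
}
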