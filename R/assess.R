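# Predicted-accuracy assessment of a GSI baseline: leave-one-out
# self-assignment of reference individuals, and simulation from the
# baseline's posterior allele frequencies.

new_assessment <- function(per_group, confusion, mode, n_unassignable = 0L,
                           n_ties = 0L, per_rep = NULL) {
  structure(list(per_group = per_group, confusion = confusion, mode = mode,
                 n_unassignable = n_unassignable, n_ties = n_ties,
                 per_rep = per_rep),
            class = "gsi_assessment")
}

#' @export
print.gsi_assessment <- function(x, ...) {
  cat(sprintf("gsi_assessment (%s): overall accuracy %.3f\n", x$mode,
              sum(diag(x$confusion)) / sum(x$confusion)))
  print(x$per_group, digits = 3, row.names = FALSE)
  invisible(x)
}

# score a likelihood matrix (individuals x collections) into group
# assignments; ties broken by lowest group index and tallied
assign_groups <- function(ll, collections, groups) {
  G <- outer(collections$reporting_group, groups, "==") + 0
  expL <- exp(ll - apply(ll, 1, max))
  post_k <- expL / rowSums(expL)        # equal collection weights
  post_g <- post_k %*% G
  ties <- apply(post_g, 1, function(r) sum(r >= max(r) - 1e-12) > 1L)
  list(assigned = groups[max.col(post_g, ties.method = "first")],
       post_g = post_g, ties = ties)
}

#' Leave-one-out self-assignment accuracy
#'
#' Scores every reference individual against the baseline after removing its
#' own alleles from its collection's allele counts, converts the
#' per-collection likelihoods to scaled posteriors with equal collection
#' weights, sums them within reporting groups, and assigns the individual to
#' the highest-posterior group. Individuals with every locus missing carry
#' no information (all likelihoods equal); they are tallied separately as
#' unassignable and excluded from the accuracies. Ties are broken toward the
#' first group and counted.
#'
#' @param reference a [sample_set] of reference samples.
#' @param lambda baseline prior mass per allele (see [build_baseline()]).
#' @return a `gsi_assessment` with `mode = "loo"`: per-group accuracies and
#'   the true-by-assigned confusion matrix.
#' @export
loo_self_assign <- function(reference, lambda = 0.5) {
  b <- build_baseline(reference, lambda = lambda)
  if (any(b$collections$n < 2)) {
    warning("collection(s) of size 1: leave-one-out leaves an empty baseline cell")
  }
  meta <- reference$samples
  groups <- unique(b$collections$reporting_group)
  dos <- dosage_matrix(reference)
  N <- nrow(dos); K <- nrow(b$collections)
  ll <- matrix(0, N, K)
  for (i in seq_len(N)) {
    bi <- b
    k <- match(meta$collection[i], b$collections$collection)
    d <- dos[i, ]
    called <- !is.na(d)
    bi$x[k, called, 1] <- bi$x[k, called, 1] - d[called]
    bi$x[k, called, 2] <- bi$x[k, called, 2] - (2 - d[called])
    ll[i, ] <- genotype_loglik(ss_subset(reference, i), bi)
  }
  sc <- assign_groups(ll, b$collections, groups)
  informative <- rowSums(!is.na(dos)) > 0
  truth <- meta$reporting_group
  confusion <- table(factor(truth[informative], levels = groups),
                     factor(sc$assigned[informative], levels = groups))
  tp <- sc$post_g[cbind(seq_len(N), match(truth, groups))]
  per_group <- data.frame(
    group = groups,
    n = as.integer(rowSums(confusion)),
    accuracy = ifelse(rowSums(confusion) > 0,
                      diag(confusion) / rowSums(confusion), NA_real_),
    mean_posterior_true = as.numeric(
      tapply(tp[informative], factor(truth[informative], levels = groups),
             mean)),
    stringsAsFactors = FALSE, row.names = NULL)
  new_assessment(per_group, unclass(confusion), "loo",
                 n_unassignable = sum(!informative),
                 n_ties = sum(sc$ties[informative]))
}

#' Simulated-mixture assignment accuracy
#'
#' For every replicate and every baseline collection, draws allele
#' frequencies from the collection's Dirichlet posterior
#' `Dirichlet(x + lambda)`, simulates `n` Hardy-Weinberg genotypes at those
#' frequencies, optionally applies per-call dropout, and assigns each
#' simulated individual to a reporting group by maximum summed scaled
#' likelihood against the (fixed) baseline. Accuracies are pooled over
#' replicates; a per-replicate breakdown is kept in `$per_rep`.
#'
#' Drawing the simulation frequencies from the posterior rather than from
#' point estimates avoids the optimism of resampling the observed genotypes
#' when the panel is small.
#'
#' @param b a [build_baseline()] object.
#' @param n simulated individuals per collection per replicate (default 200).
#' @param reps replicates (default 50).
#' @param missing_rate per-genotype dropout probability applied to simulated
#'   individuals (default 0).
#' @param seed optional integer seed.
#' @return a `gsi_assessment` with `mode = "simulated"`.
#' @export
simulate_assess <- function(b, n = 200L, reps = 50L, missing_rate = 0,
                            seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  groups <- unique(b$collections$reporting_group)
  K <- nrow(b$collections); L <- length(b$loci)
  confusion <- matrix(0L, length(groups), length(groups),
                      dimnames = list(groups, groups))
  post_sum <- setNames(numeric(length(groups)), groups)
  post_n <- setNames(numeric(length(groups)), groups)
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    dos <- matrix(NA_integer_, n * K, L)
    truth <- character(n * K)
    row0 <- 0L
    for (k in seq_len(K)) {
      alpha1 <- b$x[k, , 1] + b$lambda
      alpha2 <- b$x[k, , 2] + b$lambda
      g1 <- rgamma(L, alpha1); g2 <- rgamma(L, alpha2)
      p <- g1 / (g1 + g2)                       # Beta(alpha1, alpha2) draw
      d <- sapply(seq_len(L), function(j) rbinom(n, 2L, p[j]))
      if (n == 1L) d <- matrix(d, nrow = 1)
      if (missing_rate > 0) {
        drop <- matrix(runif(n * L) < missing_rate, n, L)
        d[drop] <- NA_integer_
      }
      dos[row0 + seq_len(n), ] <- d
      truth[row0 + seq_len(n)] <- b$collections$reporting_group[k]
      row0 <- row0 + n
    }
    ll <- loglik_from_dosage(dos, b)
    sc <- assign_groups(ll, b$collections, groups)
    informative <- rowSums(!is.na(dos)) > 0
    tab <- table(factor(truth[informative], levels = groups),
                 factor(sc$assigned[informative], levels = groups))
    confusion <- confusion + tab
    tp <- sc$post_g[cbind(seq_along(truth), match(truth, groups))]
    for (g in groups) {
      sel <- informative & truth == g
      post_sum[g] <- post_sum[g] + sum(tp[sel])
      post_n[g] <- post_n[g] + sum(sel)
    }
    per_rep[[r]] <- data.frame(rep = r, group = groups,
                               accuracy = ifelse(rowSums(tab) > 0,
                                                 diag(tab) / rowSums(tab),
                                                 NA_real_),
                               stringsAsFactors = FALSE)
  }
  per_group <- data.frame(
    group = groups,
    n = as.integer(rowSums(confusion)),
    accuracy = ifelse(rowSums(confusion) > 0,
                      diag(confusion) / rowSums(confusion), NA_real_),
    mean_posterior_true = ifelse(post_n > 0, post_sum / post_n, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
  new_assessment(per_group, confusion, "simulated",
                 per_rep = do.call(rbind, per_rep))
}

# log-likelihood straight from a dosage matrix (internal; used by the
# simulation path where no sample_set exists)
loglik_from_dosage <- function(dos, b) {
  p1 <- baseline_freqs(b)
  if (is.null(dim(p1))) p1 <- matrix(p1, nrow = nrow(b$collections))
  N <- nrow(dos); K <- nrow(p1)
  ll <- matrix(0, N, K)
  lp1 <- log(p1); lp2 <- log(1 - p1)
  for (j in seq_len(ncol(dos))) {
    d <- dos[, j]
    called <- which(!is.na(d))
    if (length(called) == 0L) next
    dj <- d[called]
    add <- matrix(0, length(called), K)
    hom1 <- dj == 2L; het <- dj == 1L; hom2 <- dj == 0L
    if (any(hom1)) add[hom1, ] <- matrix(2 * lp1[, j], sum(hom1), K, byrow = TRUE)
    if (any(het))  add[het, ]  <- matrix(log(2) + lp1[, j] + lp2[, j], sum(het), K, byrow = TRUE)
    if (any(hom2)) add[hom2, ] <- matrix(2 * lp2[, j], sum(hom2), K, byrow = TRUE)
    ll[called, ] <- ll[called, ] + add
  }
  ll
}
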