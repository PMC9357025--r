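# Bayesian genetic stock identification: conditional mixture model over
# reference collections, aggregated into reporting groups.

#' Compile a reference baseline of allele counts
#'
#' Tallies observed allele counts per collection, locus and allele from the
#' called genotypes of a reference sample set (missing genotypes contribute
#' nothing). The baseline is held fixed during mixture estimation
#' (conditional model): mixture individuals never update the reference
#' allele frequencies.
#'
#' @param reference a [sample_set] of reference samples; every sample must
#'   carry a collection and a reporting group.
#' @param lambda per-allele Dirichlet prior mass on baseline allele
#'   frequencies; the default 1/2 (= 1/number of alleles) is the
#'   unit-information prior for a biallelic locus.
#' @return object of class `gsi_baseline`: `collections` (data.frame
#'   `collection, reporting_group, n`), `x` (array collections x loci x 2 of
#'   allele counts), `loci`, `lambda`.
#' @export
build_baseline <- function(reference, lambda = 0.5) {
  stopifnot(inherits(reference, "sample_set"), lambda > 0)
  if (any(reference$samples$role != "reference")) {
    stop("baseline samples must have role 'reference'")
  }
  meta <- reference$samples
  colls <- unique(meta$collection)
  grp <- meta$reporting_group[match(colls, meta$collection)]
  L <- n_loci(reference)
  x <- array(0, dim = c(length(colls), L, 2),
             dimnames = list(colls, reference$loci, c("1", "2")))
  dos <- dosage_matrix(reference)
  for (k in seq_along(colls)) {
    d <- dos[meta$collection == colls[k], , drop = FALSE]
    ncall <- colSums(!is.na(d))
    x[k, , 1] <- colSums(d, na.rm = TRUE)
    x[k, , 2] <- 2 * ncall - x[k, , 1]
    if (all(ncall == 0)) {
      stop("collection ", colls[k], " has no called genotypes at any locus")
    }
  }
  structure(list(collections = data.frame(collection = colls,
                                          reporting_group = grp,
                                          n = as.integer(table(meta$collection)[colls]),
                                          stringsAsFactors = FALSE),
                 x = x, loci = reference$loci, lambda = lambda),
            class = "gsi_baseline")
}

#' @export
print.gsi_baseline <- function(x, ...) {
  cat(sprintf("gsi_baseline: %d collections in %d reporting groups, %d loci (lambda = %g)\n",
              nrow(x$collections), length(unique(x$collections$reporting_group)),
              length(x$loci), x$lambda))
  invisible(x)
}

# posterior-predictive allele-1 frequency per collection x locus
baseline_freqs <- function(b) {
  tot <- b$x[, , 1] + b$x[, , 2]
  (b$x[, , 1] + b$lambda) / (tot + 2 * b$lambda)
}

#' Genotype log-likelihoods against a baseline
#'
#' For each sample and collection, the log-probability of the observed
#' multilocus genotype under Hardy-Weinberg proportions at the collection's
#' posterior-predictive allele frequencies
#' `p_hat = (x + lambda) / (total + 2*lambda)`. Homozygotes contribute
#' `2*log(p_hat)`, heterozygotes `log(2) + log(p_hat_1) + log(p_hat_2)`;
#' missing loci contribute 0 (so an all-missing sample scores 0 against
#' every collection).
#'
#' @param s a [sample_set] (mixture or reference individuals to score).
#' @param b a [build_baseline()] object with the same locus panel.
#' @return numeric matrix, samples x collections, of log-likelihoods.
#' @export
genotype_loglik <- function(s, b) {
  if (!identical(s$loci, b$loci)) {
    if (!setequal(s$loci, b$loci)) stop("locus panel does not match baseline")
    ord <- match(b$loci, s$loci)
    s <- sample_set(s$samples, s$a1[, ord, drop = FALSE],
                    s$a2[, ord, drop = FALSE], loci = b$loci)
  }
  ll <- loglik_from_dosage(dosage_matrix(s), b)
  dimnames(ll) <- list(s$samples$sample_id, b$collections$collection)
  ll
}

#' Estimate mixture proportions by Gibbs sampling
#'
#' Fits the conditional GSI mixture model: each mixture individual `i` has a
#' latent origin collection `Z_i`, and the vector of mixing proportions `pi`
#' over collections gets a Dirichlet prior with mass `zeta`. The sampler
#' alternates (i) drawing each `Z_i` from
#' `P(Z_i = k) proportional to pi_k * L_ik` and (ii) drawing
#' `pi ~ Dirichlet(zeta + counts(Z))`, and retains all post-burn-in draws
#' (no thinning). Reporting-group proportions `rho_g = sum over collections
#' in g of pi_k` are aggregated from the same draws.
#'
#' @param b a [build_baseline()] object.
#' @param mix a [sample_set] of mixture individuals (QC-filtered).
#' @param n_iter MCMC sweeps (default 10000).
#' @param burn_in discarded leading sweeps (default 1000).
#' @param zeta Dirichlet prior mass per collection; default symmetric
#'   `1/K` (total mass 1). `prior = "group_balanced"` instead uses
#'   `1/(G * K_g)` so every reporting group carries equal total mass.
#' @param prior `"uniform"` or `"group_balanced"` (ignored when `zeta` is
#'   supplied).
#' @param seed optional integer seed (draws are bitwise reproducible).
#' @return object of class `mixture_result`: `pi_draws` (retained draws x
#'   collections), `rho_draws` (retained draws x groups), `z_freq`
#'   (individuals x collections posterior origin frequencies), `collections`,
#'   `groups`, `config`.
#' @export
infer_mixture <- function(b, mix, n_iter = 10000L, burn_in = 1000L,
                          zeta = NULL, prior = c("uniform", "group_balanced"),
                          seed = NULL) {
  prior <- match.arg(prior)
  if (n_samples(mix) == 0L) stop("empty mixture")
  if (burn_in < 0 || burn_in >= n_iter) stop("need 0 <= burn_in < n_iter")
  K <- nrow(b$collections)
  if (is.null(zeta)) {
    if (prior == "uniform") {
      zeta <- rep(1 / K, K)
    } else {
      gtab <- table(b$collections$reporting_group)
      zeta <- 1 / (length(gtab) * as.numeric(gtab[b$collections$reporting_group]))
    }
  }
  zeta <- rep_len(as.numeric(zeta), K)
  if (any(zeta <= 0)) stop("zeta must be positive")
  if (!is.null(seed)) set.seed(seed)

  ll <- genotype_loglik(mix, b)
  expL <- exp(ll - apply(ll, 1, max))
  fit <- gsi_gibbs(expL, zeta, as.integer(n_iter), as.integer(burn_in))
  colnames(fit$pi_draws) <- b$collections$collection
  dimnames(fit$z_freq) <- list(mix$samples$sample_id,
                               b$collections$collection)
  groups <- unique(b$collections$reporting_group)
  G <- outer(b$collections$reporting_group, groups, "==") + 0
  colnames(G) <- groups
  rho_draws <- fit$pi_draws %*% G
  structure(list(pi_draws = fit$pi_draws, rho_draws = rho_draws,
                 z_freq = fit$z_freq,
                 collections = b$collections, groups = groups,
                 config = list(n_iter = n_iter, burn_in = burn_in,
                               zeta = zeta, prior = prior, seed = seed)),
            class = "mixture_result")
}

#' Summarize a mixture fit
#'
#' Posterior means and equal-tailed 95% credible intervals of the
#' reporting-group proportions (`level = "group"`, the default) or of the
#' collection proportions (`level = "collection"`).
#'
#' @param object a [infer_mixture()] result.
#' @param level `"group"` or `"collection"`.
#' @param probs credible-interval quantiles.
#' @param ... unused.
#' @return data.frame `unit, mean, lo, hi`.
#' @export
summary.mixture_result <- function(object, level = c("group", "collection"),
                                   probs = c(0.025, 0.975), ...) {
  level <- match.arg(level)
  draws <- if (level == "group") object$rho_draws else object$pi_draws
  qs <- apply(draws, 2, quantile, probs = probs, names = FALSE)
  data.frame(unit = colnames(draws),
             mean = colMeans(draws),
             lo = qs[1, ], hi = qs[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf("mixture_result: %d retained draws, %d collections, %d groups\n",
              nrow(x$pi_draws), ncol(x$pi_draws), length(x$groups)))
  print(summary(x), digits = 3)
  invisible(x)
}
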