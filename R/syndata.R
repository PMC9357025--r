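# Synthetic-data generator emulating a two-site, two-layer archaeological
# mixed-stock study: 8 reference collections in 3 spawn-timing reporting
# groups (~347 fish), 7 biallelic loci with strong between-group divergence
# (one near-diagnostic photoperiod-gene-like locus), 4 mixtures of 48
# individuals each, per-call genotype dropout calibrated to an ~83%
# survival rate under the ">1 missing locus" filter, and duplicate
# genotyping replicates with configurable discordance.

# Group-level allele-1 frequencies of the herring preset, loci x groups.
# Locus "SYNE2like" is the near-diagnostic spawn-timing locus (cross-group
# differential >= 0.8); the remaining loci mix moderate and weak divergence.
# The winter/early-spring groups (JanFeb, MarApr) are much closer to each
# other than either is to the May group, so reporting-group assignment is
# strong while collection-level assignment within a group is weak.
herring_panel_freqs <- function() {
  m <- rbind(
    SYNE2like = c(0.95, 0.90, 0.05),
    L2        = c(0.82, 0.30, 0.10),
    L3        = c(0.12, 0.68, 0.90),
    L4        = c(0.78, 0.25, 0.08),
    L5        = c(0.28, 0.82, 0.90),
    L6        = c(0.72, 0.20, 0.48),
    L7        = c(0.18, 0.68, 0.38))
  colnames(m) <- c("JanFeb", "MarApr", "May")
  m
}

#' Per-call dropout rate matching a target QC survival fraction
#'
#' Under independent per-genotype dropout at rate `m`, the number of missing
#' loci of a sample is Binomial(`n_loci`, `m`); this solves for the `m` at
#' which `P(missing <= max_missing)` equals `target_survival`.
#'
#' @param target_survival fraction of samples expected to survive
#'   [filter_missing()] (default 0.83).
#' @param n_loci panel size (default 7).
#' @param max_missing the filter's tolerance (default 1).
#' @return the per-call dropout probability.
#' @export
calibrate_missing_rate <- function(target_survival = 0.83, n_loci = 7L,
                                   max_missing = 1L) {
  stopifnot(target_survival > 0, target_survival < 1)
  f <- function(m) stats::pbinom(max_missing, n_loci, m) - target_survival
  uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

#' Define a synthetic mixed-stock scenario
#'
#' Builds the full ground truth of a synthetic study: 3 reporting groups
#' (winter, early-spring and late-spring spawners), 8 reference collections
#' with per-collection allele frequencies (group frequency plus a small
#' within-group jitter), reference sample sizes totalling 347, four mixture
#' layers of 48 individuals whose true group proportions mirror the study
#' design qualitatively (one site dominated by the early-spring group in
#' both layers; the other site mixed, with the late-spring group present
#' only in its older layer), and a dropout rate calibrated so ~83% of
#' mixture samples survive the missingness filter.
#'
#' @param divergence `"herring"` (the preset above) or `"none"` (all
#'   collections share one frequency vector — useful for null simulations).
#' @param seed integer seed for the within-group frequency jitter.
#' @param jitter_sd SD of the within-group collection-level jitter
#'   (default 0.03).
#' @param freqs optional custom loci x groups frequency matrix overriding
#'   the preset.
#' @param missing_rate per-call dropout probability; default calibrated via
#'   [calibrate_missing_rate()].
#' @param mixture_size individuals per mixture layer (default 48).
#' @return object of class `truth_scenario`.
#' @export
make_scenario <- function(divergence = c("herring", "none"), seed = NULL,
                          jitter_sd = 0.03, freqs = NULL,
                          missing_rate = NULL, mixture_size = 48L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freqs)) {
    freqs <- herring_panel_freqs()
    divergence <- match.arg(divergence)
    if (divergence == "none") {
      freqs[] <- rowMeans(freqs)
    }
  }
  groups <- colnames(freqs)
  collections <- data.frame(
    collection = c("ref_jf1", "ref_jf2", "ref_jf3",
                   "ref_ma1", "ref_ma2", "ref_ma3",
                   "ref_may1", "ref_may2"),
    group = groups[c(1, 1, 1, 2, 2, 2, 3, 3)],
    n_ref = c(44L, 43L, 44L, 44L, 43L, 44L, 43L, 42L),  # totals 347
    stringsAsFactors = FALSE)
  L <- nrow(freqs); K <- nrow(collections)
  cf <- matrix(NA_real_, K, L,
               dimnames = list(collections$collection, rownames(freqs)))
  for (k in seq_len(K)) {
    base <- freqs[, collections$group[k]]
    cf[k, ] <- if (jitter_sd > 0) {
      pmin(0.99, pmax(0.01, base + rnorm(L, 0, jitter_sd)))
    } else base
  }
  if (is.null(missing_rate)) {
    missing_rate <- calibrate_missing_rate(0.83, n_loci = L, max_missing = 1L)
  }
  mixtures <- list(
    burton_early = c(JanFeb = 0.25, MarApr = 0.65, May = 0.10),
    burton_late  = c(JanFeb = 0.30, MarApr = 0.70, May = 0.00),
    bay_early    = c(JanFeb = 0.08, MarApr = 0.92, May = 0.00),
    bay_late     = c(JanFeb = 0.12, MarApr = 0.88, May = 0.00))
  mixtures <- lapply(mixtures, function(p) setNames(as.numeric(p), groups))
  structure(list(groups = groups, collections = collections,
                 loci = rownames(freqs), freqs = cf,
                 group_freqs = freqs, mixtures = mixtures,
                 missing_rate = missing_rate,
                 mixture_size = as.integer(mixture_size)),
            class = "truth_scenario")
}

#' @export
print.truth_scenario <- function(x, ...) {
  cat(sprintf("truth_scenario: %d collections / %d groups / %d loci; %d mixtures of %d; dropout %.3f\n",
              nrow(x$collections), length(x$groups), length(x$loci),
              length(x$mixtures), x$mixture_size, x$missing_rate))
  invisible(x)
}

# HWE genotypes at given allele-1 frequencies: returns a1/a2 matrices
hwe_genotypes <- function(n, p) {
  L <- length(p)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  for (j in seq_len(L)) {
    a1[, j] <- ifelse(runif(n) < p[j], 1L, 2L)
    a2[, j] <- ifelse(runif(n) < p[j], 1L, 2L)
  }
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  list(a1 = a1, a2 = a2)
}

#' Simulate the reference sample set of a scenario
#'
#' Hardy-Weinberg genotypes per collection at its true allele frequencies;
#' no missingness (modern reference samples are assumed completely
#' genotyped).
#'
#' @param scn a [make_scenario()] object.
#' @param seed optional integer seed.
#' @return a [sample_set] with role `"reference"`.
#' @export
sample_reference <- function(scn, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  metas <- list(); m1 <- list(); m2 <- list()
  for (k in seq_len(nrow(scn$collections))) {
    n <- scn$collections$n_ref[k]
    g <- hwe_genotypes(n, scn$freqs[k, ])
    metas[[k]] <- data.frame(
      sample_id = sprintf("%s_%03d", scn$collections$collection[k], seq_len(n)),
      role = "reference",
      collection = scn$collections$collection[k],
      reporting_group = scn$collections$group[k],
      stringsAsFactors = FALSE)
    m1[[k]] <- g$a1; m2[[k]] <- g$a2
  }
  a1 <- do.call(rbind, m1); a2 <- do.call(rbind, m2)
  colnames(a1) <- colnames(a2) <- scn$loci
  sample_set(do.call(rbind, metas), a1, a2, loci = scn$loci)
}

#' Simulate one mixture layer of a scenario
#'
#' True origins are drawn from the layer's group-proportion vector (the
#' collection is uniform within the group), genotypes are Hardy-Weinberg at
#' the origin collection's frequencies, and each genotype call then drops
#' out independently at the scenario's `missing_rate`. Truth labels are
#' returned for parameter-recovery tests.
#'
#' @param scn a [make_scenario()] object.
#' @param mixture_name one of `names(scn$mixtures)`.
#' @param seed optional integer seed.
#' @param n mixture size; defaults to the scenario's (48).
#' @return list with `samples` (a [sample_set], role `"mixture"`,
#'   collection = `mixture_name`) and `truth` (data.frame
#'   `sample_id, true_group, true_collection`).
#' @export
sample_mixture <- function(scn, mixture_name, seed = NULL,
                           n = scn$mixture_size) {
  if (!mixture_name %in% names(scn$mixtures)) {
    stop("unknown mixture name: ", mixture_name)
  }
  if (!is.null(seed)) set.seed(seed)
  props <- scn$mixtures[[mixture_name]]
  grp <- sample(scn$groups, n, replace = TRUE, prob = props)
  coll <- vapply(grp, function(g) {
    cand <- scn$collections$collection[scn$collections$group == g]
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, character(1))
  kidx <- match(coll, scn$collections$collection)
  L <- length(scn$loci)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    g <- hwe_genotypes(1L, scn$freqs[kidx[i], ])
    a1[i, ] <- g$a1; a2[i, ] <- g$a2
  }
  if (scn$missing_rate > 0) {
    drop <- matrix(runif(n * L) < scn$missing_rate, n, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  colnames(a1) <- colnames(a2) <- scn$loci
  ids <- sprintf("%s_%03d", mixture_name, seq_len(n))
  meta <- data.frame(sample_id = ids, role = "mixture",
                     collection = mixture_name,
                     reporting_group = NA_character_,
                     stringsAsFactors = FALSE)
  list(samples = sample_set(meta, a1, a2, loci = scn$loci),
       truth = data.frame(sample_id = ids, true_group = unname(grp),
                          true_collection = unname(coll),
                          stringsAsFactors = FALSE))
}

#' Simulate duplicate genotyping replicates
#'
#' Returns two copies of a sample set; in the second copy every called
#' genotype is independently replaced by one of the two other genotype
#' categories (uniformly) with probability `discordance_rate`, emulating
#' genotyping error between repeated runs.
#'
#' @param s a [sample_set].
#' @param discordance_rate per-call replacement probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return list of two [sample_set]s (`rep1`, `rep2`).
#' @export
make_replicates <- function(s, discordance_rate = 0, seed = NULL) {
  stopifnot(discordance_rate >= 0, discordance_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  a1 <- s$a1; a2 <- s$a2
  called <- which(!is.na(a1))
  flip <- called[runif(length(called)) < discordance_rate]
  if (length(flip) > 0) {
    # genotype categories by allele-1 dosage: 2 = 1/1, 1 = 1/2, 0 = 2/2
    cur <- (a1[flip] == 1L) + (a2[flip] == 1L)
    new <- vapply(cur, function(d) sample(setdiff(0:2, d), 1L), integer(1))
    a1[flip] <- ifelse(new >= 1L, 1L, 2L)
    a2[flip] <- ifelse(new == 2L, 1L, 2L)
  }
  list(rep1 = s, rep2 = sample_set(s$samples, a1, a2, loci = s$loci))
}
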