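#' Replicate-genotyping discrepancy rate
#'
#' Compares two genotyping replicates of the same samples. A sample counts as
#' mismatching when at least one locus called in *both* replicates disagrees;
#' loci missing in either replicate are not comparable and never count as
#' mismatches. The headline rate divides mismatching samples by total samples;
#' a per-call rate (mismatching calls / comparable calls) is also reported.
#'
#' @param rep1,rep2 [sample_set]s with identical samples and loci.
#' @return list with `per_sample` (the discrepancy rate), `per_call`,
#'   `n_samples`, `n_mismatch_samples`, `n_comparable_calls`,
#'   `n_mismatch_calls`, and `mismatch_ids`.
#' @export
discrepancy_rate <- function(rep1, rep2) {
  if (!identical(rep1$loci, rep2$loci) ||
      !identical(sort(rep1$samples$sample_id), sort(rep2$samples$sample_id))) {
    stop("replicates must contain the same samples and loci")
  }
  ord <- match(rep1$samples$sample_id, rep2$samples$sample_id)
  b1 <- rep2$a1[ord, , drop = FALSE]; b2 <- rep2$a2[ord, , drop = FALSE]
  comparable <- !is.na(rep1$a1) & !is.na(b1)
  # genotypes are stored with a1 <= a2, so elementwise comparison suffices
  mism <- comparable & (rep1$a1 != b1 | rep1$a2 != b2)
  n <- n_samples(rep1)
  bad <- rowSums(mism) > 0
  list(per_sample = sum(bad) / n,
       per_call = if (sum(comparable) > 0) sum(mism) / sum(comparable) else 0,
       n_samples = n,
       n_mismatch_samples = sum(bad),
       n_comparable_calls = sum(comparable),
       n_mismatch_calls = sum(mism),
       mismatch_ids = rep1$samples$sample_id[bad])
}

#' Filter samples by genotype missingness
#'
#' Removes samples missing genotypes at more than `max_missing_loci` loci —
#' the standard ancient-DNA retention rule (with the default of 1, a sample
#' on a 7-locus panel is kept only when genotyped at 6 or more loci).
#'
#' @param s a [sample_set].
#' @param max_missing_loci maximum tolerated number of missing loci
#'   (default 1).
#' @return the retained [sample_set]; attribute `"qc"` records `n_in`,
#'   `n_retained`, and `fraction_retained`. Idempotent.
#' @export
filter_missing <- function(s, max_missing_loci = 1L) {
  keep <- missing_loci(s) <= max_missing_loci
  out <- ss_subset(s, keep)
  if (n_samples(out) == 0L) warning("no samples survive the missingness filter")
  attr(out, "qc") <- list(n_in = n_samples(s), n_retained = sum(keep),
                          fraction_retained = sum(keep) / max(1L, n_samples(s)),
                          max_missing_loci = max_missing_loci)
  out
}

#' Per-collection, per-locus diversity statistics
#'
#' Observed heterozygosity Ho is the heterozygote fraction among called
#' genotypes. Expected heterozygosity He is unbiased gene diversity,
#' `(2n/(2n-1)) * (1 - sum(p_a^2))` with `p_a` the sample allele frequencies
#' among called genotypes (set `unbiased = FALSE` for the plug-in
#' `1 - sum(p_a^2)`). `Fis = 1 - Ho/He`, reported as `NA` where `He = 0`
#' (monomorphic cells).
#'
#' @param s a [sample_set].
#' @param group_by metadata column defining the cells, default `"collection"`.
#' @param unbiased apply the small-sample `2n/(2n-1)` correction to He.
#' @return data.frame with columns `collection, locus, n, Ho, He, Fis`.
#' @export
diversity <- function(s, group_by = "collection", unbiased = TRUE) {
  groups <- s$samples[[group_by]]
  dos <- dosage_matrix(s)
  het <- het_matrix(s)
  out <- list()
  for (g in unique(groups)) {
    idx <- groups == g
    n <- colSums(!is.na(dos[idx, , drop = FALSE]))
    nh <- colSums(het[idx, , drop = FALSE], na.rm = TRUE)
    p <- colSums(dos[idx, , drop = FALSE], na.rm = TRUE) / (2 * pmax(n, 1L))
    ho <- ifelse(n > 0, nh / n, NA_real_)
    he <- 1 - (p^2 + (1 - p)^2)
    if (unbiased) he <- ifelse(n > 0, (2 * n) / (2 * n - 1) * he, NA_real_)
    fis <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_)
    out[[g]] <- data.frame(collection = g, locus = s$loci, n = n,
                           Ho = ho, He = he, Fis = fis,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
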