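#' Construct a sample set
#'
#' A `sample_set` is the package's genotype container: per-sample metadata
#' plus two allele matrices for a shared panel of biallelic loci. Alleles are
#' panel-level labels `1` and `2` with no reference/alternate semantics.
#' A genotype is either two alleles or missing (both matrix cells `NA`);
#' within each cell pair the alleles are stored unordered (normalized so that
#' `a1 <= a2`).
#'
#' @param meta data.frame with columns `sample_id`, `role` (`"reference"` or
#'   `"mixture"`), `collection`, and `reporting_group` (may be `NA` for
#'   mixture samples). Reference samples must carry a reporting group;
#'   mixture samples must carry a collection (e.g. site + layer).
#' @param a1,a2 integer matrices (samples x loci) holding the two allele
#'   copies of each genotype; values in `{1, 2}` or `NA`. A genotype must be
#'   fully called or fully missing.
#' @param loci character vector of locus names; defaults to `colnames(a1)`.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(meta, a1, a2, loci = colnames(a1)) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "collection", "reporting_group")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0L) {
    stop("meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  meta <- meta[, need]
  for (cl in need) meta[[cl]] <- as.character(meta[[cl]])
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (is.null(loci)) stop("locus names are required")
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("duplicate locus names")
  if (!all(dim(a1) == dim(a2))) stop("allele matrices differ in shape")
  if (nrow(a1) != nrow(meta)) stop("allele matrices and meta disagree on sample count")
  if (ncol(a1) != length(loci)) stop("allele matrices and locus list disagree on locus count")

  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  if (!all(meta$role %in% c("reference", "mixture"))) {
    stop("role must be 'reference' or 'mixture'")
  }
  ref <- meta$role == "reference"
  if (any(ref & (is.na(meta$reporting_group) | meta$reporting_group == ""))) {
    stop("reference samples must carry a reporting_group")
  }
  if (any(!ref & (is.na(meta$collection) | meta$collection == ""))) {
    stop("mixture samples must carry a collection")
  }
  bad_allele <- !(is.na(a1) | a1 %in% c(1L, 2L)) | !(is.na(a2) | a2 %in% c(1L, 2L))
  if (any(bad_allele)) stop("allele label outside {1,2}")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop("half-called genotype: a cell must be fully called or fully missing")

  # normalize unordered pairs
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(meta$sample_id, loci)
  rownames(meta) <- NULL

  structure(list(samples = meta, loci = loci, a1 = a1, a2 = a2),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  tab <- table(x$samples$role)
  cat(sprintf("sample_set: %d samples (%s), %d loci\n",
              nrow(x$samples),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              length(x$loci)))
  cat("collections:", paste(unique(x$samples$collection), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / loci in a sample set
#' @param s a `sample_set`
#' @return integer count
#' @export
n_samples <- function(s) nrow(s$samples)

#' @rdname n_samples
#' @export
n_loci <- function(s) length(s$loci)

#' Per-sample count of missing loci
#' @param s a `sample_set`
#' @return named integer vector, one entry per sample
#' @export
missing_loci <- function(s) {
  rowSums(is.na(s$a1))
}

#' Subset a sample set by sample index
#'
#' @param s a `sample_set`
#' @param idx logical or integer index over samples
#' @return a `sample_set` restricted to the selected samples
#' @export
ss_subset <- function(s, idx) {
  sample_set(s$samples[idx, , drop = FALSE],
             s$a1[idx, , drop = FALSE],
             s$a2[idx, , drop = FALSE],
             loci = s$loci)
}

# allele-1 dosage matrix (0/1/2, NA when missing)
dosage_matrix <- function(s) {
  (s$a1 == 1L) + (s$a2 == 1L)
}

# heterozygote indicator matrix
het_matrix <- function(s) {
  s$a1 != s$a2
}
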