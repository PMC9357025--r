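#' Read a genotype table
#'
#' Two dialects are supported. The canonical *wide CSV* has one row per
#' sample and columns `sample_id, role, collection, reporting_group`,
#' followed by two columns per locus named `<locus>.1` and `<locus>.2`;
#' the missing token is an empty cell. The *genepop* dialect uses 2-digit
#' allele codes (`01`/`02`, `00` = missing, so `0000` is a missing genotype),
#' a comma after the sample name, and `POP` lines delimiting collections;
#' because genepop cannot encode roles or reporting groups, those travel in
#' a sidecar metadata CSV (`sample_id, role, collection, reporting_group`).
#'
#' @param path file to read.
#' @param format `"wide"` or `"genepop"`.
#' @param metadata for genepop: path of the sidecar metadata CSV. Defaults to
#'   `<path>.meta.csv` when that file exists. Without a sidecar, collections
#'   are named `pop1, pop2, ...` in POP order and all samples get role
#'   `"mixture"` (genepop alone cannot supply reporting groups, which
#'   reference samples require).
#' @param col_map optional named character vector remapping the metadata
#'   column names of a wide CSV, e.g.
#'   `c(sample_id = "ID", collection = "pop")`, for ingesting third-party
#'   layouts.
#' @return a validated [sample_set].
#' @export
read_genotypes <- function(path, format = c("wide", "genepop"),
                           metadata = NULL, col_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         wide = read_wide_csv(path, col_map),
         genepop = read_genepop(path, metadata))
}

read_wide_csv <- function(path, col_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = FALSE, fill = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      hit <- match(col_map[[canon]], names(df))
      if (is.na(hit)) stop("col_map: column not found: ", col_map[[canon]])
      names(df)[hit] <- canon
    }
  }
  meta_cols <- c("sample_id", "role", "collection", "reporting_group")
  if (!all(meta_cols %in% names(df))) {
    stop("malformed header: expected columns ",
         paste(meta_cols, collapse = ", "))
  }
  geno_cols <- setdiff(names(df), meta_cols)
  ok <- grepl("\\.[12]$", geno_cols)
  if (!all(ok)) stop("malformed header: genotype columns must end in .1/.2; offending: ",
                     paste(geno_cols[!ok], collapse = ", "))
  loci <- unique(sub("\\.[12]$", "", geno_cols))
  want <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  if (!setequal(geno_cols, want)) {
    stop("malformed header: each locus needs exactly a .1 and a .2 column")
  }

  parse_col <- function(v, colname) {
    v[is.na(v)] <- ""
    out <- rep(NA_integer_, length(v))
    called <- v != ""
    suppressWarnings(num <- as.integer(v[called]))
    if (any(is.na(num)) || !all(num %in% c(1L, 2L))) {
      stop("allele label outside {1,2} in column ", colname)
    }
    out[called] <- num
    out
  }
  a1 <- sapply(paste0(loci, ".1"), function(cl) parse_col(df[[cl]], cl))
  a2 <- sapply(paste0(loci, ".2"), function(cl) parse_col(df[[cl]], cl))
  if (nrow(df) == 1L) { a1 <- matrix(a1, nrow = 1); a2 <- matrix(a2, nrow = 1) }
  meta <- df[meta_cols]
  meta$reporting_group[meta$reporting_group == ""] <- NA_character_
  sample_set(meta, a1, a2, loci = loci)
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes()]; `read_genotypes(write_genotypes(s, ...))`
#' reproduces `s` exactly for both dialects.
#'
#' @param s a [sample_set].
#' @param path output file.
#' @param format `"wide"` or `"genepop"`.
#' @param metadata for genepop: where to write the sidecar metadata CSV
#'   (default `<path>.meta.csv`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(s, path, format = c("wide", "genepop"),
                            metadata = NULL) {
  format <- match.arg(format)
  if (format == "wide") {
    out <- s$samples
    for (j in seq_along(s$loci)) {
      c1 <- ifelse(is.na(s$a1[, j]), "", as.character(s$a1[, j]))
      c2 <- ifelse(is.na(s$a2[, j]), "", as.character(s$a2[, j]))
      out[[paste0(s$loci[j], ".1")]] <- c1
      out[[paste0(s$loci[j], ".2")]] <- c2
    }
    out$reporting_group[is.na(out$reporting_group)] <- ""
    write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    if (is.null(metadata)) metadata <- paste0(path, ".meta.csv")
    code <- function(a) ifelse(is.na(a), "00", sprintf("%02d", a))
    lines <- c("ancientmix genepop export", s$loci)
    for (coll in unique(s$samples$collection)) {
      lines <- c(lines, "POP")
      idx <- which(s$samples$collection == coll)
      for (i in idx) {
        gen <- paste0(code(s$a1[i, ]), code(s$a2[i, ]))
        lines <- c(lines, paste0(s$samples$sample_id[i], ", ",
                                 paste(gen, collapse = " ")))
      }
    }
    writeLines(lines, path)
    meta <- s$samples
    write.csv(meta, metadata, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

read_genepop <- function(path, metadata = NULL) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 3L) stop("malformed genepop file: too short")
  body <- lines[-1]  # drop title
  pop_idx <- which(toupper(trimws(body)) == "POP")
  if (length(pop_idx) == 0L) stop("malformed genepop file: no POP line")
  locus_lines <- body[seq_len(pop_idx[1] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  if (length(loci) == 0L) stop("malformed genepop file: no locus names")

  ids <- character(0); coll <- character(0)
  a1 <- NULL; a2 <- NULL
  pop_bounds <- c(pop_idx, length(body) + 1L)
  for (p in seq_along(pop_idx)) {
    rows <- body[seq(pop_bounds[p] + 1L, pop_bounds[p + 1L] - 1L)]
    if (pop_bounds[p] + 1L > pop_bounds[p + 1L] - 1L) next
    for (row in rows) {
      parts <- strsplit(row, ",", fixed = TRUE)[[1]]
      if (length(parts) < 2L) stop("malformed genepop row (no comma): ", row)
      id <- trimws(parts[1])
      gstr <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
      if (length(gstr) != length(loci)) {
        stop("locus count mismatch for sample ", id, ": expected ",
             length(loci), ", found ", length(gstr))
      }
      if (!all(nchar(gstr) == 4L & grepl("^[0-9]{4}$", gstr))) {
        stop("malformed genepop genotype code for sample ", id)
      }
      g1 <- as.integer(substr(gstr, 1, 2))
      g2 <- as.integer(substr(gstr, 3, 4))
      g1[g1 == 0L] <- NA_integer_; g2[g2 == 0L] <- NA_integer_
      if (any(!is.na(g1) & !(g1 %in% c(1L, 2L))) ||
          any(!is.na(g2) & !(g2 %in% c(1L, 2L)))) {
        stop("allele label outside {1,2} for sample ", id)
      }
      ids <- c(ids, id); coll <- c(coll, paste0("pop", p))
      a1 <- rbind(a1, g1); a2 <- rbind(a2, g2)
    }
  }
  colnames(a1) <- colnames(a2) <- loci

  default_meta <- paste0(path, ".meta.csv")
  if (is.null(metadata) && file.exists(default_meta)) metadata <- default_meta
  if (!is.null(metadata)) {
    md <- read.csv(metadata, stringsAsFactors = FALSE, colClasses = "character")
    hit <- match(ids, md$sample_id)
    if (anyNA(hit)) stop("sidecar metadata lacks sample(s): ",
                         paste(ids[is.na(hit)], collapse = ", "))
    # restore the sidecar's sample order (genepop groups rows by POP block)
    ord <- order(hit)
    ids <- ids[ord]
    a1 <- a1[ord, , drop = FALSE]; a2 <- a2[ord, , drop = FALSE]
    meta <- md[sort(hit), c("sample_id", "role", "collection", "reporting_group")]
    meta$reporting_group[meta$reporting_group == ""] <- NA_character_
  } else {
    meta <- data.frame(sample_id = ids, role = "mixture", collection = coll,
                       reporting_group = NA_character_,
                       stringsAsFactors = FALSE)
  }
  sample_set(meta, a1, a2, loci = loci)
}

#' Combine reference and mixture sample sets into one analysis set
#'
#' Validates that every set shares the reference panel's loci (order is
#' harmonized to the reference) and that the reference carries reporting
#' groups, then bundles everything for the downstream pipeline. Mixtures are
#' kept separate — each archaeological site/layer is always analyzed as its
#' own mixture, never pooled.
#'
#' @param reference a [sample_set] of reference (baseline) samples.
#' @param mixtures a named list of [sample_set]s, one per mixture
#'   (site + layer). May be empty for baseline-only workflows.
#' @return an object of class `analysis_set` with elements `reference`,
#'   `mixtures`, and `loci`.
#' @export
combine_sets <- function(reference, mixtures = list()) {
  stopifnot(inherits(reference, "sample_set"))
  if (any(reference$samples$role != "reference")) {
    stop("all samples in `reference` must have role 'reference'")
  }
  if (length(mixtures) > 0 && is.null(names(mixtures))) {
    names(mixtures) <- paste0("mixture", seq_along(mixtures))
  }
  mixtures <- lapply(mixtures, function(m) {
    stopifnot(inherits(m, "sample_set"))
    if (!setequal(m$loci, reference$loci)) {
      stop("locus panels differ between reference and a mixture set")
    }
    ord <- match(reference$loci, m$loci)
    sample_set(m$samples, m$a1[, ord, drop = FALSE], m$a2[, ord, drop = FALSE],
               loci = reference$loci)
  })
  structure(list(reference = reference, mixtures = mixtures,
                 loci = reference$loci),
            class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("analysis_set: %d loci; reference %d samples in %d collections\n",
              length(x$loci), n_samples(x$reference),
              length(unique(x$reference$samples$collection))))
  for (nm in names(x$mixtures)) {
    cat(sprintf("  mixture %-20s %d samples\n", nm, n_samples(x$mixtures[[nm]])))
  }
  invisible(x)
}
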