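#' Run the full mixed-stock analysis pipeline
#'
#' Orchestrates QC (replicate concordance when replicates are supplied,
#' missingness filtering of mixtures), per-layer diversity statistics,
#' pairwise F_ST with permutation tests, Hardy-Weinberg and
#' linkage-disequilibrium exact tests, PCA, mixture estimation per
#' archaeological layer (each layer always a separate mixture, never
#' pooled), and accuracy assessment (leave-one-out plus simulation) from a
#' single configuration, writing per-stage CSVs, a machine-readable
#' `summary.json`, and a log.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{simulate}{list(`preset`, `seed`) to generate synthetic inputs,
#'       or omit and supply `inputs`.}
#'     \item{inputs}{list(`reference`, `mixtures` = named paths, optional
#'       `format`, optional `replicates` = two paths).}
#'     \item{max_missing_loci}{QC filter tolerance (default 1).}
#'     \item{n_perm}{F_ST permutations (default 1000).}
#'     \item{alpha}{significance threshold for HWE/LD counting (default
#'       0.05).}
#'     \item{gsi}{list(`n_iter` = 10000, `burn_in` = 1000).}
#'     \item{assess}{list(`n` = 200, `reps` = 50).}
#'     \item{seed}{global seed; every stochastic stage derives its seed from
#'       it.}
#'   }
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and just returns the report.
#' @return the report, invisibly: a list mirroring `summary.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    max_missing_loci = 1L, n_perm = 1000L, alpha = 0.05,
    gsi = list(n_iter = 10000L, burn_in = 1000L),
    assess = list(n = 200L, reps = 50L),
    seed = 1L), config)
  seed <- as.integer(cfg$seed)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_csv <- function(df, file) {
    if (!is.null(out_dir)) write.csv(df, file.path(out_dir, file), row.names = FALSE)
  }

  ## stage: load or simulate -------------------------------------------------
  replicates <- NULL
  aset <- stage("input", {
    if (!is.null(cfg$simulate)) {
      scn <- make_scenario(divergence = cfg$simulate$preset %||% "herring",
                           seed = seed)
      ref <- sample_reference(scn, seed = seed + 1L)
      mixes <- list()
      for (i in seq_along(scn$mixtures)) {
        nm <- names(scn$mixtures)[i]
        mixes[[nm]] <- sample_mixture(scn, nm, seed = seed + 1L + i)$samples
      }
      note("simulated inputs: preset %s, %d reference samples, %d mixtures",
           cfg$simulate$preset %||% "herring", n_samples(ref), length(mixes))
      combine_sets(ref, mixes)
    } else {
      fmt <- cfg$inputs$format %||% "wide"
      ref <- read_genotypes(cfg$inputs$reference, format = fmt)
      mixes <- lapply(cfg$inputs$mixtures, read_genotypes, format = fmt)
      if (!is.null(cfg$inputs$replicates)) {
        replicates <- lapply(cfg$inputs$replicates, read_genotypes, format = fmt)
      }
      note("read inputs: %d reference samples, %d mixtures",
           n_samples(ref), length(mixes))
      combine_sets(ref, mixes)
    }
  })

  ## stage: qc ---------------------------------------------------------------
  qc_summary <- stage("qc", {
    disc <- NULL
    if (!is.null(replicates)) {
      disc <- discrepancy_rate(replicates[[1]], replicates[[2]])
      note("replicate discrepancy: %.4f per sample (%d/%d), %.4f per call",
           disc$per_sample, disc$n_mismatch_samples, disc$n_samples,
           disc$per_call)
    }
    n_in <- 0L; n_kept <- 0L
    for (nm in names(aset$mixtures)) {
      f <- filter_missing(aset$mixtures[[nm]], cfg$max_missing_loci)
      q <- attr(f, "qc")
      note("QC %s: retained %d/%d samples (%.1f%%)", nm, q$n_retained,
           q$n_in, 100 * q$fraction_retained)
      n_in <- n_in + q$n_in; n_kept <- n_kept + q$n_retained
      aset$mixtures[[nm]] <- f
    }
    list(discrepancy = disc,
         genotyping_success = if (n_in > 0) n_kept / n_in else NA_real_,
         n_mixture_in = n_in, n_mixture_retained = n_kept)
  })

  all_samples <- stage("merge", {
    meta <- rbind(aset$reference$samples,
                  do.call(rbind, lapply(aset$mixtures, function(m) m$samples)))
    a1 <- rbind(aset$reference$a1,
                do.call(rbind, lapply(aset$mixtures, function(m) m$a1)))
    a2 <- rbind(aset$reference$a2,
                do.call(rbind, lapply(aset$mixtures, function(m) m$a2)))
    sample_set(meta, a1, a2, loci = aset$loci)
  })
  mixture_names <- names(aset$mixtures)

  ## stage: diversity --------------------------------------------------------
  div <- stage("diversity", {
    d <- diversity(all_samples)
    save_csv(d, "diversity.csv")
    d
  })

  ## stage: fst --------------------------------------------------------------
  fst <- stage("fst", {
    set.seed(seed + 101L)
    f <- pairwise_fst(all_samples, n_perm = cfg$n_perm)
    save_csv(f, "fst_pairwise.csv")
    if (!is.null(out_dir)) {
      write.csv(attr(f, "theta_matrix"),
                file.path(out_dir, "fst_matrix.csv"))
    }
    f
  })

  ## stage: hwe / ld ---------------------------------------------------------
  hwe <- stage("hwe", {
    h <- hwe_test(all_samples)
    save_csv(h, "hwe.csv")
    h
  })
  ld <- stage("ld", {
    l <- ld_test(all_samples, seed = seed + 102L)
    save_csv(l, "ld.csv")
    l
  })

  ## stage: pca --------------------------------------------------------------
  pca <- stage("pca", {
    p <- pca_genotypes(all_samples)
    if (!is.null(out_dir)) {
      sc <- data.frame(sample_id = rownames(p$scores), p$meta[-1], p$scores)
      write.csv(sc, file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    }
    p
  })

  ## stage: gsi --------------------------------------------------------------
  gsi_res <- stage("gsi", {
    baseline <- build_baseline(aset$reference)
    out <- list()
    for (i in seq_along(aset$mixtures)) {
      nm <- mixture_names[i]
      fit <- infer_mixture(baseline, aset$mixtures[[nm]],
                           n_iter = cfg$gsi$n_iter, burn_in = cfg$gsi$burn_in,
                           seed = seed + 200L + i)
      sm <- summary(fit)
      note("GSI %s: %s", nm,
           paste(sprintf("%s %.3f [%.3f, %.3f]", sm$unit, sm$mean, sm$lo, sm$hi),
                 collapse = "; "))
      out[[nm]] <- list(fit = fit, summary = sm)
      save_csv(cbind(mixture = nm, sm), paste0("mixture_", nm, ".csv"))
      save_csv(cbind(mixture = nm, summary(fit, level = "collection")),
               paste0("mixture_", nm, "_collections.csv"))
    }
    out
  })

  ## stage: assess -----------------------------------------------------------
  assess_res <- stage("assess", {
    loo <- loo_self_assign(aset$reference)
    baseline <- build_baseline(aset$reference)
    sim <- simulate_assess(baseline, n = cfg$assess$n, reps = cfg$assess$reps,
                           seed = seed + 301L)
    save_csv(loo$per_group, "assess_loo.csv")
    save_csv(sim$per_group, "assess_sim.csv")
    note("accuracy: LOO %s; simulated %s",
         paste(sprintf("%s %.3f", loo$per_group$group, loo$per_group$accuracy),
               collapse = ", "),
         paste(sprintf("%s %.3f", sim$per_group$group, sim$per_group$accuracy),
               collapse = ", "))
    list(loo = loo, sim = sim)
  })

  ## report ------------------------------------------------------------------
  report <- list(
    config = cfg,
    qc = list(genotyping_success = qc_summary$genotyping_success,
              n_mixture_in = qc_summary$n_mixture_in,
              n_mixture_retained = qc_summary$n_mixture_retained,
              discrepancy_per_sample = if (!is.null(qc_summary$discrepancy))
                qc_summary$discrepancy$per_sample else NULL),
    fst = list(min = min(fst$theta, na.rm = TRUE),
               max = max(fst$theta, na.rm = TRUE),
               n_pairs = nrow(fst)),
    hwe = list(
      n_tests = nrow(hwe),
      significant_by_collection = as.list(
        tapply(hwe$p_value < cfg$alpha, hwe$collection, sum))),
    ld = list(n_tests = nrow(ld),
              n_significant = sum(ld$p_value < cfg$alpha),
              n_significant_bonferroni = sum(ld$p_value < cfg$alpha / nrow(ld))),
    pca = list(explained = as.numeric(pca$explained[seq_len(min(4, length(pca$explained)))])),
    mixtures = lapply(gsi_res, function(g) {
      sm <- g$summary
      setNames(lapply(seq_len(nrow(sm)), function(i)
        list(mean = sm$mean[i], lo = sm$lo[i], hi = sm$hi[i])), sm$unit)
    }),
    assessment = list(
      loo = setNames(as.list(assess_res$loo$per_group$accuracy),
                     assess_res$loo$per_group$group),
      simulated = setNames(as.list(assess_res$sim$per_group$accuracy),
                           assess_res$sim$per_group$group)))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
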