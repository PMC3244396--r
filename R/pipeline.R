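# End-to-end orchestration: simulate (or load) -> latent class analysis ->
# per-class genome-wide association, with report tables mirroring the
# demographic, class-profile, burden, top-hit and genotype-summary views
# of the analysis.

#' Configure an end-to-end pipeline run
#'
#' Exactly one of `cohort_spec` (simulate) or `input_dir` (load a cohort
#' previously written by [write_cohort()]) must be given.
#'
#' @param cohort_spec A [cohort_spec()] for simulated input, or `NULL`.
#' @param input_dir Directory of a written cohort, or `NULL`.
#' @param genotype_format Genotype file format inside `input_dir`.
#' @param K_max Largest class count tried during model selection.
#' @param n_starts Random EM starts per fit.
#' @param anchor_item Item anchoring the canonical class order.
#' @param phenotype_definition `"posterior_probability"` or
#'   `"modal_indicator"`.
#' @param models Genetic models to test.
#' @param K_pc Principal components for stratification correction.
#' @param maf_threshold MAF filter threshold.
#' @param alpha Bonferroni screen level for permutation retesting.
#' @param B Permutations for retested hits.
#' @param burden_items Items counted in the comorbidity burden table
#'   (`NULL` = all).
#' @param seed Master seed for every stage.
#' @param output_dir Where [write_results()] puts tables (`NULL` = don't
#'   write automatically).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_spec = NULL, input_dir = NULL,
                            genotype_format = "tsv",
                            K_max = 5, n_starts = 50,
                            anchor_item = "ALCDEP",
                            phenotype_definition = "posterior_probability",
                            models = c("dominant", "additive", "recessive"),
                            K_pc = 10, maf_threshold = 0.001, alpha = 0.05,
                            B = 1000, burden_items = NULL, seed = 1L,
                            output_dir = NULL) {
  if (is.null(cohort_spec) == is.null(input_dir))
    stop("give exactly one of `cohort_spec` or `input_dir`", call. = FALSE)
  structure(list(cohort_spec = cohort_spec, input_dir = input_dir,
                 genotype_format = genotype_format,
                 K_max = K_max, n_starts = n_starts,
                 anchor_item = anchor_item,
                 phenotype_definition = phenotype_definition,
                 models = models, K_pc = K_pc,
                 maf_threshold = maf_threshold, alpha = alpha, B = B,
                 burden_items = burden_items,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "output_dir")])
}

stamp <- function(tbl, seed, hash) {
  attr(tbl, "seed") <- seed
  attr(tbl, "config_hash") <- hash
  tbl
}

load_cohort <- function(dir, genotype_format) {
  ind <- read_indicators(file.path(dir, "indicators.tsv"))
  aux <- readr::read_tsv(file.path(dir, "covariates.tsv"),
                         col_types = readr::cols(), na = c("", "NA"),
                         progress = FALSE)
  gpath <- switch(genotype_format,
                  pedmap = file.path(dir, "genotypes"),
                  vcf = file.path(dir, "genotypes.vcf"),
                  tsv = file.path(dir, "genotypes.tsv"))
  geno <- read_genotypes(gpath, genotype_format)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- NULL
  case_flags <- NULL
  if (file.exists(truth_path)) {
    tt <- readr::read_tsv(truth_path, col_types = readr::cols(),
                          na = c("", "NA"), progress = FALSE)
    case_flags <- as.integer(tt$is_case)
    truth <- list(true_class = tt$true_class[tt$is_case],
                  planted_snps = tibble::tibble(),
                  subpopulation = if (all(is.na(tt$subpopulation))) NULL
                                  else tt$subpopulation)
  } else {
    case_flags <- as.integer(geno$sample_ids %in% ind$case_id)
  }
  structure(list(indicators = ind, genotypes = geno, case_flags = case_flags,
                 aux = aux, truth = truth),
            class = "lc_cohort")
}

#' Run the full pipeline
#'
#' Simulates or loads a cohort, fits latent class models for
#' `K = 1 .. K_max` selecting by BIC, and runs one genome-wide association
#' per latent class using that class's membership probability as
#' phenotype (all classes are tested). With `K_max = 1` the phenotype
#' degenerates to plain case/control status, so the run reduces to an
#' ordinary case-control association scan. Deterministic under the
#' config's seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `report_bundle`: `demographics`, `endorsement`
#'   (class-profile probabilities), `profile_or` (pairwise class-profile
#'   odds ratios), `burden`, `top_hits`, `genotype_summaries`,
#'   `model_selection` (BIC/entropy by K), `association` (per-class
#'   `assoc_result`), `qq`, plus the `lca_selection`, chosen fit, cohort
#'   and config. Every table carries the seed and config hash as
#'   attributes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  seeds <- sub_seeds(config$seed, 3L)

  cohort <- if (!is.null(config$cohort_spec)) {
    simulate_cohort(config$cohort_spec)
  } else {
    load_cohort(config$input_dir, config$genotype_format)
  }

  sel <- lca_select(cohort$indicators, K_max = config$K_max,
                    n_starts = config$n_starts, seed = seeds[1],
                    anchor_item = config$anchor_item)
  fit <- attr(sel, "fits")[[attr(sel, "chosen_K")]]
  assign_modal <- modal_assignment(fit$posteriors)

  # demographic table: per-class size, age, sex
  aux_cases <- cohort$aux[cohort$case_flags == 1L, , drop = FALSE]
  demographics <- tibble::tibble(class = seq_len(fit$K)) |>
    dplyr::rowwise() |>
    dplyr::mutate(n = sum(assign_modal == .data$class),
                  share = .data$n / fit$n,
                  age_mean = mean(aux_cases$age[assign_modal == .data$class],
                                  na.rm = TRUE),
                  age_sd = stats::sd(aux_cases$age[assign_modal == .data$class],
                                     na.rm = TRUE),
                  female_share = mean(aux_cases$female[assign_modal == .data$class],
                                      na.rm = TRUE)) |>
    dplyr::ungroup()

  endorsement <- tibble::as_tibble(t(fit$model$rho), rownames = "item")

  profile_or <- if (fit$K >= 2) {
    pairs <- utils::combn(fit$K, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(kl)
      dplyr::mutate(profile_odds_ratios(fit, kl[1], kl[2]),
                    class_k = kl[1], class_l = kl[2], .before = 1))
  } else {
    tibble::tibble()
  }

  burden <- comorbidity_burden(cohort$indicators, assign_modal,
                               burden_items = config$burden_items)

  assoc <- list()
  gsum <- list()
  assoc_seeds <- sub_seeds(seeds[2], fit$K)
  for (k in seq_len(fit$K)) {
    ph <- membership_phenotype(fit, cohort$case_flags, k,
                               config$phenotype_definition)
    ar <- run_association(cohort$genotypes, ph, models = config$models,
                          K_pc = config$K_pc,
                          maf_threshold = config$maf_threshold,
                          alpha = config$alpha, B = config$B,
                          seed = assoc_seeds[k])
    assoc[[k]] <- ar
    top <- dplyr::slice_head(ar, n = 10)
    gsum[[k]] <- purrr::map_dfr(unique(top$snp_id), function(s) {
      m <- match(s, cohort$genotypes$snp_info$snp_id)
      dplyr::mutate(genotype_summary(cohort$genotypes$counts[, m], ph,
                                     snp_id = s),
                    class = k, .before = 1)
    })
  }

  top_hits <- purrr::imap_dfr(assoc, function(ar, k)
    dplyr::mutate(dplyr::slice_head(tibble::as_tibble(ar), n = 5),
                  class = k, .before = 1))
  qq <- purrr::imap_dfr(assoc, function(ar, k)
    purrr::imap_dfr(attr(ar, "qq"), function(tbl, mod)
      dplyr::mutate(tbl, class = k, model = mod, .before = 1)))

  bundle <- list(demographics = stamp(demographics, config$seed, hash),
                 endorsement = stamp(endorsement, config$seed, hash),
                 profile_or = stamp(profile_or, config$seed, hash),
                 burden = stamp(burden, config$seed, hash),
                 top_hits = stamp(top_hits, config$seed, hash),
                 genotype_summaries = stamp(dplyr::bind_rows(gsum),
                                            config$seed, hash),
                 model_selection = stamp(tibble::as_tibble(sel),
                                         config$seed, hash),
                 qq = stamp(qq, config$seed, hash),
                 association = assoc,
                 selection = sel, fit = fit, cohort = cohort,
                 config = config, config_hash = hash)
  class(bundle) <- "report_bundle"
  if (!is.null(config$output_dir)) write_results(bundle, config$output_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> K = %d classes chosen (BIC), %d cases, %d SNPs\n",
              x$fit$K, x$fit$n, ncol(x$cohort$genotypes$counts)))
  cat(sprintf("  seed %d | config %s\n", x$config$seed, x$config_hash))
  invisible(x)
}

#' Write a report bundle to TSV files
#'
#' Each table is written with comment header lines recording the seed and
#' config hash that produced it, plus a JSON-lines run log.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("demographics", "endorsement", "profile_or", "burden",
              "top_hits", "genotype_summaries", "model_selection", "qq")
  for (nm in tables) {
    tbl <- bundle[[nm]]
    path <- file.path(dir, paste0(nm, ".tsv"))
    hdr <- c(sprintf("# seed=%d", attr(tbl, "seed")),
             sprintf("# config_hash=%s", attr(tbl, "config_hash")))
    writeLines(hdr, path)
    suppressWarnings(
      utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
  }
  for (k in seq_along(bundle$association)) {
    readr::write_tsv(tibble::as_tibble(bundle$association[[k]]),
                     file.path(dir, sprintf("association_class%d.tsv", k)))
  }
  log <- c(
    sprintf('{"stage":"config","seed":%d,"hash":"%s"}',
            bundle$config$seed, bundle$config_hash),
    sprintf('{"stage":"lca","chosen_K":%d,"bic":%.6f,"entropy":%s}',
            bundle$fit$K, bundle$fit$bic,
            ifelse(is.na(bundle$fit$entropy), "null",
                   sprintf("%.6f", bundle$fit$entropy))),
    sprintf('{"stage":"association","classes":%d,"snps":%d}',
            length(bundle$association),
            ncol(bundle$cohort$genotypes$counts)))
  writeLines(log, file.path(dir, "run_log.jsonl"))
  invisible(dir)
}
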