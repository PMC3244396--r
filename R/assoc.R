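# Genome-wide association of SNPs with a quantitative phenotype (latent
# class membership probability) under dominant / additive / recessive
# encodings, with optional principal-component stratification correction.

#' Build a class-membership phenotype vector
#'
#' Maps a fitted latent class model onto the full case/control sample:
#' cases receive their membership value for `target_class` (posterior
#' probability, or a 0/1 modal indicator), controls are fixed at 0. With a
#' 1-class fit the phenotype degenerates to plain case/control status.
#'
#' @param fit An `lca_fit` on the cases.
#' @param case_flags 0/1 vector over all individuals, cases first, in the
#'   genotype sample order.
#' @param target_class Class whose membership is the phenotype.
#' @param definition `"posterior_probability"` (default) or
#'   `"modal_indicator"`.
#' @return Numeric vector in `[0, 1]`, one value per individual.
#' @export
membership_phenotype <- function(fit, case_flags, target_class = 1L,
                                 definition = c("posterior_probability",
                                                "modal_indicator")) {
  definition <- match.arg(definition)
  stopifnot(inherits(fit, "lca_fit"), target_class >= 1, target_class <= fit$K)
  n_cases <- nrow(fit$posteriors)
  if (sum(case_flags == 1L) != n_cases)
    stop("`case_flags` does not match the number of fitted cases", call. = FALSE)
  vals <- switch(definition,
    posterior_probability = fit$posteriors[, target_class],
    modal_indicator = as.numeric(modal_assignment(fit$posteriors) == target_class))
  out <- numeric(length(case_flags))
  out[case_flags == 1L] <- vals
  out
}

#' Correlation trend test
#'
#' Pearson correlation `r` between the model-encoded genotype and the
#' phenotype over complete pairs, referred to chi-square:
#' `T = n r^2` on 1 degree of freedom. A SNP whose encoding is constant on
#' the complete pairs (for instance zero minor-allele homozygotes under the
#' recessive model) is not testable and is flagged rather than given a
#' spurious p-value.
#'
#' @param encoded Encoded genotype vector (see [encode_model()]).
#' @param phenotype Numeric phenotype vector, same length.
#' @return Tibble: `statistic`, `p`, `r`, `n_used`, `testable`.
#' @export
trend_test <- function(encoded, phenotype) {
  ok <- !is.na(encoded) & !is.na(phenotype)
  x <- encoded[ok]; y <- phenotype[ok]
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(statistic = NA_real_, p = NA_real_, r = NA_real_,
                          n_used = n, testable = FALSE))
  }
  r <- stats::cor(x, y)
  stat <- n * r^2
  tibble::tibble(statistic = stat,
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 r = r, n_used = n, testable = TRUE)
}

#' EIGENSTRAT-style principal components of a genotype panel
#'
#' Standardizes each SNP by centering at twice its allele frequency and
#' scaling by `sqrt(2 p (1 - p))`, sets missing entries to 0 after
#' centering, and returns the leading eigenvectors of the sample covariance
#' as per-individual scores. Monomorphic SNPs are skipped and logged.
#'
#' @param genotypes A [genotype_matrix()] or dosage matrix.
#' @param n_components Number of components to return.
#' @return List: `scores` (N x n_components), `eigenvalues`,
#'   `skipped_snps` (ids of monomorphic SNPs).
#' @export
pca_components <- function(genotypes, n_components = 10) {
  g <- if (inherits(genotypes, "genotype_matrix")) genotypes$counts
       else as.matrix(genotypes)
  ids <- if (inherits(genotypes, "genotype_matrix")) genotypes$snp_info$snp_id
         else colnames(g) %||% as.character(seq_len(ncol(g)))
  N <- nrow(g)
  if (n_components >= N)
    stop("`n_components` must be smaller than the number of individuals",
         call. = FALSE)
  p <- colMeans(g, na.rm = TRUE) / 2
  mono <- is.na(p) | p <= 0 | p >= 1
  X <- g[, !mono, drop = FALSE]
  p <- p[!mono]
  X <- sweep(X, 2L, 2 * p)
  X[is.na(X)] <- 0
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), `/`)
  # eigenvectors of the individual x individual covariance via tcrossprod
  C <- tcrossprod(X) / ncol(X)
  e <- eigen(C, symmetric = TRUE)
  k <- seq_len(n_components)
  scores <- e$vectors[, k, drop = FALSE]
  rownames(scores) <- rownames(g)
  list(scores = scores,
       eigenvalues = e$values[k],
       skipped_snps = ids[mono])
}

#' Stratification-corrected trend test
#'
#' Residualizes both the encoded genotype and the phenotype on the
#' principal-component scores (least squares with an intercept) and
#' correlates the residuals: `T = (n - K_pc - 1) r^2` on 1 df. With zero
#' components this reduces to the plain trend test up to the `n` versus
#' `n - 1` degrees-of-freedom factor.
#'
#' @inheritParams trend_test
#' @param scores N x K_pc matrix of component scores (or `NULL` / zero
#'   columns for no correction).
#' @return Tibble as [trend_test()].
#' @export
stratification_adjust <- function(encoded, phenotype, scores = NULL) {
  k_pc <- if (is.null(scores)) 0L else ncol(scores)
  ok <- !is.na(encoded) & !is.na(phenotype)
  x <- encoded[ok]; y <- phenotype[ok]
  n <- length(x)
  if (n < k_pc + 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(statistic = NA_real_, p = NA_real_, r = NA_real_,
                          n_used = n, testable = FALSE))
  }
  if (k_pc > 0) {
    Z <- cbind(1, scores[ok, , drop = FALSE])
    qz <- qr(Z)
    x <- qr.resid(qz, x)
    y <- qr.resid(qz, y)
  } else {
    x <- x - mean(x); y <- y - mean(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(statistic = NA_real_, p = NA_real_, r = NA_real_,
                          n_used = n, testable = FALSE))
  }
  r <- stats::cor(x, y)
  stat <- (n - k_pc - 1) * r^2
  tibble::tibble(statistic = stat,
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 r = r, n_used = n, testable = TRUE)
}

# vectorized stratification_adjust over the columns of an encoded genotype
# matrix: SNPs with complete calls share one QR projection; SNPs with
# missing calls fall back to the per-SNP pairwise-deletion path
batch_adjusted_tests <- function(E, phenotype, scores = NULL) {
  M <- ncol(E); N <- nrow(E)
  k_pc <- if (is.null(scores)) 0L else ncol(scores)
  out_stat <- out_p <- out_r <- rep(NA_real_, M)
  out_n <- integer(M); out_test <- logical(M)
  complete <- !col_any_na(E) & !anyNA(phenotype)
  if (any(complete)) {
    Z <- if (k_pc > 0) cbind(1, scores) else matrix(1, N, 1)
    qz <- qr(Z)
    Xr <- qr.resid(qz, E[, complete, drop = FALSE])
    yr <- qr.resid(qz, phenotype)
    ssx <- colSums(Xr^2); ssy <- sum(yr^2)
    ok <- ssx > N * .Machine$double.eps & ssy > N * .Machine$double.eps
    r <- rep(NA_real_, sum(complete))
    r[ok] <- as.vector(crossprod(Xr[, ok, drop = FALSE], yr)) /
      sqrt(ssx[ok] * ssy)
    stat <- (N - k_pc - 1) * r^2
    idx <- which(complete)
    out_stat[idx] <- stat
    out_p[idx] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    out_r[idx] <- r
    out_n[idx] <- N
    out_test[idx] <- ok
  }
  for (m in which(!complete)) {
    res <- stratification_adjust(E[, m], phenotype, scores)
    out_stat[m] <- res$statistic; out_p[m] <- res$p; out_r[m] <- res$r
    out_n[m] <- res$n_used; out_test[m] <- res$testable
  }
  tibble::tibble(statistic = out_stat, p = out_p, r = out_r,
                 n_used = out_n, testable = out_test)
}

col_any_na <- function(m) colSums(is.na(m)) > 0L

#' Permutation p-value for one SNP
#'
#' Permutes the phenotype vector `B` times with genotypes fixed (case and
#' control labels travel with the phenotype, which encodes them) and counts
#' permuted statistics at least as large as the observed one:
#' `p = (1 + #{T_perm >= T_obs}) / (B + 1)`.
#'
#' @inheritParams trend_test
#' @param B Number of permutations.
#' @param seed Seed for the permutation stream.
#' @param scores Optional component scores passed through to the adjusted
#'   test.
#' @return Permutation p-value, or `NA` for a not-testable SNP.
#' @export
permutation_p <- function(encoded, phenotype, B = 1000, seed = 1L,
                          scores = NULL) {
  obs <- stratification_adjust(encoded, phenotype, scores)
  if (!obs$testable) return(NA_real_)
  t_obs <- obs$statistic
  t_perm <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      perm <- sample(phenotype)
      res <- stratification_adjust(encoded, perm, scores)
      if (res$testable) res$statistic else -Inf
    }, numeric(1))
  })
  (1 + sum(t_perm >= t_obs - 1e-12)) / (B + 1)
}

#' Bonferroni adjustment
#'
#' @param p P-value(s).
#' @param n_tests Number of tests performed.
#' @return `min(1, p * n_tests)`, vectorized.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  stopifnot(n_tests >= 1)
  pmin(1, p * n_tests)
}

#' Per-genotype phenotype summary for one SNP
#'
#' Group sizes and dependent mean phenotype for minor-allele homozygotes
#' (DD), heterozygotes (Dd) and major-allele homozygotes (dd), plus the
#' MAF.
#'
#' @param g Dosage vector at one SNP.
#' @param phenotype Phenotype vector, same length.
#' @param snp_id Optional identifier carried into the output.
#' @return One-row tibble: `snp_id`, `maf`, `mean_DD`, `mean_Dd`,
#'   `mean_dd`, `n_DD`, `n_Dd`, `n_dd`.
#' @export
genotype_summary <- function(g, phenotype, snp_id = NA_character_) {
  ok <- !is.na(g)
  gg <- g[ok]; ph <- phenotype[ok]
  grp_mean <- function(d) if (any(gg == d)) mean(ph[gg == d], na.rm = TRUE) else NA_real_
  tibble::tibble(snp_id = snp_id,
                 maf = compute_maf(gg),
                 mean_DD = grp_mean(2L), mean_Dd = grp_mean(1L),
                 mean_dd = grp_mean(0L),
                 n_DD = sum(gg == 2L), n_Dd = sum(gg == 1L),
                 n_dd = sum(gg == 0L))
}

#' Carrier odds ratio from two binary vectors
#'
#' Cross-product ratio of the 2x2 table of carrier status against an
#' outcome flag, with the Haldane-Anscombe 0.5 continuity correction
#' applied to every cell whenever any cell is zero.
#'
#' @param carrier Binary (0/1 or logical) carrier flag.
#' @param outcome Binary outcome flag, same length.
#' @return The odds ratio (single number).
#' @export
carrier_odds_ratio <- function(carrier, outcome) {
  ok <- !is.na(carrier) & !is.na(outcome)
  carrier <- as.integer(as.logical(carrier[ok]))
  outcome <- as.integer(as.logical(outcome[ok]))
  a <- sum(carrier == 1 & outcome == 1)
  b <- sum(carrier == 1 & outcome == 0)
  c_ <- sum(carrier == 0 & outcome == 1)
  d <- sum(carrier == 0 & outcome == 0)
  if (min(a, b, c_, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c_)
}

#' Q-Q data and genomic inflation factor
#'
#' Sorted observed versus expected `-log10` p-values under the uniform
#' null, and the genomic inflation factor: the median observed 1-df
#' chi-square statistic divided by the null median.
#'
#' @param p_values Vector of p-values (`NA` dropped).
#' @return List: `qq` (tibble `expected`, `observed` on the `-log10`
#'   scale) and `lambda`.
#' @export
qq_lambda <- function(p_values) {
  p <- sort(p_values[!is.na(p_values)])
  if (!length(p)) stop("no testable p-values", call. = FALSE)
  n <- length(p)
  qq <- tibble::tibble(expected = -log10((seq_len(n) - 0.5) / n),
                       observed = -log10(pmax(p, .Machine$double.xmin)))
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  list(qq = qq, lambda = stats::median(chi) / stats::qchisq(0.5, df = 1))
}

#' Genome-wide association with latent-class membership as phenotype
#'
#' Orients SNPs to the minor allele, applies the MAF filter, computes
#' principal components when `K_pc > 0`, tests every surviving SNP under
#' each requested genetic model with the (stratification-adjusted)
#' correlation trend test, Bonferroni-corrects per model over the testable
#' SNPs of that model, and computes permutation p-values only for SNPs
#' whose Bonferroni-corrected p passes `alpha` (significant hits are
#' retested by permutation).
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype Numeric phenotype vector, one value per individual
#'   (see [membership_phenotype()]).
#' @param models Genetic models to test.
#' @param K_pc Number of principal components for stratification
#'   correction; 0 disables correction.
#' @param maf_threshold MAF filter threshold (strict `<` removal).
#' @param alpha Significance level for the Bonferroni screen that triggers
#'   permutation retesting.
#' @param B Number of permutations for retested SNPs; 0 disables the
#'   permutation stage.
#' @param seed Seed for permutations.
#' @param hwe_threshold Optional post-hoc Hardy-Weinberg exact-test filter;
#'   `NULL` (default) disables it.
#' @return Tibble of class `assoc_result`, one row per testable SNP x
#'   model, sorted by p: `snp_id`, `chromosome`, `position`, `model`,
#'   `maf`, `statistic`, `p`, `bonferroni_p`, `permutation_p`, `n_used`,
#'   `testable`. Attributes: `removal_log`, `n_tests` (per model),
#'   `lambda` (per model), `qq` (per-model Q-Q tibble), `scores`.
#' @export
run_association <- function(genotypes, phenotype,
                            models = c("dominant", "additive", "recessive"),
                            K_pc = 10, maf_threshold = 0.001, alpha = 0.05,
                            B = 1000, seed = 1L, hwe_threshold = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  models <- match.arg(models, several.ok = TRUE)
  if (length(phenotype) != nrow(genotypes$counts))
    stop("phenotype length must match the number of individuals", call. = FALSE)

  genotypes <- orient_minor(genotypes)
  flt <- maf_filter(genotypes, maf_threshold)
  removal_log <- flt$log
  g <- flt$genotypes
  if (ncol(g$counts) == 0L)
    stop("no SNPs survive the MAF filter", call. = FALSE)

  if (!is.null(hwe_threshold)) {
    hwe_p <- apply(g$counts, 2L, function(col) hwe_exact_test(col))
    keep <- hwe_p >= hwe_threshold
    removal_log <- dplyr::mutate(removal_log,
      kept = .data$kept & .data$snp_id %in% g$snp_info$snp_id[keep])
    g <- genotype_matrix(g$counts[, keep, drop = FALSE],
                         g$snp_info[keep, , drop = FALSE], g$sample_ids)
  }

  scores <- NULL
  if (K_pc > 0) scores <- pca_components(g, K_pc)$scores

  maf <- apply(g$counts, 2L, compute_maf)
  res <- purrr::map_dfr(models, function(mod) {
    E <- switch(mod,
                additive  = g$counts + 0,
                dominant  = (g$counts >= 1L) + 0,
                recessive = (g$counts == 2L) + 0)
    tests <- batch_adjusted_tests(E, phenotype, scores)
    dplyr::bind_cols(g$snp_info, tibble::tibble(model = mod, maf = maf), tests)
  })

  n_tests <- res |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(n_tests = sum(.data$testable), .groups = "drop")
  res <- res |>
    dplyr::left_join(n_tests, by = "model") |>
    dplyr::mutate(bonferroni_p = ifelse(.data$testable,
                                        bonferroni_adjust(.data$p, .data$n_tests),
                                        NA_real_))

  res$permutation_p <- NA_real_
  hits <- if (B >= 1) which(!is.na(res$bonferroni_p) & res$bonferroni_p <= alpha)
          else integer(0)
  if (length(hits)) {
    perm_seeds <- sub_seeds(seed, length(hits))
    for (i in seq_along(hits)) {
      row <- res[hits[i], ]
      m <- match(row$snp_id, g$snp_info$snp_id)
      enc <- encode_model(g$counts[, m], row$model)
      res$permutation_p[hits[i]] <-
        permutation_p(enc, phenotype, B = B, seed = perm_seeds[i],
                      scores = scores)
    }
  }

  res <- dplyr::arrange(res, !.data$testable, .data$p)
  lam <- lapply(split(res$p[res$testable], res$model[res$testable]), qq_lambda)
  structure(res,
            removal_log = removal_log,
            n_tests = n_tests,
            lambda = vapply(lam, `[[`, numeric(1), "lambda"),
            qq = lapply(lam, `[[`, "qq"),
            scores = scores,
            class = c("assoc_result", class(res)))
}
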