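# Fixtures and independent oracles used across the suite. Everything is
# generated in code; nothing is read from disk.

# indicator matrix emulating the study conditions: defaults of cohort_spec()
sim_indicators <- function(n_cases = 1000, seed = 1) {
  simulate_cohort(cohort_spec(n_cases = n_cases, n_controls = 0,
                              n_null_snps = 1, seed = seed))$indicators
}

# brute-force mixture log-likelihood: direct double loop over cases and
# classes, no shared code with the package implementation
brute_loglik <- function(U, pi, rho) {
  total <- 0
  for (i in seq_len(nrow(U))) {
    li <- 0
    for (k in seq_along(pi)) {
      term <- pi[k]
      for (j in seq_len(ncol(U))) {
        u <- U[i, j]
        if (is.na(u)) next
        term <- term * if (u == 1) rho[k, j] else 1 - rho[k, j]
      }
      li <- li + term
    }
    total <- total + log(li)
  }
  total
}

# iteratively refined grid search over (pi, rho) for a K = 2, J <= 3 binary
# mixture; independent of the EM code path. Returns the maximum
# log-likelihood found at a final per-axis resolution below 0.01.
grid_loglik_max <- function(U) {
  stopifnot(ncol(U) <= 3, !anyNA(U))
  J <- ncol(U)
  pat <- unique(U)
  cnt <- apply(pat, 1L, function(p) sum(colSums(t(U) == p) == J))
  eval_candidates <- function(TH) {
    # TH: ncand x (1 + 2J): pi, rho1 (J), rho2 (J)
    pi <- TH[, 1]
    r1 <- TH[, 1 + seq_len(J), drop = FALSE]
    r2 <- TH[, 1 + J + seq_len(J), drop = FALSE]
    f_class <- function(r) {
      lf <- pat %*% t(log(r)) + (1 - pat) %*% t(log(1 - r))  # npat x ncand
      exp(lf)
    }
    f1 <- f_class(r1); f2 <- f_class(r2)
    mix <- sweep(f1, 2L, pi, `*`) + sweep(f2, 2L, 1 - pi, `*`)
    as.vector(cnt %*% log(mix))
  }
  # same constraint box the model's EM uses for rho
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  axes <- rep(list(seq(0.1, 0.9, by = 0.2)), 1 + 2 * J)
  TH <- as.matrix(expand.grid(axes))
  ll <- eval_candidates(TH)
  center <- TH[which.max(ll), ]
  best <- max(ll)
  radius <- 0.1
  while (radius > 0.001) {
    repeat {  # re-center at this resolution until no further improvement
      axes <- lapply(center, function(c0)
        clamp(c0 + radius * c(-1, -0.5, 0, 0.5, 1)))
      TH <- as.matrix(expand.grid(axes))
      ll <- eval_candidates(TH)
      if (max(ll) <= best + 1e-12) break
      best <- max(ll)
      center <- TH[which.max(ll), ]
    }
    radius <- radius / 2
  }
  best
}

# direct K-sample Wald test on observed groups (oracle for the degenerate
# one-hot pseudo-class case)
direct_wald <- function(x, groups, n_draws = 20) {
  ks <- sort(unique(groups))
  m <- vapply(ks, function(k) mean(x[groups == k], na.rm = TRUE), numeric(1))
  v <- vapply(ks, function(k) {
    xi <- x[groups == k & !is.na(x)]
    stats::var(xi) / length(xi)
  }, numeric(1))
  w <- 1 / v
  mu <- sum(w * m) / sum(w)
  stat <- sum(w * (m - mu)^2)
  list(statistic = stat, df = length(ks) - 1,
       p_value = stats::pchisq(stat, length(ks) - 1, lower.tail = FALSE))
}

# Hardy-Weinberg genotype draw used as a null SNP fixture
hw_genotypes <- function(n, maf, seed) {
  with_seed_local(seed, stats::rbinom(n, 2L, maf))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# small genotype_matrix fixture with known MAFs
toy_panel <- function(n = 40, mafs = c(0.1, 0.3, 0.5), seed = 42) {
  counts <- with_seed_local(seed,
    vapply(mafs, function(p) stats::rbinom(n, 2L, p), integer(n)))
  genotype_matrix(counts,
                  tibble::tibble(snp_id = paste0("snp", seq_along(mafs)),
                                 chromosome = as.character(seq_along(mafs)),
                                 position = 1000L * seq_along(mafs)),
                  sprintf("ind%03d", seq_len(n)))
}
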