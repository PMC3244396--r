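# Latent class model for binary indicators: mixture over K classes with
# class-conditional independent Bernoulli items. Missing cells are skipped
# item-wise (missing-at-random), so every observed cell contributes and no
# case is dropped.

RHO_EPS <- 1e-6

#' Construct a latent class model
#'
#' @param pi Mixing proportions, length K, summing to 1.
#' @param rho K x J matrix of class-conditional endorsement probabilities.
#' @param item_names Optional item labels (defaults to `colnames(rho)`).
#' @return A list of class `lc_model`.
#' @export
lc_model <- function(pi, rho, item_names = colnames(rho)) {
  rho <- as.matrix(rho)
  if (abs(sum(pi) - 1) > 1e-10)
    stop("`pi` must sum to 1", call. = FALSE)
  assert_probability(pi, "pi")
  assert_probability(rho, "rho")
  if (nrow(rho) != length(pi))
    stop("`rho` must have one row per class", call. = FALSE)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(ncol(rho)))
  dimnames(rho) <- list(paste0("class", seq_along(pi)), item_names)
  structure(list(K = length(pi), pi = as.numeric(pi), rho = rho,
                 item_names = item_names),
            class = "lc_model")
}

# coerce an indicator table (tibble/data.frame/matrix, 0/1/NA cells) to a
# numeric matrix; non-numeric id columns are dropped
as_indicator_matrix <- function(data, allow_all_missing = FALSE) {
  if (is.matrix(data)) {
    U <- data
  } else {
    df <- as.data.frame(data)
    num <- vapply(df, is.numeric, logical(1))
    U <- as.matrix(df[num])
  }
  storage.mode(U) <- "double"
  vals <- U[!is.na(U)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("indicator values must be 0, 1 or missing", call. = FALSE)
  if (!allow_all_missing && any(rowSums(!is.na(U)) == 0))
    stop("every case must have at least one observed indicator", call. = FALSE)
  U
}

# n x K matrix of per-class log densities log P(u_i | class k); missing
# items skipped. Exact contradictions (u = 1 with rho = 0, or u = 0 with
# rho = 1) are -Inf.
class_logdensity <- function(model, U) {
  obs <- !is.na(U)
  U0 <- ifelse(obs, U, 0)
  lr <- log(pmax(model$rho, .Machine$double.xmin))
  l1r <- log(pmax(1 - model$rho, .Machine$double.xmin))
  A <- U0 %*% t(lr) + ((1 - U0) * obs) %*% t(l1r)
  contra_pos <- (model$rho == 0)  # u = 1 impossible
  contra_neg <- (model$rho == 1)  # u = 0 impossible
  if (any(contra_pos) || any(contra_neg)) {
    bad <- U0 %*% t(contra_pos) + ((1 - U0) * obs) %*% t(contra_neg)
    A[bad > 0] <- -Inf
  }
  A
}

#' Log-likelihood of a latent class model
#'
#' Sum over cases of the log mixture likelihood
#' \eqn{\log \sum_k \pi_k \prod_{j \in obs(i)} \rho_{kj}^{u_{ij}} (1-\rho_{kj})^{1-u_{ij}}},
#' with missing items skipped (missing-at-random). A case whose observed
#' pattern has probability zero under every class makes the log-likelihood
#' `-Inf`; the result then carries attribute `zero_rows` naming those cases.
#'
#' @param data Indicator table: cases x items, cells 0/1/`NA`; a matrix or
#'   a data frame whose numeric columns are the items.
#' @param model An [lc_model()].
#' @return The log-likelihood (single number).
#' @export
lca_loglik <- function(data, model) {
  U <- as_indicator_matrix(data)
  if (ncol(U) != ncol(model$rho))
    stop("data and model disagree on the number of items", call. = FALSE)
  A <- class_logdensity(model, U) +
    matrix(log(pmax(model$pi, .Machine$double.xmin)),
           nrow(U), model$K, byrow = TRUE)
  rl <- row_logsumexp(A)
  out <- sum(rl)
  if (any(!is.finite(rl))) {
    attr(out, "zero_rows") <- which(!is.finite(rl))
  }
  out
}

#' Posterior class-membership probabilities
#'
#' Bayes rule: row `i`, class `k` proportional to `pi_k` times the
#' class-conditional Bernoulli likelihood over observed items; rows are
#' normalized to sum to 1. A case with every item missing gets the prior
#' `pi` as its posterior.
#'
#' @inheritParams lca_loglik
#' @param ids Optional case identifiers for the output.
#' @return Tibble with `case_id` and one probability column per class.
#' @export
lca_posterior <- function(data, model, ids = NULL) {
  U <- as_indicator_matrix(data, allow_all_missing = TRUE)
  P <- posterior_matrix(model, U)
  tibble::tibble(case_id = ids %||% seq_len(nrow(P))) |>
    dplyr::bind_cols(tibble::as_tibble(P, .name_repair = "minimal"))
}

posterior_matrix <- function(model, U) {
  A <- class_logdensity(model, U) +
    matrix(log(pmax(model$pi, .Machine$double.xmin)),
           nrow(U), model$K, byrow = TRUE)
  rl <- row_logsumexp(A)
  if (any(!is.finite(rl)))
    stop("zero posterior mass for case(s) ",
         paste(which(!is.finite(rl)), collapse = ", "), call. = FALSE)
  P <- exp(A - rl)
  P <- P / rowSums(P)
  colnames(P) <- paste0("class", seq_len(model$K))
  P
}

#' Relative entropy of a posterior matrix
#'
#' `1 - sum_i sum_k (-p_ik log p_ik) / (n log K)`, with `0 log 0 = 0`.
#' 1 means every case is assigned crisply to one class; 0 means posteriors
#' are uniform.
#'
#' @param posteriors n x K matrix (or tibble of probability columns) of
#'   posterior membership probabilities.
#' @param K Number of classes (must be at least 2).
#' @return Relative entropy in `[0, 1]`.
#' @export
relative_entropy <- function(posteriors, K = ncol(P)) {
  P <- as.matrix(if (is.data.frame(posteriors))
    posteriors[vapply(posteriors, is.numeric, logical(1))] else posteriors)
  if (K < 2) stop("relative entropy is undefined for K = 1", call. = FALSE)
  h <- -P * log(P)
  h[P == 0] <- 0
  1 - sum(h) / (nrow(P) * log(K))
}

#' Modal class assignment
#'
#' Argmax of each posterior row; ties are broken toward the lowest class
#' index.
#'
#' @inheritParams relative_entropy
#' @return Integer class index per case.
#' @export
modal_assignment <- function(posteriors) {
  P <- as.matrix(if (is.data.frame(posteriors))
    posteriors[vapply(posteriors, is.numeric, logical(1))] else posteriors)
  max.col(P, ties.method = "first")
}

# one EM run from a given start; U has no all-missing rows
em_single <- function(U, K, max_iter, tol, start_seed) {
  n <- nrow(U); J <- ncol(U)
  obs <- !is.na(U)
  U0 <- ifelse(obs, U, 0)
  init <- with_seed(start_seed, {
    pi0 <- stats::rexp(K); pi0 <- pi0 / sum(pi0)      # symmetric Dirichlet(1)
    rho0 <- matrix(stats::runif(K * J, 0.1, 0.9), K, J)
    list(pi = pi0, rho = rho0)
  })
  pi <- init$pi; rho <- init$rho
  rho_raw <- rho
  ll_old <- -Inf; ll_trace <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    lr <- log(rho); l1r <- log(1 - rho)
    A <- U0 %*% t(lr) + ((1 - U0) * obs) %*% t(l1r) +
      matrix(log(pi), n, K, byrow = TRUE)
    rl <- row_logsumexp(A)
    ll <- sum(rl)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll) && is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    P <- exp(A - rl)
    P <- P / rowSums(P)
    Nk <- colSums(P)
    pi <- Nk / n
    num <- t(P) %*% U0                  # K x J weighted endorsements
    den <- t(P) %*% obs                 # K x J weighted observed counts
    rho_raw <- num / den
    rho_raw[den == 0] <- 0.5            # class vanished on an item
    rho <- pmin(pmax(rho_raw, RHO_EPS), 1 - RHO_EPS)
  }
  list(pi = pi, rho = rho, rho_raw = rho_raw, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, converged = converged, n_iter = length(ll_trace))
}

# reorder classes: descending endorsement of the anchor item, ties broken
# by descending pi; anchor absent -> descending pi
canonical_order <- function(pi, rho, item_names, anchor_item) {
  if (!is.null(anchor_item) && anchor_item %in% item_names) {
    a <- rho[, match(anchor_item, item_names)]
    order(-a, -pi)
  } else {
    order(-pi)
  }
}

#' Fit a latent class model by multi-start EM
#'
#' Runs EM from `n_starts` random starting values (endorsement probabilities
#' uniform on (0.1, 0.9), mixing proportions uniform on the simplex) and
#' keeps the run with the highest final log-likelihood. The E-step computes
#' posteriors by Bayes rule; the M-step takes posterior-weighted means with
#' missing cells excluded item-wise; the log-likelihood is non-decreasing
#' across iterations. Convergence is declared when the gain drops below
#' `tol`. During EM, endorsement probabilities are kept in
#' `[1e-6, 1 - 1e-6]` so a boundary estimate cannot zero out the
#' likelihood; an estimate whose unconstrained M-step value is exactly 0 or
#' 1 is reported as exactly 0 or 1.
#'
#' Classes are relabeled to a canonical order — descending endorsement of
#' `anchor_item` (falling back to descending mixing proportion) — so class
#' identities are stable across starts and seeds.
#'
#' @inheritParams lca_loglik
#' @param K Number of latent classes.
#' @param n_starts Number of random starts (use more for final analyses).
#' @param max_iter Maximum EM iterations per start.
#' @param tol Absolute log-likelihood gain below which a run has converged.
#' @param seed Seed fixing all starting values.
#' @param anchor_item Item used to canonicalize class order; default
#'   `"ALCDEP"` (the alcohol-dependence indicator).
#' @return An object of class `lca_fit`: the fitted [lc_model()],
#'   `loglik`, `bic`, `entropy` (`NA` for K = 1), posterior matrix,
#'   `n_params`, `converged`, `n_starts_used`, `best_start_seed`.
#' @export
#' @examples
#' U <- simulate_cohort(cohort_spec(n_cases = 200, n_controls = 0,
#'                                  n_null_snps = 1, seed = 3))$indicators
#' fit <- lca_fit(U, K = 3, n_starts = 10, seed = 3)
#' fit$bic
lca_fit <- function(data, K, n_starts = 50, max_iter = 1000, tol = 1e-8,
                    seed = 1L, anchor_item = "ALCDEP") {
  U <- as_indicator_matrix(data)
  n <- nrow(U); J <- ncol(U)
  if (K < 1) stop("`K` must be at least 1", call. = FALSE)
  if (K > n) stop("cannot fit more classes than cases", call. = FALSE)
  item_names <- colnames(U) %||% paste0("item", seq_len(J))

  if (K == 1L) {
    # closed form: rho = item means; loglik at the MLE with 0 log 0 = 0
    p_hat <- colMeans(U, na.rm = TRUE)
    s1 <- colSums(U == 1, na.rm = TRUE)
    s0 <- colSums(U == 0, na.rm = TRUE)
    ll <- sum(ifelse(s1 > 0, s1 * log(p_hat), 0) +
              ifelse(s0 > 0, s0 * log(1 - p_hat), 0))
    rho_raw <- matrix(p_hat, 1L, J)
    rho <- pmin(pmax(rho_raw, RHO_EPS), 1 - RHO_EPS)
    runs <- list(list(pi = 1, rho = rho, rho_raw = rho_raw,
                      loglik = ll, ll_trace = ll,
                      converged = TRUE, n_iter = 1L))
    start_seeds <- seed
    best <- 1L
  } else {
    start_seeds <- sub_seeds(seed, n_starts)
    runs <- lapply(start_seeds, function(s)
      em_single(U, K, max_iter = max_iter, tol = tol, start_seed = s))
    best <- which.max(vapply(runs, `[[`, numeric(1), "loglik"))
  }
  run <- runs[[best]]

  ord <- canonical_order(run$pi, run$rho, item_names, anchor_item)
  pi <- run$pi[ord]
  rho <- run$rho[ord, , drop = FALSE]
  rho_raw <- run$rho_raw[ord, , drop = FALSE]
  # report exact boundary estimates where the unconstrained M-step hit them
  rho_report <- rho
  rho_report[rho_raw <= 0] <- 0
  rho_report[rho_raw >= 1] <- 1

  model <- lc_model(pi, rho_report, item_names)
  model_internal <- lc_model(pi, rho, item_names)
  P <- posterior_matrix(model_internal, U)
  n_params <- (K - 1) + K * J
  bic <- -2 * run$loglik + n_params * log(n)

  # complete-data information for logit(rho): n_eff * rho * (1 - rho)
  obs <- !is.na(U)
  n_eff <- t(P) %*% obs
  se_logit_rho <- sqrt(1 / pmax(n_eff * rho * (1 - rho), .Machine$double.eps))
  dimnames(se_logit_rho) <- dimnames(model$rho)

  structure(list(model = model,
                 loglik = run$loglik,
                 bic = bic,
                 entropy = if (K >= 2) relative_entropy(P, K) else NA_real_,
                 posteriors = P,
                 n_params = n_params,
                 converged = run$converged,
                 n_starts_used = length(runs),
                 best_start_seed = start_seeds[best],
                 n_iter = run$n_iter,
                 ll_trace = run$ll_trace,
                 se_logit_rho = se_logit_rho,
                 n = n, K = K, item_names = item_names,
                 data = U),
            class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("Latent class model: K = %d, n = %d\n", x$K, x$n))
  cat(sprintf("  loglik %.2f | BIC %.2f | entropy %s | %s\n",
              x$loglik, x$bic,
              if (is.na(x$entropy)) "-" else sprintf("%.3f", x$entropy),
              if (x$converged) "converged" else "NOT converged"))
  cat("  mixing proportions:", paste(sprintf("%.3f", x$model$pi), collapse = " "), "\n")
  invisible(x)
}

#' Fit latent class models for a range of K and select by BIC
#'
#' Fits `K = 1 .. K_max` and selects the model with the smallest Bayesian
#' information criterion.
#'
#' @inheritParams lca_fit
#' @param K_max Largest class count to try.
#' @return An object of class `lca_selection`: tibble of per-K summaries
#'   (`K`, `loglik`, `n_params`, `bic`, `entropy`, `converged`) with
#'   attributes `fits` (the `lca_fit` objects) and `chosen_K`.
#' @export
lca_select <- function(data, K_max = 5, n_starts = 50, max_iter = 1000,
                       tol = 1e-8, seed = 1L, anchor_item = "ALCDEP") {
  if (K_max < 1) stop("`K_max` must be at least 1", call. = FALSE)
  seeds <- sub_seeds(seed, K_max)
  fits <- lapply(seq_len(K_max), function(K)
    lca_fit(data, K, n_starts = n_starts, max_iter = max_iter, tol = tol,
            seed = seeds[K], anchor_item = anchor_item))
  tab <- purrr::map_dfr(fits, function(f)
    tibble::tibble(K = f$K, loglik = f$loglik, n_params = f$n_params,
                   bic = f$bic, entropy = f$entropy, converged = f$converged))
  chosen <- tab$K[which.min(tab$bic)]
  structure(tab, fits = fits, chosen_K = chosen,
            class = c("lca_selection", class(tab)))
}

#' @export
print.lca_selection <- function(x, ...) {
  cat("Latent class model selection (smallest BIC wins)\n")
  NextMethod()
  cat("chosen K:", attr(x, "chosen_K"), "\n")
  invisible(x)
}

#' Compare two latent class profiles with per-item odds ratios
#'
#' For each item, the odds of endorsement in class `k` relative to class
#' `l`: `[rho_kj / (1 - rho_kj)] / [rho_lj / (1 - rho_lj)]`. An item whose
#' endorsement probability is exactly 0 or 1 in either class has undefined
#' odds and is reported as `NA` (this mirrors published class-profile
#' tables that print "N/A" for such items). Standard errors use the delta
#' method on the log odds ratio with the fit's complete-data information;
#' they are `NA` when only a bare model (no fit) is supplied.
#'
#' @param x An `lca_fit` or [lc_model()].
#' @param k,l Class indices to compare (`k` vs `l`).
#' @return Tibble: `item`, `rho_k`, `rho_l`, `odds_ratio`, `se`, `p_value`
#'   (two-tailed, from the normal approximation on the log scale).
#' @export
profile_odds_ratios <- function(x, k, l) {
  if (inherits(x, "lca_fit")) {
    model <- x$model; se_logit <- x$se_logit_rho
  } else if (inherits(x, "lc_model")) {
    model <- x; se_logit <- NULL
  } else stop("`x` must be an lca_fit or lc_model", call. = FALSE)
  if (k == l) stop("`k` and `l` must differ", call. = FALSE)
  stopifnot(k >= 1, l >= 1, k <= model$K, l <= model$K)
  rk <- model$rho[k, ]; rl <- model$rho[l, ]
  boundary <- rk %in% c(0, 1) | rl %in% c(0, 1)
  or <- (rk / (1 - rk)) / (rl / (1 - rl))
  or[boundary] <- NA_real_
  se <- p <- rep(NA_real_, length(or))
  if (!is.null(se_logit)) {
    se_log_or <- sqrt(se_logit[k, ]^2 + se_logit[l, ]^2)
    se <- or * se_log_or                       # delta method on exp scale
    z <- log(or) / se_log_or
    p <- 2 * stats::pnorm(-abs(z))
    se[boundary] <- p[boundary] <- NA_real_
  }
  tibble::tibble(item = model$item_names, rho_k = rk, rho_l = rl,
                 odds_ratio = or, se = se, p_value = p)
}

#' Pseudo-class Wald test for an auxiliary variable
#'
#' Tests equality of an auxiliary variable's mean across latent classes
#' without entering it into the likelihood. For each of `n_draws`
#' pseudo-class draws, a class is sampled for every case from its posterior
#' row and class means and variances of the variable are computed (missing
#' values excluded); estimates are pooled across draws with
#' multiple-imputation-style variance (within-draw mean variance plus
#' `(1 + 1/D)` times the between-draw variance of the means). The Wald
#' chi-square statistic for equality of the K pooled means has `K - 1`
#' degrees of freedom.
#'
#' @param posteriors n x K posterior matrix (or tibble of probability
#'   columns).
#' @param aux Auxiliary variable, length n; `NA` allowed.
#' @param n_draws Number of pseudo-class draws.
#' @param seed Seed for the draws.
#' @param classes Class indices whose means are compared (default: all K);
#'   draws always use the full posterior, so a pairwise comparison is still
#'   based on the complete class structure.
#' @return A list of class `wald_result`: `class_means`, `statistic`, `df`,
#'   `p_value`, `n_draws`.
#' @export
wald_auxiliary_test <- function(posteriors, aux, n_draws = 20, seed = 1L,
                                classes = NULL) {
  P <- as.matrix(if (is.data.frame(posteriors))
    posteriors[vapply(posteriors, is.numeric, logical(1))] else posteriors)
  n <- nrow(P); K <- ncol(P)
  if (length(aux) != n) stop("`aux` must have one value per case", call. = FALSE)
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      cls <- apply(P, 1L, function(p) sample.int(K, 1L, prob = p))
      means <- vars <- ns <- rep(NA_real_, K)
      for (kk in seq_len(K)) {
        v <- aux[cls == kk & !is.na(aux)]
        ns[kk] <- length(v)
        if (length(v) >= 1) means[kk] <- mean(v)
        if (length(v) >= 2) vars[kk] <- stats::var(v) / length(v)
      }
      list(means = means, vars = vars, ns = ns)
    })
  })
  M <- do.call(rbind, lapply(draws, `[[`, "means"))
  V <- do.call(rbind, lapply(draws, `[[`, "vars"))
  if (any(colSums(!is.na(M)) == 0))
    stop("a class was empty in every pseudo-class draw", call. = FALSE)
  m <- colMeans(M, na.rm = TRUE)
  within <- colMeans(V, na.rm = TRUE)
  between <- apply(M, 2L, stats::var)
  between[is.na(between)] <- 0
  total <- within + (1 + 1 / n_draws) * between
  total <- pmax(total, .Machine$double.eps)
  classes <- classes %||% seq_len(K)
  stopifnot(all(classes %in% seq_len(K)), length(classes) >= 2)
  mc <- m[classes]; tc <- total[classes]
  df <- length(classes) - 1L
  if (stats::var(mc) == 0) {
    stat <- 0; p <- 1
  } else {
    w <- 1 / tc
    mu <- sum(w * mc) / sum(w)
    stat <- sum(w * (mc - mu)^2)
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  structure(list(class_means = m, statistic = stat, df = df,
                 p_value = p, n_draws = n_draws),
            class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Pseudo-class Wald test: chi2(%d) = %.3f, p = %.4g (%d draws)\n",
              x$df, x$statistic, x$p_value, x$n_draws))
  cat("class means:", paste(sprintf("%.3f", x$class_means), collapse = " "), "\n")
  invisible(x)
}

#' Comorbidity burden by class
#'
#' For each class, the fraction of cases whose count of endorsed burden
#' items reaches each threshold ("two or more diagnoses", etc.). Which
#' items count toward the burden is an explicit choice (for instance,
#' psychotic symptoms may be viewed as part of the index phenotype rather
#' than a comorbid diagnosis).
#'
#' @inheritParams lca_loglik
#' @param assignment Class index per case (e.g. from [modal_assignment()]).
#' @param burden_items Items counting toward the burden; default all items.
#' @param thresholds Diagnosis-count thresholds.
#' @return Tibble: `class`, `threshold`, `proportion`, `n_cases`.
#' @export
comorbidity_burden <- function(data, assignment,
                               burden_items = NULL, thresholds = c(2, 3, 4)) {
  U <- as_indicator_matrix(data)
  items <- colnames(U) %||% paste0("item", seq_len(ncol(U)))
  colnames(U) <- items
  burden_items <- burden_items %||% items
  if (!all(burden_items %in% items))
    stop("unknown burden item(s): ",
         paste(setdiff(burden_items, items), collapse = ", "), call. = FALSE)
  counts <- rowSums(U[, burden_items, drop = FALSE], na.rm = TRUE)
  tidyr::expand_grid(class = sort(unique(assignment)),
                     threshold = thresholds) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_cases = sum(assignment == .data$class),
      proportion = mean(counts[assignment == .data$class] >= .data$threshold)) |>
    dplyr::ungroup() |>
    dplyr::select("class", "threshold", "proportion", "n_cases")
}
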