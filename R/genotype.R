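#' Construct a genotype matrix
#'
#' Container for minor-allele dosages: an `N x M` integer matrix with values
#' in `{0, 1, 2, NA}`, per-SNP metadata and sample identifiers. Chromosome
#' labels are character ("1".."22"); positions are 1-based base pairs.
#'
#' @param counts N x M matrix of minor-allele counts (`NA` = missing call).
#' @param snp_info Data frame with columns `snp_id`, `chromosome`,
#'   `position` (one row per SNP).
#' @param sample_ids Character vector of N sample identifiers.
#' @return A list of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts, snp_info, sample_ids) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  snp_info <- tibble::as_tibble(snp_info)
  stopifnot(all(c("snp_id", "chromosome", "position") %in% names(snp_info)),
            nrow(snp_info) == ncol(counts),
            length(sample_ids) == nrow(counts))
  vals <- counts[!is.na(counts)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("genotype counts must be 0, 1, 2 or NA", call. = FALSE)
  rownames(counts) <- sample_ids
  colnames(counts) <- snp_info$snp_id
  structure(list(counts = counts,
                 snp_info = snp_info,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Orient all SNPs to the minor allele
#'
#' Recomputes the frequency of the counted allele on the full sample and
#' flips (dosage `2 - g`) any SNP whose counted-allele frequency exceeds
#' 0.5, so that every column counts the minor allele. Ties (frequency
#' exactly 0.5) are left as-is.
#'
#' @param genotypes A [genotype_matrix()].
#' @return The genotype matrix with a logical `flipped` attribute per SNP.
#' @export
orient_minor <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  af <- colMeans(genotypes$counts, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) {
    genotypes$counts[, flip] <- 2L - genotypes$counts[, flip, drop = FALSE]
  }
  attr(genotypes, "flipped") <- flip
  genotypes
}

#' Minor allele frequency from a dosage vector
#'
#' @param g Minor-allele dosages `{0, 1, 2, NA}` at one SNP.
#' @return MAF in `[0, 1]`; `NA` when every call is missing.
#' @export
#' @examples
#' compute_maf(c(0, 0, 1, 2, NA))
compute_maf <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) return(NA_real_)
  sum(g) / (2 * length(g))
}

#' Minor allele frequency from genotype class counts
#'
#' @param n_hom_minor,n_het,n_hom_major Counts of minor-allele homozygotes,
#'   heterozygotes and major-allele homozygotes.
#' @return MAF `(2 * n_hom_minor + n_het) / (2 * n_total)`.
#' @export
#' @examples
#' maf_from_counts(4, 222, 1801)  # 0.0567
maf_from_counts <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  if (n == 0) return(NA_real_)
  (2 * n_hom_minor + n_het) / (2 * n)
}

#' Remove SNPs below a minor-allele-frequency threshold
#'
#' SNPs with MAF strictly below `threshold` are dropped (a SNP at exactly
#' the threshold survives). The removal log accounts for every input SNP.
#'
#' @param genotypes A [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]`; default 0.001.
#' @return List with `genotypes` (filtered) and `log`, a tibble with one
#'   row per input SNP (`snp_id`, `maf`, `kept`).
#' @export
maf_filter <- function(genotypes, threshold = 0.001) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            threshold >= 0, threshold <= 0.5)
  maf <- apply(genotypes$counts, 2L, compute_maf)
  kept <- if (threshold == 0) rep(TRUE, length(maf)) else !is.na(maf) & maf >= threshold
  log <- tibble::tibble(snp_id = genotypes$snp_info$snp_id,
                        maf = maf, kept = kept)
  out <- genotype_matrix(genotypes$counts[, kept, drop = FALSE],
                         genotypes$snp_info[kept, , drop = FALSE],
                         genotypes$sample_ids)
  list(genotypes = out, log = log)
}

#' Encode genotypes under a genetic model
#'
#' Additive keeps the dosage (0/1/2); dominant scores 1 for any copy of the
#' minor allele; recessive scores 1 only for minor-allele homozygotes.
#' Missing dosages stay missing.
#'
#' @param g Dosage vector `{0, 1, 2, NA}`.
#' @param model `"dominant"`, `"additive"` or `"recessive"`.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' encode_model(c(0, 1, 2), "recessive")
encode_model <- function(g, model = c("dominant", "additive", "recessive")) {
  model <- match.arg(model)
  switch(model,
         additive  = as.numeric(g),
         dominant  = as.numeric(g >= 1L),
         recessive = as.numeric(g == 2L))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided p-value by full enumeration of heterozygote counts
#' conditional on the allele counts, summing the probabilities of all
#' configurations no more probable than the observed one.
#'
#' @param g Dosage vector at one SNP, or omit and give counts directly.
#' @param n_hom_minor,n_het,n_hom_major Genotype class counts (used when
#'   `g` is missing).
#' @return Exact p-value; 1 for a monomorphic SNP.
#' @export
hwe_exact_test <- function(g = NULL, n_hom_minor = NULL, n_het = NULL,
                           n_hom_major = NULL) {
  if (!is.null(g)) {
    g <- g[!is.na(g)]
    n_hom_minor <- sum(g == 2L); n_het <- sum(g == 1L); n_hom_major <- sum(g == 0L)
  }
  n <- n_hom_minor + n_het + n_hom_major
  n_minor <- 2L * n_hom_minor + n_het
  if (n == 0L || n_minor == 0L || n_minor == 2L * n) return(1)
  # enumerate all heterozygote counts with the observed allele counts
  lo <- max(0L, n_minor - n)
  if ((n_minor - lo) %% 2L != 0L) lo <- lo + 1L
  het_vals <- seq.int(lo, min(n_minor, 2L * n - n_minor), by = 2L)
  log_prob <- vapply(het_vals, function(h) {
    hm <- (n_minor - h) / 2
    hM <- n - hm - h
    lchoose(n, hm) + lchoose(n - hm, h) + h * log(2) -
      lchoose(2 * n, n_minor)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  obs <- which(het_vals == n_het)
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}
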