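# Readers and writers for the package's tabular formats: indicator TSV,
# PLINK .ped/.map, VCF v4.2, and plain TSV genotype matrices. Autosomes
# only: records on other chromosomes are skipped with a warning.

AUTOSOMES <- as.character(1:22)

#' Read a binary indicator table from TSV
#'
#' One row per case with a header of item names; cells are 0, 1 or empty
#' (missing). An optional first column named `case_id` is preserved.
#'
#' @param path File path.
#' @return Tibble with `case_id` plus one 0/1/`NA` column per item.
#' @export
read_indicators <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), na = c("", "NA"),
                         progress = FALSE)
  if (!"case_id" %in% names(tbl))
    tbl <- dplyr::bind_cols(tibble::tibble(case_id = seq_len(nrow(tbl))), tbl)
  tbl
}

#' Write a binary indicator table as TSV
#'
#' @param indicators Tibble as returned by [simulate_cohort()] (`case_id`
#'   plus item columns); missing cells are written empty.
#' @param path Output path.
#' @export
write_indicators <- function(indicators, path) {
  readr::write_tsv(indicators, path, na = "")
  invisible(path)
}

#' Read a genotype matrix
#'
#' Supports PLINK `.ped`/`.map` pairs, VCF v4.2 and plain TSV dosage
#' matrices. Counts are oriented to the minor allele on read. Records on
#' non-autosomal chromosomes are skipped with a warning.
#'
#' @param path For `"pedmap"`, the path without extension (or the `.ped`
#'   path); otherwise the file path.
#' @param format `"pedmap"`, `"vcf"` or `"tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("pedmap", "vcf", "tsv")) {
  format <- match.arg(format)
  switch(format,
         pedmap = read_pedmap(path),
         vcf = read_vcf_genotypes(path),
         tsv = read_tsv_genotypes(path))
}

read_pedmap <- function(path) {
  base <- sub("\\.ped$", "", path)
  ped_path <- paste0(base, ".ped"); map_path <- paste0(base, ".map")
  if (!file.exists(ped_path)) stop("missing .ped file: ", ped_path, call. = FALSE)
  if (!file.exists(map_path)) stop("missing .map file: ", map_path, call. = FALSE)
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4L) stop("malformed .map: expected 4 columns", call. = FALSE)
  names(map) <- c("chromosome", "snp_id", "cm", "position")
  M <- nrow(map)
  lines <- readLines(ped_path)
  n_fields <- 6L + 2L * M
  alleles <- matrix(NA_character_, nrow = length(lines), ncol = 2L * M)
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != n_fields)
      stop(sprintf(".ped line %d has %d fields, expected %d", i, length(f),
                   n_fields), call. = FALSE)
    ids[i] <- f[2]
    alleles[i, ] <- f[-(1:6)]
  }
  counts <- matrix(NA_integer_, nrow = length(lines), ncol = M)
  for (m in seq_len(M)) {
    a1 <- alleles[, 2L * m - 1L]; a2 <- alleles[, 2L * m]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    if (length(obs)) {
      lv <- sort(unique(obs))
      freq <- vapply(lv, function(a) mean(obs == a), numeric(1))
      # count the minor allele; tie broken toward the alphabetically first
      minor <- lv[order(freq, lv)][1]
      counts[, m] <- (a1 == minor) + (a2 == minor)
    }
    counts[miss, m] <- NA_integer_
  }
  info <- tibble::tibble(snp_id = map$snp_id, chromosome = map$chromosome,
                         position = as.integer(map$position))
  drop_non_autosomes(genotype_matrix(counts, info, ids))
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage of the ALT allele; "." or missing -> NA
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0L)
  })
  counts <- t(dose)
  info <- tibble::tibble(snp_id = fix$ID,
                         chromosome = sub("^chr", "", fix$CHROM),
                         position = as.integer(fix$POS))
  g <- genotype_matrix(counts, info, colnames(gt))
  orient_minor(drop_non_autosomes(g))
}

read_tsv_genotypes <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  meta <- c("snp_id", "chromosome", "position")
  if (!all(meta %in% names(tbl)))
    stop("TSV genotype matrix needs snp_id, chromosome, position columns",
         call. = FALSE)
  counts <- t(as.matrix(tbl[setdiff(names(tbl), meta)]))
  g <- genotype_matrix(counts, tbl[meta], rownames(counts))
  drop_non_autosomes(g)
}

drop_non_autosomes <- function(g) {
  auto <- g$snp_info$chromosome %in% AUTOSOMES
  if (!all(auto)) {
    warning(sum(!auto), " non-autosomal record(s) skipped", call. = FALSE)
    g <- genotype_matrix(g$counts[, auto, drop = FALSE],
                         g$snp_info[auto, , drop = FALSE], g$sample_ids)
  }
  g
}

#' Write a genotype matrix
#'
#' Formats: PLINK `.ped`/`.map` pair, plain-text VCF v4.2 (ALT is the
#' counted minor allele), or a TSV matrix (SNPs as rows). Counts should be
#' minor-allele oriented (the package's canonical orientation); a write
#' then read round-trip then reproduces the matrix exactly.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path; for `"pedmap"` the base path without extension.
#' @param format `"pedmap"`, `"vcf"` or `"tsv"`.
#' @export
write_genotypes <- function(genotypes, path, format = c("pedmap", "vcf", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  switch(format,
         pedmap = write_pedmap(genotypes, path),
         vcf = write_vcf_genotypes(genotypes, path),
         tsv = write_tsv_genotypes(genotypes, path))
  invisible(path)
}

write_pedmap <- function(g, base) {
  map <- data.frame(g$snp_info$chromosome, g$snp_info$snp_id, 0,
                    g$snp_info$position)
  utils::write.table(map, paste0(base, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # minor allele written as "A", major as "G"; "A" sorts first so the
  # tie-break at MAF 0.5 re-reads identically
  allele_pairs <- c("G G", "A G", "A A")
  lines <- vapply(seq_len(nrow(g$counts)), function(i) {
    gi <- g$counts[i, ]
    al <- ifelse(is.na(gi), "0 0", allele_pairs[gi + 1L])
    paste(c("FAM", g$sample_ids[i], "0", "0", "0", "-9", al), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(base, ".ped"))
}

write_vcf_genotypes <- function(g, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(ncol(g$counts)), function(m) {
    gm <- g$counts[, m]
    gt <- ifelse(is.na(gm), "./.", gt_codes[gm + 1L])
    paste(c(g$snp_info$chromosome[m], g$snp_info$position[m],
            g$snp_info$snp_id[m], "G", "A", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

write_tsv_genotypes <- function(g, path) {
  tbl <- dplyr::bind_cols(g$snp_info,
                          tibble::as_tibble(t(g$counts), .name_repair = "minimal"))
  names(tbl) <- c(names(g$snp_info), g$sample_ids)
  readr::write_tsv(tbl, path)
}

#' Write a cohort to disk
#'
#' Indicators and covariates as TSV, genotypes in the requested format, and
#' the simulation truth record as TSV.
#'
#' @param cohort An `lc_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @param genotype_format Passed to [write_genotypes()].
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, genotype_format = "tsv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_indicators(cohort$indicators, file.path(dir, "indicators.tsv"))
  readr::write_tsv(cohort$aux, file.path(dir, "covariates.tsv"), na = "")
  gpath <- switch(genotype_format,
                  pedmap = file.path(dir, "genotypes"),
                  vcf = file.path(dir, "genotypes.vcf"),
                  tsv = file.path(dir, "genotypes.tsv"))
  write_genotypes(cohort$genotypes, gpath, genotype_format)
  truth <- tibble::tibble(sample_id = cohort$genotypes$sample_ids,
                          is_case = cohort$case_flags == 1L,
                          true_class = c(cohort$truth$true_class,
                                         rep(NA_integer_,
                                             sum(cohort$case_flags == 0L))),
                          subpopulation = cohort$truth$subpopulation %||%
                            NA_integer_)
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), na = "")
  if (nrow(cohort$truth$planted_snps))
    readr::write_tsv(cohort$truth$planted_snps,
                     file.path(dir, "planted_snps.tsv"))
  invisible(dir)
}
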