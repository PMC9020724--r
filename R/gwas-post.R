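#' Filter association records by minor allele frequency
#'
#' Removes SNPs with MAF strictly below the threshold; a SNP exactly at the
#' threshold is kept (the filter is "MAF < threshold"). Idempotent.
#'
#' @param records data.frame with at least `maf`.
#' @param threshold MAF cutoff, default 0.05.
#' @return Filtered data.frame, row order preserved.
#' @export
maf_filter <- function(records, threshold = 0.05) {
  validate_assoc(records, p_required = FALSE)
  records[records$maf >= threshold, , drop = FALSE]
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' `-log10(alpha / n_tests)`: with 113,114 tests at alpha 0.05 this is 6.35
#' (2 dp), the genome-wide line drawn on the Manhattan plots.
#'
#' @param n_tests Number of tests (SNPs after MAF filtering).
#' @param alpha Experiment-wide type I error rate.
#' @return The -log10 p-value threshold (scalar).
#' @export
bonferroni_log_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || length(n_tests) != 1 || n_tests < 1) {
    stop_spec("n_tests must be >= 1")
  }
  -log10(alpha / n_tests)
}

#' Call significant SNPs at a -log10 p threshold
#'
#' Retains records with `-log10(p) >= log_threshold` (the boundary is
#' significant). p-values must lie in (0, 1].
#'
#' @param records data.frame with `p_value`.
#' @param log_threshold Threshold on the -log10 scale (>= 0).
#' @return Significant records.
#' @export
call_significant <- function(records, log_threshold) {
  validate_assoc(records)
  if (log_threshold < 0) stop_spec("log_threshold must be >= 0")
  records[-log10(records$p_value) >= log_threshold, , drop = FALSE]
}

validate_assoc <- function(records, p_required = TRUE) {
  need <- c("snp_id", "chromosome", "position", "maf")
  if (p_required) need <- c(need, "p_value")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop_spec("association records missing column(s): ",
              paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0) return(invisible(records))
  if (any(records$maf <= 0 | records$maf > 0.5)) {
    stop_spec("maf must lie in (0, 0.5]")
  }
  if (any(records$position < 1)) stop_spec("positions are 1-based (>= 1)")
  if (p_required && any(records$p_value <= 0 | records$p_value > 1)) {
    stop_spec("p_value must lie in (0, 1]")
  }
  invisible(records)
}

#' Group significant SNPs into loci
#'
#' Chains significant SNPs on the same chromosome by single linkage:
#' consecutive (position-sorted) SNPs at most `window` bp apart join the
#' same locus (default 300 kb, the "approximately 300-kb region" rule).
#' Each locus takes its lead SNP as the member with the minimum p-value
#' (ties broken by lower position) and is named `q<TRAIT><chr>` with a
#' `-k` suffix when a chromosome carries several loci, ordered by position.
#'
#' @param records Significant association records (from
#'   [call_significant()]).
#' @param window Chaining gap threshold in bp.
#' @param trait Trait tag used in locus names (e.g. `"Pi"`, `"SR"`).
#' @return data.frame with one row per locus: `name`, `chromosome`,
#'   `n_snps`, `lead_snp`, `lead_position`, `span_start`, `span_end`,
#'   `minus_log10_p`, `maf` (of the lead), and a list-column `members` of
#'   member SNP IDs. Attribute `grouping` records the gap-based rule.
#' @export
group_loci <- function(records, window = 300000, trait = "Pi") {
  validate_assoc(records)
  if (nrow(records) == 0) {
    out <- data.frame(name = character(0), chromosome = character(0),
                      n_snps = integer(0), lead_snp = character(0),
                      lead_position = numeric(0), span_start = numeric(0),
                      span_end = numeric(0), minus_log10_p = numeric(0),
                      maf = numeric(0))
    out$members <- list()
    attr(out, "grouping") <- "single-linkage gap"
    return(out)
  }
  loci <- list()
  for (chr in unique(records$chromosome)) {
    sub <- records[records$chromosome == chr, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    gap <- c(Inf, diff(sub$position))
    cluster <- cumsum(gap > window)
    for (cl in unique(cluster)) {
      mem <- sub[cluster == cl, , drop = FALSE]
      lead <- mem[order(mem$p_value, mem$position), , drop = FALSE][1, ]
      loci[[length(loci) + 1L]] <- data.frame(
        chromosome = chr, n_snps = nrow(mem), lead_snp = lead$snp_id,
        lead_position = lead$position, span_start = min(mem$position),
        span_end = max(mem$position),
        minus_log10_p = -log10(lead$p_value), maf = lead$maf,
        stringsAsFactors = FALSE)
      loci[[length(loci)]]$members <- list(mem$snp_id)
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$chromosome, out$lead_position), , drop = FALSE]
  per_chr <- stats::ave(seq_len(nrow(out)), out$chromosome, FUN = seq_along)
  n_chr <- stats::ave(seq_len(nrow(out)), out$chromosome, FUN = length)
  out <- cbind(name = ifelse(n_chr > 1,
                             sprintf("q%s%s-%d", trait, out$chromosome, per_chr),
                             sprintf("q%s%s", trait, out$chromosome)),
               out)
  rownames(out) <- NULL
  attr(out, "grouping") <- "single-linkage gap"
  out
}

#' Candidate-SNP window around a lead SNP
#'
#' Returns the SNPs eligible for candidate-gene analysis around a lead SNP:
#' within `dist` bp of the lead (inclusive) and in linkage disequilibrium
#' with it at `r^2` strictly greater than `r2_min`. Pairs absent from the
#' LD table are treated as below the threshold (counted in a message). The
#' lead SNP itself is always included.
#'
#' @param lead One-row data.frame (or list) with `snp_id`, `chromosome`,
#'   `position`.
#' @param snps Association records to search (any p-value status).
#' @param ld data.frame with `snp_a`, `snp_b`, `r2` (unordered pairs).
#' @param dist Distance cutoff in bp (inclusive).
#' @param r2_min LD cutoff (strict `>`).
#' @return The qualifying rows of `snps`.
#' @export
ld_candidate_window <- function(lead, snps, ld, dist = 100000, r2_min = 0.50) {
  validate_assoc(snps, p_required = FALSE)
  same_chr <- snps$chromosome == lead$chromosome
  near <- same_chr & abs(snps$position - lead$position) <= dist
  cand <- snps[near, , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ld_map <- stats::setNames(ld$r2, key(ld$snp_a, ld$snp_b))
  r2 <- ld_map[key(cand$snp_id, rep(lead$snp_id, nrow(cand)))]
  n_missing <- sum(is.na(r2) & cand$snp_id != lead$snp_id)
  if (n_missing > 0) {
    message(n_missing, " candidate pair(s) missing from the LD table, ",
            "treated as below the r2 threshold")
  }
  r2[is.na(r2)] <- 0
  keep <- r2 > r2_min | cand$snp_id == lead$snp_id
  cand[keep, , drop = FALSE]
}

#' Observed-vs-expected quantiles for a QQ plot
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return data.frame with `expected` and `observed` -log10 p columns,
#'   sorted by increasing significance.
#' @export
qq_data <- function(p_values) {
  if (length(p_values) < 1) stop_spec("need at least one p-value")
  if (any(p_values <= 0 | p_values > 1)) stop_spec("p_value must lie in (0, 1]")
  n <- length(p_values)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(sort(p_values)))
}

#' Cumulative genome coordinates for a Manhattan plot
#'
#' Lays chromosomes end to end: each SNP gets `cum_position = position +
#' offset(chromosome)`, with offsets the cumulative chromosome lengths
#' (taken from `chr_lengths`, or the max observed position per chromosome).
#'
#' @param records Association records.
#' @param chr_lengths Optional named vector of chromosome lengths (bp).
#' @return `records` with `cum_position` appended and, as attribute
#'   `offsets`, the per-chromosome offsets; input order preserved.
#' @export
manhattan_data <- function(records, chr_lengths = NULL) {
  validate_assoc(records)
  chrs <- unique(records$chromosome)
  chrs <- chrs[order(suppressWarnings(as.numeric(chrs)), chrs)]
  if (is.null(chr_lengths)) {
    chr_lengths <- vapply(chrs, function(ch) {
      max(records$position[records$chromosome == ch])
    }, numeric(1))
  }
  offsets <- stats::setNames(c(0, cumsum(chr_lengths[chrs]))[seq_along(chrs)],
                             chrs)
  records$cum_position <- records$position + offsets[as.character(records$chromosome)]
  attr(records, "offsets") <- offsets
  records
}

#' Single-SNP linear association scan
#'
#' Simple per-SNP simple linear regression of the trait on allele dosage
#' (0/1/2): the p-value is the two-sided t-test on the slope. This is the
#' light-weight engine used on synthetic fixtures; real association scans
#' come from an external mixed-model tool and enter through
#' [read_gemma_assoc()]. Monomorphic SNPs get p = 1 (message).
#'
#' @param genotypes Matrix (individuals x SNPs) of 0/1/2 dosages; column
#'   names become SNP IDs.
#' @param trait Numeric phenotype vector, one per individual.
#' @param snp_info Optional data.frame (`snp_id`, `chromosome`, `position`,
#'   `maf`) aligned to the columns.
#' @return Association records: `snp_id`, `chromosome`, `position`, `maf`,
#'   `beta`, `p_value`.
#' @export
naive_assoc <- function(genotypes, trait, snp_info = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (length(trait) != n) stop_spec("trait length must match genotype rows")
  if (anyNA(genotypes)) stop_spec("genotype matrix must be complete")
  g_sd <- apply(genotypes, 2, stats::sd)
  y_sd <- stats::sd(trait)
  mono <- g_sd < 1e-12
  if (any(mono)) message(sum(mono), " monomorphic SNP(s) assigned p = 1")
  r <- rep(0, ncol(genotypes))
  if (y_sd > 1e-12) {
    ok <- !mono
    r[ok] <- suppressWarnings(
      as.vector(stats::cor(genotypes[, ok, drop = FALSE], trait)))
  }
  beta <- ifelse(mono, 0, r * y_sd / ifelse(mono, 1, g_sd))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[mono | y_sd <= 1e-12] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  maf <- colMeans(genotypes) / 2
  maf <- pmin(maf, 1 - maf)
  out <- data.frame(
    snp_id = colnames(genotypes) %||% paste0("snp", seq_len(ncol(genotypes))),
    chromosome = if (is.null(snp_info)) "1" else snp_info$chromosome,
    position = if (is.null(snp_info)) seq_len(ncol(genotypes)) else snp_info$position,
    maf = if (is.null(snp_info)) pmax(maf, 1e-6) else snp_info$maf,
    beta = beta, p_value = p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a GEMMA-style association table
#'
#' Tab-delimited with at least the columns `chr`, `rs`, `ps`, `af`,
#' `p_wald` (extra columns are ignored), mapped onto the package's
#' association-record layout.
#'
#' @param path File path.
#' @return Association records (`snp_id`, `chromosome`, `position`, `maf`,
#'   `p_value`).
#' @export
read_gemma_assoc <- function(path) {
  if (!file.exists(path)) stop_spec("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chr", "rs", "ps", "af", "p_wald")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_spec("association file missing column(s): ",
              paste(miss, collapse = ", "))
  }
  maf <- pmin(df$af, 1 - df$af)
  data.frame(snp_id = as.character(df$rs), chromosome = as.character(df$chr),
             position = df$ps, maf = maf, p_value = df$p_wald,
             stringsAsFactors = FALSE)
}

#' Read a pairwise LD table
#'
#' Tab-delimited with columns `snp_a`, `snp_b`, `r2`.
#'
#' @param path File path.
#' @return data.frame of LD pairs; r2 validated to \[0, 1\].
#' @export
read_ld_pairs <- function(path) {
  if (!file.exists(path)) stop_spec("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("snp_a", "snp_b", "r2"), names(df))
  if (length(miss) > 0) {
    stop_spec("LD file missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$r2 < 0 | df$r2 > 1)) stop_spec("r2 must lie in [0, 1]")
  df
}

#' Write a locus summary table
#'
#' One row per called locus, in the layout used for reporting association
#' signals: locus name, chromosome, number of significant SNPs, lead-SNP
#' position, -log10 p and MAF.
#'
#' @param loci A [group_loci()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(loci, path) {
  out <- loci[, c("name", "chromosome", "n_snps", "lead_position",
                  "minus_log10_p", "maf")]
  # base-pair positions as plain integers, never scientific notation
  out$lead_position <- format(out$lead_position, scientific = FALSE,
                              trim = TRUE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
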