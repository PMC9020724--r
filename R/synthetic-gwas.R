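#' Configuration for a synthetic genotype/association fixture
#'
#' Describes a SNP panel with optional planted trait loci, used to exercise
#' the association post-processing end to end without external genotype
#' data. Chromosome count and size default to a rice-like genome (12
#' chromosomes of 30 Mb).
#'
#' @param n_snps Total SNP count.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in bp (all equal).
#' @param planted_loci data.frame with columns `chromosome`, `position`,
#'   `effect` (in trait-SD units per allele), or `NULL` for a pure null
#'   panel.
#' @param n_linked Extra SNPs planted in tight LD with each causal SNP
#'   (within 50 kb, genotypes copied with a small flip rate), so LD
#'   candidate windows are non-trivial.
#' @param maf_range MAF sampling range, within (0, 0.5].
#' @param n_accessions Number of individuals (accessions).
#' @param trait_noise_sd SD of the Gaussian trait noise.
#' @param seed Root seed.
#' @return An object of class `gwas_config`.
#' @export
gwas_config <- function(n_snps = 2000, n_chromosomes = 12,
                        chromosome_length = 3e7, planted_loci = NULL,
                        n_linked = 2, maf_range = c(0.05, 0.5),
                        n_accessions = 172, trait_noise_sd = 1,
                        seed = 1L) {
  cfg <- list(
    n_snps = check_count(n_snps, "n_snps"),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    chromosome_length = check_nonneg(chromosome_length, "chromosome_length"),
    planted_loci = planted_loci,
    n_linked = check_count(n_linked, "n_linked", min = 0L),
    maf_range = maf_range,
    n_accessions = check_count(n_accessions, "n_accessions"),
    trait_noise_sd = check_nonneg(trait_noise_sd, "trait_noise_sd"),
    seed = as.integer(seed)
  )
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_spec("maf_range must lie within (0, 0.5]",
              class = "specphos_config_error")
  }
  if (!is.null(planted_loci)) {
    miss <- setdiff(c("chromosome", "position", "effect"), names(planted_loci))
    if (length(miss) > 0) {
      stop_spec("planted_loci missing column(s): ", paste(miss, collapse = ", "),
                class = "specphos_config_error")
    }
    if (any(planted_loci$position < 1 |
            planted_loci$position > chromosome_length)) {
      stop_spec("planted_loci positions must lie within chromosome lengths",
                class = "specphos_config_error")
    }
    if (any(!planted_loci$chromosome %in% seq_len(cfg$n_chromosomes))) {
      stop_spec("planted_loci chromosome out of range",
                class = "specphos_config_error")
    }
  }
  structure(cfg, class = "gwas_config")
}

#' Generate a synthetic genotype panel with planted trait loci
#'
#' Draws Hardy-Weinberg genotypes (0/1/2) at independent SNPs with MAF
#' uniform over `maf_range`, places one SNP exactly at each planted-locus
#' position (plus `n_linked` tightly linked neighbours within 50 kb whose
#' genotypes are copies with a 3% flip rate), and builds the trait as the
#' sum of planted additive effects plus Gaussian noise. Pairwise LD r^2 is
#' tabulated for all SNP pairs within `ld_max_dist` on the same chromosome.
#' If a planted SNP's drawn MAF falls below 0.05 it would not survive the
#' standard MAF filter; a warning is raised.
#'
#' @param config A [gwas_config()].
#' @param ld_max_dist Distance up to which pairwise LD is tabulated (bp).
#' @return List of class `synthetic_gwas`: `genotypes` (accessions x SNPs),
#'   `snp_info` (`snp_id`, `chromosome`, `position`, `maf` — realized
#'   frequencies), `trait`, `ld` (`snp_a`, `snp_b`, `r2`), and `truth`
#'   (config plus the causal SNP IDs).
#' @export
generate_gwas <- function(config, ld_max_dist = 100000) {
  if (!inherits(config, "gwas_config")) {
    stop_spec("config must be a gwas_config object",
              class = "specphos_config_error")
  }
  with_seed(config$seed, generate_gwas_impl(config, ld_max_dist))
}

generate_gwas_impl <- function(cfg, ld_max_dist) {
  planted <- cfg$planted_loci
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  n_extra <- n_planted * cfg$n_linked
  n_bg <- cfg$n_snps - n_planted - n_extra
  if (n_bg < 0) stop_spec("n_snps too small for the planted loci",
                          class = "specphos_config_error")

  chr <- sample.int(cfg$n_chromosomes, n_bg, replace = TRUE)
  pos <- ceiling(stats::runif(n_bg, 0, cfg$chromosome_length))
  causal_id <- character(n_planted)
  if (n_planted > 0) {
    chr <- c(chr, planted$chromosome)
    pos <- c(pos, planted$position)
    for (i in seq_len(cfg$n_linked)) {
      chr <- c(chr, planted$chromosome)
      off <- round(stats::runif(n_planted, -50000, 50000))
      pos <- c(pos, pmin(pmax(planted$position + off, 1),
                         cfg$chromosome_length))
    }
  }
  n_snps <- length(chr)
  ord <- order(chr, pos)
  chr <- chr[ord]; pos <- pos[ord]
  snp_id <- sprintf("%d_%d", chr, pos)
  # positions of planted causal SNPs after sorting
  if (n_planted > 0) {
    causal_idx <- match(sprintf("%d_%d", planted$chromosome, planted$position),
                        snp_id)
    causal_id <- snp_id[causal_idx]
  }
  # which original index each sorted SNP came from (to find linked copies)
  orig <- seq_len(n_snps)[ord]

  maf <- stats::runif(n_snps, cfg$maf_range[1], cfg$maf_range[2])
  G <- matrix(0L, cfg$n_accessions, n_snps)
  for (j in seq_len(n_snps)) {
    G[, j] <- stats::rbinom(cfg$n_accessions, 2L, maf[j])
  }
  if (n_planted > 0) {
    # linked copies: overwrite with flip-perturbed copies of their causal SNP
    for (i in seq_len(n_planted)) {
      src_orig <- n_bg + i
      for (l in seq_len(cfg$n_linked)) {
        tgt_orig <- n_bg + n_planted * l + i
        tgt <- match(tgt_orig, orig)
        src <- match(src_orig, orig)
        g <- G[, src]
        flip <- stats::runif(cfg$n_accessions) < 0.03
        g[flip] <- stats::rbinom(sum(flip), 2L, maf[src])
        G[, tgt] <- g
      }
    }
  }
  colnames(G) <- snp_id
  realized <- colMeans(G) / 2
  realized_maf <- pmin(realized, 1 - realized)

  trait <- stats::rnorm(cfg$n_accessions, 0, cfg$trait_noise_sd)
  if (n_planted > 0) {
    for (i in seq_len(n_planted)) {
      trait <- trait + planted$effect[i] * G[, causal_idx[i]]
    }
    low <- realized_maf[causal_idx] < 0.05
    if (any(low)) {
      warning("planted effect on SNP(s) below the 0.05 MAF filter: ",
              paste(causal_id[low], collapse = ", "), call. = FALSE)
    }
  }

  ld <- ld_table(G, chr, pos, ld_max_dist)
  snp_info <- data.frame(snp_id = snp_id, chromosome = as.character(chr),
                         position = pos, maf = pmax(realized_maf, 1e-6),
                         stringsAsFactors = FALSE)
  structure(list(genotypes = G, snp_info = snp_info, trait = trait, ld = ld,
                 truth = list(config = cfg, causal_snp = causal_id)),
            class = "synthetic_gwas")
}

# Pairwise genotype-correlation r2 for same-chromosome SNPs within max_dist.
ld_table <- function(G, chr, pos, max_dist) {
  pairs <- list()
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    idx <- idx[order(pos[idx])]
    for (ii in seq_along(idx)) {
      jj <- ii + 1L
      while (jj <= length(idx) && pos[idx[jj]] - pos[idx[ii]] <= max_dist) {
        a <- idx[ii]; b <- idx[jj]
        r <- suppressWarnings(stats::cor(G[, a], G[, b]))
        pairs[[length(pairs) + 1L]] <- data.frame(
          snp_a = colnames(G)[a], snp_b = colnames(G)[b],
          r2 = if (is.finite(r)) r^2 else 0, stringsAsFactors = FALSE)
        jj <- jj + 1L
      }
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(snp_a = character(0), snp_b = character(0),
                      r2 = numeric(0)))
  }
  do.call(rbind, pairs)
}

#' @export
print.synthetic_gwas <- function(x, ...) {
  cat(sprintf("<synthetic_gwas> %d accessions x %d SNPs on %d chromosomes\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$snp_info$chromosome))))
  cat(sprintf("  planted causal SNPs: %d; LD pairs tabulated: %d\n",
              length(x$truth$causal_snp), nrow(x$ld)))
  invisible(x)
}
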