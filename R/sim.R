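#' Simulation configuration
#'
#' Describes a synthetic multi-omics study: genomic layout, LD structure of
#' the genotypes, planted SNP-methylation-mRNA trio architectures, covariate
#' effects and per-layer noise.  Defaults mirror a small observational
#' methylation cohort (43 samples, age + binary disease status as
#' covariates); power and error-rate studies should raise `n_samples` to a
#' few hundred.
#'
#' @param n_samples Number of samples.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param n_snps,n_cpgs,n_genes Feature counts across the genome.
#' @param maf_range Interval in (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn.
#' @param ld_block_size Number of consecutive SNPs per LD block.
#' @param ld_decay Probability in \[0,1\] that a haplotype allele is re-drawn
#'   (rather than copied from the previous SNP) between adjacent SNPs of a
#'   block; 0 gives perfect LD within a block, 1 gives independence.
#' @param trio_architectures Data frame with columns `architecture`
#'   (mediation, common_cause, reverse, null), `n` (trio count) and the
#'   planted effects `beta_lg` (SNP->methylation, logit scale), `beta_gt`
#'   (methylation->expression, per logit unit), `beta_lt` (direct
#'   SNP->expression) and `beta_tg` (expression->methylation, logit per
#'   centred log2 unit).
#' @param covariate_effects List with numeric vectors `methylation` and
#'   `expression`, each `c(age=, disease=)`, giving covariate coefficients
#'   per layer.
#' @param noise_sd Named numeric `c(methylation=, expression=)`: residual SD
#'   on the logit (methylation) and log2 (expression) scales.
#' @param seed Master integer seed; every generator derives its own
#'   sub-stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 43,
                       n_chromosomes = 3,
                       chrom_length_bp = 5e7,
                       n_snps = 300,
                       n_cpgs = 150,
                       n_genes = 60,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_decay = 0.1,
                       trio_architectures = default_architectures(),
                       covariate_effects = list(
                         methylation = c(age = 0.01, disease = 0.3),
                         expression = c(age = 0.01, disease = 0.3)),
                       noise_sd = c(methylation = 1, expression = 1),
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_snps = as.integer(n_snps), n_cpgs = as.integer(n_cpgs),
              n_genes = as.integer(n_genes),
              maf_range = as.numeric(maf_range),
              ld_block_size = as.integer(ld_block_size),
              ld_decay = as.numeric(ld_decay),
              trio_architectures = as.data.frame(trio_architectures),
              covariate_effects = covariate_effects,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_architectures <- function() {
  data.frame(architecture = c("mediation", "common_cause", "reverse", "null"),
             n = c(5L, 5L, 5L, 5L),
             beta_lg = c(0.8, 0.8, 0, 0),
             beta_gt = c(1, 0, 0, 0),
             beta_lt = c(0, 0.8, 0.8, 0),
             beta_tg = c(0, 0, 1, 0))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_samples >= 2, n_chromosomes >= 1, chrom_length_bp >= 1,
              n_snps >= 1, n_cpgs >= 1, n_genes >= 0,
              length(maf_range) == 2, maf_range[1] > 0,
              maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
              ld_block_size >= 1, ld_decay >= 0, ld_decay <= 1)
  })
  ta <- cfg$trio_architectures
  need <- c("architecture", "n", "beta_lg", "beta_gt", "beta_lt", "beta_tg")
  if (!all(need %in% names(ta))) {
    stop("trio_architectures needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(ta$architecture %in% architecture_levels)) {
    stop("unknown architecture label; allowed: ",
         paste(architecture_levels, collapse = ", "))
  }
  if (any(ta$n < 0)) stop("architecture counts must be >= 0")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields map directly onto [sim_config()] arguments;
#' `trio_architectures` is a list of maps with the architecture columns.
#'
#' @param path Path to a YAML config.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$trio_architectures)) {
    ta <- do.call(rbind, lapply(y$trio_architectures, as.data.frame))
    # YAML 1.1 parses a bare `n:` key as logical FALSE; `count` also accepted
    names(ta)[names(ta) %in% c("FALSE.", "count")] <- "n"
    y$trio_architectures <- ta
  }
  if (!is.null(y$noise_sd)) y$noise_sd <- unlist(y$noise_sd)
  if (!is.null(y$covariate_effects)) {
    y$covariate_effects <- lapply(y$covariate_effects, unlist)
  }
  do.call(sim_config, y)
}

expand_truth <- function(cfg) {
  ta <- cfg$trio_architectures
  idx <- rep(seq_len(nrow(ta)), ta$n)
  data.frame(architecture = ta$architecture[idx],
             beta_lg = ta$beta_lg[idx], beta_gt = ta$beta_gt[idx],
             beta_lt = ta$beta_lt[idx], beta_tg = ta$beta_tg[idx],
             stringsAsFactors = FALSE)
}

sim_sample_ids <- function(cfg) sprintf("S%04d", seq_len(cfg$n_samples))

#' Generate the genomic feature map
#'
#' Places SNPs, CpGs and transcripts uniformly on the configured chromosomes
#' (1-based positions, distinct within each feature class) and lays out the
#' planted trios so that every trio SNP and CpG is within 1 Mb of its gene's
#' TSS-TES interval and within 50 kb of each other -- construction guarantees
#' cis eligibility for all three pair scans.  Each CpG is assigned one
#' island-relation category (Island, N/S_Shore, N/S_Shelf, OpenSea) and one
#' gene-region category (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR,
#' Intergenic); transcripts get strand and tss < tes in genomic coordinates.
#'
#' @param cfg A [sim_config()].
#' @return A feature-annotation data frame (see [read_annotation()]) with
#'   the planted-trio truth table attached; retrieve it with
#'   [truth_table()].
#' @export
gen_feature_map <- function(cfg) {
  validate_sim_config(cfg)
  truth <- expand_truth(cfg)
  n_trios <- nrow(truth)
  if (n_trios > 0 && cfg$n_genes == 0) {
    stop("layout error: trios requested but n_genes = 0")
  }
  if (n_trios > cfg$n_genes && n_trios > 0) {
    stop("layout error: need n_genes >= total trio count (one gene per trio)")
  }
  if (n_trios > cfg$n_snps || n_trios > cfg$n_cpgs) {
    stop("layout error: need n_snps and n_cpgs >= total trio count")
  }
  gene_margin <- 1.3e6
  if (cfg$chrom_length_bp < 2 * gene_margin + 2.1e5) {
    stop("layout error: chromosome too short for cis windows (need > ",
         format(2 * gene_margin + 2.1e5, scientific = FALSE), " bp)")
  }
  per_chrom_cap <- cfg$chrom_length_bp / 10
  if (max(cfg$n_snps, cfg$n_cpgs) > cfg$n_chromosomes * per_chrom_cap) {
    stop("layout error: chromosome too short to hold requested features ",
         "at distinct positions")
  }
  set.seed(derive_seed(cfg$seed, "map"))
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  L <- cfg$chrom_length_bp

  # transcripts
  gene_chrom <- sample.int(cfg$n_chromosomes, cfg$n_genes, replace = TRUE)
  glen <- round(stats::runif(cfg$n_genes, 5e3, 2e5))
  tss <- round(stats::runif(cfg$n_genes, gene_margin, L - gene_margin - glen))
  tes <- tss + glen
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gene_id <- sprintf("tx%04d", seq_len(cfg$n_genes))
  gene_symbol <- sprintf("G%03d", seq_len(cfg$n_genes))
  # a fraction of non-trio genes lacks an official symbol
  trio_gene <- if (n_trios > 0) sample.int(cfg$n_genes, n_trios) else integer(0)
  unnamed <- setdiff(which(stats::runif(cfg$n_genes) < 0.1), trio_gene)
  gene_symbol[unnamed] <- NA_character_

  # trio CpGs near the gene, trio SNPs near the CpG
  cpg_chrom <- integer(cfg$n_cpgs)
  cpg_pos <- numeric(cfg$n_cpgs)
  snp_chrom <- integer(cfg$n_snps)
  snp_pos <- numeric(cfg$n_snps)
  if (n_trios > 0) {
    for (k in seq_len(n_trios)) {
      g <- trio_gene[k]
      lo <- max(1, tss[g] - 5e5); hi <- min(L, tes[g] + 5e5)
      cp <- round(stats::runif(1, lo, hi))
      slo <- max(1, tss[g] - 9.5e5, cp - 5e4)
      shi <- min(L, tes[g] + 9.5e5, cp + 5e4)
      sp <- round(stats::runif(1, slo, shi))
      cpg_chrom[k] <- gene_chrom[g]; cpg_pos[k] <- cp
      snp_chrom[k] <- gene_chrom[g]; snp_pos[k] <- sp
    }
  }
  rest_c <- setdiff(seq_len(cfg$n_cpgs), seq_len(n_trios))
  cpg_chrom[rest_c] <- sample.int(cfg$n_chromosomes, length(rest_c),
                                  replace = TRUE)
  cpg_pos[rest_c] <- round(stats::runif(length(rest_c), 1, L))
  rest_s <- setdiff(seq_len(cfg$n_snps), seq_len(n_trios))
  snp_chrom[rest_s] <- sample.int(cfg$n_chromosomes, length(rest_s),
                                  replace = TRUE)
  snp_pos[rest_s] <- round(stats::runif(length(rest_s), 1, L))
  snp_pos <- dedup_positions(snp_chrom, snp_pos, L)
  cpg_pos <- dedup_positions(cpg_chrom, cpg_pos, L)

  snp_id <- sprintf("rs%06d", seq_len(cfg$n_snps))
  cpg_id <- sprintf("cg%06d", seq_len(cfg$n_cpgs))

  # CpG categories and gene assignment (trio CpGs carry their trio gene)
  island_cat <- sample(cpg_island_levels, cfg$n_cpgs, replace = TRUE,
                       prob = c(0.25, 0.15, 0.15, 0.06, 0.06, 0.33))
  region_cat <- sample(gene_region_levels, cfg$n_cpgs, replace = TRUE,
                       prob = c(0.18, 0.09, 0.08, 0.03, 0.40, 0.07, 0.15))
  cpg_gene <- rep(NA_character_, cfg$n_cpgs)
  if (n_trios > 0) cpg_gene[seq_len(n_trios)] <- gene_symbol[trio_gene]
  for (i in rest_c) {
    same <- which(gene_chrom == cpg_chrom[i] & !is.na(gene_symbol))
    if (!length(same)) next
    d <- pmax(0, pmax(tss[same] - cpg_pos[i], cpg_pos[i] - tes[same]))
    j <- same[which.min(d)]
    if (min(d) <= 1e6) cpg_gene[i] <- gene_symbol[j]
  }

  ann_snp <- data.frame(feature_id = snp_id, feature_class = "snp",
                        chrom = chroms[snp_chrom], pos = snp_pos,
                        strand = NA_character_, tss = NA_real_, tes = NA_real_,
                        gene_symbol = NA_character_,
                        cpg_island_category = NA_character_,
                        gene_region_category = NA_character_,
                        stringsAsFactors = FALSE)
  ann_cpg <- data.frame(feature_id = cpg_id, feature_class = "cpg",
                        chrom = chroms[cpg_chrom], pos = cpg_pos,
                        strand = NA_character_, tss = NA_real_, tes = NA_real_,
                        gene_symbol = cpg_gene,
                        cpg_island_category = island_cat,
                        gene_region_category = region_cat,
                        stringsAsFactors = FALSE)
  ann_tx <- data.frame(feature_id = gene_id, feature_class = "transcript",
                       chrom = chroms[gene_chrom], pos = NA_real_,
                       strand = strand, tss = tss, tes = tes,
                       gene_symbol = gene_symbol,
                       cpg_island_category = NA_character_,
                       gene_region_category = NA_character_,
                       stringsAsFactors = FALSE)
  ord <- function(d) d[order(d$chrom, ifelse(is.na(d$pos), d$tss, d$pos),
                             d$feature_id), , drop = FALSE]
  map <- rbind(ord(ann_snp), ord(ann_cpg), ord(ann_tx))
  rownames(map) <- NULL

  truth <- cbind(data.frame(snp_id = snp_id[seq_len(n_trios)],
                            cpg_id = cpg_id[seq_len(n_trios)],
                            gene_id = gene_id[trio_gene],
                            stringsAsFactors = FALSE),
                 truth)
  attr(map, "truth") <- truth
  map
}

# re-draw duplicated positions within (class, chrom) until distinct
dedup_positions <- function(chrom, pos, L) {
  for (it in 1:100) {
    key <- paste(chrom, pos)
    dup <- duplicated(key)
    if (!any(dup)) return(pos)
    pos[dup] <- round(stats::runif(sum(dup), 1, L))
  }
  stop("layout error: chromosome too short to hold requested features ",
       "at distinct positions")
}

#' @rdname gen_feature_map
#' @param map A feature map from [gen_feature_map()].
#' @export
truth_table <- function(map) {
  t <- attr(map, "truth")
  if (is.null(t)) stop("no truth table attached to this annotation")
  t
}

#' Generate covariates
#'
#' Age is drawn from Uniform(30, 70) years and disease status from
#' Bernoulli(0.5), emulating an adult case/control mix.
#'
#' @param cfg A [sim_config()].
#' @return A covariate data frame (`sample_id`, `age`, `disease_status`).
#' @export
gen_covariates <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "covariates"))
  data.frame(sample_id = sim_sample_ids(cfg),
             age = round(stats::runif(cfg$n_samples, 30, 70), 1),
             disease_status = stats::rbinom(cfg$n_samples, 1, 0.5),
             stringsAsFactors = FALSE)
}

#' Generate genotypes with block LD
#'
#' Two haplotypes per sample are simulated along each chromosome: SNPs are
#' grouped (in position order) into blocks of `ld_block_size`; the first SNP
#' of a block draws alleles from Bernoulli(MAF), and each subsequent SNP
#' copies the previous haplotype allele with probability `1 - ld_decay`,
#' otherwise re-draws.  Haplotypes are summed to additive 0/1/2 genotypes.
#' Columns whose realized MAF falls below half the lower bound of
#' `maf_range` are re-drawn, so no column is (near-)monomorphic.
#'
#' @param cfg A [sim_config()].
#' @param map Feature map from [gen_feature_map()].
#' @return An [omics_matrix()] with role `"genotype"` (samples x SNPs, SNP
#'   order as in the map).
#' @export
gen_genotypes <- function(cfg, map) {
  validate_sim_config(cfg)
  snps <- map[map$feature_class == "snp", , drop = FALSE]
  m <- nrow(snps)
  n <- cfg$n_samples
  set.seed(derive_seed(cfg$seed, "genotypes"))
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)   # map rows already position-sorted
    for (k in seq_along(idx)) {
      j <- idx[k]
      first <- ((k - 1) %% cfg$ld_block_size) == 0
      if (first) {
        h1[, j] <- stats::rbinom(n, 1, maf[j])
        h2[, j] <- stats::rbinom(n, 1, maf[j])
      } else {
        prev <- idx[k - 1]
        h1[, j] <- copy_or_redraw(h1[, prev], maf[j], cfg$ld_decay)
        h2[, j] <- copy_or_redraw(h2[, prev], maf[j], cfg$ld_decay)
      }
    }
  }
  g <- h1 + h2
  # re-draw (near-)monomorphic columns
  floor_maf <- 0.5 * cfg$maf_range[1]
  for (it in 1:100) {
    cm <- colMeans(g) / 2
    bad <- which(pmin(cm, 1 - cm) < floor_maf)
    if (!length(bad)) break
    for (j in bad) {
      g[, j] <- stats::rbinom(n, 1, maf[j]) + stats::rbinom(n, 1, maf[j])
    }
  }
  storage.mode(g) <- "double"
  dimnames(g) <- list(sim_sample_ids(cfg), snps$feature_id)
  omics_matrix(g, "genotype")
}

copy_or_redraw <- function(prev, maf, decay) {
  n <- length(prev)
  out <- prev
  redraw <- stats::runif(n) < decay
  if (any(redraw)) out[redraw] <- stats::rbinom(sum(redraw), 1, maf)
  out
}

#' Generate methylation beta values
#'
#' Methylation is generated on the logit scale:
#' `logit(beta) = alpha_cpg + beta_lg * g + covariates + N(0, noise_sd)`,
#' then mapped through the inverse logit so all values lie strictly inside
#' (0, 1).  Reverse-causation trios additionally receive
#' `beta_tg * (T - mean(T))` once expression is available (pass `expression`
#' to apply it); their noise and baseline are identical either way, so the
#' two-pass generation is deterministic.
#'
#' @param cfg A [sim_config()].
#' @param map Feature map.
#' @param genotypes Genotype [omics_matrix()].
#' @param truth Truth table (see [truth_table()]).
#' @param covariates Covariate data frame.
#' @param expression Optional expression matrix; when supplied, the
#'   expression->methylation effects of reverse trios are applied.
#' @return An [omics_matrix()] with role `"methylation-beta"`.
#' @export
gen_methylation <- function(cfg, map, genotypes, truth, covariates,
                            expression = NULL) {
  validate_sim_config(cfg)
  cpgs <- map$feature_id[map$feature_class == "cpg"]
  n <- cfg$n_samples
  set.seed(derive_seed(cfg$seed, "methylation"))
  alpha <- stats::runif(length(cpgs), -1.5, 1.5)
  eff <- cfg$covariate_effects$methylation
  covterm <- covariates$age * eff[["age"]] +
    covariates$disease_status * eff[["disease"]]
  covterm <- covterm - mean(covterm)
  eta <- matrix(alpha, n, length(cpgs), byrow = TRUE) + covterm +
    matrix(stats::rnorm(n * length(cpgs), 0, cfg$noise_sd[["methylation"]]),
           n, length(cpgs))
  colnames(eta) <- cpgs
  for (k in seq_len(nrow(truth))) {
    if (truth$beta_lg[k] != 0) {
      eta[, truth$cpg_id[k]] <- eta[, truth$cpg_id[k]] +
        truth$beta_lg[k] * unclass(genotypes)[, truth$snp_id[k]]
    }
    if (truth$beta_tg[k] != 0 && !is.null(expression)) {
      tval <- unclass(expression)[, truth$gene_id[k]]
      eta[, truth$cpg_id[k]] <- eta[, truth$cpg_id[k]] +
        truth$beta_tg[k] * (tval - mean(tval))
    }
  }
  beta <- stats::plogis(eta)
  eps <- 1e-9
  beta <- pmin(pmax(beta, eps), 1 - eps)
  rownames(beta) <- sim_sample_ids(cfg)
  omics_matrix(beta, "methylation-beta")
}

#' Generate log2 expression
#'
#' Expression follows
#' `T = mu_gene + beta_gt * logit(G) + beta_lt * g + covariates +
#' N(0, noise_sd)` with gene baselines `mu ~ U(6, 12)` on the log2 scale.
#' Generation order resolves the architectures: mediation and common-cause
#' trios draw methylation first (`beta_gt`/`beta_lt` applied here), reverse
#' trios draw expression first (`beta_lt` only; their methylation response is
#' applied afterwards by [gen_methylation()] with `expression` supplied).
#'
#' @inheritParams gen_methylation
#' @param methylation Methylation [omics_matrix()] (first pass).
#' @return An [omics_matrix()] with role `"log2-expression"`.
#' @export
gen_expression <- function(cfg, map, genotypes, methylation, truth,
                           covariates) {
  validate_sim_config(cfg)
  genes <- map$feature_id[map$feature_class == "transcript"]
  n <- cfg$n_samples
  set.seed(derive_seed(cfg$seed, "expression"))
  mu <- stats::runif(length(genes), 6, 12)
  eff <- cfg$covariate_effects$expression
  covterm <- covariates$age * eff[["age"]] +
    covariates$disease_status * eff[["disease"]]
  covterm <- covterm - mean(covterm)
  expr <- matrix(mu, n, length(genes), byrow = TRUE) + covterm +
    matrix(stats::rnorm(n * length(genes), 0, cfg$noise_sd[["expression"]]),
           n, length(genes))
  colnames(expr) <- genes
  for (k in seq_len(nrow(truth))) {
    if (truth$beta_gt[k] != 0) {
      expr[, truth$gene_id[k]] <- expr[, truth$gene_id[k]] +
        truth$beta_gt[k] *
          stats::qlogis(unclass(methylation)[, truth$cpg_id[k]])
    }
    if (truth$beta_lt[k] != 0) {
      expr[, truth$gene_id[k]] <- expr[, truth$gene_id[k]] +
        truth$beta_lt[k] * unclass(genotypes)[, truth$snp_id[k]]
    }
  }
  rownames(expr) <- sim_sample_ids(cfg)
  omics_matrix(expr, "log2-expression")
}

#' Simulate a complete multi-omics dataset
#'
#' Orchestrates the generators in causal order: feature map and truth table,
#' covariates, genotypes, first-pass methylation (all non-reverse CpGs
#' final), expression, then the reverse-trio methylation responses.  Fully
#' deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_dataset` with elements `annotation`,
#'   `truth`, `covariates`, `genotypes`, `methylation`, `expression` and
#'   `config`.
#' @export
simulate_dataset <- function(cfg) {
  map <- gen_feature_map(cfg)
  truth <- truth_table(map)
  cov <- gen_covariates(cfg)
  geno <- gen_genotypes(cfg, map)
  meth0 <- gen_methylation(cfg, map, geno, truth, cov)
  expr <- gen_expression(cfg, map, geno, meth0, truth, cov)
  meth <- gen_methylation(cfg, map, geno, truth, cov, expression = expr)
  structure(list(annotation = map, truth = truth, covariates = cov,
                 genotypes = geno, methylation = meth, expression = expr,
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("sim_dataset: %d samples, %d SNPs, %d CpGs, %d genes, ",
                     "%d planted trios\n"),
              x$config$n_samples, x$config$n_snps, x$config$n_cpgs,
              x$config$n_genes, nrow(x$truth)))
  invisible(x)
}
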