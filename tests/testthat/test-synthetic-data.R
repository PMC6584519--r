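test_that("feature map places trio SNP and CpG cis to the trio gene", {
  cfg <- small_cfg()
  map <- gen_feature_map(cfg)
  truth <- truth_table(map)
  expect_equal(nrow(truth), 9)
  tx <- map[map$feature_class == "transcript", ]
  for (k in seq_len(nrow(truth))) {
    g <- tx[tx$feature_id == truth$gene_id[k], ]
    for (id in c(truth$snp_id[k], truth$cpg_id[k])) {
      f <- map[map$feature_id == id, ]
      expect_identical(f$chrom, g$chrom)
      d <- max(0, g$tss - f$pos, f$pos - g$tes)
      expect_lte(d, 1e6)
    }
    # the SNP-CpG pair itself is cis
    sp <- map$pos[map$feature_id == truth$snp_id[k]]
    cp <- map$pos[map$feature_id == truth$cpg_id[k]]
    expect_lte(abs(sp - cp), 1e6)
  }
  expect_true(all(map$cpg_island_category[map$feature_class == "cpg"] %in%
                    c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea")))
  tr <- map[map$feature_class == "transcript", ]
  expect_true(all(tr$tss < tr$tes))
  # distinct positions within each point class/chromosome
  for (cl in c("snp", "cpg")) {
    sub <- map[map$feature_class == cl, ]
    expect_false(any(duplicated(paste(sub$chrom, sub$pos))))
  }
})

test_that("impossible layouts raise layout errors", {
  expect_error(sim_config(n_genes = 0) |> gen_feature_map(),
               "layout error")
  expect_error(gen_feature_map(sim_config(chrom_length_bp = 1e5)),
               "layout error")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(unclass(d1$genotypes), unclass(d2$genotypes))
  expect_identical(unclass(d1$methylation), unclass(d2$methylation))
  expect_identical(unclass(d1$expression), unclass(d2$expression))
  expect_identical(d1$covariates, d2$covariates)
})

test_that("ld_decay = 0 makes block columns identical; decay = 1 decorrelates", {
  cfg0 <- sim_config(n_samples = 500, n_chromosomes = 1, n_snps = 10,
                     n_cpgs = 2, n_genes = 2, ld_block_size = 5,
                     ld_decay = 0, maf_range = c(0.3, 0.4),
                     trio_architectures = data.frame(
                       architecture = "null", n = 0L, beta_lg = 0,
                       beta_gt = 0, beta_lt = 0, beta_tg = 0),
                     seed = 5)
  g0 <- unclass(gen_genotypes(cfg0, gen_feature_map(cfg0)))
  snp_ann <- gen_feature_map(cfg0)
  # blocks are consecutive position-sorted SNPs: columns within a block equal
  ann <- snp_ann[snp_ann$feature_class == "snp", ]
  ids <- ann$feature_id
  for (b in list(ids[1:5], ids[6:10])) {
    for (j in b[-1]) expect_identical(g0[, b[1]], g0[, j])
  }
  cfg1 <- sim_config(n_samples = 500, n_chromosomes = 1, n_snps = 100,
                     n_cpgs = 2, n_genes = 2, ld_block_size = 100,
                     ld_decay = 1, maf_range = c(0.2, 0.4),
                     trio_architectures = cfg0$trio_architectures, seed = 6)
  g1 <- unclass(gen_genotypes(cfg1, gen_feature_map(cfg1)))
  r2 <- sapply(1:99, function(j) cor(g1[, j], g1[, j + 1])^2)
  expect_lt(mean(r2), 0.05)
})

test_that("genotype mean matches the binomial expectation at MAF 0.5", {
  cfg <- sim_config(n_samples = 10000, n_chromosomes = 1, n_snps = 20,
                    n_cpgs = 2, n_genes = 2, ld_block_size = 1,
                    maf_range = c(0.5, 0.5),
                    trio_architectures = data.frame(
                      architecture = "null", n = 0L, beta_lg = 0,
                      beta_gt = 0, beta_lt = 0, beta_tg = 0),
                    seed = 8)
  g <- unclass(gen_genotypes(cfg, gen_feature_map(cfg)))
  expect_true(all(abs(colMeans(g) - 1) < 0.05))
  expect_true(all(g %in% 0:2))
})

test_that("methylation stays in (0,1) and recovers the planted logit slope", {
  cfg <- small_cfg(n_samples = 500)
  ds <- simulate_dataset(cfg)
  M <- unclass(ds$methylation)
  expect_true(all(M > 0 & M < 1))
  truth <- ds$truth
  med <- truth[truth$architecture == "mediation", ]
  for (k in seq_len(nrow(med))) {
    g <- unclass(ds$genotypes)[, med$snp_id[k]]
    y <- qlogis(M[, med$cpg_id[k]])
    f <- summary(lm(y ~ g + ds$covariates$age +
                      ds$covariates$disease_status))$coefficients["g", ]
    expect_lt(abs(f[["Estimate"]] - med$beta_lg[k]),
              3 * f[["Std. Error"]])
  }
  # null CpGs: slope indistinguishable from zero
  nul <- truth[truth$architecture == "null", ][1, ]
  g <- unclass(ds$genotypes)[, nul$snp_id]
  f <- summary(lm(qlogis(M[, nul$cpg_id]) ~ g))$coefficients["g", ]
  expect_lt(abs(f[["Estimate"]]), 3 * f[["Std. Error"]])
})

test_that("mediation makes genotype and expression conditionally independent given methylation", {
  set.seed(42)
  pc <- replicate(40, {
    tr <- plant_trio(500, "mediation")
    rl <- resid(lm(tr$L ~ qlogis(tr$G)))
    rt <- resid(lm(tr$T_ ~ qlogis(tr$G)))
    cor(rl, rt)
  })
  expect_gte(mean(abs(pc) < 0.1), 0.95)
  # and the marginal genotype-expression association is present
  set.seed(43)
  psig <- replicate(40, {
    tr <- plant_trio(500, "mediation")
    fit_pair(tr$L, tr$T_, tr$cov)$p_value < 0.05
  })
  expect_gte(mean(psig), 0.95)
})

test_that("null-architecture expression is independent of the trio genotype", {
  set.seed(99)
  ps <- replicate(200, {
    tr <- plant_trio(150, "null")
    fit_pair(tr$L, tr$T_, tr$cov)$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("common-cause trios show no methylation-expression link given the SNP", {
  set.seed(7)
  ps <- replicate(1000, {
    n <- 200
    cov <- toy_covariates(n)
    L <- rbinom(n, 2, 0.3)
    G <- plogis(0.8 * L + rnorm(n))
    T_ <- 0.8 * L + rnorm(n)
    summary(lm(T_ ~ qlogis(G) + L + cov$age +
                 cov$disease_status))$coefficients[2, 4]
  })
  expect_lte(mean(ps < 0.05), 0.07)
})

test_that("truth table invariants hold and round-trip through TSV", {
  cfg <- small_cfg()
  truth <- truth_table(gen_feature_map(cfg))
  med <- truth$architecture == "mediation"
  expect_true(all(truth$beta_lg[med] != 0 & truth$beta_gt[med] != 0 &
                    truth$beta_lt[med] == 0))
  cc <- truth$architecture == "common_cause"
  expect_true(all(truth$beta_lg[cc] != 0 & truth$beta_lt[cc] != 0 &
                    truth$beta_gt[cc] == 0))
  rv <- truth$architecture == "reverse"
  expect_true(all(truth$beta_lt[rv] != 0 & truth$beta_tg[rv] != 0))
  nl <- truth$architecture == "null"
  expect_true(all(truth[nl, c("beta_lg", "beta_gt", "beta_lt",
                              "beta_tg")] == 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(truth, path)
  expect_equal(read_truth(path), truth)
})

test_that("a YAML config round-trips into sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_samples: 50", "n_chromosomes: 1", "n_snps: 30", "n_cpgs: 20",
    "n_genes: 10", "seed: 4",
    "trio_architectures:",
    "  - architecture: mediation", "    n: 2", "    beta_lg: 0.8",
    "    beta_gt: 1.0", "    beta_lt: 0.0", "    beta_tg: 0.0"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_samples, 50L)
  expect_equal(sum(cfg$trio_architectures$n), 2L)
  expect_silent(gen_feature_map(cfg))
})
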