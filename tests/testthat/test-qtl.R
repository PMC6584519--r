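test_that("cis_pairs applies the inclusive 1 Mb window on both pair kinds", {
  cfg <- scan_config("meqtl")
  pred <- data.frame(feature_id = c("rs1", "rs2", "rs3"),
                     feature_class = "snp",
                     chrom = c("chr1", "chr1", "chr2"),
                     pos = c(1500000, 3500001, 1500000),
                     stringsAsFactors = FALSE)
  resp <- data.frame(feature_id = "cg1", feature_class = "cpg",
                     chrom = "chr1", pos = 2400000, stringsAsFactors = FALSE)
  p <- cis_pairs(pred, resp, cfg)
  # rs1 at 900 kb: in; rs2 at 1,100,001 bp: out; rs3 other chromosome: out
  expect_identical(p$a_id, "rs1")
  expect_equal(p$distance_bp, -900000)
  # exact boundary is inclusive
  resp2 <- resp; resp2$pos <- 2500000
  expect_identical(cis_pairs(pred, resp2, cfg)$a_id, "rs1")
  # interval anchoring: window extends from tss and tes
  tx <- data.frame(feature_id = "tx1", feature_class = "transcript",
                   chrom = "chr1", pos = NA, tss = 2e6, tes = 2.6e6,
                   stringsAsFactors = FALSE)
  p2 <- cis_pairs(pred, tx, scan_config("eqtl"))
  expect_setequal(p2$a_id, c("rs1", "rs2"))
  expect_equal(p2$distance_bp[p2$a_id == "rs1"], -500000)
  expect_equal(p2$distance_bp[p2$a_id == "rs2"], 900001)
  # overlapping the interval gives distance 0
  predin <- pred[1, ]; predin$pos <- 2.3e6
  expect_equal(cis_pairs(predin, tx, scan_config("eqtl"))$distance_bp, 0)
})

test_that("cis_pairs errors when chromosome namespaces do not overlap", {
  pred <- data.frame(feature_id = "rs1", feature_class = "snp",
                     chrom = "1", pos = 100, stringsAsFactors = FALSE)
  resp <- data.frame(feature_id = "cg1", feature_class = "cpg",
                     chrom = "chr1", pos = 200, stringsAsFactors = FALSE)
  expect_error(cis_pairs(pred, resp, scan_config("meqtl")), "chr1")
})

test_that("cis_pairs matches the exhaustive double-loop oracle", {
  cfg <- scan_config("meqtl", cis_window_bp = 4e5)
  for (s in 1:5) {
    set.seed(s)
    lay <- random_layout(80, 40,
                         responses_are_transcripts = (s %% 2 == 0))
    got <- cis_pairs(lay$pred, lay$resp, cfg)[, c("a_id", "b_id")]
    got <- got[order(got$a_id, got$b_id), ]
    want <- cis_pairs_oracle(lay$pred, lay$resp, 4e5)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("fit_pair recovers a perfect linear relation and flags degeneracies", {
  cov <- toy_covariates(10, seed = 3)
  x <- c(1:5, 5:1)
  y <- 2 * x + 1
  f <- fit_pair(x, y, cov)
  expect_equal(f$beta_hat, 2, tolerance = 1e-10)
  expect_lt(f$p_value, 1e-12)
  # constant predictor: flagged, p = 1 by convention
  f2 <- fit_pair(rep(1, 10), rnorm(10), cov)
  expect_identical(f2$flag, "constant_predictor")
  expect_equal(f2$p_value, 1)
  # too few complete observations: flagged
  f3 <- fit_pair(c(1, 2, NA, NA, NA, NA, NA, NA, NA, NA), y, cov)
  expect_identical(f3$flag, "insufficient_n")
  expect_true(is.na(f3$p_value))
  # pairwise deletion of missing genotypes
  x4 <- x; x4[3] <- NA
  f4 <- fit_pair(x4, y, cov)
  expect_equal(f4$n_used, 9)
})

test_that("fit_pair matches the lm oracle on random instances", {
  set.seed(11)
  for (r in 1:50) {
    n <- 30
    cov <- toy_covariates(n)
    x <- rbinom(n, 2, 0.3)
    if (var(x) == 0) next
    y <- 0.3 * x + 0.02 * cov$age + rnorm(n)
    got <- fit_pair(x, y, cov)
    want <- fit_pair_oracle(x, y, cov)
    expect_equal(got$beta_hat, want$beta, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$t_stat, want$t, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("bh_fdr implements the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.9)), c(0.04, 0.04, 0.04, 0.9))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  set.seed(21)
  for (r in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})

test_that("run_scan agrees with fit_pair and is order-invariant", {
  cfg <- small_cfg(n_samples = 120)
  ds <- simulate_dataset(cfg)
  ann <- ds$annotation
  snp_ann <- ann[ann$feature_class == "snp", ]
  cpg_ann <- ann[ann$feature_class == "cpg", ]
  sc <- scan_config("meqtl")
  scan <- run_scan(ds$genotypes, ds$methylation, snp_ann, cpg_ann,
                   ds$covariates, sc)
  r <- scan$results
  expect_true(all(r$p_value >= 0 & r$p_value <= 1))
  expect_true(all(r$q_value >= 0 & r$q_value <= 1))
  expect_true(all(abs(r$distance_bp) <= 1e6))
  # fast path equals the per-pair reference on a sample of pairs
  set.seed(5)
  for (i in sample(nrow(r), 20)) {
    f <- fit_pair(unclass(ds$genotypes)[, r$a_id[i]],
                  unclass(ds$methylation)[, r$b_id[i]], ds$covariates)
    expect_equal(r$beta_hat[i], f$beta_hat, tolerance = 1e-10)
    expect_equal(r$p_value[i], f$p_value, tolerance = 1e-10)
  }
  # shuffling feature columns leaves the result set unchanged
  shuf <- function(m) {
    role <- omics_role(m); u <- unclass(m)
    omics_matrix(u[, sample(ncol(u)), drop = FALSE], role)
  }
  set.seed(9)
  scan2 <- run_scan(shuf(ds$genotypes), shuf(ds$methylation),
                    snp_ann, cpg_ann, ds$covariates, sc)
  expect_equal(scan$results, scan2$results)
  # summary unique counts match the significant table
  sig <- significant_pairs(scan)
  expect_equal(scan$summary$n_significant, nrow(sig))
  expect_equal(scan$summary$n_unique_predictors, length(unique(sig$a_id)))
  expect_equal(scan$summary$n_unique_responses, length(unique(sig$b_id)))
})

test_that("run_scan handles missing genotypes via pairwise deletion", {
  cfg <- small_cfg(n_samples = 80)
  ds <- simulate_dataset(cfg)
  ann <- ds$annotation
  g <- unclass(ds$genotypes)
  set.seed(31)
  g[sample(length(g), 200)] <- NA
  gm <- omics_matrix(g, "genotype")
  scan <- run_scan(gm, ds$methylation, ann[ann$feature_class == "snp", ],
                   ann[ann$feature_class == "cpg", ], ds$covariates,
                   scan_config("meqtl"))
  r <- scan$results
  expect_true(any(r$n_used < 80))
  i <- which(r$n_used < 80)[1]
  f <- fit_pair(g[, r$a_id[i]], unclass(ds$methylation)[, r$b_id[i]],
                ds$covariates)
  expect_equal(r$p_value[i], f$p_value, tolerance = 1e-12)
})

test_that("planted meQTLs are recovered with FDR control", {
  cfg <- small_cfg(n_samples = 500, seed = 17)
  ds <- simulate_dataset(cfg)
  ann <- ds$annotation
  scan <- run_scan(ds$genotypes, ds$methylation,
                   ann[ann$feature_class == "snp", ],
                   ann[ann$feature_class == "cpg", ],
                   ds$covariates, scan_config("meqtl"))
  sig <- significant_pairs(scan)
  truth <- ds$truth
  planted <- truth[truth$beta_lg != 0, ]
  hit <- paste(planted$snp_id, planted$cpg_id) %in%
    paste(sig$a_id, sig$b_id)
  expect_gte(mean(hit), 0.8)
})

test_that("logit transform changes the scale but keeps the cis pair set", {
  cfg <- small_cfg(n_samples = 100, seed = 23)
  ds <- simulate_dataset(cfg)
  ann <- ds$annotation
  s_raw <- run_scan(ds$genotypes, ds$methylation,
                    ann[ann$feature_class == "snp", ],
                    ann[ann$feature_class == "cpg", ], ds$covariates,
                    scan_config("meqtl"))
  s_log <- run_scan(ds$genotypes, ds$methylation,
                    ann[ann$feature_class == "snp", ],
                    ann[ann$feature_class == "cpg", ], ds$covariates,
                    scan_config("meqtl", transform = "logit"))
  expect_identical(s_raw$results[, c("a_id", "b_id")],
                   s_log$results[, c("a_id", "b_id")])
  expect_false(isTRUE(all.equal(s_raw$results$beta_hat,
                                s_log$results$beta_hat)))
})
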