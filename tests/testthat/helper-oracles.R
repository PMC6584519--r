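# Independent oracles used across the suite.  These deliberately take
# different computational routes from the package internals.

# Benjamini-Hochberg step-up, coded directly from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j on the sorted list, capped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    q[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive double-loop cis pairing.
cis_pairs_oracle <- function(predictors, responses, window) {
  rows <- list()
  for (i in seq_len(nrow(predictors))) {
    for (j in seq_len(nrow(responses))) {
      if (predictors$chrom[i] != responses$chrom[j]) next
      if (responses$feature_class[j] == "transcript") {
        hit <- predictors$pos[i] >= responses$tss[j] - window &&
          predictors$pos[i] <= responses$tes[j] + window
      } else {
        hit <- abs(predictors$pos[i] - responses$pos[j]) <= window
      }
      if (hit) {
        rows[[length(rows) + 1]] <- c(predictors$feature_id[i],
                                      responses$feature_id[j])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(a_id = character(0), b_id = character(0)))
  }
  d <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(d) <- c("a_id", "b_id")
  d[order(d$a_id, d$b_id), , drop = FALSE]
}

# stats::lm as the OLS oracle (QR route, vs the package's normal equations).
fit_pair_oracle <- function(x, y, covariates) {
  fit <- lm(y ~ x + age + disease_status,
            data = data.frame(y = y, x = x, age = covariates$age,
                              disease_status = covariates$disease_status))
  s <- summary(fit)$coefficients["x", ]
  list(beta = s[["Estimate"]], se = s[["Std. Error"]],
       t = s[["t value"]], p = s[["Pr(>|t|)"]])
}

# Random annotation layout for pairing tests.
random_layout <- function(n_pred, n_resp, n_chrom = 2, L = 5e6,
                          responses_are_transcripts = FALSE) {
  pred <- data.frame(
    feature_id = sprintf("p%04d", seq_len(n_pred)), feature_class = "snp",
    chrom = paste0("chr", sample.int(n_chrom, n_pred, replace = TRUE)),
    pos = sample.int(L, n_pred), stringsAsFactors = FALSE)
  if (responses_are_transcripts) {
    tss <- sample.int(L, n_resp)
    resp <- data.frame(
      feature_id = sprintf("r%04d", seq_len(n_resp)),
      feature_class = "transcript",
      chrom = paste0("chr", sample.int(n_chrom, n_resp, replace = TRUE)),
      pos = NA_real_, tss = tss, tes = tss + sample.int(2e5, n_resp),
      stringsAsFactors = FALSE)
  } else {
    resp <- data.frame(
      feature_id = sprintf("r%04d", seq_len(n_resp)), feature_class = "cpg",
      chrom = paste0("chr", sample.int(n_chrom, n_resp, replace = TRUE)),
      pos = sample.int(L, n_resp), stringsAsFactors = FALSE)
  }
  list(pred = pred, resp = resp)
}

# Phased two-locus haplotype panel with LD; returns genotypes plus the
# haplotype-count r2 computed directly on the known phase.
phased_ld_panel <- function(n, hap_freqs) {
  haps <- sample.int(4, 2 * n, replace = TRUE, prob = hap_freqs)
  # 1=AB, 2=Ab, 3=aB, 4=ab
  aA <- as.integer(haps %in% c(1, 2))
  aB <- as.integer(haps %in% c(1, 3))
  h1 <- seq_len(n) * 2 - 1
  h2 <- seq_len(n) * 2
  g_i <- aA[h1] + aA[h2]
  g_j <- aB[h1] + aB[h2]
  tab <- tabulate(haps, 4) / (2 * n)
  pA <- tab[1] + tab[2]; pB <- tab[1] + tab[3]
  D <- tab[1] - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(g_i = g_i, g_j = g_j, r2_true = r2)
}

# Compact simulation config shared across test files.
small_cfg <- function(n_samples = 100, seed = 11) {
  sim_config(n_samples = n_samples, n_chromosomes = 2, chrom_length_bp = 2e7,
             n_snps = 60, n_cpgs = 40, n_genes = 20,
             trio_architectures = data.frame(
               architecture = c("mediation", "common_cause", "reverse",
                                "null"),
               n = c(3L, 2L, 2L, 2L),
               beta_lg = c(0.8, 0.8, 0, 0), beta_gt = c(1, 0, 0, 0),
               beta_lt = c(0, 0.8, 0.8, 0), beta_tg = c(0, 0, 1, 0)),
             seed = seed)
}

# Small covariate table for direct vector-level tests.
toy_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             age = runif(n, 30, 70),
             disease_status = rbinom(n, 1, 0.5),
             stringsAsFactors = FALSE)
}

# Directly planted trio vectors (bypasses the full generator) for CIT
# power / type-I studies.
plant_trio <- function(n, architecture, beta_lg = 0.8, beta_gt = 1,
                       beta_lt = 0.8, beta_tg = 1, maf = 0.3) {
  cov <- toy_covariates(n)
  covm <- 0.01 * cov$age + 0.3 * cov$disease_status
  L <- rbinom(n, 2, maf)
  if (architecture == "mediation") {
    G <- plogis(beta_lg * L + covm + rnorm(n))
    T_ <- beta_gt * qlogis(G) + covm + rnorm(n)
  } else if (architecture == "common_cause") {
    G <- plogis(beta_lg * L + covm + rnorm(n))
    T_ <- beta_lt * L + covm + rnorm(n)
  } else if (architecture == "reverse") {
    T_ <- beta_lt * L + covm + rnorm(n)
    G <- plogis(beta_tg * (T_ - mean(T_)) + covm + rnorm(n))
  } else {
    G <- plogis(covm + rnorm(n))
    T_ <- covm + rnorm(n)
  }
  list(L = L, G = G, T_ = T_, cov = cov)
}
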