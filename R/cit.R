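#' Assemble SNP-methylation-mRNA trios
#'
#' Takes the combinatorial closure of the three significant pair sets: every
#' (SNP, CpG, gene) triple whose SNP-CpG pair is a significant meQTL, whose
#' CpG-gene pair is a significant eQTM and whose SNP-gene pair is a
#' significant eQTL, restricted to genes carrying a non-empty official
#' symbol.  One SNP participating in k complete chains yields k trios.
#'
#' @param meqtl_sig,eqtm_sig,eqtl_sig Significant pair tables (see
#'   [significant_pairs()]): meQTL `a_id` = SNP / `b_id` = CpG, eQTM
#'   `a_id` = CpG / `b_id` = gene, eQTL `a_id` = SNP / `b_id` = gene.
#' @param annotation Feature annotation supplying transcript gene symbols.
#' @return Data frame `snp_id`, `cpg_id`, `gene_id`, `gene_symbol`,
#'   deduplicated and sorted.
#' @export
build_trios <- function(meqtl_sig, eqtm_sig, eqtl_sig, annotation) {
  empty <- data.frame(snp_id = character(0), cpg_id = character(0),
                      gene_id = character(0), gene_symbol = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(meqtl_sig) == 0 || nrow(eqtm_sig) == 0 || nrow(eqtl_sig) == 0) {
    warning("at least one significant pair table is empty; no trios")
    return(empty)
  }
  m <- unique(data.frame(snp_id = meqtl_sig$a_id, cpg_id = meqtl_sig$b_id,
                         stringsAsFactors = FALSE))
  e <- unique(data.frame(cpg_id = eqtm_sig$a_id, gene_id = eqtm_sig$b_id,
                         stringsAsFactors = FALSE))
  q <- unique(data.frame(snp_id = eqtl_sig$a_id, gene_id = eqtl_sig$b_id,
                         stringsAsFactors = FALSE))
  t1 <- merge(m, e, by = "cpg_id")
  t2 <- merge(t1, q, by = c("snp_id", "gene_id"))
  if (nrow(t2) == 0) return(empty)
  tx <- annotation[annotation$feature_class == "transcript", , drop = FALSE]
  t2$gene_symbol <- tx$gene_symbol[match(t2$gene_id, tx$feature_id)]
  t2 <- t2[!is.na(t2$gene_symbol) & t2$gene_symbol != "", , drop = FALSE]
  t2 <- unique(t2[, c("snp_id", "cpg_id", "gene_id", "gene_symbol")])
  t2 <- t2[order(t2$snp_id, t2$cpg_id, t2$gene_id), , drop = FALSE]
  rownames(t2) <- NULL
  t2
}

#' Causal inference test for one trio
#'
#' Tests whether methylation G mediates the effect of genotype L on
#' expression T by requiring four conditions simultaneously, all adjusted
#' for the covariates (age, disease status):
#' \enumerate{
#'   \item L and T are associated (`p1`: L in `T ~ L + cov`);
#'   \item L is associated with G after adjusting for T (`p2`: L in
#'     `G ~ L + T + cov`);
#'   \item G is associated with T after adjusting for L (`p3`: G in
#'     `T ~ G + L + cov`);
#'   \item L is independent of T given G (`p4`), assessed by a permutation
#'     equivalence test: with `F_obs` the F statistic for L in
#'     `T ~ L + G + cov`, fit `G ~ L + cov`, keep fitted values and
#'     residuals, and for each of B permutations recombine the fitted values
#'     with permuted residuals into `G*`, recompute `F*` for L in
#'     `T ~ L + G* + cov`; `p4 = (1 + #\{F* <= F_obs\}) / (B + 1)`.
#' }
#' The omnibus CIT p-value is the maximum of the four component p-values;
#' the trio is called a mediation chain when `p_cit < alpha`.
#'
#' @param L Genotype vector (0/1/2).
#' @param G Methylation vector.
#' @param T_ Expression vector.
#' @param covariates Covariate data frame aligned with the vectors.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param alpha Significance level for the mediation verdict.
#' @return One-row data frame: `p1`..`p4`, `p_cit`, `sign_lg`, `sign_gt`
#'   (signs of the marginal SNP->methylation and methylation->expression
#'   slopes, for network edge colouring), `n_used`, `n_permutations`,
#'   `seed`, `flag`, `verdict`.
#' @export
cit_test <- function(L, G, T_, covariates, B = 1000L, seed = 1L,
                     alpha = 0.05) {
  stopifnot(B >= 100)
  Z <- covariate_design(covariates)
  ok <- stats::complete.cases(L, G, T_, Z)
  L <- L[ok]; G <- G[ok]; T_ <- T_[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(L)
  res <- data.frame(p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
                    p4 = NA_real_, p_cit = NA_real_,
                    sign_lg = NA_integer_, sign_gt = NA_integer_,
                    n_used = n, n_permutations = as.integer(B),
                    seed = as.integer(seed), flag = "ok",
                    verdict = FALSE, stringsAsFactors = FALSE)
  degenerate <- n < 10 || stats::var(L) < .Machine$double.eps ||
    stats::var(G) < .Machine$double.eps ||
    stats::var(T_) < .Machine$double.eps
  if (degenerate) {
    res$flag <- "degenerate"
    res$p_cit <- 1
    return(res)
  }
  one <- rep(1, n)
  f1 <- ols_fit(cbind(one, L, Z), T_)          # T ~ L + cov
  f2 <- ols_fit(cbind(one, L, T_, Z), G)       # G ~ L + T + cov
  f3 <- ols_fit(cbind(one, G, L, Z), T_)       # T ~ G + L + cov
  fm <- ols_fit(cbind(one, L, G, Z), T_)       # F_obs for L given G
  fg <- ols_fit(cbind(one, L, Z), G)           # G ~ L + cov (perm base)
  fgt <- ols_fit(cbind(one, G, Z), T_)         # marginal eQTM sign
  if (is.null(f1) || is.null(f2) || is.null(f3) || is.null(fm) ||
      is.null(fg) || is.null(fgt)) {
    res$flag <- "degenerate"
    res$p_cit <- 1
    return(res)
  }
  res$p1 <- f1$p[2]
  res$p2 <- f2$p[2]
  res$p3 <- f3$p[2]
  F_obs <- fm$t[2]^2
  set.seed(seed)
  Fstar <- numeric(B)
  for (b in seq_len(B)) {
    Gstar <- fg$fitted + fg$resid[sample.int(n)]
    fb <- ols_fit(cbind(one, L, Gstar, Z), T_)
    Fstar[b] <- if (is.null(fb)) Inf else fb$t[2]^2
  }
  res$p4 <- (1 + sum(Fstar <= F_obs)) / (B + 1)
  res$p_cit <- max(res$p1, res$p2, res$p3, res$p4)
  res$sign_lg <- as.integer(sign(fg$beta[2]))
  res$sign_gt <- as.integer(sign(fgt$beta[2]))
  res$verdict <- res$p_cit < alpha
  res
}

#' Run the CIT over a batch of trios
#'
#' Each trio gets a deterministic per-trio seed derived from the batch seed
#' and the trio index, so results are reproducible and independent of
#' evaluation order.  Trios referencing features absent from the matrices
#' are skipped with a message.
#'
#' @param trios Trio table from [build_trios()].
#' @param genotypes,methylation,expression Sample-aligned `omics_matrix`
#'   objects.
#' @param covariates Covariate data frame.
#' @param B Permutations per trio.
#' @param seed Batch master seed.
#' @param alpha Significance level for the mediation verdict.
#' @return A list of class `cit_batch`: `results` (trio columns + the
#'   [cit_test()] columns) and `summary` (`n_tested`, `n_significant`,
#'   unique SNP/CpG/gene counts among significant trios).
#' @export
cit_batch <- function(trios, genotypes, methylation, expression, covariates,
                      B = 1000L, seed = 1L, alpha = 0.05) {
  G <- unclass(genotypes); M <- unclass(methylation); E <- unclass(expression)
  rows <- vector("list", nrow(trios))
  if (nrow(trios) > 0) {
    for (i in seq_len(nrow(trios))) {
      tr <- trios[i, ]
      if (!(tr$snp_id %in% colnames(G)) || !(tr$cpg_id %in% colnames(M)) ||
          !(tr$gene_id %in% colnames(E))) {
        message("cit_batch: skipping trio ", i, " (feature missing)")
        next
      }
      r <- cit_test(G[, tr$snp_id], M[, tr$cpg_id], E[, tr$gene_id],
                    covariates, B = B, seed = derive_seed(seed, paste0("trio", i)),
                    alpha = alpha)
      rows[[i]] <- cbind(trios[i, , drop = FALSE], r)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  results <- if (length(rows)) do.call(rbind, rows) else
    cbind(trios[0, , drop = FALSE],
          data.frame(p1 = numeric(0), p2 = numeric(0), p3 = numeric(0),
                     p4 = numeric(0), p_cit = numeric(0),
                     sign_lg = integer(0), sign_gt = integer(0),
                     n_used = integer(0), n_permutations = integer(0),
                     seed = integer(0), flag = character(0),
                     verdict = logical(0), stringsAsFactors = FALSE))
  rownames(results) <- NULL
  sig <- results[results$verdict %in% TRUE, , drop = FALSE]
  structure(list(results = results,
                 summary = list(n_tested = nrow(results),
                                n_significant = nrow(sig),
                                n_unique_snps = length(unique(sig$snp_id)),
                                n_unique_cpgs = length(unique(sig$cpg_id)),
                                n_unique_genes = length(unique(sig$gene_id))),
                 alpha = alpha),
            class = "cit_batch")
}

#' @export
print.cit_batch <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("cit_batch: %d trios tested, %d significant at alpha ",
                     "%g (%d SNPs, %d CpGs, %d genes)\n"),
              s$n_tested, s$n_significant, x$alpha, s$n_unique_snps,
              s$n_unique_cpgs, s$n_unique_genes))
  invisible(x)
}
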