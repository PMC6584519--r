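#' Two-locus haplotype-frequency EM and LD measures
#'
#' Estimates the four haplotype frequencies of a pair of biallelic loci from
#' unphased additive genotypes by expectation-maximization over the
#' double-heterozygote phase ambiguity, then derives the disequilibrium
#' coefficient `D = pAB - pA*pB`, the normalized `D'` and the squared
#' allelic correlation `r2 = D^2 / (pA qA pB qB)`.  `r2 = 0` means the loci
#' are independent; `r2 = 1` means the alleles at the two loci track each
#' other exactly.  Frequencies are initialized at linkage-equilibrium
#' products and iterated until the maximum frequency change drops below
#' 1e-8 (at most 1000 iterations); the observed-data log-likelihood is
#' non-decreasing across iterations.
#'
#' @param g_i,g_j Genotype vectors in \{0,1,2\} (NA allowed; pairwise
#'   complete observations are used).
#' @return A list of class `ld_result`: `hap_freqs` (named `pAB`, `pAb`,
#'   `paB`, `pab`, summing to 1), `d`, `d_prime`, `r2`, `em_iterations`,
#'   `converged`, `n_used`, `loglik`.
#' @export
em_haplotypes <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  a <- g_i[ok]; b <- g_j[ok]
  if (any(!a %in% 0:2) || any(!b %in% 0:2)) {
    stop("genotypes must be coded 0/1/2")
  }
  n <- length(a)
  if (n < 2) stop("need at least 2 complete genotype pairs")
  pA <- mean(a) / 2; pB <- mean(b) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("LD is undefined for a monomorphic locus")
  }
  # genotype cell counts n[a+1, b+1]
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[a[i] + 1, b[i] + 1] <- cnt[a[i] + 1, b[i] + 1] + 1
  # unambiguous haplotype counts (A = dosage allele at locus i, B at j)
  base <- c(AB = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
            Ab = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
            aB = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
            ab = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1])
  ndh <- cnt[2, 2]                       # double heterozygotes
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  ll <- ld_loglik(p, cnt)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(1000L)) {
    iters <- it
    den <- p[1] * p[4] + p[2] * p[3]
    x <- if (den > 0) p[1] * p[4] / den else 0.5   # E[cis phase | 1/1]
    newp <- unname(base + ndh * c(x, 1 - x, 1 - x, x)) / (2 * n)
    delta <- max(abs(newp - p))
    p <- newp
    newll <- ld_loglik(p, cnt)
    if (newll < ll - 1e-9) {
      warning("EM log-likelihood decreased; numerical trouble")
    }
    ll <- newll
    if (delta < 1e-8) {
      converged <- TRUE
      break
    }
  }
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  D <- p[1] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- D^2 / denom
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (abs(D) < 1e-12 || dmax < 1e-12) 0 else abs(D) / dmax
  structure(list(hap_freqs = c(pAB = p[1], pAb = p[2], paB = p[3],
                               pab = p[4]),
                 d = D, d_prime = min(d_prime, 1), r2 = min(r2, 1),
                 em_iterations = iters, converged = converged, n_used = n,
                 loglik = ll),
            class = "ld_result")
}

# observed-data log-likelihood of the 3x3 genotype table under haplotype
# frequencies p = (pAB, pAb, paB, pab), random mating
ld_loglik <- function(p, cnt) {
  P <- matrix(0, 3, 3)
  P[1, 1] <- p[4]^2;        P[1, 2] <- 2 * p[3] * p[4]; P[1, 3] <- p[3]^2
  P[2, 1] <- 2 * p[2] * p[4]
  P[2, 2] <- 2 * p[1] * p[4] + 2 * p[2] * p[3]
  P[2, 3] <- 2 * p[1] * p[3]
  P[3, 1] <- p[2]^2;        P[3, 2] <- 2 * p[1] * p[2]; P[3, 3] <- p[1]^2
  use <- cnt > 0
  sum(cnt[use] * log(pmax(P[use], 1e-300)))
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("ld_result: r2 = %.4f, D' = %.4f (%d EM iterations%s)\n",
              x$r2, x$d_prime, x$em_iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Pairwise LD across a SNP set
#'
#' Runs [em_haplotypes()] on every upper-triangle pair of the given SNPs.
#' Per-pair failures (e.g. a monomorphic locus) are propagated as flagged
#' rows with `r2 = NA`.
#'
#' @param genotypes Genotype `omics_matrix` (samples x SNPs).
#' @param snp_ids Optional subset of SNP column names (default: all, in
#'   column order; at least 2).
#' @return Data frame `snp_i`, `snp_j`, `r2`, `d_prime`, `em_iterations`,
#'   `converged`, `flag`, with `k(k-1)/2` rows for k SNPs.
#' @export
ld_matrix <- function(genotypes, snp_ids = NULL) {
  G <- unclass(genotypes)
  snp_ids <- snp_ids %||% colnames(G)
  if (!all(snp_ids %in% colnames(G))) stop("unknown SNP id(s)")
  k <- length(snp_ids)
  if (k < 2) stop("need at least 2 SNPs")
  out <- vector("list", k * (k - 1) / 2)
  idx <- 0L
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      idx <- idx + 1L
      r <- tryCatch(em_haplotypes(G[, snp_ids[i]], G[, snp_ids[j]]),
                    error = function(e) e)
      out[[idx]] <- if (inherits(r, "error")) {
        data.frame(snp_i = snp_ids[i], snp_j = snp_ids[j], r2 = NA_real_,
                   d_prime = NA_real_, em_iterations = NA_integer_,
                   converged = FALSE, flag = conditionMessage(r),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(snp_i = snp_ids[i], snp_j = snp_ids[j], r2 = r$r2,
                   d_prime = r$d_prime, em_iterations = r$em_iterations,
                   converged = r$converged, flag = "ok",
                   stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' LD summary for a named SNP group
#'
#' Minimum and mean pairwise r-squared within a SNP set -- the quantity used
#' to describe how tightly a group of SNPs feeding the same methylation
#' site is linked.
#'
#' @inheritParams ld_matrix
#' @return List `n_snps`, `n_pairs`, `min_r2`, `mean_r2`.
#' @export
ld_group_summary <- function(genotypes, snp_ids = NULL) {
  tab <- ld_matrix(genotypes, snp_ids)
  ok <- tab[tab$flag == "ok", , drop = FALSE]
  list(n_snps = length(snp_ids %||% colnames(unclass(genotypes))),
       n_pairs = nrow(ok),
       min_r2 = if (nrow(ok)) min(ok$r2) else NA_real_,
       mean_r2 = if (nrow(ok)) mean(ok$r2) else NA_real_)
}
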