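#' Scan configuration
#'
#' @param pair_type One of `"meqtl"` (SNP -> CpG), `"eqtm"`
#'   (CpG -> transcript), `"eqtl"` (SNP -> transcript).
#' @param cis_window_bp Cis window in bp (default 1 Mb, boundary inclusive).
#' @param fdr_threshold Benjamini-Hochberg FDR threshold (default 0.05).
#' @param transform `"none"` (default: methylation analysed on the raw beta
#'   scale) or `"logit"` (methylation predictors/responses logit
#'   transformed before regression).
#' @return A `scan_config` list.
#' @export
scan_config <- function(pair_type = c("meqtl", "eqtm", "eqtl"),
                        cis_window_bp = 1e6, fdr_threshold = 0.05,
                        transform = c("none", "logit")) {
  pair_type <- match.arg(pair_type)
  transform <- match.arg(transform)
  stopifnot(cis_window_bp > 0, fdr_threshold > 0, fdr_threshold < 1)
  structure(list(pair_type = pair_type,
                 cis_window_bp = as.numeric(cis_window_bp),
                 fdr_threshold = fdr_threshold, transform = transform),
            class = "scan_config")
}

#' Enumerate cis candidate pairs
#'
#' A point predictor (SNP or CpG) is paired with a point response (CpG) iff
#' they share a chromosome and their positions differ by at most the window;
#' with an interval response (transcript) iff its position falls within
#' `[tss - window, tes + window]`.  Boundaries are inclusive.  The signed
#' distance is predictor - response for point pairs, and 0 when the
#' predictor overlaps the transcript interval, otherwise the signed distance
#' to the nearest interval edge.
#'
#' @param predictors,responses Feature-annotation data frames (predictors
#'   must be point features; responses may be point or transcript rows).
#' @param cfg A [scan_config()].
#' @return Data frame `a_id` (predictor), `b_id` (response), `distance_bp`,
#'   sorted by (response chrom, response position, predictor position).
#' @export
cis_pairs <- function(predictors, responses, cfg) {
  stopifnot(nrow(predictors) > 0, nrow(responses) > 0)
  w <- cfg$cis_window_bp
  shared <- intersect(unique(predictors$chrom), unique(responses$chrom))
  if (length(shared) == 0) {
    stop("no shared chromosome names between predictors (",
         paste(unique(predictors$chrom), collapse = ","), ") and responses (",
         paste(unique(responses$chrom), collapse = ","), ")")
  }
  interval <- all(responses$feature_class == "transcript")
  out <- vector("list", length(shared))
  for (ci in seq_along(shared)) {
    ch <- shared[ci]
    p <- predictors[predictors$chrom == ch, , drop = FALSE]
    r <- responses[responses$chrom == ch, , drop = FALSE]
    if (!nrow(p) || !nrow(r)) next
    po <- order(p$pos)
    p <- p[po, , drop = FALSE]
    lo <- if (interval) r$tss - w else r$pos - w
    hi <- if (interval) r$tes + w else r$pos + w
    i0 <- findInterval(lo - 0.5, p$pos)      # predictors with pos >= lo
    i1 <- findInterval(hi + 0.5, p$pos)      # predictors with pos <= hi
    nper <- pmax(0L, i1 - i0)
    if (!sum(nper)) next
    ridx <- rep(seq_len(nrow(r)), nper)
    pidx <- unlist(lapply(seq_len(nrow(r)), function(k) {
      if (nper[k] > 0) (i0[k] + 1L):i1[k] else integer(0)
    }))
    d <- if (interval) {
      dl <- p$pos[pidx] - r$tss[ridx]   # < 0: predictor upstream of tss
      dr <- p$pos[pidx] - r$tes[ridx]   # > 0: predictor downstream of tes
      ifelse(dl < 0, dl, pmax(dr, 0))
    } else {
      p$pos[pidx] - r$pos[ridx]
    }
    rpos <- if (interval) r$tss else r$pos
    out[[ci]] <- data.frame(a_id = p$feature_id[pidx],
                            b_id = r$feature_id[ridx],
                            distance_bp = d,
                            .rchrom = ch, .rpos = rpos[ridx],
                            .ppos = p$pos[pidx],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(a_id = character(0), b_id = character(0),
                      distance_bp = numeric(0)))
  }
  res <- res[order(res$.rchrom, res$.rpos, res$.ppos), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("a_id", "b_id", "distance_bp")]
}

#' Fit one covariate-adjusted association
#'
#' Ordinary least squares of the response on `[1, x, age, disease]` after
#' pairwise deletion of missing observations; reports the slope, its
#' standard error, the t statistic and two-sided p for the predictor
#' coefficient with `df = n_used - 4`.  A predictor that is constant after
#' deletion is flagged with `p = 1` by convention; fewer than 5 complete
#' observations yields flag `"insufficient_n"` with `p = NA`.
#'
#' @param x Predictor vector (may contain NA for genotypes).
#' @param y Response vector.
#' @param covariates Covariate data frame aligned with `x`/`y`.
#' @return One-row data frame: `n_used`, `beta_hat`, `se`, `t_stat`,
#'   `p_value`, `flag` (`"ok"`, `"constant_predictor"`, `"insufficient_n"`).
#' @export
fit_pair <- function(x, y, covariates) {
  Z <- covariate_design(covariates)
  ok <- !is.na(x) & !is.na(y)
  n_used <- sum(ok)
  res <- data.frame(n_used = n_used, beta_hat = NA_real_, se = NA_real_,
                    t_stat = NA_real_, p_value = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  if (n_used < 5) {
    res$flag <- "insufficient_n"
    return(res)
  }
  xs <- x[ok]
  if (stats::var(xs) < .Machine$double.eps) {
    res$flag <- "constant_predictor"
    res$p_value <- 1
    return(res)
  }
  X <- cbind(1, xs, Z[ok, , drop = FALSE])
  f <- ols_fit(X, y[ok])
  if (is.null(f)) {
    res$flag <- "constant_predictor"
    res$p_value <- 1
    return(res)
  }
  res$beta_hat <- f$beta[2]; res$se <- f$se[2]
  res$t_stat <- f$t[2]; res$p_value <- f$p[2]
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: on the sorted p-values,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0,1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Run a cis-QTL scan
#'
#' Enumerates cis pairs between the predictor and response annotations,
#' fits the covariate-adjusted regression for each pair and applies BH FDR
#' over all tests of the scan jointly.  Predictors without missing values go
#' through a vectorized Frisch-Waugh path (residualize predictors and
#' responses on the covariate design once, then slope/t from residual cross
#' products -- identical to the per-pair OLS with `df = n - 4`); predictors
#' with missing genotypes fall back to [fit_pair()] with pairwise deletion.
#'
#' @param predictors,responses `omics_matrix` objects (samples x features),
#'   sample-aligned (see [align_samples()]).
#' @param predictor_ann,response_ann Annotation tables covering the matrix
#'   features.
#' @param covariates Covariate data frame aligned with the matrices.
#' @param cfg A [scan_config()].
#' @return A list of class `scan_result`: `results` (one row per cis pair:
#'   `a_id`, `b_id`, `n_used`, `beta_hat`, `se`, `t_stat`, `p_value`,
#'   `q_value`, `distance_bp`, `flag`) and `summary` (`n_tests`,
#'   `n_significant`, `max_p_significant`, `n_unique_predictors`,
#'   `n_unique_responses` -- the last three over the significant set).
#' @export
run_scan <- function(predictors, responses, predictor_ann, response_ann,
                     covariates, cfg) {
  X <- unclass(predictors); Y <- unclass(responses)
  if (nrow(X) != nrow(Y)) stop("predictor/response sample counts differ")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    stop("samples are not aligned; run align_samples() first")
  }
  n <- nrow(X)
  if (n <= 5) stop("need more than 5 samples for a covariate-adjusted scan")
  if (cfg$transform == "logit") {
    if (identical(attr(predictors, "role"), "methylation-beta")) {
      X <- stats::qlogis(X)
    }
    if (identical(attr(responses, "role"), "methylation-beta")) {
      Y <- stats::qlogis(Y)
    }
  }
  pann <- predictor_ann[predictor_ann$feature_id %in% colnames(X), ,
                        drop = FALSE]
  rann <- response_ann[response_ann$feature_id %in% colnames(Y), ,
                       drop = FALSE]
  pairs <- cis_pairs(pann, rann, cfg)
  if (nrow(pairs) == 0) {
    warning("no cis pairs within the window; empty scan")
    empty <- data.frame(a_id = character(0), b_id = character(0),
                        n_used = integer(0), beta_hat = numeric(0),
                        se = numeric(0), t_stat = numeric(0),
                        p_value = numeric(0), q_value = numeric(0),
                        distance_bp = numeric(0), flag = character(0))
    return(structure(list(results = empty,
                          summary = scan_summary(empty, cfg), config = cfg),
                     class = "scan_result"))
  }
  W <- cbind(1, covariate_design(covariates, rownames(X) %||% NULL))
  qW <- qr(W)
  ca <- match(pairs$a_id, colnames(X))
  cb <- match(pairs$b_id, colnames(Y))
  if (anyNA(ca) || anyNA(cb)) stop("annotation references features absent from the matrices")
  na_pred <- colSums(is.na(X)) > 0
  Xz <- X
  if (any(na_pred)) Xz[is.na(Xz)] <- 0  # placeholder; redone via fit_pair
  RX <- qr.resid(qW, Xz)
  RY <- qr.resid(qW, Y)
  sxx <- colSums(RX^2)
  syy <- colSums(RY^2)
  nb <- nrow(pairs)
  sxy <- numeric(nb)
  step <- 2000L
  for (s in seq(1L, nb, by = step)) {
    idx <- s:min(s + step - 1L, nb)
    sxy[idx] <- colSums(RX[, ca[idx], drop = FALSE] *
                        RY[, cb[idx], drop = FALSE])
  }
  df <- n - 4
  beta <- sxy / sxx[ca]
  rss <- pmax(syy[cb] - beta * sxy, 0)
  se <- sqrt((rss / df) / sxx[ca])
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  out <- data.frame(a_id = pairs$a_id, b_id = pairs$b_id, n_used = n,
                    beta_hat = beta, se = se, t_stat = tstat,
                    p_value = pval, q_value = NA_real_,
                    distance_bp = pairs$distance_bp, flag = "ok",
                    stringsAsFactors = FALSE)
  const <- which(!na_pred[ca] & sxx[ca] < n * .Machine$double.eps)
  if (length(const)) {
    out$flag[const] <- "constant_predictor"
    out$p_value[const] <- 1
    out$beta_hat[const] <- NA_real_
    out$se[const] <- NA_real_; out$t_stat[const] <- NA_real_
  }
  # pairwise-complete fallback for predictors with missing genotypes
  redo <- which(na_pred[ca])
  for (i in redo) {
    f <- fit_pair(X[, ca[i]], Y[, cb[i]], covariates)
    out$n_used[i] <- f$n_used; out$beta_hat[i] <- f$beta_hat
    out$se[i] <- f$se; out$t_stat[i] <- f$t_stat
    out$p_value[i] <- f$p_value; out$flag[i] <- f$flag
  }
  skipped <- out$flag == "insufficient_n"
  if (any(skipped)) {
    message("run_scan: skipped ", sum(skipped),
            " pair(s) with fewer than 5 complete observations")
    out <- out[!skipped, , drop = FALSE]
    rownames(out) <- NULL
  }
  out$q_value <- bh_fdr(out$p_value)
  structure(list(results = out, summary = scan_summary(out, cfg),
                 config = cfg),
            class = "scan_result")
}

scan_summary <- function(results, cfg) {
  sig <- results[!is.na(results$q_value) &
                 results$q_value < cfg$fdr_threshold, , drop = FALSE]
  list(n_tests = nrow(results),
       n_significant = nrow(sig),
       max_p_significant = if (nrow(sig)) max(sig$p_value) else NA_real_,
       n_unique_predictors = length(unique(sig$a_id)),
       n_unique_responses = length(unique(sig$b_id)))
}

#' @export
print.scan_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("scan_result [%s]: %d tests, %d significant at FDR %g ",
                     "(%d predictors, %d responses)\n"),
              x$config$pair_type, s$n_tests, s$n_significant,
              x$config$fdr_threshold, s$n_unique_predictors,
              s$n_unique_responses))
  invisible(x)
}

#' Significant pairs of a scan
#'
#' @param scan A `scan_result`.
#' @return The rows of `scan$results` with `q_value` below the scan's FDR
#'   threshold.
#' @export
significant_pairs <- function(scan) {
  r <- scan$results
  r[!is.na(r$q_value) & r$q_value < scan$config$fdr_threshold, , drop = FALSE]
}
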