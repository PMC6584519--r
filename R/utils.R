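# Internal numerics shared across modules.

# Deterministic sub-seed from a master seed and a stage tag, kept < 2^31 so it
# is a valid R integer seed.  Used so each generator stage has its own stream
# and is reproducible independently of call order.
derive_seed <- function(seed, tag) {
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 1663 + 11) %% 2147483629)
}

# OLS via normal equations + Cholesky.  Returns NULL on a (numerically)
# rank-deficient design; callers translate that into a degenerate flag.
ols_fit <- function(X, y) {
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  beta <- backsolve(R, backsolve(R, crossprod(X, y), transpose = TRUE))
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df <- length(y) - ncol(X)
  rss <- sum(resid * resid)
  se <- sqrt(diag(chol2inv(R)) * rss / df)
  tval <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       df = df, rss = rss, fitted = fitted, resid = resid)
}

# Percent rounding: half-up to `digits` decimals (commercial rounding, not
# banker's), the style used for printed category percentages.
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

# Covariate design columns (age, disease) from a covariate table, aligned to
# the given sample ids.
covariate_design <- function(covariates, sample_ids = NULL) {
  stopifnot(is.data.frame(covariates),
            all(c("sample_id", "age", "disease_status") %in% names(covariates)))
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, covariates$sample_id)
    if (anyNA(idx)) {
      stop("covariate table is missing samples: ",
           paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
    }
    covariates <- covariates[idx, , drop = FALSE]
  }
  cbind(age = covariates$age, disease = covariates$disease_status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
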