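#' Construct an omics matrix
#'
#' An omics matrix is a numeric samples x features matrix carrying a `role`
#' attribute that states which omics layer it holds and drives range
#' validation: methylation beta values must lie in \[0,1\], genotypes must be
#' additive allele dosages in \{0,1,2\} (missing allowed for genotypes only),
#' and log2 expression is unconstrained.
#'
#' @param values Numeric matrix, samples in rows, features in columns, with
#'   unique row and column names.
#' @param role One of `"genotype"`, `"methylation-beta"`, `"log2-expression"`.
#' @return The matrix with class `omics_matrix` and a `role` attribute.
#' @export
omics_matrix <- function(values, role = c("genotype", "methylation-beta",
                                          "log2-expression")) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have sample rownames and feature colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicated feature ids")
  validate_role_values(values, role)
  structure(values, role = role, class = c("omics_matrix", class(values)))
}

validate_role_values <- function(values, role) {
  v <- values[!is.na(values)]
  if (role == "methylation-beta") {
    if (anyNA(values)) stop("missing values are only allowed for genotypes")
    bad <- v < 0 | v > 1
    if (any(bad)) {
      j <- which(is.na(values) | values < 0 | values > 1, arr.ind = TRUE)[1, 2]
      stop("methylation beta outside [0,1] in feature ", colnames(values)[j])
    }
  } else if (role == "genotype") {
    if (any(!v %in% c(0, 1, 2))) {
      j <- which(!is.na(values) & !(values %in% c(0, 1, 2)),
                 arr.ind = TRUE)[1, 2]
      stop("genotype value outside {0,1,2} in feature ", colnames(values)[j])
    }
  } else {
    if (anyNA(values)) stop("missing values are only allowed for genotypes")
  }
  invisible(TRUE)
}

#' @rdname omics_matrix
#' @param x An `omics_matrix`.
#' @export
omics_role <- function(x) attr(x, "role")

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d samples x %d features\n",
              attr(x, "role"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read / write an omics matrix as TSV
#'
#' Files store features as rows (the microarray convention): first column
#' `feature_id`, remaining columns one per sample.  In memory the matrix is
#' transposed to samples x features.
#'
#' @param path File path.
#' @param role Omics role passed to [omics_matrix()].
#' @return `read_matrix` returns an [omics_matrix()]; `write_matrix` returns
#'   the path invisibly.
#' @export
read_matrix <- function(path, role) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("matrix file needs a feature_id column plus samples")
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids)) stop("duplicated feature ids in ", path)
  m <- t(as.matrix(d[, -1, drop = FALSE]))
  storage.mode(m) <- "double"
  colnames(m) <- ids
  omics_matrix(m, role)
}

#' @rdname read_matrix
#' @param x An `omics_matrix` (or plain samples x features matrix).
#' @export
write_matrix <- function(x, path) {
  out <- data.frame(feature_id = colnames(x), t(unclass(x)),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import genotypes from a VCF
#'
#' Reads GT fields from a VCF and codes genotypes additively as the count of
#' ALT alleles (0/1 -> 1, 1|1 -> 2, ./. -> missing).  Multiallelic records are
#' skipped with a warning; only biallelic sites are imported.
#'
#' @param path Path to a VCF file.
#' @return An [omics_matrix()] with role `"genotype"`, samples x sites,
#'   sample order as in the VCF header.
#' @export
import_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(rownames(vcf@fix), names(gt)))
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  keep <- which(!multi)
  dose <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  m <- matrix(NA_real_, nrow = ncol(gt), ncol = length(keep),
              dimnames = list(colnames(gt), ids[keep]))
  for (k in seq_along(keep)) {
    m[, k] <- vapply(gt[keep[k], ], dose, numeric(1), USE.NAMES = FALSE)
  }
  omics_matrix(m, "genotype")
}

#' Read / write feature annotation
#'
#' Annotation tables carry one row per feature with columns `feature_id`,
#' `feature_class` (snp, cpg, transcript), `chrom`, `pos` (1-based, point
#' features), `strand`/`tss`/`tes` (transcripts; tss <= tes in genomic
#' coordinates regardless of strand), `gene_symbol`, `cpg_island_category`
#' and `gene_region_category`.
#'
#' @param path File path.
#' @return A data frame with the annotation columns.
#' @export
read_annotation <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  validate_annotation(d)
  d
}

#' @rdname read_annotation
#' @param annotation Annotation data frame.
#' @export
write_annotation <- function(annotation, path) {
  validate_annotation(annotation)
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

cpg_island_levels <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                       "OpenSea")
gene_region_levels <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                        "3'UTR", "Intergenic")

validate_annotation <- function(d) {
  need <- c("feature_id", "feature_class", "chrom")
  if (!all(need %in% names(d))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$feature_id)) stop("duplicated feature ids in annotation")
  if (!all(d$feature_class %in% c("snp", "cpg", "transcript"))) {
    stop("feature_class must be snp, cpg or transcript")
  }
  pt <- d$feature_class %in% c("snp", "cpg")
  if (any(pt) && (!"pos" %in% names(d) || any(is.na(d$pos[pt])) ||
                  any(d$pos[pt] < 1))) {
    stop("point features need pos >= 1")
  }
  tr <- d$feature_class == "transcript"
  if (any(tr)) {
    if (!all(c("tss", "tes") %in% names(d))) stop("transcripts need tss/tes")
    if (any(is.na(d$tss[tr])) || any(is.na(d$tes[tr])) ||
        any(d$tss[tr] > d$tes[tr])) {
      stop("transcripts need tss <= tes in genomic coordinates")
    }
  }
  cg <- d$feature_class == "cpg"
  if (any(cg) && "cpg_island_category" %in% names(d)) {
    cat_ok <- is.na(d$cpg_island_category[cg]) |
      d$cpg_island_category[cg] %in% cpg_island_levels
    if (!all(cat_ok)) stop("unknown cpg_island_category value")
  }
  invisible(TRUE)
}

#' Read / write the covariate table
#'
#' Covariates are one row per sample: `sample_id`, `age` (years) and
#' `disease_status` (0/1).  No missing values are allowed.
#'
#' @param path File path.
#' @return A covariate data frame.
#' @export
read_covariates <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_covariates(d)
  d
}

#' @rdname read_covariates
#' @param covariates Covariate data frame.
#' @export
write_covariates <- function(covariates, path) {
  validate_covariates(covariates)
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_covariates <- function(d) {
  need <- c("sample_id", "age", "disease_status")
  if (!all(need %in% names(d))) {
    stop("covariates must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) stop("duplicated sample ids in covariates")
  if (anyNA(d[need])) stop("covariates must not contain missing values")
  if (!all(d$disease_status %in% c(0, 1))) stop("disease_status must be 0/1")
  invisible(TRUE)
}

#' Read / write a trio truth table
#'
#' The truth table records the planted causal architecture of each simulated
#' trio: ids of the SNP/CpG/gene, the architecture label and the four planted
#' effects (`beta_lg` SNP->methylation, `beta_gt` methylation->expression,
#' `beta_lt` direct SNP->expression, `beta_tg` expression->methylation).
#'
#' @param path File path.
#' @return A truth-table data frame.
#' @export
read_truth <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_truth(d)
  d
}

#' @rdname read_truth
#' @param truth Truth-table data frame.
#' @export
write_truth <- function(truth, path) {
  validate_truth(truth)
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

architecture_levels <- c("mediation", "common_cause", "reverse", "null")

validate_truth <- function(d) {
  need <- c("snp_id", "cpg_id", "gene_id", "architecture",
            "beta_lg", "beta_gt", "beta_lt", "beta_tg")
  if (!all(need %in% names(d))) {
    stop("truth table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(d$architecture %in% architecture_levels)) {
    stop("architecture labels must be in: ",
         paste(architecture_levels, collapse = ", "))
  }
  invisible(TRUE)
}

#' Align samples across omics layers
#'
#' Restricts every matrix and the covariate table to the intersection of
#' their sample ids, in a single shared order (order of appearance in the
#' first matrix).  The number of dropped samples is reported on standard
#' error.
#'
#' @param matrices Named list of `omics_matrix` objects (>= 1).
#' @param covariates Covariate data frame.
#' @return A list with elements `matrices` (aligned named list) and
#'   `covariates` (aligned data frame).
#' @export
align_samples <- function(matrices, covariates) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  validate_covariates(covariates)
  idsets <- c(lapply(matrices, rownames), list(covariates$sample_id))
  common <- Reduce(intersect, idsets)
  if (length(common) == 0) stop("no samples shared across inputs")
  keep <- idsets[[1]][idsets[[1]] %in% common]
  dropped <- sum(vapply(idsets, function(s) sum(!s %in% common), integer(1)))
  if (dropped > 0) message("align_samples: dropped ", dropped,
                           " sample entries outside the common set")
  out <- lapply(matrices, function(m) {
    role <- attr(m, "role")
    omics_matrix(unclass(m)[keep, , drop = FALSE], role)
  })
  cov <- covariates[match(keep, covariates$sample_id), , drop = FALSE]
  rownames(cov) <- NULL
  list(matrices = out, covariates = cov)
}
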