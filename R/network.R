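#' Category breakdown of significant pairs
#'
#' Counts significant pairs per annotation category of the paired feature
#' and reports percentages of the total significant pair count, rounded
#' half-up to two decimals.  For the CpG island-relation attribute,
#' aggregate roll-ups are appended: `Shore` (N + S shores), `Shelf`
#' (N + S shelves) and `CpG_region` (Island + Shores + Shelves), the
#' denominator-wide fraction of pairs whose CpG lies in or near an island.
#'
#' @param sig_pairs Significant pair table (rows of a scan's results).
#' @param annotation Feature annotation covering the categorized features.
#' @param attribute `"cpg_island_category"` or `"gene_region_category"`.
#' @param id_col Which pair column names the categorized feature (default
#'   `"b_id"`, the response; e.g. the CpG of an meQTL pair).
#' @return A list of class `category_breakdown`: `table` (data frame
#'   `category`, `count`, `percent`) and `denominator`.
#' @export
category_breakdown <- function(sig_pairs, annotation,
                               attribute = c("cpg_island_category",
                                             "gene_region_category"),
                               id_col = "b_id") {
  attribute <- match.arg(attribute)
  if (!attribute %in% names(annotation)) {
    stop("attribute ", attribute, " missing from annotation")
  }
  ids <- sig_pairs[[id_col]]
  cat_of <- annotation[[attribute]][match(ids, annotation$feature_id)]
  if (all(is.na(cat_of)) && length(ids)) {
    stop("no ", attribute, " annotation found for the ", id_col, " features")
  }
  denom <- nrow(sig_pairs)
  levels <- if (attribute == "cpg_island_category") cpg_island_levels else
    gene_region_levels
  counts <- vapply(levels, function(l) sum(cat_of == l, na.rm = TRUE),
                   numeric(1))
  tab <- data.frame(category = levels, count = as.numeric(counts),
                    stringsAsFactors = FALSE)
  if (attribute == "cpg_island_category") {
    shore <- sum(counts[c("N_Shore", "S_Shore")])
    shelf <- sum(counts[c("N_Shelf", "S_Shelf")])
    tab <- rbind(tab,
                 data.frame(category = c("Shore", "Shelf", "CpG_region"),
                            count = c(shore, shelf,
                                      counts[["Island"]] + shore + shelf),
                            stringsAsFactors = FALSE))
  }
  tab$percent <- round_half_up(100 * tab$count / max(denom, 1), 2)
  structure(list(table = tab, denominator = denom),
            class = "category_breakdown")
}

#' @export
print.category_breakdown <- function(x, ...) {
  cat("category_breakdown (denominator =", x$denominator, "pairs)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Distance profile of significant pairs
#'
#' Histogram of signed predictor-response distances (default 50 kb bins over
#' +/- the window), the per-pair (distance, -log10 p) table for
#' significance-versus-distance displays, and the fraction of significant
#' pairs within +/- 100 kb.
#'
#' @param sig_pairs Significant pair table with `distance_bp` and `p_value`.
#' @param window_bp Half-width of the histogram range (default 1 Mb).
#' @param bin_bp Bin width in bp (default 50 kb).
#' @return A list of class `distance_profile`: `histogram` (`bin_start`,
#'   `bin_end`, `count`), `points` (`distance_bp`, `neg_log10_p`),
#'   `frac_within_100kb`.
#' @export
distance_profile <- function(sig_pairs, window_bp = 1e6, bin_bp = 5e4) {
  d <- sig_pairs$distance_bp
  breaks <- seq(-window_bp, window_bp, by = bin_bp)
  counts <- if (length(d)) {
    h <- hist(pmax(pmin(d, window_bp), -window_bp), breaks = breaks,
              plot = FALSE, right = TRUE, include.lowest = TRUE)
    h$counts
  } else rep(0L, length(breaks) - 1)
  structure(list(histogram = data.frame(bin_start = breaks[-length(breaks)],
                                        bin_end = breaks[-1],
                                        count = counts),
                 points = data.frame(distance_bp = d,
                                     neg_log10_p = -log10(sig_pairs$p_value)),
                 frac_within_100kb = if (length(d)) mean(abs(d) <= 1e5) else
                   NA_real_),
            class = "distance_profile")
}

#' Quantile-quantile data for association p-values
#'
#' Observed -log10 p sorted in decreasing order against the expected
#' uniform quantiles `-log10((i - 0.5) / m)`.  Zero p-values are clamped to
#' the smallest positive double with a warning.
#'
#' @param p_values P-values in (0, 1\].
#' @return Data frame `expected`, `observed` (-log10 scale, both
#'   non-increasing).
#' @export
qq_data <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0,1]")
  }
  if (any(p_values == 0)) {
    warning("p-values of 0 clamped to the smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  m <- length(p_values)
  obs <- sort(-log10(p_values), decreasing = TRUE)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m), observed = obs)
}

#' Build the signed regulatory network
#'
#' From the CIT-significant trios, adds one SNP -> methylation edge signed
#' by the marginal meQTL slope and one methylation -> mRNA edge signed by
#' the marginal eQTM slope per trio; shared nodes are merged and duplicate
#' edges collapsed.  A duplicated edge observed with conflicting signs is
#' kept (first sign wins) and flagged.
#'
#' @param cit_results `cit_batch` results data frame (or the `cit_batch`
#'   object itself).
#' @param alpha Significance level applied to `p_cit`.
#' @return A list of class `regulatory_network`: `nodes` (`id`, `kind` in
#'   snp/methylation/mrna), `edges` (`source`, `target`, `sign` in +/-,
#'   `p_cit`, `conflict`), `n_components`.
#' @export
build_network <- function(cit_results, alpha = 0.05) {
  if (inherits(cit_results, "cit_batch")) cit_results <- cit_results$results
  sig <- cit_results[!is.na(cit_results$p_cit) & cit_results$p_cit < alpha, ,
                     drop = FALSE]
  if (nrow(sig) == 0) {
    return(structure(list(nodes = data.frame(id = character(0),
                                             kind = character(0)),
                          edges = data.frame(source = character(0),
                                             target = character(0),
                                             sign = character(0),
                                             p_cit = numeric(0),
                                             conflict = logical(0)),
                          n_components = 0L),
                     class = "regulatory_network"))
  }
  sgn <- function(s) ifelse(s >= 0, "+", "-")
  edges <- rbind(
    data.frame(source = sig$snp_id, target = sig$cpg_id,
               sign = sgn(sig$sign_lg), p_cit = sig$p_cit,
               stringsAsFactors = FALSE),
    data.frame(source = sig$cpg_id, target = sig$gene_id,
               sign = sgn(sig$sign_gt), p_cit = sig$p_cit,
               stringsAsFactors = FALSE))
  key <- paste(edges$source, edges$target)
  conflict_keys <- unique(key[duplicated(key) |
                                duplicated(key, fromLast = TRUE)])
  conflict_keys <- conflict_keys[vapply(conflict_keys, function(k) {
    length(unique(edges$sign[key == k])) > 1
  }, logical(1))]
  first <- !duplicated(key)
  edges <- edges[first, , drop = FALSE]
  edges$conflict <- paste(edges$source, edges$target) %in% conflict_keys
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(id = unique(sig$snp_id), kind = "snp",
               stringsAsFactors = FALSE),
    data.frame(id = unique(sig$cpg_id), kind = "methylation",
               stringsAsFactors = FALSE),
    data.frame(id = unique(sig$gene_id), kind = "mrna",
               stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  n_comp <- if (nrow(nodes)) {
    g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                       directed = TRUE, vertices = nodes$id)
    igraph::count_components(g, mode = "weak")
  } else 0L
  structure(list(nodes = nodes, edges = edges, n_components = n_comp),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d nodes, %d edges, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), x$n_components))
  invisible(x)
}

#' Export a regulatory network
#'
#' Writes the network in a Cytoscape-ingestible format: SIF (lines
#' `source interaction target`, interaction `pos_reg`/`neg_reg`), GraphML
#' (node attribute `kind`, edge attribute `sign`) or a plain edge TSV.
#' Ordering is deterministic (edges sorted by source then target).
#'
#' @param net A `regulatory_network`.
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"` or `"edge_tsv"`.
#' @return The path, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml",
                                                 "edge_tsv")) {
  format <- match.arg(format)
  e <- net$edges
  if (format == "sif") {
    inter <- ifelse(e$sign == "+", "pos_reg", "neg_reg")
    writeLines(paste(e$source, inter, e$target, sep = "\t"), path)
  } else if (format == "edge_tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(e[, c("source", "target")],
                                       directed = TRUE,
                                       vertices = net$nodes)
    igraph::V(g)$kind <- net$nodes$kind
    if (nrow(e)) igraph::E(g)$sign <- e$sign
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Plot helpers for scan diagnostics
#'
#' `plot_qq` draws observed vs expected -log10 p with the identity line;
#' `plot_distance` draws the signed-distance histogram of a
#' [distance_profile()].
#'
#' @param qq Output of [qq_data()].
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot_qq <- function(qq, ...) {
  plot(qq$expected, qq$observed, xlab = "expected -log10(p)",
       ylab = "observed -log10(p)", pch = 16, cex = 0.5, ...)
  abline(0, 1, col = "red")
  invisible(NULL)
}

#' @rdname plot_qq
#' @param profile Output of [distance_profile()].
#' @export
plot_distance <- function(profile, ...) {
  h <- profile$histogram
  mid <- (h$bin_start + h$bin_end) / 2
  barplot(h$count, names.arg = round(mid / 1e3),
          xlab = "SNP - CpG distance (kb)", ylab = "pairs", ...)
  invisible(NULL)
}
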