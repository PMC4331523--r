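#' Configuration for differential-expression calling
#'
#' @param fdr_threshold Adjusted-p ceiling for calling a gene differentially
#'   expressed (default 0.01; genes at exactly the threshold are included).
#' @param min_samples_per_group Minimum replicates required in each group.
#' @param var_floor Lower bound on the pooled variance (log2 scale), so that
#'   degenerate zero-variance genes yield finite statistics.
#' @param welch Use the unequal-variance (Welch) t-test instead of the
#'   pooled-variance test. Off by default: the pooled two-group test is the
#'   one-way ANOVA equivalent.
#' @return An object of class `deg_config`.
#' @export
deg_config <- function(fdr_threshold = 0.01, min_samples_per_group = 3,
                       var_floor = 1e-8, welch = FALSE) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            min_samples_per_group >= 2, var_floor >= 0)
  structure(list(fdr_threshold = fdr_threshold,
                 min_samples_per_group = as.integer(min_samples_per_group),
                 var_floor = var_floor, welch = isTRUE(welch)),
            class = "deg_config")
}

# Signed linear fold-change from a log2 difference: ratios below 1 are
# reported as -1/ratio, so |fc| >= 1 and sign encodes direction. A log2
# difference of exactly 0 maps to +1.
signed_fc_from_log2 <- function(lfc) {
  ifelse(lfc >= 0, 2^lfc, -(2^(-lfc)))
}

#' Per-gene two-group statistics
#'
#' Computes, for every gene, the group means, the signed linear fold-change
#' `group_a` vs `group_b`, and the raw p-value from the two-group one-way
#' ANOVA (identically, the pooled-variance two-sample t-test; the F statistic
#' is the squared t). All computation is vectorized over genes.
#'
#' @param mat An [expression_matrix()] (log2 values).
#' @param group_a,group_b Group labels present in `mat$groups`.
#' @param cfg A [deg_config()].
#' @return data.frame with columns `gene`, `mean_a`, `mean_b`,
#'   `fold_change`, `raw_p`.
#' @export
gene_stats <- function(mat, group_a, group_b, cfg = deg_config()) {
  stopifnot(inherits(mat, "expression_matrix"), inherits(cfg, "deg_config"))
  a <- mat$values[, mat$groups == group_a, drop = FALSE]
  b <- mat$values[, mat$groups == group_b, drop = FALSE]
  if (ncol(a) == 0L) stop("group not present: ", group_a, call. = FALSE)
  if (ncol(b) == 0L) stop("group not present: ", group_b, call. = FALSE)
  if (ncol(a) < cfg$min_samples_per_group ||
      ncol(b) < cfg$min_samples_per_group)
    stop("group below min_samples_per_group (", cfg$min_samples_per_group,
         ")", call. = FALSE)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  if (cfg$welch) {
    se2 <- pmax(va / na + vb / nb, cfg$var_floor)
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
    df[!is.finite(df)] <- na + nb - 2L
  } else {
    pooled <- pmax(((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L),
                   cfg$var_floor)
    tstat <- (ma - mb) / sqrt(pooled * (1 / na + 1 / nb))
    df <- na + nb - 2L
  }
  raw_p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(gene = rownames(mat$values),
             mean_a = ma, mean_b = mb,
             fold_change = signed_fc_from_log2(ma - mb),
             raw_p = raw_p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values with monotonicity enforcement; output order
#' matches input order.
#'
#' @param pvalues Numeric vector of raw p-values in \[0,1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0,1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE, na.last = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Call differentially expressed genes into a bioset
#'
#' Adjusts the raw p-values with [adjust_bh()] and keeps exactly the genes
#' with adjusted p <= `fdr_threshold` (inclusive). The platform universe of
#' the resulting bioset is the number of genes tested.
#'
#' @param stats Per-gene table from [gene_stats()].
#' @param cfg A [deg_config()].
#' @param metadata A [bioset_metadata()] describing the contrast.
#' @return A [bioset()] of significant genes (possibly empty), carrying
#'   `fold_change` and `adj_p`; `universe_size = nrow(stats)`.
#' @export
call_degs <- function(stats, cfg = deg_config(),
                      metadata = bioset_metadata()) {
  stopifnot(is.data.frame(stats), nrow(stats) > 0,
            all(c("gene", "fold_change", "raw_p") %in% names(stats)))
  adj <- adjust_bh(stats$raw_p)
  keep <- !is.na(adj) & adj <= cfg$fdr_threshold
  rec <- data.frame(gene = stats$gene[keep],
                    fold_change = stats$fold_change[keep],
                    adj_p = adj[keep], stringsAsFactors = FALSE)
  bioset(rec, metadata = metadata, universe_size = nrow(stats))
}

#' Full differential table for one contrast
#'
#' Convenience wrapper: [gene_stats()] plus BH adjustment, returning the
#' complete per-gene table (all genes, not just significant ones) as needed
#' by the signature builder.
#'
#' @inheritParams gene_stats
#' @return data.frame with columns `gene`, `fold_change`, `adj_p`.
#' @export
contrast_table <- function(mat, group_a, group_b, cfg = deg_config()) {
  st <- gene_stats(mat, group_a, group_b, cfg)
  data.frame(gene = st$gene, fold_change = st$fold_change,
             adj_p = adjust_bh(st$raw_p), stringsAsFactors = FALSE)
}
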