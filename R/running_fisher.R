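#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `subset_in_top` members of a subset of
#' size `subset_size` within the top `k` of a ranked list drawn from a
#' universe of size `universe`: P\[X >= subset_in_top\] for
#' X ~ Hypergeometric(universe, subset_size, k). This is the one-sided
#' Fisher exact test of overlap enrichment.
#'
#' @param k Top-rank cut size.
#' @param subset_in_top Observed overlap count within the top `k`.
#' @param subset_size Size of the query subset.
#' @param universe Universe size.
#' @param log.p Return the natural-log p-value (used internally to avoid
#'   underflow for extreme overlaps).
#' @return One-sided p-value (or its natural log).
#' @export
fisher_overlap_p <- function(k, subset_in_top, subset_size, universe,
                             log.p = FALSE) {
  stopifnot(length(universe) == 1L, universe >= 1)
  if (any(k < 0 | k > universe) || any(subset_size < 0 | subset_size > universe))
    stop("k and subset_size must lie in [0, universe]", call. = FALSE)
  if (any(subset_in_top < 0) || any(subset_in_top > pmin(k, subset_size)))
    stop("impossible overlap count", call. = FALSE)
  lp <- stats::phyper(subset_in_top - 1, subset_size, universe - subset_size,
                      k, lower.tail = FALSE, log.p = TRUE)
  if (log.p) lp else exp(lp)
}

# Orders bioset records into a ranked half: descending |fold_change|, ties
# broken by gene id in C-locale (radix) order - deterministic across
# platforms.
ranked_half_genes <- function(records) {
  if (nrow(records) == 0L) return(character())
  o <- order(-abs(records$fold_change), records$gene, method = "radix")
  records$gene[o]
}

# Running-minimum Fisher scan on the log scale. Returns log(p_pair).
running_min_logp <- function(sig_genes, ranked_genes, universe) {
  m <- length(sig_genes)
  n <- length(ranked_genes)
  if (m == 0L || n == 0L) return(0)               # log(1)
  if (m > universe || n > universe)
    stop("universe smaller than a gene list", call. = FALSE)
  hit <- ranked_genes %in% sig_genes
  scan <- sort(unique(c(which(hit), n)))
  overlap_at <- cumsum(hit)[scan]
  lp <- stats::phyper(overlap_at - 1, m, universe - m, scan,
                      lower.tail = FALSE, log.p = TRUE)
  min(min(lp) + log(length(scan)), 0)             # Bonferroni over scan, cap 1
}

#' Running Fisher scan p-value for one signature-half / bioset-half pair
#'
#' Scans down the fold-change-ranked bioset half, computing the one-sided
#' hypergeometric overlap p-value at every rank where a signature member
#' occurs (plus the endpoint), takes the minimum, and applies a Bonferroni
#' correction for the number of scan points (capped at 1). Empty inputs give
#' p = 1.
#'
#' @param signature_genes Character vector of signature-half members
#'   (already restricted to the shared universe).
#' @param ranked_genes Character vector: the bioset half ordered by
#'   descending |fold-change| (see details in [rf_compare()]).
#' @param universe Universe size.
#' @return The pair p-value in (0, 1\].
#' @export
running_min_p <- function(signature_genes, ranked_genes, universe) {
  exp(running_min_logp(signature_genes, ranked_genes, universe))
}

#' Directional signature-to-bioset similarity (running Fisher test)
#'
#' The bioset is split by fold-change sign into up- and down-regulated
#' halves, each ranked by descending |fold-change| (ties broken by gene id).
#' Four pair p-values are computed with the running Fisher scan: the
#' concordant pairs (signature-up vs bioset-up, signature-down vs
#' bioset-down) and the discordant pairs (signature-up vs bioset-down,
#' signature-down vs bioset-up). Summed -log10 evidence decides the
#' correlation direction; the winning direction's pair p-values are combined
#' by Fisher's method (chi-squared on -2*sum(log p), df = 2 x number of
#' non-empty winning pairs).
#'
#' Flipping every bioset fold-change sign exactly swaps the concordant and
#' discordant pairs, so the direction flips while the p-value is preserved
#' (antisymmetry).
#'
#' @param signature A [gene_signature()].
#' @param bioset A [bioset()].
#' @param universe_policy `"bioset_platform"` (universe = the bioset's
#'   platform size; default), `"intersection"` (restrict signature and
#'   bioset to `platform_genes` when supplied, else fall back to the bioset
#'   platform), or `"fixed"` (use `fixed_universe`).
#' @param platform_genes Optional character vector: the genes measurable on
#'   both platforms, used by the `"intersection"` policy.
#' @param fixed_universe Universe size for the `"fixed"` policy.
#' @return An object of class `running_fisher_result`: a list with
#'   `direction` (+1/-1/0), `p_value`, `signed_score`
#'   (direction x -log10 p), `pair_pvalues` (named: `up_up`, `down_down`,
#'   `up_down`, `down_up`), and `overlap` (genes shared between signature
#'   and bioset).
#' @export
rf_compare <- function(signature, bioset,
                       universe_policy = c("bioset_platform", "intersection",
                                           "fixed"),
                       platform_genes = NULL, fixed_universe = NULL) {
  stopifnot(inherits(signature, "gene_signature"), inherits(bioset, "bioset"))
  universe_policy <- match.arg(universe_policy)
  if (signature_size(signature) == 0L)
    stop("empty signature", call. = FALSE)
  sig_up <- signature$up$gene
  sig_down <- signature$down$gene
  rec <- bioset$records
  rec <- rec[rec$fold_change != 0, , drop = FALSE]
  N <- switch(universe_policy,
    bioset_platform = bioset$universe_size,
    fixed = {
      if (is.null(fixed_universe)) stop("fixed_universe required",
                                        call. = FALSE)
      as.integer(fixed_universe)
    },
    intersection = {
      if (!is.null(platform_genes)) {
        platform_genes <- unique(platform_genes)
        sig_up <- intersect(sig_up, platform_genes)
        sig_down <- intersect(sig_down, platform_genes)
        rec <- rec[rec$gene %in% platform_genes, , drop = FALSE]
        length(platform_genes)
      } else bioset$universe_size
    })
  up_half <- ranked_half_genes(rec[rec$fold_change > 0, , drop = FALSE])
  down_half <- ranked_half_genes(rec[rec$fold_change < 0, , drop = FALSE])
  overlap <- intersect(c(sig_up, sig_down), rec$gene)

  if (nrow(rec) == 0L) {
    return(rf_result(0L, 0, c(up_up = 1, down_down = 1, up_down = 1,
                              down_up = 1), character()))
  }
  lp <- c(up_up = running_min_logp(sig_up, up_half, N),
          down_down = running_min_logp(sig_down, down_half, N),
          up_down = running_min_logp(sig_up, down_half, N),
          down_up = running_min_logp(sig_down, up_half, N))
  nonempty <- c(up_up = length(sig_up) > 0 && length(up_half) > 0,
                down_down = length(sig_down) > 0 && length(down_half) > 0,
                up_down = length(sig_up) > 0 && length(down_half) > 0,
                down_up = length(sig_down) > 0 && length(up_half) > 0)
  conc <- c("up_up", "down_down"); disc <- c("up_down", "down_up")
  evidence_c <- -sum(lp[conc]) / log(10)
  evidence_d <- -sum(lp[disc]) / log(10)
  direction <- as.integer(sign(evidence_c - evidence_d))
  pairs_used <- if (direction >= 0L) conc else disc
  pairs_used <- pairs_used[nonempty[pairs_used]]
  log_p <- if (length(pairs_used) == 0L) 0 else {
    x2 <- -2 * sum(lp[pairs_used])
    stats::pchisq(x2, df = 2L * length(pairs_used), lower.tail = FALSE,
                  log.p = TRUE)
  }
  rf_result(direction, log_p, exp(lp), overlap)
}

rf_result <- function(direction, log_p, pair_pvalues, overlap) {
  p <- max(exp(log_p), .Machine$double.xmin)
  structure(list(direction = direction,
                 p_value = p,
                 signed_score = direction * (-log_p / log(10)),
                 pair_pvalues = pair_pvalues,
                 overlap = overlap),
            class = "running_fisher_result")
}

#' @export
print.running_fisher_result <- function(x, ...) {
  lab <- c("-1" = "negative", "0" = "none", "1" = "positive")
  cat(sprintf("<running_fisher_result> correlation: %s  p = %.3g  score = %.2f  overlap = %d genes\n",
              lab[as.character(x$direction)], x$p_value, x$signed_score,
              length(x$overlap)))
  invisible(x)
}
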