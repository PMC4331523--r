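#' Configuration for signature derivation
#'
#' @param fdr_threshold Adjusted-p ceiling used in the three per-chemical
#'   contrasts (default 0.01).
#' @param min_abs_avg_fc Minimum |average fold-change| (signed linear scale)
#'   for a gene to enter the signature (default 1.5).
#' @param min_chemical_support Minimum number of chemicals whose
#'   dependent-gene lists must contain the gene (default 2).
#' @param exclusion_signatures List of [gene_signature()] objects; a
#'   candidate altered in the SAME direction in any of them is dropped
#'   (specificity filter against other transcription-factor programs).
#'   An empty list disables the filter.
#' @return An object of class `builder_config`.
#' @export
builder_config <- function(fdr_threshold = 0.01, min_abs_avg_fc = 1.5,
                           min_chemical_support = 2,
                           exclusion_signatures = list()) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1, min_abs_avg_fc >= 1,
            min_chemical_support >= 1)
  structure(list(fdr_threshold = fdr_threshold,
                 min_abs_avg_fc = min_abs_avg_fc,
                 min_chemical_support = as.integer(min_chemical_support),
                 exclusion_signatures = exclusion_signatures),
            class = "builder_config")
}

#' One chemical's paired wild-type/null experiment
#'
#' Bundles the three full per-gene contrast tables required to isolate
#' receptor-dependent responses to one chemical: treated-vs-control in
#' wild-type, treated-vs-control in receptor-null, and treated wild-type vs
#' treated null. All three tables must cover the same gene universe.
#'
#' @param name Chemical name.
#' @param wt_treated_vs_ctrl,null_treated_vs_ctrl,wt_treated_vs_null_treated
#'   data.frames with columns `gene`, `fold_change`, `adj_p` covering every
#'   measured gene (e.g. from [contrast_table()]).
#' @return An object of class `chemical_experiment`.
#' @export
chemical_experiment <- function(name, wt_treated_vs_ctrl,
                                null_treated_vs_ctrl,
                                wt_treated_vs_null_treated) {
  tabs <- list(wt_treated_vs_ctrl = wt_treated_vs_ctrl,
               null_treated_vs_ctrl = null_treated_vs_ctrl,
               wt_treated_vs_null_treated = wt_treated_vs_null_treated)
  for (nm in names(tabs)) {
    t <- tabs[[nm]]
    stopifnot(is.data.frame(t),
              all(c("gene", "fold_change", "adj_p") %in% names(t)))
    if (anyDuplicated(t$gene))
      stop("duplicate gene in ", nm, call. = FALSE)
  }
  g <- sort(tabs[[1L]]$gene)
  for (nm in names(tabs)[-1L])
    if (!identical(sort(tabs[[nm]]$gene), g))
      stop("gene universe mismatch between contrast tables (", nm, ")",
           call. = FALSE)
  structure(c(list(name = as.character(name)), tabs),
            class = "chemical_experiment")
}

#' Receptor-dependent genes for one chemical
#'
#' Applies the knockout-anchoring criteria to a [chemical_experiment()]: a
#' gene qualifies iff it is (a) significantly altered in treated wild-type
#' vs control, (b) NOT significantly altered in the same direction in the
#' receptor-null treated-vs-control contrast (an opposite-direction change
#' in the null does not disqualify), and (c) significantly different between
#' treated wild-type and treated null animals.
#'
#' @param exp A [chemical_experiment()].
#' @param cfg A [builder_config()].
#' @return data.frame with columns `gene`, `direction` (+1/-1) and
#'   `wt_fold_change` (signed linear fold-change in the wild-type contrast).
#' @export
dependent_genes_for_chemical <- function(exp, cfg = builder_config()) {
  stopifnot(inherits(exp, "chemical_experiment"),
            inherits(cfg, "builder_config"))
  wt <- exp$wt_treated_vs_ctrl
  ko <- exp$null_treated_vs_ctrl[match(wt$gene, exp$null_treated_vs_ctrl$gene), ]
  wn <- exp$wt_treated_vs_null_treated[
    match(wt$gene, exp$wt_treated_vs_null_treated$gene), ]
  thr <- cfg$fdr_threshold
  sig_wt <- !is.na(wt$adj_p) & wt$adj_p <= thr
  ko_same_dir_sig <- !is.na(ko$adj_p) & ko$adj_p <= thr &
    sign(ko$fold_change) == sign(wt$fold_change)
  sig_wn <- !is.na(wn$adj_p) & wn$adj_p <= thr
  keep <- sig_wt & !ko_same_dir_sig & sig_wn
  data.frame(gene = wt$gene[keep],
             direction = as.integer(sign(wt$fold_change[keep])),
             wt_fold_change = wt$fold_change[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

# TRUE for genes altered in the same direction in signature `sig`.
in_signature_same_direction <- function(gene, direction, sig) {
  (direction > 0 & gene %in% sig$up$gene) |
    (direction < 0 & gene %in% sig$down$gene)
}

#' Combine per-chemical dependent-gene lists into a signature
#'
#' A gene enters the signature iff it: changes in the same direction in
#' every chemical where it appears; appears in at least
#' `min_chemical_support` chemicals; has |mean wild-type fold-change| over
#' the supporting chemicals at or above `min_abs_avg_fc`; (when a
#' probe-to-gene map is supplied) has all of its probes agreeing in
#' direction; and is not altered in the same direction in any exclusion
#' signature. The signature fold-change is the mean over supporting
#' chemicals.
#'
#' @param per_chemical List of tables from [dependent_genes_for_chemical()]
#'   (at least two chemicals).
#' @param cfg A [builder_config()].
#' @param probe_to_gene Optional named character vector mapping probe ids
#'   (the identifier namespace of the inputs) to gene symbols; probes of a
#'   gene disagreeing in direction drop the gene with a message.
#' @param name Name for the resulting signature.
#' @return A [gene_signature()].
#' @export
combine_signature <- function(per_chemical, cfg = builder_config(),
                              probe_to_gene = NULL, name = "signature") {
  stopifnot(is.list(per_chemical), length(per_chemical) >= 2,
            inherits(cfg, "builder_config"))
  if (cfg$min_chemical_support > length(per_chemical))
    stop("min_chemical_support exceeds number of chemicals", call. = FALSE)
  all_tab <- do.call(rbind, lapply(per_chemical, function(t)
    t[, c("gene", "direction", "wt_fold_change")]))
  if (nrow(all_tab) == 0L)
    return(gene_signature(NULL, NULL, name = name))
  # per-gene aggregation: support count, direction consistency, mean FC
  agg <- split(all_tab, all_tab$gene)
  keep_gene <- character(); keep_dir <- integer(); keep_fc <- numeric()
  for (g in names(agg)) {
    t <- agg[[g]]
    if (length(unique(t$direction)) != 1L) next       # direction conflict
    if (nrow(t) < cfg$min_chemical_support) next      # support
    fc <- mean(t$wt_fold_change)
    if (abs(fc) < cfg$min_abs_avg_fc) next            # magnitude
    keep_gene <- c(keep_gene, g)
    keep_dir <- c(keep_dir, t$direction[1L])
    keep_fc <- c(keep_fc, fc)
  }
  res <- data.frame(gene = keep_gene, direction = keep_dir,
                    avg_fold_change = keep_fc, stringsAsFactors = FALSE)
  # optional probe -> gene collapsing with direction-agreement requirement
  if (!is.null(probe_to_gene) && nrow(res) > 0L) {
    mapped <- unname(probe_to_gene[res$gene])
    if (any(is.na(mapped)))
      stop("probe_to_gene lacks mapping for: ",
           res$gene[is.na(mapped)][1L], call. = FALSE)
    res$gene <- mapped
    parts <- split(res, res$gene)
    res <- do.call(rbind, lapply(parts, function(t) {
      if (length(unique(t$direction)) != 1L) {
        message("dropping gene with direction-conflicting probes: ",
                t$gene[1L])
        return(NULL)
      }
      data.frame(gene = t$gene[1L], direction = t$direction[1L],
                 avg_fold_change = mean(t$avg_fold_change),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(res))
      res <- data.frame(gene = character(), direction = integer(),
                        avg_fold_change = numeric(), stringsAsFactors = FALSE)
  }
  # exclusion signatures: same-direction membership disqualifies
  if (length(cfg$exclusion_signatures) && nrow(res) > 0L) {
    excl <- rep(FALSE, nrow(res))
    for (sig in cfg$exclusion_signatures)
      excl <- excl | in_signature_same_direction(res$gene, res$direction, sig)
    res <- res[!excl, , drop = FALSE]
  }
  gene_signature(
    up = res[res$direction > 0, c("gene", "avg_fold_change")],
    down = res[res$direction < 0, c("gene", "avg_fold_change")],
    name = name)
}

#' Derive a signature directly from knockout experiment matrices
#'
#' End-to-end convenience: for each chemical's grouped expression matrix
#' (groups `wt_ctrl`, `wt_treated`, `ko_ctrl`, `ko_treated`), computes the
#' three contrast tables, applies the knockout-anchoring criteria, and
#' combines across chemicals.
#'
#' @param matrices Named list of [expression_matrix()] objects, one per
#'   chemical.
#' @param deg_cfg A [deg_config()].
#' @param builder_cfg A [builder_config()].
#' @param name Signature name.
#' @return A [gene_signature()].
#' @export
build_signature_from_matrices <- function(matrices,
                                          deg_cfg = deg_config(),
                                          builder_cfg = builder_config(),
                                          name = "signature") {
  per_chem <- lapply(names(matrices), function(nm) {
    m <- matrices[[nm]]
    exp <- chemical_experiment(
      name = nm,
      wt_treated_vs_ctrl = contrast_table(m, "wt_treated", "wt_ctrl", deg_cfg),
      null_treated_vs_ctrl = contrast_table(m, "ko_treated", "ko_ctrl", deg_cfg),
      wt_treated_vs_null_treated =
        contrast_table(m, "wt_treated", "ko_treated", deg_cfg))
    dependent_genes_for_chemical(exp, builder_cfg)
  })
  combine_signature(per_chem, builder_cfg, name = name)
}
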