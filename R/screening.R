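#' Configuration for compendium screening
#'
#' @param p_threshold Significance cutoff on the similarity p-value (default
#'   1e-4, the fixed operational cutoff; see [derive_cutoff()] for the
#'   BH-derived alternative).
#' @param bh_alpha Level for the Benjamini-Hochberg cutoff derivation
#'   (default 0.001).
#' @param target_gene Gene whose own expression is cross-tabulated against
#'   the calls (default `"Ppara"`).
#' @param target_fc_threshold |fold-change| at or above which the target
#'   gene counts as changed (default 1.2).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(p_threshold = 1e-4, bh_alpha = 0.001,
                          target_gene = "Ppara", target_fc_threshold = 1.2) {
  stopifnot(p_threshold > 0, p_threshold < 1, bh_alpha > 0, bh_alpha < 1,
            target_fc_threshold >= 1)
  structure(list(p_threshold = p_threshold, bh_alpha = bh_alpha,
                 target_gene = as.character(target_gene),
                 target_fc_threshold = target_fc_threshold),
            class = "screen_config")
}

call_from <- function(direction, p_value, p_threshold) {
  ifelse(p_value <= p_threshold & direction == 1L, "activated",
         ifelse(p_value <= p_threshold & direction == -1L, "suppressed",
                "neutral"))
}

#' Screen a signature across a compendium of biosets
#'
#' Runs [rf_compare()] between the signature and every bioset and applies
#' the significance threshold: `activated` when the correlation is positive
#' and p <= threshold, `suppressed` when negative and p <= threshold, else
#' `neutral`. A failing comparison degrades to a flagged neutral row rather
#' than aborting the screen.
#'
#' @param signature A [gene_signature()].
#' @param biosets List of [bioset()] objects.
#' @param cfg A [screen_config()].
#' @param ... Passed to [rf_compare()] (universe policy arguments).
#' @return A `compendium_table`: data.frame with one row per bioset and
#'   columns `bioset_id`, `study_id`, `contrast_name`, `factor_class`,
#'   `factor_name`, `sex`, `genotype`, `direction`, `p_value`,
#'   `signed_score`, `call`, `error`. Attributes `p_threshold` and
#'   `bh_cutoff` record the fixed and BH-derived cutoffs.
#' @export
screen <- function(signature, biosets, cfg = screen_config(), ...) {
  stopifnot(inherits(cfg, "screen_config"), length(biosets) > 0)
  rows <- lapply(seq_along(biosets), function(i) {
    b <- biosets[[i]]
    md <- b$metadata
    id <- if (nzchar(md$study_id) || nzchar(md$contrast_name))
      paste(md$study_id, md$contrast_name, sep = "/") else sprintf("bioset_%04d", i)
    res <- tryCatch(rf_compare(signature, b, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(bioset_id = id, study_id = md$study_id,
                 contrast_name = md$contrast_name,
                 factor_class = md$factor_class, factor_name = md$factor_name,
                 sex = md$sex, genotype = md$genotype,
                 direction = 0L, p_value = 1, signed_score = 0,
                 call = "neutral", error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(bioset_id = id, study_id = md$study_id,
                 contrast_name = md$contrast_name,
                 factor_class = md$factor_class, factor_name = md$factor_name,
                 sex = md$sex, genotype = md$genotype,
                 direction = res$direction, p_value = res$p_value,
                 signed_score = res$signed_score,
                 call = call_from(res$direction, res$p_value, cfg$p_threshold),
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- is.na(out$error)
  attr(out, "p_threshold") <- cfg$p_threshold
  attr(out, "bh_cutoff") <- if (any(ok))
    derive_cutoff(out$p_value[ok], cfg$bh_alpha) else NA_real_
  class(out) <- c("compendium_table", "data.frame")
  out
}

#' Benjamini-Hochberg p-value cutoff for a compendium of tests
#'
#' Runs the BH step-up procedure at level `alpha` over the supplied raw
#' p-values and returns the largest raw p-value among the tests declared
#' significant (0 when none is). This is how a fixed operational cutoff is
#' derived from a compendium-wide screen.
#'
#' @param pvalues Raw p-values from the similarity tests.
#' @param alpha BH level (default 0.001).
#' @return The cutoff (a raw p-value), or 0.
#' @export
derive_cutoff <- function(pvalues, alpha = 0.001) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) stop("empty p-value list", call. = FALSE)
  if (any(is.na(p) | p < 0 | p > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= alpha * seq_len(m) / m)
  if (length(ok) == 0L) 0 else ps[max(ok)]
}

#' Activation/suppression counts by perturbation class
#'
#' @param table A `compendium_table` from [screen()].
#' @return data.frame with one row per factor class (all enumeration levels
#'   present) and columns `factor_class`, `activated`, `suppressed`.
#' @export
summarize_by_category <- function(table) {
  fc <- factor(table$factor_class, levels = factor_classes())
  data.frame(factor_class = factor_classes(),
             activated = as.integer(base::table(fc[table$call == "activated"])),
             suppressed = as.integer(base::table(fc[table$call == "suppressed"])),
             stringsAsFactors = FALSE)
}

#' Cross-tabulate target-gene expression change against screen calls
#'
#' Biosets are trichotomized by the target gene's own signed fold-change -
#' up (fc >= threshold), down (fc <= -threshold), or no change (including
#' biosets where the target was not in the filtered list) - and crossed with
#' the activation calls.
#'
#' @param table A `compendium_table` from [screen()].
#' @param target_fc Named numeric vector mapping `bioset_id` to the target
#'   gene's signed fold-change; ids absent from the vector fall in the
#'   no-change bin.
#' @param cfg A [screen_config()] (supplies `target_fc_threshold`).
#' @return 3 x 3 integer matrix, rows `up`/`down`/`no_change`, columns
#'   `activated`/`suppressed`/`neutral`; the grand total equals
#'   `nrow(table)`.
#' @export
target_gene_concordance <- function(table, target_fc, cfg = screen_config()) {
  fc <- target_fc[table$bioset_id]
  thr <- cfg$target_fc_threshold
  bin <- ifelse(is.na(fc), "no_change",
                ifelse(fc >= thr, "up",
                       ifelse(fc <= -thr, "down", "no_change")))
  bin <- factor(bin, levels = c("up", "down", "no_change"))
  call <- factor(table$call, levels = c("activated", "suppressed", "neutral"))
  as.matrix(unclass(base::table(bin, call)))
}
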