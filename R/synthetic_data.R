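#' Configuration for simulated knockout experiments
#'
#' The generator emulates paired wild-type/receptor-null two-group
#' experiments for several chemicals with a planted receptor-dependent
#' program: program genes respond to treatment in wild-type animals only,
#' while a set of receptor-independent responders (modeled on
#' Cyp4a/Acox1-like genes) responds in both genotypes. The up:down split of
#' the program mirrors the strongly up-biased composition of
#' knockout-anchored hepatic signatures (about 13:1).
#'
#' @param n_genes Universe size (default 20000).
#' @param n_program Planted receptor-dependent genes (default 131; split
#'   122 up / 9 down, the 137:10 probe ratio scaled to 131).
#' @param n_independent Planted receptor-independent responders (default
#'   30).
#' @param effect_log2fc Length-2 range; planted |log2 fold-changes| are
#'   drawn uniformly from it (default c(0.8, 2.5), i.e. linear fold-changes
#'   of about 1.74 to 5.7).
#' @param noise_sd Per-sample Gaussian noise SD on the log2 scale (default
#'   0.25).
#' @param n_per_group Replicates per group (default 4).
#' @param n_chemicals Number of chemicals (default 3).
#' @param chemical_presence_prob Probability that a program gene responds to
#'   a given chemical (default 0.85).
#' @param baseline_range Length-2 range of per-gene baseline log2 expression
#'   (default c(6, 12)).
#' @param seed Integer seed; every generator output is a pure function of
#'   seed and config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20000, n_program = 131, n_independent = 30,
                       effect_log2fc = c(0.8, 2.5), noise_sd = 0.25,
                       n_per_group = 4, n_chemicals = 3,
                       chemical_presence_prob = 0.85,
                       baseline_range = c(6, 12), seed = 1) {
  stopifnot(n_program + n_independent <= n_genes,
            length(effect_log2fc) == 2, effect_log2fc[1] > 0,
            diff(effect_log2fc) >= 0, noise_sd >= 0, n_per_group >= 2,
            n_chemicals >= 1,
            chemical_presence_prob >= 0, chemical_presence_prob <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_program = as.integer(n_program),
                 n_independent = as.integer(n_independent),
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 n_per_group = as.integer(n_per_group),
                 n_chemicals = as.integer(n_chemicals),
                 chemical_presence_prob = chemical_presence_prob,
                 baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate paired wild-type/null experiments with planted truth
#'
#' For each chemical, generates a grouped log2 [expression_matrix()] with
#' four groups (`wt_ctrl`, `wt_treated`, `ko_ctrl`, `ko_treated`):
#' values = baseline + effect x indicator + Gaussian noise. Program genes
#' carry their effect in `wt_treated` only (and only for chemicals where
#' the gene responds, per `chemical_presence_prob`); independent responders
#' carry it in both genotypes' treated groups; all other genes are noise.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrices` (named list of [expression_matrix()], one
#'   per chemical) and `truth`, a `synthetic_truth` list with
#'   `program_up`, `program_down`, `independent` gene sets, the per-gene
#'   planted `effects` (named log2 values, signed) and the program x
#'   chemical `presence` indicator matrix.
#' @export
simulate_ko_experiments <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sim_gene_ids(cfg$n_genes)
  special <- sample(genes, cfg$n_program + cfg$n_independent)
  program <- special[seq_len(cfg$n_program)]
  independent <- special[-seq_len(cfg$n_program)]
  # 137:10 up:down probe ratio scaled to the program size
  n_up <- round(cfg$n_program * 137 / 147)
  program_up <- program[seq_len(n_up)]
  program_down <- program[-seq_len(n_up)]

  draw_effect <- function(n, sign) {
    sign * stats::runif(n, cfg$effect_log2fc[1], cfg$effect_log2fc[2])
  }
  effects <- c(draw_effect(length(program_up), +1),
               draw_effect(length(program_down), -1),
               draw_effect(length(independent), +1))
  names(effects) <- c(program_up, program_down, independent)
  baseline <- stats::runif(cfg$n_genes, cfg$baseline_range[1],
                           cfg$baseline_range[2])
  names(baseline) <- genes
  presence <- matrix(
    stats::rbinom(cfg$n_program * cfg$n_chemicals, 1,
                  cfg$chemical_presence_prob) == 1L,
    nrow = cfg$n_program,
    dimnames = list(program, sprintf("chem%d", seq_len(cfg$n_chemicals))))

  n <- cfg$n_per_group
  group_names <- c("wt_ctrl", "wt_treated", "ko_ctrl", "ko_treated")
  matrices <- lapply(seq_len(cfg$n_chemicals), function(ch) {
    groups <- rep(group_names, each = n)
    samples <- sprintf("chem%d_%s_r%d", ch, groups, rep(seq_len(n), times = 4))
    vals <- matrix(stats::rnorm(cfg$n_genes * length(samples),
                                sd = cfg$noise_sd),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, samples))
    vals <- vals + baseline
    eff <- numeric(cfg$n_genes); names(eff) <- genes
    responding <- program[presence[, ch]]
    eff[responding] <- effects[responding]
    vals[, groups == "wt_treated"] <-
      vals[, groups == "wt_treated"] + eff
    eff_ko <- numeric(cfg$n_genes); names(eff_ko) <- genes
    eff_ko[independent] <- effects[independent]
    vals[, groups == "wt_treated"] <-
      vals[, groups == "wt_treated"] + eff_ko
    vals[, groups == "ko_treated"] <-
      vals[, groups == "ko_treated"] + eff_ko
    expression_matrix(vals, stats::setNames(groups, samples))
  })
  names(matrices) <- colnames(presence)
  truth <- structure(list(program_up = program_up,
                          program_down = program_down,
                          independent = independent,
                          effects = effects, presence = presence),
                     class = "synthetic_truth")
  list(matrices = matrices, truth = truth)
}

#' Signature of the planted program
#'
#' Turns the ground truth of [simulate_ko_experiments()] into a
#' [gene_signature()] (the oracle signature: planted membership with the
#' planted linear fold-changes), e.g. for screening a simulated compendium
#' independently of the signature-recovery stage.
#'
#' @param truth A `synthetic_truth`.
#' @param name Signature name.
#' @return A [gene_signature()].
#' @export
truth_signature <- function(truth, name = "planted_program") {
  stopifnot(inherits(truth, "synthetic_truth"))
  lin <- signed_fc_from_log2(truth$effects)
  gene_signature(
    up = data.frame(gene = truth$program_up,
                    avg_fold_change = unname(lin[truth$program_up])),
    down = data.frame(gene = truth$program_down,
                      avg_fold_change = unname(lin[truth$program_down])),
    name = name)
}

#' Configuration for a simulated compendium
#'
#' @param n_activators,n_suppressors,n_nulls Bioset counts per class.
#' @param overlap_fraction Fraction `f` of the planted program echoed by
#'   each activator/suppressor bioset (default 0.6).
#' @param bioset_size Genes per bioset (default 300).
#' @param n_genes Universe size; must match the truth's universe (default
#'   20000).
#' @param seed Integer seed.
#' @return An object of class `compendium_sim_config`.
#' @export
compendium_sim_config <- function(n_activators = 60, n_suppressors = 30,
                                  n_nulls = 200, overlap_fraction = 0.6,
                                  bioset_size = 300, n_genes = 20000,
                                  seed = 1) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1, bioset_size >= 1)
  structure(list(n_activators = as.integer(n_activators),
                 n_suppressors = as.integer(n_suppressors),
                 n_nulls = as.integer(n_nulls),
                 overlap_fraction = overlap_fraction,
                 bioset_size = as.integer(bioset_size),
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "compendium_sim_config")
}

#' Simulate an annotated compendium of biosets with known labels
#'
#' Activator biosets echo `floor(f x program size)` randomly chosen program
#' genes with signs concordant with the program; suppressor biosets echo
#' them with opposite signs; null biosets draw all their genes uniformly
#' from the universe with random signs. Echoed genes receive |fold-changes|
#' drawn from the upper quartile of the bioset's magnitude distribution, so
#' the planted signal concentrates at the top ranks. Metadata assigns
#' factor classes round-robin over the enumeration.
#'
#' @param cfg A [compendium_sim_config()].
#' @param truth A `synthetic_truth` from [simulate_ko_experiments()].
#' @return List with `biosets` (list of [bioset()]) and `labels`
#'   (character vector: `"activator"`, `"suppressor"` or `"null"`, one per
#'   bioset, named by bioset id).
#' @export
simulate_compendium <- function(cfg = compendium_sim_config(),
                                truth) {
  stopifnot(inherits(cfg, "compendium_sim_config"),
            inherits(truth, "synthetic_truth"))
  set.seed(cfg$seed)
  genes <- sim_gene_ids(cfg$n_genes)
  program <- c(truth$program_up, truth$program_down)
  prog_sign <- stats::setNames(
    c(rep(1, length(truth$program_up)), rep(-1, length(truth$program_down))),
    program)
  if (!all(program %in% genes))
    stop("truth universe does not match cfg$n_genes", call. = FALSE)
  n_echo <- floor(cfg$overlap_fraction * length(program))
  if (n_echo > cfg$bioset_size)
    stop("overlap_fraction x program exceeds bioset_size", call. = FALSE)

  # base magnitude distribution of a statistically filtered list:
  # |log2 fc| between 0.26 (1.2-fold) and 2 (4-fold)
  draw_magnitudes <- function(n) 2^stats::runif(n, 0.263, 2)

  labels <- c(rep("activator", cfg$n_activators),
              rep("suppressor", cfg$n_suppressors),
              rep("null", cfg$n_nulls))
  classes <- factor_classes()
  biosets <- lapply(seq_along(labels), function(i) {
    lab <- labels[i]
    mags <- draw_magnitudes(cfg$bioset_size)
    if (lab == "null") {
      g <- sample(genes, cfg$bioset_size)
      fc <- sample(c(-1, 1), cfg$bioset_size, replace = TRUE) * mags
    } else {
      echoed <- sample(program, n_echo)
      fillers <- sample(setdiff(genes, program), cfg$bioset_size - n_echo)
      g <- c(echoed, fillers)
      # echoed genes take top-quartile magnitudes (rank bias)
      top_q <- mags[mags >= stats::quantile(mags, 0.75)]
      mag_echo <- sample(top_q, n_echo, replace = TRUE)
      sgn <- if (lab == "activator") prog_sign[echoed] else -prog_sign[echoed]
      fc <- c(unname(sgn) * mag_echo,
              sample(c(-1, 1), length(fillers), replace = TRUE) *
                mags[seq_along(fillers)])
    }
    md <- bioset_metadata(
      study_id = sprintf("SIM%03d", i),
      contrast_name = sprintf("%s_%03d", lab, i),
      factor_class = classes[(i - 1L) %% length(classes) + 1L],
      factor_name = lab)
    bioset(data.frame(gene = g, fold_change = fc,
                      adj_p = stats::runif(length(g), 0, 0.01),
                      stringsAsFactors = FALSE),
           metadata = md, universe_size = cfg$n_genes)
  })
  ids <- vapply(biosets, function(b)
    paste(b$metadata$study_id, b$metadata$contrast_name, sep = "/"), "")
  list(biosets = biosets, labels = stats::setNames(labels, ids))
}
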