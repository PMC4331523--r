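# Independent oracles (deliberately naive implementations) and fixture
# builders shared across the suite.

# O(m^2) Benjamini-Hochberg step-up: adj_i = min over j >= rank(i) of
# p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(sorted[i:m] * m / (i:m))), numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Brute-force BH cutoff: largest raw p among step-up-significant tests.
cutoff_oracle <- function(p, alpha) {
  m <- length(p)
  sorted <- sort(p)
  sig <- logical(m)
  for (i in seq_len(m)) {
    # significant iff some j >= i has p_(j) <= alpha * j / m
    sig[i] <- any(sorted[i:m] <= alpha * (i:m) / m)
  }
  if (!any(sig)) 0 else max(sorted[sig])
}

# Exhaustive hypergeometric upper tail: sum of PMF terms from the observed
# overlap to the maximum possible.
hyper_tail_oracle <- function(k, x, m, N) {
  hi <- min(k, m)
  if (x > hi) return(0)
  sum(vapply(x:hi, function(i)
    choose(m, i) * choose(N - m, k - i) / choose(N, k), numeric(1)))
}

# Naive confusion-matrix recount.
recount_oracle <- function(truth, call, pos_calls) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    pred <- call[i] %in% pos_calls
    if (truth[i] == "positive" && pred) tp <- tp + 1L
    if (truth[i] == "positive" && !pred) fn <- fn + 1L
    if (truth[i] == "negative" && pred) fp <- fp + 1L
    if (truth[i] == "negative" && !pred) tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# ---- fixture builders -------------------------------------------------------

random_bioset <- function(n = 50, universe = 1000, seed = NULL,
                          genes = NULL, metadata = bioset_metadata()) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genes)) genes <- sprintf("g%05d", sample.int(universe, n))
  bioset(data.frame(
    gene = genes,
    fold_change = sample(c(-1, 1), n, TRUE) * 2^runif(n, 0.3, 2),
    adj_p = runif(n, 0, 0.01),
    stringsAsFactors = FALSE), metadata = metadata, universe_size = universe)
}

random_signature <- function(n_up = 20, n_down = 5, universe = 1000,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- sprintf("g%05d", sample.int(universe, n_up + n_down))
  gene_signature(
    up = data.frame(gene = g[seq_len(n_up)],
                    avg_fold_change = 2^runif(n_up, 0.6, 2)),
    down = if (n_down > 0)
      data.frame(gene = g[n_up + seq_len(n_down)],
                 avg_fold_change = -2^runif(n_down, 0.6, 2)) else NULL,
    name = "RND")
}

# Small grouped matrix with optional planted log2 effects in group "b".
toy_matrix <- function(n_genes = 100, n_per_group = 4, noise_sd = 0.25,
                       effects = numeric(0), seed = NULL,
                       groups = c("a", "b")) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  samples <- paste0(rep(groups, each = n_per_group), "_r",
                    rep(seq_len(n_per_group), times = length(groups)))
  vals <- matrix(rnorm(n_genes * length(samples), mean = 8, sd = noise_sd),
                 nrow = n_genes, dimnames = list(genes, samples))
  if (length(effects)) {
    idx <- match(names(effects), genes)
    vals[idx, startsWith(samples, "b_")] <-
      vals[idx, startsWith(samples, "b_")] + effects
  }
  expression_matrix(vals, setNames(rep(groups, each = n_per_group), samples))
}

# Bioset echoing a signature exactly (same genes, same signed fold-changes).
self_bioset <- function(sig, universe) {
  rec <- rbind(
    data.frame(gene = sig$up$gene, fold_change = sig$up$avg_fold_change,
               adj_p = 0.001),
    data.frame(gene = sig$down$gene, fold_change = sig$down$avg_fold_change,
               adj_p = 0.001))
  bioset(rec, universe_size = universe)
}

# Flip every fold-change sign of a bioset.
flip_bioset <- function(b) {
  r <- b$records
  r$fold_change <- -r$fold_change
  bioset(r, metadata = b$metadata, universe_size = b$universe_size)
}
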