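# Closed enumerations for compendium annotation. These mirror the factor
# classes used to annotate mouse-liver expression contrasts.
FACTOR_CLASSES <- c("chemical", "gene", "diet", "hormone_cytokine",
                    "life_stage", "stress", "strain", "infection", "other")
SEX_LEVELS      <- c("male", "female", "mixed", "unknown")
GENOTYPE_LEVELS <- c("wild_type", "knockout_knockdown", "transgenic", "unknown")

# Default platform universe when neither a header directive nor a companion
# matrix supplies one (order of the shared 430A/430_2 probe count).
DEFAULT_UNIVERSE <- 22690L

clean_gene_ids <- function(x) {
  x <- trimws(as.character(x))
  if (any(!nzchar(x))) stop("empty gene identifier", call. = FALSE)
  x
}

#' Annotation metadata for a bioset
#'
#' Describes the experimental contrast a bioset came from: source study,
#' contrast name, the class and name of the perturbing factor, sex and
#' genetic model. `factor_class`, `sex` and `genotype` are closed
#' enumerations (see [factor_classes()]).
#'
#' @param study_id Source study identifier (e.g. a GEO accession).
#' @param contrast_name Human-readable contrast label.
#' @param factor_class One of `factor_classes()`.
#' @param factor_name Name of the perturbing factor (e.g. a chemical).
#' @param sex One of `"male"`, `"female"`, `"mixed"`, `"unknown"`.
#' @param genotype One of `"wild_type"`, `"knockout_knockdown"`,
#'   `"transgenic"`, `"unknown"`.
#' @return An object of class `bioset_metadata`.
#' @export
bioset_metadata <- function(study_id = "", contrast_name = "",
                            factor_class = "other", factor_name = "",
                            sex = "unknown", genotype = "unknown") {
  factor_class <- match.arg(factor_class, FACTOR_CLASSES)
  sex <- match.arg(sex, SEX_LEVELS)
  genotype <- match.arg(genotype, GENOTYPE_LEVELS)
  structure(list(study_id = as.character(study_id),
                 contrast_name = as.character(contrast_name),
                 factor_class = factor_class,
                 factor_name = as.character(factor_name),
                 sex = sex, genotype = genotype),
            class = "bioset_metadata")
}

#' Closed enumeration of perturbation classes
#' @return Character vector of the recognised factor classes.
#' @export
factor_classes <- function() FACTOR_CLASSES

#' A statistically filtered gene list (bioset)
#'
#' One experiment-vs-control contrast: gene identifiers with signed
#' linear-scale fold-changes and adjusted p-values, plus annotation and the
#' size of the measured gene universe. Fold-changes follow the signed linear
#' convention: +2 means 2-fold up, -2 means 2-fold down, so |fold_change|
#' is always >= 1 and never 0.
#'
#' @param records data.frame with columns `gene`, `fold_change`, `adj_p`
#'   (`adj_p` may be `NA` when unavailable, e.g. RNK input).
#' @param metadata A [bioset_metadata()] object.
#' @param universe_size Number of genes measured on the platform; must be at
#'   least `nrow(records)`.
#' @return An object of class `bioset`.
#' @export
bioset <- function(records, metadata = bioset_metadata(),
                   universe_size = DEFAULT_UNIVERSE) {
  stopifnot(is.data.frame(records),
            all(c("gene", "fold_change", "adj_p") %in% names(records)))
  records <- records[, c("gene", "fold_change", "adj_p")]
  records$gene <- clean_gene_ids(records$gene)
  records$fold_change <- as.numeric(records$fold_change)
  records$adj_p <- as.numeric(records$adj_p)
  if (anyDuplicated(records$gene)) {
    dup <- records$gene[duplicated(records$gene)][1L]
    stop("duplicate gene in bioset: ", dup, call. = FALSE)
  }
  if (any(records$fold_change == 0, na.rm = TRUE))
    stop("fold_change must be non-zero", call. = FALSE)
  bad_p <- !is.na(records$adj_p) &
    (records$adj_p < 0 | records$adj_p > 1)
  if (any(bad_p))
    stop("adj_p outside [0,1] for gene ", records$gene[bad_p][1L],
         call. = FALSE)
  universe_size <- as.integer(universe_size)
  if (universe_size < nrow(records))
    stop("universe_size (", universe_size, ") smaller than record count (",
         nrow(records), ")", call. = FALSE)
  if (!inherits(metadata, "bioset_metadata"))
    stop("metadata must be a bioset_metadata object", call. = FALSE)
  rownames(records) <- NULL
  structure(list(records = records, metadata = metadata,
                 universe_size = universe_size),
            class = "bioset")
}

#' @export
print.bioset <- function(x, ...) {
  cat(sprintf("<bioset> %d genes (universe %d)  %s / %s\n",
              nrow(x$records), x$universe_size,
              x$metadata$study_id, x$metadata$contrast_name))
  invisible(x)
}

#' A directional gene signature
#'
#' A fixed, directional gene list: up- and down-regulated members with their
#' average signed linear fold-changes. Serves as the query in rank-based
#' similarity testing against biosets.
#'
#' @param up data.frame with columns `gene`, `avg_fold_change` (all > 0).
#' @param down data.frame with columns `gene`, `avg_fold_change` (all < 0).
#' @param name Signature name.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(up, down = NULL, name = "signature") {
  empty <- data.frame(gene = character(), avg_fold_change = numeric(),
                      stringsAsFactors = FALSE)
  norm_half <- function(h, positive) {
    if (is.null(h) || nrow(h) == 0L) return(empty)
    stopifnot(all(c("gene", "avg_fold_change") %in% names(h)))
    h <- data.frame(gene = clean_gene_ids(h$gene),
                    avg_fold_change = as.numeric(h$avg_fold_change),
                    stringsAsFactors = FALSE)
    if (positive && any(h$avg_fold_change <= 0))
      stop("up half contains non-positive fold-change", call. = FALSE)
    if (!positive && any(h$avg_fold_change >= 0))
      stop("down half contains non-negative fold-change", call. = FALSE)
    h[order(h$gene, method = "radix"), , drop = FALSE]
  }
  up <- norm_half(up, TRUE)
  down <- norm_half(down, FALSE)
  both <- intersect(up$gene, down$gene)
  if (length(both))
    stop("gene in both up and down halves: ", both[1L], call. = FALSE)
  if (anyDuplicated(c(up$gene, down$gene)))
    stop("duplicate gene within a signature half", call. = FALSE)
  rownames(up) <- rownames(down) <- NULL
  structure(list(up = up, down = down, name = as.character(name)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> '%s': %d up, %d down\n",
              x$name, nrow(x$up), nrow(x$down)))
  invisible(x)
}

#' Number of genes in a signature
#' @param x A `gene_signature`.
#' @return Integer count of up + down members.
#' @export
signature_size <- function(x) nrow(x$up) + nrow(x$down)

#' A grouped log2 expression matrix
#'
#' Holds already-normalized log2 expression values (genes x samples) with a
#' sample-to-group assignment. Normalization itself is out of scope; this
#' container feeds the differential-expression stage.
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample
#'   labels.
#' @param groups Named character vector mapping every sample label to a
#'   group label.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames", call. = FALSE)
  rownames(values) <- clean_gene_ids(rownames(values))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample labels", call. = FALSE)
  groups <- vapply(groups, as.character, character(1))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples without a group: ", paste(missing, collapse = ", "),
         call. = FALSE)
  groups <- groups[colnames(values)]
  if (any(rowSums(is.finite(values)) < 1L))
    stop("every gene row needs at least one finite value", call. = FALSE)
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d groups)\n",
              nrow(x$values), ncol(x$values), length(unique(x$groups))))
  invisible(x)
}

# ---- readers / writers ------------------------------------------------------

parse_num <- function(txt, lineno, path) {
  v <- suppressWarnings(as.numeric(txt))
  if (any(is.na(v) & !(trimws(txt) %in% c("NA", ""))))
    stop("unparseable number at line ", lineno[is.na(v)][1L], " of ", path,
         call. = FALSE)
  v
}

# Pulls the `# universe=N` header directive out of comment lines, if present.
universe_directive <- function(comments) {
  m <- regmatches(comments, regexec("^#\\s*universe\\s*=\\s*(\\d+)", comments))
  hits <- vapply(m, length, 1L) == 2L
  if (!any(hits)) return(NULL)
  as.integer(m[hits][[1L]][2L])
}

#' Read a bioset from a TSV or RNK file
#'
#' Two dialects are supported. `tsv3col` is a tab-separated file with header
#' `gene`, `fold_change`, `adj_p`; `rnk` is the conventional headerless
#' two-column (gene, signed fold-change) ranking file, in which case `adj_p`
#' is `NA` throughout. Comment lines start with `#`; the directive
#' `# universe=N` sets the platform universe size.
#'
#' @param path File path.
#' @param dialect `"tsv3col"` or `"rnk"`.
#' @param universe_size Fallback universe size when the file carries no
#'   `# universe=` directive.
#' @param metadata A [bioset_metadata()] attached to the result.
#' @return A [bioset()] with records in file order.
#' @export
read_bioset <- function(path, dialect = c("tsv3col", "rnk"),
                        universe_size = DEFAULT_UNIVERSE,
                        metadata = bioset_metadata()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  is_comment <- startsWith(lines, "#")
  u <- universe_directive(lines[is_comment])
  keep <- !is_comment & nzchar(trimws(lines))
  body <- lines[keep]; body_no <- lineno[keep]
  if (dialect == "tsv3col") {
    if (length(body) == 0L) stop("empty bioset file: ", path, call. = FALSE)
    hdr <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(trimws(hdr[1:3]), c("gene", "fold_change", "adj_p")))
      stop("tsv3col header must be gene/fold_change/adj_p in ", path,
           call. = FALSE)
    body <- body[-1L]; body_no <- body_no[-1L]
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol_needed <- if (dialect == "tsv3col") 3L else 2L
  short <- vapply(fields, length, 1L) < ncol_needed
  if (any(short))
    stop("too few columns at line ", body_no[short][1L], " of ", path,
         call. = FALSE)
  gene <- vapply(fields, `[[`, "", 1L)
  gene <- trimws(gene)
  if (anyDuplicated(gene))
    stop("duplicate gene in ", path, ": ", gene[duplicated(gene)][1L],
         call. = FALSE)
  fc <- parse_num(vapply(fields, `[[`, "", 2L), body_no, path)
  adj <- if (dialect == "tsv3col") {
    p <- parse_num(vapply(fields, `[[`, "", 3L), body_no, path)
    bad <- !is.na(p) & (p < 0 | p > 1)
    if (any(bad))
      stop("adj_p outside [0,1] at line ", body_no[bad][1L], " of ", path,
           call. = FALSE)
    p
  } else rep(NA_real_, length(gene))
  bioset(data.frame(gene = gene, fold_change = fc, adj_p = adj,
                    stringsAsFactors = FALSE),
         metadata = metadata,
         universe_size = if (is.null(u)) universe_size else u)
}

#' Write a bioset
#'
#' Writes the `tsv3col` dialect with a `# universe=N` directive; fold-changes
#' and p-values are written with full double precision so that
#' `read_bioset(write_bioset(x))` round-trips exactly.
#'
#' @param x A [bioset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bioset <- function(x, path) {
  stopifnot(inherits(x, "bioset"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# universe=%d", x$universe_size), con)
  writeLines("gene\tfold_change\tadj_p", con)
  writeLines(sprintf("%s\t%.17g\t%s", x$records$gene, x$records$fold_change,
                     ifelse(is.na(x$records$adj_p), "NA",
                            sprintf("%.17g", x$records$adj_p))), con)
  invisible(path)
}

#' Read a directional signature from GMT (+ optional fold-change table)
#'
#' The GMT file must contain exactly two tab-separated gene sets named
#' `<name>_UP` and `<name>_DOWN` (either may be empty). The optional
#' companion table (TSV, header `gene`/`avg_fold_change`) supplies signed
#' average fold-changes; without it, placeholder magnitudes of +1.5 / -1.5
#' are used and a warning is issued.
#'
#' @param gmt_path Path to the GMT file.
#' @param fc_path Optional path to the fold-change table.
#' @return A [gene_signature()].
#' @export
read_signature <- function(gmt_path, fc_path = NULL) {
  if (!file.exists(gmt_path)) stop("no such file: ", gmt_path, call. = FALSE)
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) != 2L)
    stop("GMT must contain exactly two sets (<name>_UP, <name>_DOWN)",
         call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  set_names <- vapply(fields, `[[`, "", 1L)
  up_i <- grep("_UP$", set_names); down_i <- grep("_DOWN$", set_names)
  if (length(up_i) != 1L || length(down_i) != 1L)
    stop("GMT sets must be named <name>_UP and <name>_DOWN", call. = FALSE)
  name_up <- sub("_UP$", "", set_names[up_i])
  name_down <- sub("_DOWN$", "", set_names[down_i])
  if (!identical(name_up, name_down))
    stop("UP and DOWN sets name different signatures", call. = FALSE)
  members <- function(f) {
    g <- if (length(f) > 2L) trimws(f[-(1:2)]) else character()
    g[nzchar(g)]
  }
  up_genes <- members(fields[[up_i]])
  down_genes <- members(fields[[down_i]])
  both <- intersect(up_genes, down_genes)
  if (length(both))
    stop("gene present in both UP and DOWN: ", both[1L], call. = FALSE)
  if (is.null(fc_path)) {
    warning("no fold-change table supplied; using placeholder +/-1.5 magnitudes",
            call. = FALSE)
    up_fc <- rep(1.5, length(up_genes))
    down_fc <- rep(-1.5, length(down_genes))
  } else {
    tab <- utils::read.delim(fc_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    stopifnot(all(c("gene", "avg_fold_change") %in% names(tab)))
    fc_map <- stats::setNames(as.numeric(tab$avg_fold_change),
                              trimws(tab$gene))
    missing <- setdiff(c(up_genes, down_genes), names(fc_map))
    if (length(missing))
      stop("fold-change table lacks gene: ", missing[1L], call. = FALSE)
    up_fc <- unname(fc_map[up_genes]); down_fc <- unname(fc_map[down_genes])
    if (any(up_fc <= 0))
      stop("fold-change sign conflicts with UP membership for gene ",
           up_genes[up_fc <= 0][1L], call. = FALSE)
    if (any(down_fc >= 0))
      stop("fold-change sign conflicts with DOWN membership for gene ",
           down_genes[down_fc >= 0][1L], call. = FALSE)
  }
  gene_signature(up = data.frame(gene = up_genes, avg_fold_change = up_fc,
                                 stringsAsFactors = FALSE),
                 down = data.frame(gene = down_genes, avg_fold_change = down_fc,
                                   stringsAsFactors = FALSE),
                 name = name_up)
}

#' Write a signature as GMT plus fold-change table
#'
#' @param x A [gene_signature()].
#' @param gmt_path Output GMT path.
#' @param fc_path Optional output path for the companion fold-change table;
#'   omit to write the GMT only.
#' @return `gmt_path`, invisibly.
#' @export
write_signature <- function(x, gmt_path, fc_path = NULL) {
  stopifnot(inherits(x, "gene_signature"))
  line <- function(suffix, genes)
    paste(c(paste0(x$name, suffix), "sigscreen", genes), collapse = "\t")
  writeLines(c(line("_UP", x$up$gene), line("_DOWN", x$down$gene)), gmt_path)
  if (!is.null(fc_path)) {
    tab <- rbind(x$up, x$down)
    con <- file(fc_path, "w"); on.exit(close(con))
    writeLines("gene\tavg_fold_change", con)
    writeLines(sprintf("%s\t%.17g", tab$gene, tab$avg_fold_change), con)
  }
  invisible(gmt_path)
}

#' Read a GCT 1.2 expression matrix
#'
#' @param path GCT file path.
#' @param groups Named character vector mapping sample labels to groups, or
#'   a path to a two-column TSV (header `sample`/`group`).
#' @return An [expression_matrix()].
#' @export
read_gct <- function(path, groups) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "#1.2"))
    stop("not a GCT 1.2 file: ", path, call. = FALSE)
  dims <- as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][1:2])
  tab <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                           header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) != dims[1L] || ncol(tab) - 2L != dims[2L])
    stop("GCT dimension line disagrees with table", call. = FALSE)
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- tab[[1L]]
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gt <- utils::read.delim(groups, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    groups <- stats::setNames(gt$group, gt$sample)
  }
  expression_matrix(vals, groups)
}

#' Write a GCT 1.2 expression matrix
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(sprintf("%d\t%d", nrow(x$values), ncol(x$values)), con)
  writeLines(paste(c("Name", "Description", colnames(x$values)),
                   collapse = "\t"), con)
  body <- apply(x$values, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(x$values), "na", body, sep = "\t"), con)
  invisible(path)
}
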