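#' @title Reading and writing pipeline tables
#' @description All tables are tab-delimited with a header row, as written
#'   by [write_dataset()]. Readers validate identifiers and values and
#'   fail with messages naming the offending file and column.
#' @name data_io
NULL

stop_io <- function(path, msg) {
  stop(sprintf("%s: %s", path, msg), call. = FALSE)
}

require_file <- function(path) {
  if (!file.exists(path)) stop_io(path, "file not found")
  invisible(path)
}

#' Read a gene x sample count matrix
#'
#' @param path TSV with first column `gene_id`, remaining columns samples.
#' @return numeric matrix with `scale_tag = "counts"` attribute.
#' @export
read_counts <- function(path) {
  require_file(path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene_id")
    stop_io(path, "expected a 'gene_id' column followed by sample columns")
  if (anyDuplicated(df$gene_id))
    stop_io(path, "duplicate gene identifiers")
  if (anyDuplicated(names(df)[-1]))
    stop_io(path, "duplicate sample identifiers")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))][1]
    stop_io(path, paste0("non-numeric values in column '", bad, "'"))
  }
  if (anyNA(m) || any(!is.finite(m)))
    stop_io(path, "non-finite values in count matrix")
  if (any(m < 0)) stop_io(path, "negative counts")
  rownames(m) <- df$gene_id
  attr(m, "scale_tag") <- "counts"
  m
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id`, `treatment`, `timepoint`,
#'   `replicate`.
#' @param control label of the control treatment; must be present.
#' @return design data.frame as from [generate_design()].
#' @export
read_design <- function(path, control = "control") {
  require_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment", "timepoint", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_io(path, paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$sample_id))
    stop_io(path, "duplicate sample identifiers")
  if (!control %in% df$treatment)
    stop_io(path, paste0("control treatment '", control, "' absent"))
  df$timepoint <- as.integer(df$timepoint)
  df$replicate <- as.integer(df$replicate)
  df <- df[need]
  attr(df, "control") <- control
  df
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_id`, `is_tf`, `tf_family`,
#'   `pathways` (semicolon-delimited pathway ids, empty for none).
#' @return data.frame as from [generate_annotations()].
#' @export
read_annotations <- function(path) {
  require_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA")
  need <- c("gene_id", "is_tf", "tf_family", "pathways")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_io(path, paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$gene_id))
    stop_io(path, "duplicate gene identifiers")
  df$is_tf <- as.logical(df$is_tf)
  if (anyNA(df$is_tf)) stop_io(path, "non-logical values in 'is_tf'")
  if (any(!df$is_tf & !is.na(df$tf_family)))
    stop_io(path, "tf_family set on a non-TF gene")
  df$pathways[is.na(df$pathways)] <- ""
  df[need]
}

#' Read a metabolite abundance matrix and pathway map
#'
#' @param abundance_path TSV: first column `metabolite_id`, then samples.
#' @param pathway_path TSV with columns `metabolite_id`, `pathway`.
#' @return list with `abundance` matrix and `pathway_map` (named list
#'   pathway -> metabolite ids).
#' @export
read_metabolites <- function(abundance_path, pathway_path) {
  require_file(abundance_path); require_file(pathway_path)
  df <- utils::read.delim(abundance_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "metabolite_id")
    stop_io(abundance_path,
            "expected a 'metabolite_id' column followed by sample columns")
  if (anyDuplicated(df$metabolite_id))
    stop_io(abundance_path, "duplicate metabolite identifiers")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)) || any(m <= 0))
    stop_io(abundance_path, "abundances must be finite positive numbers")
  rownames(m) <- df$metabolite_id
  pm <- utils::read.delim(pathway_path, stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "pathway") %in% names(pm)))
    stop_io(pathway_path, "missing columns: metabolite_id, pathway")
  unknown <- setdiff(pm$metabolite_id, rownames(m))
  if (length(unknown))
    stop_io(pathway_path, paste("metabolites absent from abundance table:",
                                paste(utils::head(unknown, 3),
                                      collapse = ", ")))
  list(abundance = m,
       pathway_map = split(pm$metabolite_id, pm$pathway))
}

#' Cross-check that a design covers an expression matrix
#'
#' @param mat gene x sample matrix.
#' @param design design data.frame.
#' @return invisibly TRUE; stops when any matrix sample lacks a design row.
#' @export
check_design <- function(mat, design) {
  miss <- setdiff(colnames(mat), design$sample_id)
  if (length(miss))
    stop("samples missing from design: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Write all simulated tables to a directory
#'
#' Writes counts.tsv, design.tsv, annotations.tsv, metabolites.tsv,
#' metabolite_pathways.tsv and truth.json (planted structure, for
#' benchmarking only — no pipeline stage reads it).
#'
#' @param dataset a [simulate_dataset()] list.
#' @param dir output directory, created if needed.
#' @return invisibly the directory path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(dataset$counts, file.path(dir, "counts.tsv"), "gene_id")
  utils::write.table(dataset$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(dataset$metabolites$abundance,
               file.path(dir, "metabolites.tsv"), "metabolite_id")
  mp <- dataset$metabolites$pathway_map
  utils::write.table(
    data.frame(metabolite_id = unlist(mp, use.names = FALSE),
               pathway = rep(names(mp), lengths(mp))),
    file.path(dir, "metabolite_pathways.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  truth$eigenprofiles <- NULL  # matrices round-trip poorly through JSON
  writeLines(deparse_json(list(module = as.list(truth$module),
                               hub_tfs = truth$hub_tfs,
                               planted_pathways =
                                 as.list(dataset$planted_pathways),
                               metabolite_sets =
                                 as.list(dataset$metabolites$sets),
                               config = truth$config)),
             file.path(dir, "truth.json"))
  invisible(dir)
}

write_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# minimal JSON writer for the truth file (scalars, flat lists, named lists)
deparse_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  j <- function(v) {
    if (is.list(v) && !is.null(names(v)) && any(names(v) != ""))
      paste0("{", paste(sprintf('"%s": %s', esc(names(v)),
                                vapply(v, j, character(1))),
                        collapse = ", "), "}")
    else if (is.list(v) || length(v) > 1)
      paste0("[", paste(vapply(as.list(v), j, character(1)),
                        collapse = ", "), "]")
    else if (is.character(v)) sprintf('"%s"', esc(v))
    else if (is.logical(v)) tolower(as.character(v))
    else as.character(v)
  }
  j(x)
}

#' Median-of-ratios normalization to the log2 scale
#'
#' Computes per-sample size factors as the median across reference genes
#' (genes with all-positive counts) of the ratio between the sample's
#' count and the gene's geometric mean, then returns
#' `log2(count / size_factor + 1)`. When no gene has all-positive counts,
#' falls back to total-count size factors (scaled to geometric mean 1)
#' with a warning.
#'
#' @param counts gene x sample count matrix (`scale_tag = "counts"`).
#' @return matrix on the log2 scale with `scale_tag = "log2norm"` and the
#'   size factors in `attr(, "size_factors")`.
#' @export
normalize_counts <- function(counts) {
  tag <- attr(counts, "scale_tag")
  if (!is.null(tag) && tag != "counts")
    stop("normalize_counts expects raw counts, got scale_tag '", tag, "'",
         call. = FALSE)
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos)) {
    warning("no gene with all-positive counts; ",
            "falling back to total-count size factors")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  } else {
    ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
    sf <- apply(counts[all_pos, , drop = FALSE] / ref, 2, stats::median)
  }
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  attr(out, "scale_tag") <- "log2norm"
  attr(out, "size_factors") <- sf
  out
}

#' Flag expressed genes
#'
#' The returned set is the gene universe for the network and for every
#' enrichment background ("all genes in the network").
#'
#' @param norm log2-normalized matrix.
#' @param min_mean minimum mean normalized value (log2 units).
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(norm, min_mean = 1.0) {
  tag <- attr(norm, "scale_tag")
  if (!is.null(tag) && tag != "log2norm")
    stop("filter_expressed expects log2-normalized values", call. = FALSE)
  keep <- rownames(norm)[rowMeans(norm) >= min_mean]
  if (length(keep) == 0)
    stop("expression filter removed every gene", call. = FALSE)
  keep
}

#' Call per-contrast differentially expressed genes
#'
#' For each (aphid treatment, timepoint) pair, runs a per-gene Welch
#' two-sample t-test of normalized values against control at the same
#' timepoint, adjusts p-values by Benjamini-Hochberg within the contrast,
#' and flags DEGs at `FDR < fdr_alpha` and fold change `> min_fold`
#' (strict, configurable via `strict`). This is a deliberately simple,
#' swappable stand-in for a count-model differential test: the downstream
#' network and TF machinery only needs a calibrated DEG oracle.
#'
#' @param norm log2-normalized matrix.
#' @param design design data.frame covering its samples.
#' @param fdr_alpha FDR threshold.
#' @param min_fold fold-change threshold on the natural scale.
#' @param strict use strict inequalities for both thresholds (default);
#'   otherwise non-strict.
#' @return data.frame with columns `gene`, `treatment`, `timepoint`,
#'   `log2fc`, `pvalue`, `fdr`, `is_deg`, `direction`
#'   (`up_in_infested`/`up_in_control`).
#' @export
call_degs <- function(norm, design, fdr_alpha = 0.05, min_fold = 2,
                      strict = TRUE) {
  check_design(norm, design)
  ctrl <- design_control(design)
  design <- design[match(colnames(norm), design$sample_id), ]
  treatments <- setdiff(unique(design$treatment), ctrl)
  out <- list()
  for (trt in treatments) for (tp in sort(unique(design$timepoint))) {
    g1 <- design$sample_id[design$treatment == trt & design$timepoint == tp]
    g0 <- design$sample_id[design$treatment == ctrl & design$timepoint == tp]
    if (length(g1) < 2 || length(g0) < 2) {
      warning(sprintf("contrast %s vs %s at %d DAI skipped: < 2 replicates",
                      trt, ctrl, tp))
      next
    }
    w <- welch_rows(norm[, g1, drop = FALSE], norm[, g0, drop = FALSE])
    fdr <- stats::p.adjust(w$p, method = "BH")
    lfc <- w$delta
    pass_fdr <- if (strict) fdr < fdr_alpha else fdr <= fdr_alpha
    pass_fc <- if (strict) 2^abs(lfc) > min_fold else 2^abs(lfc) >= min_fold
    out[[length(out) + 1L]] <- data.frame(
      gene = rownames(norm), treatment = trt, timepoint = tp,
      log2fc = lfc, pvalue = w$p, fdr = fdr,
      is_deg = pass_fdr & pass_fc,
      direction = ifelse(lfc >= 0, "up_in_infested", "up_in_control"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

# vectorized Welch two-sample t-test across matrix rows (x vs y)
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero-variance rows: identical groups carry no evidence, separated
  # constant groups are unambiguous
  degen <- se2 == 0
  p[degen] <- ifelse(mx[degen] == my[degen], 1, 0)
  list(delta = mx - my, t = tstat, df = df, p = p)
}
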