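#' Default pipeline configuration
#'
#' All thresholds in one place; see the individual stage functions for
#' semantics and units.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fdr_alpha = 0.05,       # DEG FDR threshold (strict)
    min_fold = 2,           # DEG fold-change threshold (strict)
    min_mean = 1.0,         # expressed-gene mean log2 cutoff
    beta = NULL,            # soft power; NULL = scale-free selection
    candidate_betas = c(1:10, 12, 14, 16, 18, 20),
    min_module_size = 30,
    cut_height = 0.90,
    merge_threshold = 0.85,
    q_kme = 0.10,           # criterion 1 module-membership fraction
    peak_pct = 0.75,        # criterion 2 peak-expression quantile
    active_frac = 0.5,      # profile-cell activity fraction (criterion 3)
    q_subnet = 0.01,        # top TOM fraction per target TF
    fisher_alpha = 0.05,
    anova_alpha = 0.05,
    tukey_alpha = 0.05,
    top_n_genes = 200,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  chk <- function(ok, what)
    if (!ok) stop("invalid configuration: ", what, call. = FALSE)
  chk(cfg$fdr_alpha > 0 && cfg$fdr_alpha <= 1, "fdr_alpha must be in (0, 1]")
  chk(cfg$min_fold >= 1, "min_fold must be >= 1")
  chk(is.null(cfg$beta) || cfg$beta >= 1, "beta must be >= 1")
  chk(cfg$q_kme > 0 && cfg$q_kme < 1, "q_kme must be in (0, 1)")
  chk(cfg$peak_pct > 0 && cfg$peak_pct < 1, "peak_pct must be in (0, 1)")
  chk(cfg$q_subnet > 0 && cfg$q_subnet < 1, "q_subnet must be in (0, 1)")
  chk(cfg$fisher_alpha > 0 && cfg$fisher_alpha <= 1,
      "fisher_alpha must be in (0, 1]")
  chk(cfg$anova_alpha > 0 && cfg$anova_alpha <= 1,
      "anova_alpha must be in (0, 1]")
  chk(cfg$min_module_size >= 2, "min_module_size must be >= 2")
  chk(cfg$cut_height > 0 && cfg$cut_height <= 1,
      "cut_height must be in (0, 1]")
  chk(cfg$merge_threshold > 0 && cfg$merge_threshold < 1,
      "merge_threshold must be in (0, 1)")
  cfg
}

#' Per-gene z-score table
#'
#' Standardizes each gene's normalized profile across all samples using
#' the sample standard deviation (ddof 1) — the convention behind the
#' expression heatmaps (cyan = low, magenta = high). Constant genes are
#' excluded and listed in `attr(, "flagged")`.
#'
#' @param norm log2-normalized matrix.
#' @param genes genes to include (must be rows of `norm`).
#' @return z-score matrix, one row per non-constant gene.
#' @export
zscore_table <- function(norm, genes = rownames(norm)) {
  miss <- setdiff(genes, rownames(norm))
  if (length(miss))
    stop("genes not in matrix: ", paste(utils::head(miss, 3),
                                        collapse = ", "), call. = FALSE)
  x <- norm[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  z <- (x[sds > 0, , drop = FALSE] - rowMeans(x[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  attr(z, "flagged") <- genes[sds == 0]
  z
}

#' TF x pathway enrichment grid
#'
#' The reporting grid behind the subnetwork-enrichment figure: rows are
#' pathways, columns are target TFs (module order, then decreasing
#' |delta| within module); cells carry the subnetwork's member-gene count
#' in the pathway and a significance marker where the raw Fisher p is at
#' or below `alpha`.
#'
#' @param enrichment combined [fisher_enrichment()] rows whose `unit` is
#'   the TF gene id.
#' @param target_tfs a [select_target_tfs()] result (selected rows used).
#' @param alpha significance marker threshold.
#' @return data.frame `pathway`, `module`, `tf`, `count`, `significant`,
#'   column order as described.
#' @export
tf_pathway_grid <- function(enrichment, target_tfs, alpha = 0.05) {
  sel <- target_tfs[target_tfs$selected, , drop = FALSE]
  sel <- sel[order(match(sel$module, unique(sel$module)),
                   -abs(sel$delta)), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sel))) {
    e <- enrichment[enrichment$unit == sel$gene[i], , drop = FALSE]
    if (nrow(e) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = e$pathway, module = sel$module[i], tf = sel$gene[i],
      count = e$k, significant = e$p <= alpha, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(pathway = character(0), module = character(0),
                      tf = character(0), count = integer(0),
                      significant = logical(0)))
  out <- do.call(rbind, rows)
  out$tf <- factor(out$tf, levels = unique(sel$gene))
  out[order(out$pathway, out$tf), , drop = FALSE]
}

#' Table-style summary of module profiles
#'
#' Mean eigengene per (treatment, timepoint) cell for each detected
#' module — the compact description of what each module does under
#' each aphid over time.
#'
#' @param assignment a [detect_modules()] result.
#' @param design design data.frame.
#' @return data.frame `module`, `treatment`, `timepoint`,
#'   `mean_eigengene`.
#' @export
module_profile_summary <- function(assignment, design) {
  rows <- list()
  for (m in colnames(assignment$eigengenes)) {
    e <- assignment$eigengenes[, m]
    d <- design[match(rownames(assignment$eigengenes), design$sample_id), ]
    agg <- stats::aggregate(e, by = list(treatment = d$treatment,
                                         timepoint = d$timepoint), FUN = mean)
    rows[[length(rows) + 1L]] <- data.frame(module = m,
                                            treatment = agg$treatment,
                                            timepoint = agg$timepoint,
                                            mean_eigengene = agg$x,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' normalize -> expressed-gene filter -> DEGs -> signed network + TOM ->
#' modules -> target TFs -> subnetworks -> module & subnetwork pathway
#' enrichment -> metabolite differential abundance -> transcript and
#' metabolite occupancy -> report tables. Identical inputs and
#' configuration give identical outputs; when `out_dir` is given, every
#' stage's table is written there as TSV.
#'
#' @param counts gene x sample count matrix.
#' @param design design data.frame.
#' @param annotations annotation data.frame.
#' @param gene_pathways named list pathway -> gene ids.
#' @param metabolites metabolite x sample abundance matrix (optional).
#' @param metabolite_pathways named list pathway -> metabolite ids.
#' @param config a [pipeline_config()] list.
#' @param out_dir optional output directory for stage TSVs.
#' @return list with every stage result: `norm`, `expressed`,
#'   `deg_table`, `network`, `assignment`, `target_tfs`, `subnetworks`,
#'   `module_enrichment`, `subnetwork_enrichment`, `metabolite_da`,
#'   `occupancy`, `top_genes`, `tf_families`, `grid`, `profile_summary`,
#'   `zscores`, `config`.
#' @export
run_pipeline <- function(counts, design, annotations, gene_pathways,
                         metabolites = NULL, metabolite_pathways = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  config <- validate_config(config)
  check_design(counts, design)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  norm <- stage("normalize", normalize_counts(counts))
  expressed <- stage("filter_expressed",
                     filter_expressed(norm, config$min_mean))
  deg_table <- stage("call_degs",
                     call_degs(norm, design, config$fdr_alpha,
                               config$min_fold))
  norm_expr <- norm[expressed, , drop = FALSE]
  network <- stage("network", build_network(
    norm_expr, beta = config$beta,
    min_module_size = config$min_module_size,
    cut_height = config$cut_height,
    merge_threshold = config$merge_threshold))
  assignment <- network$assignment
  target_tfs <- stage("target_tfs", select_target_tfs(
    annotations, assignment, norm_expr, design, deg_table,
    q_kme = config$q_kme, peak_pct = config$peak_pct,
    active_frac = config$active_frac))

  sel <- target_tfs[target_tfs$selected, , drop = FALSE]
  subnetworks <- stage("subnetworks", {
    sub <- lapply(sel$gene, function(tf)
      tf_subnetwork(network, tf, config$q_subnet))
    if (length(sub)) do.call(rbind, sub) else
      data.frame(tf = character(0), member = character(0),
                 tom_score = numeric(0))
  })

  module_enrichment <- stage("module_enrichment", {
    res <- lapply(names(assignment$sizes), function(m)
      fisher_enrichment(
        names(assignment$modules)[assignment$modules == m],
        expressed, gene_pathways, config$fisher_alpha, unit = m))
    do.call(rbind, res)
  })
  subnetwork_enrichment <- stage("subnetwork_enrichment", {
    res <- lapply(unique(subnetworks$tf), function(tf)
      fisher_enrichment(
        subnetworks$member[subnetworks$tf == tf],
        expressed, gene_pathways, config$fisher_alpha, unit = tf))
    if (length(res)) do.call(rbind, res) else
      fisher_enrichment(character(0), expressed, gene_pathways,
                        config$fisher_alpha)
  })

  da <- occ_m <- NULL
  if (!is.null(metabolites)) {
    da <- stage("metabolite_da",
                metabolite_da(metabolites, design, config$anova_alpha,
                              config$tukey_alpha))
    if (!is.null(metabolite_pathways))
      occ_m <- stage("metabolite_occupancy",
                     metabolite_occupancy(da, metabolite_pathways,
                                          rownames(metabolites)))
  }
  occ_t <- stage("transcript_occupancy",
                 transcript_occupancy(deg_table, gene_pathways, expressed))
  occupancy <- rbind(occ_t, occ_m)

  top_genes <- stage("top_genes",
                     top_module_genes(assignment, config$top_n_genes))
  tf_families <- stage("tf_families",
                       tf_family_composition(annotations,
                                             module_top_kme(assignment,
                                                            config$q_kme)))
  grid <- stage("grid", tf_pathway_grid(subnetwork_enrichment, target_tfs,
                                        config$fisher_alpha))
  profile_summary <- stage("profile_summary",
                           module_profile_summary(assignment, design))
  deg_genes <- unique(deg_table$gene[deg_table$is_deg])
  zscores <- stage("zscores",
                   zscore_table(norm, intersect(rownames(norm), deg_genes)))

  result <- list(norm = norm, expressed = expressed, deg_table = deg_table,
                 network = network, assignment = assignment,
                 target_tfs = target_tfs, subnetworks = subnetworks,
                 module_enrichment = module_enrichment,
                 subnetwork_enrichment = subnetwork_enrichment,
                 metabolite_da = da, occupancy = occupancy,
                 top_genes = top_genes, tf_families = tf_families,
                 grid = grid, profile_summary = profile_summary,
                 zscores = zscores, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write pipeline stage tables
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory, created if needed.
#' @return invisibly the directory path.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(result$deg_table, "deg.tsv")
  am <- result$assignment
  wt(data.frame(gene = names(am$modules), module = unname(am$modules),
                kme_own_module = unname(am$kme_own)), "modules.tsv")
  write_matrix(t(am$eigengenes), file.path(dir, "eigengenes.tsv"), "module")
  wt(result$target_tfs, "target_tfs.tsv")
  wt(result$subnetworks, "subnetworks.tsv")
  wt(rbind(result$module_enrichment, result$subnetwork_enrichment),
     "enrichment.tsv")
  if (!is.null(result$metabolite_da))
    wt(result$metabolite_da, "metabolite_da.tsv")
  occ <- result$occupancy
  wt(occ[occ$layer == "transcript", ], "occupancy_transcript.tsv")
  if (any(occ$layer == "metabolite"))
    wt(occ[occ$layer == "metabolite", ], "occupancy_metabolite.tsv")
  wt(result$top_genes, "top_module_genes.tsv")
  wt(result$tf_families, "tf_family_composition.tsv")
  wt(result$grid, "tf_pathway_grid.tsv")
  wt(result$profile_summary, "module_profiles.tsv")
  write_matrix(result$zscores, file.path(dir, "zscores_deg.tsv"), "gene_id")
  invisible(dir)
}
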