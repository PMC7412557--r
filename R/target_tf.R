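#' Top module-membership gene set per module
#'
#' Within each module, the `ceiling(q * n)` genes with the highest
#' own-module kME; genes tied exactly at the boundary value are all
#' included, so the set never silently drops a tied gene.
#'
#' @param assignment a [detect_modules()] result.
#' @param q fraction of each module, in (0, 1).
#' @return named list module -> character vector of gene ids.
#' @export
module_top_kme <- function(assignment, q = 0.10) {
  stopifnot(q > 0, q < 1)
  labels <- names(assignment$sizes)
  out <- lapply(labels, function(m) {
    g <- names(assignment$modules)[assignment$modules == m]
    k <- assignment$kme_own[g]
    n_take <- ceiling(q * length(g))
    cutoff <- sort(k, decreasing = TRUE)[n_take]
    g[k >= cutoff]
  })
  stats::setNames(out, labels)
}

#' Peak expression per gene
#'
#' The maximum over the treatment x timepoint condition means of
#' normalized expression — the quantity behind the 75th-percentile
#' expression criterion.
#'
#' @param norm log2-normalized matrix.
#' @param design design data.frame.
#' @return named numeric vector gene -> peak (log2 units), with the
#'   per-gene condition-mean matrix in `attr(, "condition_means")`.
#' @export
peak_expression <- function(norm, design) {
  check_design(norm, design)
  design <- design[match(colnames(norm), design$sample_id), ]
  cell <- interaction(design$treatment, design$timepoint, drop = TRUE)
  means <- vapply(levels(cell), function(cl)
    rowMeans(norm[, cell == cl, drop = FALSE]), numeric(nrow(norm)))
  peak <- apply(means, 1, max)
  attr(peak, "condition_means") <- means
  peak
}

#' Infested-minus-control profile of a module eigengene
#'
#' For each (aphid treatment, timepoint) cell, the mean eigengene value
#' minus the mean over control samples at the same timepoint. Cells whose
#' absolute delta reaches `active_frac` of the maximum are the module's
#' "active" cells; their sign is the module's expected DEG direction
#' there.
#'
#' @param eigengene sample-named numeric vector.
#' @param design design data.frame.
#' @param active_frac fraction of the maximum |delta| that keeps a cell
#'   active.
#' @return data.frame `treatment`, `timepoint`, `delta`, `active`.
#' @export
module_profile_cells <- function(eigengene, design, active_frac = 0.5) {
  design <- design[match(names(eigengene), design$sample_id), ]
  ctrl <- design_control(design)
  rows <- list()
  for (trt in setdiff(unique(design$treatment), ctrl))
    for (tp in sort(unique(design$timepoint))) {
      inf <- eigengene[design$treatment == trt & design$timepoint == tp]
      con <- eigengene[design$treatment == ctrl & design$timepoint == tp]
      rows[[length(rows) + 1L]] <-
        data.frame(treatment = trt, timepoint = tp,
                   delta = mean(inf) - mean(con))
    }
  prof <- do.call(rbind, rows)
  prof$active <- abs(prof$delta) >= active_frac * max(abs(prof$delta))
  prof
}

#' Select target transcription factors
#'
#' The three-criterion cascade for TFs likely to drive the defense
#' response:
#' \enumerate{
#'   \item in the top `q_kme` of module membership within their module;
#'   \item peak expression at or above the `peak_pct` quantile of peak
#'     expression over all expressed genes (linear-interpolation
#'     quantile);
#'   \item differentially expressed, in the profile-matched direction, in
#'     at least one of the module's active (treatment, timepoint) cells —
#'     the operational reading of "maximal expression differences between
#'     control and infested treatments associated with each module
#'     profile".
#' }
#'
#' @param annotations annotation data.frame (`is_tf` column is read;
#'   family labels never are).
#' @param assignment a [detect_modules()] result.
#' @param norm log2-normalized matrix over expressed genes.
#' @param design design data.frame.
#' @param deg_table a [call_degs()] result.
#' @param q_kme module-membership fraction for criterion 1.
#' @param peak_pct peak-expression quantile for criterion 2.
#' @param active_frac passed to [module_profile_cells()].
#' @return data.frame `gene`, `module`, `kme`, `peak_expr`, `delta`
#'   (normalized infested-minus-control difference at the module's peak
#'   cell), `c1`, `c2`, `c3`, `selected`; rows are every TF assigned to a
#'   module, sorted within module by `|delta|` descending. Selected
#'   target TFs have all three flags.
#' @export
select_target_tfs <- function(annotations, assignment, norm, design,
                              deg_table, q_kme = 0.10, peak_pct = 0.75,
                              active_frac = 0.5) {
  tf_genes <- annotations$gene_id[annotations$is_tf]
  peak <- peak_expression(norm, design)
  cm <- attr(peak, "condition_means")
  peak_cut <- stats::quantile(peak, peak_pct, type = 7)
  top_sets <- module_top_kme(assignment, q_kme)
  ctrl <- design_control(design)

  rows <- list()
  for (m in names(assignment$sizes)) {
    prof <- module_profile_cells(assignment$eigengenes[, m], design,
                                 active_frac)
    act <- prof[prof$active, , drop = FALSE]
    peak_cell <- prof[which.max(abs(prof$delta)), ]
    mg <- names(assignment$modules)[assignment$modules == m]
    for (g in intersect(mg, tf_genes)) {
      c1 <- g %in% top_sets[[m]]
      c2 <- peak[g] >= peak_cut
      hits <- merge(act, deg_table[deg_table$gene == g, ],
                    by = c("treatment", "timepoint"))
      c3 <- any(hits$is_deg & sign(hits$log2fc) == sign(hits$delta))
      delta <- cm[g, paste(peak_cell$treatment, peak_cell$timepoint,
                           sep = ".")] -
        cm[g, paste(ctrl, peak_cell$timepoint, sep = ".")]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, module = m, kme = unname(assignment$kme_own[g]),
        peak_expr = unname(peak[g]), delta = unname(delta),
        c1 = c1, c2 = c2, c3 = c3, selected = c1 && c2 && c3,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(0), module = character(0),
                      kme = numeric(0), peak_expr = numeric(0),
                      delta = numeric(0), c1 = logical(0), c2 = logical(0),
                      c3 = logical(0), selected = logical(0)))
  out <- do.call(rbind, rows)
  out[order(match(out$module, names(assignment$sizes)), -abs(out$delta)), ,
      drop = FALSE]
}

#' Extract a target TF's top-1% TOM subnetwork
#'
#' Ranks every other network gene by topological overlap with the TF and
#' keeps the top `ceiling(q * (N - 1))`, plus any gene tied exactly at
#' the boundary score.
#'
#' @param network a [build_network()] result (or any list with a `tom`
#'   matrix).
#' @param tf gene id present in the network.
#' @param q fraction of the other `N - 1` genes to keep.
#' @return data.frame `tf`, `member`, `tom_score` sorted by score
#'   descending, with the boundary score in `attr(, "cutoff")`.
#' @export
tf_subnetwork <- function(network, tf, q = 0.01) {
  tom <- if (is.list(network)) network$tom else network
  if (!tf %in% rownames(tom))
    stop("gene '", tf, "' is not in the network", call. = FALSE)
  scores <- tom[tf, setdiff(rownames(tom), tf)]
  n_take <- ceiling(q * length(scores))
  cutoff <- sort(scores, decreasing = TRUE)[n_take]
  members <- scores[scores >= cutoff]
  members <- members[order(-members, names(members))]
  structure(data.frame(tf = tf, member = names(members),
                       tom_score = unname(members),
                       stringsAsFactors = FALSE),
            cutoff = unname(cutoff))
}

#' Top-n genes per module by module membership
#'
#' @param assignment a [detect_modules()] result.
#' @param n genes per module (all module genes when the module is
#'   smaller).
#' @return data.frame `module`, `gene`, `kme`, `rank` with kME
#'   non-increasing within module.
#' @export
top_module_genes <- function(assignment, n = 200) {
  stopifnot(n >= 1)
  out <- lapply(names(assignment$sizes), function(m) {
    g <- names(assignment$modules)[assignment$modules == m]
    k <- sort(assignment$kme_own[g], decreasing = TRUE)
    k <- utils::head(k, n)
    data.frame(module = m, gene = names(k), kme = unname(k),
               rank = seq_along(k), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' TF family composition of per-module gene sets
#'
#' Among the TFs inside each module's gene set (typically the top-10%-kME
#' set), the fraction belonging to each TF family. Modules whose set
#' contains no TF are omitted.
#'
#' @param annotations annotation data.frame.
#' @param gene_sets named list module -> gene ids.
#' @return data.frame `module`, `tf_family`, `n`, `fraction`; fractions
#'   sum to 1 within each module.
#' @export
tf_family_composition <- function(annotations, gene_sets) {
  ann <- annotations[annotations$is_tf, ]
  out <- list()
  for (m in names(gene_sets)) {
    fams <- ann$tf_family[ann$gene_id %in% gene_sets[[m]]]
    if (length(fams) == 0) next
    tab <- table(fams)
    out[[length(out) + 1L]] <- data.frame(
      module = m, tf_family = names(tab), n = as.integer(tab),
      fraction = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(module = character(0), tf_family = character(0),
                      n = integer(0), fraction = numeric(0)))
  do.call(rbind, out)
}
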