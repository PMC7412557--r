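#' Fisher's exact pathway enrichment against a network background
#'
#' One-sided (enrichment) hypergeometric right-tail test for each
#' pathway: with `N` background genes, `K` of them in the pathway, `n`
#' unit genes and `k` in both, `p = P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)`. The background is the expressed-gene
#' universe ("all genes in the network"). Benjamini-Hochberg adjusted
#' p-values across the unit's pathways are reported alongside, but the
#' significance flag uses the raw p at `alpha`, matching the study's
#' stated rule.
#'
#' @param unit_genes gene set under test (module or TF subnetwork);
#'   must be a subset of `background`.
#' @param background expressed network gene universe.
#' @param pathway_map named list pathway -> gene ids.
#' @param alpha raw-p significance threshold.
#' @param unit label recorded in the output.
#' @return data.frame `unit`, `pathway`, `k`, `n`, `K`, `N`,
#'   `odds_ratio`, `p`, `p_bh`, `significant`. Pathways with no
#'   background member are skipped (listed in `attr(, "skipped")`).
#' @export
fisher_enrichment <- function(unit_genes, background, pathway_map,
                              alpha = 0.05, unit = "unit") {
  if (!all(unit_genes %in% background))
    stop("unit genes must be a subset of the background", call. = FALSE)
  N <- length(unique(background))
  n <- length(unique(unit_genes))
  rows <- list(); skipped <- character(0)
  for (p_id in names(pathway_map)) {
    path_genes <- intersect(pathway_map[[p_id]], background)
    K <- length(path_genes)
    if (K == 0) { skipped <- c(skipped, p_id); next }
    k <- length(intersect(unit_genes, path_genes))
    pval <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max(1, (n - k) * (K - k))
    rows[[length(rows) + 1L]] <- data.frame(
      unit = unit, pathway = p_id, k = k, n = n, K = K, N = N,
      odds_ratio = or, p = pval, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(structure(data.frame(unit = character(0), pathway = character(0),
                                k = integer(0), n = integer(0),
                                K = integer(0), N = integer(0),
                                odds_ratio = numeric(0), p = numeric(0),
                                p_bh = numeric(0), significant = logical(0)),
                     skipped = skipped))
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p <= alpha
  structure(out, skipped = skipped)
}

#' Differential metabolite abundance (ANOVA + Tukey HSD)
#'
#' Per metabolite and timepoint: one-way ANOVA across treatments on
#' log-transformed abundance; when the ANOVA p-value is below `alpha`,
#' Tukey HSD comparisons of each aphid treatment against control.
#' A metabolite is significant for a treatment when the ANOVA passes and
#' the Tukey adjusted p is at most `tukey_alpha`. Metabolites that are
#' constant within a timepoint get p = 1 with `degenerate = TRUE`.
#'
#' @param metab metabolite x sample positive abundance matrix.
#' @param design design data.frame.
#' @param alpha ANOVA threshold (strict, `p < alpha`).
#' @param tukey_alpha Tukey threshold (non-strict, `p <= tukey_alpha`).
#' @return data.frame `metabolite`, `timepoint`, `anova_f`, `anova_p`,
#'   `treatment`, `tukey_p`, `direction`, `significant`, `degenerate`
#'   (one row per metabolite x timepoint x aphid treatment).
#' @export
metabolite_da <- function(metab, design, alpha = 0.05,
                          tukey_alpha = 0.05) {
  check_design(metab, design)
  design <- design[match(colnames(metab), design$sample_id), ]
  ctrl <- design_control(design)
  trts <- setdiff(unique(design$treatment), ctrl)
  rows <- list()
  for (tp in sort(unique(design$timepoint))) {
    sel <- design$timepoint == tp
    grp <- factor(design$treatment[sel],
                  levels = c(ctrl, trts))
    x <- log(metab[, sel, drop = FALSE])
    for (met in rownames(metab)) {
      y <- x[met, ]
      degen <- stats::var(y) == 0
      if (degen) {
        fstat <- NA_real_; pa <- 1
      } else {
        fit <- stats::aov(y ~ grp)
        an <- summary(fit)[[1]]
        fstat <- an[["F value"]][1]
        pa <- an[["Pr(>F)"]][1]
        if (is.na(pa)) { pa <- 1; degen <- TRUE }  # zero residual variance
        tuk <- if (pa < alpha) stats::TukeyHSD(fit)$grp else NULL
      }
      for (trt in trts) {
        dirn <- mean(y[grp == trt]) - mean(y[grp == ctrl])
        tp_p <- if (!degen && pa < alpha) {
          tuk[paste(trt, ctrl, sep = "-"), "p adj"]
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = met, timepoint = tp, anova_f = fstat, anova_p = pa,
          treatment = trt, tukey_p = tp_p,
          direction = ifelse(dirn >= 0, "up_in_infested", "up_in_control"),
          significant = !degen && pa < alpha && !is.na(tp_p) &&
            tp_p <= tukey_alpha,
          degenerate = degen, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Transcript pathway occupancy
#'
#' For each pathway, contrast and direction: the percentage of the
#' pathway's expressed genes that are DEGs with that direction —
#' "number of genes upregulated in control or aphid-infested plants
#' relative to all expressed genes in that pathway". Pathways with no
#' expressed gene are omitted; genes in several pathways count once per
#' pathway.
#'
#' @param deg_table a [call_degs()] result.
#' @param pathway_map named list pathway -> gene ids.
#' @param expressed expressed-gene universe (the denominators' scope).
#' @return occupancy data.frame (`layer = "transcript"`).
#' @export
transcript_occupancy <- function(deg_table, pathway_map, expressed) {
  hits <- deg_table[deg_table$is_deg, ]
  hits <- data.frame(id = hits$gene, treatment = hits$treatment,
                     timepoint = hits$timepoint, direction = hits$direction,
                     stringsAsFactors = FALSE)
  # every contrast present in the DEG table yields cells, DEGs or not
  all_contrasts <- unique(deg_table[, c("treatment", "timepoint")])
  occupancy_with_contrasts(hits, all_contrasts, pathway_map, expressed,
                           "transcript")
}

#' Metabolite pathway occupancy
#'
#' As [transcript_occupancy()], on differentially abundant metabolites
#' over detected metabolites per pathway.
#'
#' @param da a [metabolite_da()] result.
#' @param pathway_map named list pathway -> metabolite ids.
#' @param detected detected-metabolite universe.
#' @return occupancy data.frame (`layer = "metabolite"`).
#' @export
metabolite_occupancy <- function(da, pathway_map, detected) {
  hits <- da[da$significant, ]
  hits <- data.frame(id = hits$metabolite, treatment = hits$treatment,
                     timepoint = hits$timepoint, direction = hits$direction,
                     stringsAsFactors = FALSE)
  all_contrasts <- unique(da[, c("treatment", "timepoint")])
  occupancy_with_contrasts(hits, all_contrasts, pathway_map, detected,
                           "metabolite")
}

occupancy_with_contrasts <- function(hits, contrasts, pathway_map,
                                     universe, layer) {
  rows <- list()
  for (p_id in names(pathway_map)) {
    denom_ids <- intersect(pathway_map[[p_id]], universe)
    if (length(denom_ids) == 0) next
    for (ci in seq_len(nrow(contrasts)))
      for (dirn in c("up_in_infested", "up_in_control")) {
        trt <- contrasts$treatment[ci]; tp <- contrasts$timepoint[ci]
        num <- sum(hits$id %in% denom_ids & hits$treatment == trt &
                     hits$timepoint == tp & hits$direction == dirn)
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = p_id, treatment = trt, timepoint = tp,
          direction = dirn, layer = layer, numerator = num,
          denominator = length(denom_ids),
          percent = 100 * num / length(denom_ids),
          stringsAsFactors = FALSE)
      }
  }
  if (length(rows) == 0)
    return(data.frame(pathway = character(0), treatment = character(0),
                      timepoint = integer(0), direction = character(0),
                      layer = character(0), numerator = integer(0),
                      denominator = integer(0), percent = numeric(0)))
  do.call(rbind, rows)
}
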