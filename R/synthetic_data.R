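#' Built-in module expression profiles
#'
#' Returns the six planted co-expression profiles used by the synthetic
#' generator. Each profile is a treatment x timepoint matrix of signed
#' effects on the log2 scale (before scaling by `effect_size`):
#' \describe{
#'   \item{M1}{down under both aphids at all timepoints (up in controls)}
#'   \item{M7}{up at 5 DAI under both aphids only (basal defense burst)}
#'   \item{M2}{up at (GB, 5) and (YSA, 15)}
#'   \item{M3}{up under GB at all timepoints, not under YSA}
#'   \item{M4}{up under GB at all timepoints and under YSA at 15 DAI}
#'   \item{M6}{up under YSA at all timepoints, not under GB}
#' }
#' Control cells are always zero: profiles are defined relative to
#' uninfested plants at the same timepoint.
#'
#' @param timepoints integer timepoints in days after infestation (DAI).
#' @param treatments treatment labels; first is the uninfested control.
#' @return named list of numeric matrices (treatment x timepoint),
#'   class `"module_profiles"`.
#' @export
module_profiles <- function(timepoints = c(5L, 10L, 15L),
                            treatments = c("control", "GB", "YSA")) {
  stopifnot(length(timepoints) >= 1, length(treatments) >= 2)
  blank <- function() {
    m <- matrix(0, nrow = length(treatments), ncol = length(timepoints),
                dimnames = list(treatments, as.character(timepoints)))
    m
  }
  tp <- as.character(timepoints)
  last <- tp[length(tp)]
  ramp_dn <- seq(1.2, 0.6, length.out = length(tp))
  ramp_up <- seq(0.6, 1.2, length.out = length(tp))
  # cell magnitudes vary within each qualitative profile (responses ramp
  # up or down over the infestation) so that profiles sharing cells stay
  # distinguishable, as separately detected modules must be
  p <- list()
  m <- blank(); m["GB", ] <- -ramp_up; m["YSA", ] <- -ramp_up; p$M1 <- m
  m <- blank(); m["GB", tp[1]] <- 1.2; m["YSA", tp[1]] <- 1.2; p$M7 <- m
  m <- blank(); m["GB", tp[1]] <- 1.2; m["YSA", last] <- 1.2; p$M2 <- m
  m <- blank(); m["GB", ] <- ramp_dn; p$M3 <- m
  m <- blank(); m["GB", ] <- ramp_up; m["YSA", last] <- 1.2; p$M4 <- m
  m <- blank(); m["YSA", ] <- ramp_up; p$M6 <- m
  structure(p, class = "module_profiles",
            timepoints = timepoints, treatments = treatments)
}

#' Generate a fully crossed factorial sample design
#'
#' Emulates the study layout: treatments x harvest timepoints x
#' biological replicates, fully crossed, with opaque unique sample ids.
#'
#' @param n_reps biological replicates per cell (>= 2).
#' @param timepoints integer vector of timepoints (DAI).
#' @param treatments treatment labels; exactly one must equal `control`.
#' @param control label of the uninfested control treatment.
#' @return data.frame with columns `sample_id`, `treatment`, `timepoint`,
#'   `replicate`; the control label is stored in `attr(, "control")`.
#' @examples
#' d <- generate_design(3, c(5, 10, 15), c("control", "GB", "YSA"))
#' nrow(d)  # 27
#' @export
generate_design <- function(n_reps, timepoints, treatments,
                            control = "control") {
  if (length(timepoints) == 0 || length(treatments) == 0)
    stop("invalid configuration: empty factor list", call. = FALSE)
  if (n_reps < 2)
    stop("invalid configuration: n_reps must be >= 2", call. = FALSE)
  if (sum(treatments == control) != 1)
    stop("invalid configuration: treatments must include exactly one ",
         "control label ('", control, "')", call. = FALSE)
  if (anyDuplicated(treatments) || anyDuplicated(timepoints))
    stop("invalid configuration: duplicated factor levels", call. = FALSE)
  grid <- expand.grid(replicate = seq_len(n_reps),
                      timepoint = as.integer(timepoints),
                      treatment = treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = sprintf("S_%s_T%d_R%d", grid$treatment, grid$timepoint,
                        grid$replicate),
    treatment = grid$treatment,
    timepoint = grid$timepoint,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  attr(design, "control") <- control
  design
}

design_control <- function(design) {
  ctrl <- attr(design, "control")
  if (is.null(ctrl)) "control" else ctrl
}

profile_signal <- function(profile, design) {
  # per-sample signed signal from a treatment x timepoint effect matrix
  profile[cbind(design$treatment, as.character(design$timepoint))]
}

#' Simulate a planted-module RNA-seq count matrix
#'
#' Each module draws a per-sample eigenprofile
#' `signal(treatment, timepoint) * effect_size + N(0, noise_sd)`; a member
#' gene's log2 mean is `baseline + loading * eigenprofile + distortion`,
#' and counts are drawn negative-binomially around `2^log2mean` with the
#' given dispersion (variance `mu + dispersion * mu^2`). The distortion is
#' a per-gene, per-condition random offset with sd
#' `distortion_scale * (1 - loading) * effect_size / 3`, vanishing under a
#' global null (no response, no response distortion): loading controls both the
#' amplitude and the fidelity with which a gene tracks its module
#' profile, so tightly coupled genes (the hubs) rank at the top of module
#' membership while loosely coupled members wander around the shared
#' profile, as real module members do. Background genes have loading 0
#' and independent per-sample biological noise.
#'
#' Baselines are centred so that each gene's average log2 abundance is
#' uniform on `baseline_range` regardless of module sign — treatment
#' effects redistribute expression across conditions around a gene's
#' characteristic level. Hub TFs draw their level from
#' `hub_baseline_range` (upper range): planted hubs emulate robustly
#' expressed regulators, the kind the peak-expression criterion is meant
#' to retain.
#'
#' @param profiles a `module_profiles()` list (or any named list of
#'   treatment x timepoint effect matrices).
#' @param n_genes_per_module genes planted per module (> 0).
#' @param n_background unstructured background genes (>= 0).
#' @param design a `generate_design()` data.frame.
#' @param effect_size log2-scale effect at loading 1 (> 0 unless running
#'   a deliberate null with `effect_size = 0`).
#' @param noise_sd replicate-level Gaussian sd of the eigenprofile (log2).
#' @param bg_noise_sd per-sample independent biological noise sd (log2) of
#'   background genes; they have loading 0 on every eigenprofile but are
#'   not biologically constant.
#' @param dispersion negative-binomial dispersion on the natural scale.
#' @param n_hubs planted TF hub genes per module.
#' @param loading_range,hub_loading_range uniform loading ranges for
#'   ordinary members and hubs (disjoint by default: hub status is a
#'   coupling property, not the tail of the member distribution).
#' @param distortion_scale scale of the per-condition profile distortion
#'   (log2 units at loading 0 under the default effect size).
#' @param baseline_range,hub_baseline_range uniform ranges of per-gene
#'   mean log2 abundance for ordinary genes and hub TFs.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `counts` (gene x sample integer matrix, attr
#'   `scale_tag = "counts"`) and `truth` (planted structure: per-gene
#'   module label and loading, hub TF sets, the eigenprofiles, and the
#'   generator configuration).
#' @export
generate_expression <- function(profiles = module_profiles(),
                                n_genes_per_module = 150L,
                                n_background = 1100L,
                                design = generate_design(3L, c(5L, 10L, 15L),
                                                         c("control", "GB", "YSA")),
                                effect_size = 3,
                                noise_sd = 0.3,
                                bg_noise_sd = noise_sd,
                                dispersion = 0.01,
                                n_hubs = 5L,
                                loading_range = c(0.5, 0.88),
                                hub_loading_range = c(0.95, 1),
                                distortion_scale = 2,
                                baseline_range = c(5, 9),
                                hub_baseline_range = c(7, 9),
                                seed = 1L) {
  if (n_genes_per_module <= 0)
    stop("invalid configuration: n_genes_per_module must be positive",
         call. = FALSE)
  if (n_background < 0 || noise_sd <= 0 || dispersion <= 0 ||
      effect_size < 0 || n_hubs < 0 || n_hubs > n_genes_per_module)
    stop("invalid configuration for generate_expression", call. = FALSE)

  set.seed(as.integer(seed))
  n_samples <- nrow(design)
  mods <- names(profiles)
  n_mod_genes <- length(mods) * n_genes_per_module
  n_genes <- n_mod_genes + n_background

  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  module_of <- c(rep(mods, each = n_genes_per_module),
                 rep("background", n_background))
  names(module_of) <- gene_ids

  loading <- numeric(n_genes)
  names(loading) <- gene_ids
  hub_sets <- list()
  eigenprofiles <- matrix(0, nrow = length(mods), ncol = n_samples,
                          dimnames = list(mods, design$sample_id))

  log2mu <- matrix(0, nrow = n_genes, ncol = n_samples,
                   dimnames = list(gene_ids, design$sample_id))
  level <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
  cell <- as.integer(interaction(design$treatment, design$timepoint,
                                 drop = TRUE))
  n_cells <- max(cell)

  for (mi in seq_along(mods)) {
    m <- mods[mi]
    idx <- which(module_of == m)
    e <- profile_signal(profiles[[m]], design) * effect_size +
      stats::rnorm(n_samples, 0, noise_sd)
    eigenprofiles[m, ] <- e
    lo <- stats::runif(length(idx), loading_range[1], loading_range[2])
    if (n_hubs > 0) {
      hub_idx <- seq_len(n_hubs)
      lo[hub_idx] <- stats::runif(n_hubs, hub_loading_range[1],
                                  hub_loading_range[2])
      level[idx[hub_idx]] <- stats::runif(n_hubs, hub_baseline_range[1],
                                          hub_baseline_range[2])
      hub_sets[[m]] <- gene_ids[idx[hub_idx]]
    } else hub_sets[[m]] <- character(0)
    loading[idx] <- lo
    distort <- matrix(stats::rnorm(length(idx) * n_cells), length(idx),
                      n_cells) * (distortion_scale * (1 - lo) *
                                    effect_size / 3)
    # centre so the gene's mean log2 abundance equals its drawn level
    baseline <- level[idx] - lo * mean(e)
    log2mu[idx, ] <- baseline + outer(lo, e) + distort[, cell]
  }
  bg <- which(module_of == "background")
  if (length(bg))
    log2mu[bg, ] <- level[bg] +
      matrix(stats::rnorm(length(bg) * n_samples, 0, bg_noise_sd),
             nrow = length(bg))

  mu <- 2^log2mu
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / dispersion),
                   nrow = n_genes, dimnames = dimnames(log2mu))
  attr(counts, "scale_tag") <- "counts"

  truth <- list(
    module = module_of,
    loading = loading,
    hub_tfs = hub_sets,
    eigenprofiles = eigenprofiles,
    config = list(effect_size = effect_size, noise_sd = noise_sd,
                  bg_noise_sd = bg_noise_sd, dispersion = dispersion,
                  n_hubs = n_hubs, loading_range = loading_range,
                  hub_loading_range = hub_loading_range,
                  distortion_scale = distortion_scale,
                  baseline_range = baseline_range,
                  hub_baseline_range = hub_baseline_range,
                  n_genes_per_module = n_genes_per_module,
                  n_background = n_background, seed = as.integer(seed))
  )
  list(counts = counts, truth = truth)
}

#' Generate gene annotations with planted pathway enrichments
#'
#' Flags planted hub TFs (plus a sprinkling of background TFs so that
#' selection precision is testable) with families drawn from those named
#' for switchgrass defense modules (WRKY, NAC, MYB, bHLH, bZIP, AP2/ERF,
#' C2H2, FAR1); family labels are cosmetic metadata that the selection
#' logic never reads. One pathway per module draws `enrichment_fraction`
#' of its members from that module and the rest uniformly from outside it;
#' the remaining pathways are drawn uniformly from the whole universe.
#'
#' @param truth the `truth` element of [generate_expression()].
#' @param n_pathways total pathways (>= number of modules).
#' @param pathway_size genes per pathway.
#' @param enrichment_fraction fraction of a planted pathway drawn from its
#'   module, in (0, 1].
#' @param background_tf_fraction fraction of background genes flagged as
#'   (unselected-truth) TFs.
#' @param seed integer seed.
#' @return list with `annotations` (data.frame: `gene_id`, `is_tf`,
#'   `tf_family`, `pathways` semicolon-delimited), `pathway_map` (named
#'   list pathway -> gene ids) and `planted_pathways` (named chr vector
#'   module -> pathway id).
#' @export
generate_annotations <- function(truth, n_pathways = 40L, pathway_size = 60L,
                                 enrichment_fraction = 0.6,
                                 background_tf_fraction = 0.05,
                                 seed = 1L) {
  if (enrichment_fraction <= 0 || enrichment_fraction > 1)
    stop("invalid configuration: enrichment_fraction must be in (0, 1]",
         call. = FALSE)
  genes <- names(truth$module)
  if (pathway_size > length(genes))
    stop("invalid configuration: pathway_size exceeds gene universe",
         call. = FALSE)
  mods <- setdiff(unique(truth$module), "background")
  if (n_pathways < length(mods))
    stop("invalid configuration: need at least one pathway per module",
         call. = FALSE)
  set.seed(as.integer(seed))

  families <- c("WRKY", "NAC", "MYB", "bHLH", "bZIP", "AP2/ERF", "C2H2",
                "FAR1")
  planted_tfs <- unlist(truth$hub_tfs, use.names = FALSE)
  bg_genes <- genes[truth$module == "background"]
  n_bg_tf <- round(background_tf_fraction * length(bg_genes))
  bg_tfs <- if (n_bg_tf > 0) sample(bg_genes, n_bg_tf) else character(0)
  tfs <- c(planted_tfs, bg_tfs)

  pathway_ids <- sprintf("path%02d", seq_len(n_pathways))
  planted <- stats::setNames(pathway_ids[seq_along(mods)], mods)
  pathway_map <- vector("list", n_pathways)
  names(pathway_map) <- pathway_ids
  for (i in seq_len(n_pathways)) {
    if (i <= length(mods)) {
      m <- mods[i]
      inside <- genes[truth$module == m]
      n_in <- min(length(inside), max(1L, round(enrichment_fraction *
                                                  pathway_size)))
      n_out <- pathway_size - n_in
      outside <- setdiff(genes, inside)
      pathway_map[[i]] <- c(sample(inside, n_in),
                            if (n_out > 0) sample(outside, n_out))
    } else {
      pathway_map[[i]] <- sample(genes, pathway_size)
    }
  }

  fam <- stats::setNames(rep(NA_character_, length(genes)), genes)
  fam[tfs] <- sample(families, length(tfs), replace = TRUE)
  memb <- stats::setNames(rep("", length(genes)), genes)
  for (p in pathway_ids) {
    g <- pathway_map[[p]]
    memb[g] <- ifelse(memb[g] == "", p, paste(memb[g], p, sep = ";"))
  }
  annotations <- data.frame(
    gene_id = genes,
    is_tf = genes %in% tfs,
    tf_family = unname(fam),
    pathways = unname(memb),
    stringsAsFactors = FALSE
  )
  list(annotations = annotations, pathway_map = pathway_map,
       planted_pathways = planted)
}

#' Simulate a metabolite abundance table with planted response sets
#'
#' Plants the four qualitative metabolite behaviours seen in infested
#' switchgrass: set 1 elevated under GB (peaking 10 DAI), set 2 elevated
#' under YSA (peaking 15 DAI), sets 3 and 4 elevated under both aphids
#' with GB- and YSA-biased magnitudes, plus unresponsive null metabolites.
#' Abundances are lognormal around a planted log-scale signal.
#'
#' @param design a `generate_design()` data.frame.
#' @param n_per_set metabolites per planted set (>= 1).
#' @param n_null unresponsive metabolites.
#' @param effect_size log-scale elevation at the set's peak.
#' @param noise_sd lognormal noise sd.
#' @param seed integer seed.
#' @return list with `abundance` (metabolite x sample positive matrix),
#'   `sets` (metabolite -> planted set label, "null" for unresponsive),
#'   and `pathway_map` (named list pathway -> metabolites; one pathway per
#'   planted set plus one for the nulls).
#' @export
generate_metabolites <- function(design, n_per_set = 10L, n_null = 160L,
                                 effect_size = 1.5, noise_sd = 0.3,
                                 seed = 1L) {
  if (n_per_set < 1)
    stop("invalid configuration: n_per_set must be >= 1", call. = FALSE)
  if (n_null < 0 || noise_sd <= 0 || effect_size < 0)
    stop("invalid configuration for generate_metabolites", call. = FALSE)
  set.seed(as.integer(seed))
  tps <- sort(unique(design$timepoint))
  peak10 <- tps[min(2L, length(tps))]
  peak15 <- tps[length(tps)]
  # per-set signed log-scale signal as a function of (treatment, timepoint)
  ramp <- function(tp, peak) 0.5 + 0.5 * (tp == peak)
  sig <- function(set, trt, tp) {
    if (trt == design_control(design)) return(0)
    switch(set,
      set1 = if (trt == "GB") ramp(tp, peak10) else 0,
      set2 = if (trt == "YSA") ramp(tp, peak15) else 0,
      set3 = if (trt == "GB") 1 else 0.5,
      set4 = if (trt == "YSA") 1 else 0.5,
      0)
  }
  sets <- c(rep(c("set1", "set2", "set3", "set4"), each = n_per_set),
            rep("null", n_null))
  ids <- sprintf("met%03d", seq_along(sets))
  names(sets) <- ids
  base <- stats::runif(length(ids), 2, 6)  # log-scale baselines
  ab <- matrix(0, nrow = length(ids), ncol = nrow(design),
               dimnames = list(ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    s <- vapply(sets, sig, numeric(1), trt = design$treatment[j],
                tp = design$timepoint[j])
    ab[, j] <- exp(base + s * effect_size +
                     stats::rnorm(length(ids), 0, noise_sd))
  }
  pathway_map <- split(ids, sets)
  names(pathway_map) <- paste0("mpath_", names(pathway_map))
  list(abundance = ab, sets = sets, pathway_map = pathway_map)
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper drawing the expression matrix, annotations and
#' metabolite table for the default 3 treatments x 3 timepoints x 3
#' replicates layout with the six built-in module profiles. All
#' sub-generators are seeded deterministically from `seed`.
#'
#' @param seed integer master seed.
#' @param ... overrides passed to [generate_expression()].
#' @return list: `design`, `counts`, `truth`, `annotations`,
#'   `pathway_map`, `planted_pathways`, `metabolites` (the
#'   [generate_metabolites()] list).
#' @export
simulate_dataset <- function(seed = 1L, ...) {
  design <- generate_design(3L, c(5L, 10L, 15L), c("control", "GB", "YSA"))
  expr <- generate_expression(design = design, seed = seed, ...)
  ann <- generate_annotations(expr$truth, seed = seed + 1L)
  metab <- generate_metabolites(design, seed = seed + 2L)
  list(design = design, counts = expr$counts, truth = expr$truth,
       annotations = ann$annotations, pathway_map = ann$pathway_map,
       planted_pathways = ann$planted_pathways, metabolites = metab)
}
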