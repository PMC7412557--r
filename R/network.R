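#' Signed weighted adjacency matrix
#'
#' `a_ij = ((1 + r_ij) / 2)^beta` with `r` the Pearson correlation of
#' gene profiles across all samples, so anticorrelated genes get
#' near-zero weight. Zero-variance genes are dropped with a warning
#' before the correlation.
#'
#' @param norm log2-normalized gene x sample matrix (expressed genes).
#' @param beta soft-thresholding power (>= 1).
#' @return symmetric adjacency matrix with unit diagonal, entries in
#'   `[0, 1]`, attr `beta`.
#' @export
signed_adjacency <- function(norm, beta = 12) {
  if (ncol(norm) < 4)
    stop("need at least 4 samples for a stable correlation network",
         call. = FALSE)
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  v <- apply(norm, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped before correlation")
    norm <- norm[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(norm))
  a <- ((1 + r) / 2)^beta
  # clamp correlation round-off so downstream [0,1] invariants hold exactly
  a[a > 1] <- 1; a[a < 0] <- 0
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Pick the soft-thresholding power by scale-free fit
#'
#' For each candidate power, bins the connectivity distribution and fits
#' `log10(frequency) ~ log10(connectivity)`; the signed fit index is
#' `-sign(slope) * R^2`, so only a decreasing (scale-free-like) tail can
#' score highly. Returns the smallest candidate whose signed fit reaches
#' `r2_target` while retaining a mean connectivity of at least
#' `min_connectivity` (powers that shatter the network into isolated
#' nodes can fit a straight line spuriously); when none qualifies,
#' returns `fallback` with a warning (the signed-network convention).
#'
#' @param norm log2-normalized matrix.
#' @param candidate_betas candidate powers, ascending order recommended.
#' @param r2_target required signed scale-free fit.
#' @param n_bins connectivity histogram bins.
#' @param min_connectivity smallest acceptable mean connectivity.
#' @param fallback power returned when no candidate fits.
#' @return chosen power, with the per-candidate fit table in
#'   `attr(, "fit_table")`.
#' @export
pick_soft_threshold <- function(norm, candidate_betas = c(1:10, 12, 14, 16,
                                                          18, 20),
                                r2_target = 0.8, n_bins = 10,
                                min_connectivity = 1, fallback = 12) {
  if (length(candidate_betas) == 0)
    stop("candidate_betas must be non-empty", call. = FALSE)
  v <- apply(norm, 1, stats::var)
  s <- (1 + stats::cor(t(norm[v > 0, , drop = FALSE]))) / 2
  s[s > 1] <- 1; s[s < 0] <- 0
  diag(s) <- 0
  fits <- vapply(candidate_betas, function(b) {
    scale_free_fit(rowSums(s^b), n_bins)
  }, numeric(1))
  mean_k <- vapply(candidate_betas, function(b) mean(rowSums(s^b)),
                   numeric(1))
  tab <- data.frame(beta = candidate_betas, signed_r2 = fits,
                    mean_connectivity = mean_k)
  ok <- which(fits >= r2_target & mean_k >= min_connectivity)
  if (length(ok) == 0) {
    warning("no candidate power reached signed scale-free fit R^2 >= ",
            r2_target, "; using fallback ", fallback)
    return(structure(fallback, fit_table = tab))
  }
  structure(candidate_betas[min(ok)], fit_table = tab)
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  cuts <- cut(k, n_bins)
  freq <- tabulate(cuts, nbins = n_bins)
  mids <- tapply(k, cuts, mean)
  keep <- freq > 0 & !is.na(mids)
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mids[keep]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' the sum over `u != i, j` and `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`.
#' Shared neighbours raise the overlap of weakly adjacent genes, and
#' `1 - TOM` is the clustering dissimilarity.
#'
#' @param adjacency symmetric matrix, entries in `[0, 1]`, unit diagonal.
#' @return symmetric TOM matrix, entries in `[0, 1]`, unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  a0 <- adjacency
  diag(a0) <- 0
  shared <- a0 %*% a0          # sum_u a_iu a_uj, u != i and u != j
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- (shared + a0) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2    # symmetrize numerical round-off
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix
#' (zero mean, unit variance per gene), scaled to unit norm. The sign is
#' fixed so that the mean correlation of member profiles with the
#' eigengene (mean member kME) is positive.
#'
#' @param norm log2-normalized matrix.
#' @param genes module member gene ids.
#' @return unit-norm numeric vector over samples.
#' @export
module_eigengene <- function(norm, genes) {
  if (length(genes) == 0) stop("empty module", call. = FALSE)
  x <- norm[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (all(sds == 0))
    stop("module of all-constant genes has no eigengene", call. = FALSE)
  x <- x[sds > 0, , drop = FALSE]
  z <- t(scale(t(x)))
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (mean(stats::cor(t(x), e)) < 0) e <- -e
  stats::setNames(e, colnames(norm))
}

#' Module membership (kME) matrix
#'
#' `kME(g, M)` is the Pearson correlation between gene `g`'s normalized
#' profile and module `M`'s eigengene — the score behind the "top 10% of
#' gene module membership" hub criterion. Zero-variance genes get kME 0
#' and are listed in `attr(, "flagged")`.
#'
#' @param norm log2-normalized matrix.
#' @param eigengenes sample x module matrix of eigengenes.
#' @return gene x module kME matrix.
#' @export
kme <- function(norm, eigengenes) {
  sds <- apply(norm, 1, stats::sd)
  k <- matrix(0, nrow = nrow(norm), ncol = ncol(eigengenes),
              dimnames = list(rownames(norm), colnames(eigengenes)))
  ok <- sds > 0
  k[ok, ] <- stats::cor(t(norm[ok, , drop = FALSE]), eigengenes)
  attr(k, "flagged") <- rownames(norm)[!ok]
  k
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a static cut at
#' `cut_height`, pooling of clusters below `min_module_size` into the
#' unassigned set, iterative merging of module pairs whose eigengenes
#' correlate above `merge_threshold`, and finally membership pruning:
#' genes whose own-module kME falls below `min_kme` are returned to the
#' unassigned pool (the static-cut counterpart of WGCNA's
#' `minKMEtoStay`), which strips weakly attached bystander genes that
#' average-linkage chaining pulls into large clusters. Labels are
#' assigned by decreasing module size ("1" is the largest); unassigned
#' genes get `"unassigned"`.
#'
#' @param tom TOM matrix (gene names as dimnames).
#' @param norm log2-normalized matrix covering the TOM's genes (used for
#'   eigengenes and kME).
#' @param min_module_size smallest retained cluster.
#' @param cut_height static cut height on the 1 - TOM dissimilarity.
#' @param merge_threshold eigengene correlation above which modules merge.
#' @param min_kme smallest own-module membership that keeps a gene in its
#'   module; 0 disables pruning.
#' @return list of class `"module_assignment"`: `modules` (gene ->
#'   label), `eigengenes` (sample x module), `kme` (gene x module),
#'   `kme_own` (gene -> own-module kME, NA when unassigned), `sizes`.
#' @export
detect_modules <- function(tom, norm, min_module_size = 30,
                           cut_height = 0.90, merge_threshold = 0.85,
                           min_kme = 0.5) {
  genes <- rownames(tom)
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  keep <- names(which(table(raw) >= min_module_size))
  members <- lapply(keep, function(cl) genes[raw == as.integer(cl)])
  # drop clusters whose genes are all constant (no eigengene exists)
  members <- Filter(function(g)
    any(apply(norm[g, , drop = FALSE], 1, stats::sd) > 0), members)

  if (length(members) == 0) {
    modules <- stats::setNames(rep("unassigned", length(genes)), genes)
    return(structure(list(modules = modules,
                          eigengenes = matrix(0, ncol(norm), 0,
                                              dimnames = list(colnames(norm),
                                                              NULL)),
                          kme = matrix(0, length(genes), 0,
                                       dimnames = list(genes, NULL)),
                          kme_own = stats::setNames(rep(NA_real_,
                                                        length(genes)),
                                                    genes),
                          sizes = integer(0)),
                     class = "module_assignment"))
  }

  # iterative eigengene merging: closest pair first, recompute, repeat
  repeat {
    if (length(members) < 2) break
    eig <- vapply(members, function(g) module_eigengene(norm, g),
                  numeric(ncol(norm)))
    cc <- stats::cor(eig)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= merge_threshold) break
    i <- min(mx); j <- max(mx)
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
  }

  # membership pruning: drop weakly attached genes, then re-check size
  if (min_kme > 0) {
    members <- lapply(members, function(g) {
      e <- module_eigengene(norm, g)
      keep_sd <- apply(norm[g, , drop = FALSE], 1, stats::sd) > 0
      kv <- stats::setNames(rep(0, length(g)), g)
      kv[keep_sd] <- stats::cor(t(norm[g[keep_sd], , drop = FALSE]), e)
      g[kv >= min_kme]
    })
    members <- Filter(function(g) length(g) >= min_module_size, members)
    if (length(members) == 0) {
      modules <- stats::setNames(rep("unassigned", length(genes)), genes)
      return(structure(list(modules = modules,
                            eigengenes = matrix(0, ncol(norm), 0,
                                                dimnames =
                                                  list(colnames(norm), NULL)),
                            kme = matrix(0, length(genes), 0,
                                         dimnames = list(genes, NULL)),
                            kme_own = stats::setNames(rep(NA_real_,
                                                          length(genes)),
                                                      genes),
                            sizes = integer(0)),
                       class = "module_assignment"))
    }
  }

  ord <- order(lengths(members), decreasing = TRUE)
  members <- members[ord]
  labels <- as.character(seq_along(members))
  modules <- stats::setNames(rep("unassigned", length(genes)), genes)
  for (i in seq_along(members)) modules[members[[i]]] <- labels[i]

  eigengenes <- vapply(members, function(g) module_eigengene(norm, g),
                       numeric(ncol(norm)))
  dimnames(eigengenes) <- list(colnames(norm), labels)
  kmat <- kme(norm[genes, , drop = FALSE], eigengenes)
  kme_own <- stats::setNames(rep(NA_real_, length(genes)), genes)
  assigned <- modules != "unassigned"
  kme_own[assigned] <- kmat[cbind(names(modules)[assigned],
                                  modules[assigned])]
  structure(list(modules = modules, eigengenes = eigengenes, kme = kmat,
                 kme_own = kme_own,
                 sizes = stats::setNames(lengths(members), labels)),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("Module assignment:", length(x$sizes), "module(s),",
      sum(x$modules == "unassigned"), "unassigned of",
      length(x$modules), "genes\n")
  if (length(x$sizes)) print(x$sizes)
  invisible(x)
}

#' Build the full network model
#'
#' Convenience wrapper: soft-threshold selection (unless `beta` is
#' given), signed adjacency, TOM, connectivity and module detection.
#'
#' @param norm log2-normalized matrix restricted to expressed genes.
#' @param beta soft power; `NULL` selects by [pick_soft_threshold()].
#' @param ... passed to [detect_modules()].
#' @return list of class `"network_model"`: `beta`, `adjacency`, `tom`,
#'   `connectivity`, `assignment`.
#' @export
build_network <- function(norm, beta = NULL, ...) {
  if (is.null(beta)) beta <- pick_soft_threshold(norm)
  adj <- signed_adjacency(norm, as.numeric(beta))
  tom <- tom_similarity(adj)
  assignment <- detect_modules(tom, norm, ...)
  structure(list(beta = as.numeric(beta), adjacency = adj, tom = tom,
                 connectivity = rowSums(adj) - 1,
                 assignment = assignment),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat("Signed co-expression network: ", nrow(x$tom), " genes, beta = ",
      x$beta, "\n", sep = "")
  print(x$assignment)
  invisible(x)
}
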