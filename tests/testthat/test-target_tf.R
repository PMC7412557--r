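# builds a minimal hand-made assignment for the top-k / tie rules
toy_assignment <- function(kmes) {
  genes <- names(kmes)
  structure(list(
    modules = stats::setNames(rep("1", length(genes)), genes),
    kme_own = kmes,
    sizes = c("1" = length(genes))), class = "module_assignment")
}

test_that("top-kME sets use ceiling counts and include boundary ties", {
  k200 <- stats::setNames(seq(0.999, 0.5, length.out = 200),
                          sprintf("g%03d", 1:200))
  expect_length(module_top_kme(toy_assignment(k200), 0.10)[["1"]], 20)

  k5 <- stats::setNames(c(0.9, 0.8, 0.7, 0.6, 0.5), paste0("g", 1:5))
  expect_identical(module_top_kme(toy_assignment(k5), 0.10)[["1"]], "g1")

  # three genes tied exactly at the boundary are all included
  ktie <- stats::setNames(c(0.95, 0.9, 0.8, 0.8, 0.8, 0.7, 0.6, 0.5, 0.4,
                            0.3), paste0("g", 1:10))
  top <- module_top_kme(toy_assignment(ktie), 0.30)[["1"]]
  expect_setequal(top, c("g1", "g2", "g3", "g4", "g5"))
})

test_that("peak expression is the maximum condition mean", {
  d <- generate_design(2, c(5, 10), c("control", "GB"))
  norm <- matrix(0, 2, 8, dimnames = list(c("g1", "g2"), d$sample_id))
  cell_means <- c(2, 5, 3, 1)
  cells <- interaction(d$treatment, d$timepoint, drop = TRUE)
  for (i in seq_along(levels(cells)))
    norm["g1", cells == levels(cells)[i]] <- cell_means[i]
  norm["g2", ] <- 4.2
  attr(norm, "scale_tag") <- "log2norm"
  pk <- peak_expression(norm, d)
  expect_equal(unname(pk["g1"]), 5)
  expect_equal(unname(pk["g2"]), 4.2)  # constant gene peaks at its value

  # planted hubs peak at their module's strongest condition
  ds <- default_sim()
  res <- default_run()
  pk_all <- peak_expression(res$norm[res$expressed, ], ds$design)
  cm <- attr(pk_all, "condition_means")
  for (m in c("M3", "M6")) {
    hub <- ds$truth$hub_tfs[[m]][1]
    prof <- ds$truth$eigenprofiles[m, ]
    d_cells <- interaction(ds$design$treatment, ds$design$timepoint,
                           drop = TRUE)
    best <- names(which.max(tapply(prof, d_cells, mean)))
    expect_equal(names(which.max(cm[hub, ])), best)
  }
})

test_that("subnetwork sizes follow the ceiling law with tie inclusion", {
  make_net <- function(n, seed = 1) {
    set.seed(seed)
    a <- random_adjacency(n)
    dimnames(a) <- list(sprintf("g%04d", 1:n), sprintf("g%04d", 1:n))
    list(tom = a)  # any symmetric score matrix works for ranking
  }
  for (n in c(101, 500, 2001)) {
    net <- make_net(n)
    sub <- tf_subnetwork(net, "g0001", q = 0.01)
    expect_equal(nrow(sub), ceiling(0.01 * (n - 1)))
    expect_false("g0001" %in% sub$member)
    expect_true(all(diff(sub$tom_score) <= 0))
  }
  # boundary ties are all kept
  tied <- matrix(0.2, 11, 11)
  tied[1, 2:4] <- tied[2:4, 1] <- 0.9
  diag(tied) <- 1
  dimnames(tied) <- list(paste0("g", 1:11), paste0("g", 1:11))
  sub <- tf_subnetwork(list(tom = tied), "g1", q = 0.01)
  expect_setequal(sub$member, c("g2", "g3", "g4"))
  expect_error(tf_subnetwork(list(tom = tied), "missing"), "missing")
})

test_that("subnetworks of planted hubs stay inside their module", {
  ds <- default_sim()
  res <- default_run()
  tm <- ds$truth$module
  sel <- res$target_tfs[res$target_tfs$selected, ]
  purity <- vapply(sel$gene, function(tf) {
    members <- res$subnetworks$member[res$subnetworks$tf == tf]
    mean(tm[members] == tm[tf])
  }, numeric(1))
  expect_true(all(purity >= 0.8))
})

test_that("top module genes are ranked and truncated correctly", {
  k150 <- stats::setNames(runif(150, 0.3, 1), sprintf("g%03d", 1:150))
  tg <- top_module_genes(toy_assignment(k150), n = 200)
  expect_equal(nrow(tg), 150)          # smaller module returned whole
  expect_true(all(diff(tg$kme) <= 0))
  expect_equal(tg$gene[1], names(which.max(k150)))

  k500 <- stats::setNames(runif(500, 0.3, 1), sprintf("g%03d", 1:500))
  tg5 <- top_module_genes(toy_assignment(k500), n = 200)
  expect_equal(nrow(tg5), 200)
  expect_true(all(diff(tg5$kme) <= 0))
})

test_that("TF family composition is normalized per module", {
  ann <- data.frame(
    gene_id = paste0("g", 1:8),
    is_tf = c(rep(TRUE, 5), FALSE, FALSE, TRUE),
    tf_family = c("WRKY", "WRKY", "WRKY", "WRKY", "NAC", NA, NA, "MYB"),
    pathways = "", stringsAsFactors = FALSE)
  comp <- tf_family_composition(ann, list(A = paste0("g", 1:6),
                                          B = c("g6", "g7")))
  a <- comp[comp$module == "A", ]
  expect_equal(a$fraction[a$tf_family == "WRKY"], 0.8)
  expect_equal(a$fraction[a$tf_family == "NAC"], 0.2)
  expect_false("B" %in% comp$module)   # no TFs -> module omitted

  res <- default_run()
  for (m in unique(res$tf_families$module))
    expect_equal(sum(res$tf_families$fraction[res$tf_families$module == m]),
                 1, tolerance = 1e-12)
})

test_that("the cascade selects planted hubs and rejects the unworthy", {
  ds <- default_sim()
  res <- default_run()
  sel <- res$target_tfs[res$target_tfs$selected, ]
  hubs <- unlist(ds$truth$hub_tfs)

  expect_gte(mean(hubs %in% sel$gene), 0.8)      # sensitivity
  expect_true(all(ds$truth$module[sel$gene] != "background"))
  expect_true(all(sel$c1 & sel$c2 & sel$c3))

  # rows are sorted within module by |delta| descending
  for (m in unique(res$target_tfs$module)) {
    dm <- res$target_tfs$delta[res$target_tfs$module == m]
    expect_true(all(diff(abs(dm)) <= 1e-12))
  }
})

test_that("relaxing a cascade threshold never drops a selected TF", {
  ds <- default_sim()
  res <- default_run()
  nx <- res$norm[res$expressed, , drop = FALSE]
  base <- select_target_tfs(ds$annotations, res$assignment, nx,
                            ds$design, res$deg_table)
  wider_kme <- select_target_tfs(ds$annotations, res$assignment, nx,
                                 ds$design, res$deg_table, q_kme = 0.20)
  lower_peak <- select_target_tfs(ds$annotations, res$assignment, nx,
                                  ds$design, res$deg_table,
                                  peak_pct = 0.50)
  expect_true(all(base$gene[base$selected] %in%
                    wider_kme$gene[wider_kme$selected]))
  expect_true(all(base$gene[base$selected] %in%
                    lower_peak$gene[lower_peak$selected]))
})

test_that("constructed TFs fail the intended criterion", {
  # high-kME, well-expressed TF with flat expression across conditions
  # fails the profile-matched DEG criterion; a low-expressed one fails
  # the peak criterion
  d <- generate_design(3, c(5, 10, 15), c("control", "GB", "YSA"))
  set.seed(31)
  profile <- ifelse(d$treatment == "GB", 3, 0)
  module_genes <- t(vapply(1:40, function(i)
    8 + profile + rnorm(27, 0, 0.2), numeric(27)))
  rownames(module_genes) <- sprintf("m%02d", 1:40)
  # tracks the module tightly but with sub-threshold amplitude (FC < 2)
  flat_tf <- matrix(8 + profile * 0.2 + rnorm(27, 0, 0.05), 1,
                    dimnames = list("tf_flat", NULL))
  # responds strongly (FC > 2) but from a low expression baseline
  low_tf <- matrix(2 + profile * 0.5 + rnorm(27, 0, 0.05), 1,
                   dimnames = list("tf_low", NULL))
  filler <- matrix(rnorm(200 * 27, 8, 1), 200,
                   dimnames = list(sprintf("f%03d", 1:200), NULL))
  norm <- rbind(module_genes, flat_tf, low_tf, filler)
  colnames(norm) <- d$sample_id
  attr(norm, "scale_tag") <- "log2norm"

  tom <- tom_similarity(signed_adjacency(norm, 6))
  asg <- detect_modules(tom, norm, min_module_size = 10, min_kme = 0)
  ann <- data.frame(gene_id = rownames(norm),
                    is_tf = rownames(norm) %in% c("tf_flat", "tf_low"),
                    tf_family = ifelse(rownames(norm) %in%
                                         c("tf_flat", "tf_low"), "WRKY", NA),
                    pathways = "", stringsAsFactors = FALSE)
  deg <- call_degs(norm, d)
  tfs <- select_target_tfs(ann, asg, norm, d, deg, q_kme = 0.9)
  flat_row <- tfs[tfs$gene == "tf_flat", ]
  low_row <- tfs[tfs$gene == "tf_low", ]
  if (nrow(flat_row)) expect_false(flat_row$c3)
  if (nrow(low_row)) {
    expect_false(low_row$c2)
    expect_true(low_row$c3)
  }
  expect_false(any(tfs$selected))
})
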