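test_that("signed adjacency follows the closed form and monotonicity", {
  # three genes engineered to pairwise correlations 1, -1, and ~0
  s <- c(1, 2, 3, 4, 5, 6)
  norm <- rbind(g1 = s, g2 = s * 2 + 1, g3 = rev(s),
                g4 = c(2, 1, 4, 3, 6, 5))
  colnames(norm) <- paste0("s", 1:6)
  attr(norm, "scale_tag") <- "log2norm"
  a <- signed_adjacency(norm, beta = 12)
  expect_equal(a["g1", "g2"], 1)            # r = 1
  expect_equal(a["g1", "g3"], 0)            # r = -1
  r14 <- cor(s, c(2, 1, 4, 3, 6, 5))
  expect_equal(a["g1", "g4"], ((1 + r14) / 2)^12, tolerance = 1e-12)
  expect_true(isSymmetric(unname(a)))
  expect_equal(unname(diag(a)), rep(1, 4))

  # r = 0 at beta = 12 gives exactly 0.5^12
  x <- c(1, 1, -1, -1); y <- c(1, -1, 1, -1)
  m0 <- rbind(g1 = x, g2 = y); colnames(m0) <- paste0("s", 1:4)
  a0 <- signed_adjacency(m0, 12)
  expect_equal(a0["g1", "g2"], 0.5^12, tolerance = 1e-15)

  # strict decrease in beta for r in (-1, 1)
  a6 <- signed_adjacency(norm, 6)
  expect_lt(a["g1", "g4"], a6["g1", "g4"])

  expect_error(signed_adjacency(norm[, 1:3], 12), "4 samples")
  expect_error(signed_adjacency(norm, 0.5), "beta")
  flat <- rbind(norm, g5 = rep(5, 6))
  expect_warning(signed_adjacency(flat, 12), "zero-variance")
})

test_that("TOM matches the brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    a <- random_adjacency(n)
    expect_lt(max(abs(tom_similarity(a) - tom_brute_force(a))), 1e-12)
  }
})

test_that("TOM satisfies its algebraic identities and invariants", {
  # 2-gene network: TOM collapses to the adjacency
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(tom_similarity(a2)[1, 2], 0.3, tolerance = 1e-15)

  # fully connected block stays fully overlapping
  ones <- matrix(1, 5, 5)
  expect_equal(unname(tom_similarity(ones)), unname(ones))

  set.seed(7)
  a <- random_adjacency(12)
  tom <- tom_similarity(a)
  expect_true(isSymmetric(unname(tom)))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 12))

  bad <- a; bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(tom_similarity(bad), "symmetric")
  expect_error(tom_similarity(a * 2), "0, 1")
})

test_that("soft-threshold selection prefers fitting powers, else falls back", {
  # pure independent noise: nothing is scale-free -> fallback + warning
  set.seed(3)
  noise <- matrix(rnorm(60 * 20, 5), 60,
                  dimnames = list(sprintf("g%02d", 1:60),
                                  sprintf("s%02d", 1:20)))
  attr(noise, "scale_tag") <- "log2norm"
  expect_warning(b <- pick_soft_threshold(noise), "fallback")
  expect_equal(as.numeric(b), 12)

  # a single candidate that meets the fit target is returned as-is
  m <- two_block_matrix(n_per_block = 40, n_noise = 120, within_sd = 0.3,
                        seed = 9)
  b6 <- suppressWarnings(pick_soft_threshold(m, candidate_betas = 6,
                                             r2_target = 0))
  expect_equal(as.numeric(b6), 6)
  # modular data never needs a power beyond the signed-network fallback
  bm <- suppressWarnings(pick_soft_threshold(m))
  expect_lte(as.numeric(bm), 12)
  expect_error(pick_soft_threshold(m, candidate_betas = numeric(0)),
               "non-empty")
})

test_that("module detection recovers planted blocks and pools noise", {
  # two independent near-perfect blocks -> exactly two modules
  m <- two_block_matrix(n_per_block = 60, within_sd = 0.05, seed = 11)
  tom <- tom_similarity(signed_adjacency(m, 6))
  asg <- detect_modules(tom, m, min_module_size = 30)
  expect_equal(length(asg$sizes), 2)
  blocks <- attr(m, "blocks")
  for (lab in names(asg$sizes)) {
    members <- names(asg$modules)[asg$modules == lab]
    expect_equal(length(unique(blocks[match(members, rownames(m))])), 1)
    expect_equal(length(members), 60)
  }

  # independent noise genes stay unassigned
  set.seed(13)
  noise <- matrix(rnorm(50 * 20, 5), 50,
                  dimnames = list(sprintf("g%02d", 1:50),
                                  sprintf("s%02d", 1:20)))
  attr(noise, "scale_tag") <- "log2norm"
  tomn <- tom_similarity(signed_adjacency(noise, 6))
  asgn <- detect_modules(tomn, noise, min_module_size = 30)
  expect_true(all(asgn$modules == "unassigned"))
  expect_equal(length(asgn$sizes), 0)

  # two blocks sharing one profile are merged by eigengene correlation
  shared <- two_block_matrix(n_per_block = 60, within_sd = 0.05,
                             shared_profile = TRUE, seed = 17)
  toms <- tom_similarity(signed_adjacency(shared, 6))
  asgs <- detect_modules(toms, shared, min_module_size = 30)
  expect_equal(length(asgs$sizes), 1)
  expect_equal(unname(asgs$sizes[1]), 120)
})

test_that("eigengenes and kME satisfy their defining identities", {
  set.seed(21)
  v <- rnorm(20)
  m <- t(vapply(1:10, function(i) 3 + 2 * v, numeric(20)))
  dimnames(m) <- list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:20))
  attr(m, "scale_tag") <- "log2norm"
  e <- module_eigengene(m, rownames(m))
  # all genes identical to profile v: eigengene is standardized v
  vstd <- scale(v)[, 1]; vstd <- vstd / sqrt(sum(vstd^2))
  expect_equal(unname(e), vstd, tolerance = 1e-10)
  expect_equal(sum(e^2), 1, tolerance = 1e-12)
  k <- kme(m, cbind(M1 = e))
  expect_equal(unname(k[, 1]), rep(1, 10), tolerance = 1e-10)

  # single-gene module: that gene standardized and unit-normalized
  e1 <- module_eigengene(m, "g01")
  expect_equal(unname(e1), vstd, tolerance = 1e-10)

  # negated gene has kME -1; a random gene matches the direct formula
  m2 <- rbind(m, gneg = 3 - 2 * v, grand = rnorm(20))
  attr(m2, "scale_tag") <- "log2norm"
  k2 <- kme(m2, cbind(M1 = e))
  expect_equal(unname(k2["gneg", 1]), -1, tolerance = 1e-10)
  expect_equal(unname(k2["grand", 1]),
               cor(m2["grand", ], e), tolerance = 1e-12)

  # zero-variance gene flagged with kME 0
  m3 <- rbind(m, gflat = rep(2, 20))
  k3 <- kme(m3, cbind(M1 = e))
  expect_equal(unname(k3["gflat", 1]), 0)
  expect_identical(attr(k3, "flagged"), "gflat")

  expect_error(module_eigengene(m, character(0)), "empty")
  flat <- matrix(5, 2, 20, dimnames = list(c("a", "b"),
                                           sprintf("s%02d", 1:20)))
  expect_error(module_eigengene(flat, c("a", "b")), "constant")
})

test_that("planted modules are recovered on the default simulation", {
  ds <- default_sim()
  res <- default_run()
  asg <- res$assignment
  expect_equal(length(asg$sizes), 6)
  keep <- asg$modules != "unassigned"
  ari <- mclust::adjustedRandIndex(ds$truth$module[keep],
                                   asg$modules[keep])
  expect_gte(ari, 0.8)
  # each detected module is dominated by one planted module
  d2p <- detected_to_planted(asg, ds$truth$module)
  expect_setequal(unname(d2p), rownames(ds$truth$eigenprofiles))
  # eigengenes track the planted eigenprofiles they represent
  for (m in names(d2p)) {
    r <- cor(asg$eigengenes[, m],
             ds$truth$eigenprofiles[d2p[m],
                                    rownames(asg$eigengenes)])
    expect_gte(abs(r), 0.9)
  }
})

test_that("network results are invariant to sample order", {
  ds <- simulate_dataset(seed = 8, n_genes_per_module = 25,
                         n_background = 100)
  norm <- normalize_counts(ds$counts)
  nx <- norm[filter_expressed(norm), , drop = FALSE]
  perm <- sample(ncol(nx))
  a1 <- signed_adjacency(nx, 12)
  a2 <- signed_adjacency(nx[, perm], 12)
  expect_equal(a1, a2, tolerance = 1e-12, ignore_attr = TRUE)
  t1 <- tom_similarity(a1)
  asg1 <- detect_modules(t1, nx)
  asg2 <- detect_modules(tom_similarity(a2), nx[, perm])
  expect_identical(asg1$modules, asg2$modules)
})
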