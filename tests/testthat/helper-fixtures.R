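# shared fixtures, built once per test session and cached

.fixtures <- new.env(parent = emptyenv())

# the default study-scale simulation (6 modules x 150 genes + 1100
# background, 27 samples, seed 1) and its full pipeline result
default_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- simulate_dataset(seed = 1)
  .fixtures$sim
}

default_run <- function() {
  if (is.null(.fixtures$run)) {
    ds <- default_sim()
    .fixtures$run <- suppressWarnings(run_pipeline(
      ds$counts, ds$design, ds$annotations, ds$pathway_map,
      ds$metabolites$abundance, ds$metabolites$pathway_map))
  }
  .fixtures$run
}

# maps each detected module label to the planted label of most members
detected_to_planted <- function(assignment, truth_module) {
  vapply(names(assignment$sizes), function(m) {
    g <- names(assignment$modules)[assignment$modules == m]
    names(sort(table(truth_module[g]), decreasing = TRUE))[1]
  }, character(1))
}

# small two-block expression fixture: two groups of genes tracking two
# independent profiles, plus optional noise genes
two_block_matrix <- function(n_per_block = 60, n_samples = 20,
                             within_sd = 0.05, n_noise = 0, seed = 11,
                             shared_profile = FALSE) {
  set.seed(seed)
  p1 <- rnorm(n_samples)
  p2 <- if (shared_profile) p1 else rnorm(n_samples)
  make_block <- function(profile, prefix)
    t(vapply(seq_len(n_per_block), function(i)
      5 + profile + rnorm(n_samples, 0, within_sd), numeric(n_samples)))
  m <- rbind(make_block(p1, "a"), make_block(p2, "b"))
  if (n_noise > 0)
    m <- rbind(m, matrix(rnorm(n_noise * n_samples, 5, 1), n_noise))
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  attr(m, "scale_tag") <- "log2norm"
  attr(m, "blocks") <- rep(c("b1", "b2", "noise"),
                           c(n_per_block, n_per_block, n_noise))
  m
}

# independent oracles -------------------------------------------------

# TOM by explicit triple loop, no linear algebra shared with the package
tom_brute_force <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    shared <- 0
    for (u in seq_len(n)) if (u != i && u != j)
      shared <- shared + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (shared + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# hypergeometric right tail by explicit summation over choose()
hyper_tail_brute <- function(k, K, N, n) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# random valid adjacency matrix: symmetric, [0,1], unit diagonal
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}
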