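# independent oracles and shared fixtures for the test suite

# brute-force Brownian tip covariance: for each tip pair, sum the branch
# lengths shared on their root paths (node paths via ape, summation by hand)
brute_covariance <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  elen <- setNames(tree$edge.length, tree$edge[, 2])
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), function(i) ape::nodepath(tree, root, i))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      shared <- intersect(paths[[i]], paths[[j]])
      shared <- setdiff(shared, root)
      V[i, j] <- V[j, i] <- sum(elen[as.character(shared)])
    }
  }
  V
}

brute_nll <- function(b, x, y) {
  eta <- b[1] + b[2] * x
  -sum(y * eta - log1p(exp(eta)))
}

# brute-force logistic maximum likelihood by direct optimization of the
# Bernoulli log-likelihood (independent of IRLS)
brute_logistic <- function(x, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(c(0, 0), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit <- optim(fit$par, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# tiny two-species survey: one community, both species in the single
# subplot with equal sizes; counts 3 vs 1
two_species_survey <- function() {
  tibble::tibble(
    community_type = "c1", plot_id = "p1", subplot_id = "s1",
    species = c("A", "B"), stratum = "herb",
    count = c(3L, 1L), size = c(0.2, 0.2))
}

# small multi-community survey with hand-set structure
demo_survey <- function() {
  dplyr::bind_rows(
    tibble::tibble(community_type = "forest", plot_id = "p1",
                   subplot_id = c("s1", "s1", "s2", "s2"),
                   species = c("Quercus mongolica", "Betula platyphylla",
                               "Quercus mongolica", "Prunus sibirica"),
                   stratum = "tree", count = c(5L, 3L, 4L, 2L),
                   size = c(300, 150, 260, 90)),
    tibble::tibble(community_type = "steppe", plot_id = "p1",
                   subplot_id = c("s1", "s1", "s2"),
                   species = c("Stipa baicalensis", "Carex duriuscula",
                               "Stipa baicalensis"),
                   stratum = "herb", count = c(60L, 20L, 45L),
                   size = c(0.7, 0.2, 0.6)))
}

demo_areas <- function() {
  tibble::tibble(community_type = c("forest", "steppe"),
                 area_ratio = c(0.4, 0.6))
}

# deterministic heavy-tailed TIV spread over [0, 1000] (per-mille scale)
skewed_tiv <- function(n) 1000 * (seq_len(n) / n)^3

random_dated_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, 1, 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr$tip.label <- sprintf("t%03d", seq_len(n))
  tr
}
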