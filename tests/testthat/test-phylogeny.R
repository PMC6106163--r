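megatree <- function() {
  read_newick(system.file("extdata", "example_megatree.nwk",
                          package = "apparency"))
}
megatree_ages <- function() {
  readr::read_csv(system.file("extdata", "example_ages.csv",
                              package = "apparency"),
                  show_col_types = FALSE)
}

test_that("newick I/O round-trips and reports malformed input", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tr <- read_newick(path)
  path2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path2)
  tr2 <- read_newick(path2)
  expect_equal(tr2$tip.label, tr$tip.label)
  expect_equal(tr2$edge.length, tr$edge.length)

  writeLines("((A,B)genusX,C)famY;", path)
  named <- read_newick(path)
  expect_true("genusX" %in% named$node.label)

  writeLines("", path)
  expect_error(read_newick(path), "empty", class = "apparency_parse_error")
  writeLines("((A,B,C);", path)
  expect_error(read_newick(path), "offset", class = "apparency_parse_error")
})

test_that("grafting attaches species under genus or new genus nodes", {
  taxa <- tibble::tibble(
    family = c("Fagaceae", "Rosaceae", "Rosaceae", "Asteraceae"),
    genus = c("Quercus", "Prunus", "Prunus", "Filifolium"),
    species = c("Quercus mongolica", "Prunus sibirica", "Prunus padus",
                "Filifolium sibiricum"))
  g <- graft_taxa(megatree(), taxa)
  expect_setequal(g$tip.label,
                  gsub(" ", "_", taxa$species))
  # congeners form a clade under the existing genus node
  prunus <- ape::getMRCA(g, c("Prunus_sibirica", "Prunus_padus"))
  desc <- ape::extract.clade(g, prunus)
  expect_setequal(desc$tip.label, c("Prunus_sibirica", "Prunus_padus"))
  # a genus absent from the megatree is created under its family
  expect_true("Filifolium" %in% g$node.label)

  # single requested species leaves a usable one-tip family path
  solo <- graft_taxa(megatree(),
                     tibble::tibble(family = "Pinaceae", genus = "Larix",
                                    species = "Larix gmelinii"))
  expect_equal(length(solo$tip.label), 1)

  expect_error(graft_taxa(megatree(), taxa[0, ]), "empty",
               class = "apparency_validation_error")
  expect_error(graft_taxa(megatree(), dplyr::bind_rows(taxa, taxa[1, ])),
               "duplicate", class = "apparency_validation_error")
  bad <- taxa; bad$family[1] <- "Nothofagaceae"
  expect_error(graft_taxa(megatree(), bad), "Nothofagaceae",
               class = "apparency_validation_error")
})

test_that("grafting then pruning to the same tips is idempotent", {
  taxa <- tibble::tibble(
    family = c("Poaceae", "Poaceae", "Cyperaceae", "Betulaceae"),
    genus = c("Stipa", "Leymus", "Carex", "Betula"),
    species = c("Stipa baicalensis", "Leymus chinensis",
                "Carex duriuscula", "Betula platyphylla"))
  g1 <- graft_taxa(megatree(), taxa)
  g2 <- graft_taxa(megatree(), taxa)
  expect_equal(ape::write.tree(g1), ape::write.tree(g2))
})

# chain trees built directly: the Newick reader shifts labels on
# single-child chains, which would obscure what is being tested
chain_tree <- function(n_inner, labels) {
  # root -> inner chain -> single tip "A"
  edge <- cbind(2:(n_inner + 2), c(3:(n_inner + 2), 1))
  structure(list(edge = edge, Nnode = n_inner + 1L, tip.label = "A",
                 node.label = labels),
            class = "phylo")
}

test_that("bladj interpolation spaces undated nodes evenly", {
  # root 100, one undated node, tip: midpoint at 50
  t1 <- chain_tree(1, c("root", "n1"))
  d1 <- bladj_date(t1, c(root = 100))
  depth <- ape::node.depth.edgelength(d1)
  expect_equal(max(depth), 100)
  expect_equal(d1$edge.length, c(50, 50))

  # dated node at 90 above two undated nodes and a tip: ages 60 and 30
  t2 <- chain_tree(2, c("root", "n1", "n2"))
  d2 <- bladj_date(t2, c(root = 90))
  expect_equal(sort(d2$edge.length), c(30, 30, 30))

  # fully dated tree: interpolation is the identity on age differences
  t3 <- ape::read.tree(text = "((A,B)inner,C)root;")
  d3 <- bladj_date(t3, c(root = 10, inner = 4))
  lens <- setNames(d3$edge.length, d3$edge[, 2])
  expect_equal(unname(lens[as.character(ape::Ntip(d3) + 2)]), 6)

  # a dated node older than its dated ancestor is an error naming both
  expect_error(bladj_date(t3, c(root = 10, inner = 30)), "inner",
               class = "apparency_validation_error")
  # missing root age is an error
  expect_error(bladj_date(t3, c(inner = 4)), "root",
               class = "apparency_validation_error")
})

test_that("bladj ages decrease root-to-tip on grafted megatree subsets", {
  taxa <- tibble::tibble(
    family = c("Fagaceae", "Betulaceae", "Rosaceae", "Fabaceae", "Poaceae",
               "Cyperaceae", "Asteraceae", "Pinaceae"),
    genus = c("Quercus", "Betula", "Prunus", "Astragalus", "Stipa",
              "Carex", "Artemisia", "Larix"),
    species = c("Quercus mongolica", "Betula platyphylla", "Prunus sibirica",
                "Astragalus adsurgens", "Stipa baicalensis",
                "Carex duriuscula", "Artemisia sacrorum", "Larix gmelinii"))
  d <- bladj_date(graft_taxa(megatree(), taxa), megatree_ages())
  expect_true(all(d$edge.length >= 0))
  expect_true(ape::is.ultrametric(d, tol = 1e-8))
  # every tip sits at the root age
  expect_equal(max(ape::node.depth.edgelength(d)), 420)
})

test_that("tip covariance equals the brute-force MRCA path-sum oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- tip_covariance(tr)
  expect_equal(unname(V),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3))

  for (s in 1:100) {
    yt <- random_dated_tree(sample(3:12, 1), seed = 5000 + s)
    expect_equal(tip_covariance(yt), brute_covariance(yt),
                 tolerance = 1e-12)
  }

  # standardization puts an ultrametric tree's diagonal at 1
  yt <- random_dated_tree(10, seed = 1)
  expect_equal(unname(diag(tip_covariance(yt, standardize = TRUE))),
               rep(1, 10))
  zero <- ape::read.tree(text = "(A:0,B:0);")
  expect_error(tip_covariance(zero), "zero-depth",
               class = "apparency_validation_error")
})
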