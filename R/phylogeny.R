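#' Read a Newick tree
#'
#' Wrapper over [ape::read.tree()] that reports malformed input (empty
#' files, unbalanced parentheses) with the character offset of the
#' defect. Named internal nodes are preserved.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) {
    abort(sprintf("empty Newick file: %s", path),
          class = "apparency_parse_error")
  }
  check_newick_balance(txt)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL)
  if (is.null(tr)) {
    abort(sprintf("failed to parse Newick file %s", path),
          class = "apparency_parse_error")
  }
  tr
}

check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("unbalanced ')' at character offset %d", i),
              class = "apparency_parse_error")
      }
    }
  }
  if (depth > 0L) {
    abort(sprintf("unclosed '(' (depth %d at end of input, offset %d)",
                  depth, length(chars)),
          class = "apparency_parse_error")
  }
  invisible(txt)
}

#' Write a tree to Newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `tree`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(tree)
}

# ---- internal node-table representation -----------------------------------
# tibble(id, parent (NA for root), name (NA if unnamed), length (NA allowed))

phylo_to_table <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  ids <- seq_len(n_tip + n_node)
  parent <- rep(NA_integer_, length(ids))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  len <- rep(NA_real_, length(ids))
  if (!is.null(tree$edge.length)) len[tree$edge[, 2]] <- tree$edge.length
  name <- c(tree$tip.label,
            if (!is.null(tree$node.label)) tree$node.label
            else rep(NA_character_, n_node))
  name[name == ""] <- NA_character_
  tibble(id = ids, parent = parent, name = name, length = len,
         is_tip = ids <= n_tip)
}

# build the phylo object directly (no Newick round trip, so labels on
# single-child chain nodes stay where they belong)
table_to_phylo <- function(tb) {
  kids <- split(tb$id, factor(tb$parent, levels = tb$id))
  root <- tb$id[is.na(tb$parent)]
  stopifnot(length(root) == 1)
  leaf <- !(tb$id %in% tb$parent)
  n_tip <- sum(leaf)
  new_num <- integer(nrow(tb))
  tip_ct <- 0L; node_ct <- 0L
  edge_from <- integer(0); edge_to <- integer(0)
  walk <- function(id) {
    i <- match(id, tb$id)
    if (leaf[i]) {
      tip_ct <<- tip_ct + 1L
      new_num[i] <<- tip_ct
    } else {
      node_ct <<- node_ct + 1L
      new_num[i] <<- n_tip + node_ct
      for (ch in kids[[as.character(id)]]) {
        walk(ch)
        edge_from <<- c(edge_from, new_num[i])
        edge_to <<- c(edge_to, new_num[match(ch, tb$id)])
      }
    }
  }
  walk(root)
  clean <- function(x) ifelse(is.na(x), "", gsub("[ ,;:()\\[\\]]", "_", x))
  tr <- list(edge = cbind(edge_from, edge_to, deparse.level = 0),
             Nnode = node_ct,
             tip.label = clean(tb$name[leaf][order(new_num[leaf])]))
  node_names <- tb$name[!leaf][order(new_num[!leaf])]
  if (any(!is.na(node_names))) tr$node.label <- clean(node_names)
  if (any(!is.na(tb$length))) {
    len <- tb$length
    len[is.na(len)] <- 0
    tr$edge.length <- len[match(edge_to, new_num)]
  }
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

tb_children <- function(tb) split(tb$id, factor(tb$parent, levels = tb$id))

tb_add_child <- function(tb, parent_id, name, is_tip) {
  new_id <- nrow(tb) + 1L
  dplyr::add_row(tb, id = new_id, parent = parent_id, name = name,
                 length = NA_real_, is_tip = is_tip)
}

# ---- grafting --------------------------------------------------------------

#' Graft a taxon list onto a family/genus megatree
#'
#' Attaches each requested species as a tip under its genus clade if the
#' megatree names that genus, otherwise under a new genus node created
#' within its family clade. Congeners form a polytomy. Megatree clades
#' containing none of the requested taxa are pruned; unnamed
#' single-child nodes created by pruning are collapsed, named ones are
#' kept so that node ages can still be assigned to them. For genus- or
#' family-level analyses, pass the genus (or family) name in the
#' `species` column.
#'
#' @param megatree An [ape::phylo] reference tree whose internal nodes
#'   (or tips) are named with families and, where available, genera.
#' @param taxa Data frame with columns `family`, `genus`, `species`.
#' @return A pruned [ape::phylo] tree whose tips are exactly
#'   `taxa$species`. Branch lengths are dropped; date the tree with
#'   [bladj_date()].
#' @export
graft_taxa <- function(megatree, taxa) {
  stopifnot(all(c("family", "genus", "species") %in% names(taxa)))
  if (nrow(taxa) == 0) {
    abort("empty taxon list", class = "apparency_validation_error")
  }
  taxa <- mutate(taxa, across(c("family", "genus", "species"),
                              ~ gsub(" ", "_", .x)))
  if (anyDuplicated(taxa$species)) {
    abort(sprintf("duplicate tip names in taxon list: %s",
                  paste(unique(taxa$species[duplicated(taxa$species)]),
                        collapse = ", ")),
          class = "apparency_validation_error")
  }
  tb <- phylo_to_table(megatree)
  tb$length <- NA_real_ # megatree branch lengths are meaningless post-graft
  unmatched <- setdiff(unique(taxa$family), tb$name)
  if (length(unmatched) > 0) {
    abort(sprintf("families absent from the megatree: %s",
                  paste(sort(unmatched), collapse = ", ")),
          class = "apparency_validation_error")
  }

  find_node <- function(nm) {
    hit <- which(!is.na(tb$name) & tb$name == nm)
    if (length(hit) == 0) return(NA_integer_)
    hit[1]
  }
  promote <- function(id) {
    # a named tip becomes an internal (clade) node
    tb$is_tip[id] <<- FALSE
    id
  }

  requested <- integer(0)
  for (k in seq_len(nrow(taxa))) {
    sp <- taxa$species[k]; ge <- taxa$genus[k]; fa <- taxa$family[k]
    sp_id <- find_node(sp)
    if (!is.na(sp_id) && tb$is_tip[sp_id]) {
      requested <- c(requested, sp_id)
      next
    }
    anchor <- find_node(ge)
    if (is.na(anchor)) {
      fam <- find_node(fa)
      if (tb$is_tip[fam]) promote(fam)
      tb <- tb_add_child(tb, fam, ge, is_tip = FALSE)
      anchor <- nrow(tb)
    } else if (tb$is_tip[anchor]) {
      promote(anchor)
    }
    if (!is.na(sp_id) && !tb$is_tip[sp_id]) {
      # taxon name coincides with an internal clade (genus/family-level
      # analysis): hang the analysis tip directly beneath that clade
      anchor <- sp_id
    }
    tb <- tb_add_child(tb, anchor, sp, is_tip = TRUE)
    requested <- c(requested, nrow(tb))
  }

  tb <- prune_to_tips(tb, requested)
  table_to_phylo(tb)
}

prune_to_tips <- function(tb, keep_ids) {
  keep <- tb$id %in% keep_ids
  # iteratively strip leaves that are not requested tips
  repeat {
    has_child <- tb$id %in% tb$parent
    drop <- !has_child & !keep
    if (!any(drop)) break
    tb <- tb[!drop, , drop = FALSE]
    keep <- keep[!drop]
  }
  # collapse unnamed single-child interior nodes (a single-child root
  # hands its role to the child)
  repeat {
    n_kids <- as.integer(table(factor(tb$parent, levels = tb$id)))
    single <- which(n_kids == 1 & is.na(tb$name) & !tb$is_tip)
    if (length(single) == 0) break
    s <- single[1]
    ci <- which(!is.na(tb$parent) & tb$parent == tb$id[s])
    tb$parent[ci] <- tb$parent[s]
    tb <- tb[-s, , drop = FALSE]
  }
  tb
}

# ---- Bladj-style dating ----------------------------------------------------

#' Assign node ages by even interpolation between dated ancestors
#'
#' Implements branch-length adjustment in the style of Phylocom's bladj:
#' internal nodes whose names appear in the age table are fixed at those
#' ages (million years; tips are at age 0), and every undated node on a
#' path between two dated nodes receives an age by even spacing. Dated
#' nodes are processed oldest first and, within one dated ancestor,
#' paths are processed toward the oldest dated descendant first, so the
#' result is deterministic, ages decrease root-to-tip, and all branch
#' lengths are non-negative.
#'
#' @param tree An [ape::phylo] tree; internal node labels identify the
#'   clades to be dated. The root must be named and present in `ages`.
#' @param ages Named numeric vector (clade name -> age) or a data frame
#'   with columns `clade_name`, `age`.
#' @return The tree with branch lengths equal to age differences.
#' @export
bladj_date <- function(tree, ages) {
  if (is.data.frame(ages)) {
    ages <- setNames(as.numeric(ages$age), as.character(ages$clade_name))
  }
  if (any(ages < 0)) {
    abort("node ages must be non-negative", class = "apparency_validation_error")
  }
  tb <- phylo_to_table(tree)
  age <- rep(NA_real_, nrow(tb))
  age[tb$is_tip] <- 0
  named_internal <- which(!tb$is_tip & !is.na(tb$name) & tb$name %in% names(ages))
  age[named_internal] <- unname(ages[tb$name[named_internal]])
  root <- which(is.na(tb$parent))
  if (is.na(age[root])) {
    abort("the root must be named and have an entry in the age table",
          class = "apparency_validation_error")
  }

  # a dated node must not be older than its nearest dated ancestor
  for (v in named_internal) {
    p <- tb$parent[v]
    while (!is.na(p) && is.na(age[p])) p <- tb$parent[p]
    if (!is.na(p) && age[v] > age[p] + 1e-12) {
      abort(sprintf("dated node '%s' (age %g) is older than its dated ancestor '%s' (age %g)",
                    tb$name[v], age[v], tb$name[p], age[p]),
            class = "apparency_validation_error")
    }
  }

  kids <- tb_children(tb)
  dated_internal <- which(!tb$is_tip & !is.na(age))
  for (a in dated_internal[order(-age[dated_internal])]) {
    paths <- collect_paths(a, kids, age)
    if (length(paths) == 0) next
    endpoint_age <- vapply(paths, function(p) age[p[length(p)]], 1)
    for (p in paths[order(-endpoint_age, lengths(paths))]) {
      age <- interpolate_path(c(a, p), age)
    }
  }

  tb$length <- age[tb$parent] - age[tb$id]
  tb$length[is.na(tb$parent)] <- NA_real_
  stopifnot(all(tb$length[!is.na(tb$parent)] > -1e-9))
  tb$length <- pmax(tb$length, 0)
  out <- table_to_phylo(tb)
  out
}

# depth-first paths from dated node `a` down to the nearest dated
# descendants (or tips); intermediate nodes are undated
collect_paths <- function(a, kids, age) {
  paths <- list()
  walk <- function(v, trail) {
    for (ch in kids[[as.character(v)]]) {
      if (!is.na(age[ch])) {
        paths[[length(paths) + 1]] <<- c(trail, ch)
      } else {
        walk(ch, c(trail, ch))
      }
    }
  }
  walk(a, integer(0))
  paths
}

# even spacing along a root-to-endpoint path; nodes dated meanwhile act
# as fixed segment boundaries
interpolate_path <- function(path, age) {
  fixed <- which(!is.na(age[path]))
  for (s in seq_len(length(fixed) - 1)) {
    i0 <- fixed[s]; i1 <- fixed[s + 1]
    k <- i1 - i0
    if (k > 1) {
      a0 <- age[path[i0]]; a1 <- age[path[i1]]
      age[path[(i0 + 1):(i1 - 1)]] <- a0 - (a0 - a1) * seq_len(k - 1) / k
    }
  }
  age
}

# ---- tip covariance --------------------------------------------------------

#' Brownian-motion tip covariance of a dated tree
#'
#' V[i, j] is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances. With `standardize = TRUE`
#' (recommended before model fitting) V is scaled so its largest
#' diagonal element is 1.
#'
#' @param tree A dated [ape::phylo] tree with branch lengths.
#' @param standardize Scale V to unit height.
#' @return A symmetric matrix with tip labels as dimnames.
#' @export
tip_covariance <- function(tree, standardize = FALSE) {
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths; date it first",
          class = "apparency_validation_error")
  }
  V <- ape::vcv.phylo(tree)
  if (max(diag(V)) <= 0) {
    abort("zero-depth tree: all root-to-tip distances are 0",
          class = "apparency_validation_error")
  }
  if (standardize) V <- V / max(diag(V))
  V
}
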