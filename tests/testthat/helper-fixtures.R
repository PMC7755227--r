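# Fixtures are built in code: small hand-checked graphs plus seeded random
# generators. No files are read from disk.

two_triangles_net <- function() {
  protein_network(data.frame(
    u = c("a", "a", "b", "d", "d", "e"),
    v = c("b", "c", "c", "e", "f", "f"),
    w = 1
  ))
}

two_cliques_net <- function(k = 4L) {
  clique <- function(ids) {
    pr <- t(combn(ids, 2L))
    data.frame(u = pr[, 1L], v = pr[, 2L], w = 1, stringsAsFactors = FALSE)
  }
  protein_network(rbind(clique(paste0("x", seq_len(k))),
                        clique(paste0("y", seq_len(k)))))
}

# Running example for the view algebra: a depth-2 hierarchy whose
# between-community relations are C5--C1, C7--C1 and C5--C6 (and no others),
# with C7 a leaf holding the proteins DET1, SOC1, SPY.
running_example <- function() {
  tree <- community_tree_from_list(list(
    id = "root",
    children = list(
      list(id = "C1", members = c("A1", "A2", "A3")),
      list(id = "C4", children = list(
        list(id = "C5", members = c("M1", "M2")),
        list(id = "C6", members = c("N1", "N2")),
        list(id = "C7", members = c("DET1", "SOC1", "SPY"))
      ))
    )
  ))
  net <- protein_network(data.frame(
    u = c("A1", "A2", "M1", "N1", "DET1", "SOC1", "M1", "DET1", "M2"),
    v = c("A2", "A3", "M2", "N2", "SOC1", "SPY", "A1", "A2", "N1"),
    w = c(1, 1, 1, 1, 1, 1, 0.5, 0.8, 0.3)
  ))
  idx <- assign_tree_indexes(tree)
  ic <- build_relation_index(tree, idx, net)
  list(tree = tree, net = net, idx = idx, ic = ic)
}

# Random hierarchy over a given node set: recursive random splits, at most
# `max_levels` levels below the root. Ids T1, T2, ... in creation order.
random_tree <- function(nodes, max_levels = 3L) {
  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    paste0("T", counter)
  }
  build <- function(members, level) {
    if (level >= max_levels || length(members) < 2L || runif(1) < 0.25) {
      return(list(id = next_id(), members = members))
    }
    k <- sample(2:min(4L, length(members)), 1L)
    grp <- sample(rep(seq_len(k), length.out = length(members)))
    parts <- split(members, grp)
    list(id = next_id(), children = lapply(parts, build, level = level + 1L))
  }
  community_tree_from_list(build(nodes, 0L))
}

# One random (network, tree, index, relation-index) instance.
random_instance <- function(n = 25L, p = 0.2, max_levels = 3L, seed = 1L) {
  net <- generate_random_weighted_graph(n, p, seed = seed)
  set.seed(seed + 1000L)
  tree <- random_tree(net$nodes, max_levels = max_levels)
  idx <- assign_tree_indexes(tree)
  ic <- build_relation_index(tree, idx, net)
  list(net = net, tree = tree, idx = idx, ic = ic)
}

planted_spec_default <- function(seed = 1L) {
  hierarchical_planted_spec(
    levels = 2L, branching = c(2L, 2L), leaf_size = 30L,
    p_within_leaf = 0.5, p_within_ancestor = c(0.005, 0.05),
    weight_dist = "uniform", seed = seed
  )
}

write_tmp_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
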