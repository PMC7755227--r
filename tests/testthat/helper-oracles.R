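# Independent oracles, deliberately naive: direct formula evaluation and
# exhaustive enumeration, never sharing code with the implementation paths
# they check.

# Modularity by literal double sum over all ordered node pairs.
oracle_modularity <- function(net, partition) {
  nodes <- net$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net$edges))) {
    u <- net$edges$u[i]
    v <- net$edges$v[i]
    W[u, v] <- W[u, v] + net$edges$w[i]
    W[v, u] <- W[v, u] + net$edges$w[i]
  }
  k <- rowSums(W)
  two_m <- sum(W)
  lab <- as.character(partition[nodes])
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (lab[i] == lab[j]) {
        q <- q + W[i, j] - k[i] * k[j] / two_m
      }
    }
  }
  unname(q / two_m)
}

# All set partitions of seq_len(n) as membership vectors (restricted growth
# strings); n must stay tiny.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (lab in seq_len(maxlab + 1L)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

tree_ancestors <- function(tree, c) {
  out <- character(0)
  cur <- c
  repeat {
    p <- tree$communities[[cur]]$parent
    if (is.na(p)) break
    out <- c(out, p)
    cur <- p
  }
  out
}

# Relation index by brute force: every community pair, member-set
# disjointness, direct scan of E for a connecting edge.
oracle_relation_index <- function(tree, net) {
  ids <- names(tree$communities)
  members <- lapply(tree$communities, `[[`, "members")
  is_leaf <- vapply(tree$communities, function(c) length(c$children) == 0L,
                    logical(1))
  leaf_pairs <- character(0)
  upper_pairs <- character(0)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      c1 <- ids[i]
      c2 <- ids[j]
      if (length(intersect(members[[c1]], members[[c2]]))) next
      connected <- any(
        (net$edges$u %in% members[[c1]] & net$edges$v %in% members[[c2]]) |
        (net$edges$u %in% members[[c2]] & net$edges$v %in% members[[c1]])
      )
      if (!connected) next
      key <- paste(sort(c(c1, c2)), collapse = "\r")
      if (is_leaf[[c1]] && is_leaf[[c2]]) {
        leaf_pairs <- c(leaf_pairs, key)
      } else {
        upper_pairs <- c(upper_pairs, key)
      }
    }
  }
  list(leaf = sort(leaf_pairs), upper = sort(upper_pairs))
}

relation_index_keys <- function(ic) {
  norm <- function(df) {
    if (!nrow(df)) return(character(0))
    sort(vapply(seq_len(nrow(df)), function(i) {
      paste(sort(c(df$c1[i], df$c2[i])), collapse = "\r")
    }, character(1)))
  }
  list(leaf = norm(ic$leaf_edges), upper = norm(ic$upper_edges))
}

# Recompute all three view edge families from scratch, from the frontier
# alone: every pair of frontier elements is connected iff some network edge
# joins their member sets.
oracle_view_edges <- function(view, tree, idx, net) {
  elems <- c(view$meta_nodes, view$atomic_nodes)
  mem <- c(lapply(view$meta_nodes, function(m) community_members(tree, m)),
           as.list(view$atomic_nodes))
  names(mem) <- elems
  is_meta <- c(rep(TRUE, length(view$meta_nodes)),
               rep(FALSE, length(view$atomic_nodes)))
  names(is_meta) <- elems
  rows <- list()
  for (i in seq_along(elems)) {
    for (j in seq_along(elems)) {
      if (j <= i) next
      a <- elems[i]
      b <- elems[j]
      hit <- any(
        (net$edges$u %in% mem[[a]] & net$edges$v %in% mem[[b]]) |
        (net$edges$u %in% mem[[b]] & net$edges$v %in% mem[[a]])
      )
      if (!hit) next
      fam <- if (is_meta[[a]] && is_meta[[b]]) "cc"
             else if (!is_meta[[a]] && !is_meta[[b]]) "pp"
             else "pc"
      if (fam == "pc" && is_meta[[a]]) {
        rows[[length(rows) + 1L]] <- data.frame(u = b, v = a, family = fam,
                                                stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(u = a, v = b, family = fam,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(u = character(), v = character(), family = character(),
               stringsAsFactors = FALSE)
  view_graph(view$meta_nodes, view$atomic_nodes, edges, idx)$edges
}

# Frontier invariant: meta member sets plus atomic nodes partition V.
expect_frontier_partition <- function(view, tree, net) {
  mem <- unlist(lapply(view$meta_nodes,
                       function(m) community_members(tree, m)))
  all_ids <- c(mem, view$atomic_nodes)
  expect_false(anyDuplicated(all_ids) > 0)
  expect_setequal(all_ids, net$nodes)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Leaf-membership vector (node -> leaf label) for ARI comparisons.
leaf_labels <- function(tree, nodes) {
  lab <- character(0)
  for (lf in tree_leaves(tree)) {
    lab[community_members(tree, lf)] <- lf
  }
  unname(lab[nodes])
}

# Random zoom walk: applies `steps` random valid zoom operations, checking
# edge families, the frontier invariant and zoom_in/zoom_out inversion at
# every step. Returns the number of operations performed.
random_zoom_walk <- function(inst, steps = 6L, seed = 1L) {
  set.seed(seed)
  tree <- inst$tree
  idx <- inst$idx
  ic <- inst$ic
  net <- inst$net
  view <- initial_view(tree, idx)
  done <- 0L
  for (s in seq_len(steps)) {
    expandable <- view$meta_nodes
    collapsible_atoms <- view$atomic_nodes
    collapsible_metas <- Filter(function(m) {
      p <- parent_of(m, tree)
      !is.na(p) && all(community_children(tree, p) %in% view$meta_nodes)
    }, setdiff(view$meta_nodes, tree$root))
    do_expand <- length(expandable) &&
      (runif(1) < 0.7 || (!length(collapsible_atoms) && !length(collapsible_metas)))
    if (do_expand) {
      c <- sample(expandable, 1L)
      nxt <- zoom_in(view, c, tree, idx, ic, net)
      # inversion: collapsing any piece of c restores the previous view
      piece <- if (length(community_children(tree, c))) {
        sample(community_children(tree, c), 1L)
      } else {
        sample(community_members(tree, c), 1L)
      }
      back <- zoom_out(nxt, piece, tree, idx)
      expect_equal(back, view, ignore_attr = TRUE)
      view <- nxt
    } else if (length(collapsible_atoms) || length(collapsible_metas)) {
      pool <- c(collapsible_atoms, unlist(collapsible_metas))
      view <- zoom_out(view, sample(pool, 1L), tree, idx)
    } else {
      break
    }
    done <- done + 1L
    expect_frontier_partition(view, tree, net)
    expect_equal(view$edges, oracle_view_edges(view, tree, idx, net))
  }
  done
}
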