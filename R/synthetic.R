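#' Specification of a hierarchical planted-partition network
#'
#' Describes a balanced nested block model: `prod(branching)` leaf blocks of
#' `leaf_size` nodes arranged in a tree of `levels` levels below the root.
#' Two nodes are joined independently with the probability attached to
#' their lowest common ancestor: `p_within_leaf` for nodes of the same leaf
#' block, and `p_within_ancestor[l + 1]` for node pairs whose lowest common
#' block ancestor sits at level `l` (level 0 = root). Assortative
#' hierarchical structure requires these probabilities to increase strictly
#' with depth and stay below `p_within_leaf`.
#'
#' @param levels number of block levels below the root (>= 1)
#' @param branching integer vector of length `levels`: children per block at
#'   each level
#' @param leaf_size nodes per leaf block
#' @param p_within_leaf connection probability inside a leaf block
#' @param p_within_ancestor numeric vector of length `levels`: connection
#'   probability for pairs whose lowest common ancestor is at level
#'   `0, 1, ..., levels - 1`
#' @param weight_dist `"uniform"` (weights drawn uniformly on (0, 1)) or
#'   `"unit"` (all weights 1, the convention for curated unweighted
#'   interaction lists)
#' @param seed integer seed
#' @return a `planted_spec` list
#' @export
hierarchical_planted_spec <- function(levels, branching, leaf_size,
                                      p_within_leaf, p_within_ancestor,
                                      weight_dist = c("uniform", "unit"),
                                      seed = 1L) {
  weight_dist <- match.arg(weight_dist)
  levels <- as.integer(levels)
  branching <- as.integer(branching)
  stopifnot(levels >= 1L, length(branching) == levels, all(branching >= 1L),
            leaf_size >= 1L, length(p_within_ancestor) == levels,
            p_within_leaf >= 0, p_within_leaf <= 1,
            all(p_within_ancestor >= 0), all(p_within_ancestor <= 1))
  if (any(diff(c(p_within_ancestor, p_within_leaf)) < 0)) {
    stop("probabilities must be non-decreasing with tree depth and peak inside leaves")
  }
  if (p_within_leaf < max(p_within_ancestor)) {
    stop("p_within_leaf must dominate all ancestor probabilities")
  }
  structure(list(levels = levels, branching = branching,
                 leaf_size = as.integer(leaf_size),
                 p_within_leaf = p_within_leaf,
                 p_within_ancestor = p_within_ancestor,
                 weight_dist = weight_dist, seed = as.integer(seed)),
            class = "planted_spec")
}

# path of block b (1-based) through the branching vector, as 1-based digits
block_paths <- function(branching) {
  grid <- expand.grid(rev(lapply(branching, seq_len)))
  as.matrix(grid[, rev(seq_along(branching)), drop = FALSE])
}

#' Generate a hierarchical planted-partition network
#'
#' Draws the random network described by a [hierarchical_planted_spec()]
#' together with its ground-truth community tree (root, one community per
#' internal block, one leaf per leaf block). Deterministic given the spec's
#' seed.
#'
#' @param spec a `planted_spec`
#' @return list with elements `network` (a `protein_network`) and `tree`
#'   (the planted `community_tree`)
#' @export
generate_hierarchical_planted_graph <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  if (spec$p_within_leaf == 0 && all(spec$p_within_ancestor == 0)) {
    stop("spec yields an edgeless network in expectation")
  }
  set.seed(spec$seed)
  B <- prod(spec$branching)
  paths <- block_paths(spec$branching)
  n <- B * spec$leaf_size
  nodes <- sprintf("v%04d", seq_len(n))
  block_of <- rep(seq_len(B), each = spec$leaf_size)

  edge_u <- list()
  edge_v <- list()
  k <- 0L
  for (b1 in seq_len(B)) {
    mem1 <- nodes[block_of == b1]
    # within-block pairs
    if (spec$p_within_leaf > 0 && spec$leaf_size > 1L) {
      pr <- utils::combn(mem1, 2L)
      pick <- stats::runif(ncol(pr)) < spec$p_within_leaf
      if (any(pick)) {
        k <- k + 1L
        edge_u[[k]] <- pr[1L, pick]
        edge_v[[k]] <- pr[2L, pick]
      }
    }
    for (b2 in seq_len(B)) {
      if (b2 <= b1) next
      shared <- 0L
      for (l in seq_len(spec$levels)) {
        if (paths[b1, l] == paths[b2, l]) shared <- shared + 1L else break
      }
      p <- spec$p_within_ancestor[shared + 1L]
      if (p <= 0) next
      mem2 <- nodes[block_of == b2]
      g <- expand.grid(u = mem1, v = mem2, stringsAsFactors = FALSE)
      pick <- stats::runif(nrow(g)) < p
      if (any(pick)) {
        k <- k + 1L
        edge_u[[k]] <- g$u[pick]
        edge_v[[k]] <- g$v[pick]
      }
    }
  }
  u <- unlist(edge_u)
  v <- unlist(edge_v)
  w <- if (spec$weight_dist == "unit") rep(1, length(u)) else stats::runif(length(u))
  net <- protein_network(data.frame(u = u, v = v, w = w,
                                    stringsAsFactors = FALSE),
                         nodes = nodes)

  # ground-truth tree: nested blocks labelled by their path
  build <- function(prefix, level) {
    if (level == spec$levels) {
      b <- which(apply(paths, 1L, function(p) all(p == prefix)))
      return(list(id = paste0("B", paste(prefix, collapse = ".")),
                  members = nodes[block_of == b]))
    }
    kids <- lapply(seq_len(spec$branching[level + 1L]), function(i) {
      build(c(prefix, i), level + 1L)
    })
    id <- if (length(prefix)) paste0("B", paste(prefix, collapse = ".")) else "root"
    list(id = id, children = kids)
  }
  tree <- community_tree_from_list(build(integer(0), 0L), seed = spec$seed)
  list(network = net, tree = tree)
}

#' Generate an Erdős–Rényi network with uniform weights
#'
#' G(n, p) random graph over nodes `v00001..`, each of the `choose(n, 2)`
#' pairs present independently with probability `p`, weights uniform on
#' (0, 1). Sampling is done by drawing the edge count from the binomial and
#' then sampling that many distinct pair indices, so the cost is O(edges)
#' rather than O(pairs).
#'
#' @param n number of nodes (>= 1)
#' @param p edge probability in `[0, 1]`
#' @param seed integer seed
#' @return a `protein_network`
#' @export
generate_random_weighted_graph <- function(n, p, seed = 1L) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  set.seed(as.integer(seed))
  n <- as.integer(n)
  nodes <- sprintf("v%05d", seq_len(n))
  M <- as.numeric(n) * (n - 1) / 2
  m <- if (M > 0 && p > 0) stats::rbinom(1L, size = M, prob = p) else 0L
  if (m == 0L) {
    return(protein_network(nodes = nodes))
  }
  pick <- sort(sample.int(M, m))
  # decode linear pair index (pairs ordered by first endpoint, then second)
  counts <- (n - 1):1
  cs0 <- c(0, cumsum(counts))
  i <- findInterval(pick - 0.5, cs0)
  j <- i + (pick - cs0[i])
  w <- stats::runif(m)
  protein_network(data.frame(u = nodes[i], v = nodes[j], w = w,
                             stringsAsFactors = FALSE),
                  nodes = nodes)
}
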