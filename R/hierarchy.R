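#' Weighted Newman–Girvan modularity
#'
#' Evaluates \deqn{Q = \frac{1}{2m}\sum_{ij}\left[W_{ij} -
#' \frac{k_i k_j}{2m}\right]\delta(c_i, c_j)} where \eqn{m} is the total
#' edge weight and \eqn{k_i} the weighted degree of node \eqn{i}. The
#' single-community partition scores exactly 0, and \eqn{Q \in [-1/2, 1]}.
#'
#' @param net a `protein_network` with at least one edge
#' @param partition named vector (node id -> community label) covering every
#'   node of `net`; labels may be any atomic type
#' @return modularity Q as a single numeric
#' @export
modularity_q <- function(net, partition) {
  stopifnot(is_protein_network(net))
  if (!all(net$nodes %in% names(partition))) {
    stop("partition does not cover every node of the network")
  }
  m <- sum(net$edges$w)
  if (m <= 0) stop("modularity undefined: network has zero total edge weight")
  lab <- as.character(partition[net$nodes])
  names(lab) <- net$nodes
  cu <- lab[net$edges$u]
  cv <- lab[net$edges$v]
  q_in <- sum(net$edges$w[cu == cv]) / m
  # weighted degree mass per community: each edge adds its weight to both
  # endpoint communities
  K <- tapply(c(net$edges$w, net$edges$w), c(cu, cv), sum)
  q_exp <- sum((K / (2 * m))^2)
  q_in - q_exp
}

#' Final Louvain partition of a network
#'
#' Runs the Louvain modularity heuristic and keeps only its final
#' aggregation level — the partition with the highest modularity — rather
#' than the full dendrogram. Randomness (the node-visit order) is confined
#' to R's RNG: pass `seed` for a self-contained reproducible call, or leave
#' it `NULL` to consume the current RNG stream (used by [build_hierarchy()],
#' which seeds once and calls sequentially).
#'
#' @param net a `protein_network` with at least one edge
#' @param seed optional integer seed
#' @return named integer vector node id -> community label (labels are
#'   consecutive integers, numbered by first appearance over the sorted
#'   node order)
#' @export
louvain_top_partition <- function(net, seed = NULL) {
  stopifnot(is_protein_network(net))
  if (nrow(net$edges) == 0L) stop("Louvain undefined on an edgeless network")
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(net)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  mem <- igraph::membership(cl)
  ids <- igraph::V(g)$name
  # relabel to consecutive integers in order of first appearance over the
  # sorted node order, so labels are stable across igraph versions
  lab <- as.integer(factor(as.integer(mem), levels = unique(as.integer(mem))))
  stats::setNames(lab, ids)
}

#' Does a proposed split improve on the trivial partition?
#'
#' The split-acceptance test of the divisive hierarchy: a community is worth
#' splitting when the Louvain partition of its induced subgraph is
#' non-trivial (at least two parts) and scores Q > 0 there, i.e. beats the
#' single-community partition whose Q is identically 0. Edgeless subgraphs
#' and single-part proposals return `FALSE`.
#'
#' @param subnet induced `protein_network` of the community
#' @param proposed named vector node -> label over `subnet`'s nodes
#' @return logical
#' @export
gain_modularity_check <- function(subnet, proposed) {
  stopifnot(is_protein_network(subnet))
  if (nrow(subnet$edges) == 0L) return(FALSE)
  if (length(unique(as.character(proposed[subnet$nodes]))) < 2L) return(FALSE)
  modularity_q(subnet, proposed) > 1e-12
}

#' Build the divisive community hierarchy
#'
#' Top-down divisive scheme: the first level is the final Louvain partition
#' of the whole network; each community of size at least `minsplit` whose
#' induced subgraph admits a non-trivial Louvain partition with positive
#' modularity is replaced by the parts of that partition, recursively, until
#' no community can be split. Only internal edges of a community are used
#' when splitting it. The leaves of the returned tree partition the node
#' set. The whole construction is deterministic given (`net`, `minsplit`,
#' `seed`).
#'
#' @param net a non-empty `protein_network` with at least one edge
#' @param minsplit minimum community size eligible for further splitting
#'   (default 50, suited to networks of a few hundred nodes; larger networks
#'   warrant larger values)
#' @param seed integer seed controlling the Louvain visit order
#' @return a `community_tree`: list with `communities` (named list of
#'   community records: `id`, `members`, `level`, `parent`, `children`),
#'   `root`, `minsplit`, `seed`
#' @export
build_hierarchy <- function(net, minsplit = 50L, seed = 1L) {
  stopifnot(is_protein_network(net))
  if (length(net$nodes) == 0L) stop("empty network")
  if (nrow(net$edges) == 0L) stop("edgeless network: modularity-based splitting undefined")
  minsplit <- as.integer(minsplit)
  if (minsplit < 2L) stop("minsplit must be at least 2")
  set.seed(as.integer(seed))

  comms <- list()
  root_id <- "C0"
  comms[[root_id]] <- list(id = root_id, members = net$nodes, level = 0L,
                           parent = NA_character_, children = character(0))
  counter <- 0L

  new_children <- function(parent_id, subnet, partition) {
    groups <- split(subnet$nodes, as.character(partition[subnet$nodes]))
    groups <- lapply(groups, sort)
    # deterministic child order: by smallest member id
    groups <- groups[order(vapply(groups, `[[`, character(1), 1L))]
    ids <- character(length(groups))
    lev <- comms[[parent_id]]$level + 1L
    for (i in seq_along(groups)) {
      counter <<- counter + 1L
      id <- paste0("C", counter)
      ids[i] <- id
      comms[[id]] <<- list(id = id, members = groups[[i]], level = lev,
                           parent = parent_id, children = character(0))
    }
    comms[[parent_id]]$children <<- ids
    ids
  }

  top <- louvain_top_partition(net)
  queue <- new_children(root_id, net, top)

  while (length(queue)) {
    cid <- queue[1L]
    queue <- queue[-1L]
    members <- comms[[cid]]$members
    if (length(members) < minsplit) next
    subnet <- induced_subnetwork(net, members)
    if (nrow(subnet$edges) == 0L) next
    part <- louvain_top_partition(subnet)
    if (!gain_modularity_check(subnet, part)) next
    queue <- c(queue, new_children(cid, subnet, part))
  }

  structure(list(communities = comms, root = root_id,
                 minsplit = minsplit, seed = as.integer(seed)),
            class = "community_tree")
}

#' Build a community tree from a nested list
#'
#' Constructs a `community_tree` directly from a nested description —
#' useful for ground-truth trees of synthetic generators and for tests.
#' Each node of the nested list is `list(id =, children = list(...))` for an
#' internal community or `list(id =, members = c(...))` for a leaf; internal
#' member sets are the union of their leaves.
#'
#' @param nested nested list as above (the root)
#' @param minsplit,seed metadata recorded on the tree (`NA` by default)
#' @return a `community_tree`
#' @export
community_tree_from_list <- function(nested, minsplit = NA_integer_,
                                     seed = NA_integer_) {
  comms <- list()
  build <- function(node, level, parent) {
    id <- node$id
    if (is.null(id) || id %in% names(comms)) {
      stop("every nested node needs a unique 'id'")
    }
    if (!is.null(node$children) && length(node$children)) {
      kids <- vapply(node$children, function(ch) build(ch, level + 1L, id), character(1))
      members <- sort(unique(unlist(lapply(kids, function(k) comms[[k]]$members))))
      comms[[id]] <<- list(id = id, members = members, level = level,
                           parent = parent, children = kids)
    } else {
      if (is.null(node$members) || !length(node$members)) {
        stop("leaf '", id, "' needs a non-empty 'members' vector")
      }
      comms[[id]] <<- list(id = id, members = sort(as.character(node$members)),
                           level = level, parent = parent,
                           children = character(0))
    }
    id
  }
  root_id <- build(nested, 0L, NA_character_)
  tree <- structure(list(communities = comms, root = root_id,
                         minsplit = as.integer(minsplit),
                         seed = as.integer(seed)),
                    class = "community_tree")
  validate_community_tree(tree)
}

#' Validate community-tree invariants
#'
#' Checks tree structure (single root, one parent each, consistent levels),
#' that each internal community's children partition its member set, and
#' that the leaves partition the root's member set.
#'
#' @param tree a `community_tree`
#' @return `tree`, invisibly; stops on violation
#' @export
validate_community_tree <- function(tree) {
  stopifnot(inherits(tree, "community_tree"))
  comms <- tree$communities
  root <- tree$root
  if (!root %in% names(comms)) stop("root id not present")
  if (!is.na(comms[[root]]$parent)) stop("root must have no parent")
  for (c in comms) {
    if (!identical(c$id, root)) {
      p <- comms[[c$parent]]
      if (is.null(p)) stop("community ", c$id, " has unknown parent")
      if (!c$id %in% p$children) stop("parent of ", c$id, " does not list it as child")
      if (c$level != p$level + 1L) stop("level of ", c$id, " is not parent level + 1")
    }
    if (length(c$children)) {
      kid_members <- unlist(lapply(c$children, function(k) comms[[k]]$members))
      if (anyDuplicated(kid_members)) {
        stop("children of ", c$id, " overlap")
      }
      if (!setequal(kid_members, c$members)) {
        stop("children of ", c$id, " do not cover its member set")
      }
    }
  }
  leaves <- unlist(lapply(comms, function(c) if (!length(c$children)) c$members))
  if (anyDuplicated(leaves) || !setequal(leaves, comms[[root]]$members)) {
    stop("leaves do not partition the node set")
  }
  invisible(tree)
}

#' @export
print.community_tree <- function(x, ...) {
  n_leaf <- length(tree_leaves(x))
  cat(sprintf("community_tree: %d communities (%d leaves), depth %d, %d nodes\n",
              length(x$communities), n_leaf, tree_depth(x),
              length(x$communities[[x$root]]$members)))
  invisible(x)
}

#' Community-tree accessors
#'
#' @param tree a `community_tree`
#' @param c a community id
#' @return `community_members`: character vector of node ids;
#'   `community_children`: character vector of child community ids;
#'   `community_level`: integer depth (root = 0); `parent_of`: parent id or
#'   `NA` for the root; `tree_leaves`: ids of leaf communities in stored
#'   (depth-first) order; `tree_depth`: maximum level; `display_label`:
#'   label of the form `"C4-L1"` combining id and level.
#' @export
community_members <- function(tree, c) community_record(tree, c)$members

#' @rdname community_members
#' @export
community_children <- function(tree, c) community_record(tree, c)$children

#' @rdname community_members
#' @export
community_level <- function(tree, c) community_record(tree, c)$level

#' @rdname community_members
#' @export
parent_of <- function(c, tree) community_record(tree, c)$parent

#' @rdname community_members
#' @export
tree_leaves <- function(tree) {
  out <- character(0)
  walk <- function(id) {
    kids <- tree$communities[[id]]$children
    if (!length(kids)) out <<- c(out, id) else for (k in kids) walk(k)
  }
  walk(tree$root)
  out
}

#' @rdname community_members
#' @export
tree_depth <- function(tree) {
  max(vapply(tree$communities, `[[`, integer(1), "level"))
}

#' @rdname community_members
#' @export
display_label <- function(tree, c) {
  rec <- community_record(tree, c)
  paste0(rec$id, "-L", rec$level)
}

community_record <- function(tree, c) {
  stopifnot(inherits(tree, "community_tree"))
  rec <- tree$communities[[c]]
  if (is.null(rec)) stop("unknown community id: ", c)
  rec
}
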