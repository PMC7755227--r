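#' Assign pre/post/level interval labels to a community tree
#'
#' Depth-first traversal in stored child order. `pre` numbers communities in
#' visit-entry order and `post` in visit-exit order, each 1..|V_C| with its
#' own counter. The interval characterization then holds: c1 is a
#' (reflexive) descendant of c2 iff `pre(c2) <= pre(c1)` and
#' `post(c1) <= post(c2)`. Every network node is labelled with the (pre,
#' post) of the unique leaf community containing it, enabling constant-time
#' membership tests.
#'
#' @param tree a `community_tree`
#' @return a `tree_index`: list with named integer vectors `pre`, `post`,
#'   `level` over community ids; `leaf_of` (node id -> leaf community id);
#'   `leaf_rank` (leaf id -> position in pre order among leaves); and
#'   `leaf_lo`/`leaf_hi` (community id -> range of leaf ranks below it).
#' @export
assign_tree_indexes <- function(tree) {
  stopifnot(inherits(tree, "community_tree"))
  n <- length(tree$communities)
  pre <- post <- level <- integer(0)
  leaf_ids <- character(0)
  leaf_lo <- leaf_hi <- integer(0)
  pre_ctr <- 0L
  post_ctr <- 0L
  walk <- function(id) {
    pre_ctr <<- pre_ctr + 1L
    pre[[id]] <<- pre_ctr
    level[[id]] <<- tree$communities[[id]]$level
    kids <- tree$communities[[id]]$children
    if (!length(kids)) {
      leaf_ids <<- c(leaf_ids, id)
      leaf_lo[[id]] <<- length(leaf_ids)
      leaf_hi[[id]] <<- length(leaf_ids)
    } else {
      lo <- length(leaf_ids) + 1L
      for (k in kids) walk(k)
      leaf_lo[[id]] <<- lo
      leaf_hi[[id]] <<- length(leaf_ids)
    }
    post_ctr <<- post_ctr + 1L
    post[[id]] <<- post_ctr
  }
  walk(tree$root)
  stopifnot(pre_ctr == n, post_ctr == n)
  leaf_of <- character(0)
  for (lf in leaf_ids) {
    mem <- tree$communities[[lf]]$members
    leaf_of[mem] <- lf
  }
  structure(
    list(pre = unlist(pre), post = unlist(post), level = unlist(level),
         leaf_of = leaf_of,
         leaf_rank = stats::setNames(seq_along(leaf_ids), leaf_ids),
         leaf_lo = unlist(leaf_lo), leaf_hi = unlist(leaf_hi)),
    class = "tree_index"
  )
}

check_indexed <- function(idx, ids) {
  unknown <- ids[!ids %in% names(idx$pre)]
  if (length(unknown)) stop("unknown community id: ", unknown[1L])
  invisible(TRUE)
}

#' Constant-time hierarchy predicates
#'
#' Interval-label tests on a `tree_index`. `is_descendant` is reflexive:
#' `is_descendant(c, c)` is `TRUE` (the relation-index construction relies
#' on a leaf witnessing itself). `are_disjoint(c1, c2)` holds iff neither is
#' a descendant of the other, which for a tree coincides with member-set
#' disjointness. `class_of` returns the unique leaf community containing a
#' node, and `member_of(v, c)` tests whether `class_of(v)` descends from
#' `c`.
#'
#' @param c1,c2,c community ids present in the index
#' @param v a node id of the indexed network
#' @param idx a `tree_index` from [assign_tree_indexes()]
#' @return logical (`class_of`: a community id)
#' @export
is_descendant <- function(c1, c2, idx) {
  check_indexed(idx, c(c1, c2))
  unname(idx$pre[c2] <= idx$pre[c1] & idx$post[c1] <= idx$post[c2])
}

#' @rdname is_descendant
#' @export
are_disjoint <- function(c1, c2, idx) {
  !is_descendant(c1, c2, idx) && !is_descendant(c2, c1, idx)
}

#' @rdname is_descendant
#' @export
class_of <- function(v, idx) {
  lf <- idx$leaf_of[v]
  if (anyNA(lf)) stop("unknown node id: ", v[is.na(lf)][1L])
  unname(lf)
}

#' @rdname is_descendant
#' @export
member_of <- function(v, c, idx) {
  is_descendant(class_of(v, idx), c, idx)
}

#' Build the community-relation index
#'
#' Records which pairs of disjoint communities are connected by at least
#' one underlying network edge. Two phases: first, every network edge whose
#' endpoints fall into different leaf communities contributes that leaf
#' pair (`leaf_edges`); second, every ordered disjoint community pair
#' (smaller pre first, excluding pairs where both are leaves) is added to
#' `upper_edges` when some recorded leaf pair descends from it — with
#' descent reflexive, so leaf–internal pairs are reachable. Phase 1 touches
#' each edge exactly once; phase 2 examines only community pairs, using a
#' 2-D prefix-sum over the leaf-adjacency matrix (leaves below a community
#' are contiguous in pre-order) for a constant-time witness test.
#'
#' @param tree a `community_tree`
#' @param idx its `tree_index`
#' @param net the `protein_network` the tree was built from
#' @return a `community_relation_index`: list with data frames `leaf_edges`
#'   and `upper_edges` (columns `c1`, `c2`, canonically `pre(c1) < pre(c2)`),
#'   a combined lookup key set, and counters `edge_inspections`,
#'   `pair_inspections`
#' @export
build_relation_index <- function(tree, idx, net) {
  stopifnot(inherits(tree, "community_tree"), inherits(idx, "tree_index"),
            is_protein_network(net))
  if (!all(net$nodes %in% names(idx$leaf_of))) {
    stop("network node(s) not covered by any leaf community")
  }
  leaves <- names(idx$leaf_rank)
  L <- length(leaves)
  e <- net$edges
  edge_inspections <- nrow(e)

  # phase 1: leaf pairs induced by cross-edges, one pass over E
  ru <- unname(idx$leaf_rank[idx$leaf_of[e$u]])
  rv <- unname(idx$leaf_rank[idx$leaf_of[e$v]])
  cross <- ru != rv
  r1 <- pmin(ru[cross], rv[cross])
  r2 <- pmax(ru[cross], rv[cross])
  pair_key <- unique((r1 - 1) * L + r2)
  lr1 <- (pair_key - 1) %/% L + 1
  lr2 <- (pair_key - 1) %% L + 1
  ord <- order(lr1, lr2)
  lr1 <- lr1[ord]
  lr2 <- lr2[ord]
  leaf_edges <- data.frame(c1 = leaves[lr1], c2 = leaves[lr2],
                           stringsAsFactors = FALSE)

  # 2-D prefix sums over the symmetric leaf-adjacency matrix: the number of
  # adjacent leaf pairs inside any rank rectangle is then an O(1) lookup
  A <- matrix(0L, L, L)
  if (length(lr1)) {
    A[cbind(lr1, lr2)] <- 1L
    A[cbind(lr2, lr1)] <- 1L
  }
  if (L > 1L) {
    S <- apply(A, 2L, cumsum)
    S <- t(apply(S, 1L, cumsum))
  } else {
    S <- A
  }
  rect_any <- function(a1, a2, b1, b2) {
    # any adjacency with row rank in [a1, a2], col rank in [b1, b2]
    tot <- S[cbind(a2, b2)]
    if_a <- ifelse(a1 > 1L, S[cbind(pmax(a1 - 1L, 1L), b2)], 0)
    if_b <- ifelse(b1 > 1L, S[cbind(a2, pmax(b1 - 1L, 1L))], 0)
    if_ab <- ifelse(a1 > 1L & b1 > 1L,
                    S[cbind(pmax(a1 - 1L, 1L), pmax(b1 - 1L, 1L))], 0)
    (tot - if_a - if_b + if_ab) > 0
  }

  # phase 2: enumerate disjoint ordered pairs (pre(c1) < pre(c2)), skipping
  # pairs where both are leaves
  ids <- names(sort(idx$pre))
  lo <- unname(idx$leaf_lo[ids])
  hi <- unname(idx$leaf_hi[ids])
  is_leaf <- lo == hi & ids %in% leaves
  n <- length(ids)
  # with ids in pre-order, c1 before c2 and disjoint <=> hi(c1) < lo(c2)
  i_idx <- rep(seq_len(n), each = n)
  j_idx <- rep(seq_len(n), times = n)
  disjoint <- hi[i_idx] < lo[j_idx]
  pair_inspections <- sum(disjoint)
  keep <- disjoint & !(is_leaf[i_idx] & is_leaf[j_idx])
  ii <- i_idx[keep]
  jj <- j_idx[keep]
  hit <- logical(length(ii))
  if (length(ii)) {
    hit <- rect_any(lo[ii], hi[ii], lo[jj], hi[jj])
  }
  upper_edges <- data.frame(c1 = ids[ii[hit]], c2 = ids[jj[hit]],
                            stringsAsFactors = FALSE)
  ord2 <- order(idx$pre[upper_edges$c1], idx$pre[upper_edges$c2])
  upper_edges <- upper_edges[ord2, , drop = FALSE]
  rownames(upper_edges) <- NULL

  keys <- c(paste(leaf_edges$c1, leaf_edges$c2, sep = "\r"),
            paste(upper_edges$c1, upper_edges$c2, sep = "\r"))
  structure(
    list(leaf_edges = leaf_edges, upper_edges = upper_edges, keys = keys,
         edge_inspections = edge_inspections,
         pair_inspections = pair_inspections),
    class = "community_relation_index"
  )
}

#' Are two disjoint communities related in the index?
#'
#' @param ic a `community_relation_index`
#' @param c1,c2 community ids
#' @param idx the `tree_index` (for canonical ordering)
#' @return logical: the pair carries at least one underlying network edge
#' @export
ic_connected <- function(ic, c1, c2, idx) {
  check_indexed(idx, c(c1, c2))
  a <- if (idx$pre[c1] < idx$pre[c2]) c(c1, c2) else c(c2, c1)
  paste(a[1L], a[2L], sep = "\r") %in% ic$keys
}

#' Dump index structures as JSON
#'
#' Debug/export view of the interval labels and relation index:
#' `{communities: {id: {pre, post, level}}, leaf_edges: [...],
#' upper_edges: [...]}`.
#'
#' @param idx a `tree_index`
#' @param ic optional `community_relation_index`
#' @param file optional path; when given the JSON is written there
#' @return JSON string, invisibly when `file` is given
#' @export
index_to_json <- function(idx, ic = NULL, file = NULL) {
  ids <- names(sort(idx$pre))
  comm <- lapply(stats::setNames(ids, ids), function(id) {
    list(pre = unname(idx$pre[id]), post = unname(idx$post[id]),
         level = unname(idx$level[id]))
  })
  obj <- list(communities = comm)
  if (!is.null(ic)) {
    obj$leaf_edges <- unname(apply(ic$leaf_edges, 1L, as.list))
    obj$upper_edges <- unname(apply(ic$upper_edges, 1L, as.list))
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
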