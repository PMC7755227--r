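#' Multi-resolution view graphs
#'
#' A view is a graph over a *frontier* of the community hierarchy: a set of
#' meta-nodes (pairwise disjoint communities) plus atomic nodes (proteins)
#' whose member sets together partition the network's node set. Three edge
#' families connect them: `"pp"` (protein–protein, an underlying network
#' edge), `"cc"` (community–community, some network edge joins the two
#' member sets), and `"pc"` (protein–community, some network edge joins the
#' protein to a member). Views are immutable values; the zoom operations
#' return new views.
#'
#' @param meta_nodes character vector of community ids
#' @param atomic_nodes character vector of node ids
#' @param edges data frame with columns `u`, `v`, `family`
#' @param idx a `tree_index`, used to canonicalize `cc` edge orientation
#' @return a `view_graph`
#' @export
view_graph <- function(meta_nodes, atomic_nodes, edges, idx) {
  edges <- normalize_view_edges(edges, idx)
  structure(
    list(meta_nodes = meta_nodes[order(idx$pre[meta_nodes])],
         atomic_nodes = sort(atomic_nodes),
         edges = edges),
    class = "view_graph"
  )
}

empty_view_edges <- function() {
  data.frame(u = character(), v = character(), family = character(),
             stringsAsFactors = FALSE)
}

normalize_view_edges <- function(edges, idx) {
  if (!nrow(edges)) return(empty_view_edges())
  u <- as.character(edges$u)
  v <- as.character(edges$v)
  fam <- as.character(edges$family)
  cc <- fam == "cc"
  if (any(cc)) {
    swap <- idx$pre[v[cc]] < idx$pre[u[cc]]
    tmp <- u[cc]
    u[cc] <- ifelse(swap, v[cc], u[cc])
    v[cc] <- ifelse(swap, tmp, v[cc])
  }
  pp <- fam == "pp"
  if (any(pp)) {
    a <- pmin(u[pp], v[pp])
    b <- pmax(u[pp], v[pp])
    u[pp] <- a
    v[pp] <- b
  }
  key <- paste(fam, u, v, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(u = u[keep], v = v[keep], family = fam[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$family, out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.view_graph <- function(x, ...) {
  fam <- table(factor(x$edges$family, levels = c("pp", "cc", "pc")))
  cat(sprintf(
    "view_graph: %d meta-node(s), %d atomic node(s); edges pp=%d cc=%d pc=%d\n",
    length(x$meta_nodes), length(x$atomic_nodes),
    fam[["pp"]], fam[["cc"]], fam[["pc"]]))
  invisible(x)
}

#' Initial (fully collapsed) view
#'
#' The coarsest multi-resolution representation: a single meta-node — the
#' root of the hierarchy — and no edges.
#'
#' @param tree a `community_tree`
#' @param idx its `tree_index`
#' @return a `view_graph`
#' @export
initial_view <- function(tree, idx) {
  view_graph(tree$root, character(0), empty_view_edges(), idx)
}

#' First-screen view: the level-1 communities
#'
#' Convenience wrapper applying one [zoom_in()] on the root of the initial
#' view, yielding the communities at the first level of the hierarchy (the
#' usual opening screen of a community-based browser).
#'
#' @inheritParams zoom_in
#' @return a `view_graph`
#' @export
level1_view <- function(tree, idx, ic, net) {
  zoom_in(initial_view(tree, idx), tree$root, tree, idx, ic, net)
}

# locate, for each node id in w, the surviving frontier meta-node containing
# it (NA when none does); metas' leaf-rank intervals are disjoint
frontier_locate <- function(w, metas, idx) {
  if (!length(metas) || !length(w)) return(rep(NA_character_, length(w)))
  lo <- unname(idx$leaf_lo[metas])
  hi <- unname(idx$leaf_hi[metas])
  ord <- order(lo)
  lo <- lo[ord]
  hi <- hi[ord]
  metas <- metas[ord]
  r <- unname(idx$leaf_rank[idx$leaf_of[w]])
  pos <- findInterval(r, lo)
  out <- rep(NA_character_, length(w))
  okpos <- pos >= 1L
  inside <- okpos & r <= hi[pmax(pos, 1L)]
  out[inside] <- metas[pos[inside]]
  out
}

#' Expand a meta-node (zoom in)
#'
#' Replaces the meta-node `c` by its contents. A leaf community is replaced
#' by its member proteins together with their internal network edges; edges
#' from those proteins to the surviving frontier are derived from the
#' underlying network (protein–protein to surviving atomic nodes,
#' protein–community to surviving meta-nodes). An internal community is
#' replaced by its children, with child–child and child–meta edges taken
#' from the community-relation index and child–protein edges derived from
#' the network. All edges formerly incident to `c` are removed. Each
#' underlying network edge is inspected at most once; the number inspected
#' is recorded in the `"edges_inspected"` attribute of the result.
#'
#' @param view a `view_graph` containing `c` as a meta-node
#' @param c community id to expand
#' @param tree a `community_tree`
#' @param idx its `tree_index`
#' @param ic its `community_relation_index`
#' @param net the underlying `protein_network`
#' @return a new `view_graph`
#' @export
zoom_in <- function(view, c, tree, idx, ic, net) {
  stopifnot(inherits(view, "view_graph"))
  if (!c %in% view$meta_nodes) stop("'", c, "' is not a meta-node of the view")
  rec <- community_record(tree, c)
  e <- view$edges
  incident <- e$u == c | e$v == c
  survivors_meta <- setdiff(view$meta_nodes, c)
  kids <- rec$children
  inspected <- 0L

  if (!length(kids)) {
    # leaf: substitute member proteins
    members <- rec$members
    ne <- net$edges
    iu <- ne$u %in% members
    iv <- ne$v %in% members
    touch <- iu | iv
    inspected <- sum(touch)
    both <- iu & iv
    new_edges <- ne[both, c("u", "v"), drop = FALSE]
    if (nrow(new_edges)) new_edges$family <- "pp"  else new_edges <- NULL
    cross <- touch & !both
    if (any(cross)) {
      inner <- ifelse(iu[cross], ne$u[cross], ne$v[cross])
      outer <- ifelse(iu[cross], ne$v[cross], ne$u[cross])
      is_atomic <- outer %in% view$atomic_nodes
      if (any(is_atomic)) {
        new_edges <- rbind(new_edges,
                           data.frame(u = inner[is_atomic],
                                      v = outer[is_atomic], family = "pp",
                                      stringsAsFactors = FALSE))
      }
      if (any(!is_atomic)) {
        m <- frontier_locate(outer[!is_atomic], survivors_meta, idx)
        if (anyNA(m)) stop("view frontier does not cover an edge endpoint")
        new_edges <- rbind(new_edges,
                           data.frame(u = inner[!is_atomic], v = m,
                                      family = "pc",
                                      stringsAsFactors = FALSE))
      }
    }
    meta2 <- survivors_meta
    atomic2 <- c(view$atomic_nodes, members)
  } else {
    # internal: substitute child communities
    # child-child edges from the relation index
    new_edges <- NULL
    if (length(kids) > 1L) {
      pr <- idx$pre[kids]
      kid_ord <- kids[order(pr)]
      pairs <- utils::combn(kid_ord, 2L)
      hit <- paste(pairs[1L, ], pairs[2L, ], sep = "\r") %in% ic$keys
      if (any(hit)) {
        new_edges <- data.frame(u = pairs[1L, hit], v = pairs[2L, hit],
                                family = "cc", stringsAsFactors = FALSE)
      }
    }
    # child-meta edges from the relation index
    if (length(survivors_meta)) {
      grid_c1 <- rep(kids, times = length(survivors_meta))
      grid_c2 <- rep(survivors_meta, each = length(kids))
      lo1 <- idx$pre[grid_c1]
      lo2 <- idx$pre[grid_c2]
      a <- ifelse(lo1 < lo2, grid_c1, grid_c2)
      b <- ifelse(lo1 < lo2, grid_c2, grid_c1)
      hit <- paste(a, b, sep = "\r") %in% ic$keys
      if (any(hit)) {
        new_edges <- rbind(new_edges,
                           data.frame(u = a[hit], v = b[hit], family = "cc",
                                      stringsAsFactors = FALSE))
      }
    }
    # child-protein edges from the network (one pass over edges leaving c)
    if (length(view$atomic_nodes)) {
      members <- rec$members
      ne <- net$edges
      iu <- ne$u %in% members
      iv <- ne$v %in% members
      touch <- (iu | iv) & !(iu & iv)
      inspected <- sum(iu | iv)
      if (any(touch)) {
        inner <- ifelse(iu[touch], ne$u[touch], ne$v[touch])
        outer <- ifelse(iu[touch], ne$v[touch], ne$u[touch])
        keep <- outer %in% view$atomic_nodes
        if (any(keep)) {
          child <- frontier_locate(inner[keep], kids, idx)
          new_edges <- rbind(new_edges,
                             data.frame(u = outer[keep], v = child,
                                        family = "pc",
                                        stringsAsFactors = FALSE))
        }
      }
    }
    meta2 <- c(survivors_meta, kids)
    atomic2 <- view$atomic_nodes
  }

  kept <- e[!incident, , drop = FALSE]
  if (is.null(new_edges)) new_edges <- empty_view_edges()
  out <- view_graph(meta2, atomic2, rbind(kept, new_edges), idx)
  attr(out, "edges_inspected") <- inspected
  out
}

#' Collapse a node into its enclosing community (zoom out)
#'
#' Collapsing an atomic node replaces *all* atomic nodes of its leaf
#' community by that leaf as a meta-node; collapsing a meta-node replaces
#' it and its sibling meta-nodes by their parent. Edges incident to the
#' collapsed set are redirected to the new meta-node (protein neighbours
#' yield `pc` edges, meta neighbours `cc` edges); edges internal to the
#' collapsed set disappear. Collapsing requires every sibling to be present
#' as a meta-node: if a sibling is itself expanded, collapse it first
#' (otherwise the frontier would no longer partition the node set).
#'
#' @param view a `view_graph`
#' @param x an atomic node or non-root meta-node of the view
#' @param tree a `community_tree`
#' @param idx its `tree_index`
#' @return a new `view_graph`
#' @export
zoom_out <- function(view, x, tree, idx) {
  stopifnot(inherits(view, "view_graph"))
  if (identical(x, tree$root)) stop("cannot zoom out on the root")
  if (x %in% view$atomic_nodes) {
    cp <- class_of(x, idx)
    collapsed <- intersect(community_members(tree, cp), view$atomic_nodes)
    if (!setequal(collapsed, community_members(tree, cp))) {
      stop("leaf community ", cp, " is only partially present in the view")
    }
    meta2 <- c(view$meta_nodes, cp)
    atomic2 <- setdiff(view$atomic_nodes, collapsed)
  } else if (x %in% view$meta_nodes) {
    cp <- parent_of(x, tree)
    siblings <- community_children(tree, cp)
    absent <- setdiff(siblings, view$meta_nodes)
    if (length(absent)) {
      stop("cannot collapse ", x, " into ", cp, ": sibling(s) ",
           paste(absent, collapse = ", "),
           " are not meta-nodes of the view (collapse them first)")
    }
    collapsed <- siblings
    meta2 <- c(setdiff(view$meta_nodes, collapsed), cp)
    atomic2 <- view$atomic_nodes
  } else {
    stop("'", x, "' is not present in the view")
  }
  e <- view$edges
  inu <- e$u %in% collapsed
  inv <- e$v %in% collapsed
  kept <- e[!inu & !inv, , drop = FALSE]
  redirect <- xor(inu, inv)
  new_edges <- NULL
  if (any(redirect)) {
    other <- ifelse(inu[redirect], e$v[redirect], e$u[redirect])
    # surviving endpoint atomic => pc edge, meta => cc edge (orientation is
    # canonicalized by the view constructor)
    is_atom <- other %in% atomic2
    new_edges <- data.frame(u = other, v = cp,
                            family = ifelse(is_atom, "pc", "cc"),
                            stringsAsFactors = FALSE)
  }
  if (is.null(new_edges)) new_edges <- empty_view_edges()
  view_graph(meta2, atomic2, rbind(kept, new_edges), idx)
}

#' Root-to-leaf community path of a protein
#'
#' The unique path in the hierarchy from the root down to the leaf
#' community containing `v`, root first.
#'
#' @param v node id
#' @param tree a `community_tree`
#' @param idx its `tree_index`
#' @return character vector of community ids
#' @export
path_to_node <- function(v, tree, idx) {
  cur <- class_of(v, idx)
  path <- cur
  while (!is.na(parent_of(cur, tree))) {
    cur <- parent_of(cur, tree)
    path <- c(cur, path)
  }
  path
}

#' Statistics of the network edges underlying a view edge
#'
#' For a view edge between `u` and `v` (each a protein or a community),
#' collects the weights of all underlying network edges joining the two
#' member sets and reports their count, minimum, maximum and mean.
#'
#' @param view a `view_graph`
#' @param u,v endpoints of an edge present in the view
#' @param tree a `community_tree`
#' @param idx its `tree_index`
#' @param net the underlying `protein_network`
#' @return a `meta_edge_stats` list: `count`, `min_w`, `max_w`, `mean_w`
#' @export
meta_edge_stats <- function(view, u, v, tree, idx, net) {
  e <- view$edges
  present <- (e$u == u & e$v == v) | (e$u == v & e$v == u)
  if (!any(present)) stop("edge ", u, " -- ", v, " is absent from the view")
  set_of <- function(x) {
    if (x %in% view$atomic_nodes) x else community_members(tree, x)
  }
  su <- set_of(u)
  sv <- set_of(v)
  ne <- net$edges
  hit <- (ne$u %in% su & ne$v %in% sv) | (ne$u %in% sv & ne$v %in% su)
  w <- ne$w[hit]
  if (!length(w)) stop("internal error: view edge with no underlying network edge")
  structure(list(count = length(w), min_w = min(w), max_w = max(w),
                 mean_w = mean(w)),
            class = "meta_edge_stats")
}

#' @export
print.meta_edge_stats <- function(x, ...) {
  cat(sprintf("meta_edge_stats: count=%d min=%.4g mean=%.4g max=%.4g\n",
              x$count, x$min_w, x$mean_w, x$max_w))
  invisible(x)
}

#' Serialize a view to JSON
#'
#' Deterministic JSON of the form `{meta_nodes: [{id, size, level}],
#' atomic_nodes: [{id, leaf}], edges: [{u, v, family, stats?}]}`; per-edge
#' weight statistics are included when `net` is supplied. An optional named
#' numeric `scores` vector attaches a `score` field to atomic nodes.
#'
#' @param view a `view_graph`
#' @param tree a `community_tree`
#' @param idx its `tree_index`
#' @param net optional `protein_network` enabling edge statistics
#' @param scores optional named numeric vector of per-protein scores
#' @param file optional output path
#' @return JSON string (invisibly when `file` is given)
#' @export
view_to_json <- function(view, tree, idx, net = NULL, scores = NULL,
                         file = NULL) {
  metas <- lapply(view$meta_nodes, function(m) {
    list(id = m, label = display_label(tree, m),
         size = length(community_members(tree, m)),
         level = unname(idx$level[m]))
  })
  atoms <- lapply(view$atomic_nodes, function(a) {
    rec <- list(id = a, leaf = class_of(a, idx))
    if (!is.null(scores) && a %in% names(scores)) rec$score <- unname(scores[a])
    rec
  })
  edges <- lapply(seq_len(nrow(view$edges)), function(i) {
    rec <- as.list(view$edges[i, c("u", "v", "family")])
    if (!is.null(net)) {
      s <- meta_edge_stats(view, rec$u, rec$v, tree, idx, net)
      rec$stats <- list(count = s$count, min_w = s$min_w, max_w = s$max_w,
                        mean_w = s$mean_w)
    }
    rec
  })
  txt <- jsonlite::toJSON(list(meta_nodes = metas, atomic_nodes = atoms,
                               edges = edges),
                          auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
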