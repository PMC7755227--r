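#' Weighted protein network
#'
#' Constructs a `protein_network`: an undirected weighted graph over opaque
#' string node identifiers. Edges are stored once per unordered pair with a
#' weight in (0, 1]; an absent pair is equivalent to weight 0. Isolated
#' (degree-zero) nodes are permitted.
#'
#' @param edges data frame with columns `u`, `v` (character) and `w`
#'   (numeric); one row per undirected edge. May have zero rows.
#' @param nodes character vector of node ids. Defaults to the endpoints of
#'   `edges`; extra entries declare isolated nodes.
#' @return An object of class `protein_network` with elements `nodes`
#'   (sorted character vector) and `edges` (data frame `u`, `v`, `w`, with
#'   `u < v` lexicographically and rows sorted).
#' @export
protein_network <- function(edges = data.frame(u = character(), v = character(), w = numeric()),
                            nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("u", "v", "w") %in% names(edges)))
  u <- as.character(edges$u)
  v <- as.character(edges$v)
  w <- as.numeric(edges$w)
  if (any(u == v)) {
    stop("self-loop edge(s): ", paste(unique(u[u == v]), collapse = ", "))
  }
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1)) {
    stop("edge weights must lie in (0, 1]")
  }
  # canonical orientation within a record: lexicographically smaller id first
  a <- pmin(u, v)
  b <- pmax(u, v)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate edge record(s): ",
         paste(gsub("\r", "--", dup[seq_len(min(5, length(dup)))]), collapse = ", "))
  }
  if (is.null(nodes)) {
    nodes <- c(a, b)
  } else {
    nodes <- as.character(nodes)
    missing <- setdiff(c(a, b), nodes)
    if (length(missing)) {
      stop("edge endpoint(s) not in declared node set: ",
           paste(missing[seq_len(min(5, length(missing)))], collapse = ", "))
    }
  }
  ord <- order(a, b)
  structure(
    list(nodes = sort(unique(nodes)),
         edges = data.frame(u = a[ord], v = b[ord], w = w[ord],
                            stringsAsFactors = FALSE)),
    class = "protein_network"
  )
}

#' @export
print.protein_network <- function(x, ...) {
  cat(sprintf("protein_network: %d nodes, %d edges, total weight %.4g\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$w)))
  invisible(x)
}

#' Number of nodes / edges of a protein network
#' @param net a `protein_network`
#' @return integer count
#' @export
network_order <- function(net) length(net$nodes)

#' @rdname network_order
#' @export
network_size <- function(net) nrow(net$edges)

is_protein_network <- function(x) inherits(x, "protein_network")

#' Validate a protein network's invariants
#'
#' Checks undirectedness (one record per unordered pair, no self-loops),
#' weight bounds, and endpoint closure. Called by the constructor; exported
#' so callers can re-assert after manual manipulation.
#'
#' @param net a `protein_network`
#' @return `net`, invisibly; stops on violation.
#' @export
validate_protein_network <- function(net) {
  stopifnot(is_protein_network(net))
  e <- net$edges
  if (any(e$u >= e$v)) stop("edges not in canonical orientation (u < v)")
  if (anyDuplicated(paste(e$u, e$v, sep = "\r"))) stop("duplicate unordered pair")
  if (any(e$w <= 0 | e$w > 1)) stop("weight outside (0, 1]")
  if (!all(c(e$u, e$v) %in% net$nodes)) stop("edge endpoint missing from node set")
  invisible(net)
}

#' Convert a protein network to an igraph graph
#'
#' @param net a `protein_network`
#' @return an undirected `igraph` graph with `weight` edge attribute;
#'   vertices ordered by sorted node id (a fixed order keeps downstream
#'   seeded algorithms reproducible).
#' @export
as_igraph <- function(net) {
  stopifnot(is_protein_network(net))
  d <- net$edges
  names(d)[names(d) == "w"] <- "weight"
  igraph::graph_from_data_frame(
    d = d, directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Induced subgraph on a node subset
#'
#' Keeps only edges with both endpoints inside `members`; edges leaving the
#' subset are dropped. Nodes in `members` with no surviving edge remain as
#' isolated nodes.
#'
#' @param net a `protein_network`
#' @param members character vector of node ids (must all be in `net`)
#' @return a `protein_network`
#' @export
induced_subnetwork <- function(net, members) {
  stopifnot(is_protein_network(net))
  members <- as.character(members)
  if (!all(members %in% net$nodes)) stop("members not all present in network")
  keep <- net$edges$u %in% members & net$edges$v %in% members
  protein_network(net$edges[keep, , drop = FALSE], nodes = members)
}

#' Read a network tuple file (tab-separated edge list)
#'
#' The tuple format is one edge per line: `node1 <tab> node2 <tab> weight`,
#' with the weight column optional (defaulting to 1, the convention for
#' unweighted interaction lists such as curated physical-interaction sets).
#' `(a, b)` and `(b, a)` denote the same undirected edge; a file containing
#' both is rejected as a duplicate record. Self-loops, explicit zero or
#' out-of-range weights, and malformed lines are errors naming the line.
#'
#' @param path path to the edge-list file
#' @param header logical; skip one header line (default `FALSE`)
#' @param nodes_file optional path to a one-id-per-line node list; use it to
#'   declare isolated nodes the tuple format cannot express
#' @param default_weight weight used when the third column is absent
#' @return a `protein_network`
#' @export
read_network_tsv <- function(path, header = FALSE, nodes_file = NULL,
                             default_weight = 1.0) {
  lines <- readLines(path)
  offset <- 0L
  if (header && length(lines)) {
    lines <- lines[-1L]
    offset <- 1L
  }
  keep <- nzchar(trimws(lines))
  lineno <- which(keep) + offset
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop(sprintf("malformed line %d: expected 2 or 3 tab-separated fields, found %d",
                 lineno[bad[1L]], nf[bad[1L]]))
  }
  u <- vapply(parts, `[[`, character(1), 1L)
  v <- vapply(parts, `[[`, character(1), 2L)
  w <- rep(default_weight, length(parts))
  has_w <- nf == 3L
  if (any(has_w)) {
    wtxt <- vapply(parts[has_w], `[[`, character(1), 3L)
    wnum <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wnum)) {
      i <- which(has_w)[which(is.na(wnum))[1L]]
      stop(sprintf("malformed line %d: non-numeric weight '%s'",
                   lineno[i], wtxt[which(is.na(wnum))[1L]]))
    }
    w[has_w] <- wnum
  }
  if (any(w <= 0 | w > 1)) {
    i <- which(w <= 0 | w > 1)[1L]
    stop(sprintf("invalid weight %g on line %d: weights must lie in (0, 1] (0 means no edge)",
                 w[i], lineno[i]))
  }
  if (any(u == v)) {
    i <- which(u == v)[1L]
    stop(sprintf("self-loop on line %d: %s", lineno[i], u[i]))
  }
  nodes <- NULL
  if (!is.null(nodes_file)) {
    extra <- trimws(readLines(nodes_file))
    extra <- extra[nzchar(extra)]
    nodes <- unique(c(u, v, extra))
  }
  protein_network(data.frame(u = u, v = v, w = w, stringsAsFactors = FALSE),
                  nodes = nodes)
}

#' Write a network tuple file
#'
#' Edges are written one per line as `node1 <tab> node2 <tab> weight` in
#' canonical order. Without a tree index the canonical order is
#' lexicographic on the (oriented) endpoint pair; with `idx` supplied,
#' endpoints are oriented so that the pre-order label of the first
#' endpoint's leaf community is the smaller one (lexicographic tie-break
#' within a leaf), and rows are sorted accordingly.
#'
#' @param net a `protein_network`
#' @param path output path
#' @param mapping optional `id_mapping_table` for identifier translation
#' @param scheme optional identifier scheme (see [translate_ids()]); requires
#'   `mapping`. Ids without a correspondence are written unchanged.
#' @param idx optional `tree_index` used for canonical edge ordering
#' @return `path`, invisibly
#' @export
write_network_tsv <- function(net, path, mapping = NULL, scheme = NULL,
                              idx = NULL) {
  stopifnot(is_protein_network(net))
  if (!is.null(scheme) && is.null(mapping)) {
    stop("'scheme' requires 'mapping'")
  }
  e <- net$edges
  if (!is.null(idx)) {
    e <- canonicalize_edges(net, idx)
  }
  u <- e$u
  v <- e$v
  if (!is.null(scheme)) {
    u <- translate_ids(u, mapping, scheme)
    v <- translate_ids(v, mapping, scheme)
  }
  out <- sprintf("%s\t%s\t%s", u, v, format(e$w, trim = TRUE, digits = 15))
  writeLines(out, path)
  invisible(path)
}

#' Canonically ordered edge table under a tree index
#'
#' Orients each edge so that the first endpoint belongs to the leaf
#' community with the smaller pre-order label; for intra-leaf edges (equal
#' labels) the lexicographically smaller node id comes first. Rows are
#' sorted by (leaf pre of first, leaf pre of second, u, v).
#'
#' @param net a `protein_network`
#' @param idx a `tree_index` built on a hierarchy of `net`
#' @return data frame `u`, `v`, `w`
#' @export
canonicalize_edges <- function(net, idx) {
  e <- net$edges
  if (!nrow(e)) return(e)
  pu <- idx$pre[idx$leaf_of[e$u]]
  pv <- idx$pre[idx$leaf_of[e$v]]
  swap <- pv < pu | (pu == pv & e$v < e$u)
  u <- ifelse(swap, e$v, e$u)
  v <- ifelse(swap, e$u, e$v)
  p1 <- pmin(pu, pv)
  p2 <- pmax(pu, pv)
  ord <- order(p1, p2, u, v)
  data.frame(u = u[ord], v = v[ord], w = e$w[ord], stringsAsFactors = FALSE)
}
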