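#' Export the sub-network of a community
#'
#' Extracts the induced sub-network on a community's members and renders it
#' in TSV or JSON form, optionally attaching per-protein prediction scores
#' and translating identifiers. The TSV layout is a directory with two
#' files, `edges.tsv` (`u`, `v`, `w`, with header) and `nodes.tsv` (`id`
#' plus a `score` column when scores are given), so isolated members and
#' node attributes survive the round trip. The JSON layout is a single
#' versioned document.
#'
#' @param c community id
#' @param tree a `community_tree`
#' @param net the underlying `protein_network`
#' @param format `"tsv"` or `"json"`
#' @param path output location: a directory for TSV, a file for JSON;
#'   `NULL` returns the content without writing
#' @param scores optional named numeric vector node id -> score
#' @param mapping optional `id_mapping_table`
#' @param scheme optional identifier scheme (requires `mapping`)
#' @return invisibly, a `community_export` list: `schema_version`,
#'   `community`, `level`, `nodes` (data frame), `edges` (data frame)
#' @export
export_community <- function(c, tree, net, format = c("tsv", "json"),
                             path = NULL, scores = NULL, mapping = NULL,
                             scheme = NULL) {
  format <- match.arg(format)
  rec <- community_record(tree, c)
  sub <- induced_subnetwork(net, rec$members)
  ids <- sub$nodes
  shown <- ids
  if (!is.null(scheme)) {
    if (is.null(mapping)) stop("'scheme' requires 'mapping'")
    shown <- translate_ids(ids, mapping, scheme)
  }
  name_of <- stats::setNames(shown, ids)
  nodes_df <- data.frame(id = unname(name_of[ids]), stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    nodes_df$score <- unname(scores[ids])
  }
  edges_df <- data.frame(u = unname(name_of[sub$edges$u]),
                         v = unname(name_of[sub$edges$v]),
                         w = sub$edges$w, stringsAsFactors = FALSE)
  out <- list(schema_version = "1.0", community = c, level = rec$level,
              nodes = nodes_df, edges = edges_df)
  class(out) <- "community_export"
  if (!is.null(path)) {
    if (format == "tsv") {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      utils::write.table(edges_df, file.path(path, "edges.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(nodes_df, file.path(path, "nodes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      obj <- list(schema_version = out$schema_version, community = c,
                  level = rec$level,
                  nodes = unname(lapply(seq_len(nrow(nodes_df)), function(i) {
                    as.list(nodes_df[i, , drop = FALSE])
                  })),
                  edges = unname(lapply(seq_len(nrow(edges_df)), function(i) {
                    as.list(edges_df[i, , drop = FALSE])
                  })))
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA), path)
    }
  }
  invisible(out)
}

maptree_nested <- function(tree, id) {
  rec <- tree$communities[[id]]
  node <- list(id = id, level = rec$level, size = length(rec$members))
  if (length(rec$children)) {
    node$children <- lapply(rec$children, function(k) maptree_nested(tree, k))
  }
  node
}

sanitize_newick_label <- function(x) {
  gsub("[][(),:;[:space:]]", "_", x)
}

maptree_newick <- function(tree, id) {
  rec <- tree$communities[[id]]
  lab <- paste0(sanitize_newick_label(id), "[", length(rec$members), "]")
  if (!length(rec$children)) return(lab)
  paste0("(", paste(vapply(rec$children, function(k) maptree_newick(tree, k),
                           character(1)), collapse = ","),
         ")", lab)
}

#' Export the maptree (hierarchy overview)
#'
#' Serializes the whole community hierarchy: as nested JSON
#' (`{id, level, size, children: [...]}`) or as a Newick string with
#' community ids as labels and member counts as bracketed comments
#' (strippable with `gsub("\\\\[[0-9]+\\\\]", "", x)` for parsers that do not
#' accept comments).
#'
#' @param tree a `community_tree`
#' @param format `"json"` or `"newick"`
#' @param file optional output path
#' @return a character scalar (invisibly when `file` is given)
#' @export
export_maptree <- function(tree, format = c("json", "newick"), file = NULL) {
  format <- match.arg(format)
  txt <- if (format == "json") {
    as.character(jsonlite::toJSON(maptree_nested(tree, tree$root),
                                  auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA))
  } else {
    paste0(maptree_newick(tree, tree$root), ";")
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Rebuild a maptree skeleton from its JSON export
#'
#' Parses the nested JSON produced by [export_maptree()] back into the
#' nested-list form accepted by [community_tree_from_list()] — with leaf
#' `members` replaced by placeholder singletons of the leaf id, since the
#' maptree records sizes, not memberships. Intended for topology
#' round-trips.
#'
#' @param txt JSON string
#' @return nested list with `id`, `level`, `size`, `children`
#' @export
maptree_from_json <- function(txt) {
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}
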