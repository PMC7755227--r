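#' Supported protein identifier schemes
#'
#' The seven alternative identification schemes a mapping table may carry,
#' matching the columns of the mapping-table format.
#' @export
ID_SCHEMES <- c("gene_name", "ensembl_gene", "ensembl_protein", "entrez",
                "refseq_protein", "refseq_mrna", "uniprot")

#' Read a protein ID-mapping table
#'
#' Tab-separated file with a header line and columns `primary_id`,
#' `gene_name`, `ensembl_gene`, `ensembl_protein`, `entrez`,
#' `refseq_protein`, `refseq_mrna`, `uniprot`, `aliases` (pipe-separated;
#' may be empty). Missing alternatives are empty fields or the literal
#' `NA`, stored as `NA`.
#'
#' @param path path to the mapping TSV
#' @return an `id_mapping_table`: a data frame keyed by unique `primary_id`
#'   plus an `aliases` list column
#' @export
read_id_mapping <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = c("", "NA"),
                          check.names = FALSE)
  required <- c("primary_id", ID_SCHEMES, "aliases")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("mapping table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$primary_id)) {
    stop("duplicate primary_id in mapping table: ",
         df$primary_id[duplicated(df$primary_id)][1L])
  }
  df$aliases <- lapply(strsplit(ifelse(is.na(df$aliases), "", df$aliases),
                                "|", fixed = TRUE),
                       function(x) x[nzchar(x)])
  class(df) <- c("id_mapping_table", "data.frame")
  df
}

#' Build an ID-mapping table in code
#'
#' @param primary_id character vector of unique primary identifiers
#' @param ... named character vectors, one per scheme in [ID_SCHEMES]
#'   (unsupplied schemes are all-`NA`); `aliases` may be a list column.
#' @return an `id_mapping_table`
#' @export
id_mapping_table <- function(primary_id, ...) {
  primary_id <- as.character(primary_id)
  if (anyDuplicated(primary_id)) stop("primary ids must be unique")
  extra <- list(...)
  unknown <- setdiff(names(extra), c(ID_SCHEMES, "aliases"))
  if (length(unknown)) stop("unknown scheme column(s): ", paste(unknown, collapse = ", "))
  df <- data.frame(primary_id = primary_id, stringsAsFactors = FALSE)
  for (s in ID_SCHEMES) {
    col <- extra[[s]]
    df[[s]] <- if (is.null(col)) NA_character_ else as.character(col)
  }
  df$aliases <- if (is.null(extra$aliases)) {
    replicate(length(primary_id), character(0), simplify = FALSE)
  } else {
    extra$aliases
  }
  class(df) <- c("id_mapping_table", "data.frame")
  df
}

#' Translate node identifiers to another scheme
#'
#' Order-preserving translation of `ids` to the requested scheme. An id with
#' no row in the mapping, or whose row lacks a correspondence for the
#' scheme, passes through unchanged (the convention when no cross-scheme
#' correspondence exists: the original identifier is kept).
#'
#' @param ids character vector of node ids
#' @param mapping an `id_mapping_table`
#' @param scheme one of [ID_SCHEMES]
#' @return character vector, same length and order as `ids`
#' @export
translate_ids <- function(ids, mapping, scheme) {
  if (!scheme %in% ID_SCHEMES) {
    stop("unknown scheme '", scheme, "'; valid schemes: ",
         paste(ID_SCHEMES, collapse = ", "))
  }
  if (!length(ids)) return(character(0))
  stopifnot(inherits(mapping, "id_mapping_table"))
  ids <- as.character(ids)
  pos <- match(ids, mapping$primary_id)
  alt <- mapping[[scheme]][pos]
  out <- ifelse(is.na(pos) | is.na(alt), ids, alt)
  as.character(out)
}
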