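#' Read a layered edge list from TSV
#'
#' The on-disk dialect is a UTF-8 TSV with a header line and columns `u`,
#' `v`, `layer`; any further columns are carried along as edge tags (`rel`,
#' `workplace_size`, `school_level`, ...). Rows are validated: malformed rows
#' (missing endpoint or layer) raise an error naming the offending line;
#' self-loops are rejected and logged; duplicate rows within a layer are
#' collapsed with a logged count.
#'
#' @param path file path of the TSV edge list
#' @param nodes optional character vector fixing the aligned node set (e.g.
#'   from a node attribute table); defaults to the nodes seen in the file
#' @param allow_extra_layers if `FALSE` (default), layer codes outside
#'   `C,E,H,N,S,W` raise an error
#' @param quiet suppress log messages
#' @return an `mln_graph`; attributes `n_duplicates` and `n_self_loops`
#'   record the cleaning counts
#' @seealso [write_mln_edgelist()]
#' @export
read_mln_edgelist <- function(path, nodes = NULL, allow_extra_layers = FALSE,
                              quiet = FALSE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = NA, check.names = TRUE)
  required <- c("u", "v", "layer")
  if (!all(required %in% names(raw))) {
    stop("edge list header must contain columns u, v, layer (got: ",
         paste(names(raw), collapse = ", "), ")", call. = FALSE)
  }
  for (col in required) raw[[col]] <- as.character(raw[[col]])
  bad <- which(is.na(raw$u) | is.na(raw$v) | is.na(raw$layer) |
                 raw$u == "" | raw$v == "" | raw$layer == "")
  if (length(bad) > 0) {
    stop(sprintf("malformed edge row at line %d of %s (1-based, incl. header)",
                 bad[1] + 1L, path), call. = FALSE)
  }
  loops <- raw$u == raw$v
  n_loops <- sum(loops)
  if (n_loops > 0) {
    if (!quiet) message(n_loops, " self-loop row(s) rejected")
    raw <- raw[!loops, , drop = FALSE]
  }
  if (!allow_extra_layers) {
    unknown <- setdiff(unique(raw$layer), LAYER_CODES)
    if (length(unknown) > 0) {
      stop("unknown layer code(s): ", paste(unknown, collapse = ", "),
           " (use allow_extra_layers = TRUE to accept)", call. = FALSE)
    }
  }
  g <- mln_graph(raw, nodes = nodes)
  n_dup <- attr(g, "n_duplicates")
  if (!quiet && n_dup > 0) {
    message(n_dup, " duplicate edge row(s) collapsed")
  }
  attr(g, "n_self_loops") <- n_loops
  g
}

#' Write a multilayer graph as a TSV edge list
#'
#' @param g an `mln_graph`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_mln_edgelist <- function(g, path) {
  stopifnot(inherits(g, "mln_graph"))
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

NODE_TABLE_COLUMNS <- c("node_id", "age", "income_decile", "education_level",
                        "urbanization_level", "family_info_complete",
                        "migration_generation")

#' Read / write a node attribute table
#'
#' Node tables are CSVs with one row per person. Required column: `node_id`.
#' Recognised demographic columns: `age` (years), `income_decile` (1-10 or
#' NA), `education_level` (ordinal 1-5: elementary, secondary, secondary
#' special, vocational, higher), `urbanization_level` (ordinal),
#' `family_info_complete` (logical), `migration_generation` (`"native"`,
#' `"first"` or `"second"`).
#'
#' @param path CSV file path
#' @return data.frame with validated columns
#' @export
read_node_table <- function(path) {
  nt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"node_id" %in% names(nt)) {
    stop("node table must contain column node_id", call. = FALSE)
  }
  nt$node_id <- as.character(nt$node_id)
  if (anyDuplicated(nt$node_id)) {
    stop("duplicate node_id in node table", call. = FALSE)
  }
  if ("family_info_complete" %in% names(nt)) {
    nt$family_info_complete <- as.logical(nt$family_info_complete)
  }
  if ("income_decile" %in% names(nt)) {
    bad <- !is.na(nt$income_decile) &
      (nt$income_decile < 1 | nt$income_decile > 10)
    if (any(bad)) stop("income_decile outside 1-10", call. = FALSE)
  }
  if ("migration_generation" %in% names(nt)) {
    ok <- nt$migration_generation %in% c("native", "first", "second")
    if (!all(ok | is.na(nt$migration_generation))) {
      stop("migration_generation must be native/first/second", call. = FALSE)
    }
  }
  nt
}

#' @rdname read_node_table
#' @param nodes a node table data.frame
#' @export
write_node_table <- function(nodes, path) {
  utils::write.csv(nodes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
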