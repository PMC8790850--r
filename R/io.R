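#' Validate an OTU count table
#'
#' An OTU table is an integer matrix with samples in rows and OTUs in
#' columns, row names holding sample identifiers and column names holding
#' OTU identifiers. Every retained sample must have at least one read.
#'
#' @param x matrix to validate.
#' @return the validated matrix (invisibly unchanged).
#' @export
validate_otu_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("OTU table must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("OTU table must carry sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(x)))
    stop("duplicated sample IDs: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicated OTU IDs: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x) || any(x < 0)) stop("OTU table contains NA or negative counts")
  if (any(x != round(x))) stop("OTU table contains non-integer counts")
  if (any(rowSums(x) == 0))
    stop("samples with zero total counts: ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  invisible(x)
}

#' Read an OTU count table from a tab-separated file
#'
#' Expects one header row and one leading ID column. A `#OTU ID`-style
#' header (QIIME dialect) is tolerated. The returned matrix is always
#' oriented samples x OTUs.
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default) or `"otus_as_rows"`
#'   describing the file layout.
#' @return integer matrix, samples in rows, OTUs in columns.
#' @export
read_otu_table <- function(path,
                           orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("OTU table file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != nfield[1L]))
    stop("ragged OTU table: line ", which(nfield != nfield[1L])[1L],
         " has ", nfield[which(nfield != nfield[1L])[1L]],
         " fields, expected ", nfield[1L])
  header <- fields[[1L]]
  ids <- vapply(fields[-1L], `[[`, "", 1L)
  body <- t(vapply(fields[-1L], function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    v
  }, numeric(nfield[1L] - 1L)))
  if (anyNA(body)) {
    bad <- which(apply(body, 1L, anyNA))[1L]
    stop("non-numeric count on line ", bad + 1L, " of ", path)
  }
  dimnames(body) <- list(ids, header[-1L])
  if (orientation == "otus_as_rows") body <- t(body)
  storage.mode(body) <- "double"
  validate_otu_table(body)
  storage.mode(body) <- "integer"
  body
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `source` (values `wild`/`farmed`), `batch`,
#' and optionally `season` and `body_weight` (grams). Each batch must map to
#' a single source, mirroring the batch-nested study design.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' @rdname read_metadata
#' @param md data.frame to validate in place of a file.
#' @export
validate_metadata <- function(md) {
  need <- c("sample_id", "source", "batch")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols))
    stop("metadata lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(md$source), c("wild", "farmed"))
  if (length(bad))
    stop("unknown source value(s): ", paste(bad, collapse = ", "),
         "; allowed: wild, farmed")
  per_batch <- tapply(md$source, md$batch, function(s) length(unique(s)))
  if (any(per_batch > 1L))
    stop("batch mapped to more than one source: ",
         paste(names(per_batch)[per_batch > 1L], collapse = ", "))
  rownames(md) <- md$sample_id
  md
}

#' Read a rooted phylogenetic tree in newick format
#'
#' Missing branch lengths are set to zero with a warning (trees exported by
#' the usual 16S pipelines always carry lengths).
#'
#' @param path file path to a single-tree newick file.
#' @return an [ape::read.tree] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree from ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning(sum(is.na(tree$edge.length)),
            " missing branch length(s) set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0) || any(!is.finite(tree$edge.length)))
    stop("tree has negative or non-finite branch lengths")
  tree
}

#' Write a pipeline result to JSON
#'
#' Serializes any of the pipeline's report objects (neutral fits, null-model
#' results, classifier reports, linkage results, plain lists) with full
#' numeric precision so that write-then-read round-trips losslessly.
#'
#' @param obj result object (a list-like structure).
#' @param path output file path.
#' @export
write_report <- function(obj, path) {
  obj <- c(list(schema_version = "1.0"), unclass_recursive(obj))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @return `read_report` returns the parsed list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else if (is.matrix(x)) {
    x # jsonlite handles matrices row-wise
  } else x
}

#' Write a distance matrix as square TSV
#'
#' Square "phylip-like" format with a header row and an ID column, the
#' layout mothur emits for its distance files.
#'
#' @param d a `dist` object or square symmetric matrix with names.
#' @param path output file path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  utils::write.table(data.frame(sample_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
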