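#' Construct a validated ASV count table
#'
#' The universal input of the package: an integer abundance matrix with taxa
#' as rows and samples as columns, tagged with the kingdom the marker gene
#' targeted (16S -> bacteria, ITS -> fungi).
#'
#' @param counts Numeric matrix, taxa x samples, with unique rownames
#'   (taxon ids) and colnames (sample ids). All cells must be non-negative
#'   integers.
#' @param kingdom One of `"bacteria"`, `"fungi"`, `"unspecified"`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix), `kingdom`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 1L, 3L, 4L), nrow = 3,
#'             dimnames = list(paste0("asv", 1:3), c("s1", "s2")))
#' ct <- count_table(m, "bacteria")
#' @export
count_table <- function(counts, kingdom = c("unspecified", "bacteria", "fungi")) {
  kingdom <- match.arg(kingdom)
  if (!is.matrix(counts)) stop("`counts` must be a matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have taxon ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integral")
  empty <- colSums(counts) == 0
  if (any(empty))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[empty], collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, kingdom = kingdom), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts), x$kingdom))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Taxon and sample identifiers of a count table
#' @param x A `count_table`.
#' @return Character vector of ids.
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname taxon_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Read an ASV count table from disk
#'
#' Two dialects are supported: plain TSV (first column taxon id, header row
#' sample ids, UTF-8, no quoting) and the dense-JSON flavor of the BIOM
#' schema ("matrix_type": "dense"). Sparse BIOM variants are rejected with a
#' clear message.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param kingdom Kingdom tag to attach; for biom-json the tag stored in the
#'   file (if any) takes precedence unless overridden here.
#' @return A validated [count_table].
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json"),
                             kingdom = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            comment.char = "", check.names = FALSE,
                            stringsAsFactors = FALSE, row.names = NULL,
                            fileEncoding = "UTF-8")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop("duplicate taxon ids in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric cell(s) in ", path)
    rownames(m) <- ids
    count_table(m, kingdom %||% "unspecified")
  } else {
    j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!identical(j$matrix_type, "dense"))
      stop("only dense BIOM JSON is supported (matrix_type = \"dense\"); ",
           "got: ", j$matrix_type %||% "<missing>")
    m <- j$data
    if (is.list(m)) m <- do.call(rbind, m)
    m <- as.matrix(m)
    rownames(m) <- if (is.data.frame(j$rows)) j$rows$id else
      vapply(j$rows, `[[`, "", "id")
    colnames(m) <- if (is.data.frame(j$columns)) j$columns$id else
      vapply(j$columns, `[[`, "", "id")
    kd <- kingdom %||% (if (!is.null(j$leafendo_kingdom)) j$leafendo_kingdom
                        else "unspecified")
    count_table(m, kd)
  }
}

#' Write an ASV count table to disk
#'
#' Round-trips losslessly with [read_count_table] for both formats: counts,
#' taxon order, and sample order are preserved bit for bit.
#'
#' @param x A `count_table`.
#' @param path Output file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "count_table"))
  if (format == "tsv") {
    df <- data.frame(taxon_id = rownames(x$counts), x$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    obj <- list(
      id = "leafendo count table",
      format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table",
      generated_by = paste0("leafendo ", as.character(utils::packageVersion("leafendo"))),
      matrix_type = "dense",
      matrix_element_type = "int",
      shape = dim(x$counts),
      leafendo_kingdom = x$kingdom,
      rows = data.frame(id = rownames(x$counts), stringsAsFactors = FALSE),
      columns = data.frame(id = colnames(x$counts), stringsAsFactors = FALSE),
      data = unname(x$counts)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Filter taxa by prevalence
#'
#' Keeps taxa observed at >= `min_reads` reads in >= `min_samples` samples.
#' The defaults used in the per-group network stage are (5, 2) for bacteria
#' and (3, 2) for fungi. The sample set is unchanged; the returned counts are
#' a row submatrix of the input.
#'
#' @param x A `count_table`.
#' @param min_samples Minimum number of qualifying samples (>= 1).
#' @param min_reads Minimum reads for a sample to qualify (>= 1).
#' @return Filtered `count_table`.
#' @export
prevalence_filter <- function(x, min_samples, min_reads = 2) {
  stopifnot(inherits(x, "count_table"), min_samples >= 1, min_reads >= 1)
  keep <- rowSums(x$counts >= min_reads) >= min_samples
  if (!any(keep))
    stop("prevalence_filter removed all taxa (min_samples = ", min_samples,
         ", min_reads = ", min_reads, ")")
  count_table(x$counts[keep, , drop = FALSE], x$kingdom)
}

#' Subset a count table by sample ids
#' @param x A `count_table`.
#' @param samples Character vector of sample ids to keep.
#' @param drop_empty_taxa Drop taxa with zero total in the subset.
#' @return A `count_table`.
#' @export
subset_samples <- function(x, samples, drop_empty_taxa = TRUE) {
  stopifnot(inherits(x, "count_table"), all(samples %in% sample_ids(x)))
  m <- x$counts[, samples, drop = FALSE]
  if (drop_empty_taxa) m <- m[rowSums(m) > 0, , drop = FALSE]
  count_table(m, x$kingdom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
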