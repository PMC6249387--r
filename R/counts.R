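#' Well/cell-by-antibody count matrix
#'
#' The central container of the pipeline: a wells (or, after filtering,
#' cells) x antibodies matrix of UMI counts with per-well metadata
#' (`well_id`, `well_type`, `gate_label`, `total_umis`), per-antibody
#' metadata (the panel sheet columns), and a processing-state tag tracking
#' where in the pipeline the matrix sits: `raw` (all wells, integer UMI
#' counts), `filtered` (cell wells only), `subsampled` (equal row totals),
#' `scaled` (each antibody min-max scaled to \[0, 1\] across cells).
#'
#' @param values Numeric matrix, rows = wells/cells, columns = antibodies.
#' @param row_meta data.frame with `well_id`, `well_type`, `gate_label`;
#'   `total_umis` is (re)computed from `values`.
#' @param col_meta data.frame of antibody metadata (`antibody_name` first).
#' @param state One of `raw`, `filtered`, `subsampled`, `scaled`.
#' @return A `scid_counts` object.
#' @export
scid_counts <- function(values, row_meta, col_meta,
                        state = c("raw", "filtered", "subsampled", "scaled")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  row_meta <- as.data.frame(row_meta, stringsAsFactors = FALSE)
  col_meta <- as.data.frame(col_meta, stringsAsFactors = FALSE)
  if (nrow(values) != nrow(row_meta)) {
    stop("row_meta has ", nrow(row_meta), " rows but matrix has ",
         nrow(values))
  }
  if (ncol(values) != nrow(col_meta)) {
    stop("col_meta has ", nrow(col_meta), " rows but matrix has ",
         ncol(values), " columns")
  }
  for (col in c("well_id", "well_type", "gate_label")) {
    if (!col %in% names(row_meta)) stop("row_meta missing column: ", col)
  }
  if (!"antibody_name" %in% names(col_meta)) {
    stop("col_meta missing column: antibody_name")
  }
  if (state != "scaled") {
    if (any(values < 0) || any(values != round(values))) {
      stop("counts must be non-negative integers in state '", state, "'")
    }
    storage.mode(values) <- "integer"
  } else {
    if (any(values < -1e-9) || any(values > 1 + 1e-9)) {
      stop("scaled values must lie in [0, 1]")
    }
  }
  row_meta$total_umis <- as.numeric(rowSums(values))
  rownames(values) <- row_meta$well_id
  colnames(values) <- col_meta$antibody_name
  structure(
    list(values = values, row_meta = row_meta, col_meta = col_meta,
         state = state),
    class = "scid_counts"
  )
}

#' @export
print.scid_counts <- function(x, ...) {
  cat(sprintf("scid_counts [%s]: %d wells x %d antibodies\n",
              x$state, nrow(x$values), ncol(x$values)))
  tab <- table(x$row_meta$well_type)
  cat("  wells:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  median row total: %.1f\n", median(x$row_meta$total_umis)))
  invisible(x)
}

#' @export
dim.scid_counts <- function(x) dim(x$values)

META_COLS <- c("well_id", "well_type", "gate_label", "total_umis")

#' Read and write count matrices (TSV and MatrixMarket)
#'
#' The TSV dialect is a single self-describing file: a first comment line
#' `#scid_counts state=<state>`, then a header of the four well-metadata
#' columns (`well_id`, `well_type`, `gate_label`, `total_umis`) followed by
#' one column per antibody. The MTX dialect is a triplet: `<prefix>.mtx`
#' (MatrixMarket sparse matrix), `<prefix>.rows.tsv` (well metadata),
#' `<prefix>.cols.tsv` (antibody metadata), `<prefix>.json` (state tag).
#' Both round-trip values, metadata and state losslessly.
#'
#' @param matrix A `scid_counts`.
#' @param path Output path: a `.tsv` file, or the `<prefix>.mtx` path for
#'   the MatrixMarket triplet.
#' @param format `"tsv"` or `"mtx"`; default guessed from the extension.
#' @return `write_count_matrix()` returns `path` invisibly;
#'   `read_count_matrix()` returns a `scid_counts`.
#' @export
write_count_matrix <- function(matrix, path, format = NULL) {
  stopifnot(inherits(matrix, "scid_counts"))
  if (is.null(format)) {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  format <- match.arg(format, c("tsv", "mtx"))
  if (format == "tsv") {
    vals <- matrix$values
    if (matrix$state == "scaled") {
      vals <- matrix(formatC(vals, digits = 10, format = "g"),
                     nrow = nrow(vals), dimnames = dimnames(vals))
    }
    df <- cbind(matrix$row_meta[, META_COLS], as.data.frame(vals))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#scid_counts state=", matrix$state), con)
    suppressWarnings(
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                  na = "")
    )
  } else {
    prefix <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(unname(matrix$values), sparse = TRUE),
                    paste0(prefix, ".mtx"))
    write.table(matrix$row_meta[, META_COLS], paste0(prefix, ".rows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    write.table(matrix$col_meta, paste0(prefix, ".cols.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    jsonlite::write_json(list(state = matrix$state), paste0(prefix, ".json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_count_matrix
#' @param col_meta Optional antibody metadata data.frame to attach when
#'   reading the TSV dialect (which stores only antibody names).
#' @export
read_count_matrix <- function(path, format = NULL, col_meta = NULL) {
  if (!file.exists(path)) stop("count matrix not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  format <- match.arg(format, c("tsv", "mtx"))
  if (format == "tsv") {
    first <- readLines(path, n = 1L)
    state <- sub("^#scid_counts state=", "", first)
    if (identical(state, first)) {
      stop("not a scid_counts TSV (missing '#scid_counts state=' header): ",
           path)
    }
    df <- read.table(path, sep = "\t", header = TRUE, skip = 1L,
                     check.names = FALSE, stringsAsFactors = FALSE,
                     na.strings = "NA", comment.char = "")
    missing_meta <- setdiff(META_COLS, names(df))
    if (length(missing_meta)) {
      stop("count matrix TSV missing metadata column(s): ",
           paste(missing_meta, collapse = ", "))
    }
    ab_cols <- setdiff(names(df), META_COLS)
    if (!length(ab_cols)) stop("count matrix TSV has no antibody columns")
    vals <- as.matrix(df[, ab_cols, drop = FALSE])
    rm <- df[, META_COLS]
    rm$gate_label[is.na(rm$gate_label)] <- "none"
    cm <- if (is.null(col_meta)) data.frame(antibody_name = ab_cols) else col_meta
    scid_counts(vals, rm, cm, state = state)
  } else {
    prefix <- sub("\\.mtx$", "", path)
    for (suffix in c(".mtx", ".rows.tsv", ".cols.tsv", ".json")) {
      if (!file.exists(paste0(prefix, suffix))) {
        stop("MTX triplet member missing: ", paste0(prefix, suffix))
      }
    }
    vals <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
    rm <- read.table(paste0(prefix, ".rows.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, na.strings = "NA")
    rm$gate_label[is.na(rm$gate_label)] <- "none"
    cm <- read.table(paste0(prefix, ".cols.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE,
                     colClasses = "character", na.strings = c("NA", ""))
    state <- jsonlite::read_json(paste0(prefix, ".json"))$state
    scid_counts(vals, rm, cm, state = state)
  }
}
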