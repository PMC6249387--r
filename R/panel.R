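#' @rdname load_panel
#' @param tags data.frame with columns `antibody_name` and `barcode`, and
#'   optionally `epitope_class`, `total_partner`, `pathway_group`,
#'   `replicate_group`. Missing optional columns are added as `NA`.
#' @export
scid_panel <- function(tags) {
  tags <- as.data.frame(tags, stringsAsFactors = FALSE)
  required <- c("antibody_name", "barcode")
  missing_cols <- setdiff(required, names(tags))
  if (length(missing_cols)) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  optional <- c("epitope_class", "total_partner", "pathway_group",
                "replicate_group")
  for (col in setdiff(optional, names(tags))) tags[[col]] <- NA_character_
  tags <- tags[, c(required, optional)]
  tags$epitope_class[is.na(tags$epitope_class)] <- "other"

  classes <- c("total", "phospho", "ligand", "receptor", "other")
  bad_class <- setdiff(unique(tags$epitope_class), classes)
  if (length(bad_class)) {
    stop("unknown epitope_class value(s): ", paste(bad_class, collapse = ", "),
         " (expected one of ", paste(classes, collapse = ", "), ")")
  }

  bad_nt <- grep("[^ACGT]", tags$barcode)
  if (length(bad_nt)) {
    stop("non-ACGT character in barcode at row(s) ",
         paste(bad_nt, collapse = ", "), ": ",
         paste(tags$barcode[bad_nt], collapse = ", "))
  }
  bad_len <- which(nchar(tags$barcode) != 10L)
  if (length(bad_len)) {
    stop("antibody barcodes must be 10 nt; offending row(s): ",
         paste(bad_len, collapse = ", "))
  }
  dup <- tags$barcode[duplicated(tags$barcode)]
  if (length(dup)) {
    rows <- which(tags$barcode %in% dup)
    stop("duplicate barcode(s) ", paste(unique(dup), collapse = ", "),
         " at rows ", paste(rows, collapse = ", "),
         " (", paste(tags$antibody_name[rows], collapse = ", "), ")")
  }
  dup_name <- tags$antibody_name[duplicated(tags$antibody_name)]
  if (length(dup_name)) {
    stop("duplicate antibody_name(s): ", paste(unique(dup_name), collapse = ", "))
  }

  # total_partner must name a 'total' entry in the same panel
  has_partner <- !is.na(tags$total_partner) & nzchar(tags$total_partner)
  if (any(has_partner)) {
    totals <- tags$antibody_name[tags$epitope_class == "total"]
    dangling <- setdiff(tags$total_partner[has_partner], totals)
    if (length(dangling)) {
      stop("total_partner refers to missing or non-total antibody: ",
           paste(dangling, collapse = ", "))
    }
  }

  structure(
    list(tags = tags,
         min_pairwise_distance = min_pairwise_distance(tags$barcode)),
    class = "scid_panel"
  )
}

#' Load an antibody panel sheet
#'
#' Reads a tab- or comma-delimited panel sheet mapping 10-nt antibody
#' barcodes to antibody names, epitope class (`total`, `phospho`, `ligand`,
#' `receptor`, `other`), the paired total-protein antibody for phospho
#' epitopes, a free-text pathway group, and an optional replicate group
#' (several barcodes conjugated independently to the same antibody). The
#' panel is validated (unique names and barcodes, ACGT alphabet, resolvable
#' phospho/total pairing) and annotated with the minimum pairwise Hamming
#' distance over all barcodes, which gates error-tolerant matching: distance
#' `d` supports unambiguous correction of up to `(d - 1) %/% 2` mismatches.
#'
#' @param path Path to a delimited text file with a header row. The
#'   delimiter (tab or comma) is sniffed from the header.
#' @return A `scid_panel`: list with `tags` (data.frame, one row per
#'   antibody-DNA conjugate) and `min_pairwise_distance` (integer).
#' @examples
#' p <- scid_panel(data.frame(
#'   antibody_name = c("ITGB1", "TGM1"),
#'   barcode = c("ACGTACGTAC", "TTTTGGGGCC")
#' ))
#' p$min_pairwise_distance
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel sheet not found: ", path)
  sep <- sniff_delim(path)
  tags <- read.table(path, sep = sep, header = TRUE,
                     colClasses = "character", na.strings = c("NA", ""),
                     stringsAsFactors = FALSE, quote = "\"",
                     comment.char = "")
  scid_panel(tags)
}

#' @rdname load_panel
#' @param panel A `scid_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "scid_panel"))
  write.table(panel$tags, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Hamming distances within a set of equal-length sequences
#'
#' @param x Character vector of equal-length nucleotide strings.
#' @return `min_pairwise_distance()`: the smallest Hamming distance over all
#'   unordered pairs (`Inf` for fewer than two sequences);
#'   `hamming_matrix()`: the full symmetric distance matrix.
#' @export
min_pairwise_distance <- function(x) {
  if (length(x) < 2L) return(Inf)
  d <- hamming_matrix(x)
  min(d[upper.tri(d)])
}

#' @rdname min_pairwise_distance
#' @export
hamming_matrix <- function(x) {
  if (length(unique(nchar(x))) != 1L) {
    stop("sequences must all have the same length")
  }
  chm <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  n <- length(x)
  d <- matrix(0L, n, n)
  for (k in seq_len(ncol(chm))) {
    d <- d + outer(chm[, k], chm[, k], "!=")
  }
  dimnames(d) <- list(x, x)
  d
}

#' @export
print.scid_panel <- function(x, ...) {
  cat("scid_panel:", nrow(x$tags), "antibody-DNA conjugates\n")
  cat("  epitope classes:",
      paste(sprintf("%s=%d", names(table(x$tags$epitope_class)),
                    table(x$tags$epitope_class)), collapse = ", "), "\n")
  n_paired <- sum(!is.na(x$tags$total_partner) & nzchar(x$tags$total_partner))
  cat("  phospho/total pairs:", n_paired, "\n")
  cat("  min pairwise barcode Hamming distance:", x$min_pairwise_distance, "\n")
  invisible(x)
}
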