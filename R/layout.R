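#' Read layout: where each barcode segment sits in a read
#'
#' Describes, in 0-based half-open coordinates, where the well (cell)
#' barcode, the 10-nt antibody barcode and the 15-nt UMI sit inside a
#' single-end read. The library architecture places the well barcode on the
#' indexing primer and is configurable; the default layout is a single
#' in-line read: well barcode at 0-8, antibody barcode at 8-18, UMI at
#' 18-33.
#'
#' @param well_bc,ab_bc,umi Integer vectors `c(offset, length)` in 0-based
#'   half-open coordinates. `ab_bc` length must be 10 and `umi` length 15.
#' @param min_read_length Minimum read length; defaults to the furthest
#'   segment end. Shorter reads are flagged, not assigned.
#' @return A `scid_layout` list.
#' @examples
#' read_layout()                       # default 8 + 10 + 15 nt architecture
#' read_layout(well_bc = c(0, 6), ab_bc = c(6, 10), umi = c(16, 15))
#' @export
read_layout <- function(well_bc = c(0L, 8L), ab_bc = c(8L, 10L),
                        umi = c(18L, 15L), min_read_length = NULL) {
  seg <- function(v, name) {
    v <- as.integer(v)
    if (length(v) != 2L || any(is.na(v)) || v[1] < 0L || v[2] <= 0L) {
      stop(name, " must be c(offset, length) with offset >= 0, length > 0")
    }
    v
  }
  well_bc <- seg(well_bc, "well_bc")
  ab_bc <- seg(ab_bc, "ab_bc")
  umi <- seg(umi, "umi")
  if (ab_bc[2] != 10L) stop("antibody barcode segment length must be 10")
  if (umi[2] != 15L) stop("UMI segment length must be 15")

  ends <- c(well_bc[1] + well_bc[2], ab_bc[1] + ab_bc[2], umi[1] + umi[2])
  if (is.null(min_read_length)) min_read_length <- max(ends)
  min_read_length <- as.integer(min_read_length)

  layout <- structure(
    list(well_bc = well_bc, ab_bc = ab_bc, umi = umi,
         min_read_length = min_read_length),
    class = "scid_layout"
  )
  if (segments_overlap(layout)) stop("read layout segments overlap")
  if (min_read_length < max(ends)) {
    stop("min_read_length (", min_read_length,
         ") is smaller than the furthest segment end (", max(ends), ")")
  }
  layout
}

segments_overlap <- function(layout) {
  s <- rbind(layout$well_bc, layout$ab_bc, layout$umi)
  starts <- s[, 1]
  ends <- s[, 1] + s[, 2]
  ord <- order(starts)
  any(ends[ord][-3] > starts[ord][-1])
}

#' Check that a read layout fits within a read length
#'
#' Pure predicate: `TRUE` iff the well-barcode, antibody-barcode and UMI
#' segments are pairwise non-overlapping and all end at or before
#' `read_length`.
#'
#' @param layout A `scid_layout` (or a list with `well_bc`, `ab_bc`, `umi`
#'   segments as `c(offset, length)`).
#' @param read_length Integer read length.
#' @return Logical scalar.
#' @examples
#' validate_layout(read_layout(), 40) # TRUE
#' validate_layout(read_layout(), 30) # FALSE: UMI ends at 33
#' @export
validate_layout <- function(layout, read_length) {
  s <- rbind(layout$well_bc, layout$ab_bc, layout$umi)
  all(s[, 1] + s[, 2] <= read_length) && !segments_overlap(layout)
}

#' @rdname read_layout
#' @param path JSON file with keys `well_bc`, `ab_bc`, `umi` (each
#'   `[offset, length]`) and optionally `min_read_length`.
#' @export
load_read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("well_bc", "ab_bc", "umi", "min_read_length")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown key(s) in read layout: ", paste(unknown, collapse = ", "))
  }
  do.call(read_layout, cfg)
}

#' @rdname read_layout
#' @param layout A `scid_layout`.
#' @export
write_read_layout <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, auto_unbox = FALSE)
  invisible(path)
}

#' @export
print.scid_layout <- function(x, ...) {
  cat("scid_layout (0-based half-open):\n")
  for (nm in c("well_bc", "ab_bc", "umi")) {
    cat(sprintf("  %-8s [%d, %d)\n", nm, x[[nm]][1], x[[nm]][1] + x[[nm]][2]))
  }
  cat("  min read length:", x$min_read_length, "\n")
  invisible(x)
}

#' Plate layout: well barcodes, well types, FACS gates
#'
#' Maps each well barcode to its well identifier, type (`cell` for wells
#' that received a FACS-sorted single cell, `empty` for background wells)
#' and FACS gate label (`ITGB1+`, `ITGB1low`, or `none`). Empty wells are
#' the technical-background control: they went through staining, sorting
#' and library preparation without a cell.
#'
#' @param wells data.frame with columns `well_barcode`, `well_id`,
#'   `well_type`, and optionally `gate_label`.
#' @return A `scid_plate` (validated data.frame).
#' @export
scid_plate <- function(wells) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  required <- c("well_barcode", "well_id", "well_type")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    stop("plate layout is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"gate_label" %in% names(wells)) wells$gate_label <- "none"
  wells$gate_label[is.na(wells$gate_label)] <- "none"
  wells <- wells[, c(required, "gate_label")]

  if (anyDuplicated(wells$well_barcode)) {
    stop("duplicate well barcode(s): ",
         paste(unique(wells$well_barcode[duplicated(wells$well_barcode)]),
               collapse = ", "))
  }
  if (anyDuplicated(wells$well_id)) {
    stop("duplicate well id(s): ",
         paste(unique(wells$well_id[duplicated(wells$well_id)]),
               collapse = ", "))
  }
  bad_type <- setdiff(unique(wells$well_type), c("cell", "empty"))
  if (length(bad_type)) {
    stop("well_type must be 'cell' or 'empty'; found: ",
         paste(bad_type, collapse = ", "))
  }
  if (!any(wells$well_type == "cell")) stop("plate has no cell wells")
  if (length(unique(nchar(wells$well_barcode))) != 1L) {
    stop("well barcodes must all have the same length")
  }
  class(wells) <- c("scid_plate", "data.frame")
  wells
}

#' @rdname scid_plate
#' @param path Delimited text file (tab or comma) with a header row.
#' @export
load_plate <- function(path) {
  if (!file.exists(path)) stop("plate layout not found: ", path)
  sep <- sniff_delim(path)
  wells <- read.table(path, sep = sep, header = TRUE,
                      colClasses = "character", na.strings = c("NA", ""),
                      stringsAsFactors = FALSE, comment.char = "")
  scid_plate(wells)
}

#' @rdname scid_plate
#' @param plate A `scid_plate`.
#' @export
write_plate <- function(plate, path) {
  write.table(as.data.frame(plate), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
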