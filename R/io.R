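# Readers and writers for the plain-text and image formats the pipeline
# consumes. Every reader validates on the way in; every writer round-trips
# its own output.

#' Read a count matrix
#'
#' TSV format: genes/cells as row names in the first column, one column per
#' sample/gene. MatrixMarket triplet format: a `.mtx` file plus one-id-per-line
#' row and column id files; dimensions must match the header.
#'
#' @param path path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`.
#' @param row_ids,col_ids id file paths (required for `"mtx"`).
#' @return numeric matrix with dimnames; negative entries are an error.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"), row_ids = NULL,
                        col_ids = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop_input("count TSV contains non-numeric entries")
  } else {
    if (is.null(row_ids) || is.null(col_ids)) {
      stop_input("`row_ids` and `col_ids` files are required for MTX input")
    }
    sm <- Matrix::readMM(path)
    rid <- readLines(row_ids)
    cid <- readLines(col_ids)
    if (length(rid) != nrow(sm) || length(cid) != ncol(sm)) {
      stop_input(sprintf("MTX header says %d x %d but ids give %d x %d",
                         nrow(sm), ncol(sm), length(rid), length(cid)))
    }
    m <- as.matrix(sm)
    dimnames(m) <- list(rid, cid)
  }
  if (any(m < 0)) stop_input("count matrix has negative entries")
  m
}

#' Write a count matrix
#'
#' @param m matrix with dimnames.
#' @param path output path (TSV) or `.mtx` path.
#' @param format `"tsv"` or `"mtx"`.
#' @param row_ids,col_ids id file paths (required for `"mtx"`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("tsv", "mtx"), row_ids = NULL,
                         col_ids = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(row_ids) || is.null(col_ids)) {
      stop_input("`row_ids` and `col_ids` paths are required for MTX output")
    }
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    path)
    writeLines(rownames(m), row_ids)
    writeLines(colnames(m), col_ids)
  }
  invisible(path)
}

#' Read a gene-to-zone annotation table
#'
#' TSV with columns `gene_id` and `zone`; duplicate genes or unknown zone
#' labels are errors.
#'
#' @param path file path.
#' @return validated zone table.
#' @export
read_zone_table <- function(path) {
  validate_zone_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a gene-to-zone table
#' @param zones zone table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zone_table <- function(zones, path) {
  zones <- validate_zone_table(zones)
  write.table(zones, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BED intervals
#'
#' 0-based half-open intervals; zero- or negative-width intervals are an
#' error.
#'
#' @param path BED file path.
#' @return data frame `chrom`, `start`, `end` (+ `name`, `strand` when
#'   present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  if (nrow(out) && any(out$start >= out$end)) {
    stop_input("BED intervals must satisfy start < end")
  }
  out
}

#' Write BED intervals
#' @param df interval data frame (`chrom`, `start`, `end`, optional `name`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(df)) cols <- c(cols, "name")
  write.table(format(df[cols], scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file path.
#' @param normalized normalization state to record (`"raw"` default).
#' @return a [coverage_track()] (unsorted input is sorted with a warning).
#' @export
read_bedgraph <- function(path, normalized = "raw") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                            start = GenomicRanges::start(gr) - 1L,
                            end = GenomicRanges::end(gr),
                            value = gr$score,
                            stringsAsFactors = FALSE),
                 normalized = normalized)
}

#' Write a coverage track as bedGraph
#' @param track a [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  write.table(format(as.data.frame(track)[c("chrom", "start", "end", "value")],
                     scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a 3D volume from a multi-page TIFF
#'
#' @param path TIFF stack path.
#' @return 3D numeric array (rows x cols x slices); a single-page file is
#'   an error for 3D use.
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop_input("TIFF has a single page; a 3D stack is required")
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  arr
}

#' Write a 3D volume as a multi-page float TIFF
#'
#' Values must lie in \[0, 1\] (the float TIFF range); rescale before
#' writing if needed.
#'
#' @param arr 3D numeric array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, path) {
  if (!is.array(arr) || length(dim(arr)) != 3) stop_input("`arr` must be a 3D array")
  if (min(arr) < 0 || max(arr) > 1) stop_input("volume values must lie in [0, 1]")
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a label volume as a multi-page TIFF
#'
#' Integer labels are stored as `label / 255` in a float TIFF, which
#' round-trips exactly through [read_labels()].
#'
#' @param labels integer 3D array with values in 0..255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (!is.array(labels) || length(dim(labels)) != 3) stop_input("`labels` must be a 3D array")
  if (min(labels) < 0 || max(labels) > 255 || any(labels != round(labels))) {
    stop_input("labels must be integers in 0..255")
  }
  write_volume(labels / 255, path)
}

#' Read a label volume written by [write_labels()]
#' @param path TIFF path.
#' @return integer 3D array.
#' @export
read_labels <- function(path) {
  arr <- read_volume(path)
  lab <- round(arr * 255)
  storage.mode(lab) <- "integer"
  array(lab, dim(arr))
}
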