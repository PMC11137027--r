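#' Read fragment intervals from BED3 or BEDPE
#'
#' BED3 lines become fragments directly; BEDPE mate pairs on the same
#' chromosome become one fragment spanning the outer coordinates (mates on
#' different chromosomes are an error). Plain or gzip-compressed files are
#' accepted. Coordinates are validated as 0-based half-open intervals and
#' malformed lines are reported with their line numbers.
#'
#' @param path Path to a \code{.bed} / \code{.bedpe} file (optionally
#'   \code{.gz}).
#' @param format \code{"auto"} (from the extension), \code{"bed"} or
#'   \code{"bedpe"}.
#' @param library_id Library label attached to the fragments (default: the
#'   file name).
#' @return A [GenomicRanges::GRanges] of fragments with metadata column
#'   \code{library_id}.
#' @export
readFragments <- function(path, format = c("auto", "bed", "bedpe"),
                          library_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bedpe(\\.gz)?$", path, ignore.case = TRUE))
      "bedpe" else "bed"
  if (is.null(library_id))
    library_id <- sub("\\.(bed|bedpe)(\\.gz)?$", "", basename(path),
                      ignore.case = TRUE)
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(GenomicRanges::width(gr) < 1L))
      stop("empty interval(s) in ", path)
    gr <- GenomicRanges::granges(gr)
  } else {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    lines <- readLines(con)
    close(con)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    lineno <- which(keep)
    nf <- lengths(fields)
    if (any(nf < 6L))
      stop("BEDPE line ", lineno[which(nf < 6L)[1]], " has fewer than 6 fields")
    m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
    s1 <- suppressWarnings(as.integer(m[, 2]))
    e1 <- suppressWarnings(as.integer(m[, 3]))
    s2 <- suppressWarnings(as.integer(m[, 5]))
    e2 <- suppressWarnings(as.integer(m[, 6]))
    bad <- is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2)
    if (any(bad))
      stop("non-numeric coordinates at line ", lineno[which(bad)[1]])
    bad <- s1 >= e1 | s2 >= e2
    if (any(bad))
      stop("mate with start >= end at line ", lineno[which(bad)[1]])
    if (any(m[, 1] != m[, 4]))
      stop("interchromosomal mate pair at line ",
           lineno[which(m[, 1] != m[, 4])[1]])
    start0 <- pmin(s1, s2)
    end0 <- pmax(e1, e2)
    bad <- start0 >= end0
    if (any(bad))
      stop("start >= end at line ", lineno[which(bad)[1]])
    gr <- GenomicRanges::GRanges(m[, 1],
            IRanges::IRanges(start = start0 + 1L, end = end0))
  }
  gr$library_id <- library_id
  gr
}

#' Read anchors from BED6
#'
#' Anchors are 1-bp points; intervals wider than one base are reduced to
#' their midpoint (with a message). A \code{"."} strand is treated as
#' \code{"+"}.
#'
#' @param path Path to a BED6 file (BED4+ also accepted; strand defaults to
#'   \code{"+"} when absent).
#' @param kind Anchor kind label (\code{"TSS"}, \code{"enhancer"},
#'   \code{"motif"}).
#' @return GRanges of anchor points with \code{anchor_id} and \code{kind}.
#' @export
readAnchors <- function(path, kind = "TSS") {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) > 1L)) {
    message(sum(GenomicRanges::width(gr) > 1L),
            " interval anchor(s) reduced to their midpoint")
    gr <- fragmentMidpointsKeepMcols(gr)
  }
  st <- as.character(GenomicRanges::strand(gr))
  GenomicRanges::strand(gr) <- ifelse(st == "-", "-", "+")
  ids <- if (!is.null(gr$name) && !anyNA(gr$name) &&
             !anyDuplicated(gr$name)) gr$name
         else paste0("anchor_", seq_along(gr))
  out <- GenomicRanges::granges(gr)
  out$anchor_id <- ids
  out$kind <- kind
  out
}

## midpoint reduction that keeps strand and metadata
fragmentMidpointsKeepMcols <- function(gr) {
  mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(mid, width = 1L),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

#' Write fragments as BED3
#'
#' @param fragments GRanges of fragments.
#' @param path Output path (0-based half-open BED).
#' @return \code{path}, invisibly.
#' @export
writeFragmentsBED <- function(fragments, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(fragments)),
                   start = GenomicRanges::start(fragments) - 1L,
                   end = GenomicRanges::end(fragments))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a table as TSV
#'
#' @param x data.frame or DataFrame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTSV <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
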