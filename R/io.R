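# Readers and writers for the interchange formats: SEG (tab-separated,
# 1-based inclusive coordinates internally), GCT v1.2, plain TSV tables,
# and a BED-style peak export (0-based half-open, per BED convention).
# Numeric payloads round-trip at full precision.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", vapply(x, format, character(1), digits = 17,
                                trim = TRUE))
}

#' Write / read SEG segmented copy-number profiles
#'
#' Columns: Sample, Chromosome, Start, End, Num_Probes, Segment_Mean;
#' coordinates are 1-based inclusive. `read_seg` validates coordinate
#' sanity and numeric payloads, reporting the offending line.
#'
#' @param segments SEG-shaped data.frame.
#' @param path file path.
#' @return `read_seg` returns the validated data.frame.
#' @export
write_seg <- function(segments, path) {
  need <- c("Sample", "Chromosome", "Start", "End", "Num_Probes",
            "Segment_Mean")
  stopifnot(all(need %in% names(segments)))
  out <- segments[need]
  out$Segment_Mean <- fmt_num(out$Segment_Mean)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, check.names = FALSE,
                  colClasses = list(Sample = "character"))
  need <- c("Sample", "Chromosome", "Start", "End", "Num_Probes",
            "Segment_Mean")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("SEG file lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("Start", "End", "Num_Probes", "Segment_Mean"))
    if (!is.numeric(d[[col]]))
      stop("SEG column ", col, " is not numeric")
  bad <- which(d$End < d$Start)
  if (length(bad))
    stop(sprintf("SEG row %d (line %d): End < Start (%s:%d-%d)",
                 bad[1L], bad[1L] + 1L, as.character(d$Chromosome[bad[1L]]),
                 d$Start[bad[1L]], d$End[bad[1L]]))
  d
}

#' Write / read GCT v1.2 expression or screen matrices
#'
#' The GCT v1.2 layout: a `#1.2` version line, a `rows<TAB>columns`
#' dimension line, then a header `Name, Description, <sample ids>` and
#' one row per feature. Dimensions are validated against the payload;
#' duplicate feature names and non-numeric cells are errors naming the
#' line.
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @param description optional per-row description column (defaults to
#'   the row names).
#' @return `read_gct` returns the numeric matrix (descriptions in
#'   attribute `description`).
#' @export
write_gct <- function(mat, path, description = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (is.null(description)) description <- rownames(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(mat)), collapse = "\t"),
             con)
  body <- apply(mat, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(paste(rownames(mat), description, body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_gct
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1L]) != "#1.2")
    stop("not a GCT v1.2 file (missing '#1.2' on line 1): ", path)
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(dims) < 2L || anyNA(dims))
    stop("malformed GCT dimension line (line 2)")
  body <- read.delim(text = lines[-(1:2)], check.names = FALSE,
                     colClasses = c("character", "character",
                                    rep("numeric", dims[2L])))
  if (nrow(body) != dims[1L])
    stop(sprintf("GCT declares %d rows but contains %d (line 2 vs payload)",
                 dims[1L], nrow(body)))
  if (ncol(body) - 2L != dims[2L])
    stop(sprintf("GCT declares %d columns but contains %d",
                 dims[2L], ncol(body) - 2L))
  if (anyDuplicated(body$Name))
    stop("duplicate feature names in GCT: ",
         paste(unique(body$Name[duplicated(body$Name)]), collapse = ", "))
  m <- as.matrix(body[, -(1:2), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric payload in GCT: ", path)
  rownames(m) <- body$Name
  attr(m, "description") <- body$Description
  m
}

#' Write / read plain TSV tables
#'
#' Thin, validated wrappers: tab-separated, header row, no quoting, full
#' numeric precision on write.
#'
#' @param table data.frame.
#' @param path file path.
#' @return `read_tsv_table` returns the data.frame.
#' @export
write_tsv_table <- function(table, path) {
  out <- as.data.frame(table)
  for (col in names(out))
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- fmt_num(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, check.names = FALSE)
}

#' Export peaks as a BED-like track
#'
#' BED compliance: 0-based half-open coordinates (`start - 1`, `end`),
#' name = `direction:index`, score = max G; extra columns carry min_q,
#' frequency and the gene list.
#'
#' @param peaks data.frame from [detect_peaks()].
#' @param path file path.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(chrom = peaks$chromosome,
                    chromStart = peaks$start - 1L,
                    chromEnd = peaks$end,
                    name = sprintf("%s:%d", peaks$direction,
                                   seq_len(nrow(peaks))),
                    score = fmt_num(peaks$max_G),
                    min_q = fmt_num(peaks$min_q),
                    frequency = fmt_num(peaks$frequency),
                    genes = peaks$genes)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
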