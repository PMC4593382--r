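# Light-weight SAM text handling. Subsampling must reproduce input records
# byte-for-byte, so records are kept as raw lines; only the handful of
# fields needed for selection and counting are parsed out.

FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

# Read a SAM (or, if Rsamtools is available, BAM) file into its header
# lines and alignment record lines.
read_sam <- function(path) {
  if (!file.exists(path)) stop_user("alignment file not found: %s", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop_user("reading BAM requires the Rsamtools package; convert %s to SAM",
                path)
    }
    tmp <- tempfile(fileext = ".sam")
    Rsamtools::asSam(path, sub("\\.sam$", "", tmp), overwrite = TRUE)
    path <- tmp
    on.exit(unlink(tmp))
  }
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  n_head <- if (any(!is_header)) which(!is_header)[1L] - 1L else length(lines)
  list(header = lines[seq_len(n_head)],
       records = lines[seq.int(n_head + 1L, length.out = length(lines) - n_head)])
}

# Extract tab-separated field `i` from each record line without splitting
# the whole line.
sam_field <- function(records, i) {
  if (i == 1L) return(sub("\t.*$", "", records))
  vapply(strsplit(records, "\t", fixed = TRUE),
         function(x) x[[i]], character(1L))
}

# Parse the mandatory fields needed for counting.
parse_sam_records <- function(records) {
  if (length(records) == 0L) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), stringsAsFactors = FALSE))
  }
  parts <- data.table::tstrsplit(records, "\t", fixed = TRUE, keep = 1:6)
  data.frame(
    qname = parts[[1L]],
    flag = as.integer(parts[[2L]]),
    rname = parts[[3L]],
    pos = as.integer(parts[[4L]]),
    cigar = parts[[6L]],
    stringsAsFactors = FALSE
  )
}

#' Load an alignment file for subsampling
#'
#' Reads a SAM (or BAM, via Rsamtools) file and indexes its alignment
#' records by fragment. A fragment is identified by the read name (QNAME),
#' so both mates of a paired-end fragment and any secondary records travel
#' together through subsampling.
#'
#' @param path Path to a SAM or BAM file.
#' @return An `alignment_set`: list with `source` (the path), `header`
#'   (header lines, preserved verbatim), `records` (alignment lines),
#'   `qname` (per-record fragment id), `fragment_ids` (distinct fragment
#'   ids in order of first appearance), `n_fragments`, and `n_mapped`
#'   (fragments with at least one mapped record).
#' @export
alignment_set <- function(path) {
  sam <- read_sam(path)
  qname <- sam_field(sam$records, 1L)
  fragment_ids <- unique(qname)
  if (length(sam$records)) {
    flag <- as.integer(sam_field(sam$records, 2L))
    mapped <- !bitwAnd(flag, FLAG_UNMAPPED)
    n_mapped <- length(unique(qname[mapped]))
  } else {
    n_mapped <- 0L
  }
  structure(list(
    source = path,
    header = sam$header,
    records = sam$records,
    qname = qname,
    fragment_ids = fragment_ids,
    n_fragments = length(fragment_ids),
    n_mapped = n_mapped
  ), class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d fragments (%d mapped), %d records [%s]\n",
              x$n_fragments, x$n_mapped, length(x$records), x$source))
  invisible(x)
}

write_sam <- function(header, records, path) {
  con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                  error = function(e) stop_user("cannot write to %s: %s",
                                                path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(header, records), con)
  invisible(path)
}
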