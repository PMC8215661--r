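#' MOTU read-count table
#'
#' The central object of the pipeline: a matrix of read counts (one row per
#' molecular operational taxonomic unit, one column per PCR) together with
#' per-MOTU annotations (sequence, amplicon length, taxonomy).
#'
#' @param motus data.frame of per-MOTU annotations. Must contain `motu_id`;
#'   recognised optional columns are `sequence`, `length`, `class`, `genus`,
#'   `species` and `clade_path` (a `;`-separated lineage string).
#' @param counts integer matrix of read counts, rows matching `motus$motu_id`,
#'   columns named by PCR id. Negative entries are rejected.
#' @return An object of class `motu_table`: a list with elements `motus` and
#'   `counts`.
#' @examples
#' m <- data.frame(motu_id = c("m1", "m2"), length = c(100L, 120L))
#' cnt <- matrix(c(5L, 0L, 3L, 12L), 2, 2,
#'               dimnames = list(c("m1", "m2"), c("p1", "p2")))
#' motu_table(m, cnt)
#' @export
motu_table <- function(motus, counts) {
  stopifnot(is.data.frame(motus), "motu_id" %in% names(motus))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(motus))
    stop("counts must have one row per MOTU")
  if (any(counts < 0)) stop("counts matrix has negative entries")
  if (is.null(colnames(counts))) stop("counts columns must be named by PCR id")
  if (is.null(rownames(counts))) rownames(counts) <- motus$motu_id
  if (nrow(counts) > 0 &&
      !identical(rownames(counts), as.character(motus$motu_id)))
    stop("counts rownames must match motus$motu_id")
  if (!is.null(motus$sequence) && !is.null(motus$length)) {
    has_seq <- !is.na(motus$sequence) & nzchar(motus$sequence)
    bad <- has_seq & !is.na(motus$length) &
      nchar(motus$sequence) != motus$length
    if (any(bad))
      stop("length column disagrees with sequence length for: ",
           paste(motus$motu_id[bad], collapse = ", "))
  }
  structure(list(motus = motus, counts = counts), class = "motu_table")
}

#' @export
print.motu_table <- function(x, ...) {
  cat("MOTU table:", nrow(x$counts), "MOTUs x", ncol(x$counts), "PCRs;",
      format(sum(x$counts), big.mark = ","), "reads\n")
  invisible(x)
}

#' @export
dim.motu_table <- function(x) dim(x$counts)

# internal row/column subsetting that keeps annotations and counts in step
subset_motus <- function(x, keep) {
  motu_table(x$motus[keep, , drop = FALSE], x$counts[keep, , drop = FALSE])
}

subset_pcrs <- function(x, keep_cols) {
  motu_table(x$motus, x$counts[, keep_cols, drop = FALSE])
}

# per-PCR relative frequencies; zero-depth PCRs give all-zero columns
pcr_rel_freq <- function(counts) {
  depth <- colSums(counts)
  depth[depth == 0] <- 1
  sweep(counts, 2, depth, "/")
}

validate_pcrs <- function(x, pcrs) {
  stopifnot(is.data.frame(pcrs),
            all(c("pcr_id", "sample_id", "control_type") %in% names(pcrs)))
  if (!setequal(colnames(x$counts), pcrs$pcr_id))
    stop("PCR ids in counts matrix and PCR metadata do not match")
  pcrs[match(colnames(x$counts), pcrs$pcr_id), , drop = FALSE]
}

#' Read / write the pipeline's text formats
#'
#' The MOTU table travels as tab-separated text: annotation columns first
#' (`motu_id`, `sequence`, `length`, `class`, `genus`, `species`,
#' `clade_path`), then one integer column per PCR. PCR metadata, environment
#' tables and ground-truth niches are plain CSV.
#'
#' @param x a `motu_table`.
#' @param file path to read from / write to.
#' @return `read_motu_table` returns a `motu_table`; the writer returns the
#'   file path invisibly.
#' @export
write_motu_table <- function(x, file) {
  ann <- x$motus
  df <- cbind(ann, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_motu_table
#' @export
read_motu_table <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  ann_cols <- intersect(
    c("motu_id", "sequence", "length", "class", "genus", "species",
      "clade_path"), names(df))
  count_cols <- setdiff(names(df), ann_cols)
  counts <- as.matrix(df[count_cols])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$motu_id
  motu_table(df[ann_cols], counts)
}

#' Annotated FASTA in `key=value;` header dialect
#'
#' Writes one record per MOTU with attributes appended to the header as
#' `key=value; ` pairs (the dialect used by OBITools-style exports), and
#' parses such files back into an annotation data.frame.
#'
#' @param motus data.frame with `motu_id` and `sequence` plus any annotation
#'   columns to embed in headers.
#' @param file path.
#' @return `read_annotated_fasta` returns a data.frame of annotations with a
#'   `sequence` column.
#' @export
write_annotated_fasta <- function(motus, file) {
  stopifnot(all(c("motu_id", "sequence") %in% names(motus)))
  attr_cols <- setdiff(names(motus), c("motu_id", "sequence"))
  lines <- character(0)
  for (i in seq_len(nrow(motus))) {
    attrs <- vapply(attr_cols, function(k) {
      paste0(k, "=", motus[[k]][i], ";")
    }, character(1))
    lines <- c(lines,
               paste(c(paste0(">", motus$motu_id[i]), attrs), collapse = " "),
               motus$sequence[i])
  }
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_annotated_fasta
#' @export
read_annotated_fasta <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^>", lines)
  stopifnot(length(hdr) > 0)
  ends <- c(hdr[-1] - 1, length(lines))
  recs <- lapply(seq_along(hdr), function(i) {
    h <- sub("^>", "", lines[hdr[i]])
    toks <- strsplit(h, " +")[[1]]
    id <- toks[1]
    attrs <- toks[-1][grepl("=", toks[-1])]
    kv <- sub(";$", "", attrs)
    keys <- sub("=.*", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    seq <- paste(lines[(hdr[i] + 1):ends[i]], collapse = "")
    out <- c(list(motu_id = id, sequence = seq), as.list(stats::setNames(vals, keys)))
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  cols <- unique(unlist(lapply(recs, names)))
  recs <- lapply(recs, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  })
  out <- do.call(rbind, recs)
  if ("length" %in% names(out)) out$length <- as.integer(out$length)
  out
}
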