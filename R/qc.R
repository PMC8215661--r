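#' Marker defaults
#'
#' Amplicon length bounds and minimum read counts per marker: lengths
#' 65--200 bp for Chlo01 and Euka03, 65--130 bp for Chlo02; a PCR must reach
#' 200 reads (Chlo01/Chlo02) or 1,000 reads (Euka03) to be considered
#' successful.
#'
#' @param marker "Chlo01", "Chlo02" or "Euka03" (unknown markers fall back
#'   to the Chlo01 defaults with a warning).
#' @return `marker_length_bounds`: length-2 integer vector (min, max bp);
#'   `marker_min_reads`: a single count.
#' @export
marker_length_bounds <- function(marker) {
  switch(marker,
         Chlo01 = c(65L, 200L),
         Euka03 = c(65L, 200L),
         Chlo02 = c(65L, 130L),
         {
           warning("unknown marker '", marker, "'; using Chlo01 bounds")
           c(65L, 200L)
         })
}

#' @rdname marker_length_bounds
#' @export
marker_min_reads <- function(marker) {
  switch(marker,
         Chlo01 = 200L,
         Chlo02 = 200L,
         Euka03 = 1000L,
         {
           warning("unknown marker '", marker, "'; using 200-read threshold")
           200L
         })
}

qc_report <- function(stage, before, after, pcrs_removed = 0L,
                      details = NULL) {
  structure(list(
    stage = stage,
    motus_removed = nrow(before$counts) - nrow(after$counts),
    pcrs_removed = pcrs_removed,
    reads_removed = sum(before$counts) - sum(after$counts),
    details = details), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("[%s] removed %d MOTUs, %d PCRs, %s reads\n", x$stage,
              x$motus_removed, x$pcrs_removed,
              format(x$reads_removed, big.mark = ",")))
  invisible(x)
}

#' Amplicon length filter
#'
#' Removes MOTUs whose amplicon length falls outside `[min_bp, max_bp]`
#' (bounds inclusive). Defaults are the per-marker bounds of
#' [marker_length_bounds()].
#'
#' @param x a [motu_table()] with a `length` column.
#' @param min_bp,max_bp inclusive bounds in bp.
#' @return list with the filtered `table` and a `report`.
#' @export
filter_length <- function(x, min_bp = 65, max_bp = 200) {
  stopifnot(inherits(x, "motu_table"), min_bp <= max_bp)
  if (is.null(x$motus$length) || all(is.na(x$motus$length)))
    stop("MOTU table carries no length information")
  keep <- !is.na(x$motus$length) &
    x$motus$length >= min_bp & x$motus$length <= max_bp
  out <- subset_motus(x, keep)
  list(table = out,
       report = qc_report("length", x, out,
                          details = x$motus$motu_id[!keep]))
}

#' Rare sequence-variant filter
#'
#' Retains a MOTU only if it is represented by more than `min_peak_reads`
#' reads in at least one PCR (i.e. variants never exceeding 10 reads in any
#' single PCR are discarded under the default).
#'
#' @param x a [motu_table()].
#' @param min_peak_reads strict threshold on the per-PCR maximum.
#' @return list with the filtered `table` and a `report`.
#' @export
filter_rare <- function(x, min_peak_reads = 10) {
  stopifnot(inherits(x, "motu_table"))
  peak <- apply(x$counts, 1, max)
  keep <- peak > min_peak_reads
  out <- subset_motus(x, keep)
  list(table = out,
       report = qc_report("rare", x, out, details = x$motus$motu_id[!keep]))
}

#' Target-clade restriction
#'
#' Keeps only MOTUs whose taxonomic lineage contains the target clade
#' (membership at any rank counts: a MOTU annotated at a descendant rank of
#' the clade is retained).
#'
#' @param x a [motu_table()] with a `clade_path` column (`;`-separated
#'   lineage) or a `class` column used as fallback.
#' @param clade target clade label, e.g. "Chlorophyta".
#' @return list with the filtered `table` and a `report`.
#' @export
restrict_clade <- function(x, clade = "Chlorophyta") {
  stopifnot(inherits(x, "motu_table"))
  path <- x$motus$clade_path
  if (is.null(path)) path <- x$motus$class
  if (is.null(path)) stop("MOTU table carries no taxonomy")
  keep <- vapply(strsplit(ifelse(is.na(path), "", path), ";"),
                 function(p) clade %in% trimws(p), logical(1))
  out <- subset_motus(x, keep)
  list(table = out,
       report = qc_report("clade", x, out, details = x$motus$motu_id[!keep]))
}

#' Negative-control contaminant removal
#'
#' A MOTU is flagged as a contaminant and removed if its maximum abundance
#' across negative controls (extraction and PCR blanks) strictly exceeds its
#' maximum abundance across all sample PCRs. Abundance is by default the
#' within-PCR relative frequency (blank and sample depths differ by orders
#' of magnitude); raw read counts are available as an option. Positive
#' controls take no part in the comparison.
#'
#' @param x a [motu_table()].
#' @param pcrs PCR metadata with `pcr_id` and `control_type`.
#' @param metric "rel_freq" (default) or "raw_reads".
#' @return list with the filtered `table` and a `report`.
#' @export
remove_contaminants <- function(x, pcrs, metric = c("rel_freq", "raw_reads")) {
  stopifnot(inherits(x, "motu_table"))
  metric <- match.arg(metric)
  pcrs <- validate_pcrs(x, pcrs)
  is_blank <- pcrs$control_type %in% c("extraction_blank", "pcr_blank")
  is_sample <- pcrs$control_type == "sample"
  if (!any(is_blank)) {
    warning("no negative controls present; contaminant filter is a no-op")
    return(list(table = x,
                report = qc_report("contaminants", x, x,
                                   details = "no negative controls")))
  }
  A <- if (metric == "rel_freq") pcr_rel_freq(x$counts) else x$counts
  max_blank <- apply(A[, is_blank, drop = FALSE], 1, max)
  max_sample <- if (any(is_sample))
    apply(A[, is_sample, drop = FALSE], 1, max) else rep(0, nrow(A))
  keep <- max_blank <= max_sample
  out <- subset_motus(x, keep)
  list(table = out,
       report = qc_report("contaminants", x, out,
                          details = x$motus$motu_id[!keep]))
}

#' Failed-PCR rejection
#'
#' Drops PCRs whose total read count falls below the marker's minimum
#' (200 reads for Chlo01/Chlo02, 1,000 for Euka03). The threshold is read as
#' a minimum to reach -- PCRs *below* it are the unreliable ones and are
#' rejected; `direction = "max"` inverts this for completeness.
#'
#' @param x a [motu_table()].
#' @param pcrs PCR metadata.
#' @param min_reads threshold; default from `marker` column via
#'   [marker_min_reads()].
#' @param direction "min" (reject below threshold, default) or "max".
#' @return list with filtered `table`, filtered `pcrs` and a `report`.
#' @export
reject_failed_pcrs <- function(x, pcrs, min_reads = NULL,
                               direction = c("min", "max")) {
  stopifnot(inherits(x, "motu_table"))
  direction <- match.arg(direction)
  pcrs <- validate_pcrs(x, pcrs)
  if (is.null(min_reads)) {
    if (is.null(pcrs$marker)) stop("min_reads not given and no marker column")
    min_reads <- marker_min_reads(pcrs$marker[1])
  }
  stopifnot(min_reads >= 0)
  tot <- colSums(x$counts)
  keep <- if (direction == "min") tot >= min_reads else tot <= min_reads
  if (!any(keep))
    stop("all ", length(keep), " PCRs rejected at threshold ", min_reads,
         " (max observed total: ", max(tot), ")")
  out <- subset_pcrs(x, keep)
  list(table = out,
       pcrs = pcrs[keep, , drop = FALSE],
       report = qc_report("failed_pcrs", x, out, pcrs_removed = sum(!keep),
                          details = pcrs$pcr_id[!keep]))
}

#' Replicate-outlier detection
#'
#' For each sample with at least two retained replicates, each replicate's
#' read profile is Hellinger-transformed and its Euclidean distance to the
#' unweighted barycenter of the sample's transformed replicates computed.
#' Distances are pooled across samples and outliers flagged above the Tukey
#' fence Q3 + k*IQR (or above a fixed quantile).
#'
#' @param x a [motu_table()].
#' @param pcrs PCR metadata (`sample_id`, `control_type`).
#' @param rule "tukey" (default) or "quantile".
#' @param k Tukey fence factor.
#' @param probs quantile used when `rule = "quantile"`.
#' @return data.frame with `pcr_id`, `sample_id`, `distance`, `flagged`.
#' @export
replicate_outliers <- function(x, pcrs, rule = c("tukey", "quantile"),
                               k = 1.5, probs = 0.95) {
  stopifnot(inherits(x, "motu_table"))
  rule <- match.arg(rule)
  pcrs <- validate_pcrs(x, pcrs)
  is_sample <- pcrs$control_type == "sample"
  H <- t(hellinger(t(x$counts[, is_sample, drop = FALSE])))
  ids <- pcrs$pcr_id[is_sample]
  samples <- pcrs$sample_id[is_sample]
  res <- lapply(unique(samples), function(s) {
    j <- which(samples == s)
    if (length(j) < 2) {
      warning("sample ", s, " has a single replicate; distance undefined")
      return(NULL)
    }
    bary <- rowMeans(H[, j, drop = FALSE])
    d <- sqrt(colSums((H[, j, drop = FALSE] - bary)^2))
    data.frame(pcr_id = ids[j], sample_id = s, distance = d,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(pcr_id = character(0), sample_id = character(0),
                      distance = numeric(0), flagged = logical(0)))
  fence <- if (rule == "tukey") {
    q <- stats::quantile(res$distance, c(0.25, 0.75), names = FALSE)
    q[2] + k * (q[2] - q[1])
  } else stats::quantile(res$distance, probs, names = FALSE)
  res$flagged <- res$distance > fence
  res
}

#' Aggregate retained replicates into a community matrix
#'
#' Per sample, the mean of the retained replicates' relative-frequency
#' vectors, re-normalized to sum to 1. Samples with no retained replicate
#' are dropped. Only sample PCRs (not controls) contribute.
#'
#' @param x a [motu_table()].
#' @param pcrs PCR metadata.
#' @param exclude PCR ids to exclude (e.g. flagged replicate outliers).
#' @return matrix samples x MOTUs of relative frequencies (rows sum to 1).
#' @export
aggregate_replicates <- function(x, pcrs, exclude = character(0)) {
  stopifnot(inherits(x, "motu_table"))
  if (nrow(x$counts) == 0) stop("empty MOTU table")
  pcrs <- validate_pcrs(x, pcrs)
  keep <- pcrs$control_type == "sample" & !(pcrs$pcr_id %in% exclude)
  rf <- pcr_rel_freq(x$counts[, keep, drop = FALSE])
  samples <- pcrs$sample_id[keep]
  M <- t(sapply(unique(samples), function(s) {
    rowMeans(rf[, samples == s, drop = FALSE])
  }))
  rs <- rowSums(M)
  M <- M[rs > 0, , drop = FALSE]
  M / rowSums(M)
}

#' Full QC filtering chain
#'
#' Applies the table-level filters in their canonical order: amplicon length
#' -> rarity -> target clade -> negative-control contaminants -> failed
#' PCRs -> replicate outliers. Returns the filtered table, the surviving PCR
#' metadata, the per-stage reports, the replicate-outlier distances and the
#' aggregated sample x MOTU community matrix.
#'
#' @param x a [motu_table()].
#' @param pcrs PCR metadata.
#' @param marker marker label (defaults from `pcrs$marker`).
#' @param clade target clade.
#' @param min_reads failed-PCR threshold (marker default when `NULL`).
#' @param fence Tukey fence factor for replicate outliers.
#' @param contaminant_metric passed to [remove_contaminants()].
#' @param drop_outliers exclude flagged replicates from aggregation.
#' @return list with `table`, `pcrs`, `community`, `outliers`, `reports`.
#' @export
qc_pipeline <- function(x, pcrs, marker = NULL, clade = "Chlorophyta",
                        min_reads = NULL, fence = 1.5,
                        contaminant_metric = "rel_freq",
                        drop_outliers = TRUE) {
  if (is.null(marker)) marker <- pcrs$marker[1]
  bounds <- marker_length_bounds(marker)
  reports <- list()
  s <- filter_length(x, bounds[1], bounds[2])
  reports$length <- s$report
  s2 <- filter_rare(s$table)
  reports$rare <- s2$report
  s3 <- restrict_clade(s2$table, clade)
  reports$clade <- s3$report
  s4 <- remove_contaminants(s3$table, pcrs, metric = contaminant_metric)
  reports$contaminants <- s4$report
  if (is.null(min_reads)) min_reads <- marker_min_reads(marker)
  s5 <- reject_failed_pcrs(s4$table, pcrs, min_reads)
  reports$failed_pcrs <- s5$report
  out <- replicate_outliers(s5$table, s5$pcrs, k = fence)
  community <- aggregate_replicates(
    s5$table, s5$pcrs,
    exclude = if (drop_outliers) out$pcr_id[out$flagged] else character(0))
  list(table = s5$table, pcrs = s5$pcrs, community = community,
       outliers = out, reports = reports)
}
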