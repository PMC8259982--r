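#' Genomic interval
#'
#' Light-weight container for a genomic interval. Positions are stored
#' 1-based as printed in clinical tables; intersection and length use
#' half-open `[start, end)` semantics, so the length of an interval is
#' `end - start` base pairs. This convention reproduces published terminal
#' deletion sizes exactly (e.g. 51244566 - 42740931 = 8503635 bp = 8.503635
#' Mb) and makes adjacent intervals (`[1,10)` and `[10,20)`) non-overlapping.
#'
#' @param chrom Chromosome label (scalar character).
#' @param start 1-based start position, `>= 1`.
#' @param end 1-based end position, `>= start`; exclusive under the
#'   half-open convention.
#' @return An object of class `ginterval` with fields `chrom`, `start`,
#'   `end`.
#' @examples
#' iv <- ginterval("chr22", 42740931, 51244566)
#' interval_length(iv)  # 8503635
#' @export
ginterval <- function(chrom, start, end) {
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    stop("ginterval() takes scalar chrom/start/end")
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end))
    stop("interval positions must be finite")
  if (start < 1)
    stop("invalid interval: start must be >= 1")
  if (end < start)
    stop(sprintf("invalid interval: end (%s) < start (%s)",
                 format(end, scientific = FALSE),
                 format(start, scientific = FALSE)))
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "ginterval")
}

#' @export
print.ginterval <- function(x, ...) {
  cat(sprintf("<ginterval> %s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              format(interval_length(x), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Coerce to a genomic interval
#'
#' Accepts a `ginterval`, or any list-like object (including a one-row
#' data frame) with `chrom`, `start` and `end` fields.
#'
#' @param x Object to coerce.
#' @return A `ginterval`.
#' @export
as_ginterval <- function(x) {
  if (inherits(x, "ginterval")) return(x)
  if (is.null(x$chrom) || is.null(x$start) || is.null(x$end))
    stop("cannot coerce to ginterval: need chrom, start, end")
  ginterval(x$chrom[[1L]], x$start[[1L]], x$end[[1L]])
}

.same_chrom <- function(a, b) {
  if (!identical(a$chrom, b$chrom))
    stop(sprintf("intervals on different chromosomes (%s vs %s)",
                 a$chrom, b$chrom))
  invisible(TRUE)
}

#' Interval length in base pairs
#'
#' @param iv A [ginterval()] (or coercible object).
#' @return Length in bp, `end - start`.
#' @export
interval_length <- function(iv) {
  iv <- as_ginterval(iv)
  iv$end - iv$start
}

#' Interval length rendered in megabases
#'
#' @param iv A [ginterval()] (or coercible object).
#' @return Character scalar, length in Mb with 6 decimals (e.g.
#'   `"8.503635"`).
#' @export
interval_length_mb <- function(iv) {
  sprintf("%.6f", interval_length(iv) / 1e6)
}

#' Do two intervals overlap?
#'
#' Half-open semantics: `[start, end)` point sets must intersect, so
#' adjacent intervals sharing an endpoint do not overlap and zero-length
#' intervals overlap nothing.
#'
#' @param a,b Intervals on the same chromosome.
#' @return Logical flag.
#' @export
overlaps <- function(a, b) {
  a <- as_ginterval(a); b <- as_ginterval(b)
  .same_chrom(a, b)
  max(a$start, b$start) < min(a$end, b$end)
}

#' Gap between two intervals
#'
#' @param a,b Intervals on the same chromosome.
#' @return 0 when the intervals overlap, otherwise the gap in bp between
#'   the nearest ends.
#' @export
interval_distance <- function(a, b) {
  a <- as_ginterval(a); b <- as_ginterval(b)
  .same_chrom(a, b)
  if (max(a$start, b$start) < min(a$end, b$end)) return(0)
  if (a$end <= b$start) b$start - a$end else a$start - b$end
}

#' Classify a gene relative to a deletion
#'
#' Reproduces the presence/absence and within-window logic of the candidate
#' status table: a gene fully contained in the deletion is `deleted`; a gene
#' overlapping a breakpoint is `partially_deleted`; a disjoint gene at most
#' `window` bp away is `within_window`; anything farther is `distal`.
#'
#' @param gene Gene interval (a [ginterval()] or an annotation row with
#'   `chrom`/`start`/`end`).
#' @param deletion Deletion interval (same forms accepted).
#' @param window Flanking window in bp; default 2 Mb.
#' @return One of `"deleted"`, `"partially_deleted"`, `"within_window"`,
#'   `"distal"`.
#' @export
classify_gene_vs_deletion <- function(gene, deletion, window = 2e6) {
  g <- as_ginterval(gene); d <- as_ginterval(deletion)
  .same_chrom(g, d)
  if (window < 0) stop("window must be non-negative")
  if (g$start >= d$start && g$end <= d$end) return("deleted")
  if (max(g$start, d$start) < min(g$end, d$end)) return("partially_deleted")
  if (interval_distance(g, d) <= window) return("within_window")
  "distal"
}

#' Vectorised gene-vs-deletion classification
#'
#' [classify_gene_vs_deletion()] applied to every row of an annotation
#' table; used by the prediction and qPCR pipelines.
#'
#' @param annotation Gene annotation data frame.
#' @param deletion One deletion.
#' @param window Flanking window in bp.
#' @return Character vector of statuses, one per annotation row.
#' @export
classify_genes <- function(annotation, deletion, window = 2e6) {
  d <- as_ginterval(deletion)
  if (nrow(annotation) == 0L) return(character(0))
  if (any(annotation$chrom != d$chrom))
    stop("annotation and deletion must share a chromosome")
  gs <- annotation$start; ge <- annotation$end
  status <- rep("distal", nrow(annotation))
  inside <- gs >= d$start & ge <= d$end
  overl <- pmax(gs, d$start) < pmin(ge, d$end)
  gap <- ifelse(ge <= d$start, d$start - ge, gs - d$end)
  status[!inside & !overl & gap <= window] <- "within_window"
  status[overl & !inside] <- "partially_deleted"
  status[inside] <- "deleted"
  status
}

#' Build a deletion table
#'
#' @param patient_id Patient labels.
#' @param chrom Chromosome labels (recycled).
#' @param start,end Breakpoints, 1-based; `end` exclusive.
#' @param terminal Logical; `TRUE` for terminal deletions (no annotated
#'   genes distal of `end`). Recycled.
#' @return A data frame with one row per deletion and a `size_class`
#'   column initialised to `NA` (see [assign_size_class()]).
#' @export
deletion_table <- function(patient_id, chrom, start, end, terminal = TRUE) {
  n <- length(patient_id)
  df <- data.frame(patient_id = as.character(patient_id),
                   chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start), end = as.numeric(end),
                   terminal = rep_len(as.logical(terminal), n),
                   size_class = NA_character_,
                   stringsAsFactors = FALSE)
  bad <- df$end < df$start | df$start < 1
  if (any(bad))
    stop("invalid deletion interval(s) for: ",
         paste(df$patient_id[bad], collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicated patient_id in deletion table")
  df
}

#' Assign deletion size classes
#'
#' The grouping of deletions into Small/Mid/Large is an arbitrary
#' stratification, so the cutoffs are fully configurable. A deletion is
#' `Small` when its length is below the lower cutoff, `Large` when its
#' length is at or above the upper cutoff (inclusive), `Mid` otherwise.
#' Defaults (5 Mb, 8 Mb) reproduce the published labels for the five
#' validation deletions.
#'
#' @param deletions Deletion table (see [deletion_table()]).
#' @param cutoffs Two strictly increasing bp thresholds.
#' @return The deletion table with `size_class` filled in.
#' @export
assign_size_class <- function(deletions, cutoffs = c(5e6, 8e6)) {
  if (length(cutoffs) != 2L || !all(is.finite(cutoffs)) ||
      cutoffs[1] >= cutoffs[2])
    stop("cutoffs must be two strictly increasing thresholds")
  len <- deletions$end - deletions$start
  deletions$size_class <- ifelse(len < cutoffs[1], "Small",
                          ifelse(len >= cutoffs[2], "Large", "Mid"))
  deletions
}

#' Validate a TAD map
#'
#' TADs must be sorted by start and non-overlapping (half-open semantics:
#' contiguous domains sharing a boundary are allowed).
#'
#' @param tads Data frame with `chrom`, `start`, `end` columns.
#' @return The validated TAD table (invisibly unchanged).
#' @export
validate_tad_map <- function(tads) {
  .assert_cols(tads, c("chrom", "start", "end"), "TAD map")
  if (nrow(tads) > 1L) {
    for (ch in unique(tads$chrom)) {
      t <- tads[tads$chrom == ch, , drop = FALSE]
      if (is.unsorted(t$start))
        stop("TAD map not sorted by start on ", ch)
      if (any(t$start[-1L] < t$end[-nrow(t)]))
        stop("overlapping TADs on ", ch)
    }
  }
  if (any(tads$end < tads$start)) stop("TAD with end < start")
  invisible(tads)
}
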