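#' Delta-Ct normalisation
#'
#' Normalises a target gene's cycle threshold to the housekeeping gene
#' measured in the same sample: `dCt = Ct_gene - Ct_housekeeping`.
#'
#' @param ct_gene Target-gene Ct (cycles).
#' @param ct_housekeeping Housekeeping-gene Ct (cycles).
#' @return Delta-Ct (cycles). Vectorised.
#' @export
delta_ct <- function(ct_gene, ct_housekeeping) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_housekeeping)))
    stop("Ct values must be finite")
  ct_gene - ct_housekeeping
}

#' Relative expression (2^-ddCt)
#'
#' `fold = 2^-(dCt_sample - dCt_control)`: the relative quantity of a
#' target transcript in a sample, normalised to the housekeeping gene and
#' referenced to the control.
#'
#' @param delta_ct_sample Sample delta-Ct.
#' @param delta_ct_control Control delta-Ct.
#' @return Positive fold change. Vectorised.
#' @export
fold_change <- function(delta_ct_sample, delta_ct_control) {
  2^(-(delta_ct_sample - delta_ct_control))
}

#' Classify a relative expression level
#'
#' Thresholds are inclusive as printed: folds `>= elevated` (default 1.5)
#' are `elevated`, folds `<= decreased` (default 0.66) are `decreased`,
#' anything between is `normal`.
#'
#' @param fold Positive fold change(s).
#' @param elevated Elevated threshold (default 1.5).
#' @param decreased Decreased threshold (default 0.66).
#' @return Character vector of categories.
#' @export
classify_expression <- function(fold, elevated = 1.5, decreased = 0.66) {
  if (any(!is.finite(fold) | fold <= 0))
    stop("fold changes must be positive and finite")
  ifelse(fold >= elevated, "elevated",
         ifelse(fold <= decreased, "decreased", "normal"))
}

#' Status-stratified expression summary
#'
#' Mirrors the published summary table: for each gene, the arithmetic mean
#' fold change over samples in which the gene was (i) not deleted, (ii)
#' deleted (including breakpoint-overlapping genes) and (iii) within the
#' flanking window of the deletion. The within-window group is a subset of
#' the not-deleted group. Empty groups are reported as `NA`.
#'
#' @param folds Data frame with `sample_id`, `gene`, `fold`.
#' @param statuses Data frame with `sample_id`, `gene`, `status` (values
#'   from [classify_gene_vs_deletion()], or `"unknown"`).
#' @return Per-gene data frame with `mean_not_deleted`, `mean_deleted`,
#'   `mean_within_window` and group sizes.
#' @export
summarize_by_status <- function(folds, statuses) {
  .assert_cols(folds, c("sample_id", "gene", "fold"), "fold table")
  .assert_cols(statuses, c("sample_id", "gene", "status"), "status table")
  m <- merge(folds, statuses, by = c("sample_id", "gene"), all.x = TRUE)
  m$status[is.na(m$status)] <- "unknown"
  m <- m[m$status != "unknown", , drop = FALSE]
  genes <- unique(m$gene)
  grp_mean <- function(g, sel) {
    v <- m$fold[m$gene == g & sel]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  del <- m$status %in% c("deleted", "partially_deleted")
  win <- m$status == "within_window"
  data.frame(gene = genes,
             mean_not_deleted = vapply(genes, grp_mean, numeric(1),
                                       sel = !del),
             mean_deleted = vapply(genes, grp_mean, numeric(1), sel = del),
             mean_within_window = vapply(genes, grp_mean, numeric(1),
                                         sel = win),
             n_not_deleted = vapply(genes, function(g)
               sum(m$gene == g & !del), integer(1)),
             n_deleted = vapply(genes, function(g)
               sum(m$gene == g & del), integer(1)),
             n_within_window = vapply(genes, function(g)
               sum(m$gene == g & win), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full qPCR relative-expression pipeline
#'
#' Replicates are averaged on the Ct scale within sample x gene (the
#' alternative, averaging per-replicate fold changes, is available via
#' `replicate_average = "fold"`). Each sample's delta-Ct is referenced to
#' the mean delta-Ct of the pooled control samples. Genes annotated as not
#' expressed in blood are excluded. Gene-vs-deletion statuses come from
#' [classify_gene_vs_deletion()]; samples without a deletion record (e.g.
#' the controls themselves) and genes absent from the annotation get
#' status `"unknown"` and are excluded from the status-stratified summary
#' but kept in the per-record output.
#'
#' @param ct Long-format Ct table (`sample_id`, `gene`, `replicate`, `ct`).
#' @param control_ids Sample ids of the control individuals (>= 1).
#' @param deletions Deletion table (may omit samples).
#' @param annotation Gene annotation.
#' @param housekeeping Housekeeping gene symbol (default `"TBP"`).
#' @param window Flanking window for status calls (default 2 Mb).
#' @param elevated,decreased Classification thresholds (default 1.5 / 0.66).
#' @param replicate_average `"ct"` (default) or `"fold"`.
#' @return List with `records` (per sample x gene fold changes and
#'   categories), `summary` (see [summarize_by_status()]), `matrix`
#'   (genes x samples fold-change matrix; gene rows ordered by coordinate,
#'   patient columns by deletion size descending) and `statuses`.
#' @export
run_qpcr_pipeline <- function(ct, control_ids, deletions, annotation,
                              housekeeping = "TBP", window = 2e6,
                              elevated = 1.5, decreased = 0.66,
                              replicate_average = c("ct", "fold")) {
  replicate_average <- match.arg(replicate_average)
  .assert_cols(ct, c("sample_id", "gene", "replicate", "ct"), "Ct table")
  if (length(control_ids) < 1L) stop("need at least one control sample")
  if (any(!is.finite(ct$ct) | ct$ct <= 0))
    stop("Ct values must be finite and positive")
  missing_ctrl <- setdiff(control_ids, ct$sample_id)
  if (length(missing_ctrl))
    stop("control sample(s) absent from Ct table: ",
         paste(missing_ctrl, collapse = ", "))

  no_blood <- annotation$symbol[!(annotation$expressed_in_blood %||%
                                    rep(TRUE, nrow(annotation)))]
  ct <- ct[!ct$gene %in% no_blood, , drop = FALSE]

  samples <- unique(ct$sample_id)
  hk_missing <- samples[!vapply(samples, function(s)
    any(ct$sample_id == s & ct$gene == housekeeping), logical(1))]
  if (length(hk_missing))
    stop("housekeeping gene ", housekeeping,
         " missing for sample(s): ", paste(hk_missing, collapse = ", "))

  # mean Ct per sample x gene (replicates collapse on the Ct scale)
  ag <- stats::aggregate(ct ~ sample_id + gene, data = ct, FUN = mean)
  hk <- ag[ag$gene == housekeeping, c("sample_id", "ct")]
  names(hk)[2L] <- "ct_hk"
  ag <- merge(ag[ag$gene != housekeeping, , drop = FALSE], hk,
              by = "sample_id")
  ag$dct <- delta_ct(ag$ct, ag$ct_hk)

  ctrl <- ag[ag$sample_id %in% control_ids, , drop = FALSE]
  ctrl_dct <- stats::aggregate(dct ~ gene, data = ctrl, FUN = mean)
  names(ctrl_dct)[2L] <- "dct_control"
  rec <- merge(ag, ctrl_dct, by = "gene")
  rec$delta_delta_ct <- rec$dct - rec$dct_control
  rec$fold <- fold_change(rec$dct, rec$dct_control)

  if (replicate_average == "fold") {
    # per-replicate folds, then averaged on the fold scale
    hk_rep <- ct[ct$gene == housekeeping,
                 c("sample_id", "replicate", "ct")]
    names(hk_rep)[3L] <- "ct_hk"
    rep_tab <- merge(ct[ct$gene != housekeeping, , drop = FALSE], hk_rep,
                     by = c("sample_id", "replicate"))
    rep_tab$dct <- delta_ct(rep_tab$ct, rep_tab$ct_hk)
    rep_tab <- merge(rep_tab, ctrl_dct, by = "gene")
    rep_tab$fold <- fold_change(rep_tab$dct, rep_tab$dct_control)
    fold_avg <- stats::aggregate(fold ~ sample_id + gene, data = rep_tab,
                                 FUN = mean)
    rec$fold <- fold_avg$fold[match(paste(rec$sample_id, rec$gene),
                                    paste(fold_avg$sample_id,
                                          fold_avg$gene))]
    rec$delta_delta_ct <- -log2(rec$fold)
  }
  rec$category <- classify_expression(rec$fold, elevated, decreased)

  # statuses: per patient sample x gene from the genome model
  status_rows <- list()
  for (s in samples) {
    drow <- deletions[deletions$patient_id == s, , drop = FALSE]
    for (g in setdiff(unique(ct$gene), housekeeping)) {
      arow <- annotation[annotation$symbol == g, , drop = FALSE]
      st <- if (nrow(drow) == 1L && nrow(arow) == 1L)
        classify_gene_vs_deletion(arow, drow, window) else "unknown"
      status_rows[[length(status_rows) + 1L]] <-
        data.frame(sample_id = s, gene = g, status = st,
                   stringsAsFactors = FALSE)
    }
  }
  statuses <- do.call(rbind, status_rows)

  records <- merge(rec[, c("sample_id", "gene", "dct", "delta_delta_ct",
                           "fold", "category")],
                   statuses, by = c("sample_id", "gene"))
  names(records)[names(records) == "dct"] <- "delta_ct"
  records <- records[order(records$gene, records$sample_id), , drop = FALSE]
  rownames(records) <- NULL

  summ <- summarize_by_status(records[, c("sample_id", "gene", "fold")],
                              statuses)

  # matrix export: gene rows by coordinate, patient columns by deletion
  # size descending (heat-map order)
  pat <- intersect(deletions$patient_id, samples)
  dsub <- deletions[deletions$patient_id %in% pat, , drop = FALSE]
  pat <- dsub$patient_id[order(dsub$end - dsub$start, decreasing = TRUE)]
  gset <- intersect(annotation$symbol[order(annotation$start)],
                    unique(records$gene))
  mat <- matrix(NA_real_, nrow = length(gset), ncol = length(pat),
                dimnames = list(gset, pat))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$gene %in% gset && r$sample_id %in% pat)
      mat[r$gene, r$sample_id] <- r$fold
  }

  list(records = records, summary = summ, matrix = mat, statuses = statuses)
}
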