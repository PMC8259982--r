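#' Flanking windows around a deletion
#'
#' Windows extend up to `window` bp on either side of the deletion
#' breakpoints: a proximal window `[start - window, start]` (clipped at
#' position 1) and, for interstitial deletions only, a distal window
#' `[end, end + window]`. Terminal deletions have no distal flank.
#'
#' @param deletion One deletion (row of a deletion table, or list with
#'   `chrom`, `start`, `end`, `terminal`).
#' @param window Window size in bp (default 2 Mb).
#' @return Data frame with columns `chrom`, `start`, `end`, `side`
#'   (one or two rows).
#' @export
flanking_windows <- function(deletion, window = 2e6) {
  d <- as_ginterval(deletion)
  terminal <- isTRUE(as.logical(deletion$terminal[[1L]] %||% FALSE))
  out <- data.frame(chrom = d$chrom,
                    start = max(1, d$start - window),
                    end = d$start,
                    side = "proximal",
                    stringsAsFactors = FALSE)
  if (!terminal) {
    out <- rbind(out, data.frame(chrom = d$chrom, start = d$end,
                                 end = d$end + window, side = "distal",
                                 stringsAsFactors = FALSE))
  }
  out
}

#' TADs disrupted by a deletion
#'
#' A TAD is disrupted when a deletion breakpoint falls strictly inside it.
#' A breakpoint sitting exactly on a TAD edge disrupts nothing: TADs are
#' half-open like every interval here, and a boundary position belongs to
#' the boundary, not the domain interior.
#'
#' @param deletion One deletion.
#' @param tads TAD map data frame (`chrom`, `start`, `end`).
#' @return The subset of TAD rows containing a breakpoint in their
#'   interior.
#' @export
tads_disrupted <- function(deletion, tads) {
  validate_tad_map(tads)
  d <- as_ginterval(deletion)
  t <- tads[tads$chrom == d$chrom, , drop = FALSE]
  if (nrow(t) == 0L) return(t)
  hit <- (t$start < d$start & d$start < t$end) |
         (t$start < d$end & d$end < t$end)
  t[hit, , drop = FALSE]
}

#' Count a gene's regulatory contacts disrupted by a deletion
#'
#' Counts contacts of the given gene whose regulatory element overlaps the
#' deletion. Contacts are only position-effect evidence for genes that are
#' not themselves deleted; callers should not pass deleted genes.
#'
#' @param gene_symbol Gene symbol.
#' @param deletion One deletion.
#' @param contacts Contact data frame (`gene_symbol`, `chrom`, `start`,
#'   `end`).
#' @return Non-negative integer count.
#' @export
disrupted_contacts <- function(gene_symbol, deletion, contacts) {
  d <- as_ginterval(deletion)
  cc <- contacts[contacts$gene_symbol == gene_symbol &
                 contacts$chrom == d$chrom, , drop = FALSE]
  if (nrow(cc) == 0L) return(0L)
  sum(cc$start < d$end & d$start < cc$end)
}

#' Phenotypic overlap between a patient and a gene
#'
#' Jaccard index of the two term sets, `|A ∩ B| / |A ∪ B|`. A gene with an
#' empty term set scores 0. The patient term set must be non-empty.
#'
#' @param patient_terms Character vector of patient term identifiers.
#' @param gene_terms Character vector of gene term identifiers.
#' @return Score in \[0, 1\].
#' @export
phenotype_overlap <- function(patient_terms, gene_terms) {
  patient_terms <- unique(patient_terms[nzchar(patient_terms)])
  gene_terms <- unique(gene_terms[nzchar(gene_terms)])
  if (length(patient_terms) == 0L)
    stop("patient term set must be non-empty")
  if (length(gene_terms) == 0L) return(0)
  length(intersect(patient_terms, gene_terms)) /
    length(union(patient_terms, gene_terms))
}

#' Percentile ranks of a score vector
#'
#' Percentile of each score is `100 * (# scores strictly below) / (n - 1)`
#' for `n > 1`; a single score gets percentile 100. Tied scores share a
#' percentile.
#'
#' @param scores Non-empty numeric vector.
#' @return Numeric vector of percentiles in \[0, 100\].
#' @export
percentile_rank <- function(scores) {
  n <- length(scores)
  if (n == 0L) stop("percentile_rank() needs a non-empty vector")
  if (n == 1L) return(100)
  vapply(scores, function(s) 100 * sum(scores < s) / (n - 1), numeric(1))
}

#' Ranking parameters for candidate prediction
#'
#' The published criteria (contact disruption, 2 Mb/TAD windows, HI
#' <= 10%, phenotype overlap above the 75th percentile) are combined into
#' an explicit additive score for reproducibility:
#' `w_contacts * min(contacts, cap)/cap + w_tad * [in disrupted TAD] +
#'  w_window * [within window] + w_hi * [HI flag] +
#'  w_phenotype * [percentile > gate]`.
#'
#' @param window Flanking window in bp (default 2 Mb).
#' @param weights Named numeric vector of the five weights
#'   (`contacts`, `tad`, `window`, `hi`, `phenotype`), default all 1.
#' @param contact_cap Contact count saturating the contact term (default 5).
#' @param hi_cutoff HI percentage at or below which the HI flag is set
#'   (default 10). Missing HI never sets the flag.
#' @param percentile_gate Phenotype-overlap percentile that must be
#'   exceeded (default 75).
#' @param tad_window_rule `"and"` (default): a position-effect candidate
#'   must be within the window AND have TAD or contact evidence. `"or"`:
#'   within-window or in-disrupted-TAD suffices as location evidence,
#'   still requiring TAD or contact evidence.
#' @return List of parameters (class `pe_params`).
#' @export
pe_params <- function(window = 2e6,
                      weights = c(contacts = 1, tad = 1, window = 1,
                                  hi = 1, phenotype = 1),
                      contact_cap = 5, hi_cutoff = 10,
                      percentile_gate = 75,
                      tad_window_rule = c("and", "or")) {
  if (length(weights) != 5L) stop("weights must have five entries")
  if (is.null(names(weights)) || !all(nzchar(names(weights))))
    names(weights) <- c("contacts", "tad", "window", "hi", "phenotype")
  if (contact_cap < 1) stop("contact_cap must be >= 1")
  structure(list(window = window, weights = weights,
                 contact_cap = contact_cap, hi_cutoff = hi_cutoff,
                 percentile_gate = percentile_gate,
                 tad_window_rule = match.arg(tad_window_rule)),
            class = "pe_params")
}

#' Predict candidate dysregulated genes for one deletion
#'
#' Every gene that is deleted, breakpoint-overlapping, or within the
#' flanking window receives a feature row. Candidate classes:
#' * `by_deletion` — gene deleted or partially deleted AND phenotypically
#'   relevant (HI flag, or phenotype percentile above the gate);
#' * `by_position_effect` — gene preserved, within the window, and either
#'   lying in a disrupted TAD or having at least one disrupted regulatory
#'   contact (see `tad_window_rule` in [pe_params()]);
#' * `none` otherwise.
#'
#' Rows are sorted by `rank_score` descending, ties broken by distance to
#' the nearest breakpoint (ascending) then symbol, so ranked output is
#' reproducible.
#'
#' @param deletion One deletion (row of a deletion table).
#' @param annotation Gene annotation data frame.
#' @param tads TAD map data frame.
#' @param contacts Contact data frame (may have zero rows).
#' @param patient_terms Character vector of the patient's phenotype terms.
#' @param params A [pe_params()] object.
#' @return Data frame of candidate features, one row per non-distal gene.
#' @export
predict_candidates <- function(deletion, annotation, tads, contacts,
                               patient_terms, params = pe_params()) {
  validate_annotation(annotation)
  empty <- data.frame(patient_id = character(0), gene = character(0),
                      status = character(0), in_disrupted_tad = logical(0),
                      disrupted_contacts = integer(0), hi_score = numeric(0),
                      phenotype_overlap = numeric(0),
                      phenotype_percentile = numeric(0),
                      rank_score = numeric(0), candidate_class = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(annotation) == 0L) return(empty)

  unknown <- setdiff(unique(contacts$gene_symbol), annotation$symbol)
  if (length(unknown)) {
    warning("skipping contacts for unknown gene symbol(s): ",
            paste(unknown, collapse = ", "))
    contacts <- contacts[!contacts$gene_symbol %in% unknown, , drop = FALSE]
  }

  status <- classify_genes(annotation, deletion, params$window)
  keep <- status != "distal"
  if (!any(keep)) return(empty)
  ann <- annotation[keep, , drop = FALSE]
  status <- status[keep]

  dis_tads <- tads_disrupted(deletion, tads)
  in_tad <- vapply(seq_len(nrow(ann)), function(i) {
    if (nrow(dis_tads) == 0L) return(FALSE)
    any(dis_tads$chrom == ann$chrom[i] &
        ann$start[i] < dis_tads$end & dis_tads$start < ann$end[i])
  }, logical(1))

  deleted <- status %in% c("deleted", "partially_deleted")
  n_contacts <- integer(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    if (!deleted[i])
      n_contacts[i] <- disrupted_contacts(ann$symbol[i], deletion, contacts)
  }

  hi <- ann$hi_pct %||% rep(NA_real_, nrow(ann))
  hi_flag <- !is.na(hi) & hi <= params$hi_cutoff
  terms <- split_terms(ann$phenotype_terms %||% rep("", nrow(ann)))
  ph <- vapply(terms, function(t) phenotype_overlap(patient_terms, t),
               numeric(1))
  pct <- percentile_rank(ph)
  ph_gate <- pct > params$percentile_gate

  in_window <- status == "within_window"
  location_ok <- if (params$tad_window_rule == "and") in_window
                 else (in_window | in_tad)
  cls <- rep("none", nrow(ann))
  cls[deleted & (hi_flag | ph_gate)] <- "by_deletion"
  cls[!deleted & location_ok & (in_tad | n_contacts > 0L)] <-
    "by_position_effect"

  w <- params$weights
  score <- w[["contacts"]] * pmin(n_contacts, params$contact_cap) /
             params$contact_cap +
           w[["tad"]] * in_tad + w[["window"]] * in_window +
           w[["hi"]] * hi_flag + w[["phenotype"]] * ph_gate

  d <- as_ginterval(deletion)
  bp_dist <- vapply(seq_len(nrow(ann)), function(i) {
    min(vapply(c(d$start, d$end), function(p)
      max(0, ann$start[i] - p, p - ann$end[i]), numeric(1)))
  }, numeric(1))

  out <- data.frame(patient_id = deletion$patient_id[[1L]] %||% NA_character_,
                    gene = ann$symbol, status = status,
                    in_disrupted_tad = in_tad,
                    disrupted_contacts = n_contacts, hi_score = hi,
                    phenotype_overlap = ph, phenotype_percentile = pct,
                    rank_score = as.numeric(score), candidate_class = cls,
                    stringsAsFactors = FALSE)
  out[order(-out$rank_score, bp_dist, out$gene), , drop = FALSE]
}

#' Aggregate candidate calls across a cohort
#'
#' @param per_patient_candidates List of [predict_candidates()] outputs,
#'   one per patient.
#' @return Per-gene detection table: number of patients in which the gene
#'   is a candidate, split by candidate class.
#' @export
aggregate_cohort <- function(per_patient_candidates) {
  if (length(per_patient_candidates) == 0L)
    stop("aggregate_cohort() needs at least one patient")
  all <- do.call(rbind, per_patient_candidates)
  genes <- sort(unique(all$gene))
  count_cls <- function(g, cls)
    sum(all$gene == g & all$candidate_class == cls)
  data.frame(gene = genes,
             n_by_deletion = vapply(genes, count_cls, integer(1),
                                    cls = "by_deletion"),
             n_by_position_effect = vapply(genes, count_cls, integer(1),
                                           cls = "by_position_effect"),
             n_candidate = vapply(genes, function(g)
               sum(all$gene == g & all$candidate_class != "none"),
               integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
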