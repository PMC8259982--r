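#' @name tadpose-synthetic
#' @title Seeded synthetic-data generators
#'
#' @description
#' Generators that emulate every input the pipeline consumes — a gene /
#' TAD / contact landscape over a synthetic chromosome arm, cohorts of
#' (mostly terminal) deletions, qPCR Ct tables with known fold changes and
#' Biolog plate data with known per-well effects — so that every stage is
#' testable without external downloads. Each generator is a pure function
#' of its parameters and seed, and every dataset carries its ground truth.
NULL

#' Ground-truth container for synthetic datasets
#'
#' @param seed Seed the dataset was generated from.
#' @param planted_position_effect_genes Genes planted as position-effect
#'   dysregulated.
#' @param planted_deletion_genes Genes dysregulated by deletion.
#' @param true_fold_changes Named numeric vector, gene -> true fold.
#' @param true_well_effects Named list, plate -> named numeric vector of
#'   per-well amplitude shifts in control-SD units.
#' @param compensated_genes Genes whose remaining allele compensates
#'   (elevated fold regardless of deletion status).
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(seed = NA_integer_,
                            planted_position_effect_genes = character(0),
                            planted_deletion_genes = character(0),
                            true_fold_changes = numeric(0),
                            true_well_effects = list(),
                            compensated_genes = character(0)) {
  structure(list(seed = seed,
                 planted_position_effect_genes =
                   planted_position_effect_genes,
                 planted_deletion_genes = planted_deletion_genes,
                 true_fold_changes = true_fold_changes,
                 true_well_effects = true_well_effects,
                 compensated_genes = compensated_genes),
            class = "synthetic_truth")
}

#' Generate a synthetic gene/TAD/contact landscape
#'
#' Emulates a distal chromosome-arm locus: non-overlapping genes sorted by
#' start, haploinsufficiency percentages with a configurable low-HI
#' fraction, phenotype terms drawn from a fixed vocabulary, TADs
#' partitioning a prefix of the chromosome, and regulatory contacts
#' linking genes to elements at most 2 Mb away.
#'
#' @param n_genes Number of genes (>= 1).
#' @param chrom_length Chromosome length in bp.
#' @param tad_count Number of TADs.
#' @param contact_rate Mean number of contacts per gene (Poisson).
#' @param hi_low_fraction Fraction of genes with HI <= 10.
#' @param hi_missing_fraction Fraction of genes with missing HI.
#' @param blood_fraction Fraction of genes expressed in blood.
#' @param vocab_size Size of the phenotype-term vocabulary.
#' @param chrom Chromosome label.
#' @param seed RNG seed.
#' @return List with `annotation`, `tads`, `contacts`, `vocab`, `seed`.
#' @export
gen_locus <- function(n_genes = 50, chrom_length = 52e6, tad_count = 20,
                      contact_rate = 2, hi_low_fraction = 0.15,
                      hi_missing_fraction = 0.1, blood_fraction = 0.85,
                      vocab_size = 40, chrom = "chrS", seed = 1) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(seed)
  lens <- round(stats::runif(n_genes, 5e3, 1e5))
  free <- chrom_length - 1 - sum(lens)
  if (free <= n_genes)
    stop("infeasible packing: genes do not fit on the chromosome")
  gp <- stats::runif(n_genes + 1)
  gaps <- floor(gp / sum(gp) * free)
  starts <- 1 + cumsum(gaps[seq_len(n_genes)]) +
    c(0, cumsum(lens[-n_genes]))
  ends <- starts + lens

  hi <- stats::runif(n_genes, 10, 100)
  n_low <- round(hi_low_fraction * n_genes)
  if (n_low > 0) hi[sample.int(n_genes, n_low)] <- stats::runif(n_low, 0, 10)
  n_miss <- round(hi_missing_fraction * n_genes)
  if (n_miss > 0) hi[sample.int(n_genes, n_miss)] <- NA_real_

  vocab <- sprintf("T%02d", seq_len(vocab_size))
  terms <- vapply(seq_len(n_genes), function(i) {
    k <- stats::rpois(1, 3)
    paste(sample(vocab, min(k, vocab_size)), collapse = ";")
  }, character(1))

  annotation <- data.frame(
    symbol = sprintf("G%03d", seq_len(n_genes)), chrom = chrom,
    start = starts, end = ends, hi_pct = hi, phenotype_terms = terms,
    expressed_in_blood = stats::runif(n_genes) < blood_fraction,
    stringsAsFactors = FALSE)

  # TADs partition a prefix of the chromosome into contiguous domains
  prefix_end <- round(chrom_length * 0.98)
  bounds <- sort(sample(seq(2e5, prefix_end - 2e5, by = 1e4),
                        max(tad_count - 1L, 0L)))
  tstarts <- c(1, bounds)
  tends <- c(bounds, prefix_end)
  tads <- data.frame(chrom = chrom, start = tstarts, end = tends,
                     name = sprintf("tad%02d", seq_along(tstarts)),
                     stringsAsFactors = FALSE)
  validate_tad_map(tads)

  contact_rows <- list()
  for (i in seq_len(n_genes)) {
    k <- stats::rpois(1, contact_rate)
    if (k == 0) next
    off <- stats::runif(k, -2e6, 2e6)
    es <- pmax(1, round(starts[i] + off))
    ee <- es + round(stats::runif(k, 2e3, 1e4))
    contact_rows[[length(contact_rows) + 1L]] <-
      data.frame(gene_symbol = annotation$symbol[i], chrom = chrom,
                 start = es, end = ee, stringsAsFactors = FALSE)
  }
  contacts <- if (length(contact_rows)) do.call(rbind, contact_rows)
    else data.frame(gene_symbol = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    stringsAsFactors = FALSE)

  list(annotation = validate_annotation(annotation), tads = tads,
       contacts = contacts, vocab = vocab, seed = seed)
}

#' Generate a synthetic deletion cohort
#'
#' Terminal deletions share the chromosome end; sizes are drawn uniformly
#' from `size_range` (default spanning 0.1-8.5 Mb, the published span of
#' validation deletions).
#'
#' @param n_patients Number of patients (>= 1).
#' @param size_range Deletion size range in bp.
#' @param terminal_fraction Fraction of terminal deletions (default 1).
#' @param chrom Chromosome label.
#' @param chrom_end Chromosome end position.
#' @param seed RNG seed.
#' @return Deletion table (see [deletion_table()]).
#' @export
gen_cohort <- function(n_patients = 5, size_range = c(0.1e6, 8.5e6),
                       terminal_fraction = 1, chrom = "chrS",
                       chrom_end = 52e6, seed = 1) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  set.seed(seed)
  sizes <- round(stats::runif(n_patients, size_range[1], size_range[2]))
  terminal <- stats::runif(n_patients) < terminal_fraction
  end <- ifelse(terminal, chrom_end,
                chrom_end - round(stats::runif(n_patients, 5e5, 5e6)))
  start <- pmax(1, end - sizes)
  deletion_table(sprintf("S%02d", seq_len(n_patients)), chrom, start, end,
                 terminal)
}

#' Plant position-effect genes into a synthetic locus
#'
#' Selects preserved genes within the flanking window of the deletion
#' (preferring genes inside a TAD disrupted by a breakpoint), gives each
#' of them `n_contacts` regulatory contacts whose elements lie inside the
#' deletion, assigns them true fold changes, and aligns their phenotype
#' terms with the patient's so that the planted signal carries the
#' phenotypic relevance a real position-effect gene would.
#'
#' @param locus A [gen_locus()] result.
#' @param deletion One deletion row.
#' @param patient_terms The patient's phenotype terms.
#' @param n Maximum number of genes to plant.
#' @param n_contacts Contacts added per planted gene.
#' @param fold_options True fold changes sampled for planted genes.
#' @param window Flanking window (default 2 Mb).
#' @param seed RNG seed.
#' @return List with updated `locus` (augmented contacts, adjusted
#'   phenotype terms) and `truth` (a [synthetic_truth()]).
#' @export
plant_position_effects <- function(locus, deletion, patient_terms,
                                   n = 3, n_contacts = 5,
                                   fold_options = c(0.55, 1.8),
                                   window = 2e6, seed = 1) {
  set.seed(seed)
  ann <- locus$annotation
  status <- classify_genes(ann, deletion, window)
  eligible <- which(status == "within_window")
  dis <- tads_disrupted(deletion, locus$tads)
  if (nrow(dis)) {
    in_dis <- vapply(eligible, function(i)
      any(ann$start[i] < dis$end & dis$start < ann$end[i]), logical(1))
    eligible <- c(eligible[in_dis], eligible[!in_dis])
  }
  planted <- utils::head(eligible, n)
  truth <- synthetic_truth(seed = seed)
  d <- as_ginterval(deletion)
  for (i in planted) {
    es <- round(stats::runif(n_contacts, d$start,
                             max(d$start + 1, d$end - 1e4)))
    locus$contacts <- rbind(locus$contacts,
      data.frame(gene_symbol = ann$symbol[i], chrom = ann$chrom[i],
                 start = es, end = es + 5e3, stringsAsFactors = FALSE))
    # planted genes share most of the patient's clinical terms
    keep <- sample(patient_terms,
                   max(1L, round(0.8 * length(patient_terms))))
    locus$annotation$phenotype_terms[i] <- paste(keep, collapse = ";")
    truth$true_fold_changes[ann$symbol[i]] <-
      sample(fold_options, 1)
  }
  truth$planted_position_effect_genes <- ann$symbol[planted]
  truth$planted_deletion_genes <-
    ann$symbol[status %in% c("deleted", "partially_deleted")]
  list(locus = locus, truth = truth)
}

#' Generate a synthetic qPCR Ct table
#'
#' The measurement model is `Ct = baseline_gene - log2(expression) +
#' N(0, noise_sd)` per replicate. Control samples sit at expression 1 for
#' every gene; deleted genes in patients drop to `deleted_fold` (one lost
#' allele, no compensation, default 0.5); planted position-effect genes
#' take their true fold change where they are within the window of the
#' patient's deletion; genes in `truth$compensated_genes` take
#' `compensated_fold` in every patient regardless of status (the pattern
#' of an enzyme up-regulating its remaining allele). The housekeeping gene
#' is constant across samples up to noise.
#'
#' @param annotation Gene annotation (blood-silent genes are skipped).
#' @param deletions Deletion table (patients to simulate).
#' @param truth Optional [synthetic_truth()].
#' @param noise_sd Ct noise standard deviation in cycles (default 0.2).
#' @param n_replicates Replicates per sample x gene (default 2).
#' @param control_ids Control sample ids (default `C1`, `C2`).
#' @param housekeeping Housekeeping gene symbol (default `"TBP"`).
#' @param deleted_fold Expression of deleted genes relative to control.
#' @param compensated_fold Expression of compensated genes.
#' @param window Window for status calls (default 2 Mb).
#' @param seed RNG seed.
#' @return Long-format Ct data frame (`sample_id`, `gene`, `replicate`,
#'   `ct`).
#' @export
gen_ct_table <- function(annotation, deletions, truth = NULL,
                         noise_sd = 0.2, n_replicates = 2,
                         control_ids = c("C1", "C2"),
                         housekeeping = "TBP", deleted_fold = 0.5,
                         compensated_fold = 2.7, window = 2e6, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  ann <- annotation[annotation$expressed_in_blood %||%
                      rep(TRUE, nrow(annotation)), , drop = FALSE]
  genes <- c(ann$symbol, housekeeping)
  baseline <- stats::setNames(stats::runif(length(genes), 22, 30), genes)
  baseline[housekeeping] <- 20

  expr_for <- function(sample, gene) {
    if (gene == housekeeping) return(1)
    if (sample %in% control_ids) return(1)
    if (!is.null(truth) && gene %in% truth$compensated_genes)
      return(compensated_fold)
    drow <- deletions[deletions$patient_id == sample, , drop = FALSE]
    if (nrow(drow) != 1L) return(1)
    st <- classify_gene_vs_deletion(ann[ann$symbol == gene, ], drow, window)
    if (st %in% c("deleted", "partially_deleted")) return(deleted_fold)
    if (!is.null(truth) && st == "within_window" &&
        gene %in% names(truth$true_fold_changes))
      return(unname(truth$true_fold_changes[gene]))
    1
  }

  samples <- c(control_ids, deletions$patient_id)
  rows <- expand.grid(sample_id = samples, gene = genes,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expr <- mapply(expr_for, rows$sample_id, rows$gene)
  rows$ct <- baseline[rows$gene] - log2(expr) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  rows <- rows[order(rows$sample_id, rows$gene, rows$replicate), ,
               drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Generate synthetic Biolog plate data
#'
#' Per well the NADH kinetic curve is logistic,
#' `OD(t) = baseline + A / (1 + exp(-k (t - t0))) + noise`, read every 15
#' minutes over 24 h (96 points). Lines share well-specific parameters;
#' each line's amplitude gets line noise of SD `sd_amplitude`, and
#' `truth$true_well_effects[[plate]][well]` shifts the focal sample's
#' amplitude by that many SD units. Empty plates are baseline plus noise,
#' in triplicate. Endpoint A590 readings are the 24 h curve value plus the
#' A750 background.
#'
#' @param plate_ids Plates to simulate (default `"PM-M5"`).
#' @param n_controls Control-panel size (default 50, >= 2).
#' @param n_replicates Focal-sample replicates (default 2).
#' @param truth Optional [synthetic_truth()] with `true_well_effects`.
#' @param sample_id Focal sample id (default `"S1"`).
#' @param sd_amplitude Line-level amplitude SD (default 0.1).
#' @param sd_meas Measurement noise SD (default 0.01).
#' @param kinetics Also emit the 96-point kinetic series? Default `FALSE`
#'   (endpoint-only datasets are much smaller).
#' @param seed RNG seed.
#' @return List with `endpoint`, `empty`, `kinetics` (or `NULL`),
#'   `layouts`, `truth`.
#' @export
gen_plate_data <- function(plate_ids = "PM-M5", n_controls = 50,
                           n_replicates = 2, truth = NULL,
                           sample_id = "S1", sd_amplitude = 0.1,
                           sd_meas = 0.01, kinetics = FALSE, seed = 1) {
  if (n_controls < 2) stop("n_controls must be >= 2")
  set.seed(seed)
  wells <- well_labels()
  t_min <- seq(15, 1440, by = 15)  # 96 points, 15-min sampling over 24 h
  th <- t_min / 60
  ctrl_ids <- sprintf("C%02d", seq_len(n_controls))
  endpoint <- list(); empty <- list(); kin <- list()
  layouts <- list()

  for (pl in plate_ids) {
    layouts[[pl]] <- if (identical(pl, "Trp")) trp_layout()
                     else plate_layout(pl)
    A0 <- stats::runif(96, 0.5, 1.5)
    kk <- stats::runif(96, 0.3, 0.6)
    t0 <- stats::runif(96, 6, 12)
    base <- 0.1
    shifts <- rep(0, 96)
    names(shifts) <- wells
    eff <- truth$true_well_effects[[pl]]
    if (!is.null(eff)) shifts[names(eff)] <- eff

    lines <- data.frame(
      sample_id = c(rep(sample_id, n_replicates), ctrl_ids),
      role = c(rep("sample", n_replicates), rep("control", n_controls)),
      replicate = c(seq_len(n_replicates), rep(1L, n_controls)),
      stringsAsFactors = FALSE)

    for (li in seq_len(nrow(lines))) {
      is_sample <- lines$role[li] == "sample"
      A <- A0 + stats::rnorm(96, 0, sd_amplitude) +
        if (is_sample) shifts * sd_amplitude else 0
      od24 <- base + A / (1 + exp(-kk * (24 - t0)))
      a750 <- stats::rnorm(96, 0.05, 0.005)
      endpoint[[length(endpoint) + 1L]] <- data.frame(
        plate_id = pl, well = wells, sample_id = lines$sample_id[li],
        role = lines$role[li], replicate = lines$replicate[li],
        a590 = od24 + a750 + stats::rnorm(96, 0, sd_meas), a750 = a750,
        stringsAsFactors = FALSE)
      if (kinetics) {
        od <- vapply(seq_len(96), function(w)
          base + A[w] / (1 + exp(-kk[w] * (th - t0[w]))) +
            stats::rnorm(length(th), 0, sd_meas),
          numeric(length(th)))
        kin[[length(kin) + 1L]] <- data.frame(
          plate_id = pl, well = rep(wells, each = length(t_min)),
          sample_id = lines$sample_id[li], role = lines$role[li],
          replicate = lines$replicate[li], time_min = rep(t_min, 96),
          od = as.vector(od), stringsAsFactors = FALSE)
      }
    }

    for (r in 1:3) {
      a750 <- stats::rnorm(96, 0.05, 0.005)
      empty[[length(empty) + 1L]] <- data.frame(
        plate_id = pl, well = wells, replicate = r,
        a590 = base + a750 + stats::rnorm(96, 0, sd_meas), a750 = a750,
        stringsAsFactors = FALSE)
      if (kinetics) {
        kin[[length(kin) + 1L]] <- data.frame(
          plate_id = pl, well = rep(wells, each = length(t_min)),
          sample_id = "EMPTY", role = "empty", replicate = r,
          time_min = rep(t_min, 96),
          od = base + stats::rnorm(96 * length(t_min), 0, sd_meas),
          stringsAsFactors = FALSE)
      }
    }
  }

  list(endpoint = do.call(rbind, endpoint),
       empty = do.call(rbind, empty),
       kinetics = if (kinetics) do.call(rbind, kin) else NULL,
       layouts = layouts,
       truth = truth %||% synthetic_truth(seed = seed))
}

#' Write a synthetic truth object as JSON
#'
#' @param truth A [synthetic_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
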