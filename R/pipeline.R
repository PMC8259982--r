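#' Run configuration
#'
#' Collects every tunable the pipeline exposes, with defaults equal to
#' the published analysis parameters: 2 Mb flanking window, HI <= 10%,
#' 75th-percentile phenotype gate, 1.5 / 0.66 expression thresholds, and
#' alpha = 0.05 with no multiplicity adjustment. The configuration
#' round-trips through JSON unchanged (see [write_config()] /
#' [read_config()]).
#'
#' @param genes,deletions,tads,contacts,phenotypes,ct,endpoint,empty,kinetics
#'   Input file paths (any may be `NULL` for stages not being run).
#' @param control_ids qPCR control sample ids.
#' @param biolog_sample Focal sample id for the Biolog stage.
#' @param window Flanking window in bp.
#' @param weights Five ranking weights (see [pe_params()]).
#' @param contact_cap,hi_cutoff,percentile_gate See [pe_params()].
#' @param elevated,decreased qPCR classification thresholds.
#' @param alpha Per-well significance cutoff.
#' @param adjust `"none"` or `"bh"`.
#' @param statistic Biolog per-well statistic.
#' @param housekeeping qPCR housekeeping gene.
#' @param seed RNG seed used by the simulate stage.
#' @param outdir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(genes = NULL, deletions = NULL, tads = NULL,
                       contacts = NULL, phenotypes = NULL, ct = NULL,
                       endpoint = NULL, empty = NULL, kinetics = NULL,
                       control_ids = c("C1", "C2"), biolog_sample = NULL,
                       window = 2e6,
                       weights = c(contacts = 1, tad = 1, window = 1,
                                   hi = 1, phenotype = 1),
                       contact_cap = 5, hi_cutoff = 10,
                       percentile_gate = 75, elevated = 1.5,
                       decreased = 0.66, alpha = 0.05, adjust = "none",
                       statistic = "endpoint", housekeeping = "TBP",
                       seed = 1, outdir = "tadpose-out") {
  cfg <- list(genes = genes, deletions = deletions, tads = tads,
              contacts = contacts, phenotypes = phenotypes, ct = ct,
              endpoint = endpoint, empty = empty, kinetics = kinetics,
              control_ids = control_ids, biolog_sample = biolog_sample,
              window = window, weights = weights,
              contact_cap = contact_cap, hi_cutoff = hi_cutoff,
              percentile_gate = percentile_gate, elevated = elevated,
              decreased = decreased, alpha = alpha, adjust = adjust,
              statistic = statistic, housekeeping = housekeeping,
              seed = seed, outdir = outdir)
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param config A `run_config`.
#' @return The config, invisibly, or an error naming the offending field.
#' @export
validate_config <- function(config) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid config field '", field, "': ", msg)
  chk(is.numeric(config$window) && config$window >= 0, "window",
      "must be a non-negative bp count")
  chk(length(config$weights) == 5L && all(is.finite(config$weights)),
      "weights", "must be five finite numbers")
  chk(config$contact_cap >= 1, "contact_cap", "must be >= 1")
  chk(config$hi_cutoff >= 0 && config$hi_cutoff <= 100, "hi_cutoff",
      "must be a percentage")
  chk(config$percentile_gate >= 0 && config$percentile_gate <= 100,
      "percentile_gate", "must be a percentile")
  chk(config$elevated > config$decreased, "elevated",
      "elevated threshold must exceed decreased threshold")
  chk(config$alpha >= 0 && config$alpha <= 1, "alpha",
      "must be in [0, 1]")
  chk(config$adjust %in% c("none", "bh"), "adjust",
      "must be 'none' or 'bh'")
  chk(config$statistic %in% c("endpoint", "slope", "auc"), "statistic",
      "must be endpoint, slope or auc")
  chk(is.numeric(config$seed) && abs(config$seed) < 2^31, "seed",
      "must be a 32-bit integer")
  invisible(config)
}

#' Write / read a configuration as JSON
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `path` (write) or the config (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$weights <- unlist(raw$weights)
  cfg <- do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
  cfg
}

.write_manifest <- function(config, outdir, stage) {
  inputs <- unlist(config[c("genes", "deletions", "tads", "contacts",
                            "phenotypes", "ct", "endpoint", "empty",
                            "kinetics")]) %||% character(0)
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  manifest <- list(
    stage = stage,
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("tadpose")),
    r_version = R.version.string,
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run a pipeline stage
#'
#' Subcommands:
#' * `simulate` — generate a synthetic locus, cohort, Ct table and plate
#'   dataset under `config$seed` and write them to `outdir`;
#' * `predict` — candidate prediction and cohort aggregation;
#' * `qpcr` — the relative-expression pipeline;
#' * `biolog` — the plate pipeline for `config$biolog_sample`;
#' * `report` — merge stage outputs (see [write_report()]).
#'
#' Every invocation writes `manifest.json` (config, seed, package and R
#' versions, input checksums) into `outdir`.
#'
#' @param subcommand One of `simulate`, `predict`, `qpcr`, `biolog`,
#'   `report`.
#' @param config A [run_config()].
#' @return Invisible named list of output file paths.
#' @export
run_pipeline <- function(subcommand = c("simulate", "predict", "qpcr",
                                        "biolog", "report"),
                         config = run_config()) {
  subcommand <- match.arg(subcommand)
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  if (subcommand == "simulate") {
    seed <- as.integer(config$seed)
    locus <- gen_locus(seed = seed)
    cohort <- gen_cohort(seed = child_seed(seed, 1))
    terms <- sample(locus$vocab, 10)
    planted <- plant_position_effects(locus, cohort[1, ], terms,
                                      seed = child_seed(seed, 2))
    locus <- planted$locus
    ctab <- gen_ct_table(locus$annotation, cohort, planted$truth,
                         seed = child_seed(seed, 3))
    plates <- gen_plate_data(sample_id = cohort$patient_id[1],
                             truth = planted$truth,
                             seed = child_seed(seed, 4))
    out$genes <- write_tsv(locus$annotation,
                           file.path(outdir, "genes.tsv"))
    out$tads <- write_tsv(locus$tads, file.path(outdir, "tads.tsv"))
    out$contacts <- write_tsv(locus$contacts,
                              file.path(outdir, "contacts.tsv"))
    out$deletions <- write_tsv(cohort, file.path(outdir, "deletions.tsv"))
    out$phenotypes <- write_tsv(
      data.frame(patient_id = cohort$patient_id,
                 terms = paste(terms, collapse = ";"),
                 stringsAsFactors = FALSE),
      file.path(outdir, "phenotypes.tsv"), comment = character(0))
    out$ct <- write_csv(ctab, file.path(outdir, "ct.csv"))
    out$endpoint <- write_csv(plates$endpoint,
                              file.path(outdir, "endpoint.csv"))
    out$empty <- write_csv(plates$empty, file.path(outdir, "empty.csv"))
    out$truth <- write_truth(planted$truth,
                             file.path(outdir, "truth.json"))
  } else if (subcommand == "predict") {
    ann <- read_genes(config$genes)
    dels <- read_deletions(config$deletions)
    tads <- read_tads(config$tads)
    contacts <- if (!is.null(config$contacts)) read_contacts(config$contacts)
      else data.frame(gene_symbol = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0))
    phen <- if (!is.null(config$phenotypes)) read_phenotypes(config$phenotypes)
      else list()
    params <- pe_params(window = config$window, weights = config$weights,
                        contact_cap = config$contact_cap,
                        hi_cutoff = config$hi_cutoff,
                        percentile_gate = config$percentile_gate)
    per_patient <- lapply(seq_len(nrow(dels)), function(i) {
      pid <- dels$patient_id[i]
      terms <- phen[[pid]] %||% "unspecified"
      predict_candidates(dels[i, ], ann, tads, contacts, terms, params)
    })
    cand <- do.call(rbind, per_patient)
    out$candidates <- write_tsv(cand, file.path(outdir, "candidates.tsv"))
    out$cohort <- write_tsv(aggregate_cohort(per_patient),
                            file.path(outdir, "cohort_aggregate.tsv"),
                            comment = character(0))
  } else if (subcommand == "qpcr") {
    ctab <- read_ct_table(config$ct)
    ann <- read_genes(config$genes)
    dels <- read_deletions(config$deletions)
    res <- run_qpcr_pipeline(ctab, config$control_ids, dels, ann,
                             housekeeping = config$housekeeping,
                             window = config$window,
                             elevated = config$elevated,
                             decreased = config$decreased)
    out$records <- write_tsv(res$records,
                             file.path(outdir, "qpcr_records.tsv"),
                             comment = character(0))
    out$summary <- write_tsv(res$summary,
                             file.path(outdir, "qpcr_summary.tsv"),
                             comment = character(0))
    out$matrix <- write_csv(as.data.frame(res$matrix),
                            file.path(outdir, "fold_matrix.csv"),
                            row_names = TRUE)
  } else if (subcommand == "biolog") {
    ep <- read_endpoints(config$endpoint)
    em <- read_empty_plate(config$empty)
    kin <- if (!is.null(config$kinetics)) read_kinetics(config$kinetics)
      else NULL
    focal <- config$biolog_sample %||%
      ep$sample_id[ep$role == "sample"][1L]
    res <- run_biolog_pipeline(ep, em, focal, kinetics = kin,
                               statistic = config$statistic,
                               alpha = config$alpha,
                               adjust = config$adjust)
    out$wells <- write_tsv(res$wells, file.path(outdir, "biolog_wells.tsv"),
                           comment = character(0))
    jsonlite::write_json(res$plates,
                         file.path(outdir, "biolog_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out$summary <- file.path(outdir, "biolog_summary.json")
  } else if (subcommand == "report") {
    out$report <- write_report(outdir)
  }

  .write_manifest(config, outdir, subcommand)
  out$manifest <- file.path(outdir, "manifest.json")
  invisible(out)
}

#' Merge stage outputs into a per-patient report
#'
#' Builds one row per patient x gene from whichever stage outputs exist
#' in `outdir` (`candidates.tsv`, `qpcr_records.tsv`,
#' `biolog_summary.json`): candidate class, expression category and
#' per-plate significant-well counts. Stages that were not run contribute
#' empty columns; rows are never dropped. Patients appearing in the qPCR
#' output but not in the candidate output (when both exist) are an error.
#'
#' @param outdir Directory holding the stage outputs.
#' @return Path to the written `report.tsv` (a `report.json` twin is
#'   written alongside).
#' @export
write_report <- function(outdir) {
  cand_p <- file.path(outdir, "candidates.tsv")
  qpcr_p <- file.path(outdir, "qpcr_records.tsv")
  biolog_p <- file.path(outdir, "biolog_summary.json")
  have_cand <- file.exists(cand_p)
  have_qpcr <- file.exists(qpcr_p)
  have_biolog <- file.exists(biolog_p)
  if (!have_cand && !have_qpcr && !have_biolog)
    stop("write_report() needs at least one stage output in ", outdir)

  cand <- if (have_cand)
    utils::read.delim(cand_p, comment.char = "#",
                      stringsAsFactors = FALSE) else NULL
  qpcr <- if (have_qpcr)
    utils::read.delim(qpcr_p, comment.char = "#",
                      stringsAsFactors = FALSE) else NULL
  if (have_cand && have_qpcr) {
    qpcr_pat <- unique(qpcr$sample_id[qpcr$status != "unknown"])
    extra <- setdiff(qpcr_pat, unique(cand$patient_id))
    if (length(extra))
      stop("conflicting patient ids across stages: ",
           paste(extra, collapse = ", "))
  }

  base <- if (have_cand)
    cand[, c("patient_id", "gene", "status", "rank_score",
             "candidate_class")]
  else if (have_qpcr)
    data.frame(patient_id = qpcr$sample_id, gene = qpcr$gene,
               status = qpcr$status, rank_score = NA_real_,
               candidate_class = NA_character_, stringsAsFactors = FALSE)
  else
    data.frame(patient_id = character(0), gene = character(0),
               status = character(0), rank_score = numeric(0),
               candidate_class = character(0), stringsAsFactors = FALSE)

  if (have_qpcr && have_cand) {
    m <- match(paste(base$patient_id, base$gene),
               paste(qpcr$sample_id, qpcr$gene))
    base$fold <- qpcr$fold[m]
    base$expression_category <- qpcr$category[m]
  } else if (have_qpcr) {
    base$fold <- qpcr$fold
    base$expression_category <- qpcr$category
  } else {
    base$fold <- NA_real_
    base$expression_category <- NA_character_
  }

  if (have_biolog) {
    bs <- jsonlite::read_json(biolog_p, simplifyVector = TRUE)
    base$biolog_significant_wells <-
      paste(vapply(names(bs), function(p) paste0(p, "=", bs[[p]]$label),
                   character(1)), collapse = "; ")
  } else {
    base$biolog_significant_wells <- NA_character_
  }

  path <- file.path(outdir, "report.tsv")
  write_tsv(base, path, comment = character(0))
  jsonlite::write_json(base, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  path
}
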