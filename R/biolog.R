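#' Well labels of a 96-well plate
#'
#' @return Character vector `"A1"..."H12"` in row-major order.
#' @export
well_labels <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Plate layout
#'
#' Maps the 96 wells of a PM-M plate to compound names. The layout is
#' total: every well must be named.
#'
#' @param plate_id Plate label, e.g. `"PM-M5"` or `"Trp"`.
#' @param compounds Named character vector (names = wells `A1`-`H12`) or
#'   `NULL` for generic per-well names.
#' @return Data frame `plate_id`, `well`, `compound` (96 rows).
#' @export
plate_layout <- function(plate_id, compounds = NULL) {
  wells <- well_labels()
  if (is.null(compounds))
    compounds <- stats::setNames(paste0(plate_id, ":", wells), wells)
  if (!setequal(names(compounds), wells))
    stop("layout must name exactly the 96 wells A1-H12")
  data.frame(plate_id = plate_id, well = wells,
             compound = unname(compounds[wells]), stringsAsFactors = FALSE)
}

#' Layout of the custom tryptophan plate
#'
#' Twelve 8-well columns, each holding glucose, an empty well, tryptophan
#' alone, and five tryptophan dipeptides (rows A-H), one concentration
#' series per column.
#'
#' @return Layout data frame (see [plate_layout()]).
#' @export
trp_layout <- function() {
  row_contents <- c("D-Glucose", "Empty", "L-Tryptophan", "Gly-Trp",
                    "Lys-Trp", "Leu-Trp", "Arg-Trp", "Ala-Trp")
  wells <- well_labels()
  comp <- stats::setNames(
    paste0(row_contents[match(substr(wells, 1, 1), LETTERS[1:8])],
           " c", substring(wells, 2)),
    wells)
  plate_layout("Trp", comp)
}

#' Relative absorbance
#'
#' Endpoint readout of the redox dye: the 590 nm absorbance peak minus the
#' 750 nm background, `A590 - A750`.
#'
#' @param a590,a750 Absorbances (vectorised).
#' @return `a590 - a750`.
#' @export
relative_absorbance <- function(a590, a750) {
  if (any(!is.finite(a590)) || any(!is.finite(a750)))
    stop("absorbances must be finite")
  a590 - a750
}

#' Normalise per-well values against an empty plate
#'
#' Subtracts, per well, the mean of the triplicate empty-plate readings
#' (plates run with media and dye but no cells), flooring the result at
#' `eps` so that every well survives the subsequent log transform and the
#' well count stays at 96.
#'
#' @param readings Data frame `well`, `value` (replicates allowed).
#' @param empty_plate Data frame `well`, `value` with exactly three
#'   replicate rows per well.
#' @param eps Floor, default `1e-6`.
#' @return `readings` with `value` replaced by the normalised value.
#' @export
normalize_to_empty <- function(readings, empty_plate, eps = 1e-6) {
  .assert_cols(readings, c("well", "value"), "readings")
  .assert_cols(empty_plate, c("well", "value"), "empty plate")
  cnt <- table(empty_plate$well)
  if (any(cnt != 3L))
    stop("empty plate must have exactly 3 replicates per well")
  missing <- setdiff(unique(readings$well), empty_plate$well)
  if (length(missing))
    stop("empty-plate reading missing for well(s): ",
         paste(missing, collapse = ", "))
  mu <- tapply(empty_plate$value, empty_plate$well, mean)
  readings$value <- pmax(readings$value - as.numeric(mu[readings$well]), eps)
  readings
}

#' Log-transform normalised values
#'
#' `log10(value + eps)`; values must be non-negative.
#'
#' @param values Numeric vector `>= 0`.
#' @param eps Offset, default `1e-6`.
#' @return Transformed vector.
#' @export
log_transform <- function(values, eps = 1e-6) {
  if (any(values < 0)) stop("log_transform() requires non-negative values")
  log10(values + eps)
}

#' Kinetic parameters of a well curve
#'
#' From an optical-density time series (15-minute sampling over 24 h in
#' the standard run): `slope` is the maximum least-squares slope over any
#' sliding 1-hour window (OD per hour), `endpoint` is the final reading,
#' and `auc` is the trapezoid area under the curve (OD x hours).
#'
#' @param time_min Time points in minutes, increasing.
#' @param od Optical densities, same length (`>= 2`).
#' @return List with `slope`, `endpoint`, `auc`.
#' @export
kinetic_params <- function(time_min, od) {
  n <- length(od)
  if (n < 2L || length(time_min) != n)
    stop("kinetic_params() needs >= 2 matched time/od points")
  if (is.unsorted(time_min, strictly = TRUE))
    stop("time points must be strictly increasing")
  th <- time_min / 60
  slope <- -Inf
  for (i in seq_len(n - 1L)) {
    j <- which(th <= th[i] + 1 + 1e-9)
    j <- j[j >= i]
    if (length(j) < 2L) j <- c(i, i + 1L)
    x <- th[j]; y <- od[j]
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    if (b > slope) slope <- b
  }
  auc <- sum(diff(th) * (od[-1L] + od[-n]) / 2)
  list(slope = slope, endpoint = od[n], auc = auc)
}

#' Per-well Mann-Whitney comparison against the control panel
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of the sample's
#' replicate values against the per-well control-panel values: exact
#' distribution when `min(n) <= 8` and there are no ties, normal
#' approximation with tie/continuity correction otherwise. When every
#' value in both groups is identical the test is degenerate: `p = 1`,
#' direction `none`. The direction of utilisation is the sign of
#' (median sample - median control), reported only for significant wells.
#'
#' @param sample_values Numeric vector, `>= 2` replicate values.
#' @param control_values Numeric vector, `>= 2` control-panel values.
#' @param alpha Significance cutoff, default 0.05 (`p <= alpha`).
#' @return List with `p_value`, `significant`, `direction`
#'   (`increased`/`decreased`/`none`), `median_diff`, `n_sample`,
#'   `n_control`.
#' @export
mann_whitney_well <- function(sample_values, control_values, alpha = 0.05) {
  ns <- length(sample_values); nc <- length(control_values)
  if (ns < 2L)
    stop("need >= 2 sample-side replicate values per well ",
         "(single-replicate input is rejected, not silently tested)")
  if (nc < 2L) stop("need >= 2 control values per well")
  md <- stats::median(sample_values) - stats::median(control_values)
  pooled <- c(sample_values, control_values)
  if (length(unique(pooled)) == 1L) {
    return(list(p_value = 1, significant = FALSE, direction = "none",
                median_diff = 0, n_sample = ns, n_control = nc))
  }
  ties <- any(duplicated(pooled))
  exact <- min(ns, nc) <= 8L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(sample_values, control_values,
                       alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  sig <- is.finite(p) && p <= alpha
  dir <- if (!sig || md == 0) "none" else if (md > 0) "increased"
         else "decreased"
  list(p_value = p, significant = sig, direction = dir,
       median_diff = md, n_sample = ns, n_control = nc)
}

#' Summarise per-well comparisons for one plate
#'
#' Renders the significant-well fraction in the printed style, e.g.
#' `"43/96 (44.8%)"`; percentages carry one decimal except that an exact
#' 100 prints as `"100%"`.
#'
#' @param comparisons Data frame with at least `significant` and
#'   `direction` columns (<= 96 rows).
#' @return List with `n_significant`, `n_total`, `percent`, `label`,
#'   `n_increased`, `n_decreased`.
#' @export
plate_summary <- function(comparisons) {
  .assert_cols(comparisons, c("significant", "direction"), "comparisons")
  n <- nrow(comparisons)
  if (n > 96L) stop("a plate has at most 96 wells")
  k <- sum(comparisons$significant)
  pct <- round(100 * k / n, 1)
  pct_str <- if (pct == 100) "100" else sprintf("%.1f", pct)
  list(n_significant = k, n_total = n, percent = pct,
       label = sprintf("%d/%d (%s%%)", k, n, pct_str),
       n_increased = sum(comparisons$direction == "increased"),
       n_decreased = sum(comparisons$direction == "decreased"))
}

# statistic per (line, well): endpoint relative absorbance, or a kinetic
# parameter computed from the matching curve
.well_statistic <- function(endpoint, kinetics, statistic) {
  if (statistic == "endpoint") {
    v <- endpoint
    v$value <- relative_absorbance(v$a590, v$a750)
    return(v[, c("plate_id", "well", "sample_id", "replicate", "value")])
  }
  if (is.null(kinetics))
    stop("kinetic statistic '", statistic, "' requested but no kinetics data")
  key <- interaction(kinetics$plate_id, kinetics$well, kinetics$sample_id,
                     kinetics$replicate, drop = TRUE)
  out <- lapply(split(kinetics, key), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    kp <- kinetic_params(d$time_min, d$od)
    data.frame(plate_id = d$plate_id[1L], well = d$well[1L],
               sample_id = d$sample_id[1L], replicate = d$replicate[1L],
               value = kp[[statistic]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the Biolog plate pipeline for one focal sample
#'
#' Per plate and well: compute the chosen statistic (endpoint relative
#' absorbance by default; `slope` or `auc` from the kinetic series),
#' normalise against the empty-plate triplicates, log-transform, then
#' compare the focal sample's replicate values against the control-panel
#' values with a two-sided Mann-Whitney test. Optional Benjamini-Hochberg
#' adjustment is applied per plate across its wells.
#'
#' @param endpoint Endpoint data (`plate_id`, `well`, `sample_id`, `role`,
#'   `replicate`, `a590`, `a750`) covering the focal sample
#'   (`role = "sample"`) and the control panel (`role = "control"`).
#' @param empty Empty-plate endpoint data (`plate_id`, `well`,
#'   `replicate`, `a590`, `a750`), triplicate per well.
#' @param sample_id Focal sample id.
#' @param kinetics Optional kinetic data (required for `slope`/`auc`),
#'   covering the same lines plus `sample_id = "EMPTY"` rows for the empty
#'   plate when a kinetic statistic is normalised.
#' @param statistic `"endpoint"` (default), `"slope"` or `"auc"`.
#' @param alpha Significance cutoff (default 0.05).
#' @param adjust `"none"` (default, raw `p <= alpha`) or `"bh"`.
#' @return List with `wells` (per-well comparison table across plates)
#'   and `plates` (named list of [plate_summary()] results).
#' @export
run_biolog_pipeline <- function(endpoint, empty, sample_id,
                                kinetics = NULL,
                                statistic = c("endpoint", "slope", "auc"),
                                alpha = 0.05, adjust = c("none", "bh")) {
  statistic <- match.arg(statistic)
  adjust <- match.arg(adjust)
  .assert_cols(endpoint, c("plate_id", "well", "sample_id", "role",
                           "replicate", "a590", "a750"), "endpoint data")
  .assert_cols(empty, c("plate_id", "well", "replicate", "a590", "a750"),
               "empty-plate data")
  if (!sample_id %in% endpoint$sample_id[endpoint$role == "sample"])
    stop("focal sample '", sample_id, "' not present with role=sample")

  stat_tab <- .well_statistic(endpoint, kinetics, statistic)
  stat_tab$role <- endpoint$role[match(
    paste(stat_tab$plate_id, stat_tab$well, stat_tab$sample_id,
          stat_tab$replicate),
    paste(endpoint$plate_id, endpoint$well, endpoint$sample_id,
          endpoint$replicate))]

  empty_stat <- empty
  empty_stat$value <- relative_absorbance(empty$a590, empty$a750)
  if (statistic != "endpoint") {
    ek <- kinetics[kinetics$sample_id == "EMPTY", , drop = FALSE]
    if (nrow(ek))
      empty_stat <- .well_statistic(
        data.frame(), ek, statistic)[, c("plate_id", "well", "replicate",
                                         "value")]
    else
      stop("kinetic statistic requested but no EMPTY kinetic rows")
  }

  plates <- unique(stat_tab$plate_id[stat_tab$sample_id == sample_id])
  well_rows <- list()
  for (pl in plates) {
    st <- stat_tab[stat_tab$plate_id == pl, , drop = FALSE]
    em <- empty_stat[empty_stat$plate_id == pl, c("well", "value")]
    wells_here <- sort(unique(st$well[st$sample_id == sample_id]))
    mismatch <- setdiff(unique(st$well), unique(em$well))
    if (length(mismatch))
      stop("layout mismatch on plate ", pl, ": wells ",
           paste(mismatch, collapse = ", "), " missing from empty plate")
    norm <- normalize_to_empty(
      data.frame(well = st$well, value = st$value,
                 stringsAsFactors = FALSE), em)
    st$nvalue <- log_transform(norm$value)
    # control value per (control line, well): mean over its replicates
    ctrl <- st[st$role == "control", , drop = FALSE]
    ctrl_vals <- stats::aggregate(nvalue ~ sample_id + well, data = ctrl,
                                  FUN = mean)
    for (w in wells_here) {
      sv <- st$nvalue[st$sample_id == sample_id & st$well == w]
      cv <- ctrl_vals$nvalue[ctrl_vals$well == w]
      cmp <- mann_whitney_well(sv, cv, alpha = alpha)
      well_rows[[length(well_rows) + 1L]] <-
        data.frame(plate_id = pl, well = w, p_value = cmp$p_value,
                   median_diff = cmp$median_diff,
                   significant = cmp$significant, direction = cmp$direction,
                   stringsAsFactors = FALSE)
    }
  }
  wells <- do.call(rbind, well_rows)

  if (adjust == "bh") {
    wells$p_adjusted <- NA_real_
    for (pl in unique(wells$plate_id)) {
      i <- wells$plate_id == pl
      wells$p_adjusted[i] <- stats::p.adjust(wells$p_value[i],
                                             method = "BH")
    }
    wells$significant <- wells$p_adjusted <= alpha
    wells$direction[!wells$significant] <- "none"
    wells$direction[wells$significant & wells$median_diff > 0] <- "increased"
    wells$direction[wells$significant & wells$median_diff < 0] <- "decreased"
  }

  summaries <- lapply(split(wells, wells$plate_id), plate_summary)
  list(wells = wells, plates = summaries)
}
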