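#' Structure-based docking metrics: data model, consensus and calibration
#'
#' Nineteen per-pose evaluation values are carried for each
#' (ligand, representation, template) triple. Scores are stored in their
#' native units and orientation -- lower-is-better raw scores (Plants, DSX,
#' MedusaScore) are never sign-flipped, since tree ensembles are invariant to
#' monotone orientation and silent transforms would hide provenance. The
#' `*LR` columns, `XScore`, `AnchKd` and `AtomeScore` live on the pKa scale
#' (-log10 of a molar dissociation constant).
#'
#' @name docking_data
NULL

#: the 19 metric columns, fixed order
METRIC_NAMES <- c("PlantsFull", "Plants", "PlantsLR", "MedusaScore",
                  "MedusaLR", "XScore", "DSX", "DSXLR", "AtomeScore",
                  "Tanimoto", "AtomSA", "QMean", "AnchKd", "AnchorFit",
                  "LigandEnergy", "LPC", "PSim", "CpxQuality", "LPE")

POSE_KEY <- c("ligand_id", "representation_tag", "template_id")

#' Metric schema registry
#'
#' One row per metric with its scale (`pKa`, `raw` or `unitless`) and
#' orientation (`higher` or `lower` is better). Downstream learners receive
#' values unchanged; the registry documents how to read them.
#'
#' @return a data frame with columns `metric`, `scale`, `orientation`.
#' @export
metric_schema <- function() {
  data.frame(
    metric = METRIC_NAMES,
    scale = c("raw", "raw", "pKa", "raw", "pKa", "pKa", "raw", "pKa", "pKa",
              "unitless", "raw", "unitless", "pKa", "raw", "raw", "raw",
              "unitless", "unitless", "raw"),
    orientation = c("lower", "lower", "higher", "lower", "higher", "higher",
                    "lower", "higher", "higher", "higher", "higher", "higher",
                    "higher", "higher", "lower", "higher", "higher", "higher",
                    "lower"),
    stringsAsFactors = FALSE)
}

#' Consensus affinity score from four pKa-scale components
#'
#' Arithmetic mean of the calibrated PLANTS, XScore, MedusaScore and DSX
#' pKa-scale values. In strict mode (default) a missing component is an
#' error; with `allow_partial = TRUE` the mean of the available components
#' is returned and the result carries attribute `partial = TRUE`.
#'
#' @param plants_lr,xscore,medusa_lr,dsx_lr the four pKa-scale scores
#'   (vectorized; equal lengths).
#' @param allow_partial average available components instead of failing.
#' @return consensus pKa vector.
#' @export
consensus_atome_score <- function(plants_lr, xscore, medusa_lr, dsx_lr,
                                  allow_partial = FALSE) {
  m <- cbind(plants_lr, xscore, medusa_lr, dsx_lr)
  miss <- !is.finite(m)
  if (any(miss) && !allow_partial) {
    bad <- which(rowSums(miss) > 0)
    stop_dockrf(
      "missing consensus component(s) in row(s) %s (strict mode; set allow_partial = TRUE to average available scores)",
      paste(utils::head(bad, 5L), collapse = ", "),
      class = "dockrf_missing_error")
  }
  out <- rowMeans(m, na.rm = allow_partial)
  out[!is.finite(out)] <- NA_real_
  if (any(miss)) attr(out, "partial") <- TRUE
  out
}

#' Linear calibration of a raw score onto the pKa scale
#'
#' @param metric_name one of `"Plants"`, `"MedusaScore"`, `"DSX"`.
#' @param slope pKa per native score unit.
#' @param intercept pKa offset.
#' @return a `dockrf_calibration` object.
#' @export
calibration_line <- function(metric_name, slope, intercept) {
  if (!metric_name %in% c("Plants", "MedusaScore", "DSX"))
    stop_dockrf("no calibration defined for metric '%s'", metric_name,
                class = "dockrf_validation_error")
  assert_scalar_number(slope, "slope")
  assert_scalar_number(intercept, "intercept")
  structure(list(metric_name = metric_name, slope = slope,
                 intercept = intercept),
            class = "dockrf_calibration")
}

#' Apply a calibration line: pKa = slope * raw + intercept
#'
#' @param raw raw score vector.
#' @param line a `dockrf_calibration` (see [calibration_line()],
#'   [fit_calibration()]).
#' @return calibrated pKa vector.
#' @export
calibrate_score <- function(raw, line) {
  if (!inherits(line, "dockrf_calibration"))
    stop_dockrf("no calibration line supplied", class = "dockrf_validation_error")
  line$slope * raw + line$intercept
}

#' Fit a calibration line by ordinary least squares
#'
#' For users holding their own (raw score, known pKa) reference pairs, e.g.
#' from an affinity-annotated complex collection.
#'
#' @param raw raw score values (length >= 2, non-constant).
#' @param pka known affinities on the pKa scale.
#' @param metric_name metric being calibrated.
#' @return a `dockrf_calibration` with `slope`, `intercept` and residual `sse`.
#' @export
fit_calibration <- function(raw, pka, metric_name = "Plants") {
  if (length(raw) != length(pka))
    stop_dockrf("raw and pka lengths differ", class = "dockrf_validation_error")
  if (length(raw) < 2L)
    stop_dockrf("need at least 2 reference pairs", class = "dockrf_validation_error")
  if (var(raw) == 0)
    stop_dockrf("raw scores are constant; slope undefined",
                class = "dockrf_degenerate_error")
  slope <- cov(raw, pka) / var(raw)
  intercept <- mean(pka) - slope * mean(raw)
  line <- calibration_line(metric_name, slope, intercept)
  line$sse <- sum((pka - calibrate_score(raw, line))^2)
  line
}

#' @export
print.dockrf_calibration <- function(x, ...) {
  cat(sprintf("<calibration> %s: pKa = %.6g * raw + %.6g\n",
              x$metric_name, x$slope, x$intercept))
  invisible(x)
}

#' Read/write calibration configuration (JSON map metric -> slope/intercept)
#' @param lines named list of `dockrf_calibration` objects.
#' @param path file path.
#' @export
write_calibration_config <- function(lines, path) {
  obj <- lapply(lines, function(l) list(slope = l$slope, intercept = l$intercept))
  names(obj) <- vapply(lines, `[[`, "", "metric_name")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_config
#' @export
read_calibration_config <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(stats::setNames(names(obj), names(obj)), function(m)
    calibration_line(m, obj[[m]]$slope, obj[[m]]$intercept))
}

validate_pose_table <- function(df) {
  need <- c(POSE_KEY, METRIC_NAMES)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_dockrf("pose table missing column(s): %s",
                paste(miss, collapse = ", "), class = "dockrf_schema_error")
  key <- do.call(paste, c(df[POSE_KEY], sep = "\r"))
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), POSE_KEY, drop = FALSE][1L, ]
    stop_dockrf("duplicate pose key (%s, %s, %s)", d$ligand_id,
                d$representation_tag, d$template_id,
                class = "dockrf_schema_error")
  }
  tn <- df$Tanimoto[is.finite(df$Tanimoto)]
  if (length(tn) && (min(tn) < 0 || max(tn) > 1))
    stop_dockrf("Tanimoto column outside [0, 1]", class = "dockrf_validation_error")
  invisible(df)
}

#' Read / write a per-pose docking-metric table
#'
#' CSV (or TSV) with the exact header `ligand_id, representation_tag,
#' template_id` followed by the 19 metric columns of [metric_schema()].
#' Unknown extra columns are preserved as opaque extras. Duplicate
#' (ligand, tag, template) keys and missing required columns are errors.
#'
#' @param path file path; tab-separated when the extension is `.tsv`.
#' @return a `dockrf_pose_table` data frame.
#' @export
read_pose_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  for (k in POSE_KEY)
    if (k %in% names(df)) df[[k]] <- as.character(df[[k]])
  validate_pose_table(df)
  class(df) <- c("dockrf_pose_table", "data.frame")
  df
}

#' @rdname read_pose_table
#' @param rows pose table to write.
#' @export
write_pose_table <- function(rows, path) {
  validate_pose_table(rows)
  extras <- setdiff(names(rows), c(POSE_KEY, METRIC_NAMES))
  cols <- c(POSE_KEY, METRIC_NAMES, extras)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(rows[, cols], path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Construct and validate a pose table from a data frame
#' @param df data frame with the pose-table schema.
#' @return a `dockrf_pose_table`.
#' @export
as_pose_table <- function(df) {
  validate_pose_table(df)
  class(df) <- unique(c("dockrf_pose_table", class(df)))
  df
}
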