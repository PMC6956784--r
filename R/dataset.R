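#' Dataset assembly: affinity labels, representation grouping, splits
#'
#' Affinities are modeled on the p-scale (pKi / pIC50, i.e. -log10 of a
#' molar constant): Ki and IC50 in nM map to `9 - log10(value)`; relative
#' binding activity (RBA, estradiol = 100) maps to `log10(RBA) - 8`.
#' Splitting and cross-validation stratify on quantile bins of the label and
#' operate at the ligand level: every representation row of a ligand stays
#' on one side of any split, which prevents leakage through
#' representation duplicates in combined datasets.
#'
#' @name dataset_builder
NULL

REPRESENTATION_GROUPS <- list(
  dConf = c("BDB", "OB3D", "Frog3D"),
  dCharge = c("MMFF", "Gast", "BDB"),
  ALL = c("MMFF", "Gast", "BDB", "OB3D", "Frog3D"))

#' Transform a measured affinity to the p-scale
#'
#' @param kind `"Ki"`, `"IC50"` (value in nM unless `units` says otherwise)
#'   or `"RBA"` (percent relative binding activity, unitless).
#' @param value positive measurement(s).
#' @param units for Ki/IC50: `"nM"` (default), `"uM"` or `"M"`.
#' @return p-affinity: `9 - log10(value_nM)` for Ki/IC50,
#'   `log10(RBA) - 8` for RBA.
#' @export
to_p_affinity <- function(kind, value, units = "nM") {
  if (any(!is.finite(value)) || any(value <= 0))
    stop_dockrf("affinity values must be positive and finite",
                class = "dockrf_validation_error")
  kind <- match.arg(kind, c("Ki", "IC50", "RBA"))
  if (kind == "RBA") return(log10(value) - 8)
  factor <- switch(units, nM = 1, uM = 1e3, `µM` = 1e3, M = 1e9,
                   stop_dockrf("unknown units '%s'", units,
                               class = "dockrf_validation_error"))
  9 - log10(value * factor)
}

#' Build an affinity record table
#'
#' @param ligand_id identifiers.
#' @param kind measurement kind per record (`Ki`, `IC50`, `RBA`).
#' @param value measured values (> 0).
#' @param units units for Ki/IC50 records (recycled).
#' @return data frame with `ligand_id`, `measure_kind`, `value`, `units`,
#'   `p_affinity`.
#' @export
affinity_records <- function(ligand_id, kind, value, units = "nM") {
  n <- length(ligand_id)
  kind <- rep_len(kind, n); units <- rep_len(units, n)
  p <- vapply(seq_len(n), function(i)
    to_p_affinity(kind[i], value[i], units[i]), numeric(1))
  data.frame(ligand_id = as.character(ligand_id), measure_kind = kind,
             value = value, units = units, p_affinity = p,
             stringsAsFactors = FALSE)
}

#' Read / write an affinity table CSV
#'
#' Columns: `ligand_id, measure_kind, value, units`; `p_affinity` is
#' (re)computed on read.
#' @param path CSV path.
#' @export
read_affinity_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(ligand_id = "character"))
  miss <- setdiff(c("ligand_id", "measure_kind", "value"), names(df))
  if (length(miss))
    stop_dockrf("affinity table missing column(s): %s",
                paste(miss, collapse = ", "), class = "dockrf_schema_error")
  if (is.null(df$units)) df$units <- "nM"
  affinity_records(df$ligand_id, df$measure_kind, df$value, df$units)
}

#' @rdname read_affinity_table
#' @param records affinity table from [affinity_records()].
#' @export
write_affinity_table <- function(records, path) {
  write.csv(records[, c("ligand_id", "measure_kind", "value", "units")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach p-affinity labels to an assembled feature table
#'
#' @param features a `dockrf_features` table ([assemble_features()]).
#' @param affinities an affinity table with `ligand_id` and `p_affinity`.
#' @return a `dockrf_dataset` data frame: `ligand_id`,
#'   `representation_tag`, `p_affinity`, then feature columns.
#' @export
build_dataset <- function(features, affinities) {
  i <- match(features$ligand_id, affinities$ligand_id)
  if (anyNA(i))
    stop_dockrf("no affinity for ligand(s): %s",
                paste(unique(features$ligand_id[is.na(i)]), collapse = ", "),
                class = "dockrf_validation_error")
  fcols <- feature_names(features)
  out <- data.frame(ligand_id = features$ligand_id,
                    representation_tag = features$representation_tag,
                    p_affinity = affinities$p_affinity[i],
                    stringsAsFactors = FALSE)
  out <- cbind(out, features[, fcols, drop = FALSE])
  key <- paste(out$ligand_id, out$representation_tag, sep = "\r")
  if (anyDuplicated(key))
    stop_dockrf("duplicate (ligand_id, representation_tag) rows",
                class = "dockrf_validation_error")
  attr(out, "feature_mode") <- attr(features, "feature_mode")
  class(out) <- c("dockrf_dataset", "data.frame")
  out
}

#' Concatenate per-representation datasets into a combined dataset
#'
#' Groupings: `dConf` = BDB + OB3D + Frog3D (3D-generator variation),
#' `dCharge` = MMFF + Gast + BDB (charge-model variation), `ALL` = all five.
#'
#' @param tagged_tables named list of `dockrf_dataset` tables, names =
#'   representation tags.
#' @param grouping `"dConf"`, `"dCharge"` or `"ALL"`.
#' @return combined `dockrf_dataset`; attribute `grouping_label` records
#'   the grouping.
#' @export
combine_representations <- function(tagged_tables, grouping) {
  if (!grouping %in% names(REPRESENTATION_GROUPS))
    stop_dockrf("unknown grouping '%s'", grouping,
                class = "dockrf_validation_error")
  need <- REPRESENTATION_GROUPS[[grouping]]
  miss <- setdiff(need, names(tagged_tables))
  if (length(miss))
    stop_dockrf("grouping '%s' missing member tag(s): %s", grouping,
                paste(miss, collapse = ", "), class = "dockrf_validation_error")
  parts <- tagged_tables[need]
  schema <- lapply(parts, names)
  if (length(unique(vapply(schema, paste, "", collapse = "|"))) != 1L)
    stop_dockrf("member tables have differing column schemas",
                class = "dockrf_schema_error")
  out <- do.call(rbind, c(parts, make.row.names = FALSE))
  attr(out, "grouping_label") <- grouping
  attr(out, "feature_mode") <- attr(parts[[1L]], "feature_mode")
  class(out) <- c("dockrf_dataset", "data.frame")
  out
}

# Ligand-level units for stratification: one row per ligand with its label.
ligand_units <- function(table, grouped = TRUE) {
  if (grouped) {
    ids <- unique(table$ligand_id)
    lab <- vapply(split(table$p_affinity, table$ligand_id)[ids], mean,
                  numeric(1))
    data.frame(unit = ids, label = lab, stringsAsFactors = FALSE)
  } else {
    data.frame(unit = paste(table$ligand_id, table$representation_tag,
                            sep = "\r"),
               label = table$p_affinity, stringsAsFactors = FALSE)
  }
}

# Equal-count quantile bins over labels; deterministic under ties.
label_bins <- function(units, n_bins) {
  ord <- order(units$label, units$unit)
  n <- nrow(units)
  bins <- integer(n)
  bins[ord] <- ceiling(seq_len(n) * n_bins / n)
  bins
}

#' Stratified hold-out split
#'
#' Labels are cut into `n_bins` equal-count quantile bins at the ligand
#' level; per-bin test quotas are allocated by largest remainder so the test
#' set has exactly `floor(test_fraction * n)` units. All representation rows
#' of one ligand land on the same side (set `grouped = FALSE` for ungrouped,
#' per-row splitting).
#'
#' @param table a `dockrf_dataset`.
#' @param test_fraction fraction held out (default 0.2).
#' @param n_bins stratification bins (default 5).
#' @param seed integer seed; two seeds give different memberships, identical
#'   sizes.
#' @param grouped keep all rows of a ligand together (default TRUE).
#' @return list with `train` and `test` (`dockrf_dataset`s).
#' @export
stratified_holdout <- function(table, test_fraction = 0.2, n_bins = 5,
                               seed = 1, grouped = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_dockrf("test_fraction must lie in (0, 1)",
                class = "dockrf_validation_error")
  units <- ligand_units(table, grouped)
  n <- nrow(units)
  if (n < n_bins)
    stop_dockrf("fewer units (%d) than bins (%d)", n, n_bins,
                class = "dockrf_validation_error")
  bins <- label_bins(units, n_bins)
  target <- floor(test_fraction * n)
  sizes <- tabulate(bins, n_bins)
  quota_raw <- test_fraction * sizes
  quota <- floor(quota_raw)
  left <- target - sum(quota)
  if (left > 0) {
    extra <- order(-(quota_raw - quota), seq_len(n_bins))
    take <- extra[quota[extra] < sizes[extra]][seq_len(left)]
    quota[take] <- quota[take] + 1L
  }
  test_units <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_bins), function(b) {
      members <- units$unit[bins == b]
      if (quota[b] == 0L) character(0)
      else members[sample.int(length(members), quota[b])]
    }), use.names = FALSE)
  })
  in_test <- if (grouped) table$ligand_id %in% test_units
             else paste(table$ligand_id, table$representation_tag,
                        sep = "\r") %in% test_units
  split_tab <- function(rows) {
    out <- table[rows, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "feature_mode") <- attr(table, "feature_mode")
    class(out) <- class(table)
    out
  }
  list(train = split_tab(!in_test), test = split_tab(in_test))
}

#' Repeated stratified k-fold assignments
#'
#' Per repeat, ligands are dealt round-robin within each label bin so fold
#' sizes differ by at most one per bin; every representation row of a
#' ligand lands in the same fold. Reproducible from `seed`.
#'
#' @param table a `dockrf_dataset`.
#' @param k folds (default 10).
#' @param repeats repeats (default 10).
#' @param n_bins stratification bins (default 5).
#' @param seed integer master seed.
#' @param grouped ligand-level folding (default TRUE).
#' @return list of length `repeats`; each element an integer fold id (1..k)
#'   per row of `table`.
#' @export
make_cv_folds <- function(table, k = 10, repeats = 10, n_bins = 5, seed = 1,
                          grouped = TRUE) {
  if (k < 2) stop_dockrf("k must be >= 2", class = "dockrf_validation_error")
  units <- ligand_units(table, grouped)
  n <- nrow(units)
  if (n < k)
    stop_dockrf("fewer units (%d) than folds (%d)", n, k,
                class = "dockrf_validation_error")
  bins <- label_bins(units, min(n_bins, max(1L, n %/% k)))
  row_unit <- if (grouped) table$ligand_id
              else paste(table$ligand_id, table$representation_tag, sep = "\r")
  withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      fold_of <- integer(n)
      for (b in unique(bins)) {
        members <- which(bins == b)
        shuffled <- members[sample.int(length(members))]
        start <- sample.int(k, 1L)
        fold_of[shuffled] <- as.integer((seq_along(shuffled) + start - 2L) %% k) + 1L
      }
      fold_of[match(row_unit, units$unit)]
    })
  })
}

#' Write / read a dataset table (CSV)
#'
#' Columns: `ligand_id, representation_tag, p_affinity`, then features.
#' @param table a `dockrf_dataset`.
#' @param path CSV path.
#' @export
write_dataset <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(ligand_id = "character",
                                 representation_tag = "character"))
  miss <- setdiff(c("ligand_id", "representation_tag", "p_affinity"),
                  names(out))
  if (length(miss))
    stop_dockrf("dataset missing column(s): %s", paste(miss, collapse = ", "),
                class = "dockrf_schema_error")
  class(out) <- c("dockrf_dataset", "data.frame")
  out
}
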