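#' Ensemble aggregation: templates, poses, unified instances
#'
#' One ligand is docked against an ensemble of receptor templates (20 by
#' default), each template contributing one pose and one row of docking
#' metrics. Rows are aggregated per (ligand, representation) into a "unified
#' instance": the median and sample standard deviation of every metric over
#' the poses.
#'
#' @name ensemble_aggregation
NULL

#' Docking-protocol configuration constants
#'
#' Records the ensemble-docking protocol as configuration: number of
#' templates selected by anchor-ligand similarity, the shape-restraint
#' weight handed to the docking engine, the binding-site distance cutoff
#' around the anchor ligand, and poses kept per template.
#'
#' @param n_templates templates selected per ligand (default 20).
#' @param shape_restraint_weight shape-restraint weighting (default -3).
#' @param site_cutoff binding-site cutoff around the anchor, Angstrom
#'   (default 8).
#' @param poses_per_template poses computed per template (default 1).
#' @return a `dockrf_protocol` list.
#' @export
docking_protocol <- function(n_templates = 20, shape_restraint_weight = -3,
                             site_cutoff = 8, poses_per_template = 1) {
  if (n_templates < 1 || site_cutoff <= 0 || poses_per_template < 1)
    stop_dockrf("invalid docking protocol configuration",
                class = "dockrf_validation_error")
  structure(list(n_templates = n_templates,
                 shape_restraint_weight = shape_restraint_weight,
                 site_cutoff = site_cutoff,
                 poses_per_template = poses_per_template),
            class = "dockrf_protocol")
}

#' Template library of receptor structures with anchor-ligand fingerprints
#'
#' @param template_id unique template identifiers.
#' @param fingerprints list of fingerprints of the co-crystallized (anchor)
#'   ligands.
#' @param anchor_pka optional known affinity of each anchor, pKa scale.
#' @return a `dockrf_template_library` data frame with a fingerprint
#'   list-column.
#' @export
template_library <- function(template_id, fingerprints, anchor_pka = NULL) {
  if (length(template_id) == 0L)
    stop_dockrf("empty template library", class = "dockrf_validation_error")
  if (anyDuplicated(template_id))
    stop_dockrf("duplicated template_id in library",
                class = "dockrf_validation_error")
  if (length(fingerprints) != length(template_id))
    stop_dockrf("one fingerprint per template required",
                class = "dockrf_validation_error")
  out <- data.frame(template_id = as.character(template_id),
                    stringsAsFactors = FALSE)
  out$fingerprint <- unname(fingerprints)
  out$anchor_pka <- anchor_pka %||% NA_real_
  class(out) <- c("dockrf_template_library", "data.frame")
  out
}

#' Select docking templates by anchor-ligand Tanimoto similarity
#'
#' Ranks templates by Tanimoto similarity between the candidate ligand's
#' fingerprint and each template's anchor fingerprint, descending; ties are
#' broken by ascending `template_id` so rankings are stable and prefix
#' rankings extend rather than reorder.
#'
#' @param candidate fingerprint of the ligand to dock.
#' @param library a [template_library()].
#' @param k number of templates (default 20). If `k` exceeds the library
#'   size, all templates are returned with a warning.
#' @return data frame `template_id`, `similarity`, ranked.
#' @export
select_templates <- function(candidate, library, k = 20) {
  if (!inherits(library, "dockrf_template_library") || nrow(library) == 0L)
    stop_dockrf("empty or invalid template library",
                class = "dockrf_validation_error")
  if (k < 1) stop_dockrf("k must be >= 1", class = "dockrf_validation_error")
  sim <- vapply(library$fingerprint, function(fp)
    suppressWarnings(tanimoto(candidate, fp)), numeric(1))
  ord <- order(-sim, library$template_id)
  if (k > nrow(library)) {
    warning(sprintf("k = %d exceeds library size %d; returning all templates",
                    k, nrow(library)))
    k <- nrow(library)
  }
  sel <- ord[seq_len(k)]
  data.frame(template_id = library$template_id[sel], similarity = sim[sel],
             stringsAsFactors = FALSE)
}

pose_rmsd <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop_dockrf("poses have mismatched atom counts",
                class = "dockrf_validation_error")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Cluster docking poses by coordinate RMSD (single linkage)
#'
#' Poses must share atom count and ordering and live in a common reference
#' frame (receptors pre-aligned). Two poses land in one cluster iff they are
#' connected by a chain of pairwise RMSD values at or below the threshold.
#' No symmetry correction is applied.
#'
#' @param poses list of n_atoms x 3 coordinate matrices.
#' @param rmsd_threshold Angstrom, default 2.0.
#' @return integer cluster assignment (1-based, numbered by first
#'   appearance), one entry per pose.
#' @export
cluster_poses <- function(poses, rmsd_threshold = 2.0) {
  if (length(poses) == 0L)
    stop_dockrf("empty pose list", class = "dockrf_validation_error")
  n <- length(poses)
  if (n == 1L) return(1L)
  dims <- vapply(poses, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop_dockrf("poses have mismatched atom counts: %s",
                paste(unique(dims), collapse = " vs "),
                class = "dockrf_validation_error")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      d[i, j] <- d[j, i] <- pose_rmsd(poses[[i]], poses[[j]])
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  cl <- stats::cutree(hc, h = rmsd_threshold)
  # renumber by first appearance for a stable labelling
  as.integer(factor(cl, levels = unique(cl)))
}

#' Select the representative pose: largest cluster, best consensus score
#'
#' The winner comes from the largest cluster; cluster-size ties are broken
#' by higher mean consensus score, then by first appearance. Within the
#' winning cluster the pose with the highest consensus score wins (stable on
#' ties).
#'
#' @param clusters integer cluster assignment from [cluster_poses()].
#' @param pose_scores consensus pKa score per pose.
#' @return index of the selected pose.
#' @export
select_best_pose <- function(clusters, pose_scores) {
  if (length(clusters) == 0L)
    stop_dockrf("empty clustering", class = "dockrf_validation_error")
  if (length(pose_scores) != length(clusters))
    stop_dockrf("one score per pose required", class = "dockrf_validation_error")
  ids <- unique(clusters)
  sizes <- vapply(ids, function(c) sum(clusters == c), integer(1))
  means <- vapply(ids, function(c) mean(pose_scores[clusters == c]), numeric(1))
  win <- ids[order(-sizes, -means)][1L]
  members <- which(clusters == win)
  if (anyNA(pose_scores[members]))
    stop_dockrf("missing consensus score for pose(s) %s in the winning cluster",
                paste(members[is.na(pose_scores[members])], collapse = ", "),
                class = "dockrf_missing_error")
  members[which.max(pose_scores[members])]
}

#' Aggregate per-pose metrics into per-ligand unified instances
#'
#' For every (ligand_id, representation_tag) group, computes the median
#' (even counts: midpoint of the central pair) and the sample standard
#' deviation (n-1 denominator) of each of the 19 metrics over the group's
#' poses.
#'
#' @param pose_table a `dockrf_pose_table`.
#' @param min_poses minimum poses per group (default 2; the SD is undefined
#'   below that). May be set to 1, in which case single-pose groups get
#'   SD = 0 with a warning.
#' @return a `dockrf_unified` data frame: `ligand_id`,
#'   `representation_tag`, `n_poses`, then `<Metric>_Med`, `<Metric>_SD`
#'   per metric in registry order.
#' @export
aggregate_metrics <- function(pose_table, min_poses = 2) {
  validate_pose_table(pose_table)
  for (m in METRIC_NAMES) {
    if (!is.numeric(pose_table[[m]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(pose_table[[m]]))))[1L]
      stop_dockrf("non-numeric value in column '%s' (row %d)", m, bad,
                  class = "dockrf_validation_error")
    }
  }
  key <- interaction(pose_table$ligand_id, pose_table$representation_tag,
                     drop = TRUE, lex.order = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(pose_table)), key)
  small <- names(groups)[lengths(groups) < min_poses]
  if (length(small))
    stop_dockrf("group(s) with fewer than %d poses: %s", min_poses,
                paste(gsub("\r", "/", small), collapse = ", "),
                class = "dockrf_validation_error")
  singletons <- any(lengths(groups) == 1L)
  if (singletons)
    warning("single-pose group(s): SD set to 0")
  rows <- lapply(groups, function(idx) {
    g <- pose_table[idx, , drop = FALSE]
    out <- list(ligand_id = g$ligand_id[1L],
                representation_tag = g$representation_tag[1L],
                n_poses = length(idx))
    for (m in METRIC_NAMES) {
      v <- g[[m]]
      out[[paste0(m, "_Med")]] <- median(v)
      out[[paste0(m, "_SD")]] <- if (length(v) > 1L) sd(v) else 0
    }
    out
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("dockrf_unified", "data.frame")
  out
}

#: structure-feature names, registry order, Med before SD per metric
structure_feature_names <- function()
  as.vector(rbind(paste0(METRIC_NAMES, "_Med"), paste0(METRIC_NAMES, "_SD")))

FEATURE_MODES <- c("structure_only", "ligand_only", "combined",
                   "combined_engineered", "maccs_only", "combined_maccs")

#' Assemble model-ready feature rows from unified instances and descriptors
#'
#' Joins unified docking instances with per-ligand descriptors (by
#' `ligand_id`; descriptors are 2D properties shared by all representation
#' tags) and selects one of the fixed feature sets:
#'
#' * `structure_only`: 38 features (19 metrics x Med/SD);
#' * `ligand_only`: the 11 descriptors;
#' * `combined`: 49;
#' * `combined_engineered`: 48 -- `nRotBond` and `nBond` replaced by the
#'   flexibility ratio `nRotB.nB`;
#' * `maccs_only`: the 166 MACCS bits;
#' * `combined_maccs`: 49 + 166.
#'
#' Feature order is frozen: structure features in metric-registry order
#' (Med, SD interleaved), then descriptors in table order, then MACCS bits.
#'
#' @param unified a `dockrf_unified` table ([aggregate_metrics()]); may be
#'   `NULL` for the ligand-only/MACCS-only modes.
#' @param descriptors a `dockrf_descriptors` table; may be `NULL` for
#'   structure-only mode.
#' @param mode one of the six feature-set selectors.
#' @param maccs named list of fingerprints (by ligand_id) for the MACCS
#'   modes.
#' @return a `dockrf_features` data frame: `ligand_id`,
#'   `representation_tag`, then the selected feature columns.
#' @export
assemble_features <- function(unified = NULL, descriptors = NULL,
                              mode = "combined", maccs = NULL) {
  if (!mode %in% FEATURE_MODES)
    stop_dockrf("unknown feature mode '%s' (expected one of %s)", mode,
                paste(FEATURE_MODES, collapse = ", "),
                class = "dockrf_validation_error")
  need_struct <- mode %in% c("structure_only", "combined",
                             "combined_engineered", "combined_maccs")
  need_desc <- mode %in% c("ligand_only", "combined", "combined_engineered",
                           "combined_maccs")
  need_maccs <- mode %in% c("maccs_only", "combined_maccs")
  if (need_struct && is.null(unified))
    stop_dockrf("mode '%s' needs a unified instance table", mode,
                class = "dockrf_validation_error")
  if (need_desc && is.null(descriptors))
    stop_dockrf("mode '%s' needs a descriptor table", mode,
                class = "dockrf_validation_error")
  if (need_maccs && is.null(maccs))
    stop_dockrf("mode '%s' needs MACCS fingerprints", mode,
                class = "dockrf_validation_error")

  base <- if (!is.null(unified))
    unified[, c("ligand_id", "representation_tag"), drop = FALSE]
  else
    descriptors[, c("ligand_id", "representation_tag"), drop = FALSE]
  out <- base

  if (need_struct)
    out <- cbind(out, unified[, structure_feature_names(), drop = FALSE])

  if (need_desc || mode == "maccs_only") {
    if (!is.null(unified) && !is.null(descriptors)) {
      i <- match(out$ligand_id, descriptors$ligand_id)
      if (anyNA(i))
        stop_dockrf("no descriptors for ligand(s): %s",
                    paste(unique(out$ligand_id[is.na(i)]), collapse = ", "),
                    class = "dockrf_validation_error")
      drow <- descriptors[i, , drop = FALSE]
    } else drow <- descriptors
    if (need_desc) {
      if (mode == "combined_engineered") {
        keep <- setdiff(LIGAND_DESCRIPTORS, c("nRotBond", "nBond"))
        dpart <- drow[, keep, drop = FALSE]
        dpart[["nRotB.nB"]] <- drow$nRotB_nB
      } else {
        dpart <- drow[, LIGAND_DESCRIPTORS, drop = FALSE]
      }
      rownames(dpart) <- NULL
      out <- cbind(out, dpart)
    }
  }

  if (need_maccs) {
    i <- match(out$ligand_id, names(maccs))
    if (anyNA(i))
      stop_dockrf("no MACCS fingerprint for ligand(s): %s",
                  paste(unique(out$ligand_id[is.na(i)]), collapse = ", "),
                  class = "dockrf_validation_error")
    bits <- matrix(0L, nrow(out), 166,
                   dimnames = list(NULL, paste0("MACCS_", 1:166)))
    for (r in seq_len(nrow(out))) {
      on <- maccs[[i[r]]]
      if (length(on)) bits[r, on] <- 1L
    }
    out <- cbind(out, as.data.frame(bits))
  }

  rownames(out) <- NULL
  attr(out, "feature_mode") <- mode
  class(out) <- c("dockrf_features", "data.frame")
  out
}

#' Names of the feature columns of an assembled feature table
#' @param features a `dockrf_features` or dataset table.
#' @export
feature_names <- function(features) {
  setdiff(names(features),
          c("ligand_id", "representation_tag", "n_poses", "p_affinity"))
}

#' Write / read a unified-instance table (CSV)
#'
#' Header: `ligand_id, representation_tag, n_poses`, then `<Metric>_Med`,
#' `<Metric>_SD` for the 19 metrics in registry order.
#'
#' @param unified a `dockrf_unified` table.
#' @param path CSV path.
#' @export
write_unified_table <- function(unified, path) {
  cols <- c("ligand_id", "representation_tag", "n_poses",
            structure_feature_names())
  write.csv(unified[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_unified_table
#' @export
read_unified_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(ligand_id = "character",
                                 representation_tag = "character"))
  miss <- setdiff(c("ligand_id", "representation_tag", "n_poses",
                    structure_feature_names()), names(out))
  if (length(miss))
    stop_dockrf("unified table missing column(s): %s",
                paste(miss, collapse = ", "), class = "dockrf_schema_error")
  class(out) <- c("dockrf_unified", "data.frame")
  out
}
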