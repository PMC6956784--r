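#' Synthetic ensemble-docking benchmark
#'
#' Generates complete offline studies emulating the statistical structure of
#' an ensemble-docking + rescoring run: a latent p-affinity per ligand, a
#' template library with anchor similarities, per-pose metric tables whose
#' pKa-scale scores track the latent affinity noisily (optionally modulated
#' by anchor similarity), raw-scale scores derived through inverse
#' calibration lines, a descriptor table with a configurable amount of
#' independent ligand-channel signal, and affinity labels. Multiple
#' representation tags share the latent affinity but re-draw all noise,
#' emulating conformer/charge-model variation.
#'
#' What the generator does NOT emulate: real chemistry (descriptors are
#' drawn from plausible ranges, not computed from structures), receptor
#' geometry, and the heavy-tailed error structure of real scoring
#' functions.
#'
#' @name synthetic_benchmark
NULL

#' Default raw-score calibration lines used by the simulator
#'
#' Slopes are negative: the native Plants/MedusaScore/DSX scores are
#' lower-is-better energies.
#' @return named list of `dockrf_calibration` objects.
#' @export
default_calibration <- function() {
  list(Plants = calibration_line("Plants", -0.05, 1.5),
       MedusaScore = calibration_line("MedusaScore", -0.12, 0.8),
       DSX = calibration_line("DSX", -0.06, 0.5))
}

#' Simulation configuration
#'
#' @param n_ligands ligands to simulate.
#' @param n_templates_library receptor templates in the library (default 60).
#' @param n_templates_selected templates kept per ligand by anchor
#'   similarity (default 20, one pose each).
#' @param p_affinity_range latent label range, pKa units (default
#'   `c(4, 14)`: about ten orders of magnitude).
#' @param tags representation tags to emit (default `"BDB"`).
#' @param signal_slope slope `a` of pKa-scale scoring metrics vs the latent
#'   affinity (default 1).
#' @param sigma per-metric score noise SD, pKa units (default 0.8).
#' @param tau per-pose jitter SD shared by the signal metrics of one pose
#'   (default 0.5).
#' @param theta in `[0, 1]`: how strongly metric quality couples to anchor
#'   similarity (`m ~ a * (theta * T + (1 - theta)) * pKa`; default 0.3).
#' @param descriptor_signal in `[0, 1]`: strength of the independent
#'   affinity signal carried by the informative descriptors (XLogP, the
#'   rotatable-bond fraction and MW; default 0.5).
#' @param seed integer; a study is bit-reproducible from (config, seed).
#' @return a `dockrf_sim_config` list.
#' @export
simulation_config <- function(n_ligands, n_templates_library = 60,
                              n_templates_selected = 20,
                              p_affinity_range = c(4, 14), tags = "BDB",
                              signal_slope = 1, sigma = 0.8, tau = 0.5,
                              theta = 0.3, descriptor_signal = 0.5,
                              seed = 1) {
  if (n_ligands < 1 || n_templates_library < 1 || n_templates_selected < 1)
    stop_dockrf("counts must be >= 1", class = "dockrf_validation_error")
  if (n_templates_selected > n_templates_library)
    stop_dockrf("cannot select more templates than the library holds",
                class = "dockrf_validation_error")
  if (sigma < 0 || tau < 0 || theta < 0 || theta > 1)
    stop_dockrf("need sigma, tau >= 0 and theta in [0, 1]",
                class = "dockrf_validation_error")
  if (diff(range(p_affinity_range)) <= 0)
    stop_dockrf("empty p_affinity range", class = "dockrf_validation_error")
  structure(list(n_ligands = n_ligands,
                 n_templates_library = n_templates_library,
                 n_templates_selected = n_templates_selected,
                 p_affinity_range = sort(p_affinity_range), tags = tags,
                 signal_slope = signal_slope, sigma = sigma, tau = tau,
                 theta = theta, descriptor_signal = descriptor_signal,
                 seed = as.integer(seed)),
            class = "dockrf_sim_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Per-pose metric block for one representation tag.
sim_pose_tag <- function(cfg, tag, ids, pka, sel_templates, sel_T, cal) {
  n_pose <- cfg$n_templates_selected
  N <- cfg$n_ligands * n_pose
  pka_row <- rep(pka, each = n_pose)
  T_row <- as.vector(t(sel_T))
  q <- cfg$theta * T_row + (1 - cfg$theta)     # similarity-coupled quality
  jitter <- rnorm(N, 0, cfg$tau)               # shared per-pose jitter
  sig <- function(a, b, nu)                    # pKa-scale signal metric
    a * q * pka_row + b + jitter + rnorm(N, 0, nu * cfg$sigma)
  aux <- function(a, b, nu) a * pka_row + b + rnorm(N, 0, nu * cfg$sigma)

  a <- cfg$signal_slope
  PlantsLR <- sig(a, 0, 1)
  MedusaLR <- sig(a, 0, 1)
  XScore   <- sig(a, 0, 1)
  DSXLR    <- sig(a, 0, 1)
  df <- data.frame(
    ligand_id = rep(ids, each = n_pose),
    representation_tag = tag,
    template_id = as.vector(t(sel_templates)),
    stringsAsFactors = FALSE)
  df$Plants <- (PlantsLR - cal$Plants$intercept) / cal$Plants$slope
  df$PlantsFull <- df$Plants + (-3) * 10 * T_row + rnorm(N, 0, cfg$sigma)
  df$PlantsLR <- PlantsLR
  df$MedusaScore <- (MedusaLR - cal$MedusaScore$intercept) /
    cal$MedusaScore$slope
  df$MedusaLR <- MedusaLR
  df$XScore <- XScore
  df$DSX <- (DSXLR - cal$DSX$intercept) / cal$DSX$slope
  df$DSXLR <- DSXLR
  df$AtomeScore <- (PlantsLR + XScore + MedusaLR + DSXLR) / 4
  df$Tanimoto <- T_row
  df$AtomSA <- aux(0.2, 2, 2)
  df$QMean <- 0.6 + 0.25 * T_row + rnorm(N, 0, 0.1 * cfg$sigma)
  df$AnchKd <- sig(0.5 * a, 3, 2)
  df$AnchorFit <- 5 + 4 * T_row + rnorm(N, 0, 0.6 * cfg$sigma)
  df$LigandEnergy <- aux(0, 40, 12)
  df$LPC <- aux(0.15, 2, 1.2)
  df$PSim <- aux(0.03, 0.3, 0.2)
  df$CpxQuality <- 0.3 + 0.4 * T_row + rnorm(N, 0, 0.2 * cfg$sigma)
  df$LPE <- aux(0, 2, 1)
  as_pose_table(df[, c(POSE_KEY, METRIC_NAMES)])
}

sim_descriptors <- function(cfg, ids, pka) {
  n <- cfg$n_ligands
  s <- cfg$descriptor_signal
  mid <- mean(cfg$p_affinity_range)
  z <- (pka - mid) / (diff(cfg$p_affinity_range) / 2)  # in ~[-1, 1]

  nBond <- round(runif(n, 12, 40))
  # tighter binders tend to be more rigid: the flexibility latent falls with z
  flex <- stats::plogis(-1 - 1.5 * s * z + rnorm(n, 0, 0.7))
  nRotBond <- clamp(round(flex * 0.45 * nBond), 0, nBond)
  nAromBond <- round(runif(n, 0, 0.6) * nBond)
  nHBDon <- stats::rpois(n, 1.5)
  nHBAcc <- stats::rpois(n, 3)
  out <- data.frame(
    ligand_id = ids, representation_tag = "user",
    MW = 320 + 80 * s * z + rnorm(n, 0, 50),
    VABC = 14.5 * (nBond + 1) + rnorm(n, 0, 15),
    nAtom = pmax(nBond + 1, round(2.1 * nBond + rnorm(n, 0, 3))),
    nBond = nBond, nRotBond = nRotBond, nAromBond = nAromBond,
    nHBDon = nHBDon, nHBAcc = nHBAcc,
    TPSA = pmax(0, 20 * nHBDon + 9 * nHBAcc + rnorm(n, 0, 8)),
    XLogP = 3 + 2 * s * z + rnorm(n, 0, 1.2 * (1 - s) + 0.3),
    HybRatio = clamp(1 - nAromBond / nBond + rnorm(n, 0, 0.05), 0, 1),
    stringsAsFactors = FALSE)
  out$nRotB_nB <- out$nRotBond / out$nBond
  class(out) <- c("dockrf_descriptors", "data.frame")
  out
}

#' Generate a complete synthetic study
#'
#' @param config a [simulation_config()].
#' @return a `dockrf_study` list: `config`, `ground_truth` (ligand_id,
#'   p_affinity), `affinity` (Ki records whose nM values round-trip to the
#'   latent labels), `descriptors`, `poses` (named list of pose tables, one
#'   per representation tag), `template_similarity` (selected anchor
#'   Tanimoto values per ligand) and `calibration` (the raw-score lines
#'   used).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "dockrf_sim_config"))
  cal <- default_calibration()
  withr::with_seed(config$seed, {
    n <- config$n_ligands
    ids <- sprintf("L%04d", seq_len(n))
    pka <- runif(n, config$p_affinity_range[1], config$p_affinity_range[2])
    lib_ids <- sprintf("T%03d", seq_len(config$n_templates_library))
    # anchor similarity per (ligand, library template); top-k kept
    k <- config$n_templates_selected
    sel_templates <- matrix("", n, k)
    sel_T <- matrix(0, n, k)
    for (i in seq_len(n)) {
      Tli <- runif(config$n_templates_library, 0.05, 0.95)
      ord <- order(-Tli, lib_ids)[seq_len(k)]
      sel_templates[i, ] <- lib_ids[ord]
      sel_T[i, ] <- Tli[ord]
    }
    poses <- lapply(config$tags, function(tag)
      sim_pose_tag(config, tag, ids, pka, sel_templates, sel_T, cal))
    names(poses) <- config$tags
    desc <- sim_descriptors(config, ids, pka)
    gt <- data.frame(ligand_id = ids, p_affinity = pka,
                     stringsAsFactors = FALSE)
    aff <- affinity_records(ids, "Ki", 10^(9 - pka), "nM")
    structure(list(config = config, ground_truth = gt, affinity = aff,
                   descriptors = desc, poses = poses,
                   template_similarity = sel_T, calibration = cal),
              class = "dockrf_study")
  })
}

#' Write a study to a directory of CSV files
#'
#' Emits `affinity.csv`, `descriptors.csv`, `ground_truth.csv`,
#' `poses_<tag>.csv` and `calibration.json` in the package's standard
#' schemas.
#'
#' @param study a `dockrf_study`.
#' @param dir output directory (created if missing).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_affinity_table(study$affinity, file.path(dir, "affinity.csv"))
  write_descriptor_table(study$descriptors, file.path(dir, "descriptors.csv"))
  write.csv(study$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE, quote = FALSE)
  for (tag in names(study$poses))
    write_pose_table(study$poses[[tag]],
                     file.path(dir, paste0("poses_", tag, ".csv")))
  write_calibration_config(study$calibration,
                           file.path(dir, "calibration.json"))
  invisible(dir)
}

#' Build a model-ready dataset from a study
#'
#' Aggregates every pose table, assembles the requested feature mode and
#' attaches labels; multiple tags are concatenated row-wise.
#'
#' @param study a `dockrf_study`.
#' @param mode feature mode (see [assemble_features()]; MACCS modes are not
#'   available for synthetic studies, which have no structures).
#' @param permute_labels permute labels across ligands (null control).
#' @param permute_seed seed for the permutation.
#' @return a `dockrf_dataset`.
#' @export
study_dataset <- function(study, mode = "combined", permute_labels = FALSE,
                          permute_seed = study$config$seed + 1L) {
  if (mode %in% c("maccs_only", "combined_maccs"))
    stop_dockrf("MACCS modes need real structures; not available for synthetic studies",
                class = "dockrf_validation_error")
  aff <- study$affinity
  if (permute_labels)
    aff$p_affinity <- withr::with_seed(permute_seed,
                                       sample(aff$p_affinity))
  per_tag <- lapply(names(study$poses), function(tag) {
    unified <- aggregate_metrics(study$poses[[tag]])
    feats <- assemble_features(unified, study$descriptors, mode = mode)
    build_dataset(feats, aff)
  })
  out <- do.call(rbind, c(per_tag, make.row.names = FALSE))
  attr(out, "feature_mode") <- mode
  class(out) <- c("dockrf_dataset", "data.frame")
  out
}

#' End-to-end recovery experiment
#'
#' Runs generate -> aggregate -> assemble -> stratified split -> train ->
#' evaluate and returns the held-out evaluation plus the importance table.
#'
#' @param config a [simulation_config()].
#' @param mode feature mode (default `"combined"`).
#' @param test_fraction,n_bins hold-out layout (defaults 0.2 / 5).
#' @param n_trees,min_node,mtry forest controls; `mtry = NULL` uses p/3
#'   without tuning (set `tune = TRUE` for the cross-validated grid).
#' @param tune run CV-based mtry selection (default FALSE: tuning is slow
#'   and orthogonal to recovery checks).
#' @param permute_labels label-permutation null control (default FALSE).
#' @param seed experiment seed; defaults to the config seed.
#' @return list: `report` (held-out `dockrf_report`), `importance`,
#'   `model`, `n_train`, `n_test`, `seeds`.
#' @export
recovery_experiment <- function(config, mode = "combined",
                                test_fraction = 0.2, n_bins = 5,
                                n_trees = 300, min_node = 5, mtry = NULL,
                                tune = FALSE, permute_labels = FALSE,
                                seed = config$seed) {
  study <- generate_study(config)
  data <- study_dataset(study, mode = mode, permute_labels = permute_labels,
                        permute_seed = seed + 1L)
  split <- stratified_holdout(data, test_fraction = test_fraction,
                              n_bins = n_bins, seed = seed + 2L)
  p <- length(feature_names(data))
  model <- train_rf(split$train,
                    mtry_grid = if (tune) NULL else (mtry %||% max(1L, p %/% 3L)),
                    n_trees = n_trees, min_node = min_node, seed = seed + 3L,
                    k = 10, repeats = if (tune) 3 else 1)
  pred <- predict(model, split$test)
  list(report = evaluate(pred, split$test$p_affinity),
       importance = variable_importance(model),
       model = model,
       n_train = nrow(split$train), n_test = nrow(split$test),
       seeds = c(study = config$seed, split = seed + 2L, train = seed + 3L))
}
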