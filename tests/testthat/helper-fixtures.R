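# Shared fixture builders. Everything is generated in code; no binary data.

# A random but schema-valid pose table: n_lig ligands x n_pose poses.
random_pose_table <- function(n_lig = 5, n_pose = 4, tag = "BDB", seed = 1) {
  withr::with_seed(seed, {
    rows <- expand.grid(pose = seq_len(n_pose), lig = seq_len(n_lig))
    df <- data.frame(ligand_id = sprintf("L%02d", rows$lig),
                     representation_tag = tag,
                     template_id = sprintf("T%02d", rows$pose),
                     stringsAsFactors = FALSE)
    for (m in dockrf::metric_schema()$metric)
      df[[m]] <- if (m == "Tanimoto") runif(nrow(df)) else rnorm(nrow(df), 0, 5)
    dockrf::as_pose_table(df)
  })
}

# Independent textbook-formula evaluation oracle (kept free of evaluate()).
oracle_metrics <- function(pred, obs) {
  n <- length(obs)
  rp <- sum((pred - mean(pred)) * (obs - mean(obs))) /
    sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  rk_p <- rank(pred); rk_o <- rank(obs)  # average ranks on ties
  rs <- sum((rk_p - mean(rk_p)) * (rk_o - mean(rk_o))) /
    sqrt(sum((rk_p - mean(rk_p))^2) * sum((rk_o - mean(rk_o))^2))
  list(rP = rp, rS = rs,
       R2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
       RMSE = sqrt(sum((obs - pred)^2) / n))
}

# A small regression dataset with a known generative model:
# y = 2 f1 - f2 + 0.5 f3 (+ optional noise); f4.. are pure noise.
linear_dataset <- function(n = 200, p_noise = 5, noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * (3 + p_noise)), n,
                dimnames = list(NULL, paste0("f", seq_len(3 + p_noise))))
    y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3] + rnorm(n, 0, noise_sd)
    out <- data.frame(ligand_id = sprintf("L%04d", seq_len(n)),
                      representation_tag = "BDB", p_affinity = y)
    out <- cbind(out, as.data.frame(X))
    class(out) <- c("dockrf_dataset", "data.frame")
    out
  })
}

# Two V2000 SDF renderings of ethanol with permuted atom order.
ethanol_sdf <- function(path, permuted = FALSE) {
  block <- if (!permuted) c(
    "ethanol", "  fixture", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0", "M  END", "$$$$")
  else c(
    "ethanol", "  fixture", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    2.1000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  2  3  1  0", "  3  1  1  0", "M  END", "$$$$")
  writeLines(block, path)
  path
}
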