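#!/usr/bin/env Rscript
# Pilot run that informed the frozen acceptance thresholds (recorded in the
# methods vignette). Run once before the thresholds were fixed; kept in the
# repository for provenance. Usage: Rscript scripts/pilot.R

suppressPackageStartupMessages(library(dockrf))

cat("== low-noise recovery (n = 400, sigma = 0.3, tau = 0.2), 5 seeds ==\n")
rp <- vapply(1:5, function(s)
  recovery_experiment(simulation_config(400, sigma = 0.3, tau = 0.2,
                                        seed = 400 + s),
                      n_trees = 300)$report$rP, numeric(1))
cat(sprintf("held-out rP: %s  (mean %.3f)\n",
            paste(sprintf("%.3f", rp), collapse = " "), mean(rp)))

cat("== permuted-label null, 5 seeds ==\n")
rp0 <- vapply(1:5, function(s)
  recovery_experiment(simulation_config(400, sigma = 0.3, tau = 0.2,
                                        seed = 500 + s),
                      n_trees = 300, permute_labels = TRUE)$report$rP,
  numeric(1))
cat(sprintf("null rP: %s  (mean %.3f)\n",
            paste(sprintf("%.3f", rp0), collapse = " "), mean(rp0)))

cat("== feature-mode ordering (default regime, n = 300), 10 seeds ==\n")
res <- vapply(1:10, function(s) {
  cfg <- simulation_config(300, seed = 700 + s)
  vapply(c("structure_only", "ligand_only", "combined"), function(mode)
    recovery_experiment(cfg, mode = mode, n_trees = 150)$report$rP,
    numeric(1))
}, numeric(3))
cat(sprintf("structure > ligand in %d/10; combined > ligand in %d/10\n",
            sum(res["structure_only", ] > res["ligand_only", ]),
            sum(res["combined", ] > res["ligand_only", ])))
cat(sprintf("mean rP: structure %.3f, ligand %.3f, combined %.3f\n",
            mean(res["structure_only", ]), mean(res["ligand_only", ]),
            mean(res["combined", ])))
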