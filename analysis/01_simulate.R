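#!/usr/bin/env Rscript
# Generate the synthetic study cohort: nine miFISH samples spanning the
# founder scenarios (diploid, WGD-tetraploid, hypodiploid) at increasing
# clonal complexity, written as signal TSVs with their ground truth, plus
# the reconstruction of the published low-instability diploid case from
# its printed signal patterns.

library(mifishr)

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

founders <- c("diploid", "wgd_tetraploid", "hypodiploid")
manifest <- list()
for (f in founders) {
  for (k in c(1L, 3L, 5L)) {
    id <- sprintf("%s_k%d", f, k)
    sim <- simulate_sample(sim_config(seed = 100L * k + match(f, founders),
                                      founder = f, n_clones = k))
    path <- file.path(out, paste0(id, ".tsv"))
    write_signal_table(sim$records, path)
    manifest[[id]] <- list(
      path = path, founder = f, n_clones = k,
      true_ploidy = sim$truth$ploidy,
      true_ploidy_class = sim$truth$ploidy_class,
      major_clone_frequency = max(sim$truth$frequencies))
  }
}
yaml::write_yaml(manifest, file.path(out, "ground_truth.yaml"))

# published-case reconstruction shipped with the package
src <- system.file("extdata", "case7L_reconstruction_synthetic.tsv",
                   package = "mifishr")
stopifnot(nzchar(src),
          file.copy(src, file.path(out, "case7L_reconstruction.tsv"),
                    overwrite = TRUE))

cat(sprintf("wrote %d simulated samples + 1 reconstruction to %s\n",
            length(manifest), out))
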