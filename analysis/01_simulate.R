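#!/usr/bin/env Rscript
# Generate the synthetic TIRF data underlying the whole analysis: one
# vesicle-dynamics movie (continuous 2 Hz) and one translocation-kinetics
# movie (10-frame bursts at 1-min time points), both with exported
# per-vesicle ground truth, written under results/data/.
#
# These are single representative realisations for inspection; the
# replicate studies in 03/04 regenerate their movies internally.

suppressPackageStartupMessages(library(tirfdyn))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("-- dynamics movie (docked 4 -> 3 per 100 um^2; mobile visits 1 -> 2 per 100 um^2/min)")
sim_d <- simulate_tirf_movie(dynamics_study_config(seed = 1),
                             dynamics_geometry())
write_movie(sim_d$movie, file.path(out, "dynamics_movie.tif"),
            extra = list(seed = 1))
write_truth(sim_d$truth, file.path(out, "dynamics_truth.csv"))
print(sim_d$movie)
cat(sprintf("ground truth: %d vesicle-frame records, %d distinct vesicles\n",
            nrow(sim_d$truth), length(unique(sim_d$truth$id))))

message("-- kinetics movie (HeLa-like: fold 1.89, half-time 17.1 min)")
sim_k <- simulate_tirf_movie(kinetics_study_config(1.89, 17.1, seed = 1),
                             kinetics_geometry())
write_movie(sim_k$movie, file.path(out, "kinetics_movie.tif"),
            extra = list(seed = 1))
write_truth(sim_k$truth, file.path(out, "kinetics_truth.csv"))
print(sim_k$movie)

message("-- calibration bead (10 um, rendered at d = 110 nm)")
geo_b <- acquisition_geometry(pixel_size = 0.1, penetration_depth = 110)
bead <- simulate_bead_image(geo_b, bead_diameter = 10, brightness = 1000)
write.csv(bead, file.path(out, "bead_image.csv"), row.names = FALSE)
cat(sprintf("bead image %d x %d px, peak %g\n", nrow(bead), ncol(bead),
            max(bead)))
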