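#!/usr/bin/env Rscript
# Step 1 — simulate the study's synthetic subjects.
#
# Builds one verapamil-like dynamic acquisition with a 5-mm
# transmission-emission mismatch (the artefact-prone case) and one
# aligned raclopride-like acquisition, and writes both to
# results/acquisitions/ as sinogram containers + NIfTI ground truth with
# a JSON manifest. Later steps re-simulate internally (everything is
# seeded), so this step mainly documents what the inputs look like.

suppressPackageStartupMessages(library(acfmargin))
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "_common.R"))

dir.create("results/acquisitions", recursive = TRUE, showWarnings = FALSE)

ph <- make_head_phantom(do.call(phantom_spec, BENCH_PHANTOM), BENCH_GEO,
                        nx = 40)
inp <- make_input_function()

acq_ver <- simulate_acquisition(
  ph, tracer_profile("verapamil_like"),
  make_frame_schedule("verapamil_raclopride"), inp, BENCH_GEO,
  mismatch = rigid_shift(5, 0, 0), scatter_fraction = 0.35,
  counts_total = 2e7, seed = 1001L, sss_args = SARGS)
save_acquisition(acq_ver, "results/acquisitions/verapamil_shift5")
message("verapamil-like, 5-mm mismatch: ",
        length(acq_ver$frames), " frames, ",
        round(sum(vapply(acq_ver$frames,
                         function(f) sum(f$emission$values), 1)) / 1e6, 1),
        "M counts, scatter fraction ", acq_ver$scatter_fraction)

acq_rac <- simulate_acquisition(
  ph, tracer_profile("raclopride_like"),
  make_frame_schedule("verapamil_raclopride"), inp, BENCH_GEO,
  mismatch = rigid_shift(0, 0, 0), scatter_fraction = 0.35,
  counts_total = 2e7, seed = 2001L, sss_args = SARGS)
save_acquisition(acq_rac, "results/acquisitions/raclopride_aligned")
message("raclopride-like, aligned: written")

message("done: results/acquisitions/")
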