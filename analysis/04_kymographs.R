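#!/usr/bin/env Rscript
# Builds kymographs along each neurite of the first cell of every comet run
# and fits the dominant line slope, the classical visual read-out of comet
# direction.  Writes kymograph TIFFs next to the movies.

suppressMessages(library(neuritemt))
root <- "results/runs"
runs <- list.files(root, pattern = "^comets_", full.names = TRUE)
if (!length(runs)) stop("no comet runs found; run analysis/01_simulate.R first")

for (dir in runs) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cell <- man$cells[[1]]
  movie <- read_movie(file.path(dir, cell$movie))
  rois <- read_roi(file.path(dir, cell$rois))
  for (roi in rois) {
    ky <- make_kymograph(movie, roi, "particles", 5)
    f <- file.path(dir, sprintf("%s_kymo_n%02d.tif", cell$tag, roi$neurite_id))
    write_kymograph(ky, f)
    spd <- tryCatch(kymograph_speed(ky), error = function(e) NULL)
    cat(sprintf("%-22s neurite %d: kymograph %d x %d px%s\n",
                basename(dir), roi$neurite_id, nrow(ky$image), ncol(ky$image),
                if (is.null(spd)) "" else
                  sprintf(", dominant slope %+.3f um/s", spd$speed_um_s)))
  }
}
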