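#!/usr/bin/env Rscript
# Process the simulated FIDs: 0.3 Hz exponential apodization, zero filling,
# Fourier transform, automatic phasing, polynomial baseline correction and
# ppm calibration on the residual DMSO line. Writes processed spectra as
# JCAMP-DX with the processing log in the header and as a sidecar CSV.

library(arsqnmr)

in_dir <- "results/sim"
out_dir <- "results/processed"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

fid_files <- list.files(in_dir, pattern = "\\.fid\\.dx$", full.names = TRUE)
stopifnot(length(fid_files) > 0)

for (f in fid_files) {
  fid <- read_jcamp(f)
  spec <- process_fid(fid, phase_with = "auto")
  stem <- sub("\\.fid\\.dx$", "", basename(f))
  out <- file.path(out_dir, paste0(stem, ".spec.dx"))
  write_jcamp(spec, out, title = stem)
  write.csv(data.frame(step = spec$processing_log),
            file.path(out_dir, paste0(stem, ".processing_log.csv")),
            row.names = FALSE)
  cat(sprintf("%s:\n  %s\n", stem,
              paste(spec$processing_log, collapse = "\n  ")))
}
cat(sprintf("\n%d spectra processed into %s.\n", length(fid_files), out_dir))
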