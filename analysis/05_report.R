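#!/usr/bin/env Rscript
# Published-table-style summary: noise-free end-to-end quantification of
# every preset (flours, grains, processed products), with ND calls for the
# ARS-free matrices, next to the published concentrations.

library(arsqnmr)

seed <- 20L
tab <- published_presets()

rows <- lapply(seq_len(nrow(tab)), function(i) {
  s <- preset_sample(tab$preset[i], seed = seed + i)
  # ARS-free matrices need the noise floor for an honest ND call
  sigma <- if (tab$ars_mg_per_kg[i] == 0) default_noise_sigma() else 0
  q <- quantify_sample(s, noise_sigma = sigma)
  r <- report_rounding(q$c_mg_per_kg, q$c_mmol_per_kg)
  data.frame(category = tab$category[i], sample = tab$matrix_name[i],
             published_mg_per_kg = ifelse(tab$ars_mg_per_kg[i] == 0, NA,
                                          tab$ars_mg_per_kg[i]),
             measured_mg_per_kg = if (q$status == "nd") NA else r$c_mg_per_kg,
             measured_mmol_per_kg = if (q$status == "nd") NA else r$c_mmol_per_kg,
             status = q$status, stringsAsFactors = FALSE)
})
summary_tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(summary_tab, "results/table_summary.csv", row.names = FALSE)

print(summary_tab, row.names = FALSE)
ok <- !is.na(summary_tab$published_mg_per_kg)
err <- with(summary_tab[ok, ], 100 * abs(measured_mg_per_kg /
                                           published_mg_per_kg - 1))
cat(sprintf("\nmax |error| over quantifiable presets: %.1f%%; ND matrices: %d.\n",
            max(err), sum(!ok)))
cat("summary written to results/table_summary.csv\n")
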