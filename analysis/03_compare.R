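#!/usr/bin/env Rscript

# Step 3 -- model selection.
#
# Collects the per-participant BIC values from step 2, sums them per design,
# ranks the designs, and compares the winner against the runner-up with the
# nonparametric sign test on per-participant BIC differences.
#
# Writes results/comparison/ranking.csv and comparison.json.

suppressPackageStartupMessages(library(lbadecide))

in_dir <- "results/fits"
out_dir <- "results/comparison"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

files <- list.files(in_dir, pattern = "^fit_p.*\\.json$", full.names = TRUE)
stopifnot(length(files) > 0)
info <- do.call(rbind, lapply(files, function(f) {
  js <- jsonlite::fromJSON(f)
  m <- regmatches(f, regexec("fit_p([0-9]+)_d([0-9]+)", f))[[1]]
  data.frame(participant = as.integer(m[2]), design = as.integer(m[3]),
             bic = js$bic, k = js$k)
}))

designs <- sort(unique(info$design))
bic <- matrix(NA_real_, length(unique(info$participant)), length(designs),
              dimnames = list(NULL, paste0("design_", designs)))
for (i in seq_len(nrow(info)))
  bic[info$participant[i], match(info$design[i], designs)] <- info$bic[i]

kvec <- info$k[match(designs, info$design)]
cmp <- rank_designs(bic, n_params = kvec, design_index = designs)
print(cmp)

best <- cmp$ranking$design[1]
second <- cmp$ranking$design[2]
dif <- bic[, second] - bic[, best]
st <- sign_test(dif)
cat(sprintf(
  "sign test, %s vs %s: %d of %d participants favour the winner, p = %.4f\n",
  best, second, st$statistic, st$n, st$p.value))

write_design_comparison(cmp, csv = file.path(out_dir, "ranking.csv"),
                        json = file.path(out_dir, "comparison.json"))
cat("wrote", file.path(out_dir, "ranking.csv"), "\n")
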