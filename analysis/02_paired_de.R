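#!/usr/bin/env Rscript
# Stage 2: donor-paired differential expression over the demo cohort.
#
# Fits every left-right (LR) contrast and every within-hemisphere (WH)
# area pair with the moderated-t engine, then applies the four-level
# FDR adjustment (within contrast, global, within family, within
# functional module).

suppressMessages(library(hemivox))
dir.create("results/de", recursive = TRUE, showWarnings = FALSE)

dat <- read_counts("results/cohort/counts.tsv", "results/cohort/meta.tsv")
areas <- sort(unique(dat$meta$area))

fits <- list()
for (a in areas)
  fits[[paste0("LR_", a)]] <- suppressMessages(
    fit_contrast(dat$counts, build_contrast(dat$meta, "LR", a)))
pairs <- combn(areas, 2)
for (j in seq_len(ncol(pairs)))
  for (h in c("WH_L", "WH_R"))
    fits[[paste(h, pairs[1, j], pairs[2, j], sep = "_")]] <-
      suppressMessages(fit_contrast(
        dat$counts,
        build_contrast(dat$meta, h, pairs[1, j], pairs[2, j])))

adj <- adjust_multilevel(fits)
for (nm in names(adj))
  write.table(adj[[nm]], sprintf("results/de/%s.tsv", gsub("/", ".", nm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(adj, "results/de/contrasts.rds")

n_sig <- count_significant(adj)
cat("significant genes per contrast (FDR < 0.05, within contrast):\n")
print(n_sig)
cat(sprintf("\nLR BA44 recovers the injected lateralization: %d of 12 injected genes called\n",
            sum(adj$LR_BA44$q_contrast < 0.05 &
                  adj$LR_BA44$gene_id %in% sprintf("gene%05d", 1:12))))
cat("wrote per-contrast tables under results/de/\n")
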