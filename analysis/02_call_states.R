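#!/usr/bin/env Rscript
# Call per-accession gene epigenetic states from the simulated bisulfite
# read tables and summarize their population conservation.

library(epiqtl)

sim <- "results/sim"; out <- "results/states"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genes <- read_annotation(file.path(sim, "genes.bed"))
allc_files <- list.files(file.path(sim, "allc"), full.names = TRUE)
tabs <- lapply(allc_files, function(f) {
  tab <- read_allc(f)
  tab$accession <- sub("\\.tsv$", "", basename(f))
  tab
})
allc <- assign_sites_to_genes(data.table::rbindlist(tabs), genes)

calls <- call_epistate_matrix(allc, error_rate = 0.005)
data.table::fwrite(calls, file.path(out, "epistates.tsv"), sep = "\t")

truth <- read_matrix_tsv(file.path(sim, "true_states.tsv"))
m <- merge(calls, data.table::data.table(
  gene_id = rep(rownames(truth), ncol(truth)),
  accession = rep(colnames(truth), each = nrow(truth)),
  true = as.vector(truth)), by = c("gene_id", "accession"))
cat(sprintf("state recovery vs simulation truth: %.2f%% of %d gene-accession pairs\n",
            100 * mean(m$state == m$true), nrow(m)))

cons <- conservation_summary(calls)
data.table::fwrite(cons, file.path(out, "conservation.tsv"), sep = "\t")
cat("conservation bins (gbM):\n")
print(table(cons$gbm_bin))

scc <- state_count_correlation(calls)
data.table::fwrite(scc$counts, file.path(out, "state_counts.tsv"),
                   sep = "\t")
cat(sprintf("per-accession gbM vs teM gene counts: r = %.3f (p = %.3g)\n",
            scc$r, scc$p_value))
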