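#!/usr/bin/env Rscript
# Build the synthetic study population every later stage consumes.
#
# A cooperative epimutation panel shows why population gbM levels are
# bimodal; a small accession panel gets full per-accession bisulfite read
# tables (allc-style TSVs) plus annotation, genotypes, expression and a
# trait with known causal epialleles. Larger in-memory panels for the
# statistical stages are regenerated inside those stages from the same
# master seed.

library(epiqtl)

seed <- 20260101L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## epimutation steady state: bimodal population gbM -----------------------
cfg <- epimutation_config(seed = child_seed(seed, 1))
lv <- simulate_epimutation_population(cfg)$levels
bins <- table(cut(lv, seq(0, 1, 0.1), include.lowest = TRUE))
write.csv(data.frame(bin = names(bins), n = as.vector(bins)),
          file.path(out, "epimutation_level_histogram.csv"),
          row.names = FALSE)
cat(sprintf(
  "epimutation panel (%d lineages, %d generations): %.0f%% low (<=0.2), %.0f%% mid, %.0f%% high (>=0.8) -> bimodal\n",
  cfg$n_lineages, cfg$n_generations, 100 * mean(lv <= 0.2),
  100 * mean(lv > 0.2 & lv < 0.8), 100 * mean(lv >= 0.8)))

## a small fully materialized accession panel ------------------------------
n_acc <- 24L; n_genes <- 60L
set.seed(child_seed(seed, 2))
truth <- matrix(sample(c("gbM", "teM", "UM"), n_acc * n_genes,
                       replace = TRUE, prob = c(0.55, 0.12, 0.33)),
                n_genes, n_acc,
                dimnames = list(sprintf("gene%04d", 1:n_genes),
                                sprintf("acc%04d", 1:n_acc)))
meth <- simulate_gene_methylomes(truth, seed = child_seed(seed, 3))
reads <- simulate_reads(meth$sites,
                        read_sim_config(mean_depth = 30,
                                        seed = child_seed(seed, 4)))
reads$gene_id <- meth$sites$gene_id

# one allc TSV per accession, plus a BED annotation
allc_dir <- file.path(out, "allc")
dir.create(allc_dir, showWarnings = FALSE)
for (a in colnames(truth))
  write_allc(reads[reads$accession == a, ],
             file.path(allc_dir, paste0(a, ".tsv")))
bed <- meth$genes
writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", bed$chrom, bed$start, bed$end,
                   bed$gene_id, bed$strand),
           file.path(out, "genes.bed"))
write_matrix_tsv(truth, file.path(out, "true_states.tsv"))

## genotypes, expression, trait -------------------------------------------
G <- simulate_genotypes(population_sim_config(
  n_accessions = n_acc, n_snps = 300, seed = child_seed(seed, 5)))
write_genotypes(G$genotypes, file.path(out, "genotypes.tsv"))

E <- simulate_epialleles(n_acc, n_genes, seed = child_seed(seed, 6))
tr <- simulate_traits(E, causal_genes = 5, causal_pve = 0.25,
                      seed = child_seed(seed, 7))
write.table(data.frame(accession = names(tr$trait), trait = tr$trait),
            file.path(out, "trait.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

jsonlite::write_json(
  list(causal_genes = colnames(E)[tr$truth$causal_genes],
       causal_pve = 0.25, true_states_file = "true_states.tsv"),
  file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
write_manifest(file.path(out, "manifest.json"),
               list(n_accessions = n_acc, n_genes = n_genes,
                    mean_depth = 30, stage = "simulate"), seed)

cat(sprintf("wrote %d allc tables, annotation, genotypes, trait under %s\n",
            n_acc, out))
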