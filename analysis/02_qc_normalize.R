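#!/usr/bin/env Rscript

# Stage 2: QC (detection filter, haemolysis exclusion, missingness filter),
# quantile normalization and Bayesian-PCA imputation.
# Reads data/ct_matrix.csv + data/metadata.tsv; writes results/processed_ct.csv,
# results/qc_hemolysis.tsv and results/qc_summary.tsv.

suppressPackageStartupMessages(library(premodmir))

dir.create("results", showWarnings = FALSE)
meta <- read_metadata_tsv("data/metadata.tsv")
ct <- read_ct_csv("data/ct_matrix.csv", metadata = meta)

qc <- qc_pipeline(ct)
imp <- impute_bpca(qc$ct, n_components = 5)

write_ct_csv(imp, "results/processed_ct.csv")
utils::write.table(qc$hemolysis, "results/qc_hemolysis.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(
  data.frame(metric = names(qc$counts), value = unname(qc$counts)),
  "results/qc_summary.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("QC: %d/%d features and %d/%d samples retained; %d cells imputed\n",
            qc$counts["features_out"], qc$counts["features_in"],
            qc$counts["samples_out"], qc$counts["samples_in"],
            sum(attr(imp, "imputed_mask"))))
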