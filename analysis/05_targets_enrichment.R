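#!/usr/bin/env Rscript

# Stage 5: aggregate miRNA target predictions across sources, project the
# shared-signature miRNAs' consensus targets onto the disease module, extract
# the targeted subnetwork, and run annotation-set and attribute enrichment.
# Reads data/rank_tables.tsv, data/annotation.gmt, data/attributes.tsv plus
# the stage 3/4 outputs; writes results/consensus_targets.tsv,
# results/module_targets.tsv, results/target_subnetwork.graphml and
# results/enrichment.tsv.

suppressPackageStartupMessages(library(premodmir))

net <- read_interactome("data/interactome.tsv", min_score = 0.4)
module <- extract_lcc(net, map_gene_set(net, read_gene_list("data/gene_list.txt")))
inter <- utils::read.delim("results/signature_intersection.tsv",
                           stringsAsFactors = FALSE)

tables <- read_rank_tables_tsv("data/rank_tables.tsv")
targets <- aggregate_targets(tables, min_sources = 2)
sig <- data.frame(feature = inter$feature, direction = inter$direction_a,
                  stringsAsFactors = FALSE)
mt <- map_targets_to_module(targets, module, sig)

write_target_table_tsv(targets, "results/consensus_targets.tsv")
write_module_targets_tsv(mt, "results/module_targets.tsv")
tg <- unique(mt$hits$target)
if (length(tg)) {
  sub <- target_subnetwork(net, module, tg)
  if (length(sub$members))
    igraph::write_graph(sub$graph, "results/target_subnetwork.graphml",
                        format = "graphml")
  cat(sprintf("targets: %d hits (%d unique), subnetwork of %d genes, top hub %s\n",
              mt$totals["total"], mt$totals["unique"], length(sub$members),
              if (length(sub$hubs)) sub$hubs[1] else "none"))
} else {
  cat("no consensus targets fall inside the module\n")
}

sets <- read_gmt("data/annotation.gmt")
universe <- igraph::V(net)$name
enr <- hypergeometric_enrichment(module$lcc_members, sets, universe)
write_enrichment_tsv(enr, "results/enrichment.tsv")

attrib <- utils::read.delim("data/attributes.tsv", stringsAsFactors = FALSE)
ae <- attribute_enrichment(module$mapped_genes, attrib, universe)
cat(sprintf("enrichment: top set %s (fdr = %.3g); attribute carried by %.1f%% of the module (p = %.3g)\n",
            enr$set_id[1], enr$fdr[1], 100 * ae$fraction, ae$p_value))
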