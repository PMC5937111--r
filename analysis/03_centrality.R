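#!/usr/bin/env Rscript
# Centrality analysis of the synthetic study network: expand the seed
# list to its one-hop neighbourhood in the simulated interactome, rank
# every node by degree and normalized betweenness, and report the top-20
# hub and bottleneck blocks — the same summaries the published study
# tabulates for its two networks.

suppressPackageStartupMessages(library(ppiscreen))
out <- "results/synthetic"
if (!file.exists(file.path(out, "interactome.tsv")))
  stop("run analysis/02_simulate_interactome.R first")

g <- suppressMessages(read_edge_list(file.path(out, "interactome.tsv"), "tsv"))
seeds <- readLines(file.path(out, "seed_list.tsv"))
net <- expand_seed_neighborhood(seeds, g)
cat(sprintf("analysis network: %d of %d interactome nodes (%d edges)\n",
            igraph::vcount(net), igraph::vcount(g), igraph::ecount(net)))

tab <- suppressMessages(rank_table(net))
write.table(tab, file.path(out, "centrality.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

hubs <- select_hubs(tab)
bottlenecks <- select_bottlenecks(tab)
hb <- intersect_hub_bottleneck(hubs, bottlenecks)
cat("top-20 hubs:       ", paste(hubs, collapse = " "), "\n")
cat("top-20 bottlenecks:", paste(bottlenecks, collapse = " "), "\n")
cat(sprintf("hub-bottlenecks (%d): %s\n", length(hb), paste(hb, collapse = " ")))
cat("wrote", file.path(out, "centrality.tsv"), "\n")
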