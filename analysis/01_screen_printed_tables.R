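#!/usr/bin/env Rscript
# Screening cascade over the published laryngeal carcinoma tables.
#
# The packaged fixtures carry the study's printed data: 136 up- and 139
# down-regulated proteins, the top-20 degree (hub) and betweenness
# (bottleneck) blocks of each PPI network, and the detected modules with
# their hub proteins. This driver runs the full cascade — hub selection,
# bottleneck selection, hub-bottleneck intersection, module-membership
# filtering, inclusive degree-1200 panel cutoff — and writes the results.
#
# Finding: 15 up and 11 down hub-bottlenecks (26 total); 12 of them
# reside in detected modules; the degree cutoff leaves the 4-protein
# candidate panel YWHAZ, PPP2R1A, HSP90AA1, CALM3.

suppressPackageStartupMessages(library(ppiscreen))
dir.create("results", showWarnings = FALSE)

genes <- laryngeal_gene_list("both")
cat(sprintf("differentially expressed records: %d up, %d down, %d total\n",
            sum(genes$direction == "up"), sum(genes$direction == "down"),
            nrow(genes)))

scr <- laryngeal_screen()
for (dir in c("up", "down")) {
  cat(sprintf("%s network: top-20 hubs, top-20 bottlenecks -> %d hub-bottlenecks\n",
              dir, length(scr[[dir]]$hub_bottlenecks)))
  cat("  ", paste(scr[[dir]]$hub_bottlenecks, collapse = ", "), "\n")
}
cat(sprintf("module-resident hub-bottlenecks (%d): %s\n",
            length(scr$module_resident),
            paste(scr$module_resident, collapse = ", ")))
cat(sprintf("panel after degree >= 1200 (%d): %s\n",
            length(scr$panel), paste(scr$panel, collapse = ", ")))

report <- data.frame(
  symbol = scr$hub_bottlenecks,
  direction = ifelse(scr$hub_bottlenecks %in% scr$up$hub_bottlenecks,
                     "up", "down"),
  degree = laryngeal_degrees()[scr$hub_bottlenecks],
  module_resident = scr$hub_bottlenecks %in% scr$module_resident,
  panel = scr$hub_bottlenecks %in% scr$panel)
write.table(report, "results/printed_hub_bottlenecks.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  scr[c("hub_bottlenecks", "module_resident", "panel")],
  "results/printed_screen.json", pretty = TRUE)
cat("wrote results/printed_hub_bottlenecks.tsv, results/printed_screen.json\n")
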