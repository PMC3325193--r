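#!/usr/bin/env Rscript
# Repeat and microsatellite survey of the synthetic chondrome: maximal
# exact direct/inverted repeats >=100 bp, near-exact extension/fusion,
# origin annotation, and the microsatellite screen at the conventional
# thresholds (di >= 6 units, tri..hexa >= 4).  Writes results/repeats.tsv
# and results/microsats.tsv.

library(chondromics)
library(jsonlite)

g <- read_genbank("results/synthetic/genome.gb")
m <- fromJSON("results/synthetic/manifest.json")

cat("exact repeat detection (>=100 bp)...\n")
cls <- find_exact_repeats(g, 100)
cls <- extend_near_exact(cls, g)
cls <- lapply(cls, annotate_origin, genome = g)
tab <- repeat_class_table(cls)
print(tab)
cat(sprintf("planted: %d classes (largest: the duplicated rRNA cluster, %d bp)\n",
            nrow(m$repeat_table), max(m$repeat_table$length_bp)))

ms <- find_microsatellites(g)
cat(sprintf("microsatellites: %d (by unit size: %s); planted %d\n",
            nrow(ms),
            paste(names(table(ms$unit_size)), table(ms$unit_size),
                  sep = "bp:", collapse = ", "),
            nrow(m$microsat_table)))

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/repeats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ms, "results/microsats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/repeats.tsv, results/microsats.tsv\n")
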