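#!/usr/bin/env Rscript
# Step 4 — associate selected H3.3 nucleosomes with genomic features.
#
# Each selected nucleosome is linked to its nearest feature when no more
# than 2,000 bp away, classified into promoter / TTS / body / ambiguous
# windows of protein-coding genes, and the per-gene categories
# (promoter-only / TTS-only / both / none) are tallied. Protein-coding
# enrichment of the selected set is tested against random subsets of all
# positioned nucleosomes.

suppressMessages(library(varnuc))
suppressMessages(library(data.table))

scored <- read_nucleosome_calls("results/nucleosomes_scored.tsv")
genes <- read_annotation("results/sim/genes.gff3")
params <- association_params(seed = 42)
sel <- scored[selected == TRUE]

assoc <- nearest_feature(sel, genes, params$max_distance)
classified <- classify_positions(sel, genes[feature_type ==
                                              "protein_coding"], params)
cats <- gene_h33_categories(genes, classified)
comp <- feature_composition(assoc)
enr <- enrichment_vs_random(sel$id, scored, genes, params = params)

n_assoc <- sum(!is.na(assoc$feature_id))
cat(sprintf("selected nucleosomes           : %d\n", nrow(sel)))
cat(sprintf("associated within 2,000 bp     : %d (%.1f%%)\n",
            n_assoc, percent(n_assoc, nrow(sel))))
cat(sprintf("promoter- / TTS-classified     : %d / %d\n",
            sum(classified$position_class == "promoter"),
            sum(classified$position_class == "TTS")))
cat("gene categories:\n")
print(attr(cats, "counts"))
cat(sprintf("protein-coding share           : %.1f%% (fold %.2f vs random, p = %.3g)\n",
            100 * comp[feature_type == "protein_coding", frac_features],
            enr$fold, enr$p_value))

fwrite(assoc, "results/associations.tsv", sep = "\t")
fwrite(classified, "results/position_classes.tsv", sep = "\t")
fwrite(cats, "results/gene_categories.tsv", sep = "\t")
fwrite(comp, "results/feature_composition.tsv", sep = "\t")
cat("wrote results/{associations,position_classes,gene_categories,feature_composition}.tsv\n")
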