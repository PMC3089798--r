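#!/usr/bin/env Rscript

# Stage 3: ortholog-anchored cross-species comparison.
#
# Maps the per-species DE calls onto ortholog groups, classifies each
# group (conserved / divergent / species-specific / partial), counts
# pairwise platform overlaps and the three-way Venn partition, and
# scores category recovery against the planted truth.

suppressMessages(library(ahrcompare))

run <- "results/run"
stopifnot(file.exists(file.path(run, "de_calls.tsv")))

calls <- utils::read.delim(file.path(run, "de_calls.tsv"))
orthologs <- read_ortholog_table(file.path(run, "orthologs.tsv"))
truth <- utils::read.delim(file.path(run, "truth_expression.tsv"))

species <- sort(unique(truth$species))
summaries <- lapply(stats::setNames(species, species), function(s)
  de_call_summary(calls[calls$species == s, ]))
universes <- lapply(stats::setNames(species, species), function(s)
  truth$gene_id[truth$species == s])

cross <- map_calls(summaries, orthologs, universes)
utils::write.table(cross, file.path(run, "cross_species_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("ortholog group categories:")
print(table(cross$category))

pairs <- utils::combn(species, 2, simplify = FALSE)
overlap <- do.call(rbind, lapply(pairs, function(p) {
  ov <- pairwise_overlap(cross, p[1], p[2])
  data.frame(species_a = p[1], species_b = p[2],
             n_shared_orthologs = ov[["n_shared_orthologs"]],
             n_shared_de = ov[["n_shared_de"]],
             shared_pct = shared_fraction(
               ov[["n_shared_de"]], max(ov[["n_shared_orthologs"]], 1)))
}))
utils::write.table(overlap, file.path(run, "pairwise_overlap.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(overlap)

venn <- venn_partition(cross, species[1:3])
utils::write.table(data.frame(region = names(venn),
                              count = as.integer(venn)),
                   file.path(run, "venn_regions.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("Venn regions (", paste(species[1:3], collapse = "/"), "):")
print(venn)

tg <- unique(truth[!is.na(truth$group_id) & truth$group_id != "",
                   c("group_id", "category")])
tg$category <- sub("^specific_.*", "specific",
                   sub("^conserved_(up|down)$", "conserved", tg$category))
cmp <- merge(cross, tg, by = "group_id", suffixes = c("_called", "_true"))
exp_cat <- ifelse(cmp$category_true == "null", "none", cmp$category_true)
message(sprintf("category recovery vs planted truth: %.1f%% of %d groups",
                100 * mean(cmp$category_called == exp_cat), nrow(cmp)))
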