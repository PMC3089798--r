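#!/usr/bin/env Rscript

# Stage 6: summary report.
#
# Re-aggregates the stage outputs into one key-value table: per-species
# DE counts and response percentages, ortholog category counts, pairwise
# shared fractions, Venn regions and CHX class counts. Also prints the
# worked-example percentages computed from the published platform counts
# for side-by-side context.

suppressMessages(library(ahrcompare))

run <- "results/run"
stopifnot(file.exists(file.path(run, "de_calls.tsv")),
          file.exists(file.path(run, "cross_species_calls.tsv")),
          file.exists(file.path(run, "chx_classes.tsv")))

calls <- utils::read.delim(file.path(run, "de_calls.tsv"))
cross <- utils::read.delim(file.path(run, "cross_species_calls.tsv"))
overlap <- utils::read.delim(file.path(run, "pairwise_overlap.tsv"))
venn <- utils::read.delim(file.path(run, "venn_regions.tsv"))
chx <- utils::read.delim(file.path(run, "chx_classes.tsv"))

rows <- list()
add <- function(metric, value)
  rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value)

for (s in sort(unique(calls$species))) {
  summ <- de_call_summary(calls[calls$species == s, ])
  add(paste0("n_genes_", s), nrow(summ))
  add(paste0("n_de_any_time_", s), sum(summ$any_time))
  add(paste0("response_pct_", s),
      response_percentage(sum(summ$any_time), nrow(summ)))
}
for (cat in c("conserved", "divergent", "specific", "partial", "none"))
  add(paste0("n_groups_", cat), sum(cross$category == cat))
for (i in seq_len(nrow(overlap)))
  add(paste0("shared_de_pct_", overlap$species_a[i], "_",
             overlap$species_b[i]), overlap$shared_pct[i])
for (i in seq_len(nrow(venn)))
  add(paste0("venn_", venn$region[i]), venn$count[i])
for (cl in c("primary", "secondary", "unclassified", "nonresponsive"))
  add(paste0("n_chx_", cl), sum(chx$class == cl))

report <- do.call(rbind, rows)
utils::write.table(report, file.path(run, "summary.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(report, row.names = FALSE)

message("\nworked-example percentages from the published platform counts:")
message("  cDNA time course:  ",
        response_percentage(691, 6995), "% / ",
        response_percentage(439, 8478), "% / ",
        response_percentage(57, 5169), "%  (human / mouse / rat)")
message("  whole-genome 24 h: ",
        response_percentage(865, 18499), "% / ",
        response_percentage(508, 20929), "% / ",
        response_percentage(129, 18244), "%")
message("  shared DE orthologs: ", shared_fraction(41, 4546), "% (hs-mm), ",
        shared_fraction(8, 3850), "% (mm-rn), ",
        shared_fraction(5, 2625), "% (hs-rn)")
message("wrote ", file.path(run, "summary.tsv"))
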