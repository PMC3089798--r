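# End-to-end orchestration: fixtures -> normalize -> DE -> orthology ->
# CHX -> DRE -> summary, under one config and one master seed. Every
# stage writes plain-text tables into the run directory and the manifest
# records config hash, seed and file digests so a rerun with the same
# config and seed is byte-reproducible.

#' Derive a per-stage seed from the master seed
#'
#' Distinct per-stage streams derived from the master seed, kept within
#' 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param stage stage index (integer).
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 101 + stage * 7919) %% 2147483647)
}

#' Run the full comparative workflow on synthetic data
#'
#' Executes every stage of the cross-species analysis against generated
#' data: time-course simulation, normalization, empirical-Bayes DE calling
#' per species and time, profile clustering, ortholog mapping with
#' pairwise overlaps and the three-way Venn partition, the cycloheximide
#' factorial classification, and the DRE promoter scan with cross-species
#' clustering. All randomness flows from `config$seed` via per-stage
#' derived seeds.
#'
#' @param config a config list from [default_config()] or a path to a YAML
#'   config file.
#' @param out_dir output directory (created if needed).
#' @param n_genes,times_hr generator scale overrides (passed to
#'   [generate_experiment()]).
#' @param quiet suppress stage progress messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config = default_config(), out_dir = tempfile("run_"),
                    n_genes = c(human = 600, mouse = 600, rat = 500),
                    times_hr = c(1, 2, 4, 8, 12, 24, 48), quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  t0 <- Sys.time()

  run_stage <- function(name, fun) {
    say("stage: ", name)
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1. simulate the cross-species time course
  sim <- run_stage("simulate", function() {
    sim <- generate_experiment(n_genes = n_genes, times_hr = times_hr,
                               seed = derive_seed(config$seed, 1L))
    write_expression(sim$expression, file.path(out_dir, "expression_raw.tsv"))
    write_sample_sheet(sim$samples, file.path(out_dir, "samples.tsv"))
    write_ortholog_table(sim$orthologs, file.path(out_dir, "orthologs.tsv"))
    utils::write.table(sim$truth, file.path(out_dir, "truth_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sim
  })

  ## 2. normalize and call differential expression
  de <- run_stage("de", function() {
    norm <- normalize_expression(sim$expression, sim$samples)
    species <- unique(sim$samples$species)
    stats_all <- do.call(rbind, lapply(species, function(s) {
      do.call(rbind, lapply(times_hr, function(t)
        fit_empirical_bayes(norm, species = s, time_hr = t,
                            prior_df = config$eb$prior_df,
                            pi1 = config$eb$pi1,
                            effect_var_scale = config$eb$effect_var_scale)))
    }))
    stats_all$species <- sub("_.*$", "", stats_all$condition)
    calls <- call_de(stats_all, config$de$p1_min, config$de$abs_fc_min)
    utils::write.table(calls, file.path(out_dir, "de_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summaries <- lapply(stats::setNames(species, species), function(s)
      de_call_summary(calls[calls$species == s, ]))
    # profile clustering of any-time genes, one dendrogram per species
    for (s in species) {
      genes <- summaries[[s]]$gene_id[summaries[[s]]$any_time]
      if (length(genes) >= 2) {
        sub <- calls[calls$species == s & calls$gene_id %in% genes, ]
        mat <- tapply(sub$m_bar, list(sub$gene_id, sub$condition), mean)
        write_dendrogram(cluster_de_profiles(mat),
                         file.path(out_dir, paste0("clusters_", s, ".nwk")))
      }
    }
    list(norm = norm, calls = calls, summaries = summaries)
  })

  ## 3. ortholog mapping and cross-species categories
  ortho <- run_stage("orthology", function() {
    species <- names(de$summaries)
    universes <- lapply(stats::setNames(species, species), function(s)
      sim$truth$gene_id[sim$truth$species == s])
    cross <- map_calls(de$summaries, sim$orthologs, universes)
    utils::write.table(cross, file.path(out_dir, "cross_species_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pairs <- utils::combn(species, 2, simplify = FALSE)
    overlap <- do.call(rbind, lapply(pairs, function(p) {
      ov <- pairwise_overlap(cross, p[1], p[2])
      data.frame(species_a = p[1], species_b = p[2],
                 n_shared_orthologs = ov[["n_shared_orthologs"]],
                 n_shared_de = ov[["n_shared_de"]],
                 shared_pct = shared_fraction(ov[["n_shared_de"]],
                                              max(ov[["n_shared_orthologs"]], 1)),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(overlap, file.path(out_dir, "pairwise_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    venn <- if (length(species) >= 3)
      venn_partition(cross, species[1:3]) else NULL
    if (!is.null(venn))
      utils::write.table(data.frame(region = names(venn), count = as.integer(venn)),
                         file.path(out_dir, "venn_regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    list(cross = cross, overlap = overlap, venn = venn)
  })

  ## 4. cycloheximide factorial classification
  chx <- run_stage("chx", function() {
    chx_sim <- generate_chx_experiment(seed = derive_seed(config$seed, 2L),
                                       times_hr = config$chx$times_hr)
    norm <- normalize_expression(chx_sim$expression, chx_sim$samples)
    res <- classify_chx(norm, times_hr = config$chx$times_hr,
                        p1_min = config$de$p1_min,
                        abs_fc_min = config$de$abs_fc_min,
                        retention_alpha = config$chx$retention_alpha,
                        prior_df = config$eb$prior_df, pi1 = config$eb$pi1,
                        effect_var_scale = config$eb$effect_var_scale)
    utils::write.table(res$per_time, file.path(out_dir, "chx_per_time.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$merged, file.path(out_dir, "chx_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(chx_sim$truth, file.path(out_dir, "truth_chx.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    c(res, list(truth = chx_sim$truth))
  })

  ## 5. DRE promoter analysis
  dre <- run_stage("dre", function() {
    train <- generate_dre_training_set(n = 200,
                                       seed = derive_seed(config$seed, 3L))
    pwm <- build_pwm(train)
    write_pwm(pwm, file.path(out_dir, "dre_pwm.tsv"))
    # one conserved mouse/rat DRE pair plus a dissimilar human site, and a
    # background-only promoter, per the divergent-ortholog narrative
    plants <- data.frame(
      species = c("mouse", "rat", "human"),
      gene_id = c("mm_gsta5", "rn_gsta5", "hs_gsta5"),
      position = c(-5L, -22L, -4120L),
      strand = c("+", "+", "-"),
      seq19 = c("CTCCAGGGCGTGCGGAGTT", "CTCCAGGGCGTGCGGAGAT",
                "AATTCTAGCGTGATCGTAC"),
      stringsAsFactors = FALSE)
    genes <- rbind(plants[c("species", "gene_id")],
                   data.frame(species = "human", gene_id = "hs_bg"))
    prom <- generate_promoters(plants, genes = genes,
                               core = config$dre$core,
                               seed = derive_seed(config$seed, 4L))
    write_promoters(prom$records, file.path(out_dir, "promoters.fasta"))
    hits <- scan_promoters(prom$records, pwm, core = config$dre$core,
                           flank_bp = config$dre$flank_bp,
                           ms_min = config$dre$ms_min)
    write_dre_hits(hits, file.path(out_dir, "dre_hits.tsv"), "tsv")
    clus <- cluster_orthologous_dres(hits,
                                     theta = config$dre$distance_threshold)
    utils::write.table(clus$clusters, file.path(out_dir, "dre_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clus$members, file.path(out_dir, "dre_members.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(pwm = pwm, promoters = prom, hits = hits, clusters = clus)
  })

  ## 6. summary report
  report <- run_stage("summary", function() {
    rep <- summarize_run(de, ortho, chx)
    utils::write.table(rep, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })

  files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- list(
    tool_version = as.character(utils::packageVersion("ahrcompare")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(write_config_tmp(config))),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done in ", round(difftime(Sys.time(), t0, units = "secs"), 1), " s")
  invisible(list(sim = sim, de = de, orthology = ortho, chx = chx,
                 dre = dre, report = report, manifest = manifest,
                 out_dir = out_dir))
}

write_config_tmp <- function(config) {
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, p)
  p
}

#' Summarise stage outputs into a report table
#'
#' Per-species per-time DE counts, any-time counts, response percentages,
#' ortholog category counts and CHX class counts, in a long key-value
#' table.
#'
#' @param de,ortho,chx stage result lists as produced inside [run_all()].
#' @return data.frame with `metric` and `value` columns.
#' @export
summarize_run <- function(de, ortho, chx) {
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value,
                                             stringsAsFactors = FALSE)
  for (s in names(de$summaries)) {
    summ <- de$summaries[[s]]
    n_tot <- nrow(summ)
    n_any <- sum(summ$any_time)
    add(paste0("n_genes_", s), n_tot)
    add(paste0("n_de_any_time_", s), n_any)
    add(paste0("response_pct_", s), response_percentage(n_any, n_tot))
    calls_s <- de$calls[de$calls$species == s & de$calls$significant, ]
    per_time <- table(calls_s$condition)
    for (cond in names(per_time))
      add(paste0("n_de_", cond), as.integer(per_time[[cond]]))
  }
  for (cat in c("conserved", "divergent", "specific", "partial", "none"))
    add(paste0("n_groups_", cat), sum(ortho$cross$category == cat))
  for (i in seq_len(nrow(ortho$overlap)))
    add(paste0("shared_de_pct_", ortho$overlap$species_a[i], "_",
               ortho$overlap$species_b[i]), ortho$overlap$shared_pct[i])
  if (!is.null(ortho$venn))
    for (r in names(ortho$venn))
      add(paste0("venn_", r), as.integer(ortho$venn[[r]]))
  for (cl in c("primary", "secondary", "unclassified", "nonresponsive"))
    add(paste0("n_chx_", cl), sum(chx$merged$class == cl))
  do.call(rbind, rows)
}
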