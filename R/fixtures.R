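# Synthetic-data generators. Every generator is a pure function of
# (configuration, seed) and returns a truth table sufficient to score the
# downstream stage without re-reading intensities or sequences.

SPECIES_PREFIX <- c(human = "hs", mouse = "mm", rat = "rn")

#' Evaluate the dye-bias curve
#'
#' Smooth intensity-dependent dye bias added to the log2 ratio M as a cubic
#' polynomial in centred mean log intensity A. The sign of the contribution
#' flips on dye-swap arrays (the bias belongs to the dyes, not the
#' treatment).
#'
#' @param A mean log2 intensity.
#' @param coef polynomial coefficients (intercept, linear, quadratic,
#'   cubic) in `(A - 10)`.
#' @return bias in log2-ratio units.
#' @export
dye_bias_curve <- function(A, coef = c(0.25, -0.1, 0.02, 0.015)) {
  z <- A - 10
  coef[1] + coef[2] * z + coef[3] * z^2 + coef[4] * z^3
}

category_levels <- function(species) {
  c("null", "conserved_up", "conserved_down",
    paste0("specific_", species), "divergent")
}

#' Simulate a cross-species two-color microarray time course
#'
#' Generates raw two-channel intensities for a TCDD-versus-vehicle time
#' course in several species, mirroring the design of the study this
#' workflow models: 7 time points, 3 biological replicates, each hybridised
#' twice with dyes swapped. Ortholog groups are planted with conserved
#' (same-sign), species-specific, or divergent (opposite-sign) log2
#' effects; the remainder are null. The log2 ratio of each probe on each
#' array is effect + intensity-dependent dye bias (sign flipped on swaps) +
#' Gaussian noise, realised as multiplicative lognormal noise on the two
#' channels.
#'
#' @param n_genes named integer vector of genes per species.
#' @param group_fraction fraction of each species' genes that belong to an
#'   ortholog group (the rest are platform singletons).
#' @param category_props named proportions over ortholog-group categories
#'   (`null`, `conserved_up`, `conserved_down`, `specific_<species>`,
#'   `divergent`); must sum to 1. `NULL` uses 90% null, 3% conserved up,
#'   1% conserved down, 1% specific per species and the rest divergent.
#' @param effect_log2 planted absolute effect size in log2 units.
#' @param noise_sd replicate noise standard deviation (log2 units).
#' @param dye_bias_coef coefficients for [dye_bias_curve()]; zeros disable
#'   the bias.
#' @param n_reps biological replicates per time point.
#' @param times_hr time points in hours.
#' @param seed RNG seed (integer).
#' @return list with `expression` (raw `expression_table`), `samples`
#'   (sample sheet), `orthologs` (ortholog table), and `truth`
#'   (per species x gene: group, category, signed `effect_log2`).
#' @export
generate_experiment <- function(n_genes = c(human = 1000, mouse = 1000,
                                            rat = 800),
                                group_fraction = 0.6,
                                category_props = NULL,
                                effect_log2 = 2,
                                noise_sd = 0.2,
                                dye_bias_coef = c(0.25, -0.1, 0.02, 0.015),
                                n_reps = 3,
                                times_hr = c(1, 2, 4, 8, 12, 24, 48),
                                seed = 1L) {
  species <- names(n_genes)
  stopifnot(length(species) >= 1, !is.null(species))
  if (length(species) < 2 && group_fraction > 0)
    stop("ortholog groups need >= 2 species; use group_fraction = 0 for a ",
         "single-species experiment")
  if (is.null(category_props)) {
    # study-condition defaults: 90% null, a small conserved core, 1%
    # specific responses per species, the rest divergent
    category_props <- c(null = 0.90, conserved_up = 0.03,
                        conserved_down = 0.01,
                        stats::setNames(rep(0.01, length(species)),
                                        paste0("specific_", species)))
    category_props <- c(category_props,
                        divergent = 1 - sum(category_props))
  }
  if (abs(sum(category_props) - 1) > 1e-8)
    stop("category proportions must sum to 1")
  known <- category_levels(species)
  bad <- setdiff(names(category_props), known)
  if (length(bad))
    stop("unknown categories for this species set: ",
         paste(bad, collapse = ", "))
  set.seed(seed)

  ## ortholog groups: each group spans >= 2 species
  n_in_groups <- floor(n_genes * group_fraction)
  n_groups <- min(n_in_groups)
  membership <- matrix(FALSE, n_groups, length(species),
                       dimnames = list(NULL, species))
  # groups 1..n_groups exist in every species with room; extra per-species
  # slots beyond n_groups stay singletons, giving partial platform overlap
  for (s in species) membership[seq_len(min(n_groups, n_in_groups[s])), s] <- TRUE
  # drop a random 15% of memberships per species (keeping >= 2 per group)
  for (s in species) {
    cand <- which(membership[, s] & rowSums(membership) > 2)
    drop <- sample(cand, size = floor(0.15 * length(cand)))
    membership[drop, s] <- FALSE
  }
  group_id <- sprintf("HG%05d", seq_len(n_groups))

  ## category assignment with feasibility checks
  counts <- round(category_props * n_groups)
  counts["null"] <- n_groups - sum(counts[names(counts) != "null"])
  if (counts["null"] < 0) stop("category proportions leave no null genes")
  cat_of_group <- rep("null", n_groups)
  unassigned <- sample.int(n_groups)  # random order for assignment
  for (cat in setdiff(names(counts), "null")) {
    k <- counts[[cat]]
    if (k == 0) next
    ok <- if (startsWith(cat, "specific_")) {
      sp <- sub("^specific_", "", cat)
      if (!sp %in% species) stop("category ", cat, " names unknown species")
      unassigned[membership[unassigned, sp]]
    } else {
      unassigned
    }
    if (length(ok) < k)
      stop("category proportions infeasible given ortholog overlap: ",
           "need ", k, " groups for ", cat, ", only ", length(ok),
           " available")
    take <- ok[seq_len(k)]
    cat_of_group[take] <- cat
    unassigned <- setdiff(unassigned, take)
  }

  ## per-species truth
  truth <- do.call(rbind, lapply(species, function(s) {
    n <- n_genes[[s]]
    gid <- sprintf("%s_g%04d", SPECIES_PREFIX[[s]] %||% s, seq_len(n))
    in_grp <- membership[, s]
    grp <- rep(NA_character_, n)
    grp[seq_len(sum(in_grp))] <- group_id[in_grp]
    cat <- rep("null", n)
    cat[seq_len(sum(in_grp))] <- cat_of_group[in_grp]
    eff <- numeric(n)
    eff[cat == "conserved_up"] <- effect_log2
    eff[cat == "conserved_down"] <- -effect_log2
    eff[cat == paste0("specific_", s)] <- effect_log2
    # members of a specific_<other-species> group keep the group category
    # but a zero effect in this species; effect_log2 carries the truth
    data.frame(species = s, gene_id = gid, group_id = grp, category = cat,
               effect_log2 = eff, stringsAsFactors = FALSE)
  }))
  ## divergent groups: one randomly chosen member species flips sign
  for (g in group_id[cat_of_group == "divergent"]) {
    rows <- which(truth$group_id %in% g)
    flip <- sample(seq_along(rows), 1)
    truth$effect_log2[rows] <- effect_log2
    truth$effect_log2[rows[flip]] <- -effect_log2
  }

  ortho <- truth[!is.na(truth$group_id),
                 c("group_id", "species", "gene_id")]
  ortho <- ortho[order(ortho$group_id, ortho$species), ]
  rownames(ortho) <- NULL
  validate_ortholog_table(ortho)

  ## arrays and intensities
  sheets <- list(); mats <- list()
  for (s in species) {
    tr <- truth[truth$species == s, ]
    n <- nrow(tr)
    base_A <- stats::runif(n, 7, 13)
    blocks <- list()
    for (t in times_hr) for (r in seq_len(n_reps)) for (lab in c("fwd", "swp")) {
      aid <- sprintf("%s_t%02d_r%d_%s", SPECIES_PREFIX[[s]] %||% s, t, r, lab)
      treated_dye <- if (lab == "fwd") "Cy5" else "Cy3"
      control_dye <- setdiff(DYE_LEVELS, treated_dye)
      sgn <- if (lab == "fwd") 1 else -1
      A <- base_A + stats::rnorm(n, 0, 0.3)
      M <- tr$effect_log2 + stats::rnorm(n, 0, noise_sd) +
        sgn * dye_bias_curve(A, dye_bias_coef)
      block <- cbind(2^(A + M / 2), 2^(A - M / 2))
      colnames(block) <- paste0(aid, c("_T", "_C"))
      blocks[[length(blocks) + 1L]] <- block
      sheets[[length(sheets) + 1L]] <- data.frame(
        sample_id = paste0(aid, c("_T", "_C")), species = s,
        treatment = c("TCDD", "vehicle"), time_hr = t,
        dye = c(treated_dye, control_dye), replicate = r, array_id = aid,
        stringsAsFactors = FALSE)
    }
    mats[[s]] <- do.call(cbind, blocks)
  }
  sheet <- validate_sample_sheet(do.call(rbind, sheets))
  all_vals <- matrix(NA_real_, nrow(truth), nrow(sheet),
                     dimnames = list(truth$gene_id, sheet$sample_id))
  for (s in species) {
    rows <- truth$species == s
    all_vals[rows, colnames(mats[[s]])] <- as.matrix(mats[[s]])
  }
  expr <- expression_table(all_vals, truth$gene_id, truth$gene_id,
                           value_kind = "raw_two_channel")
  list(expression = expr, samples = sheet, orthologs = ortho, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a 2x2 cycloheximide co-treatment experiment
#'
#' Produces raw two-channel arrays for the factorial design used to
#' separate primary from secondary TCDD responses: direct-ratio arrays
#' for TCDD vs vehicle and for TCDD+CHX vs CHX at 4 and 12 h, with dye-swap
#' triplicates. Planted primary genes keep (or exceed) their TCDD effect
#' under co-treatment (`chx_modifier >= 1`); secondary genes are attenuated
#' or blocked (`chx_modifier` near 0); nonresponsive genes have no effect.
#'
#' @param n_genes number of genes.
#' @param class_props proportions of `primary`, `secondary`,
#'   `nonresponsive` (must sum to 1).
#' @param tcdd_effect_log2 absolute TCDD effect for responsive genes.
#' @param primary_modifier_range,secondary_modifier_range uniform sampling
#'   ranges for the co-treatment modifier of each class.
#' @param species species label for the sheet.
#' @param noise_sd,dye_bias_coef,n_reps,times_hr,seed as in
#'   [generate_experiment()].
#' @return list with `expression`, `samples` and `truth`
#'   (gene, class, `tcdd_effect_log2` signed, `chx_modifier`).
#' @export
generate_chx_experiment <- function(n_genes = 600,
                                    class_props = c(primary = 0.06,
                                                    secondary = 0.06,
                                                    nonresponsive = 0.88),
                                    tcdd_effect_log2 = 2,
                                    primary_modifier_range = c(1, 2),
                                    secondary_modifier_range = c(0, 0.2),
                                    species = "mouse",
                                    noise_sd = 0.2,
                                    dye_bias_coef = c(0.25, -0.1, 0.02, 0.015),
                                    n_reps = 3,
                                    times_hr = c(4, 12),
                                    seed = 1L) {
  if (abs(sum(class_props) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  set.seed(seed)
  n <- n_genes
  counts <- round(class_props * n)
  counts["nonresponsive"] <- n - sum(counts[names(counts) != "nonresponsive"])
  cls <- sample(rep(names(counts), counts))
  gid <- sprintf("%s_chx_g%04d", SPECIES_PREFIX[[species]] %||% species,
                 seq_len(n))
  sign_eff <- sample(c(-1, 1), n, replace = TRUE)
  eff <- ifelse(cls == "nonresponsive", 0, sign_eff * tcdd_effect_log2)
  modifier <- rep(1, n)
  modifier[cls == "primary"] <- stats::runif(sum(cls == "primary"),
                                             primary_modifier_range[1],
                                             primary_modifier_range[2])
  modifier[cls == "secondary"] <- stats::runif(sum(cls == "secondary"),
                                               secondary_modifier_range[1],
                                               secondary_modifier_range[2])
  truth <- data.frame(species = species, gene_id = gid, class = cls,
                      tcdd_effect_log2 = eff, chx_modifier = modifier,
                      stringsAsFactors = FALSE)

  base_A <- stats::runif(n, 7, 13)
  sheets <- list(); vals <- NULL
  contrasts <- list(tcdd = c("TCDD", "vehicle"),
                    chx = c("TCDD+CHX", "CHX"))
  for (t in times_hr) for (cn in names(contrasts)) {
    mu <- if (cn == "tcdd") eff else eff * modifier
    for (r in seq_len(n_reps)) for (lab in c("fwd", "swp")) {
      aid <- sprintf("%s_%s_t%02d_r%d_%s",
                     SPECIES_PREFIX[[species]] %||% species, cn, t, r, lab)
      treated_dye <- if (lab == "fwd") "Cy5" else "Cy3"
      sgn <- if (lab == "fwd") 1 else -1
      A <- base_A + stats::rnorm(n, 0, 0.3)
      M <- mu + stats::rnorm(n, 0, noise_sd) +
        sgn * dye_bias_curve(A, dye_bias_coef)
      block <- cbind(2^(A + M / 2), 2^(A - M / 2))
      colnames(block) <- paste0(aid, c("_T", "_C"))
      vals <- cbind(vals, block)
      sheets[[length(sheets) + 1L]] <- data.frame(
        sample_id = paste0(aid, c("_T", "_C")), species = species,
        treatment = contrasts[[cn]], time_hr = t,
        dye = c(treated_dye, setdiff(DYE_LEVELS, treated_dye)),
        replicate = r, array_id = aid, stringsAsFactors = FALSE)
    }
  }
  sheet <- validate_sample_sheet(do.call(rbind, sheets))
  rownames(vals) <- gid
  expr <- expression_table(vals, gid, gid, value_kind = "raw_two_channel")
  list(expression = expr, samples = sheet, truth = truth)
}

## ---- promoters and DRE training sets ------------------------------------

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

# i.i.d. uniform ACGT with rejection of any window matching the core or its
# reverse complement, so planted-core counts are exact by construction.
core_free_sequence <- function(len, core, rng_max_iter = 1000L) {
  rc <- revcomp(core)
  k <- nchar(core)
  seq <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  txt <- paste(seq, collapse = "")
  for (iter in seq_len(rng_max_iter)) {
    pos <- sort(unique(c(find_all(txt, core), find_all(txt, rc))))
    if (!length(pos)) return(txt)
    for (p in pos) {  # resample the offending window (1-based start p)
      substr(txt, p, p + k - 1) <- paste(
        sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }
  }
  stop("failed to generate core-free background")
}

# all 1-based start positions of fixed pattern (overlapping)
find_all <- function(txt, pat) {
  out <- integer(0); from <- 1L
  repeat {
    hit <- regexpr(pat, substr(txt, from, nchar(txt)), fixed = TRUE)
    if (hit < 0) return(out)
    out <- c(out, from + hit - 1L)
    from <- from + hit  # advance one base: overlapping occurrences count
  }
}

#' Simulate promoter sequences with planted DREs
#'
#' Builds TSS-anchored promoter windows on a core-free background (i.i.d.
#' uniform nucleotides, rejection-sampled so neither the DRE core nor its
#' reverse complement occurs anywhere except at planted sites) and plants
#' 19-mers whose central 5 bp are the core. Planting on the minus strand
#' inserts the reverse complement.
#'
#' @param plants data.frame with columns `species`, `gene_id`, `position`
#'   (TSS-relative core-center), `strand` (`+`/`-`), and optionally `seq19`
#'   (19-mer in DRE orientation; generated with random core-free flanks if
#'   absent).
#' @param genes data.frame with columns `species`, `gene_id` naming every
#'   promoter to emit (supersets of `plants` allowed: background-only
#'   promoters).
#' @param window_up,window_down window in bp around the TSS.
#' @param core the invariant core (default GCGTG).
#' @param seed RNG seed.
#' @return list with `records` (promoter records) and `truth`
#'   (the planted sites, one row each).
#' @export
generate_promoters <- function(plants,
                               genes = unique(plants[c("species", "gene_id")]),
                               window_up = 10000, window_down = 1000,
                               core = "GCGTG", seed = 1L) {
  set.seed(seed)
  stopifnot(all(c("species", "gene_id") %in% names(genes)))
  if (nrow(plants) &&
      !all(c("species", "gene_id", "position", "strand") %in% names(plants)))
    stop("plants needs columns species, gene_id, position, strand")
  len <- window_up + window_down + 1L
  tss <- as.integer(window_up)          # 0-based index of TSS base
  if (nrow(plants)) {
    out_of_window <- plants$position < -window_up + 9 |
      plants$position > window_down - 9
    if (any(out_of_window))
      stop("planted DRE at position ",
           plants$position[which(out_of_window)[1]],
           " falls outside (or too close to the edge of) the window [",
           -window_up, ", ", window_down, "]")
  }
  records <- list(); truth <- list()
  for (i in seq_len(nrow(genes))) {
    sp <- genes$species[i]; g <- genes$gene_id[i]
    seq <- core_free_sequence(len, core)
    mine <- plants[nrow(plants) > 0 & plants$species == sp &
                     plants$gene_id == g, , drop = FALSE]
    if (nrow(mine)) {
      start19 <- tss + mine$position - 2L - 7L  # 0-based start of the 19-mer
      o <- order(start19)
      if (any(diff(start19[o]) < 19))
        stop("planted DREs overlap in promoter ", sp, "|", g)
      for (j in seq_len(nrow(mine))) {
        s19 <- mine$seq19
        s19 <- if (!is.null(s19) && !is.na(s19[j]) && nzchar(s19[j]))
          toupper(s19[j]) else random_dre_19mer(core)
        if (substr(s19, 8, 12) != core)
          stop("planted 19-mer lacks the core at positions 8-12: ", s19)
        ins <- if (mine$strand[j] == "-") revcomp(s19) else s19
        substr(seq, start19[j] + 1L, start19[j] + 19L) <- ins
        truth[[length(truth) + 1L]] <- data.frame(
          species = sp, gene_id = g, position = mine$position[j],
          strand = mine$strand[j], seq19 = s19, stringsAsFactors = FALSE)
      }
      # planting may create incidental cores at plant boundaries; reject
      expected <- sort(mine$position)
      sc <- core_positions(seq, tss, core)
      if (!identical(sort(sc), expected))
        seq <- patch_incidental_cores(seq, tss, core, expected)
    }
    records[[length(records) + 1L]] <-
      promoter_record(sp, g, seq, tss, window_up, window_down)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species = character(0), gene_id = character(0),
               position = integer(0), strand = character(0),
               seq19 = character(0))
  list(records = records, truth = truth)
}

# helper: core centers (TSS-relative) on both strands
core_positions <- function(seq, tss, core) {
  sort(c(find_all(seq, core), find_all(seq, revcomp(core))) - 1L + 2L - tss)
}

# resample single bases inside incidental (non-planted) core occurrences
# without touching any planted 19-mer
patch_incidental_cores <- function(seq, tss, core, expected,
                                   max_iter = 200L) {
  protected <- unlist(lapply(expected, function(p) {
    s <- tss + p - 2L - 7L
    seq(s + 1L, s + 19L)  # 1-based protected range
  }))
  for (iter in seq_len(max_iter)) {
    pos <- core_positions(seq, tss, core)
    extra <- setdiff(pos, expected)
    if (!length(extra)) return(seq)
    p <- extra[1]
    win <- (tss + p - 2L + 1L):(tss + p + 2L + 1L)  # 1-based core window
    editable <- setdiff(win, protected)
    if (!length(editable))
      stop("cannot remove incidental core overlapping a planted site")
    b <- editable[sample.int(length(editable), 1)]
    substr(seq, b, b) <- sample(c("A", "C", "G", "T"), 1)
  }
  stop("failed to remove incidental cores")
}

random_dre_19mer <- function(core = "GCGTG") {
  repeat {
    flank <- function() paste(sample(c("A", "C", "G", "T"), 7,
                                     replace = TRUE), collapse = "")
    s <- paste0(flank(), core, flank())
    # exactly one core occurrence, none on the reverse strand
    if (length(find_all(s, core)) == 1 && !length(find_all(s, revcomp(core))))
      return(s)
  }
}

#' Simulate a DRE training set
#'
#' Generates `n` 19-mers from a consensus by independent per-position
#' substitution: with probability `sub_rates[i]` position i is replaced by
#' a base drawn uniformly from the three alternatives. Stands in for a
#' curated collection of functional DREs when building a position weight
#' matrix.
#'
#' @param consensus 19-mer with the core at positions 8-12.
#' @param sub_rates per-position substitution probabilities (length 19).
#' @param n number of sequences (> 0).
#' @param seed RNG seed.
#' @return character vector of 19-mers.
#' @export
generate_dre_training_set <- function(consensus = DEFAULT_DRE_CONSENSUS,
                                      sub_rates = c(rep(0.1, 7), rep(0, 5),
                                                    rep(0.1, 7)),
                                      n = 100, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  if (nchar(consensus) != 19) stop("consensus must be a 19-mer")
  if (length(sub_rates) != 19) stop("sub_rates must have length 19")
  set.seed(seed)
  cons <- strsplit(consensus, "")[[1]]
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    s <- cons
    hit <- stats::runif(19) < sub_rates
    for (j in which(hit)) s[j] <- sample(setdiff(bases, cons[j]), 1)
    paste(s, collapse = "")
  }, "")
}

#' Default DRE consensus 19-mer (core GCGTG at positions 8-12)
#' @export
DEFAULT_DRE_CONSENSUS <- "CCTCAGGGCGTGCGGAGTT"

#' Write a set of 19-mers as FASTA
#' @param seqs character vector of sequences.
#' @param path output path.
#' @export
write_training_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- sprintf("dre_%04d", seq_along(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
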