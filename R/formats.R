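# Coordinate conventions used throughout:
#  * DRE positions are signed offsets with TSS = 0, upstream negative.
#  * Internal sequence indices are 0-based; BED output is 0-based half-open.

SPECIES_LEVELS <- c("human", "mouse", "rat")
TREATMENT_LEVELS <- c("vehicle", "TCDD", "CHX", "TCDD+CHX")
DYE_LEVELS <- c("Cy3", "Cy5")

#' Default analysis configuration
#'
#' Returns the configuration bundle used across the workflow: differential
#' expression thresholds (posterior probability P1(t) and absolute fold
#' change, both applied as strict inequalities), DRE scan settings (the
#' 5-bp core, flank width used to extend a core hit to a 19-mer, the
#' Euclidean distance threshold under which cross-species DREs are called
#' orthologous, and an optional minimum matrix similarity), cycloheximide
#' classification settings, and the master seed.
#'
#' @param ... named overrides, e.g. `de = list(p1_min = 0.99)`. Overrides
#'   are merged shallowly per section.
#' @return a named list with sections `de`, `dre`, `chx`, `eb` and `seed`.
#' @export
default_config <- function(...) {
  cfg <- list(
    de  = list(p1_min = 0.999, abs_fc_min = 1.4),
    dre = list(core = "GCGTG", flank_bp = 7, distance_threshold = 3.0,
               ms_min = 0),
    chx = list(retention_alpha = 0.5, times_hr = c(4, 12)),
    eb  = list(prior_df = 4, pi1 = 0.01, effect_var_scale = 25),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_config(cfg)
  cfg
}

#' Validate a configuration bundle
#'
#' @param cfg a list as returned by [default_config()] or [read_config()].
#' @return the validated config, invisibly usable; errors on violations.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  de <- cfg$de
  if (!is.numeric(de$p1_min) || de$p1_min < 0 || de$p1_min > 1)
    stop("de$p1_min must lie in [0, 1], got ", de$p1_min)
  if (!is.numeric(de$abs_fc_min) || de$abs_fc_min < 1)
    stop("de$abs_fc_min must be >= 1 (fold-change magnitude), got ",
         de$abs_fc_min)
  dre <- cfg$dre
  if (nchar(dre$core) != 5L)
    stop("dre$core must be a 5-mer, got '", dre$core, "'")
  if (!is.numeric(dre$distance_threshold) || dre$distance_threshold < 0)
    stop("dre$distance_threshold must be non-negative")
  if (!is.numeric(dre$ms_min) || dre$ms_min < 0 || dre$ms_min > 1)
    stop("dre$ms_min must lie in [0, 1]")
  chx <- cfg$chx
  if (!is.numeric(chx$retention_alpha) || chx$retention_alpha <= 0 ||
      chx$retention_alpha > 1)
    stop("chx$retention_alpha must lie in (0, 1]")
  invisible(cfg)
}

#' Read a configuration file
#'
#' The file is YAML mirroring the sections of [default_config()]; absent
#' fields fall back to the defaults.
#'
#' @param path path to a YAML config file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

## ---- sample sheets -------------------------------------------------------

#' Read and validate a sample sheet
#'
#' A sample sheet is a tab-delimited table with columns `sample_id`,
#' `species`, `treatment`, `time_hr`, `dye`, `replicate` and `array_id`.
#' Each two-color array must appear as exactly two rows (one per channel)
#' with opposite dyes.
#'
#' @param path tab-delimited file with a header row.
#' @return a validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet a data.frame to validate in place of reading a file.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "species", "treatment", "time_hr", "dye",
            "replicate", "array_id")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  bad_trt <- setdiff(unique(sheet$treatment), TREATMENT_LEVELS)
  if (length(bad_trt))
    stop("unknown treatment level(s): ", paste(bad_trt, collapse = ", "))
  bad_dye <- setdiff(unique(sheet$dye), DYE_LEVELS)
  if (length(bad_dye))
    stop("unknown dye(s): ", paste(bad_dye, collapse = ", "))
  if (any(sheet$replicate < 1))
    stop("replicate indices must be >= 1")
  for (aid in unique(sheet$array_id)) {
    rows <- sheet[sheet$array_id == aid, ]
    if (nrow(rows) != 2L || length(unique(rows$dye)) != 2L)
      stop("array '", aid, "' must have exactly two samples with opposite ",
           "dyes (found ", nrow(rows), " sample(s), dye(s): ",
           paste(rows$dye, collapse = ","), ")")
  }
  sheet
}

#' Write a sample sheet
#' @param sheet validated sample sheet data.frame.
#' @param path output path (TSV).
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- expression tables ---------------------------------------------------

#' Construct an expression table
#'
#' The main data carrier of the workflow: a probe-by-sample numeric matrix
#' together with probe/gene annotation and a value kind. For
#' `raw_two_channel` data the columns are channel samples (two per array);
#' after normalization the columns are arrays and the values are log2
#' ratios M of treated over control.
#'
#' @param values numeric matrix, rows probes, columns samples or arrays.
#' @param probe_id,gene_id character vectors along the rows.
#' @param value_kind `"raw_two_channel"` or `"log2_ratio"`.
#' @return an object of class `expression_table`.
#' @export
expression_table <- function(values, probe_id, gene_id,
                             value_kind = c("raw_two_channel", "log2_ratio")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  stopifnot(length(probe_id) == nrow(values),
            length(gene_id) == nrow(values))
  if (any(!nzchar(gene_id)))
    stop("gene_id must be nonempty for every probe")
  if (anyDuplicated(probe_id))
    stop("duplicate probe ids: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  rownames(values) <- probe_id
  structure(list(values = values, probe_id = as.character(probe_id),
                 gene_id = as.character(gene_id), value_kind = value_kind),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$values), "probes x", ncol(x$values),
      if (x$value_kind == "raw_two_channel") "channel samples" else "arrays",
      sprintf("(%s)\n", x$value_kind))
  invisible(x)
}

#' Read an expression matrix with its sample sheet
#'
#' The expression file is tab-delimited with columns `probe_id`, `gene_id`
#' and one numeric column per sample named by `sample_id`. Every sample
#' column must appear in the sheet and vice versa; non-numeric cells are a
#' hard error reported with row and column context. Empty cells encode
#' missing values.
#'
#' @param path expression TSV.
#' @param sample_sheet_path sample sheet TSV (see [read_sample_sheet()]).
#' @param value_kind the value kind of the stored matrix.
#' @return list with elements `expression` and `samples`.
#' @export
read_expression <- function(path, sample_sheet_path,
                            value_kind = "raw_two_channel") {
  sheet <- read_sample_sheet(sample_sheet_path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% names(tab)))
    stop("expression file must have probe_id and gene_id columns")
  sample_cols <- setdiff(names(tab), c("probe_id", "gene_id"))
  unmatched <- setdiff(sample_cols, sheet$sample_id)
  if (length(unmatched))
    stop("expression column(s) absent from the sample sheet: ",
         paste(unmatched, collapse = ", "))
  missing_samples <- setdiff(sheet$sample_id, sample_cols)
  if (length(missing_samples))
    stop("sample(s) in sheet but not in the expression file: ",
         paste(missing_samples, collapse = ", "))
  vals <- matrix(NA_real_, nrow(tab), length(sample_cols),
                 dimnames = list(tab$probe_id, sample_cols))
  for (j in sample_cols) {
    raw <- tab[[j]]
    empty <- !nzchar(trimws(raw)) | is.na(raw)
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop("non-numeric cell in expression file: row ", bad[1],
           " (probe '", tab$probe_id[bad[1]], "'), column '", j,
           "', value '", raw[bad[1]], "'")
    vals[, j] <- num
  }
  expr <- expression_table(vals, tab$probe_id, tab$gene_id,
                           value_kind = value_kind)
  list(expression = expr, samples = sheet)
}

#' Write an expression table
#' @param expr an `expression_table`.
#' @param path output TSV path.
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(probe_id = expr$probe_id, gene_id = expr$gene_id,
                    expr$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

## ---- ortholog tables -----------------------------------------------------

#' Read an ortholog mapping table
#'
#' Tab-delimited with columns `group_id`, `species`, `gene_id`, one row per
#' group membership (HomoloGene-style). Each (species, gene) pair may occur
#' in at most one group and every group must span at least two species.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_ortholog_table(tab)
}

#' @rdname read_ortholog_table
#' @param tab a data.frame to validate directly.
#' @export
validate_ortholog_table <- function(tab) {
  need <- c("group_id", "species", "gene_id")
  if (!all(need %in% names(tab)))
    stop("ortholog table needs columns: ", paste(need, collapse = ", "))
  key <- paste(tab$species, tab$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    stop("gene mapped to more than one ortholog group: ",
         paste(unique(paste0(dup$species, ":", dup$gene_id)), collapse = ", "))
  }
  nsp <- tapply(tab$species, tab$group_id, function(s) length(unique(s)))
  bad <- names(nsp)[nsp < 2]
  if (length(bad))
    stop("ortholog group(s) with fewer than two species: ",
         paste(bad, collapse = ", "))
  tab
}

#' @rdname read_ortholog_table
#' @export
write_ortholog_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- promoters -----------------------------------------------------------

#' Read promoter records from FASTA
#'
#' Headers follow the dialect `>species|gene_id|tss_index=<int>` where
#' `tss_index` is the 0-based index of the TSS base within the sequence.
#' Sequences are uppercased and must contain only A, C, G, T or N.
#'
#' @param fasta_path promoter FASTA.
#' @param window_up,window_down promoter window half-widths in bp (positive).
#' @return a list of `promoter_record` objects.
#' @export
read_promoters <- function(fasta_path, window_up = 10000, window_down = 1000) {
  set <- Biostrings::readBStringSet(fasta_path)
  lapply(seq_along(set), function(i) {
    promoter_record_from_header(names(set)[i], as.character(set[[i]]),
                                window_up, window_down)
  })
}

promoter_record_from_header <- function(header, sequence, window_up,
                                        window_down) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  if (length(parts) != 3L || !grepl("^tss_index=-?[0-9]+$", parts[3]))
    stop("malformed promoter header '", header,
         "'; expected species|gene_id|tss_index=<int>")
  tss <- as.integer(sub("^tss_index=", "", parts[3]))
  promoter_record(species = parts[1], gene_id = parts[2],
                  sequence = sequence, tss_index = tss,
                  window_up = window_up, window_down = window_down)
}

#' Construct a promoter record
#'
#' @param species,gene_id identifiers.
#' @param sequence DNA sequence (will be uppercased; ACGTN only).
#' @param tss_index 0-based index of the TSS base within `sequence`.
#' @param window_up,window_down scan window in bp around the TSS
#'   (defaults: 10 kb upstream, 1 kb downstream).
#' @return an object of class `promoter_record`.
#' @export
promoter_record <- function(species, gene_id, sequence, tss_index,
                            window_up = 10000, window_down = 1000) {
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0)
    stop("promoter ", species, "|", gene_id,
         ": invalid character '", substr(sequence, bad, bad),
         "' at position ", as.integer(bad))
  if (tss_index < 0 || tss_index >= nchar(sequence))
    stop("promoter ", species, "|", gene_id, ": tss_index ", tss_index,
         " out of bounds for sequence of length ", nchar(sequence))
  if (window_up <= 0 || window_down <= 0)
    stop("window bounds must be positive")
  structure(list(species = species, gene_id = gene_id, sequence = sequence,
                 tss_index = as.integer(tss_index),
                 window_up = window_up, window_down = window_down),
            class = "promoter_record")
}

#' Write promoter records to FASTA
#' @param records list of `promoter_record`s.
#' @param path output FASTA path.
#' @export
write_promoters <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r)
    sprintf("%s|%s|tss_index=%d", r$species, r$gene_id, r$tss_index), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

## ---- DRE hit files -------------------------------------------------------

#' Write DRE hits as TSV or BED
#'
#' TSV rows carry species, gene, TSS-relative core-center position, strand,
#' the 19-mer in DRE orientation and its matrix similarity. BED output
#' (0-based half-open over the 19-mer) requires genomic coordinates
#' (`chrom`, `genomic_start0` columns) on the hits and uses
#' `round(1000 * ms)` as the score.
#'
#' @param hits data.frame of DRE hits (see [extend_to_19mer()]).
#' @param path output path.
#' @param dialect `"tsv"` or `"bed"`.
#' @export
write_dre_hits <- function(hits, path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  cols <- c("species", "gene_id", "core_center", "strand", "seq19", "ms")
  if (dialect == "tsv") {
    out <- if (nrow(hits)) hits[, cols, drop = FALSE] else
      stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                      cols)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (nrow(hits) &&
        !all(c("chrom", "genomic_start0") %in% names(hits)))
      stop("BED output requires genomic coordinates ",
           "(chrom, genomic_start0 columns)")
    bed <- data.frame(
      chrom = if (nrow(hits)) hits$chrom else character(0),
      start = if (nrow(hits)) as.integer(hits$genomic_start0) else integer(0),
      end = if (nrow(hits)) as.integer(hits$genomic_start0) + 19L else
        integer(0),
      name = if (nrow(hits)) paste0(hits$species, ":", hits$gene_id) else
        character(0),
      score = if (nrow(hits)) as.integer(round(1000 * hits$ms)) else
        integer(0),
      strand = if (nrow(hits)) hits$strand else character(0))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a DRE hits TSV written by [write_dre_hits()]
#' @param path TSV path.
#' @return data.frame of hits.
#' @export
read_dre_hits <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

## ---- dendrograms ---------------------------------------------------------

#' Write a merge tree as Newick
#'
#' Accepts an `hclust` object (a binary merge tree with heights) and writes
#' Newick text with branch lengths derived from merge heights (leaves sit
#' at height zero, so a two-leaf tree merged at height h becomes
#' `(A:h,B:h);`). A single leaf may be given as a character scalar.
#'
#' @param tree an `hclust` object, or a single leaf label.
#' @param path output path.
#' @export
write_dendrogram <- function(tree, path) {
  if (is.character(tree) && length(tree) == 1L) {
    writeLines(paste0(tree, ";"), path)
    return(invisible(path))
  }
  if (!inherits(tree, "hclust"))
    stop("tree must be an hclust object (binary merge tree with heights)")
  if (ncol(tree$merge) != 2L)
    stop("merge tree must be binary")
  # edge length = height(parent) - height(child); leaves sit at height 0
  node_text <- function(idx) {
    if (idx < 0) return(list(text = tree$labels[-idx], height = 0))
    a <- node_text(tree$merge[idx, 1])
    b <- node_text(tree$merge[idx, 2])
    h <- tree$height[idx]
    list(text = sprintf("(%s:%s,%s:%s)", a$text, format(h - a$height),
                        b$text, format(h - b$height)),
         height = h)
  }
  writeLines(paste0(node_text(nrow(tree$merge))$text, ";"), path)
  invisible(path)
}
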