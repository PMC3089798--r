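# Shared builders for small in-code fixtures.

# minimal two-array dye-swap sample sheet for one species/time
tiny_sheet <- function(species = "mouse", time_hr = 24) {
  data.frame(
    sample_id = c("a1_T", "a1_C", "a2_T", "a2_C"),
    species = species,
    treatment = c("TCDD", "vehicle", "TCDD", "vehicle"),
    time_hr = time_hr,
    dye = c("Cy5", "Cy3", "Cy3", "Cy5"),
    replicate = c(1, 1, 1, 1),
    array_id = c("a1", "a1", "a2", "a2"),
    stringsAsFactors = FALSE)
}

`%+%` <- function(a, b) paste0(a, b)

# write a tiny expression TSV + sheet, return both paths
write_tiny_expression <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fix_")
    dir.create(dir)
  }
  sheet <- tiny_sheet()
  expr_path <- file.path(dir, "expr.tsv")
  sheet_path <- file.path(dir, "sheet.tsv")
  tab <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("g1", "g2", "g3"),
                    a1_T = c(100, 200, 300), a1_C = c(50, 100, 150),
                    a2_T = c(110, 190, 310), a2_C = c(55, 95, 160),
                    check.names = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_sample_sheet(sheet, sheet_path)
  list(expr = expr_path, sheet = sheet_path)
}

# brute-force both-strand 5-mer scanner: the independent oracle for
# scan_cores, written against the raw string only
oracle_scan <- function(sequence, tss_index, core = "GCGTG",
                        window_up = 10000, window_down = 1000) {
  rc <- function(x) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  hits <- list()
  for (s0 in 0:(nchar(sequence) - 5)) {
    w <- substr(sequence, s0 + 1, s0 + 5)
    center <- s0 + 2 - tss_index
    if (center < -window_up || center > window_down) next
    if (w == core)
      hits[[length(hits) + 1]] <- data.frame(core_center = center,
                                             strand = "+")
    if (w == rc(core))
      hits[[length(hits) + 1]] <- data.frame(core_center = center,
                                             strand = "-")
  }
  if (!length(hits))
    return(data.frame(core_center = integer(0), strand = character(0)))
  out <- do.call(rbind, hits)
  out[order(out$core_center, out$strand), , drop = FALSE]
}

# brute-force PWM rescoring oracle: naive per-position lookup
oracle_ms <- function(seq19, prob, weight) {
  b <- strsplit(seq19, "")[[1]]
  idx <- match(b, c("A", "C", "G", "T"))
  S <- sum(weight * prob[cbind(idx, seq_len(19))])
  smin <- sum(weight * apply(prob, 2, min))
  smax <- sum(weight * apply(prob, 2, max))
  (S - smin) / (smax - smin)
}

random_acgt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# random flank guaranteed free of the DRE core on either strand
random_flank <- function(n) {
  repeat {
    s <- random_acgt(n)
    if (!grepl("GCGTG|CACGC", s)) return(s)
  }
}
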