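# Dioxin response element (DRE) promoter analysis: scan for the invariant
# 5-bp core GCGTG on both strands of a TSS-anchored promoter window,
# extend hits by 7 bp of flank to a 19-mer, score against an
# information-weighted position weight matrix (matrix similarity in
# [0, 1]), and cluster orthologous 19-mers across species by Euclidean
# distance over one-hot encodings (threshold 3.0, i.e. at most 4
# mismatches).

#' Scan a promoter for DRE cores
#'
#' Finds every occurrence of the core on the plus strand and of its
#' reverse complement (the core on the minus strand) whose core center --
#' the third base of the 5-mer -- falls inside the record's TSS window.
#' Positions are signed TSS-relative offsets (TSS = 0, upstream negative):
#' `core_center = (0-based core start + 2) - tss_index`. `N` never
#' matches.
#'
#' @param record a `promoter_record`.
#' @param core the 5-bp core (default `"GCGTG"`).
#' @param strand `"both"` (default) or `"+"` for a plus-strand-only scan.
#' @return data.frame with `species`, `gene_id`, `core_center`, `strand`,
#'   `core_seq` (in DRE orientation) and `seq_start0` (0-based start of
#'   the 5-mer in the stored sequence).
#' @export
scan_cores <- function(record, core = "GCGTG", strand = c("both", "+")) {
  strand <- match.arg(strand)
  stopifnot(inherits(record, "promoter_record"), nchar(core) == 5L)
  subject <- Biostrings::DNAString(record$sequence)
  hit_tab <- function(pattern, strand_label) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject)
    starts0 <- Biostrings::start(m) - 1L
    data.frame(species = rep(record$species, length(starts0)),
               gene_id = rep(record$gene_id, length(starts0)),
               core_center = starts0 + 2L - record$tss_index,
               strand = rep(strand_label, length(starts0)),
               core_seq = rep(core, length(starts0)),
               seq_start0 = starts0, stringsAsFactors = FALSE)
  }
  hits <- hit_tab(core, "+")
  if (strand == "both") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(core)))
    hits <- rbind(hits, hit_tab(rc, "-"))
  }
  hits <- hits[hits$core_center >= -record$window_up &
                 hits$core_center <= record$window_down, , drop = FALSE]
  hits <- hits[order(hits$core_center, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Extend core hits to 19-mers in DRE orientation
#'
#' Each 5-bp core hit is extended by `flank_bp` (default 7) bases on both
#' sides. Minus-strand hits are reverse-complemented so the reported
#' 19-mer always carries the core at positions 8-12 in DRE orientation.
#' Hits with insufficient flanking sequence are dropped with a warning
#' rather than padded.
#'
#' @param hits data.frame from [scan_cores()] for this record.
#' @param record the same `promoter_record` the hits came from.
#' @param flank_bp flank width.
#' @return the hits with a `seq19` column (dropped rows removed).
#' @export
extend_to_19mer <- function(hits, record, flank_bp = 7) {
  stopifnot(inherits(record, "promoter_record"))
  if (nrow(hits) &&
      (!all(hits$species == record$species) ||
       !all(hits$gene_id == record$gene_id)))
    stop("hits do not belong to this promoter record")
  len <- nchar(record$sequence)
  s0 <- hits$seq_start0 - flank_bp
  e0 <- hits$seq_start0 + 4L + flank_bp
  ok <- s0 >= 0 & e0 <= len - 1L
  if (any(!ok))
    warning(sum(!ok), " core hit(s) in ", record$species, "|",
            record$gene_id, " dropped: fewer than ", flank_bp,
            " bp of flank available")
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits)) {
    hits$seq19 <- character(0)
    return(hits)
  }
  s0 <- s0[ok]; e0 <- e0[ok]
  seq19 <- substring(record$sequence, s0 + 1L, e0 + 1L)
  minus <- hits$strand == "-"
  if (any(minus)) seq19[minus] <- revcomp(seq19[minus])
  hits$seq19 <- seq19
  rownames(hits) <- NULL
  hits
}

## ---- position weight matrix ---------------------------------------------

#' Build a DRE position weight matrix from training 19-mers
#'
#' Column base probabilities are pseudocount-smoothed frequencies
#' `(count + pseudocount) / (n + 4 * pseudocount)`. Each position carries
#' an information weight `c_i = 2 + sum_b p log2 p` (zero for a uniform
#' column, 2 bits for a fixed base as n grows). The minimum and maximum
#' attainable raw scores are precomputed for similarity normalization.
#'
#' @param training character vector of 19-mers (ACGT only, n >= 2), or a
#'   FASTA path.
#' @param pseudocount per-base pseudocount (default 0.25).
#' @return object of class `dre_pwm`: `prob` (4 x 19), `weight` (length
#'   19), `s_min`, `s_max`, `consensus`.
#' @export
build_pwm <- function(training, pseudocount = 0.25) {
  if (length(training) == 1L && file.exists(training))
    training <- as.character(Biostrings::readDNAStringSet(training))
  training <- toupper(training)
  if (length(training) < 2) stop("need at least 2 training sequences")
  if (any(nchar(training) != 19))
    stop("training sequences must all be 19 bp")
  if (any(grepl("[^ACGT]", training)))
    stop("training sequences must contain only A, C, G, T")
  n <- length(training)
  chars <- do.call(rbind, strsplit(training, ""))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(19), function(i)
    vapply(bases, function(b) sum(chars[, i] == b), numeric(1)),
    numeric(4))
  prob <- (counts + pseudocount) / (n + 4 * pseudocount)
  weight <- apply(prob, 2, function(p) 2 + sum(p * log2(p)))
  weight <- pmax(weight, 0)  # guard tiny negative rounding at uniform
  s_min <- sum(weight * apply(prob, 2, min))
  s_max <- sum(weight * apply(prob, 2, max))
  structure(list(prob = prob, weight = weight, s_min = s_min,
                 s_max = s_max,
                 consensus = paste(bases[apply(prob, 2, which.max)],
                                   collapse = "")),
            class = "dre_pwm")
}

#' @export
print.dre_pwm <- function(x, ...) {
  cat("DRE position weight matrix (19 positions)\n",
      "consensus:", x$consensus, "\n",
      "score range: [", signif(x$s_min, 4), ",", signif(x$s_max, 4), "]\n")
  invisible(x)
}

#' Write / read a PWM as TSV (4 base rows x 19 columns plus a weights row)
#' @param pwm a `dre_pwm`.
#' @param path file path.
#' @export
write_pwm <- function(pwm, path) {
  tab <- rbind(pwm$prob, weight = pwm$weight)
  rownames(tab) <- c("A", "C", "G", "T", "weight")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     col.names = paste0("pos", 1:19))
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  tab <- as.matrix(utils::read.delim(path, row.names = 1))
  prob <- tab[c("A", "C", "G", "T"), ]
  weight <- as.numeric(tab["weight", ])
  dimnames(prob) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(prob = prob, weight = weight,
                 s_min = sum(weight * apply(prob, 2, min)),
                 s_max = sum(weight * apply(prob, 2, max)),
                 consensus = paste(c("A", "C", "G", "T")[
                   apply(prob, 2, which.max)], collapse = "")),
            class = "dre_pwm")
}

#' Matrix similarity of 19-mers against a PWM
#'
#' Information-weighted normalized score: raw score
#' `S = sum_i c_i * p_i(base_i)` rescaled to
#' `(S - s_min) / (s_max - s_min)`, so the consensus sequence scores 1 and
#' a per-position worst-base sequence scores 0.
#'
#' @param seq19 character vector of ACGT 19-mers.
#' @param pwm a `dre_pwm`.
#' @return numeric vector of similarities in [0, 1].
#' @export
matrix_similarity <- function(seq19, pwm) {
  seq19 <- toupper(seq19)
  if (any(nchar(seq19) != 19)) stop("sequences must be 19 bp")
  if (any(grepl("[^ACGT]", seq19)))
    stop("sequences must contain only A, C, G, T")
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  vapply(seq19, function(s) {
    idx <- base_idx[strsplit(s, "")[[1]]]
    S <- sum(pwm$weight * pwm$prob[cbind(idx, 1:19)])
    (S - pwm$s_min) / (pwm$s_max - pwm$s_min)
  }, numeric(1), USE.NAMES = FALSE)
}

## ---- sequence distance and orthologous clustering -----------------------

#' Euclidean distance between two 19-mers under one-hot encoding
#'
#' Each position is encoded as a one-hot vector over \{A,C,G,T\}; the
#' Euclidean distance between two sequences is then
#' `sqrt(2 * hamming(a, b))`. Under this encoding the orthologous-DRE
#' threshold of 3.0 admits at most 4 mismatches (sqrt(8) = 2.828) and
#' rejects 5 (sqrt(10) = 3.162).
#'
#' @param a,b equal-length ACGT sequences.
#' @return Euclidean distance.
#' @export
dre_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stop("sequences must contain only A, C, G, T")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sqrt(2 * sum(av != bv))
}

#' Cluster DRE 19-mers across species into orthologous groups
#'
#' Agglomerative clustering (complete linkage) over the one-hot Euclidean
#' distance, with the tree cut at `theta` (default 3.0). Complete linkage
#' guarantees that every within-cluster pairwise distance is at most
#' `theta`. A cluster is flagged orthologous when it holds hits from at
#' least two species. Hits are ordered by (species, position) before
#' clustering for deterministic output.
#'
#' @param hits data.frame of DRE hits (columns `species`, `gene_id`,
#'   `core_center`, `strand`, `seq19`), typically all hits of one ortholog
#'   group.
#' @param theta distance threshold.
#' @return list with `members` (the hits plus a `cluster` column) and
#'   `clusters` (per cluster: size, number of species, maximum pairwise
#'   distance, `orthologous` flag).
#' @export
cluster_orthologous_dres <- function(hits, theta = 3.0) {
  if (!nrow(hits)) {
    hits$cluster <- integer(0)
    return(list(members = hits,
                clusters = data.frame(cluster = integer(0),
                                      n_members = integer(0),
                                      n_species = integer(0),
                                      max_dist = numeric(0),
                                      orthologous = logical(0))))
  }
  hits <- hits[order(hits$species, hits$core_center, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  n <- nrow(hits)
  if (n == 1L) {
    cl <- 1L
  } else {
    dmat <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dmat[i, j] <- dmat[j, i] <- dre_distance(hits$seq19[i], hits$seq19[j])
    }
    tree <- stats::hclust(stats::as.dist(dmat), method = "complete")
    cl <- stats::cutree(tree, h = theta)
  }
  hits$cluster <- as.integer(cl)
  clusters <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    sub <- hits[hits$cluster == k, , drop = FALSE]
    md <- 0
    if (nrow(sub) > 1) {
      for (i in seq_len(nrow(sub) - 1)) for (j in (i + 1):nrow(sub))
        md <- max(md, dre_distance(sub$seq19[i], sub$seq19[j]))
    }
    data.frame(cluster = k, n_members = nrow(sub),
               n_species = length(unique(sub$species)),
               max_dist = md,
               orthologous = length(unique(sub$species)) >= 2 &&
                 md <= theta,
               stringsAsFactors = FALSE)
  }))
  list(members = hits, clusters = clusters)
}

#' Positional conservation within a DRE cluster
#'
#' Reports each member's signed TSS-relative core-center position and the
#' positional spread (max minus min). Descriptive only; no threshold is
#' applied.
#'
#' @param members data.frame of one cluster's hits (columns `species`,
#'   `gene_id`, `core_center`).
#' @return list with `positions` (the table) and `spread`.
#' @export
positional_conservation <- function(members) {
  if (!nrow(members)) stop("empty cluster")
  pos <- members[, c("species", "gene_id", "core_center")]
  list(positions = pos,
       spread = max(members$core_center) - min(members$core_center))
}

#' Scan, extend and score all promoters
#'
#' Convenience wrapper running [scan_cores()], [extend_to_19mer()] and
#' [matrix_similarity()] over a list of promoter records.
#'
#' @param records list of `promoter_record`s.
#' @param pwm a `dre_pwm` (or NULL to skip scoring).
#' @param core,strand,flank_bp scan parameters.
#' @param ms_min drop hits with matrix similarity below this value
#'   (default 0 keeps all scored hits).
#' @return data.frame of DRE hits with `ms` column (NA when unscored).
#' @export
scan_promoters <- function(records, pwm = NULL, core = "GCGTG",
                           strand = "both", flank_bp = 7, ms_min = 0) {
  out <- lapply(records, function(rec) {
    hits <- scan_cores(rec, core = core, strand = strand)
    hits <- extend_to_19mer(hits, rec, flank_bp = flank_bp)
    hits
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(species = character(0), gene_id = character(0),
                      core_center = integer(0), strand = character(0),
                      core_seq = character(0), seq_start0 = integer(0),
                      seq19 = character(0))
  }
  out$ms <- if (!is.null(pwm) && nrow(out))
    matrix_similarity(out$seq19, pwm) else rep(NA_real_, nrow(out))
  if (!is.null(pwm) && ms_min > 0) out <- out[out$ms >= ms_min, ,
                                              drop = FALSE]
  rownames(out) <- NULL
  out
}
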