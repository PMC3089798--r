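test_that("core scan matches the convention-forcing examples", {
  rec <- promoter_record("mouse", "g", "AAGCGTGAA", 0,
                         window_up = 100, window_down = 100)
  hits <- scan_cores(rec)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$core_center, 4L)
  expect_equal(hits$strand, "+")
  rec2 <- promoter_record("mouse", "g", "AACACGCAA", 0,
                          window_up = 100, window_down = 100)
  hits2 <- scan_cores(rec2)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$core_center, 4L)
  expect_equal(hits2$strand, "-")
  # N never matches
  recN <- promoter_record("mouse", "g", "AAGCGTNAA", 0,
                          window_up = 100, window_down = 100)
  expect_equal(nrow(scan_cores(recN)), 0)
})

test_that("core scan equals the brute-force oracle on random promoters", {
  set.seed(101)
  for (i in 1:60) {
    len <- sample(50:2000, 1)
    seq <- random_acgt(len)
    tss <- sample(0:(len - 1), 1)
    rec <- promoter_record("rat", paste0("g", i), seq, tss,
                           window_up = 10000, window_down = 1000)
    got <- scan_cores(rec)
    want <- oracle_scan(seq, tss)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$core_center, want$core_center)
    expect_equal(got$strand, want$strand)
  }
})

test_that("scanning the reverse complement mirrors hits with strands flipped", {
  set.seed(102)
  for (i in 1:20) {
    len <- 300
    seq <- random_acgt(len)
    tss <- 150
    rec <- promoter_record("rat", "g", seq, tss,
                           window_up = 200, window_down = 200)
    fwd <- scan_cores(rec)
    rc_seq <- chartr("ACGT", "TGCA",
                     paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
    rc_rec <- promoter_record("rat", "g", rc_seq, len - 1 - tss,
                              window_up = 200, window_down = 200)
    rev <- scan_cores(rc_rec)
    expect_equal(sort(-rev$core_center), sort(fwd$core_center))
    expect_equal(sum(fwd$strand == "+"), sum(rev$strand == "-"))
    expect_equal(sum(fwd$strand == "-"), sum(rev$strand == "+"))
  }
})

test_that("19-mer extension respects strand orientation and edges", {
  # plus-strand hit with full flanks carries the core at positions 8-12
  seq <- paste0(random_flank(7), "GCGTG", random_flank(7))
  rec <- promoter_record("mouse", "g", seq, 0,
                         window_up = 100, window_down = 100)
  hits <- extend_to_19mer(scan_cores(rec), rec)
  expect_equal(substr(hits$seq19, 8, 12), "GCGTG")
  # minus-strand hit reverse-complements into DRE orientation, and
  # rescanning the reported 19-mer finds the core on the plus strand
  seq_m <- paste0(random_flank(7), "CACGC", random_flank(7))
  rec_m <- promoter_record("mouse", "g", seq_m, 0,
                           window_up = 100, window_down = 100)
  hits_m <- extend_to_19mer(scan_cores(rec_m), rec_m)
  expect_equal(hits_m$strand, "-")
  expect_equal(substr(hits_m$seq19, 8, 12), "GCGTG")
  rec_check <- promoter_record("mouse", "chk", hits_m$seq19, 0,
                               window_up = 100, window_down = 100)
  rescan <- scan_cores(rec_check)
  expect_true(any(rescan$strand == "+" & rescan$seq_start0 == 7))
  # a core flush against the sequence start is dropped with a warning
  seq_edge <- paste0("GC", "GCGTG", random_flank(20))
  rec_edge <- promoter_record("mouse", "g", seq_edge, 0,
                              window_up = 100, window_down = 100)
  core_hits <- scan_cores(rec_edge)
  expect_warning(kept <- extend_to_19mer(core_hits, rec_edge), "dropped")
  expect_lt(nrow(kept), nrow(core_hits))
})

test_that("PWM construction matches counting with pseudocounts", {
  # n identical sequences: modal probability (n + 0.25) / (n + 1)
  n <- 8
  pwm <- build_pwm(rep(DEFAULT_DRE_CONSENSUS, n))
  expect_equal(max(pwm$prob[, 1]), (n + 0.25) / (n + 1))
  expect_equal(colSums(pwm$prob), rep(1, 19), ignore_attr = TRUE)
  expect_equal(pwm$consensus, DEFAULT_DRE_CONSENSUS)
  # mixed set: frequencies equal brute-force counts
  seqs <- generate_dre_training_set(n = 50, seed = 7)
  pwm2 <- build_pwm(seqs)
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (i in c(1, 5, 10, 19)) {
    want <- (sum(chars[, i] == "A") + 0.25) / (50 + 1)
    expect_equal(unname(pwm2$prob["A", i]), want)
  }
  # a uniform column has zero information weight
  uniform <- c("AAAA", "CCCC", "GGGG", "TTTT")
  seqs_u <- vapply(1:4, function(k)
    paste0(strrep(substr(uniform[k], 1, 1), 1),
           substr(DEFAULT_DRE_CONSENSUS, 2, 19)), "")
  pwm_u <- build_pwm(seqs_u)
  expect_equal(pwm_u$weight[1], 0, tolerance = 1e-12)
  expect_error(build_pwm(c("GCGTG", "GCGTG")), "19")
  expect_error(build_pwm(rep("ACGTACGTACGTACGTACG", 1)), "at least 2")
})

test_that("matrix similarity hits its bounds and decreases per mutation", {
  seqs <- generate_dre_training_set(n = 200, seed = 8)
  pwm <- build_pwm(seqs)
  expect_equal(matrix_similarity(pwm$consensus, pwm), 1)
  bases <- c("A", "C", "G", "T")
  worst <- paste(bases[apply(pwm$prob, 2, which.min)], collapse = "")
  expect_equal(matrix_similarity(worst, pwm), 0)
  # every one of the 57 single mutants scores strictly below the
  # consensus and matches a brute-force rescoring oracle
  cons <- strsplit(pwm$consensus, "")[[1]]
  for (i in 1:19) for (b in setdiff(bases, cons[i])) {
    mut <- cons; mut[i] <- b
    mut <- paste(mut, collapse = "")
    ms <- matrix_similarity(mut, pwm)
    expect_lt(ms, 1)
    expect_equal(ms, oracle_ms(mut, pwm$prob, pwm$weight))
  }
  # bounds hold for arbitrary sequences
  set.seed(9)
  rand <- vapply(1:50, function(i) random_acgt(19), "")
  ms <- matrix_similarity(rand, pwm)
  expect_true(all(ms >= 0 & ms <= 1))
  expect_error(matrix_similarity("ACGTNACGTACGTACGTAC", pwm), "A, C, G, T")
})

test_that("sequence distance is sqrt(2 x hamming) and a metric", {
  a <- DEFAULT_DRE_CONSENSUS
  expect_equal(dre_distance(a, a), 0)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (i in seq_len(k)) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  expect_equal(dre_distance(a, mut(a, 1)), sqrt(2))
  expect_equal(dre_distance(a, mut(a, 4)), sqrt(8))   # <= 3.0: clusterable
  expect_equal(dre_distance(a, mut(a, 5)), sqrt(10))  # > 3.0: rejected
  expect_lt(sqrt(8), 3.0); expect_gt(sqrt(10), 3.0)
  # enumerated mutant panel: closed form holds for every mismatch count
  for (k in 0:19) expect_equal(dre_distance(a, mut(a, k)), sqrt(2 * k))
  # metric properties on random triples
  set.seed(10)
  for (i in 1:25) {
    x <- random_acgt(19); y <- random_acgt(19); z <- random_acgt(19)
    expect_equal(dre_distance(x, y), dre_distance(y, x))
    expect_lte(dre_distance(x, z),
               dre_distance(x, y) + dre_distance(y, z) + 1e-12)
  }
  expect_error(dre_distance("ACGT", "ACGTA"), "length")
})

test_that("orthologous clustering separates conserved from dissimilar DREs", {
  hits <- data.frame(
    species = c("mouse", "rat", "human", "human"),
    gene_id = c("gm", "gr", "gh", "gh"),
    core_center = c(-5L, -22L, -100L, -4000L),
    strand = "+",
    seq19 = c("CTCCAGGGCGTGCGGAGTT",  # mouse
              "CTCCAGGGCGTGCGGAGAT",  # rat: 1 mismatch from mouse
              "AATTCTAGCGTGATCGTAC",  # human: far from both
              "TTAAGGCGCGTGTATATAC"), # human: far from everything
    stringsAsFactors = FALSE)
  res <- cluster_orthologous_dres(hits, theta = 3.0)
  expect_equal(nrow(res$clusters), 3)
  ortho <- res$clusters[res$clusters$orthologous, ]
  expect_equal(nrow(ortho), 1)
  members <- res$members[res$members$cluster == ortho$cluster, ]
  expect_setequal(members$species, c("mouse", "rat"))
  # positional conservation of the conserved pair
  pc <- positional_conservation(members)
  expect_equal(pc$spread, 17)
  expect_equal(positional_conservation(members[1, ])$spread, 0)
})

test_that("clustering respects the distance threshold at its extremes", {
  seqs <- c("CTCCAGGGCGTGCGGAGTT", "CTCCAGGGCGTGCGGAGTT",
            "AATTCTAGCGTGATCGTAC")
  hits <- data.frame(species = c("mouse", "rat", "human"),
                     gene_id = c("a", "b", "c"),
                     core_center = c(-1L, -2L, -3L), strand = "+",
                     seq19 = seqs, stringsAsFactors = FALSE)
  # theta = 0: only exact duplicates cluster
  res0 <- cluster_orthologous_dres(hits, theta = 0)
  expect_equal(nrow(res0$clusters), 2)
  expect_true(any(res0$clusters$n_members == 2 & res0$clusters$orthologous))
  # enormous theta: everything in one cluster
  res_inf <- cluster_orthologous_dres(hits, theta = 100)
  expect_equal(nrow(res_inf$clusters), 1)
  expect_true(res_inf$clusters$n_species[1] == 3)
  # all pairwise beyond theta: all singletons, none orthologous
  far <- data.frame(species = c("mouse", "rat", "human"),
                    gene_id = c("a", "b", "c"),
                    core_center = c(-1L, -2L, -3L), strand = "+",
                    seq19 = c("AAAAAAAGCGTGAAAAAAA",
                              "CCCCCCCGCGTGCCCCCCC",
                              "TTTTTTTGCGTGTTTTTTT"),
                    stringsAsFactors = FALSE)
  res_far <- cluster_orthologous_dres(far, theta = 3.0)
  expect_equal(nrow(res_far$clusters), 3)
  expect_false(any(res_far$clusters$orthologous))
  # three species pairwise within theta form one orthologous cluster
  near <- far
  near$seq19 <- c("CTCCAGGGCGTGCGGAGTT", "CTCCAGGGCGTGCGGAGAT",
                  "CTCCAGGGCGTGCGGAGAA")
  res_near <- cluster_orthologous_dres(near, theta = 3.0)
  expect_equal(nrow(res_near$clusters), 1)
  expect_true(res_near$clusters$orthologous[1])
  expect_equal(res_near$clusters$n_species[1], 3)
})

test_that("promoter scan pipeline recovers exactly the planted sites", {
  plants <- data.frame(species = c("mouse", "mouse", "rat"),
                       gene_id = c("g1", "g1", "g2"),
                       position = c(-800L, 30L, -10L),
                       strand = c("+", "-", "+"),
                       stringsAsFactors = FALSE)
  prom <- generate_promoters(plants, window_up = 1000, window_down = 100,
                             seed = 12)
  pwm <- build_pwm(generate_dre_training_set(n = 100, seed = 13))
  hits <- scan_promoters(prom$records, pwm)
  expect_equal(nrow(hits), 3)
  expect_setequal(hits$core_center, c(-800L, 30L, -10L))
  expect_setequal(hits$strand[hits$core_center == 30], "-")
  expect_true(all(hits$ms >= 0 & hits$ms <= 1))
  expect_true(all(substr(hits$seq19, 8, 12) == "GCGTG"))
})
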