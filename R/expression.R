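# Differential expression: intensity-dependent normalization, moderated-t
# empirical Bayes with posterior probability of activity P1(t), threshold
# calling, profile clustering.

treatment_rank <- c(vehicle = 0, CHX = 1, TCDD = 2, "TCDD+CHX" = 3)

#' Normalize raw two-channel arrays to log2 ratios
#'
#' For each array, forms M = log2(treated/control) and A = mean log2
#' intensity over the two channels, fits a smooth trend of M on A
#' (lowess by default, or a cubic polynomial), and subtracts it. Removing
#' the intensity-dependent trend cancels dye bias; because M is always
#' oriented treated-over-control, dye-swap replicates come out
#' sign-aligned. Within each pair the control is the channel with the
#' lower treatment rank (vehicle < CHX < TCDD < TCDD+CHX), so TCDD+CHX
#' arrays are expressed relative to CHX alone.
#'
#' @param expr a raw two-channel `expression_table`.
#' @param sheet the matching sample sheet.
#' @param method `"lowess"` or `"poly"` (cubic).
#' @param span lowess smoother span.
#' @return an `expression_table` of kind `log2_ratio` with one column per
#'   array and an `array_info` attribute (array id, species, time,
#'   replicate, contrast label).
#' @export
normalize_expression <- function(expr, sheet, method = c("lowess", "poly"),
                                 span = 0.4) {
  method <- match.arg(method)
  if (expr$value_kind != "raw_two_channel")
    stop("normalize_expression expects raw two-channel data")
  validate_sample_sheet(sheet)
  if (nrow(expr$values) < 20)
    stop("array has fewer than 20 probes; the intensity trend cannot be ",
         "fitted - supply log2 ratios directly instead")
  arrays <- unique(sheet$array_id)
  M_out <- matrix(NA_real_, nrow(expr$values), length(arrays),
                  dimnames = list(expr$probe_id, arrays))
  info <- vector("list", length(arrays))
  for (k in seq_along(arrays)) {
    rows <- sheet[sheet$array_id == arrays[k], ]
    rk <- treatment_rank[rows$treatment]
    if (rk[1] == rk[2])
      stop("array '", arrays[k], "' pairs two samples of equal treatment ",
           "rank (", rows$treatment[1], "); cannot orient the ratio")
    trt <- rows$sample_id[which.max(rk)]
    ctl <- rows$sample_id[which.min(rk)]
    Ti <- expr$values[, trt]; Ci <- expr$values[, ctl]
    ok <- is.finite(Ti) & is.finite(Ci) & Ti > 0 & Ci > 0
    M <- A <- rep(NA_real_, length(Ti))
    M[ok] <- log2(Ti[ok] / Ci[ok])
    A[ok] <- 0.5 * (log2(Ti[ok]) + log2(Ci[ok]))
    if (sum(ok) < 20)
      stop("array '", arrays[k], "' has fewer than 20 usable probes")
    trend <- fit_ma_trend(A[ok], M[ok], method, span)
    M[ok] <- M[ok] - trend
    M_out[, k] <- M
    info[[k]] <- data.frame(
      array_id = arrays[k], species = rows$species[1],
      time_hr = rows$time_hr[1], replicate = rows$replicate[1],
      contrast = paste(rows$treatment[which.max(rk)], "vs",
                       rows$treatment[which.min(rk)]),
      stringsAsFactors = FALSE)
  }
  out <- expression_table(M_out, expr$probe_id, expr$gene_id,
                          value_kind = "log2_ratio")
  attr(out, "array_info") <- do.call(rbind, info)
  out
}

fit_ma_trend <- function(A, M, method, span) {
  if (method == "lowess") {
    fit <- stats::lowess(A, M, f = span)
    stats::approx(fit$x, fit$y, xout = A, rule = 2)$y
  } else {
    z <- A - mean(A)
    stats::fitted(stats::lm(M ~ z + I(z^2) + I(z^3)))
  }
}

#' Array metadata attached by [normalize_expression()]
#' @param expr a normalized `expression_table`.
#' @return data.frame with one row per array.
#' @export
array_info <- function(expr) {
  ai <- attr(expr, "array_info")
  if (is.null(ai)) stop("no array_info attribute; normalize first")
  ai
}

#' Empirical-Bayes differential expression for one condition
#'
#' For the arrays selected by `species`, `time_hr` and `contrast`, computes
#' per gene the mean log2 ratio, a moderated t statistic with the residual
#' variance shrunk toward a pooled prior (prior df `d0`), and the posterior
#' probability of activity P1(t) from a two-component mixture: under the
#' null the moderated t follows a t distribution with augmented degrees of
#' freedom; under the active component the effect inflates its scale by
#' `sqrt(1 + effect_var_scale)`. P1 is strictly increasing in |t| at fixed
#' hyperparameters.
#'
#' @param expr normalized `expression_table` (kind `log2_ratio`).
#' @param species,time_hr,contrast condition selectors matched against the
#'   array metadata; `NULL` selects all.
#' @param prior_df prior degrees of freedom d0 for variance shrinkage.
#' @param pi1 prior probability that a gene is active.
#' @param effect_var_scale ratio of active-effect variance to the squared
#'   standard error of the mean.
#' @return data.frame with `gene_id`, `condition`, `n_arrays`, `m_bar`,
#'   `fc` (signed fold change, magnitude >= 1), `t_mod`, `p1`.
#' @export
fit_empirical_bayes <- function(expr, species = NULL, time_hr = NULL,
                                contrast = "TCDD vs vehicle",
                                prior_df = 4, pi1 = 0.01,
                                effect_var_scale = 25) {
  if (expr$value_kind != "log2_ratio")
    stop("fit_empirical_bayes expects normalized log2 ratios")
  ai <- array_info(expr)
  keep <- rep(TRUE, nrow(ai))
  if (!is.null(species)) keep <- keep & ai$species %in% species
  if (!is.null(time_hr)) keep <- keep & ai$time_hr %in% time_hr
  if (!is.null(contrast)) keep <- keep & ai$contrast %in% contrast
  if (sum(keep) < 2)
    stop("need at least 2 replicate arrays for the condition (found ",
         sum(keep), ")")
  vals <- expr$values[, ai$array_id[keep], drop = FALSE]
  n_obs <- rowSums(is.finite(vals))
  m_bar <- rowMeans(vals, na.rm = TRUE)
  m_bar[n_obs == 0] <- NA_real_
  resid_df <- pmax(n_obs - 1, 0)
  s2 <- apply(vals, 1, stats::var, na.rm = TRUE)
  s2[resid_df < 1] <- NA_real_
  if (prior_df <= 0 && all(resid_df < 1, na.rm = TRUE))
    stop("zero residual degrees of freedom and no prior: cannot moderate ",
         "variances")
  s2_prior <- mean(s2, na.rm = TRUE)
  if (!is.finite(s2_prior)) s2_prior <- 0.01
  s2_mod <- (prior_df * s2_prior + resid_df * ifelse(is.na(s2), 0, s2)) /
    (prior_df + resid_df)
  df_tot <- prior_df + resid_df
  se <- sqrt(s2_mod / pmax(n_obs, 1))
  t_mod <- m_bar / se
  p1 <- posterior_p1(t_mod, df_tot, pi1, effect_var_scale)
  cond <- paste0(
    if (!is.null(species)) paste0(species, collapse = "+") else "all", "_",
    if (!is.null(time_hr)) paste0("t", time_hr, collapse = "+") else "all",
    "_", if (!is.null(contrast)) gsub(" ", ".", contrast) else "all")
  out <- data.frame(gene_id = expr$gene_id, condition = cond,
                    n_arrays = as.integer(n_obs), m_bar = m_bar,
                    fc = signed_fold_change(m_bar), t_mod = t_mod, p1 = p1,
                    stringsAsFactors = FALSE, row.names = NULL)
  # genes never measured in this condition (e.g. another species' probes)
  # are not part of the platform for it
  out[out$n_arrays > 0, , drop = FALSE]
}

#' Posterior probability of activity from a moderated t value
#'
#' Two-component Gaussian mixture on the moderated statistic (the
#' theoretical-null form standard in large-scale testing): under the null
#' the statistic is N(0, 1); under the active component its variance is
#' inflated to 1 + c. Returns pi1*f1 / (pi1*f1 + (1-pi1)*f0), strictly
#' increasing in |t|.
#'
#' @param t moderated t values.
#' @param df total (augmented) degrees of freedom of the moderated
#'   statistic; retained for reporting, the mixture itself uses the
#'   Gaussian approximation justified by the variance shrinkage.
#' @param pi1 prior active proportion.
#' @param c effect-variance scale (variance of the active effect relative
#'   to the squared standard error).
#' @return posterior probabilities in [0, 1].
#' @export
posterior_p1 <- function(t, df = Inf, pi1 = 0.01, c = 25) {
  s <- sqrt(1 + c)
  lf0 <- stats::dnorm(t, log = TRUE)
  lf1 <- stats::dnorm(t / s, log = TRUE) - log(s)
  odds <- pi1 / (1 - pi1) * exp(lf1 - lf0)
  p <- odds / (1 + odds)
  p[is.infinite(odds)] <- 1
  p
}

#' Signed fold change from a mean log2 ratio
#'
#' Magnitude is always >= 1; the sign gives direction (-1.56 means
#' 1.56-fold down).
#'
#' @param m_bar mean log2 ratio.
#' @return signed fold change.
#' @export
signed_fold_change <- function(m_bar) {
  ifelse(is.na(m_bar), NA_real_,
         ifelse(m_bar >= 0, 2^m_bar, -(2^(-m_bar))))
}

#' Apply differential-expression thresholds
#'
#' A gene is significant in a condition when P1 strictly exceeds `p1_min`
#' and |fold change| strictly exceeds `abs_fc_min` (both boundaries
#' excluded). Direction is the sign of the fold change when significant,
#' `"ns"` otherwise.
#'
#' @param stats_df output of [fit_empirical_bayes()] (rows may span several
#'   conditions).
#' @param p1_min,abs_fc_min thresholds (defaults 0.999 and 1.4).
#' @return the input with `significant` and `direction` columns added.
#' @export
call_de <- function(stats_df, p1_min = 0.999, abs_fc_min = 1.4) {
  sig <- !is.na(stats_df$p1) & !is.na(stats_df$fc) &
    stats_df$p1 > p1_min & abs(stats_df$fc) > abs_fc_min
  dir <- ifelse(sig, ifelse(stats_df$fc > 0, "up", "down"), "ns")
  stats_df$significant <- sig
  stats_df$direction <- dir
  stats_df
}

#' Collapse per-condition calls to one row per gene
#'
#' `any_time` is TRUE when the gene is significant in at least one
#' condition. The per-gene direction is taken from the significant
#' condition with the largest |fold change| (deterministic tie-break by
#' condition label), `"ns"` when never significant.
#'
#' @param calls output of [call_de()].
#' @return data.frame with `gene_id`, `any_time`, `n_sig`, `direction`,
#'   `max_abs_fc`.
#' @export
de_call_summary <- function(calls) {
  split_idx <- split(seq_len(nrow(calls)), calls$gene_id)
  out <- lapply(names(split_idx), function(g) {
    rows <- calls[split_idx[[g]], ]
    sig <- rows[rows$significant, , drop = FALSE]
    if (nrow(sig)) {
      sig <- sig[order(-abs(sig$fc), sig$condition), , drop = FALSE]
      data.frame(gene_id = g, any_time = TRUE, n_sig = nrow(sig),
                 direction = sig$direction[1], max_abs_fc = abs(sig$fc[1]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = g, any_time = FALSE, n_sig = 0L,
                 direction = "ns",
                 max_abs_fc = suppressWarnings(max(abs(rows$fc), na.rm = TRUE)),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out[order(out$gene_id), , drop = FALSE]
}

#' Hierarchically cluster differential-expression profiles
#'
#' Agglomerative clustering of gene-by-condition log2-ratio profiles with
#' Euclidean distance and average linkage. Missing cells use
#' pairwise-complete distances rescaled by sqrt(total/observed). Rows are
#' ordered by gene id before clustering so the result is invariant to
#' input row order.
#'
#' @param mat numeric matrix, rows genes (rownames required), columns
#'   conditions.
#' @return an `hclust` object.
#' @export
cluster_de_profiles <- function(mat) {
  if (is.null(rownames(mat))) stop("profile matrix needs gene-id rownames")
  if (nrow(mat) < 2) stop("need at least two genes to cluster")
  all_missing <- rowSums(is.finite(mat)) == 0
  if (any(all_missing))
    stop("gene(s) with all-missing profiles: ",
         paste(rownames(mat)[all_missing], collapse = ", "))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  d <- stats::dist(mat)  # Euclidean; NA cells handled pairwise-complete,
                         # sum rescaled by total/observed dimensions
  stats::hclust(d, method = "average")
}

#' Percentage of responsive genes, to one decimal
#'
#' 100 * n_de / n_total rounded half-up to one decimal place (so 9.879
#' becomes 9.9 and 2.427 becomes 2.4).
#'
#' @param n_de number of differentially expressed genes.
#' @param n_total number of genes interrogated (> 0).
#' @return percentage with one decimal.
#' @export
response_percentage <- function(n_de, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_de < 0) || any(n_de > n_total))
    stop("need 0 <= n_de <= n_total")
  round_half_up(100 * n_de / n_total, 1)
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
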