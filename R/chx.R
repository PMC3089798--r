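# Primary vs secondary response classification from the 2x2 cycloheximide
# (CHX) co-treatment factorial: r0 = TCDD effect without CHX, r1 = TCDD
# effect under CHX (TCDD+CHX relative to CHX alone). Responses maintained
# or enhanced under CHX are putative primary (direct AhR) responses;
# attenuated or blocked responses are secondary.

#' Fit the 2x2 cycloheximide factorial
#'
#' For each requested time point, computes the TCDD-versus-vehicle
#' contrast r0 and the TCDD+CHX-versus-CHX contrast r1 with the
#' empirical-Bayes machinery of [fit_empirical_bayes()] applied per
#' contrast.
#'
#' @param expr normalized `expression_table` from a CHX factorial
#'   experiment (arrays carry contrasts `"TCDD vs vehicle"` and
#'   `"TCDD+CHX vs CHX"`).
#' @param times_hr time points to fit (default 4 and 12 h).
#' @param ... empirical-Bayes hyperparameters passed through.
#' @return data.frame with `gene_id`, `time_hr`, `r0`, `p1_r0`, `r1`,
#'   `p1_r1`.
#' @export
fit_factorial <- function(expr, times_hr = c(4, 12), ...) {
  ai <- array_info(expr)
  out <- list()
  for (t in times_hr) {
    for (ctr in c("TCDD vs vehicle", "TCDD+CHX vs CHX")) {
      if (!any(ai$time_hr == t & ai$contrast == ctr))
        stop("missing factorial condition: '", ctr, "' at ", t, " h")
    }
    f0 <- fit_empirical_bayes(expr, time_hr = t,
                              contrast = "TCDD vs vehicle", ...)
    f1 <- fit_empirical_bayes(expr, time_hr = t,
                              contrast = "TCDD+CHX vs CHX", ...)
    stopifnot(identical(f0$gene_id, f1$gene_id))
    out[[length(out) + 1L]] <- data.frame(
      gene_id = f0$gene_id, time_hr = t,
      r0 = f0$m_bar, p1_r0 = f0$p1,
      r1 = f1$m_bar, p1_r1 = f1$p1, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Classify primary vs secondary responses at one time point
#'
#' A gene is `nonresponsive` when r0 fails the DE thresholds. Among
#' responsive genes: `primary` when r1 also passes the thresholds, keeps
#' the sign of r0, and retains at least `retention_alpha` of its magnitude
#' (superinduction, |r1| > |r0|, always qualifies); `secondary` when r1
#' fails the thresholds or is attenuated below the retention cut;
#' `unclassified` for the remaining case of a significant sign flip.
#'
#' @param factorial data.frame from [fit_factorial()].
#' @param p1_min,abs_fc_min DE thresholds (strict inequalities).
#' @param retention_alpha minimum retained fraction |r1|/|r0| for a
#'   primary call, in (0, 1].
#' @return the input with a `class` column added.
#' @export
classify_primary_secondary <- function(factorial, p1_min = 0.999,
                                       abs_fc_min = 1.4,
                                       retention_alpha = 0.5) {
  if (retention_alpha <= 0 || retention_alpha > 1)
    stop("retention_alpha must lie in (0, 1]")
  fc0 <- signed_fold_change(factorial$r0)
  fc1 <- signed_fold_change(factorial$r1)
  resp <- !is.na(factorial$p1_r0) & !is.na(fc0) &
    factorial$p1_r0 > p1_min & abs(fc0) > abs_fc_min
  r1_pass <- !is.na(factorial$p1_r1) & !is.na(fc1) &
    factorial$p1_r1 > p1_min & abs(fc1) > abs_fc_min
  same_sign <- sign(factorial$r1) == sign(factorial$r0)
  retained <- abs(factorial$r1) >= retention_alpha * abs(factorial$r0)
  cls <- rep("unclassified", nrow(factorial))
  cls[!resp] <- "nonresponsive"
  is_primary <- resp & r1_pass & same_sign & retained
  cls[is_primary] <- "primary"
  is_secondary <- resp & !is_primary & (!r1_pass | !retained)
  cls[is_secondary] <- "secondary"
  factorial$class <- cls
  factorial
}

#' Merge classifications across the 4 h and 12 h factorials
#'
#' Identical classes keep that class; a primary or secondary call at one
#' time combined with `nonresponsive` at the other keeps the classified
#' call; a primary-versus-secondary conflict, or any combination involving
#' `unclassified`, is conservatively `unclassified`. Two `nonresponsive`
#' calls stay `nonresponsive`.
#'
#' @param class_a,class_b classes at the two time points.
#' @return merged class vector.
#' @export
merge_times <- function(class_a, class_b) {
  mapply(function(a, b) {
    if (a == b) return(a)
    if ("unclassified" %in% c(a, b)) return("unclassified")
    if (all(c("primary", "secondary") %in% c(a, b))) return("unclassified")
    setdiff(c(a, b), "nonresponsive")[1]
  }, class_a, class_b, USE.NAMES = FALSE)
}

#' End-to-end CHX classification
#'
#' Fits the factorial at both time points, classifies each, and merges.
#'
#' @param expr normalized factorial `expression_table`.
#' @param times_hr the two factorial time points.
#' @param p1_min,abs_fc_min,retention_alpha see
#'   [classify_primary_secondary()].
#' @param ... empirical-Bayes hyperparameters.
#' @return list with `per_time` (classified factorial table) and `merged`
#'   (gene_id, overall class).
#' @export
classify_chx <- function(expr, times_hr = c(4, 12), p1_min = 0.999,
                         abs_fc_min = 1.4, retention_alpha = 0.5, ...) {
  fac <- fit_factorial(expr, times_hr = times_hr, ...)
  fac <- classify_primary_secondary(fac, p1_min, abs_fc_min,
                                    retention_alpha)
  wide <- split(fac, fac$time_hr)
  stopifnot(length(wide) == 2)
  a <- wide[[1]][order(wide[[1]]$gene_id), ]
  b <- wide[[2]][order(wide[[2]]$gene_id), ]
  stopifnot(identical(a$gene_id, b$gene_id))
  merged <- data.frame(gene_id = a$gene_id,
                       class = merge_times(a$class, b$class),
                       stringsAsFactors = FALSE)
  list(per_time = fac, merged = merged)
}
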