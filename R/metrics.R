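#' Metrics configuration
#'
#' @param diff_threshold Relative score-difference threshold separating
#'   concordant from discordant shared sites (fraction, default 0.05).
#' @param p_definition How to count "different" variants between the two
#'   callsets: `"symmetric"` (symmetric difference, default) or
#'   `"missed_by_A"` (variants in B absent from A).
#' @param missing_denominator Denominator of the missing rate: `"m"`
#'   (callset A, default) or `"n"` (callset B).
#' @return A `metrics_config` list.
#' @export
metrics_config <- function(diff_threshold = 0.05,
                           p_definition = c("symmetric", "missed_by_A"),
                           missing_denominator = c("m", "n")) {
  stopifnot(diff_threshold > 0, diff_threshold < 1)
  structure(list(diff_threshold = diff_threshold,
                 p_definition = match.arg(p_definition),
                 missing_denominator = match.arg(missing_denominator)),
            class = "metrics_config")
}

# one key per (chrom, pos, ref, alt); multi-allelic rows expand to one key
# per alternate allele, sharing the site QUAL
.callset_keys <- function(x) {
  vs <- if (inherits(x, "variant_set")) x else read_vcf(x)
  if (!n_variants(vs))
    return(data.frame(key = character(0), score = numeric(0)))
  alts <- strsplit(vs$alt, ",", fixed = TRUE)
  nn <- lengths(alts)
  idx <- rep(seq_along(nn), nn)
  out <- data.frame(
    key = paste(vs$chrom[idx], vs$pos1[idx], vs$ref[idx],
                unlist(alts), sep = ":"),
    score = vs$qual[idx],
    stringsAsFactors = FALSE)
  out[!duplicated(out$key), , drop = FALSE]
}

#' Compare two callsets
#'
#' Matches variants exactly on the (chrom, pos, ref, alt) key. With A the
#' callset under evaluation and B the comparator: `m` and `n` are the two
#' key sets with their QUAL scores, `l` their intersection, and `p_count`
#' the number of "different" variants between them (symmetric difference
#' by default).
#'
#' @param a,b VCF paths or `variant_set`s (A first).
#' @param config A [metrics_config()].
#' @return A `callset_comparison`: `m`, `n` (key/score data.frames),
#'   `l_keys`, `l_scores` (paired scores over the intersection),
#'   `p_count`.
#' @export
compare_callsets <- function(a, b, config = metrics_config()) {
  m <- .callset_keys(a)
  n <- .callset_keys(b)
  l_keys <- intersect(m$key, n$key)
  s_a <- m$score[match(l_keys, m$key)]
  s_b <- n$score[match(l_keys, n$key)]
  if (length(l_keys) && (anyNA(s_a) || anyNA(s_b)))
    stop(sprintf("missing QUAL on matched key(s): %s",
                 paste(utils::head(l_keys[is.na(s_a) | is.na(s_b)], 3L),
                       collapse = ", ")), call. = FALSE)
  p_count <- switch(config$p_definition,
    symmetric = length(setdiff(m$key, n$key)) + length(setdiff(n$key, m$key)),
    missed_by_A = length(setdiff(n$key, m$key)))
  structure(list(m = m, n = n, l_keys = l_keys,
                 l_scores = data.frame(s_a = s_a, s_b = s_b),
                 p_count = p_count, config = config),
            class = "callset_comparison")
}

#' @export
print.callset_comparison <- function(x, ...) {
  cat(sprintf(
    "callset_comparison: |m|=%d |n|=%d |l|=%d p=%d (%s)\n",
    nrow(x$m), nrow(x$n), length(x$l_keys), x$p_count,
    x$config$p_definition))
  invisible(x)
}

#' Missing rate between two callsets
#'
#' Number of different variants over the size of callset A (or B when the
#' configuration selects the `n` denominator).
#'
#' @param cmp A `callset_comparison`.
#' @return Fraction in `[0, ...)`.
#' @export
missing_rate <- function(cmp) {
  denom <- switch(cmp$config$missing_denominator,
                  m = nrow(cmp$m), n = nrow(cmp$n))
  if (denom == 0L)
    stop("missing rate undefined: empty denominator callset", call. = FALSE)
  cmp$p_count / denom
}

#' Relative score difference of a shared site
#'
#' `|s_a - s_b| / max(s_a, s_b)`, using the larger score as base so the
#' measure is scale-free across callers with different QUAL conventions;
#' defined as 0 when both scores are 0. Vectorized.
#'
#' @param s_a,s_b Non-negative scores.
#' @return Fractions in `[0, 1]`.
#' @export
relative_score_difference <- function(s_a, s_b) {
  stopifnot(all(s_a >= 0), all(s_b >= 0))
  mx <- pmax(s_a, s_b)
  ifelse(mx == 0, 0, abs(s_a - s_b) / mx)
}

#' Difference rate over the shared sites
#'
#' Fraction of the intersection whose relative score difference is at or
#' above the threshold.
#'
#' @param cmp A `callset_comparison`.
#' @return Fraction in `[0, 1]`.
#' @export
difference_rate <- function(cmp) {
  if (!length(cmp$l_keys))
    stop("difference rate undefined: empty intersection", call. = FALSE)
  d <- relative_score_difference(cmp$l_scores$s_a, cmp$l_scores$s_b)
  mean(d >= cmp$config$diff_threshold)
}

#' Score correlation over concordant shared sites
#'
#' Pearson correlation of the paired QUAL scores restricted to shared
#' sites whose relative score difference is at or below the threshold.
#' With fewer than two concordant pairs, or zero variance on either side,
#' the correlation is undefined and an `undefined_metric` signal (not a
#' number) is returned with an explanation.
#'
#' @param cmp A `callset_comparison`.
#' @return A correlation coefficient, or an `undefined_metric` object.
#' @export
score_correlation <- function(cmp) {
  d <- relative_score_difference(cmp$l_scores$s_a, cmp$l_scores$s_b)
  keep <- d <= cmp$config$diff_threshold
  s_a <- cmp$l_scores$s_a[keep]
  s_b <- cmp$l_scores$s_b[keep]
  if (length(s_a) < 2L)
    return(undefined_metric(sprintf(
      "correlation undefined: %d concordant pair(s), need at least 2",
      length(s_a))))
  if (stats::var(s_a) == 0 || stats::var(s_b) == 0)
    return(undefined_metric(
      "correlation undefined: zero score variance among concordant pairs"))
  stats::cor(s_a, s_b)
}

#' Undefined-metric signal
#' @param reason Human-readable explanation.
#' @return An `undefined_metric` object.
#' @export
undefined_metric <- function(reason) {
  structure(list(reason = reason), class = "undefined_metric")
}

#' @export
print.undefined_metric <- function(x, ...) {
  cat("undefined metric:", x$reason, "\n")
  invisible(x)
}

#' Full concordance report between two VCFs
#'
#' Computes the comparison and all three metrics; optionally writes them
#' as JSON.
#'
#' @param a,b VCF paths or `variant_set`s.
#' @param config A [metrics_config()].
#' @param json Optional output path for a JSON report.
#' @return List with counts, rates, correlation and the thresholds used.
#' @export
concordance_report <- function(a, b, config = metrics_config(),
                               json = NULL) {
  cmp <- compare_callsets(a, b, config)
  corr <- score_correlation(cmp)
  out <- list(
    n_a = nrow(cmp$m), n_b = nrow(cmp$n),
    n_shared = length(cmp$l_keys), p_count = cmp$p_count,
    missing_rate = if (nrow(cmp$m)) missing_rate(cmp) else NA_real_,
    difference_rate = if (length(cmp$l_keys)) difference_rate(cmp)
                      else NA_real_,
    correlation = if (inherits(corr, "undefined_metric")) NA_real_ else corr,
    correlation_note = if (inherits(corr, "undefined_metric")) corr$reason
                       else "",
    diff_threshold = config$diff_threshold,
    p_definition = config$p_definition)
  if (!is.null(json))
    jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA)
  out
}
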