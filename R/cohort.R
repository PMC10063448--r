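#' Rank-percentile single-sample signature score
#'
#' Within each sample, genes are ranked (average ties) and converted to rank
#' percentiles; the score is the mean percentile of the signature genes. The
#' score depends only on within-sample ranks, so it is invariant to any
#' strictly increasing per-sample transform of expression. This is a
#' self-contained rank-based enrichment score; it preserves the analysis
#' logic (score, median split, response comparison) without an external
#' enrichment tool.
#'
#' @param cohort Wide cohort tibble (see [simulate_cohort()]): `sample_id`,
#'   gene columns, and clinical columns `time`, `event`, `response`, `arm`.
#' @param signature Character vector of gene names, or a `gene_signature`.
#' @return Tibble: `sample_id`, `score`, plus the cohort's clinical columns;
#'   the signature/cohort overlap size is the `"n_overlap"` attribute.
#' @export
sample_signature_score <- function(cohort, signature) {
  if (inherits(signature, "gene_signature") || is.data.frame(signature)) {
    signature <- signature$gene
  }
  clinical <- intersect(c("time", "event", "response", "arm", "true_fraction"),
                        names(cohort))
  gene_cols <- setdiff(names(cohort), c("sample_id", clinical))
  overlap <- intersect(signature, gene_cols)
  if (!length(overlap)) abort("signature has no overlap with the cohort genes.")
  expr <- as.matrix(cohort[, gene_cols, drop = FALSE])
  g <- ncol(expr)
  scores <- apply(expr, 1, function(v) {
    mean(rank(v)[match(overlap, gene_cols)]) / g
  })
  out <- dplyr::bind_cols(
    tibble(sample_id = cohort$sample_id, score = unname(scores)),
    cohort[, clinical, drop = FALSE]
  )
  attr(out, "n_overlap") <- length(overlap)
  out
}

#' Median split of signature scores
#'
#' Samples strictly above the median are `"high"`; at or below the median,
#' `"low"` (the tie convention, so an odd cohort's median sample is low).
#' All-equal scores produce an all-low split with a warning.
#'
#' @param scores Numeric vector.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) abort("need at least 2 samples to split.")
  med <- median(scores)
  if (all(scores == scores[1])) warn("all scores equal; every sample labelled low.")
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit`; at tied times, events are handled before
#' censorings, per the standard product-limit convention.
#'
#' @param time,event Equal-length follow-up times and 0/1 event indicators.
#' @param group Optional group factor for stratified curves.
#' @return A `gdtcr_km` object; `tidy()` gives the per-time curve
#'   (`time`, `n_risk`, `n_event`, `estimate`, and `group` when stratified).
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  if (!length(time)) abort("empty survival input.")
  if (length(time) != length(event)) abort("`time` and `event` lengths differ.")
  df <- data.frame(time = time, event = event)
  fit <- if (is.null(group)) {
    survival::survfit(survival::Surv(time, event) ~ 1, data = df)
  } else {
    df$group <- group
    survival::survfit(survival::Surv(time, event) ~ group, data = df)
  }
  structure(list(fit = fit, grouped = !is.null(group)), class = "gdtcr_km")
}

#' @method tidy gdtcr_km
#' @export
tidy.gdtcr_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  out <- tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    estimate = s$surv
  )
  if (x$grouped) out$group <- sub("^group=", "", as.character(s$strata))
  out
}

#' @method glance gdtcr_km
#' @export
glance.gdtcr_km <- function(x, ...) {
  med <- summary(x$fit)$table
  if (is.null(dim(med))) med <- matrix(med, nrow = 1, dimnames = list("all", names(med)))
  tibble(
    group = rownames(med),
    n = med[, "records"],
    events = med[, "events"],
    median_survival = med[, "median"]
  )
}

#' @export
print.gdtcr_km <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Chi-square statistic on one degree of freedom via `survival::survdiff`.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Two-level group factor/vector.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2) abort("log-rank test needs exactly two groups.")
  if (min(table(g)) == 0) abort("a group has no subjects.")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  tibble(
    statistic = sd$chisq, df = 1L,
    p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  )
}

#' Truncate survival at a horizon
#'
#' Administrative censoring at `horizon` months (default 60, a five-year
#' analysis): later times are set to the horizon with `event = 0`.
#'
#' @param time,event Survival vectors.
#' @param horizon Truncation time in months.
#' @return Tibble with truncated `time` and `event`.
#' @export
truncate_survival <- function(time, event, horizon = 60) {
  over <- time > horizon
  tibble(time = pmin(time, horizon), event = ifelse(over, 0L, as.integer(event)))
}

#' Associate signature scores with clinical response
#'
#' Two-sided Wilcoxon rank-sum comparison of scores between responders
#' (CR/PR) and non-responders (SD/PD), with per-class medians and quartiles
#' for box-plot-style reporting.
#'
#' @param scores Numeric score vector.
#' @param response Character/factor vector with two classes (responders
#'   detected by the `"CR"` prefix match `"CR/PR"`, everything else SD/PD).
#' @return One-row tibble: `statistic` (W), `p_value`, per-class `n`,
#'   `median` and quartiles.
#' @export
response_association <- function(scores, response) {
  resp <- grepl("^CR", as.character(response))
  if (!any(resp) || all(resp)) abort("both response classes must be present.")
  a <- scores[resp]; b <- scores[!resp]
  exact <- length(a) <= 25 && length(b) <= 25 && !any(duplicated(c(a, b)))
  res <- suppressWarnings(wilcox.test(a, b, exact = exact))
  q <- function(v, p) unname(quantile(v, p))
  tibble(
    statistic = unname(res$statistic), p_value = res$p.value,
    n_responder = length(a), n_nonresponder = length(b),
    median_responder = median(a), median_nonresponder = median(b),
    q1_responder = q(a, .25), q3_responder = q(a, .75),
    q1_nonresponder = q(b, .25), q3_nonresponder = q(b, .75)
  )
}
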