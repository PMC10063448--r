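#' Configure a synthetic bulk cohort
#'
#' Configuration for [simulate_cohort()]. Each sample carries a planted
#' signature fraction; survival hazard is log-linear and response probability
#' logit-linear in the standardized fraction, so positive effects make
#' high-signature samples die faster (or slower, if the hazard ratio is below
#' one) and respond accordingly.
#'
#' @param n_samples Number of cohort samples.
#' @param signature_fraction_range Uniform range of the planted per-sample
#'   signature fraction.
#' @param hazard_ratio_per_sd Hazard ratio per standard deviation of the
#'   planted fraction (1 = null).
#' @param response_logit_slope Log-odds slope of response per SD of the
#'   planted fraction (0 = null). Baseline response rate is 30%.
#' @param censor_rate Expected censoring proportion at the null
#'   (exponential censoring competing with an exponential event time).
#' @param n_genes Size of the expression panel.
#' @param signature_genes Genes whose expression scales with the planted
#'   fraction (`signature_effect` log-units per unit fraction).
#' @param signature_effect Log-scale expression shift per unit fraction.
#' @param median_survival Median survival in months at the standardized
#'   fraction's mean (default 24, a realistic advanced-cancer figure).
#' @param seed Integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_samples = 200,
                              signature_fraction_range = c(0, 0.5),
                              hazard_ratio_per_sd = 1,
                              response_logit_slope = 0,
                              censor_rate = 0.3,
                              n_genes = 200,
                              signature_genes = paste0("SIG", seq_len(20)),
                              signature_effect = 2,
                              median_survival = 24,
                              seed = 1L) {
  if (censor_rate < 0 || censor_rate >= 1) abort("`censor_rate` must be in [0, 1).")
  if (hazard_ratio_per_sd <= 0) abort("`hazard_ratio_per_sd` must be positive.")
  if (length(signature_fraction_range) != 2 ||
      diff(signature_fraction_range) <= 0 ||
      any(signature_fraction_range < 0) || any(signature_fraction_range > 1)) {
    abort("`signature_fraction_range` must be an increasing pair inside [0, 1].")
  }
  if (n_genes < length(signature_genes)) {
    abort("`n_genes` smaller than the signature panel.")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      signature_fraction_range = signature_fraction_range,
      hazard_ratio_per_sd = hazard_ratio_per_sd,
      response_logit_slope = response_logit_slope,
      censor_rate = censor_rate, n_genes = as.integer(n_genes),
      signature_genes = signature_genes, signature_effect = signature_effect,
      median_survival = median_survival, seed = as.integer(seed)
    ),
    class = "cohort_sim_config"
  )
}

#' Simulate a bulk expression cohort with survival and response
#'
#' Expression is a log-scale background profile plus, for signature genes, a
#' shift proportional to the sample's planted signature fraction. Survival
#' times are exponential with log-hazard linear in the standardized fraction;
#' censoring is an independent exponential calibrated to `censor_rate` at the
#' null. Response is Bernoulli with logit linear in the same covariate.
#'
#' @param config A [cohort_sim_config()].
#' @return A wide tibble: `sample_id`, one column per gene, then `time`
#'   (months), `event` (0/1), `response` (`"CR/PR"`/`"SD/PD"`), `arm`, and
#'   the planted `true_fraction`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    ng <- config$n_genes
    sig <- config$signature_genes
    genes <- c(sig, sprintf("BG%04d", seq_len(ng - length(sig))))
    f <- runif(n, config$signature_fraction_range[1], config$signature_fraction_range[2])
    z <- as.numeric(scale(f))

    base <- rnorm(ng, 5, 1)
    expr <- matrix(rnorm(n * ng, 0, 1), n, ng, dimnames = list(NULL, genes))
    expr <- sweep(expr, 2, base, "+")
    expr[, sig] <- expr[, sig] + config$signature_effect * f

    h0 <- log(2) / config$median_survival
    haz <- h0 * config$hazard_ratio_per_sd^z
    t_event <- rexp(n, rate = haz)
    if (config$censor_rate > 0) {
      cens_rate <- h0 * config$censor_rate / (1 - config$censor_rate)
      t_cens <- rexp(n, rate = cens_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    p_resp <- plogis(qlogis(0.3) + config$response_logit_slope * z)
    response <- ifelse(rbinom(n, 1, p_resp) == 1, "CR/PR", "SD/PD")

    dplyr::bind_cols(
      tibble(sample_id = sprintf("SAMPLE%04d", seq_len(n))),
      as_tibble(expr),
      tibble(
        time = time, event = event, response = response,
        arm = "synthetic", true_fraction = f
      )
    )
  })
}
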