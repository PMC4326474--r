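# broom-style accessors for the fitted/result objects

#' @method tidy anneal_fit
#' @export
tidy.anneal_fit <- function(x, ...) x$ordering

#' @method glance anneal_fit
#' @export
glance.anneal_fit <- function(x, ...) {
  tibble(n = nrow(x$ordering), alpha = x$config$alpha, beta = x$config$beta,
         f_init = x$f_init, f_best = x$f_best, n_mcs = nrow(x$trace),
         final_temperature = x$trace$temperature[nrow(x$trace)],
         seed = x$config$seed)
}

#' @method tidy variance_components
#' @export
tidy.variance_components <- function(x, ...) x$genes

#' @method glance variance_components
#' @export
glance.variance_components <- function(x, ...) {
  tibble(sigma2_xi = x$summary$sigma2_xi, sigma2_b = x$summary$sigma2_b,
         sigma_xi = sqrt(x$summary$sigma2_xi),
         sigma_b = sqrt(x$summary$sigma2_b),
         kappa_bar = mean(x$positions$kappa_bar, na.rm = TRUE),
         r = x$summary$r)
}

#' @method tidy noise_report
#' @export
tidy.noise_report <- function(x, ...) x$positions

#' @method glance noise_report
#' @export
glance.noise_report <- function(x, ...) {
  tibble(Omega = x$Omega, omega = x$omega, snr = x$snr,
         global_mean = x$global_mean, n_replicates = x$n_replicates)
}

#' @method glance xgram_comparison
#' @export
glance.xgram_comparison <- function(x, ...) {
  tibble(n_positions = sum(!is.na(x$p_value)),
         family_size = attr(x, "family_size"),
         bonferroni_threshold = attr(x, "bonferroni_threshold"),
         n_bonferroni = sum(x$bonferroni, na.rm = TRUE),
         n_q05 = sum(x$q_value < 0.05, na.rm = TRUE),
         pi0 = attr(x, "pi0"))
}
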