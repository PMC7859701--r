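#' Two-allele TZ-incorporation competition model
#'
#' In a heterozygote carrying one fluorescently tagged and one untagged
#' allele, the two protein pools compete for a fixed number of TZ docking
#' sites. With first-order incorporation efficiencies `k_tagged` and
#' `k_untagged`, the tagged protein occupies a fraction
#' `k_tagged / (k_tagged + k_untagged)` of the sites, so heterozygote
#' fluorescence is that fraction of the tagged-homozygote signal
#' (`site_capacity`). Equal efficiencies predict exactly half the
#' homozygote fluorescence; a non-competing untagged variant leaves the
#' tagged signal near 100%.
#'
#' @param k_tagged,k_untagged nonnegative incorporation efficiencies of the
#'   tagged and untagged alleles' proteins.
#' @param site_capacity total TZ fluorescence of the tagged homozygote
#'   (arbitrary intensity units, default 1).
#' @return An object of class `competition_model`.
#' @export
competition_model <- function(k_tagged, k_untagged, site_capacity = 1) {
  check_that(is.numeric(k_tagged) && k_tagged >= 0,
             "k_tagged must be nonnegative")
  check_that(is.numeric(k_untagged) && k_untagged >= 0,
             "k_untagged must be nonnegative")
  if (k_tagged + k_untagged <= 0)
    stop("degenerate competition: k_tagged + k_untagged must be positive",
         call. = FALSE)
  check_that(is.numeric(site_capacity) && site_capacity > 0,
             "site_capacity must be positive")
  structure(list(k_tagged = k_tagged, k_untagged = k_untagged,
                 site_capacity = site_capacity),
            class = "competition_model")
}

#' @export
print.competition_model <- function(x, ...) {
  cat(sprintf(
    "<competition_model> k_tagged %.3g, k_untagged %.3g -> het fraction %.3f\n",
    x$k_tagged, x$k_untagged, predict_het_fraction(x)))
  invisible(x)
}

#' Predicted heterozygote fluorescence fraction
#'
#' @param model a [competition_model].
#' @return `k_tagged / (k_tagged + k_untagged)`, the predicted heterozygote
#'   TZ fluorescence as a fraction of the homozygote `site_capacity`.
#' @export
predict_het_fraction <- function(model) {
  check_that(inherits(model, "competition_model"),
             "model must be a competition_model")
  model$k_tagged / (model$k_tagged + model$k_untagged)
}

#' Simulate heterozygote and homozygote fluorescence cohorts
#'
#' Draws `n` homozygote measurements centred on the model's
#' `site_capacity` and `n` heterozygote measurements centred on
#' `predict_het_fraction(model) * site_capacity`, with multiplicative
#' lognormal noise of the stated coefficient of variation (the lognormal
#' is parameterised so the arithmetic means equal the targets).
#'
#' @param model a [competition_model].
#' @param n number of worms per group.
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (0 gives exact values).
#' @param seed integer seed.
#' @return A list with numeric vectors `het` and `homo` and the predicted
#'   `fraction`.
#' @export
simulate_het_cohort <- function(model, n, noise_cv = 0.2, seed = 1L) {
  check_that(inherits(model, "competition_model"),
             "model must be a competition_model")
  check_that(n >= 1, "n must be at least 1")
  check_that(noise_cv >= 0, "noise_cv must be nonnegative")
  frac <- predict_het_fraction(model)
  mu_homo <- model$site_capacity
  mu_het <- frac * mu_homo
  draw <- function(n, mu) {
    if (noise_cv == 0 || mu == 0) return(rep(mu, n))
    sdlog <- sqrt(log1p(noise_cv^2))
    rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  }
  set.seed(as.integer(seed))
  list(homo = draw(n, mu_homo), het = draw(n, mu_het), fraction = frac)
}
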