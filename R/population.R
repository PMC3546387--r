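#' Synthetic acute-MI-style covariate population
#'
#' Generates a population of subjects whose fixed linear predictor
#' \eqn{\eta = \beta'x} is built from one continuous covariate (a
#' standardised, age-like severity score) and ten binary covariates with
#' configurable prevalences and log-hazard-ratio coefficients. The
#' structure mirrors a hospital AMI cohort risk model — age, sex, four
#' cardiac-severity indicators and four comorbidity indicators — and is a
#' synthetic stand-in for registry-fitted linear predictors, which are not
#' publicly available. Only the structure is emulated; the default
#' coefficients are chosen to give a clinically plausible spread
#' (mean \eqn{\eta \approx 0.57}, sd \eqn{\approx 0.91}).
#'
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @param coefficients Named numeric vector of log hazard ratios; the first
#'   element multiplies the continuous covariate.
#' @param prevalences Named numeric vector of binary-covariate prevalences
#'   (same names as `coefficients` minus the continuous one).
#' @return A tibble with `id`, the covariate columns, and `eta`.
#' @examples
#' pop <- synth_population(1000, seed = 1)
#' mean(pop$eta); sd(pop$eta)
#' @export
synth_population <- function(n, seed = NULL,
                             coefficients = default_population_coefficients(),
                             prevalences = default_population_prevalences()) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cont_name <- names(coefficients)[1]
  bin_names <- names(coefficients)[-1]
  if (!setequal(bin_names, names(prevalences))) {
    stop("`prevalences` must name the same binary covariates as ",
         "`coefficients`.", call. = FALSE)
  }
  out <- tibble::tibble(id = seq_len(n))
  out[[cont_name]] <- stats::rnorm(n)
  eta <- coefficients[[cont_name]] * out[[cont_name]]
  for (nm in bin_names) {
    out[[nm]] <- stats::rbinom(n, 1L, prevalences[[nm]])
    eta <- eta + coefficients[[nm]] * out[[nm]]
  }
  out$eta <- eta
  out
}

#' @rdname synth_population
#' @export
default_population_coefficients <- function() {
  c(age_std = 0.7, female = 0.3, chf = 0.8, shock = 1.5, arrhythmia = 0.4,
    pulm_edema = 0.6, diabetes_comp = 0.5, stroke = 0.6, renal_acute = 0.9,
    renal_chronic = 0.7, malignancy = 0.9)
}

#' @rdname synth_population
#' @export
default_population_prevalences <- function() {
  c(female = 0.35, chf = 0.20, shock = 0.02, arrhythmia = 0.15,
    pulm_edema = 0.05, diabetes_comp = 0.10, stroke = 0.05,
    renal_acute = 0.04, renal_chronic = 0.04, malignancy = 0.05)
}

population_covariate_names <- function(population) {
  setdiff(names(population), c("id", "eta"))
}
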