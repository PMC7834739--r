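#' Logit transform of a survival proportion
#'
#' @param p proportion strictly between 0 and 1.
#' @return log(p / (1 - p)).
#' @export
logit <- function(p) {
  assert_that(all(p > 0 & p < 1, na.rm = TRUE),
              "logit: p must be strictly between 0 and 1")
  log(p / (1 - p))
}

#' Inverse logit (back-transform to a proportion)
#'
#' @param alpha real number(s).
#' @return exp(alpha) / (exp(alpha) + 1), in (0, 1).
#' @export
inv_logit <- function(alpha) {
  1 / (1 + exp(-alpha))
}

#' Centre and scale a logit-survival series
#'
#' Standardizes the logit-transformed survivals (subtract the mean, divide
#' by the sample SD) and records the constants needed to back-transform
#' model output to the survival scale: beta = alpha * scale + centre, then
#' S = inv_logit(beta).
#'
#' @param alphas numeric vector of logit survivals (>= 2 values, non-zero
#'   variance).
#' @return list with `alpha` (standardized series), `centre`, `scale`.
#' @export
centre_scale <- function(alphas) {
  alphas_ok <- alphas[!is.na(alphas)]
  assert_that(length(alphas_ok) >= 2, "centre_scale: need >= 2 values")
  centre <- mean(alphas_ok)
  scale <- stats::sd(alphas_ok)
  if (!is.finite(scale) || scale == 0) {
    stop("centre_scale: zero variance")
  }
  list(alpha = (alphas - centre) / scale, centre = centre, scale = scale)
}

#' Scaled-logit survival response for one stock
#'
#' Converts a survival series (proportions) to the standardized logit
#' response used for regression modelling. Records flagged `preliminary`
#' are excluded from the centring statistics (and from fitting) but their
#' standardized values are still returned for comparison.
#'
#' @param survival data.frame with columns `ocean_entry_year`, `survival`,
#'   and optionally `status` ("final" or "preliminary").
#' @return list: `data` (year, survival, status, alpha standardized),
#'   `centre`, `scale`.
#' @export
survival_response <- function(survival) {
  status <- survival$status %||% rep("final", nrow(survival))
  a <- logit(survival$survival)
  cs <- centre_scale(a[status == "final"])
  data.frame(
    ocean_entry_year = survival$ocean_entry_year,
    survival = survival$survival,
    status = status,
    alpha = (a - cs$centre) / cs$scale
  ) -> d
  list(data = d, centre = cs$centre, scale = cs$scale)
}

#' Back-transform a scaled-logit value to survival units
#'
#' @param alpha standardized logit value(s) (model scale).
#' @param centre,scale constants from [survival_response()] /
#'   [centre_scale()].
#' @return survival proportion(s).
#' @export
back_transform_survival <- function(alpha, centre, scale) {
  inv_logit(alpha * scale + centre)
}
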