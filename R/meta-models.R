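## Linear models of DAS / DEG counts on design covariates ---------------------

#' Effective read length
#'
#' Single-end libraries contribute the read length; paired-end libraries
#' contribute the sum of the two mate lengths (twice the read length for
#' equal mates, the stated per-mate lengths summed otherwise).
#'
#' @param layout Character vector, `"single"` or `"paired"`.
#' @param read_length Per-mate read length(s) in bp.
#' @param mate2_length Optional second-mate length for unequal pairs.
#' @return Effective length L in bp.
#' @export
#' @examples
#' effective_read_length("single", 100)  # 100
#' effective_read_length("paired", 100)  # 200
effective_read_length <- function(layout, read_length, mate2_length = NULL) {
  if (any(!layout %in% c("single", "paired")))
    stop("unknown layout: ",
         paste(unique(setdiff(layout, c("single", "paired"))), collapse = ", "),
         call. = FALSE)
  if (any(read_length <= 0)) stop("'read_length' must be positive", call. = FALSE)
  mate2 <- if (is.null(mate2_length)) read_length else mate2_length
  ifelse(layout == "paired", read_length + mate2, read_length)
}

#' Filter comparisons on sequencing quality covariates
#'
#' Keeps comparisons with total reads >= `min_spots` (default 1e8 spots)
#' AND effective read length >= `min_eff_len` (default 150 bp); both bounds
#' inclusive.
#'
#' @param metas data.frame with columns `spots` and `L` (see [gen_meta()]
#'   or [read_meta()]).
#' @param min_spots,min_eff_len Inclusive lower bounds.
#' @return The retained subset of `metas`.
#' @export
filter_comparisons <- function(metas, min_spots = 1e8, min_eff_len = 150) {
  .check_columns(metas, c("spots", "L"), "metas")
  if (!nrow(metas)) stop("'metas' is empty", call. = FALSE)
  metas[metas$spots >= min_spots & metas$L >= min_eff_len, , drop = FALSE]
}

.fit_linear <- function(formula, data, response) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  structure(list(terms = names(stats::coef(fit)),
                 beta = stats::coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 t = sm$coefficients[, "t value"],
                 p = sm$coefficients[, "Pr(>|t|)"],
                 sigma_hat = sm$sigma,
                 leverages = unname(stats::hatvalues(fit)),
                 residuals = unname(stats::residuals(fit)),
                 fitted = unname(stats::fitted(fit)),
                 r2 = sm$r.squared,
                 response = response,
                 lm = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear_fit (%s): sigma_hat = %.3f, R^2 = %.3f\n",
              x$response, x$sigma_hat, x$r2))
  print(data.frame(beta = x$beta, se = x$se, t = x$t, p = x$p))
  invisible(x)
}

#' Fit the six-term linear model of DAS counts
#'
#' `#DAS = b0 + bT*T + bL*L + bS*S + bTL*(T:L) + bTS*(T:S)`; the L:S and
#' T:L:S interactions are deliberately absent. Ordinary least squares with
#' per-coefficient t-tests, on the covariates' natural scales.
#'
#' @param metas data.frame with columns `spots` (T), `L`, `n_samples` (S).
#' @param das_counts Numeric response, one value per row of `metas`.
#' @return A `linear_fit`.
#' @export
fit_das_model <- function(metas, das_counts) {
  .check_columns(metas, c("spots", "L", "n_samples"), "metas")
  if (nrow(metas) < 7L)
    stop("need >= 7 observations for the 6-parameter DAS model", call. = FALSE)
  d <- data.frame(y = das_counts, T = metas$spots, L = metas$L,
                  S = metas$n_samples)
  .fit_linear(y ~ T + L + S + T:L + T:S, d, "das")
}

#' Fit the four-term linear model of DEG counts
#'
#' `#DEG = b0 + bT*T + bS*S + bTS*(T:S)`; read length does not bear on
#' gene-level power, so L and T:L are omitted.
#'
#' @param metas data.frame with columns `spots`, `n_samples`.
#' @param deg_counts Numeric response.
#' @return A `linear_fit`.
#' @export
fit_deg_model <- function(metas, deg_counts) {
  .check_columns(metas, c("spots", "n_samples"), "metas")
  if (nrow(metas) < 5L)
    stop("need >= 5 observations for the 4-parameter DEG model", call. = FALSE)
  d <- data.frame(y = deg_counts, T = metas$spots, S = metas$n_samples)
  .fit_linear(y ~ T + S + T:S, d, "deg")
}

#' Normalize counts to a canonical experimental design
#'
#' Shifts internally studentized residuals onto the model's prediction at a
#' canonical design point: `r_i = e_i / (sigma_hat * sqrt(1 - h_ii))` and
#' `normalized_i = yhat(canonical) + r_i * sigma_hat`. Two observations
#' with equal standardized residuals therefore receive equal normalized
#' counts regardless of their own covariates. Observations with leverage 1
#' have no residual information and are excluded (flagged `NA`).
#'
#' @param fit A `linear_fit` from [fit_das_model()] / [fit_deg_model()].
#' @param canonical Named list/vector of covariates (`T`, `S`, and `L` for
#'   the DAS model) defining the canonical design; default is the
#'   component-wise median of the fitted observations' covariates.
#' @return List: `normalized` (numeric, NA for excluded observations),
#'   `canonical` (the design point used), `yhat_canonical`,
#'   `std_residuals`.
#' @export
normalize_counts <- function(fit, canonical = NULL) {
  stopifnot(inherits(fit, "linear_fit"))
  mf <- stats::model.frame(fit$lm)
  covars <- mf[setdiff(names(mf), "y")]
  if (is.null(canonical)) {
    canonical <- lapply(covars, stats::median)
  } else {
    canonical <- as.list(canonical)
    miss <- setdiff(names(covars), names(canonical))
    if (length(miss))
      stop("canonical design is missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    for (v in names(covars)) {
      rng <- range(covars[[v]])
      if (canonical[[v]] < rng[1L] || canonical[[v]] > rng[2L])
        warning(sprintf("canonical %s = %g lies outside the observed range [%g, %g]",
                        v, canonical[[v]], rng[1L], rng[2L]), call. = FALSE)
    }
  }
  yhat_c <- unname(stats::predict(fit$lm, newdata = as.data.frame(canonical)))
  h <- fit$leverages
  ok <- h < 1 - 1e-12
  r <- rep(NA_real_, length(h))
  r[ok] <- fit$residuals[ok] / (fit$sigma_hat * sqrt(1 - h[ok]))
  if (any(!ok))
    warning(sum(!ok), " observation(s) with leverage 1 excluded", call. = FALSE)
  list(normalized = yhat_c + r * fit$sigma_hat,
       canonical = canonical,
       yhat_canonical = yhat_c,
       std_residuals = r)
}

#' Pearson correlation of normalized DAS and DEG counts
#'
#' @param norm_das,norm_deg Paired numeric vectors (NAs dropped pairwise).
#' @return List: `r`, `p` (two-sided, via the t reference
#'   `t = r * sqrt((n - 2) / (1 - r^2))`), `n`.
#' @export
correlate_normalized <- function(norm_das, norm_deg) {
  if (length(norm_das) != length(norm_deg))
    stop("inputs must be paired", call. = FALSE)
  ok <- is.finite(norm_das) & is.finite(norm_deg)
  x <- norm_das[ok]; y <- norm_deg[ok]
  if (length(x) < 3L) stop("need >= 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
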