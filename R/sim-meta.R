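## Synthetic experimental-design metadata -------------------------------------

#' Generate design metadata and DAS/DEG counts under the linear models
#'
#' Samples realistic design covariates — total reads `T` uniform on
#' 2e7–4e8 spots, read length from {50, 100, 150} with single/paired layout
#' (so effective length `L` covers {50, ..., 300}), samples `S` in 4–16 —
#' and produces response counts from the stated linear predictors plus
#' Gaussian noise.
#'
#' @param config A [sim_config()] (supplies the seed).
#' @param n Number of comparisons to simulate.
#' @param beta_das Named coefficients for the six-term #DAS model:
#'   `(Intercept)`, `T`, `L`, `S`, `T:L`, `T:S`.
#' @param beta_deg Named coefficients for the four-term #DEG model:
#'   `(Intercept)`, `T`, `S`, `T:S`; `NULL` skips the DEG response.
#' @param sigma Residual standard deviation (>= 0).
#' @param integerize When TRUE (default) responses are floored at 0 and
#'   rounded to whole counts; set FALSE for exact noiseless recovery
#'   checks, where rounding would mask the linear structure.
#' @return List: `meta` (data.frame comparison_id, spots, read_length,
#'   layout, n_samples, L), `das` (numeric), `deg` (numeric or NULL),
#'   `beta_das`, `beta_deg`.
#' @export
gen_meta <- function(config, n = 60L,
                     beta_das = c("(Intercept)" = 50, "T" = 1e-6, "L" = 0.5,
                                  "S" = 5, "T:L" = 2e-9, "T:S" = 5e-8),
                     beta_deg = c("(Intercept)" = 200, "T" = 2e-6,
                                  "S" = 10, "T:S" = 1e-7),
                     sigma = 25, integerize = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  .check_number(sigma, "sigma", lower = 0)
  .check_number(n, "n", lower = 7, integer = TRUE)
  set.seed(.module_seed(config$seed, "meta"))

  spots <- stats::runif(n, 2e7, 4e8)
  read_length <- sample(c(50L, 100L, 150L), n, replace = TRUE)
  layout <- sample(c("single", "paired"), n, replace = TRUE)
  S <- sample(4:16, n, replace = TRUE)
  L <- effective_read_length(layout, read_length)
  meta <- data.frame(comparison_id = sprintf("CMP%03d", seq_len(n)),
                     spots = spots, read_length = read_length,
                     layout = layout, n_samples = S, L = L,
                     stringsAsFactors = FALSE)

  predict_lin <- function(beta) {
    X <- cbind(`(Intercept)` = 1, "T" = spots, "L" = L, "S" = S,
               "T:L" = spots * L, "T:S" = spots * S)
    drop(X[, names(beta), drop = FALSE] %*% beta)
  }
  finish <- function(y) {
    y <- y + stats::rnorm(n, 0, sigma)
    if (integerize) y <- round(pmax(y, 0))
    y
  }
  das <- finish(predict_lin(beta_das))
  deg <- if (!is.null(beta_deg)) finish(predict_lin(beta_deg)) else NULL
  list(meta = meta, das = das, deg = deg,
       beta_das = beta_das, beta_deg = beta_deg)
}
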