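#' Indicator metadata for the adaptive-capacity composite
#'
#' The 15 indicators across the five capacity dimensions (social, physical,
#' natural, human, financial), with the default benefit direction of each.
#' Directions are reconstructions from each indicator's meaning: ratios of
#' dependent population, population pressure, distance to research, debt and
#' subsidy dependence count against capacity; everything else counts for it.
#'
#' @return data.frame: `indicator`, `dimension`, `direction`
#'   (`"higher_is_better"` / `"lower_is_better"`).
#' @export
ac_indicator_info <- function() {
  data.frame(
    indicator = c("aging_index", "dependency_ratio", "population_density",
                  "road_length", "mechanization_index", "naturalness",
                  "shift_in_space", "water_availability", "climatic_niches",
                  "labor_force", "education_level", "research_accessibility",
                  "debt_ratio", "return_on_assets", "subsidy_dependence"),
    dimension = rep(c("social", "physical", "natural", "human", "financial"),
                    each = 3),
    direction = c("lower_is_better", "lower_is_better", "lower_is_better",
                  "higher_is_better", "higher_is_better", "higher_is_better",
                  "higher_is_better", "higher_is_better", "higher_is_better",
                  "higher_is_better", "higher_is_better", "lower_is_better",
                  "lower_is_better", "higher_is_better", "lower_is_better"),
    stringsAsFactors = FALSE
  )
}

# plausible location/scale per indicator for the synthetic draw
ac_indicator_scales <- function() {
  info <- ac_indicator_info()
  info$mean <- c(1.3, 0.55, 1.5, 800, 1200, 35, 150, 120, 1.5,
                 60, 2.5, 120, 35, 6, 25)
  info$sd <- c(0.3, 0.08, 0.7, 300, 400, 12, 80, 60, 0.6,
               15, 0.7, 60, 12, 3, 10)
  info
}

#' Generate the regional adaptive-capacity indicator table
#'
#' One row per region; the 15 indicator columns are an equicorrelated
#' multivariate normal draw (target pairwise correlation
#' `config$indicator_corr`) mapped onto plausible per-indicator locations
#' and scales.
#'
#' @param config a [synth_config()] object.
#' @param regions a [generate_regions()] result, or an integer number of
#'   regions (ids `R001...` are fabricated).
#' @return data.frame with `region_id` and the 15 indicator columns;
#'   attribute `directions` holds the per-column direction flags.
#' @export
generate_indicators <- function(config, regions) {
  stopifnot(inherits(config, "synth_config"))
  ids <- if (inherits(regions, "region_set")) {
    regions$regions$region_id
  } else if (is.numeric(regions) && length(regions) == 1) {
    sprintf("R%03d", seq_len(regions))
  } else stop("regions must be a region_set or a count")
  rho <- config$indicator_corr
  if (abs(rho) >= 1) stop("|indicator_corr| must be < 1")
  p <- 15L
  sigma <- matrix(rho, p, p); diag(sigma) <- 1
  scales <- ac_indicator_scales()
  with_seed(derive_seed(config$seed, 404L), {
    z <- MASS::mvrnorm(length(ids), mu = rep(0, p), Sigma = sigma)
    z <- matrix(z, ncol = p)
    x <- sweep(sweep(z, 2, scales$sd, `*`), 2, scales$mean, `+`)
    colnames(x) <- scales$indicator
    out <- data.frame(region_id = ids, x, stringsAsFactors = FALSE,
                      check.names = FALSE)
    attr(out, "directions") <- stats::setNames(scales$direction,
                                               scales$indicator)
    out
  })
}

#' Generate expert AHP pairwise-comparison matrices with known weights
#'
#' For each synthetic expert, a true weight vector over the 15 indicators is
#' drawn and the consistent pairwise matrix `a_ij = w_i / w_j` is perturbed
#' multiplicatively (log-normal, `perturb_sd`) while preserving reciprocal
#' symmetry, emulating imperfect but near-consistent expert judgements.
#'
#' @param config a [synth_config()] object.
#' @param n_experts number of expert matrices.
#' @param perturb_sd SD of the log-scale perturbation (0 = fully consistent).
#' @return list with `matrices` (list of 15 x 15 matrices) and
#'   `true_weights` (n_experts x 15 matrix, rows summing to 1).
#' @export
generate_ahp_matrices <- function(config, n_experts = 5, perturb_sd = 0.1) {
  stopifnot(inherits(config, "synth_config"))
  p <- 15L
  ind <- ac_indicator_info()$indicator
  with_seed(derive_seed(config$seed, 505L), {
    tw <- matrix(0, n_experts, p, dimnames = list(NULL, ind))
    mats <- vector("list", n_experts)
    for (e in seq_len(n_experts)) {
      w <- stats::rexp(p); w <- w / sum(w)
      tw[e, ] <- w
      A <- outer(w, w, `/`)
      if (perturb_sd > 0) {
        up <- upper.tri(A)
        A[up] <- A[up] * exp(stats::rnorm(sum(up), sd = perturb_sd))
        A[lower.tri(A)] <- t(1 / A)[lower.tri(A)]
        diag(A) <- 1
      }
      dimnames(A) <- list(ind, ind)
      mats[[e]] <- A
    }
    list(matrices = mats, true_weights = tw)
  })
}
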