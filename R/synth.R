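#' Synthetic trial-arm design
#'
#' Defines a simulated meta-analytic dataset: per-drug exposure grids given
#' directly as x = log10(Cavg in pmol/L) (decoupling recovery experiments
#' from any dose-to-exposure table), a common number of subjects per arm,
#' the endpoint and the generating parameter set.
#'
#' @param exposure_grid Named list: per drug, a numeric vector of positive
#'   log10-pmol/L exposures.
#' @param n_per_arm Subjects per arm (>= 1).
#' @param true_params Generating [operational_params()]; its drugs must
#'   cover the grid's drugs.
#' @param seed Integer seed.
#' @return A `synth_design` list.
#' @export
synth_design <- function(exposure_grid, n_per_arm, true_params, seed = 1L) {
  if (is.null(names(exposure_grid)))
    stop("exposure_grid must be a named list (one entry per drug)")
  missing <- setdiff(names(exposure_grid), names(true_params$tau))
  if (length(missing))
    stop("true_params lacks tau for drug(s): ", paste(missing, collapse = ", "))
  if (any(unlist(exposure_grid) <= 0))
    stop("exposure grid values (log10 pmol/L) must be > 0")
  if (n_per_arm < 1) stop("n_per_arm must be >= 1")
  structure(list(drugs = names(exposure_grid), exposure_grid = exposure_grid,
                 n_per_arm = as.integer(n_per_arm),
                 endpoint = true_params$endpoint, true_params = true_params,
                 seed = as.integer(seed)),
            class = "synth_design")
}

#' Generate synthetic trial arms
#'
#' For every drug x grid point, the observation is the operational-model
#' mean plus additive noise `eps ~ N(0, sigma_i^2 / n_per_arm)` — the
#' residual model the pooled fit assumes. Observations are deliberately not
#' truncated at zero, matching the additive-normal assumption. Reproducible
#' given the design seed.
#'
#' @param design A [synth_design()].
#' @param registry Drug registry (molecular weights convert the log10
#'   exposures to the stored ng/mL scale).
#' @param scale Concentration scale used for the mean model.
#' @return Trial-arm data frame with the [read_arms()] schema.
#' @export
generate_arms <- function(design, registry = default_drug_registry(),
                          scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  p <- design$true_params
  set.seed(design$seed)
  rows <- lapply(design$drugs, function(d) {
    x <- design$exposure_grid[[d]]
    spec <- .get_spec(registry, d)
    cavg <- from_molar(10^x, spec)
    mu <- operational_response(cavg, d, p, registry, scale)
    eps <- rnorm(length(x), 0, p$sigma[[d]] / sqrt(design$n_per_arm))
    data.frame(study_id = paste0("synth_", d),
               arm_id = paste0(d, "_", seq_along(x)),
               drug_id = d, dose_ug = NA_real_, ee_dose_ug = NA_real_,
               endpoint = design$endpoint,
               observed = mu + eps,
               n_subjects = design$n_per_arm,
               cavg_ng_ml = cavg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameter-recovery suite
#'
#' Generates replicate synthetic datasets at a known truth — by default the
#' published Pearl-Index operational parameters — with 20 arms per drug on
#' an evenly spaced log10-pmol/L grid spanning the informative transition
#' regions of both drugs' response curves, and a manifest recording truth,
#' seeds and design. Refitting each dataset and taking medians across seeds
#' is the package's recovery experiment.
#'
#' @param truth Generating [operational_params()] (default: published PI
#'   set).
#' @param seeds Integer vector of dataset seeds.
#' @param n_per_arm Subjects per arm.
#' @param n_arms_per_drug Grid points per drug.
#' @param x_range Range of the log10-pmol/L grid.
#' @param registry Drug registry.
#' @return List with `datasets` (list of arm data frames, one per seed) and
#'   `manifest` (truth, seeds, grid, n_per_arm).
#' @export
generate_recovery_suite <- function(truth = default_operational_params("PI"),
                                    seeds = 1:20, n_per_arm = 5000,
                                    n_arms_per_drug = 20,
                                    x_range = c(1.8, 5.2),
                                    registry = default_drug_registry()) {
  grid <- seq(x_range[1], x_range[2], length.out = n_arms_per_drug)
  drugs <- names(truth$tau)
  datasets <- lapply(seeds, function(s) {
    d <- synth_design(setNames(rep(list(grid), length(drugs)), drugs),
                      n_per_arm = n_per_arm, true_params = truth, seed = s)
    generate_arms(d, registry)
  })
  list(datasets = datasets,
       manifest = list(truth = truth, seeds = seeds, grid = grid,
                       n_per_arm = n_per_arm))
}
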