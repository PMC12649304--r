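#' Incidence-rate ratio
#'
#' Scenario rate divided by the no-induction reference rate.
#'
#' @param reference_rate Reference incidence rate; must be > 0.
#' @param rate Scenario incidence rate.
#' @return `rate / reference_rate`.
#' @export
irr <- function(reference_rate, rate) {
  if (any(reference_rate <= 0)) stop("reference_rate must be > 0")
  rate / reference_rate
}

#' Round half-up
#'
#' Rounds half away from zero (so 16.25 prints as 16.3), matching the
#' convention of published summary tables; base `round()` rounds half to
#' even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent change versus reference
#'
#' `100 * (value/reference - 1)`, rounded half-up to `digits` decimals for
#' table output (use `digits = NULL` for the raw value).
#'
#' @param reference Reference endpoint value (> 0).
#' @param value Scenario endpoint value.
#' @param digits Decimals for half-up rounding, or `NULL` for unrounded.
#' @return Percent change.
#' @export
percent_change <- function(reference, value, digits = 1) {
  pc <- 100 * (irr(reference, value) - 1)
  if (is.null(digits)) pc else round_half_up(pc, digits)
}

#' Construct a DDI/BMI scenario
#'
#' @param drug_id,dose_ug,ee_dose_ug,bmi_group,inducer Stratum of the
#'   scenario.
#' @param n_virtual Virtual subjects to simulate (default 100).
#' @param seed Integer seed for the exposure draws.
#' @return A `scenario` list.
#' @export
scenario <- function(drug_id, dose_ug, ee_dose_ug, bmi_group,
                     inducer = "none", n_virtual = 100, seed = 1L) {
  if (n_virtual < 1) stop("n_virtual must be >= 1")
  structure(list(drug_id = drug_id, dose_ug = dose_ug,
                 ee_dose_ug = ee_dose_ug, bmi_group = bmi_group,
                 inducer = inducer, n_virtual = n_virtual,
                 seed = as.integer(seed)),
            class = "scenario")
}

# Mean endpoint plus subject-level percentile CI for one scenario.
.scenario_mean <- function(scen, params, registry, exposure_table, scale) {
  rec <- resolve_exposure(exposure_table, scen$drug_id, scen$dose_ug,
                          scen$ee_dose_ug, scen$bmi_group, scen$inducer)
  cavg <- simulate_virtual_population(scen$n_virtual, rec$cavg_ng_ml,
                                      rec$gcv_percent, seed = scen$seed)
  resp <- suppressWarnings(
    operational_response(cavg, scen$drug_id, params, registry, scale))
  list(mean = mean(resp),
       ci = unname(quantile(resp, c(0.025, 0.975), type = 7)))
}

#' Predict one DDI/BMI scenario
#'
#' Simulates the scenario's virtual population from the exposure table,
#' pushes each subject's Cavg through the operational model, and summarises
#' the endpoint as the subject average with a 2.5/97.5 percentile interval.
#' The incidence-rate ratio and percent change are computed against the
#' reference scenario's mean.
#'
#' @param scen,reference [scenario()] objects; `reference` is typically the
#'   same stratum with no inducer.
#' @param params Fitted or published [operational_params()].
#' @param registry Drug registry.
#' @param exposure_table Exposure table (see [default_exposure_table()]).
#' @param scale Concentration scale.
#' @return A `scenario_result` list: `scenario`, `mean_endpoint`, `ci95`,
#'   `ref_mean`, `irr_vs_ref`, `percent_change_vs_ref` (unrounded).
#' @export
predict_scenario <- function(scen, params,
                             registry = default_drug_registry(),
                             exposure_table = default_exposure_table(),
                             reference = NULL,
                             scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  sm <- .scenario_mean(scen, params, registry, exposure_table, scale)
  if (is.null(reference)) reference <- scen
  rm_ <- if (identical(reference, scen)) sm else
    .scenario_mean(reference, params, registry, exposure_table, scale)
  if (rm_$mean == 0) stop("reference endpoint mean is 0; IRR undefined")
  structure(list(scenario = scen,
                 mean_endpoint = sm$mean, ci95 = sm$ci,
                 ref_mean = rm_$mean,
                 irr_vs_ref = irr(rm_$mean, sm$mean),
                 percent_change_vs_ref = percent_change(rm_$mean, sm$mean,
                                                        digits = NULL)),
            class = "scenario_result")
}

#' Default scenario grid
#'
#' The published scenario design: LNG 100 ug/EE 20 ug and 150 ug/EE 30 ug,
#' DRSP 3000 ug with EE 20 or 30 ug, across three BMI groups and
#' no-induction / carbamazepine 400 mg / rifampicin 600 mg, 100 virtual
#' subjects each. Reference rows are the no-inducer rows of each stratum.
#'
#' @param seed Base seed; each row gets `seed + row - 1`.
#' @param n_virtual Virtual subjects per scenario.
#' @return Data frame with the [read_scenarios()] schema.
#' @export
default_scenarios <- function(seed = 1L, n_virtual = 100) {
  doses <- rbind(data.frame(drug_id = "LNG", dose_ug = c(100, 150),
                            ee_dose_ug = c(20, 30)),
                 data.frame(drug_id = "DRSP", dose_ug = c(3000, 3000),
                            ee_dose_ug = c(20, 30)))
  grid <- expand.grid(row = seq_len(nrow(doses)),
                      bmi_group = .bmi_levels,
                      inducer = c("none", "CBZ400", "RIF600"),
                      stringsAsFactors = FALSE)
  out <- data.frame(drug_id = doses$drug_id[grid$row],
                    dose_ug = doses$dose_ug[grid$row],
                    ee_dose_ug = doses$ee_dose_ug[grid$row],
                    bmi_group = grid$bmi_group,
                    inducer = grid$inducer,
                    n_virtual = n_virtual,
                    seed = seed + seq_len(nrow(grid)) - 1L,
                    is_reference = grid$inducer == "none")
  out[order(out$drug_id, out$dose_ug, out$ee_dose_ug, out$bmi_group,
            out$inducer), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

.scenario_cols <- c("drug_id", "dose_ug", "ee_dose_ug", "bmi_group",
                    "inducer", "n_virtual", "seed", "is_reference")

#' Read a scenario table
#'
#' @param path CSV with the columns of [default_scenarios()].
#' @return Validated scenario data frame.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.scenario_cols, names(tab))
  if (length(missing))
    stop("scenario table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(!tab$bmi_group %in% .bmi_levels |
                 !tab$inducer %in% .inducer_levels | tab$n_virtual < 1)
  if (length(bad))
    stop("invalid scenario rows: ", paste(bad, collapse = ", "))
  tab$is_reference <- as.logical(tab$is_reference)
  tab[, .scenario_cols]
}

#' DDI summary table
#'
#' One row per scenario with the mean predicted endpoint, subject-level
#' percentile interval, incidence-rate ratio and percent change versus the
#' reference row (the `is_reference` row of the same
#' drug/dose/EE/BMI stratum). `percent_change_printed` applies the half-up
#' one-decimal table convention; the unrounded value is kept alongside.
#'
#' @param scenarios Scenario data frame ([default_scenarios()] schema).
#' @param params [operational_params()] for the endpoint being predicted.
#' @param registry Drug registry.
#' @param exposure_table Exposure table.
#' @param scale Concentration scale.
#' @return Data frame with stable column order: the scenario columns plus
#'   `mean_endpoint`, `ci_low`, `ci_high`, `irr`, `percent_change`,
#'   `percent_change_printed`.
#' @export
ddi_summary_table <- function(scenarios, params,
                              registry = default_drug_registry(),
                              exposure_table = default_exposure_table(),
                              scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  key <- function(df) paste(df$drug_id, df$dose_ug, df$ee_dose_ug,
                            df$bmi_group, sep = "|")
  refs <- scenarios[scenarios$is_reference, , drop = FALSE]
  ref_of <- match(key(scenarios), key(refs))
  if (anyNA(ref_of))
    stop("no reference scenario for stratum ",
         paste(unique(key(scenarios)[is.na(ref_of)]), collapse = "; "))
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    rf <- refs[ref_of[i], ]
    res <- predict_scenario(
      scenario(sc$drug_id, sc$dose_ug, sc$ee_dose_ug, sc$bmi_group,
               sc$inducer, sc$n_virtual, sc$seed),
      params, registry, exposure_table,
      reference = scenario(rf$drug_id, rf$dose_ug, rf$ee_dose_ug,
                           rf$bmi_group, rf$inducer, rf$n_virtual, rf$seed),
      scale = scale)
    data.frame(sc[, .scenario_cols],
               mean_endpoint = res$mean_endpoint,
               ci_low = res$ci95[1], ci_high = res$ci95[2],
               irr = res$irr_vs_ref,
               percent_change = res$percent_change_vs_ref,
               percent_change_printed =
                 round_half_up(res$percent_change_vs_ref, 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plain forest-style plot of a DDI summary table
#'
#' Mean endpoint with subject-level percentile interval per scenario, one
#' line per row, grouped label `drug dose/EE bmi inducer`. A by-product for
#' eyeballing; the CSV table is the primary output.
#'
#' @param table Output of [ddi_summary_table()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the label vector.
#' @export
plot_forest <- function(table, ...) {
  lab <- paste0(table$drug_id, " ", table$dose_ug, "/EE", table$ee_dose_ug,
                " ", table$bmi_group, " ", table$inducer)
  y <- rev(seq_len(nrow(table)))
  graphics::plot(table$mean_endpoint, y, xlab = "predicted endpoint",
                 ylab = "", yaxt = "n",
                 xlim = range(table$ci_low, table$ci_high), ...)
  graphics::segments(table$ci_low, y, table$ci_high, y)
  graphics::axis(2, at = y, labels = lab, las = 1, cex.axis = 0.5)
  invisible(lab)
}
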