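.bmi_levels <- c("lt25", "25to30", "ge30")
.inducer_levels <- c("none", "CBZ400", "RIF600", "custom")

#' Synthetic default dose-to-exposure table
#'
#' A configurable stand-in for the external PBPK exposure models: one row
#' per drug x dose x EE dose x BMI group x inducer stratum with the mean
#' average steady-state concentration (ng/mL) and the geometric CV of
#' inter-individual variability. Baseline (BMI < 25, no inducer) values are
#' anchored to the published exposure ranges — 0.54-3.63 ng/mL for LNG over
#' 30-150 ug and 5.47-43.72 ng/mL for DRSP over 500-4000 ug (dose
#' proportional) — while the BMI and inducer effects are plain multiplicative
#' factors that are illustrative placeholders, not study-derived.
#'
#' @param bmi_factors Named multipliers on `cavg_ng_ml` per BMI group.
#' @param inducer_factors Named multipliers per CYP3A4-inducer scenario
#'   (induction lowers exposure).
#' @param gcv_percent Geometric CV of inter-individual variability applied
#'   to every stratum.
#' @return Data frame with columns `drug_id`, `dose_ug`, `ee_dose_ug`,
#'   `bmi_group`, `inducer`, `cavg_ng_ml`, `gcv_percent`.
#' @export
default_exposure_table <- function(bmi_factors = c(lt25 = 1, "25to30" = 0.82,
                                                   ge30 = 0.78),
                                   inducer_factors = c(none = 1, CBZ400 = 0.55,
                                                       RIF600 = 0.45),
                                   gcv_percent = 30) {
  base <- rbind(
    data.frame(drug_id = "LNG",
               dose_ug = c(30, 90, 100, 150),
               ee_dose_ug = c(0, 30, 20, 30),
               cavg_ng_ml = c(0.54, 2.18, 2.42, 3.63)),
    data.frame(drug_id = "DRSP",
               dose_ug = rep(c(500, 1000, 2000, 3000, 4000), each = 2),
               ee_dose_ug = rep(c(20, 30), times = 5),
               cavg_ng_ml = rep(43.72 * c(500, 1000, 2000, 3000, 4000) / 4000,
                                each = 2))
  )
  out <- do.call(rbind, lapply(names(bmi_factors), function(b) {
    do.call(rbind, lapply(names(inducer_factors), function(ind) {
      data.frame(drug_id = base$drug_id, dose_ug = base$dose_ug,
                 ee_dose_ug = base$ee_dose_ug, bmi_group = b, inducer = ind,
                 cavg_ng_ml = base$cavg_ng_ml * bmi_factors[[b]] *
                   inducer_factors[[ind]],
                 gcv_percent = gcv_percent)
    }))
  }))
  rownames(out) <- NULL
  out
}

.exposure_cols <- c("drug_id", "dose_ug", "ee_dose_ug", "bmi_group",
                    "inducer", "cavg_ng_ml", "gcv_percent")

#' Read and validate an exposure table
#'
#' Comma-separated, UTF-8, header required; columns must match the exposure
#' schema exactly. Every malformed row is reported with its line number.
#'
#' @param path CSV path.
#' @return Validated exposure data frame.
#' @export
read_exposure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.exposure_cols, names(tab))
  if (length(missing))
    stop("exposure table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("exposure table is empty")
    return(tab[, .exposure_cols])
  }
  bad <- character(0)
  chk <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) bad <<- c(bad, paste0("row ", rows, ": ", msg))
  }
  chk(!tab$bmi_group %in% .bmi_levels, "unknown bmi_group")
  chk(!tab$inducer %in% .inducer_levels, "unknown inducer")
  chk(!is.finite(tab$cavg_ng_ml) | tab$cavg_ng_ml <= 0,
      "cavg_ng_ml must be > 0")
  chk(!is.finite(tab$gcv_percent) | tab$gcv_percent < 0,
      "gcv_percent must be >= 0")
  if (length(bad))
    stop("invalid exposure table:\n", paste(bad, collapse = "\n"))
  tab[, .exposure_cols]
}

#' Resolve a dose to an exposure record
#'
#' Exact-match lookup in the drug/EE/BMI/inducer stratum; when the exact
#' dose is absent, the mean concentration (and geometric CV) is linearly
#' interpolated between the bracketing doses of the same stratum. BMI and
#' inducer strata are never interpolated across, and queries outside a
#' stratum's dose hull raise an error rather than extrapolating.
#'
#' @param table Exposure data frame (schema of [default_exposure_table()]).
#' @param drug_id,dose_ug,ee_dose_ug,bmi_group,inducer Query strata.
#' @return One-row exposure data frame.
#' @export
resolve_exposure <- function(table, drug_id, dose_ug, ee_dose_ug,
                             bmi_group, inducer) {
  if (nrow(table) == 0L) stop("exposure table is empty")
  if (!bmi_group %in% .bmi_levels) stop("unknown bmi_group '", bmi_group, "'")
  if (!inducer %in% .inducer_levels) stop("unknown inducer '", inducer, "'")
  stratum <- table[table$drug_id == drug_id &
                     table$ee_dose_ug == ee_dose_ug &
                     table$bmi_group == bmi_group &
                     table$inducer == inducer, , drop = FALSE]
  if (nrow(stratum) == 0L)
    stop("no exposure rows for stratum ", drug_id, "/EE", ee_dose_ug, "/",
         bmi_group, "/", inducer)
  hit <- stratum[stratum$dose_ug == dose_ug, , drop = FALSE]
  if (nrow(hit) >= 1L) return(hit[1L, ])
  if (nrow(stratum) < 2L || dose_ug < min(stratum$dose_ug) ||
      dose_ug > max(stratum$dose_ug))
    stop("dose ", dose_ug, " ug outside the dose hull of stratum ",
         drug_id, "/EE", ee_dose_ug, "/", bmi_group, "/", inducer,
         " (no extrapolation)")
  stratum <- stratum[order(stratum$dose_ug), ]
  out <- stratum[1L, ]
  out$dose_ug <- dose_ug
  out$cavg_ng_ml <- stats::approx(stratum$dose_ug, stratum$cavg_ng_ml,
                                  xout = dose_ug)$y
  out$gcv_percent <- stats::approx(stratum$dose_ug, stratum$gcv_percent,
                                   xout = dose_ug)$y
  out
}

#' Simulate a virtual population's exposures
#'
#' Log-normal inter-individual variability around the stratum mean: draws
#' have median `cavg_mean` and geometric CV `gcv_percent`
#' (sdlog = sqrt(log(1 + (gcv/100)^2))). `gcv_percent = 0` returns the mean
#' exactly for every subject.
#'
#' @param n Number of virtual subjects.
#' @param cavg_mean Stratum mean concentration, ng/mL.
#' @param gcv_percent Geometric CV in percent, >= 0.
#' @param seed Integer seed.
#' @return Numeric vector of `n` concentrations (ng/mL).
#' @export
simulate_virtual_population <- function(n, cavg_mean, gcv_percent, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (cavg_mean <= 0) stop("cavg_mean must be > 0")
  if (gcv_percent < 0) stop("gcv_percent must be >= 0")
  if (gcv_percent == 0) return(rep(cavg_mean, n))
  sdlog <- sqrt(log1p((gcv_percent / 100)^2))
  set.seed(seed)
  rlnorm(n, meanlog = log(cavg_mean), sdlog = sdlog)
}
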