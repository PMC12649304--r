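#' Drug specification
#'
#' A progestin's identity, molecular weight and receptor affinity. The
#' dissociation constant is carried as log10 of KD expressed in pmol/L, the
#' scale on which the operational model works.
#'
#' @param drug_id Single drug label, e.g. `"LNG"` or `"DRSP"`.
#' @param molecular_weight Molecular weight in g/mol; must be positive.
#' @param log10_kd log10 of the receptor dissociation constant in pmol/L;
#'   must be finite.
#' @return An object of class `drug_spec`.
#' @examples
#' drug_spec("LNG", 312.45, 3.556)
#' @export
drug_spec <- function(drug_id, molecular_weight, log10_kd) {
  if (!is.character(drug_id) || length(drug_id) != 1L || !nzchar(drug_id))
    stop("drug_id must be a single non-empty string")
  if (!is.numeric(molecular_weight) || length(molecular_weight) != 1L ||
      !is.finite(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be a positive number (drug ", drug_id, ")")
  if (!is.numeric(log10_kd) || length(log10_kd) != 1L || !is.finite(log10_kd))
    stop("log10_kd must be finite (drug ", drug_id, ")")
  structure(
    list(drug_id = drug_id,
         molecular_weight = as.numeric(molecular_weight),
         log10_kd = as.numeric(log10_kd)),
    class = "drug_spec"
  )
}

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf("<drug_spec> %s: MW %.2f g/mol, log10 KD %.3f [pmol/L]\n",
              x$drug_id, x$molecular_weight, x$log10_kd))
  invisible(x)
}

#' Default drug registry
#'
#' Levonorgestrel (LNG) and drospirenone (DRSP) with standard molecular
#' weights and literature receptor affinities on the log10 pmol/L scale.
#'
#' @return A named list of [drug_spec()] objects keyed by drug id.
#' @export
default_drug_registry <- function() {
  list(
    LNG  = drug_spec("LNG", 312.45, 3.556),
    DRSP = drug_spec("DRSP", 366.49, 2.949)
  )
}

.get_spec <- function(registry, drug_id) {
  sp <- registry[[drug_id]]
  if (is.null(sp))
    stop("drug '", drug_id, "' not present in the drug registry")
  sp
}

#' Mass/molar concentration conversion
#'
#' Converts an average steady-state concentration between ng/mL and pmol/L
#' using the drug's molecular weight: pmol/L = ng/mL * 1e6 / MW.
#'
#' @param value Concentration value(s); must be positive.
#' @param spec A [drug_spec()] (or a molecular weight in g/mol).
#' @return Numeric vector in the target unit.
#' @examples
#' to_molar(1, drug_spec("X", 1000, 0))  # 1000 pmol/L
#' @export
to_molar <- function(value, spec) {
  mw <- if (inherits(spec, "drug_spec")) spec$molecular_weight else spec
  if (!is.numeric(mw) || mw <= 0) stop("molecular_weight must be positive")
  if (any(!is.finite(value)) || any(value <= 0))
    stop("concentration value must be positive and finite (ng/mL)")
  value * 1e6 / mw
}

#' @rdname to_molar
#' @export
from_molar <- function(value, spec) {
  mw <- if (inherits(spec, "drug_spec")) spec$molecular_weight else spec
  if (!is.numeric(mw) || mw <= 0) stop("molecular_weight must be positive")
  if (any(!is.finite(value)) || any(value <= 0))
    stop("concentration value must be positive and finite (pmol/L)")
  value * mw / 1e6
}
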