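#' Round half away from zero
#'
#' Decimal rounding in the conventional clinical-reporting sense: ties go up
#' (away from zero), unlike [base::round()], which rounds half to even.
#' Reported 1-decimal ratio tables are only reproducible under this
#' convention (e.g. `31.85/2.60 = 12.25` must print as `12.3`).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(12.25, 1)  # 12.3, where round() gives 12.2
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) * sign(x) / p
}

## canonical analyte set; SDMA is carried descriptively but never enters the index
ANALYTES <- c("adma", "sdma", "tmao", "is", "pcs")
INDEX_ANALYTES <- c("pcs", "tmao", "is", "adma")

UNIT_STATES <- c("raw_umol_per_L", "normalized_umol_per_mmol")
TOXIN_FLAGS <- c("ok", "below_loq", "missing")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_migd <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "migd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
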