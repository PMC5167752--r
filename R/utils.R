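#' @keywords internal
"_PACKAGE"

#' @useDynLib bna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median mad rnorm sd var approx
#' @importFrom utils head tail
NULL

# Signal a classed error so callers can test for specific failure modes.
bna_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "bna_error", "error", "condition")))
}

# Deterministic half-up rounding (round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

# Conditions recognised by the oddball simulator and the pipeline default.
BNA_CONDITIONS <- c("Frequent", "Target", "Novel")

# Band edges in Hz, as conventionally used for ERP decomposition.  The
# edges deliberately overlap (theta starts below the delta upper edge).
BNA_BANDS <- list(
  delta = c(0.5, 4),
  theta = c(3, 8),
  alpha = c(7, 13),
  beta  = c(12, 30)
)

# Carrier (band-centre) frequencies used by the simulator, Hz.
BNA_BAND_CENTER <- c(delta = 2, theta = 5.5, alpha = 10, beta = 20)

check_band <- function(band) {
  if (!band %in% names(BNA_BANDS))
    bna_stop("bna_invalid_band",
             sprintf("unknown frequency band '%s' (expected one of %s)",
                     band, paste(names(BNA_BANDS), collapse = ", ")))
  band
}
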