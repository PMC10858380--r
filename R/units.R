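# Unit conversion constants. All internal geometry is in millimeters;
# distances are reported in centimeters, volumes in cubic centimeters and
# standardized distances in inverse meters. Every conversion in the package
# goes through this table so the convention lives in exactly one place.
.units <- list(
  mm_per_cm  = 10,
  cm_per_m   = 100,
  mm3_per_cm3 = 1000
)

#' Convert millimeters to centimeters
#' @param x numeric vector of lengths in mm.
#' @return lengths in cm.
#' @keywords internal
mm_to_cm <- function(x) x / .units$mm_per_cm

#' Convert cubic millimeters to cubic centimeters
#' @param x numeric vector of volumes in mm^3.
#' @return volumes in cm^3.
#' @keywords internal
mm3_to_cm3 <- function(x) x / .units$mm3_per_cm3

#' Convert centimeters to meters
#' @param x numeric vector of lengths in cm.
#' @return lengths in m.
#' @keywords internal
cm_to_m <- function(x) x / .units$cm_per_m

# Evaluate `expr` under a temporary, seeded RNG state, restoring the caller's
# state afterwards. All stochastic operations in the package route through
# this helper so that explicit seeds give exact reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
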