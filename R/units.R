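# Unit conversion helpers. All internal computation is SI; the unit systems
# common in the intravital-microscopy literature (mmHg, um, cm, minutes) are
# accepted only at the configuration boundary.

#' Convert pressure from mmHg to Pa
#'
#' @param p_mmHg Pressure in millimetres of mercury. Must be finite.
#' @return Pressure in pascal (1 mmHg = 133.322 Pa).
#' @examples
#' mmhg_to_pa(50)  # arterial boundary pressure
#' @export
mmhg_to_pa <- function(p_mmHg) {
  stopifnot(is.numeric(p_mmHg), all(is.finite(p_mmHg)))
  p_mmHg * 133.322
}

#' Convert pressure from Pa to mmHg
#' @param p_Pa Pressure in pascal.
#' @return Pressure in mmHg.
#' @export
pa_to_mmhg <- function(p_Pa) {
  stopifnot(is.numeric(p_Pa), all(is.finite(p_Pa)))
  p_Pa / 133.322
}

# internal scalar validators
.check_positive <- function(..., .names = NULL) {
  vals <- list(...)
  nms <- if (is.null(.names)) {
    vapply(substitute(list(...))[-1], deparse, character(1))
  } else {
    .names
  }
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid parameter: `", nms[[i]], "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

um2_to_m2 <- function(x) x * 1e-12
um_to_m <- function(x) x * 1e-6
cm_to_m <- function(x) x * 1e-2
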