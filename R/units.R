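# All internal quantities are in cm-g-min units. Conversions live at the
# I/O boundary only (configs, CSV, CLI flags).

#' Unit conversions for the cm-g-min internal unit system
#'
#' All model quantities are held internally in centimetres, grams and
#' minutes. These helpers convert the laboratory units used in configs and
#' on the command line (microlitres, micrometres, micrograms, mg/mL,
#' mL/min) to and from the internal system.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
#' @examples
#' ul_to_cm3(25)      # 0.025 cm^3
#' um_to_cm(62.5)     # hydrated membrane thickness in cm
#' mg_per_ml_to_g_per_cm3(0.46)
NULL

#' @rdname units
#' @export
ul_to_cm3 <- function(x) x * 1e-3

#' @rdname units
#' @export
cm3_to_ul <- function(x) x * 1e3

#' @rdname units
#' @export
um_to_cm <- function(x) x * 1e-4

#' @rdname units
#' @export
cm_to_um <- function(x) x * 1e4

#' @rdname units
#' @export
ug_to_g <- function(x) x * 1e-6

#' @rdname units
#' @export
g_to_ug <- function(x) x * 1e6

#' @rdname units
#' @export
mg_per_ml_to_g_per_cm3 <- function(x) x * 1e-3

#' @rdname units
#' @export
g_per_cm3_to_mg_per_ml <- function(x) x * 1e3
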