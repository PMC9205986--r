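#' Convert normalized gaze units to degrees of visual angle
#'
#' Horizontal gaze is expressed in percent of the memory-item eccentricity:
#' 100% corresponds to fixating the centre of an item placed at
#' `eccentricity_deg` (5.7 degrees by default, the task geometry).
#'
#' @param pct Gaze position(s) in % units.
#' @param eccentricity_deg Eccentricity of the item centre, degrees.
#' @return Degrees of visual angle.
#' @examples
#' pct_to_deg(100)  # 5.7
#' pct_to_deg(1)    # 0.057, the minimum-magnitude floor
#' @export
pct_to_deg <- function(pct, eccentricity_deg = 5.7) {
  pct / 100 * eccentricity_deg
}

#' Convert degrees of visual angle to normalized gaze units
#'
#' @inheritParams pct_to_deg
#' @param deg Degrees of visual angle.
#' @return Gaze position(s) in % units.
#' @export
deg_to_pct <- function(deg, eccentricity_deg = 5.7) {
  deg / eccentricity_deg * 100
}
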