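#' Rice phenological calendar
#'
#' The default calendar splits the 149-day rice season (day 0 = emergence)
#' into six contiguous development windows. Weather covariates are summarized
#' per window, so each daily variable yields six stage-tagged covariates.
#'
#' @param stages data frame with columns `stage`, `start`, `end` (days after
#'   emergence, inclusive). Defaults to the standard rice calendar:
#'   EM_MAX.TIL 0--44, MAX.TIL_PAN.INIT 45--59, PAN.INIT_PRE.FLW 60--74,
#'   PRE.FLW_FLW 75--89, FLW_POST.FLW 90--104, POST.FLW_MAT 105--148.
#' @return A validated `phenology_calendar` data frame.
#' @export
#' @examples
#' phenology_calendar()
phenology_calendar <- function(stages = NULL) {
  if (is.null(stages)) {
    stages <- data.frame(
      stage = c("EM_MAX.TIL", "MAX.TIL_PAN.INIT", "PAN.INIT_PRE.FLW",
                "PRE.FLW_FLW", "FLW_POST.FLW", "POST.FLW_MAT"),
      start = c(0L, 45L, 60L, 75L, 90L, 105L),
      end   = c(44L, 59L, 74L, 89L, 104L, 148L),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(stages),
            all(c("stage", "start", "end") %in% names(stages)))
  if (any(stages$end < stages$start)) {
    stop("phenology_calendar: stage end before start")
  }
  if (nrow(stages) > 1) {
    # windows must be contiguous, non-overlapping, ascending
    if (!all(stages$start[-1] == stages$end[-nrow(stages)] + 1L)) {
      stop("phenology_calendar: windows must be contiguous and ascending")
    }
  }
  if (anyDuplicated(stages$stage)) stop("phenology_calendar: duplicate stage names")
  class(stages) <- c("phenology_calendar", "data.frame")
  stages
}

#' Cardinal temperatures for thermal-time accumulation
#'
#' Cardinal limits used to tune temperature covariates to the crop response.
#' Published sources for rice rarely print a single canonical triplet; the
#' defaults (base 10, optimum 30, maximum 42 degrees C) sit inside the commonly
#' cited ranges and are fully configurable.
#'
#' @param t_base base temperature (degrees C) below which development stops
#' @param t_opt optimum temperature (degrees C)
#' @param t_max maximum temperature (degrees C) capping thermal accumulation
#' @return A `cardinal_temps` list.
#' @export
cardinal_temps <- function(t_base = 10, t_opt = 30, t_max = 42) {
  stopifnot(is.numeric(t_base), is.numeric(t_opt), is.numeric(t_max))
  if (!(t_base < t_opt && t_opt < t_max)) {
    stop("cardinal_temps: require t_base < t_opt < t_max")
  }
  structure(list(t_base = t_base, t_opt = t_opt, t_max = t_max),
            class = "cardinal_temps")
}

#' Daily growing degree-days
#'
#' Capped single-triangle average method: each daily extreme is clipped to the
#' cardinal interval \[t_base, t_max\] and thermal time is the excess of the
#' clipped mean over the base temperature, never negative:
#' `max(0, (clip(t_min) + clip(t_max)) / 2 - t_base)`.
#'
#' @param t_min,t_max daily minimum and maximum air temperature (degrees C);
#'   vectors are accepted and recycled by position
#' @param cardinal a [cardinal_temps()] object
#' @return Numeric vector of degree-days (degrees C day).
#' @export
#' @examples
#' gdd_daily(20, 30, cardinal_temps(10, 30, 42)) # 15
gdd_daily <- function(t_min, t_max, cardinal = cardinal_temps()) {
  stopifnot(inherits(cardinal, "cardinal_temps"))
  if (length(t_min) != length(t_max)) {
    stop("gdd_daily: t_min and t_max must have equal length")
  }
  if (any(t_min > t_max)) stop("gdd_daily: t_min > t_max")
  clip <- function(x) pmin(pmax(x, cardinal$t_base), cardinal$t_max)
  pmax(0, (clip(t_min) + clip(t_max)) / 2 - cardinal$t_base)
}
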