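#' Budget model constants
#'
#' Returns the immutable set of constants used throughout the carbonate
#' budget equations: the coralline-algal production rate, the sediment
#' ceiling, the macroboring erosion constant, the parrotfish bite-volume,
#' scar-proportion and bite-rate regression coefficients, the echinoid
#' allometries, and the unit-conversion factors. Overrides are applied on
#' top of the defaults and recorded in the `overridden` attribute so a run
#' can audit exactly which constants it used.
#'
#' @param ... named overrides, e.g. `reeftime_h = 8` or `sediment = 0.2`.
#'   Unknown names are an error.
#'
#' @return An object of class `budget_constants`: a named list with
#'   components
#'   \describe{
#'     \item{cca_rate}{gross carbonate production of coralline algae,
#'       g cm^-2 y^-1 per unit cover (0.018).}
#'     \item{gcm2_to_kgm2}{10; converts g cm^-2 to kg m^-2.}
#'     \item{sediment}{positive sediment contribution, kg CaCO3 m^-2 y^-1
#'       (ceiling 0.4).}
#'     \item{sediment_sign}{+1 under low local sedimentation (default), -1
#'       for high-sedimentation scenarios.}
#'     \item{mec}{macroboring erosion constant, kg CaCO3 m^-2 y^-1 (10).}
#'     \item{reeftime_h}{hours per day parrotfishes spend grazing (9).}
#'     \item{bite_vol}{intercept/slope of the log bite-volume regression
#'       (1.32, 0.06) and the mm^3-to-cm^3 divisor (1000).}
#'     \item{scar}{logistic scar-proportion coefficients (-2.46, 0.089).}
#'     \item{bite_rate}{bite-rate coefficients (60, 4.31, -0.36, 0.045).}
#'     \item{urchin}{per-genus allometric coefficient and exponent, each
#'       multiplied downstream by `0.365 * 0.57`.}
#'     \item{g_day_to_kg_yr}{365 * 0.001 = 0.365 (g day^-1 to kg y^-1).}
#'     \item{default_coral_density}{fallback mean coral skeletal density,
#'       g cm^-3, used when a site has no living coral (1.5).}
#'     \item{fish_area_m2, urchin_area_m2}{surveyed area per transect for
#'       the fish video belt (120) and the echinoid belt (6).}
#'     \item{rcp_slr_mm}{projected sea-level-rise rates (mm y^-1) per RCP
#'       scenario used by [keep_up_assessment()].}
#'   }
#' @export
#' @examples
#' k <- budget_constants()
#' k$mec
#' budget_constants(reeftime_h = 8)$reeftime_h
budget_constants <- function(...) {
  k <- list(
    cca_rate = 0.018,
    gcm2_to_kgm2 = 10,
    sediment = 0.4,
    sediment_sign = 1,
    mec = 10,
    reeftime_h = 9,
    bite_vol = c(intercept = 1.32, slope = 0.06, mm3_per_cm3 = 1000),
    scar = c(intercept = -2.46, slope = 0.089),
    bite_rate = c(min_per_h = 60, a = 4.31, b = -0.36, c = 0.045),
    urchin = list(
      Diadema     = c(coef = 1e-6, exp = 3.42),
      Echinometra = c(coef = 4e-4, exp = 1.98),
      Other       = c(coef = 1e-4, exp = 2.32)
    ),
    urchin_retention = 0.57,
    g_day_to_kg_yr = 365 * 0.001,
    default_coral_density = 1.5,
    fish_area_m2 = 120,
    urchin_area_m2 = 6,
    rcp_slr_mm = c(RCP2.6 = 5.0, RCP4.5 = 6.5, RCP6 = 6.7, RCP8.5 = 9.0)
  )
  # unit sanity for the day->year, g->kg factor baked into the allometries
  stopifnot(isTRUE(all.equal(k$g_day_to_kg_yr, 0.365)))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(k))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown budget constant(s): ", paste(bad, collapse = ", "))
    }
    k[names(dots)] <- dots
    attr(k, "overridden") <- names(dots)
  } else {
    attr(k, "overridden") <- character(0)
  }
  class(k) <- "budget_constants"
  k
}

#' @export
print.budget_constants <- function(x, ...) {
  cat("Carbonate budget constants\n")
  ov <- attr(x, "overridden")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.list(val)) {
      cat(sprintf("  %s:\n", nm))
      for (g in names(val)) {
        cat(sprintf("    %-12s %s\n", g, paste(signif(val[[g]], 6), collapse = " ")))
      }
    } else {
      cat(sprintf("  %-22s %s%s\n", nm,
                  paste(signif(unname(val), 6), collapse = " "),
                  if (nm %in% ov) "  [override]" else ""))
    }
  }
  invisible(x)
}
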