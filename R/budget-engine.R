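#' Coralline algal calcification
#'
#' Gross carbonate production contributed by crustose coralline algae (CCA)
#' at a given planar percent cover: `0.018 * pca * 10` kg CaCO3 m^-2 y^-1,
#' where 0.018 g cm^-2 y^-1 is the average gross production per unit cover
#' and 10 converts g cm^-2 to kg m^-2.
#'
#' @param pca_percent planar CCA cover, percent in `[0, 100]`.
#' @param constants a [budget_constants()] object.
#' @return kg CaCO3 m^-2 y^-1, vectorised.
#' @export
#' @examples
#' cca_calcification(15) # 2.7
cca_calcification <- function(pca_percent, constants = budget_constants()) {
  if (any(!is.finite(pca_percent)) || any(pca_percent < 0 | pca_percent > 100)) {
    stop("pca_percent must lie in [0, 100]")
  }
  constants$cca_rate * pca_percent * constants$gcm2_to_kgm2
}

#' Gross coral and CCA calcification for one transect
#'
#' Rugosity-corrected gross carbonate production:
#' `r * ( sum_j m_j * (x_j / 100) * d_j * g_j * 10  +  ca )`,
#' where for each coral taxon j, `m` is the morphological adjustment
#' coefficient, `x` its planar percent cover, `d` its skeletal density
#' (g cm^-3), `g` its vertical growth (cm y^-1); `ca` is the CCA term of
#' [cca_calcification()]; and `r` the rugosity index converting planar to
#' true substrate area.
#'
#' @param cover data.frame `taxon_code, cover_pct` of coral cover per taxon
#'   (percent of the tape), or a named numeric vector of percents.
#' @param traits a trait table ([read_traits()]); every taxon in `cover`
#'   must resolve to finite `m`, `d`, `g` unless `permissive`.
#' @param rugosity_index dimensionless rugosity, >= 1.
#' @param cca_cover_pct planar CCA percent cover (default 0).
#' @param constants a [budget_constants()] object.
#' @param permissive if `TRUE`, taxa missing from the trait table fall back
#'   to generic coral traits (m = 1, d = `default_coral_density`, g = 0.5)
#'   with a warning instead of an error.
#' @return Gross calcification, kg CaCO3 m^-2 y^-1 (scalar).
#' @export
#' @examples
#' tr <- data.frame(taxon_code = "A", m = 1, d = 1.4, g = 0.8, brc = NA)
#' coral_calcification(c(A = 40), tr, rugosity_index = 1.5) # 6.72
coral_calcification <- function(cover, traits, rugosity_index,
                                cca_cover_pct = 0,
                                constants = budget_constants(),
                                permissive = FALSE) {
  if (is.numeric(cover)) {
    cover <- data.frame(taxon_code = names(cover), cover_pct = as.numeric(cover))
  }
  stopifnot(rugosity_index >= 1)
  ca <- cca_calcification(cca_cover_pct, constants)
  acc <- 0
  if (nrow(cover)) {
    i <- match(cover$taxon_code, traits$taxon_code)
    m <- traits$m[i]; d <- traits$d[i]; g <- traits$g[i]
    bad <- is.na(i) | is.na(m) | is.na(d) | is.na(g)
    if (any(bad)) {
      if (permissive) {
        warning("substituting generic coral traits for: ",
                paste(unique(cover$taxon_code[bad]), collapse = ", "))
        m[bad] <- 1; d[bad] <- constants$default_coral_density; g[bad] <- 0.5
      } else {
        stop("missing coral trait(s) for taxon: ",
             paste(unique(cover$taxon_code[bad]), collapse = ", "), call. = FALSE)
      }
    }
    acc <- sum(m * (cover$cover_pct / 100) * d * g * constants$gcm2_to_kgm2)
  }
  rugosity_index * (acc + ca)
}

#' Parrotfish bite volume
#'
#' Allometric bite volume from fish fork length:
#' `exp(1.32 + 0.06 * length) / 1000` cm^3 (the regression predicts mm^3).
#' Strictly increasing in length.
#'
#' @param length_cm fork length, cm, > 0.
#' @param constants a [budget_constants()] object.
#' @return Bite volume, cm^3, vectorised.
#' @export
bite_volume <- function(length_cm, constants = budget_constants()) {
  if (any(!is.finite(length_cm)) || any(length_cm <= 0)) {
    stop("length_cm must be > 0")
  }
  b <- constants$bite_vol
  exp(b[["intercept"]] + b[["slope"]] * length_cm) / b[["mm3_per_cm3"]]
}

#' Proportion of parrotfish bites leaving a scar
#'
#' Logistic in fork length: `1 / (1 + exp(-(-2.46 + 0.089 * length)))`,
#' bounded in (0, 1) with midpoint near 27.6 cm.
#'
#' @inheritParams bite_volume
#' @return Scar proportion, vectorised.
#' @export
scar_proportion <- function(length_cm, constants = budget_constants()) {
  if (any(!is.finite(length_cm)) || any(length_cm <= 0)) {
    stop("length_cm must be > 0")
  }
  s <- constants$scar
  1 / (1 + exp(-(s[["intercept"]] + s[["slope"]] * length_cm)))
}

#' Parrotfish bite rate
#'
#' Bites per day from fork length and the species bite-rate constant:
#' `60 * ((4.31 + brc - 0.36) - 0.045 * reeftime * length)` with
#' `reeftime = 9` h of daily grazing. The linear form goes negative outside
#' the fitted size range, so the rate is clamped at 0 (a fish cannot erode
#' negatively).
#'
#' @param length_cm fork length, cm, > 0.
#' @param brc species bite-rate constant; must be finite.
#' @param constants a [budget_constants()] object.
#' @return Bites per day, >= 0, vectorised over length and brc.
#' @export
bite_rate <- function(length_cm, brc, constants = budget_constants()) {
  if (any(!is.finite(length_cm)) || any(length_cm <= 0)) {
    stop("length_cm must be > 0")
  }
  if (any(!is.finite(brc))) stop("missing bite-rate constant (brc)")
  k <- constants$bite_rate
  raw <- k[["min_per_h"]] *
    ((k[["a"]] + brc + k[["b"]]) -
       (k[["c"]] * constants$reeftime_h * length_cm))
  pmax(raw, 0)
}

#' Parrotfish erosion over a surveyed area
#'
#' Per-individual erosion is bite volume x scar proportion x bite rate x
#' mean coral skeletal density, converted from g day^-1 to kg y^-1
#' (x 365 x 0.001); individuals are summed and normalised by the surveyed
#' video-transect area so the result carries kg CaCO3 m^-2 y^-1.
#'
#' @param length_cm fork lengths of the observed fishes (may be empty).
#' @param brc species bite-rate constant per fish (recycled if scalar).
#' @param mean_coral_density site mean coral skeletal density, g cm^-3.
#' @param area_m2 surveyed fish area (n transects x 120 m^2).
#' @param constants a [budget_constants()] object.
#' @return kg CaCO3 m^-2 y^-1 (scalar, >= 0).
#' @export
parrotfish_erosion <- function(length_cm, brc, mean_coral_density,
                               area_m2, constants = budget_constants()) {
  stopifnot(area_m2 > 0)
  if (!length(length_cm)) return(0)
  per_fish <- bite_volume(length_cm, constants) *
    scar_proportion(length_cm, constants) *
    bite_rate(length_cm, brc, constants)
  sum(per_fish) * mean_coral_density * constants$g_day_to_kg_yr / area_m2
}

#' Echinoid erosion per individual
#'
#' Genus-level allometries in test diameter (cm), each converted from
#' g day^-1 to kg y^-1 (x 0.365) and scaled by 0.57 for the reef-carbonate
#' fraction of gut contents:
#' Diadema `1e-6 * diam^3.42`, Echinometra `4e-4 * diam^1.98`, other
#' urchins `1e-4 * diam^2.32`.
#'
#' @param genus_class `"Diadema"`, `"Echinometra"` or `"Other"` (vectorised).
#' @param diameter_cm test diameter, cm, > 0.
#' @param constants a [budget_constants()] object.
#' @return kg CaCO3 y^-1 per individual, vectorised.
#' @export
#' @examples
#' urchin_erosion_individual("Diadema", 5) # ~5.11e-5
urchin_erosion_individual <- function(genus_class, diameter_cm,
                                      constants = budget_constants()) {
  if (any(!is.finite(diameter_cm)) || any(diameter_cm <= 0)) {
    stop("diameter_cm must be > 0")
  }
  bad <- setdiff(unique(genus_class), names(constants$urchin))
  if (length(bad)) {
    stop("unknown urchin genus_class: ", paste(bad, collapse = ", "))
  }
  cf <- vapply(constants$urchin[genus_class], `[[`, numeric(1), "coef")
  ex <- vapply(constants$urchin[genus_class], `[[`, numeric(1), "exp")
  cf * diameter_cm^ex * constants$g_day_to_kg_yr * constants$urchin_retention
}

#' Echinoid erosion over a surveyed belt area
#'
#' Sums [urchin_erosion_individual()] over all counted echinoids and
#' normalises by the surveyed belt area (n transects x 6 m^2).
#'
#' @param genus_class,diameter_cm parallel vectors of observations.
#' @param area_m2 surveyed belt area, m^2.
#' @param constants a [budget_constants()] object.
#' @return kg CaCO3 m^-2 y^-1 (scalar, >= 0).
#' @export
urchin_erosion <- function(genus_class, diameter_cm, area_m2,
                           constants = budget_constants()) {
  stopifnot(area_m2 > 0)
  if (!length(diameter_cm)) return(0)
  sum(urchin_erosion_individual(genus_class, diameter_cm, constants)) / area_m2
}

#' Macroboring erosion
#'
#' `plamc * mec`, where `plamc` is the mean planar cover of macroboring
#' organisms as a proportion (0-1) and `mec` is the macroboring erosion
#' constant (conservatively 10 kg CaCO3 m^-2 y^-1 for clionaid sponges).
#'
#' @param plamc proportion cover of macroborers, in `[0, 1]`. Values above 1
#'   raise an error suggesting a percent/proportion mix-up.
#' @param constants a [budget_constants()] object.
#' @return kg CaCO3 m^-2 y^-1, vectorised.
#' @export
#' @examples
#' macroboring_erosion(0.0058) # 0.058
macroboring_erosion <- function(plamc, constants = budget_constants()) {
  if (any(!is.finite(plamc)) || any(plamc < 0)) stop("plamc must be in [0, 1]")
  if (any(plamc > 1)) {
    stop("plamc > 1: macroborer cover must be a proportion (0-1), not a percent")
  }
  plamc * constants$mec
}

#' Site mean coral skeletal density
#'
#' Cover-weighted mean of trait densities over the coral taxa present at a
#' site (weights = summed chord length per taxon). With no living coral the
#' configurable default density is returned.
#'
#' @param cover data.frame `taxon_code, cover_pct` (site-level coral cover).
#' @param traits trait table.
#' @param constants a [budget_constants()] object.
#' @param permissive substitute the default density for taxa with unknown
#'   density instead of erroring.
#' @return g cm^-3 (scalar).
#' @export
mean_coral_density <- function(cover, traits, constants = budget_constants(),
                               permissive = FALSE) {
  cover <- cover[cover$cover_pct > 0, , drop = FALSE]
  if (!nrow(cover)) return(constants$default_coral_density)
  d <- traits$d[match(cover$taxon_code, traits$taxon_code)]
  if (any(is.na(d))) {
    if (permissive) {
      d[is.na(d)] <- constants$default_coral_density
    } else {
      stop("missing density for taxon: ",
           paste(cover$taxon_code[is.na(d)], collapse = ", "), call. = FALSE)
    }
  }
  sum(d * cover$cover_pct) / sum(cover$cover_pct)
}

#' Per-transect carbonate budgets
#'
#' Solves the full budget for every transect of a survey dataset: gross
#' calcification (corals + CCA, rugosity-corrected), the three erosion
#' components, the sediment term, and net production
#' `net = gross + sign * sediment - (parrotfish + urchin + macroboring)`.
#' The site mean coral density feeds the parrotfish term; fish and urchin
#' observations are normalised by their per-transect survey areas.
#'
#' @param x a `survey_dataset`.
#' @param traits trait table (default [default_traits()]).
#' @param constants a [budget_constants()] object.
#' @param permissive passed to the trait lookups.
#' @return data.frame with one row per transect: `site_id, transect_id,
#'   rugosity, coral_cover_pct, cca_cover_pct, gross_calcification,
#'   parrotfish_erosion, urchin_erosion, macroboring_erosion, sediment,
#'   net_production`.
#' @export
transect_budgets <- function(x, traits = default_traits(),
                             constants = budget_constants(),
                             permissive = FALSE) {
  stopifnot(inherits(x, "survey_dataset"))
  roster <- x$rugosity
  n <- nrow(roster)
  r <- rugosity(roster$contour_length_cm, roster$horizontal_length_cm)

  coral <- x$benthic[x$benthic$category == "coral", , drop = FALSE]
  cca <- planar_cover(x, category = "coralline_algae")$cover_pct
  coral_pct <- planar_cover(x, category = "coral")$cover_pct
  mb_pct <- planar_cover(x, category = "macroborer")$cover_pct

  # site-level mean coral density (cover-weighted across the whole site)
  dens <- vapply(unique(roster$site_id), function(sid) {
    b <- coral[coral$site_id == sid, , drop = FALSE]
    cov <- if (nrow(b)) {
      agg <- tapply(b$chord_cm, b$taxon_code, sum)
      data.frame(taxon_code = names(agg), cover_pct = as.numeric(agg))
    } else data.frame(taxon_code = character(), cover_pct = numeric())
    mean_coral_density(cov, traits, constants, permissive)
  }, numeric(1))
  names(dens) <- unique(roster$site_id)

  rkey <- transect_key(roster)
  gross <- parrot <- urch <- macro <- numeric(n)
  for (i in seq_len(n)) {
    key <- rkey[i]
    b <- coral[transect_key(coral) == key, , drop = FALSE]
    cov <- if (nrow(b)) {
      agg <- tapply(b$chord_cm, b$taxon_code, sum)
      data.frame(taxon_code = names(agg),
                 cover_pct = 100 * as.numeric(agg) / roster$contour_length_cm[i])
    } else data.frame(taxon_code = character(), cover_pct = numeric())
    gross[i] <- coral_calcification(cov, traits, r[i], cca[i], constants,
                                    permissive)

    f <- x$fish[transect_key(x$fish) == key, , drop = FALSE]
    if (nrow(f)) {
      brc <- traits$brc[match(f$species_code, traits$taxon_code)]
      if (any(is.na(brc))) {
        if (permissive) {
          warning("substituting median brc for: ",
                  paste(unique(f$species_code[is.na(brc)]), collapse = ", "))
          brc[is.na(brc)] <- stats::median(traits$brc, na.rm = TRUE)
        } else {
          stop("missing brc for parrotfish species: ",
               paste(unique(f$species_code[is.na(brc)]), collapse = ", "),
               call. = FALSE)
        }
      }
      parrot[i] <- parrotfish_erosion(f$length_cm, brc,
                                      dens[[roster$site_id[i]]],
                                      constants$fish_area_m2, constants)
    }
    u <- x$urchins[transect_key(x$urchins) == key, , drop = FALSE]
    if (nrow(u)) {
      urch[i] <- urchin_erosion(u$genus_class, u$test_diameter_cm,
                                constants$urchin_area_m2, constants)
    }
    macro[i] <- macroboring_erosion(mb_pct[i] / 100, constants)
  }
  sed <- constants$sediment_sign * constants$sediment
  data.frame(
    site_id = roster$site_id, transect_id = roster$transect_id,
    rugosity = r, coral_cover_pct = coral_pct, cca_cover_pct = cca,
    gross_calcification = gross, parrotfish_erosion = parrot,
    urchin_erosion = urch, macroboring_erosion = macro,
    sediment = sed,
    net_production = gross + sed - (parrot + urch + macro),
    stringsAsFactors = FALSE)
}

#' Site carbonate budgets
#'
#' Averages [transect_budgets()] within each site and joins site metadata
#' (island, habitat, coordinates) and live coral cover. The budget identity
#' `net = gross + sediment - total erosion` holds exactly at both levels.
#' Sites where erosion exceeds gross plus sediment carry a `net_erosion`
#' flag.
#'
#' @inheritParams transect_budgets
#' @return data.frame, one row per site, of class `site_budgets`.
#' @export
site_budgets <- function(x, traits = default_traits(),
                         constants = budget_constants(),
                         permissive = FALSE) {
  tb <- transect_budgets(x, traits, constants, permissive)
  num <- c("rugosity", "coral_cover_pct", "cca_cover_pct",
           "gross_calcification", "parrotfish_erosion", "urchin_erosion",
           "macroboring_erosion", "sediment", "net_production")
  agg <- stats::aggregate(tb[num], by = list(site_id = tb$site_id), mean)
  n_tr <- as.data.frame(table(tb$site_id), stringsAsFactors = FALSE)
  names(n_tr) <- c("site_id", "n_transects")
  out <- merge(x$sites, agg, by = "site_id")
  out <- merge(out, n_tr, by = "site_id")
  out <- merge(out, live_coral_cover(x), by = "site_id")
  out$net_erosion <- out$net_production < 0
  out <- out[order(out$island, out$habitat, out$site_id), ]
  rownames(out) <- NULL
  class(out) <- c("site_budgets", "data.frame")
  out
}

#' Calibrate the vertical-growth coefficient
#'
#' The quadratic conversion `vertical = Cp + alpha * Cp^2` maps carbonate
#' production Cp (kg CaCO3 m^-2 y^-1) to vertical reef growth (mm y^-1).
#' Given calibration pairs `(Cp, vertical_mm)`, the least-squares
#' coefficient is `alpha = sum(Cp^2 (v - Cp)) / sum(Cp^4)`; a single pair
#' inverts exactly.
#'
#' @param cp carbonate production values, kg CaCO3 m^-2 y^-1.
#' @param vertical_mm corresponding vertical growth rates, mm y^-1.
#' @return `alpha`, units (kg m^-2 y^-1)^-1.
#' @export
#' @examples
#' calibrate_alpha(9.7, 7.9) # ~ -0.01913
calibrate_alpha <- function(cp, vertical_mm) {
  stopifnot(length(cp) == length(vertical_mm), length(cp) >= 1)
  if (all(cp == 0)) stop("alpha is unidentifiable: all Cp are zero")
  sum(cp^2 * (vertical_mm - cp)) / sum(cp^4)
}

#' Vertical reef growth from carbonate production
#'
#' Evaluates `vertical = Cp + alpha * Cp^2` (mm y^-1). For `alpha < 0` the
#' parabola peaks at `Cp = -1 / (2 alpha)`; beyond the apex the conversion
#' would decrease, which is outside the calibrated domain, so values are
#' clamped at the apex with a warning.
#'
#' @param cp carbonate production, kg CaCO3 m^-2 y^-1, >= 0 (vectorised).
#' @param alpha conversion coefficient, e.g. from [calibrate_alpha()].
#' @return Vertical growth, mm y^-1.
#' @export
#' @examples
#' a <- calibrate_alpha(9.7, 7.9)
#' vertical_growth(20, a) # ~12.35
vertical_growth <- function(cp, alpha) {
  if (any(!is.finite(cp)) || any(cp < 0)) stop("cp must be >= 0")
  if (alpha < 0) {
    apex <- -1 / (2 * alpha)
    if (any(cp > apex)) {
      warning(sprintf(
        "Cp beyond the parabola apex (%.2f); clamping to the apex value", apex))
      cp <- pmin(cp, apex)
    }
  }
  cp + alpha * cp^2
}

#' Keep-up assessment against sea-level-rise scenarios
#'
#' Compares a vertical reef-growth rate against the projected sea-level-rise
#' rate of an RCP climate scenario (RCP2.6: 5.0, RCP4.5: 6.5, RCP6: 6.7,
#' RCP8.5: 9.0 mm y^-1). A reef "keeps up" when its growth rate is at least
#' the scenario rate (ties keep up).
#'
#' @param vertical_mm vertical growth rate, mm y^-1.
#' @param scenario one of `"RCP2.6"`, `"RCP4.5"`, `"RCP6"`, `"RCP8.5"`.
#' @param constants a [budget_constants()] object (scenario table lives in
#'   `rcp_slr_mm`).
#' @return list with `keeps_up` (logical), `margin_mm` (vertical minus
#'   scenario rate) and `slr_mm` (the scenario rate).
#' @export
#' @examples
#' keep_up_assessment(7.9, "RCP2.6")$margin_mm # 2.9
keep_up_assessment <- function(vertical_mm, scenario,
                               constants = budget_constants()) {
  rates <- constants$rcp_slr_mm
  if (!scenario %in% names(rates)) {
    stop("unknown scenario '", scenario, "'; use one of: ",
         paste(names(rates), collapse = ", "))
  }
  slr <- rates[[scenario]]
  list(keeps_up = vertical_mm >= slr, margin_mm = vertical_mm - slr,
       slr_mm = slr)
}
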