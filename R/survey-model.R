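#' @keywords internal
"_PACKAGE"

# Legal category / island / habitat levels used throughout the package.
BENTHIC_CATEGORIES <- c("coral", "coralline_algae", "macroborer", "other")
ISLANDS <- c("Palau", "Yap")
HABITATS <- c("outer_west", "outer_east", "patch", "inner")
URCHIN_GENERA <- c("Diadema", "Echinometra", "Other")

#' Construct a survey dataset
#'
#' Bundles the five survey tables (sites, benthic line-intercepts, rugosity
#' line pairs, parrotfish observations, echinoid observations) into a single
#' validated container. The tables follow the CSV schemas documented in
#' [read_survey_dataset()].
#'
#' @param sites data.frame with columns `site_id, island, habitat, lat, lon`.
#' @param benthic data.frame with columns
#'   `site_id, transect_id, taxon_code, category, morphology_code, chord_cm`.
#' @param rugosity data.frame with columns
#'   `site_id, transect_id, contour_length_cm, horizontal_length_cm`. One row
#'   per transect; this table is the transect roster.
#' @param fish data.frame with columns
#'   `site_id, transect_id, species_code, length_cm` (may have zero rows).
#' @param urchins data.frame with columns
#'   `site_id, transect_id, genus_class, test_diameter_cm` (may have zero rows).
#' @param validate run [validate_survey_dataset()] (default `TRUE`).
#'
#' @return An object of class `survey_dataset` (a named list of the five
#'   data.frames).
#' @export
survey_dataset <- function(sites, benthic, rugosity, fish, urchins,
                           validate = TRUE) {
  x <- structure(
    list(sites = as.data.frame(sites), benthic = as.data.frame(benthic),
         rugosity = as.data.frame(rugosity), fish = as.data.frame(fish),
         urchins = as.data.frame(urchins)),
    class = "survey_dataset")
  if (validate) validate_survey_dataset(x)
  x
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf(
    "survey_dataset: %d sites, %d transects, %d benthic intercepts, %d fish, %d urchins\n",
    nrow(x$sites), nrow(x$rugosity), nrow(x$benthic), nrow(x$fish),
    nrow(x$urchins)))
  tab <- table(x$sites$island, x$sites$habitat)
  print(tab)
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in %s: missing column(s) %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Validate a survey dataset
#'
#' Checks the schema, referential integrity and the field invariants of a
#' [survey_dataset()]: positive chord lengths summing to no more than the
#' tape length, contour lines at least as long as their horizontal pairs
#' (within tolerance), fish lengths in (1, 150) cm, urchin test diameters in
#' (0.1, 25) cm, legal island/habitat combinations (Yap carries no patch
#' stratum), and one to six transects per site.
#'
#' @param x a `survey_dataset`.
#' @param tape_tolerance_cm slack allowed on the summed intercepted chord
#'   versus the contour tape length (default 1 cm).
#' @return `x`, invisibly. Errors describe the first violated constraint.
#' @export
validate_survey_dataset <- function(x, tape_tolerance_cm = 1) {
  check_columns(x$sites, c("site_id", "island", "habitat", "lat", "lon"), "sites")
  check_columns(x$benthic,
                c("site_id", "transect_id", "taxon_code", "category",
                  "morphology_code", "chord_cm"), "benthic")
  check_columns(x$rugosity,
                c("site_id", "transect_id", "contour_length_cm",
                  "horizontal_length_cm"), "rugosity")
  check_columns(x$fish, c("site_id", "transect_id", "species_code", "length_cm"),
                "fish")
  check_columns(x$urchins,
                c("site_id", "transect_id", "genus_class", "test_diameter_cm"),
                "urchins")

  s <- x$sites
  if (anyDuplicated(s$site_id)) stop("duplicate site_id in sites table")
  bad_isl <- setdiff(unique(s$island), ISLANDS)
  if (length(bad_isl)) stop("unknown island: ", paste(bad_isl, collapse = ", "))
  bad_hab <- setdiff(unique(s$habitat), HABITATS)
  if (length(bad_hab)) stop("unknown habitat: ", paste(bad_hab, collapse = ", "))
  if (any(s$island == "Yap" & s$habitat == "patch")) {
    stop("validation error: habitat 'patch' is not a legal stratum on Yap")
  }

  # referential integrity: every transect-bearing table resolves to sites,
  # and every transect resolves to the rugosity roster
  for (tab in c("benthic", "rugosity", "fish", "urchins")) {
    orphan <- setdiff(unique(x[[tab]]$site_id), s$site_id)
    if (length(orphan)) {
      stop(sprintf("referential error: %s references unknown site_id %s",
                   tab, paste(orphan, collapse = ", ")), call. = FALSE)
    }
  }
  roster <- paste(x$rugosity$site_id, x$rugosity$transect_id)
  if (anyDuplicated(roster)) stop("duplicate transect in rugosity roster")
  for (tab in c("benthic", "fish", "urchins")) {
    keys <- unique(paste(x[[tab]]$site_id, x[[tab]]$transect_id))
    orphan <- setdiff(keys, roster)
    if (length(orphan)) {
      stop(sprintf("referential error: %s references transect(s) absent from rugosity roster: %s",
                   tab, paste(orphan, collapse = "; ")), call. = FALSE)
    }
  }
  n_tr <- table(x$rugosity$site_id)
  if (any(n_tr < 1) || any(n_tr > 6)) {
    stop("each site must carry between 1 and 6 transects")
  }

  b <- x$benthic
  if (nrow(b)) {
    if (any(!is.finite(b$chord_cm)) || any(b$chord_cm <= 0)) {
      stop("validation error: benthic chord_cm must be > 0")
    }
    bad_cat <- setdiff(unique(b$category), BENTHIC_CATEGORIES)
    if (length(bad_cat)) {
      stop("unknown benthic category: ", paste(bad_cat, collapse = ", "))
    }
    tape <- x$rugosity$contour_length_cm[
      match(paste(b$site_id, b$transect_id), roster)]
    tot <- tapply(b$chord_cm, paste(b$site_id, b$transect_id), sum)
    lim <- tapply(tape, paste(b$site_id, b$transect_id), `[`, 1L)
    over <- tot > lim + tape_tolerance_cm
    if (any(over)) {
      stop(sprintf("validation error: intercepted chords exceed tape length on transect(s) %s",
                   paste(names(tot)[over], collapse = "; ")), call. = FALSE)
    }
  }
  r <- x$rugosity
  if (any(r$horizontal_length_cm <= 0) || any(r$contour_length_cm <= 0)) {
    stop("validation error: rugosity line lengths must be > 0")
  }
  if (nrow(x$fish)) {
    if (any(x$fish$length_cm <= 1 | x$fish$length_cm >= 150)) {
      stop("validation error: fish length_cm must lie in (1, 150)")
    }
  }
  if (nrow(x$urchins)) {
    bad_gen <- setdiff(unique(x$urchins$genus_class), URCHIN_GENERA)
    if (length(bad_gen)) {
      stop("unknown urchin genus_class: ", paste(bad_gen, collapse = ", "))
    }
    d <- x$urchins$test_diameter_cm
    if (any(d <= 0.1 | d >= 25)) {
      stop("validation error: urchin test_diameter_cm must lie in (0.1, 25)")
    }
  }
  invisible(x)
}

#' Read a survey dataset from CSV files
#'
#' Reads the five survey tables and returns a validated [survey_dataset()].
#' The expected schemas (UTF-8, comma-separated, mandatory header row) are:
#' \itemize{
#'   \item `sites.csv`: `site_id,island,habitat,lat,lon` with island in
#'     Palau/Yap, habitat in outer_west/outer_east/patch/inner, coordinates
#'     in decimal degrees WGS84;
#'   \item `benthic.csv`:
#'     `site_id,transect_id,taxon_code,category,morphology_code,chord_cm`,
#'     one row per line-intercept record;
#'   \item `rugosity.csv`:
#'     `site_id,transect_id,contour_length_cm,horizontal_length_cm`, one row
#'     per transect (the transect roster);
#'   \item `fish.csv`: `site_id,transect_id,species_code,length_cm`, one row
#'     per parrotfish seen on the 30 m x 4 m video transect;
#'   \item `urchins.csv`: `site_id,transect_id,genus_class,test_diameter_cm`,
#'     one row per echinoid in the 10 m x 0.6 m belt.
#' }
#'
#' @param dir directory holding the five CSVs under their default names;
#'   alternatively pass the paths individually.
#' @param sites_path,benthic_path,rugosity_path,fish_path,urchins_path
#'   individual file paths (override `dir`).
#' @return A validated `survey_dataset`.
#' @export
read_survey_dataset <- function(dir = NULL,
                                sites_path = file.path(dir, "sites.csv"),
                                benthic_path = file.path(dir, "benthic.csv"),
                                rugosity_path = file.path(dir, "rugosity.csv"),
                                fish_path = file.path(dir, "fish.csv"),
                                urchins_path = file.path(dir, "urchins.csv")) {
  rd <- function(p) {
    if (!file.exists(p)) stop("survey file not found: ", p, call. = FALSE)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  survey_dataset(sites = rd(sites_path), benthic = rd(benthic_path),
                 rugosity = rd(rugosity_path), fish = rd(fish_path),
                 urchins = rd(urchins_path))
}

#' Write a survey dataset to CSV files
#'
#' Inverse of [read_survey_dataset()]: writes the five tables under their
#' default names into `dir`. Round-tripping a valid dataset is
#' field-identical.
#'
#' @param x a `survey_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_survey_dataset <- function(x, dir) {
  stopifnot(inherits(x, "survey_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("sites", "benthic", "rugosity", "fish", "urchins")) {
    utils::write.csv(x[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Rugosity index of a transect
#'
#' The ratio of the contour-following tape length to the straight-line
#' horizontal length above it. A perfectly flat substrate gives 1; complex
#' substrate gives values above 1. Measurement noise can push the raw ratio
#' marginally below 1, so ratios in `[1 - clamp_eps, 1)` are clamped to 1;
#' ratios below `1 - clamp_eps` indicate inconsistent line measurements and
#' raise an error.
#'
#' @param contour_length_cm tape length following the substrate contour.
#' @param horizontal_length_cm straight-line length; must be > 0.
#' @param clamp_eps clamping tolerance below 1 (default 0.05).
#' @return Dimensionless rugosity index, vectorised; always >= 1.
#' @export
#' @examples
#' rugosity(1000, 800) # 1.25
rugosity <- function(contour_length_cm, horizontal_length_cm,
                     clamp_eps = 0.05) {
  if (any(!is.finite(horizontal_length_cm)) || any(horizontal_length_cm <= 0)) {
    stop("horizontal_length_cm must be > 0")
  }
  r <- contour_length_cm / horizontal_length_cm
  low <- r < 1 - clamp_eps
  if (any(low)) {
    stop(sprintf("rugosity ratio %.3f below 1 - clamp_eps: contour shorter than horizontal line",
                 min(r)), call. = FALSE)
  }
  pmax(r, 1)
}

transect_key <- function(df) paste(df$site_id, df$transect_id, sep = "\r")

#' Planar percent cover per transect
#'
#' Percent of the contour tape intercepted by benthic records matching a
#' selector, computed per transect: `100 * sum(chord_cm) / contour_length_cm`.
#' Transects with no matching record report 0.
#'
#' @param x a `survey_dataset`.
#' @param taxon_code optional character vector of taxon codes to select.
#' @param category optional character vector of benthic categories
#'   (`"coral"`, `"coralline_algae"`, `"macroborer"`, `"other"`).
#'   With neither selector, all records are counted (total intercepted cover).
#' @return data.frame `site_id, transect_id, cover_pct` with one row per
#'   transect in the roster; `cover_pct` lies in `[0, 100]` (up to the tape
#'   tolerance admitted by validation).
#' @export
planar_cover <- function(x, taxon_code = NULL, category = NULL) {
  stopifnot(inherits(x, "survey_dataset"))
  b <- x$benthic
  keep <- rep(TRUE, nrow(b))
  if (!is.null(taxon_code)) keep <- keep & b$taxon_code %in% taxon_code
  if (!is.null(category)) keep <- keep & b$category %in% category
  b <- b[keep, , drop = FALSE]
  roster <- x$rugosity
  out <- data.frame(site_id = roster$site_id, transect_id = roster$transect_id,
                    cover_pct = 0, stringsAsFactors = FALSE)
  if (nrow(b)) {
    tot <- tapply(b$chord_cm, transect_key(b), sum)
    i <- match(names(tot), transect_key(roster))
    out$cover_pct[i] <- 100 * as.numeric(tot) / roster$contour_length_cm[i]
  }
  out
}

#' Site-level live coral cover
#'
#' Mean over a site's transects of the per-transect planar percent cover of
#' the `coral` category.
#'
#' @param x a `survey_dataset`.
#' @return data.frame `site_id, live_coral_cover_pct` with one row per site.
#' @export
live_coral_cover <- function(x) {
  cov <- planar_cover(x, category = "coral")
  m <- tapply(cov$cover_pct, cov$site_id, mean)
  data.frame(site_id = names(m), live_coral_cover_pct = as.numeric(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a taxon trait table
#'
#' Traits drive the calcification and parrotfish-erosion equations:
#' `m` is the morphological adjustment coefficient converting planar cover
#' to accreting surface, `d` the skeletal density (g cm^-3), `g` the
#' vertical growth rate (cm y^-1), and `brc` the species bite-rate constant
#' (parrotfish rows only; NA otherwise).
#'
#' @param path CSV with columns `taxon_code,m,d,g,brc`.
#' @return data.frame of class `taxon_traits`.
#' @export
read_traits <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(tr, c("taxon_code", "m", "d", "g", "brc"), "traits")
  validate_traits(tr)
}

validate_traits <- function(tr) {
  tr <- as.data.frame(tr)
  if (anyDuplicated(tr$taxon_code)) stop("duplicate taxon_code in traits")
  benthic <- !is.na(tr$m)
  if (any(tr$m[benthic] <= 0)) stop("trait m must be > 0")
  if (any(!is.na(tr$d) & (tr$d <= 0.5 | tr$d >= 3.0))) {
    stop("trait d (skeletal density) must lie in (0.5, 3.0) g cm^-3")
  }
  if (any(!is.na(tr$g) & tr$g < 0)) stop("trait g (vertical growth) must be >= 0")
  class(tr) <- c("taxon_traits", "data.frame")
  tr
}

#' Default taxon trait table
#'
#' Literature-typical morphological coefficients, skeletal densities and
#' growth rates for common western-Pacific benthic taxa, plus bite-rate
#' constants for common parrotfish species. These defaults are synthetic
#' stand-ins assembled from typical published ranges, shipped so the
#' pipeline and the synthetic generator run out of the box; for real
#' analyses supply measured values via [read_traits()].
#'
#' @return data.frame of class `taxon_traits`.
#' @export
default_traits <- function() {
  read_traits(system.file("extdata", "default_traits.csv",
                          package = "reefbudget", mustWork = TRUE))
}
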