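# Small in-code fixtures shared across test files.

# Two-site / two-transect toy survey with simple round numbers.
make_toy_dataset <- function() {
  sites <- data.frame(
    site_id = c("S1", "S2"), island = c("Palau", "Yap"),
    habitat = c("patch", "inner"),
    lat = c(7.5, 9.5), lon = c(134.5, 138.1))
  rugosity <- data.frame(
    site_id = rep(c("S1", "S2"), each = 2),
    transect_id = rep(c("T1", "T2"), 2),
    contour_length_cm = 1000,
    horizontal_length_cm = c(800, 1000, 625, 500))
  benthic <- data.frame(
    site_id = c("S1", "S1", "S1", "S2", "S2"),
    transect_id = c("T1", "T1", "T2", "T1", "T2"),
    taxon_code = c("ACR_BRA", "CCA", "POR_MAS", "POR_MAS", "MACROBORER"),
    category = c("coral", "coralline_algae", "coral", "coral", "macroborer"),
    morphology_code = c("ACR_BRA", "CCA", "POR_MAS", "POR_MAS", "MACROBORER"),
    chord_cm = c(250, 100, 300, 400, 5))
  fish <- data.frame(
    site_id = "S1", transect_id = "T1",
    species_code = "CHL_SOR", length_cm = 20)
  urchins <- data.frame(
    site_id = "S2", transect_id = "T2",
    genus_class = "Echinometra", test_diameter_cm = 3)
  survey_dataset(sites, benthic, rugosity, fish, urchins)
}

# A flat single-taxon trait table for hand-checkable arithmetic.
toy_traits <- function() {
  validate_traits_df <- reefbudget:::validate_traits
  validate_traits_df(data.frame(
    taxon_code = c("A", "B", "FISH1"),
    m = c(1, 2, NA), d = c(1.4, 1.2, NA), g = c(0.8, 0.5, NA),
    brc = c(NA, NA, 2)))
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(abs(expected), 1e-12)),
              label = sprintf("%.12g vs %.12g", actual[1], expected[1]))
}
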