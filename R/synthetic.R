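#' Scenario configuration for the synthetic survey generator
#'
#' Describes the survey design the generator emulates: two islands with
#' habitat-stratified site counts (Palau 8/10/6 outer/patch/inner with the
#' outer stratum split 4 west / 4 east; Yap 10/14 outer/inner, split 6/4,
#' and no patch stratum), six transects per site, per-habitat Beta
#' distributions for coral, coralline-algal and macroborer cover, a
#' parrotfish community with truncated log-normal lengths, an echinoid
#' community with genus mix and size distribution, and a rugosity
#' distribution. All distribution parameters are package choices
#' (qualitatively matched to the study system) and are documented as
#' non-canonical.
#'
#' @param seed mandatory integer seed.
#' @param n_transects transects per site (default 6).
#' @param noise if `FALSE`, every transect realises its site-level values
#'   exactly (no within-site variation) — used for the closed-form oracle.
#' @param islands named list of site counts per habitat for each island.
#' @param coral_cover,cca_cover,macroborer_cover named lists of Beta
#'   shape pairs per habitat (`c(shape1, shape2)`); cover is a proportion.
#' @param fish list with `species` (codes found in the trait table),
#'   `abundance` (mean fish per transect), `meanlog, sdlog` (log-normal
#'   length, cm), `length_range` truncation (default 5-60 cm), and optional
#'   `bumphead` (`prob`, `length_range`) emulating rare large
#'   *Bolbometopon muricatum* schools.
#' @param urchins list with `density` (mean per transect), `genus_probs`
#'   (Diadema/Echinometra/Other mix), `meanlog, sdlog`, `size_range` cm.
#' @param rugosity list with `shape, scale` of the Gamma excess over 1.
#' @param centers island centres, decimal degrees, and `spread` (degrees)
#'   for site placement.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed,
    n_transects = 6,
    noise = TRUE,
    islands = list(
      Palau = c(outer_west = 4, outer_east = 4, patch = 10, inner = 6),
      Yap = c(outer_west = 6, outer_east = 4, inner = 14)),
    coral_cover = list(outer_west = c(8, 12), outer_east = c(4, 16),
                       patch = c(7, 13), inner = c(3, 17)),
    cca_cover = list(outer_west = c(4, 21), outer_east = c(4, 21),
                     patch = c(3, 22), inner = c(2, 23)),
    macroborer_cover = list(outer_west = c(1.2, 199), outer_east = c(1.2, 199),
                            patch = c(1.2, 199), inner = c(1.6, 199)),
    fish = list(species = c("CHL_SOR", "SCA_DIM", "SCA_PSI", "CET_BIC"),
                abundance = 4, meanlog = log(18), sdlog = 0.35,
                length_range = c(5, 60),
                bumphead = list(prob = 0, species = "BOL_MUR",
                                length_range = c(60, 120))),
    urchins = list(density = 3, genus_probs = c(Diadema = 0.25,
                                                Echinometra = 0.55,
                                                Other = 0.20),
                   meanlog = log(4), sdlog = 0.4, size_range = c(1, 15)),
    rugosity = list(shape = 16, scale = 0.025),
    centers = list(Palau = c(lon = 134.5, lat = 7.5),
                   Yap = c(lon = 138.12, lat = 9.53), spread = 0.15)) {
  if (missing(seed) || !is.numeric(seed)) stop("a numeric seed is mandatory")
  for (isl in names(islands)) {
    habs <- names(islands[[isl]])
    if (isl == "Yap" && "patch" %in% habs) {
      stop("invalid config: Yap carries no patch stratum")
    }
    bad <- setdiff(habs, HABITATS)
    if (length(bad)) stop("invalid habitat in config: ", paste(bad, collapse = ", "))
  }
  if (abs(sum(urchins$genus_probs) - 1) > 1e-8) {
    stop("urchin genus_probs must sum to 1")
  }
  structure(as.list(environment()), class = "scenario_config")
}

rtrunc_lnorm <- function(n, meanlog, sdlog, range) {
  p <- stats::plnorm(range, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, p[1], p[2]), meanlog, sdlog)
}

#' Generate a synthetic survey dataset with known ground truth
#'
#' Draws a full survey realisation under a [scenario_config()]: stratified
#' sites with coordinates, six transects per site with line-intercept
#' records (coral taxa, CCA, macroborers), rugosity line pairs, parrotfish
#' and echinoid observations. Alongside the dataset it returns a
#' `ground_truth` table of per-site budget components computed by an
#' independent arithmetic path (the equations written out inline, not by
#' calling the budget engine), so pipeline output can be checked against it.
#'
#' @param config a [scenario_config()].
#' @param traits trait table used both to pick taxa and for the ground-truth
#'   arithmetic (default [default_traits()]).
#' @param constants a [budget_constants()] object.
#' @return list with `dataset` (a validated [survey_dataset()]),
#'   `ground_truth` (data.frame per site: all budget components plus
#'   `live_coral_cover_pct`), and `config`.
#' @export
generate_survey_dataset <- function(config, traits = default_traits(),
                                    constants = budget_constants()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  coral_taxa <- traits$taxon_code[!is.na(traits$m) & !is.na(traits$g) &
                                    traits$taxon_code != "CCA"]
  sites <- benthic <- rug <- fish <- urch <- list()
  idx <- 0
  for (isl in names(config$islands)) {
    ctr <- config$centers[[isl]]
    for (hab in names(config$islands[[isl]])) {
      for (s in seq_len(config$islands[[isl]][[hab]])) {
        idx <- idx + 1
        sid <- sprintf("%s_%s_%02d", substr(isl, 1, 1), hab, s)
        sites[[idx]] <- data.frame(
          site_id = sid, island = isl, habitat = hab,
          lat = ctr[["lat"]] + stats::rnorm(1, 0, config$centers$spread),
          lon = ctr[["lon"]] + stats::rnorm(1, 0, config$centers$spread),
          stringsAsFactors = FALSE)

        # site-level "true" state
        cc <- config$coral_cover[[hab]]
        site_coral <- stats::rbeta(1, cc[1], cc[2])
        taxa <- sample(coral_taxa, min(3, length(coral_taxa)))
        wt <- stats::rgamma(length(taxa), 2); wt <- wt / sum(wt)
        ca <- config$cca_cover[[hab]]
        site_cca <- stats::rbeta(1, ca[1], ca[2])
        mb <- config$macroborer_cover[[hab]]
        site_mb <- stats::rbeta(1, mb[1], mb[2])
        site_rug <- 1 + config$rugosity$shape * config$rugosity$scale

        for (t in seq_len(config$n_transects)) {
          tid <- sprintf("T%d", t)
          if (config$noise) {
            cor_t <- pmin(stats::rbeta(1, cc[1], cc[2]), 0.9)
            cca_t <- stats::rbeta(1, ca[1], ca[2])
            mb_t <- stats::rbeta(1, mb[1], mb[2])
            r_t <- 1 + stats::rgamma(1, config$rugosity$shape,
                                     scale = config$rugosity$scale)
            n_f <- stats::rpois(1, config$fish$abundance)
            n_u <- stats::rpois(1, config$urchins$density)
          } else {
            cor_t <- site_coral; cca_t <- site_cca; mb_t <- site_mb
            r_t <- site_rug
            n_f <- round(config$fish$abundance)
            n_u <- round(config$urchins$density)
          }
          # keep total intercepted cover within the tape
          scale_cov <- min(1, 0.999 / (cor_t + cca_t + mb_t))
          cor_t <- cor_t * scale_cov; cca_t <- cca_t * scale_cov
          mb_t <- mb_t * scale_cov
          tape <- 1000
          chords <- round(wt * cor_t * tape, 6)
          rows <- data.frame(
            site_id = sid, transect_id = tid, taxon_code = taxa,
            category = "coral",
            morphology_code = taxa, chord_cm = chords,
            stringsAsFactors = FALSE)
          rows <- rows[rows$chord_cm > 0, , drop = FALSE]
          extra <- data.frame(
            site_id = sid, transect_id = tid,
            taxon_code = c("CCA", "MACROBORER"),
            category = c("coralline_algae", "macroborer"),
            morphology_code = c("CCA", "MACROBORER"),
            chord_cm = round(c(cca_t, mb_t) * tape, 6),
            stringsAsFactors = FALSE)
          extra <- extra[extra$chord_cm > 0, , drop = FALSE]
          benthic[[length(benthic) + 1]] <- rbind(rows, extra)
          rug[[length(rug) + 1]] <- data.frame(
            site_id = sid, transect_id = tid, contour_length_cm = tape,
            horizontal_length_cm = round(tape / r_t, 6),
            stringsAsFactors = FALSE)
          if (n_f > 0) {
            if (config$noise) {
              sp <- sample(config$fish$species, n_f, replace = TRUE)
              len <- rtrunc_lnorm(n_f, config$fish$meanlog, config$fish$sdlog,
                                  config$fish$length_range)
              bh <- config$fish$bumphead
              if (!is.null(bh) && bh$prob > 0) {
                big <- stats::runif(n_f) < bh$prob
                sp[big] <- bh$species
                len[big] <- stats::runif(sum(big), bh$length_range[1],
                                         bh$length_range[2])
              }
            } else {
              sp <- rep(config$fish$species, length.out = n_f)
              len <- rep(exp(config$fish$meanlog), n_f)
            }
            fish[[length(fish) + 1]] <- data.frame(
              site_id = sid, transect_id = tid, species_code = sp,
              length_cm = round(len, 3), stringsAsFactors = FALSE)
          }
          if (n_u > 0) {
            if (config$noise) {
              gen <- sample(names(config$urchins$genus_probs), n_u,
                            replace = TRUE, prob = config$urchins$genus_probs)
              dia <- rtrunc_lnorm(n_u, config$urchins$meanlog,
                                  config$urchins$sdlog,
                                  config$urchins$size_range)
            } else {
              gen <- rep(names(config$urchins$genus_probs), length.out = n_u)
              dia <- rep(exp(config$urchins$meanlog), n_u)
            }
            urch[[length(urch) + 1]] <- data.frame(
              site_id = sid, transect_id = tid, genus_class = gen,
              test_diameter_cm = round(dia, 3), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  empty_fish <- data.frame(site_id = character(), transect_id = character(),
                           species_code = character(), length_cm = numeric())
  empty_urch <- data.frame(site_id = character(), transect_id = character(),
                           genus_class = character(),
                           test_diameter_cm = numeric())
  ds <- survey_dataset(
    sites = do.call(rbind, sites),
    benthic = do.call(rbind, benthic),
    rugosity = do.call(rbind, rug),
    fish = if (length(fish)) do.call(rbind, fish) else empty_fish,
    urchins = if (length(urch)) do.call(rbind, urch) else empty_urch)
  list(dataset = ds, ground_truth = closed_form_truth(ds, traits, constants),
       config = config)
}

# Independent arithmetic path for the ground-truth budget: the equations
# are written out inline from first principles so a bug in the budget
# engine cannot silently confirm itself.
closed_form_truth <- function(ds, traits, constants) {
  ro <- ds$rugosity
  key <- paste(ro$site_id, ro$transect_id)
  rows <- lapply(seq_len(nrow(ro)), function(i) {
    sid <- ro$site_id[i]
    b <- ds$benthic[paste(ds$benthic$site_id, ds$benthic$transect_id) == key[i], ]
    r <- ro$contour_length_cm[i] / ro$horizontal_length_cm[i]
    if (r < 1) r <- 1
    tape <- ro$contour_length_cm[i]
    cor <- b[b$category == "coral", ]
    gross_sum <- 0
    for (k in seq_len(nrow(cor))) {
      j <- match(cor$taxon_code[k], traits$taxon_code)
      x <- 100 * cor$chord_cm[k] / tape
      gross_sum <- gross_sum +
        traits$m[j] * (x / 100) * traits$d[j] * traits$g[j] * 10
    }
    pca <- 100 * sum(b$chord_cm[b$category == "coralline_algae"]) / tape
    gross <- r * (gross_sum + 0.018 * pca * 10)

    # site-level cover-weighted coral density
    ball <- ds$benthic[ds$benthic$site_id == sid &
                         ds$benthic$category == "coral", ]
    if (nrow(ball)) {
      dj <- traits$d[match(ball$taxon_code, traits$taxon_code)]
      D <- sum(dj * ball$chord_cm) / sum(ball$chord_cm)
    } else D <- constants$default_coral_density

    f <- ds$fish[paste(ds$fish$site_id, ds$fish$transect_id) == key[i], ]
    pf <- 0
    for (k in seq_len(nrow(f))) {
      L <- f$length_cm[k]
      brc <- traits$brc[match(f$species_code[k], traits$taxon_code)]
      vol <- exp(1.32 + 0.06 * L) / 1000
      sp <- 1 / (1 + exp(-(-2.46 + 0.089 * L)))
      br <- max(0, 60 * ((4.31 + brc - 0.36) - 0.045 * 9 * L))
      pf <- pf + vol * sp * br
    }
    pf <- pf * D * 365 * 0.001 / 120

    u <- ds$urchins[paste(ds$urchins$site_id, ds$urchins$transect_id) == key[i], ]
    ue <- 0
    for (k in seq_len(nrow(u))) {
      dd <- u$test_diameter_cm[k]
      ue <- ue + switch(u$genus_class[k],
        Diadema = 1e-6 * dd^3.42,
        Echinometra = 4e-4 * dd^1.98,
        Other = 1e-4 * dd^2.32) * 0.365 * 0.57
    }
    ue <- ue / 6

    plamc <- sum(b$chord_cm[b$category == "macroborer"]) / tape
    macro <- plamc * 10
    lcc <- 100 * sum(cor$chord_cm) / tape
    data.frame(site_id = sid, gross = gross, parrotfish = pf, urchin = ue,
               macroboring = macro, lcc = lcc, stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  agg <- stats::aggregate(tb[c("gross", "parrotfish", "urchin", "macroboring",
                               "lcc")],
                          by = list(site_id = tb$site_id), mean)
  sed <- constants$sediment_sign * constants$sediment
  data.frame(
    site_id = agg$site_id,
    gross_calcification = agg$gross,
    parrotfish_erosion = agg$parrotfish,
    urchin_erosion = agg$urchin,
    macroboring_erosion = agg$macroboring,
    sediment = sed,
    net_production = agg$gross + sed -
      (agg$parrotfish + agg$urchin + agg$macroboring),
    live_coral_cover_pct = agg$lcc,
    stringsAsFactors = FALSE)
}

#' Generate a transect table with known production-vs-cover thresholds
#'
#' Supports testing of the threshold model: live coral cover is drawn
#' uniformly on (0, 60)%, and net production for habitat h follows
#' `G = s_h (LCC - LCC*_h) + p(LCC) - p(LCC*_h) + e`, with the shared
#' smooth perturbation `p(LCC) = wiggle * sin(2 pi LCC / 60)` and
#' `e ~ Normal(0, sigma)`. Subtracting `p(LCC*_h)` re-anchors each
#' habitat's curve so its deterministic part vanishes exactly at `LCC*_h`,
#' and the curve stays strictly increasing because the slope dominates the
#' perturbation derivative — so the true zero crossing of habitat h is
#' `LCC*_h` by construction, while the mean structure (shared smooth curve
#' plus habitat offsets) stays inside the additive-model family.
#' Habitats prefixed `P-`/`Y-` are assigned to Palau/Yap.
#'
#' @param true_thresholds named numeric vector of per-habitat thresholds in
#'   (0, 100)%.
#' @param n_transects total rows (split evenly over habitats); 0 gives an
#'   empty table.
#' @param sigma residual standard deviation, > 0.
#' @param seed integer seed.
#' @param slope positive production slope per habitat (recycled).
#' @param wiggle amplitude of the smooth perturbation (must stay below
#'   `slope * 30 / pi` to keep the curve monotone).
#' @return data.frame `live_coral_cover, net_production, habitat, country,
#'   true_threshold`.
#' @export
generate_threshold_dataset <- function(
    true_thresholds = c("P-inner" = 21, "P-outer" = 10.2, "P-patch" = 11.8,
                        "Y-inner" = 9.5, "Y-outer" = 11.5),
    n_transects = 288, sigma = 1, seed = 1, slope = 0.25, wiggle = 0.3) {
  stopifnot(all(true_thresholds > 0 & true_thresholds < 100), sigma > 0)
  if (wiggle * 2 * pi / 60 >= slope) {
    stop("wiggle too large: the mean curve must stay monotone increasing")
  }
  if (n_transects == 0) {
    return(data.frame(live_coral_cover = numeric(), net_production = numeric(),
                      habitat = character(), country = character(),
                      true_threshold = numeric()))
  }
  set.seed(seed)
  habs <- rep(names(true_thresholds), length.out = n_transects)
  thr <- true_thresholds[habs]
  lcc <- stats::runif(n_transects, 0, 60)
  p <- function(v) wiggle * sin(2 * pi * v / 60)
  g <- slope * (lcc - thr) + p(lcc) - p(thr) +
    stats::rnorm(n_transects, 0, sigma)
  data.frame(
    live_coral_cover = lcc, net_production = as.numeric(g), habitat = habs,
    country = ifelse(startsWith(habs, "Y"), "Yap", "Palau"),
    true_threshold = as.numeric(thr), stringsAsFactors = FALSE,
    row.names = NULL)
}

#' Simulate a Gaussian random field at given locations
#'
#' Draws one realisation of a zero-mean (plus optional trend) Gaussian
#' random field whose covariance derives from a semivariogram model:
#' `C(h) = (nugget + partial_sill) - gamma(h)`. The covariance matrix is
#' factorised by Cholesky (with a tiny jitter retry); as the range shrinks
#' the field tends to iid noise with variance equal to the total sill.
#'
#' @param x,y coordinates, meters.
#' @param model a [variogram_model()].
#' @param mean scalar or per-point mean surface (default 0).
#' @param seed integer seed.
#' @return A [spatial_sample()] carrying the simulated values.
#' @export
generate_spatial_field <- function(x, y, model, mean = 0, seed = 1) {
  stopifnot(inherits(model, "variogram_model"), length(x) == length(y))
  set.seed(seed)
  n <- length(x)
  D <- aniso_dist(x, y, x, y, model)
  sill <- model$nugget + model$partial_sill
  C <- sill - semivariance(model, D)
  diag(C) <- sill
  L <- tryCatch(chol(C), error = function(e) {
    tryCatch(chol(C + diag(1e-8 * sill, n)), error = function(e2) {
      stop("covariance matrix is not positive definite", call. = FALSE)
    })
  })
  z <- mean + as.numeric(t(L) %*% stats::rnorm(n))
  spatial_sample(x, y, z)
}
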