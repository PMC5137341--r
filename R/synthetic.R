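#' Synthetic forest scenario
#'
#' Bundles every knob of the synthetic stand generator. The packaged
#' scenarios are:
#'
#' * `"alpine_default"`: a conifer-dominated mountain stand whose tree sizes
#'   respect realistic Alpine ranges (DBH 3.5-121 cm, heights 1.5-48.8 m,
#'   crown areas 1.5-55.4 m2), 48 pulses/m2, five species with separable
#'   spectral signatures, and understorey ("hidden") trees holding about 19%
#'   of stand carbon beneath dominant crowns.
#' * `"separable_stand"`: widely spaced trees with non-overlapping crowns and
#'   no understorey, so every crown is delineable — the end-to-end ground
#'   truth case.
#' * `"null_spectra"`: spectrally identical species (JM near 0), the
#'   chance-level classification control.
#'
#' @param name one of the packaged scenario names.
#' @param ... named overrides of any scenario field.
#' @return an object of class `forest_scenario` (a named list).
#' @export
forest_scenario <- function(name = c("alpine_default", "separable_stand",
                                     "null_spectra"), ...) {
  name <- match.arg(name)
  sc <- list(
    name = name,
    extent_m = 100,                 # square stand side
    stem_density_ha = 350,          # overstorey stems per ha
    species_props = c(Picea_abies = 0.50, Larix_decidua = 0.22,
                      Abies_alba = 0.10, Pinus_cembra = 0.08,
                      Angiosperm = 0.10),
    dbh_meanlog = log(35), dbh_sdlog = 0.45,
    dbh_range = c(3.5, 121), height_range = c(1.5, 48.8),
    ca_range = c(1.5, 55.4),
    ca_slope = 0.625,               # m2 crown area per cm DBH, before scatter
    ca_sdlog = 0.25,
    h_sdlog = 0.06,                 # lognormal scatter around inverted allometry
    min_spacing_factor = 0.5,       # hard-core distance as fraction of r_i + r_j
    understorey_carbon_fraction = 0.19,
    understorey_rel_height = c(0.20, 0.45),  # height relative to host tree
    crown_depth_frac = 0.6,         # paraboloid depth as fraction of apex
    pulse_density = 48,             # pulses per m2
    vertical_noise_sd = 0.2,        # m, on first-return heights
    n_bands = 16,
    band_range = c(400, 990),       # nm
    target_jm = 1.9,                # pairwise class separability
    spectral_sigma = 0.01,          # within-class band sd (reflectance)
    base_reflectance = 0.2,
    shade_factor = 0.6,             # brightness of shaded crown-edge pixels
    shade_radius_frac = 0.75,       # crown-edge shading starts here
    dbh_error = 0.015, height_error = 0.05,  # field measurement noise
    dbh_coefficients = read_dbh_coefficients(),
    agb_coefficients = read_agb_coefficients(),
    seed = 42)
  if (name == "separable_stand") {
    sc$stem_density_ha <- 60
    sc$min_spacing_factor <- 1.2
    sc$understorey_carbon_fraction <- 0
    sc$dbh_meanlog <- log(40)
    sc$dbh_sdlog <- 0.25
  }
  if (name == "null_spectra") sc$target_jm <- 0.001
  dots <- list(...)
  bad <- setdiff(names(dots), names(sc))
  if (length(bad)) stop("unknown scenario field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  sc[names(dots)] <- dots
  stopifnot(abs(sum(sc$species_props) - 1) < 1e-8, sc$pulse_density > 0)
  structure(sc, class = "forest_scenario")
}

#' @export
print.forest_scenario <- function(x, ...) {
  cat(sprintf("forest_scenario '%s': %g x %g m, %g stems/ha, %d species\n",
              x$name, x$extent_m, x$extent_m, x$stem_density_ha,
              length(x$species_props)))
  invisible(x)
}

species_group <- function(species) {
  ifelse(grepl("^Angiosperm", species), "angiosperm", "conifer")
}

# Ground-truth sizes for one tree: DBH from a truncated lognormal, crown
# area roughly proportional to DBH, and H by inverting the DBH allometry
# with lognormal scatter; rejection keeps everything in the scenario ranges.
draw_tree_sizes <- function(n, sc, species) {
  co <- sc$dbh_coefficients
  out <- data.frame(dbh_cm = numeric(n), crown_area_m2 = numeric(n),
                    height_m = numeric(n))
  i <- coeff_row(co, species, "DBH")
  eps <- co$epsilon[i]; rho <- co$rho[i]; th <- co$theta[i]
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) && (tries <- tries + 1L) <= 50L) {
    m <- length(todo)
    dbh <- stats::rlnorm(m, sc$dbh_meanlog, sc$dbh_sdlog)
    ca <- pmin(pmax(sc$ca_slope * dbh * stats::rlnorm(m, 0, sc$ca_sdlog),
                    sc$ca_range[1]), sc$ca_range[2])
    h <- (dbh / (eps[todo] * (1 + th[todo] * ca)))^(1 / rho[todo]) *
      stats::rlnorm(m, 0, sc$h_sdlog)
    ok <- dbh >= sc$dbh_range[1] & dbh <= sc$dbh_range[2] &
      h >= sc$height_range[1] & h <= sc$height_range[2]
    out$dbh_cm[todo[ok]] <- dbh[ok]
    out$crown_area_m2[todo[ok]] <- ca[ok]
    out$height_m[todo[ok]] <- h[ok]
    todo <- todo[!ok]
  }
  if (length(todo))
    stop("could not draw tree sizes inside the scenario ranges", call. = FALSE)
  out
}

#' Simulate a synthetic forest
#'
#' Places overstorey trees by a Poisson process with hard-core inhibition
#' (minimum stem spacing proportional to the crown radii involved), draws
#' per-tree DBH, crown area and height from the scenario's ground-truth
#' allometry, and computes true biomass and carbon from the scenario's AGB
#' coefficients. Understorey trees are then tucked beneath randomly chosen
#' dominant crowns until they hold the scenario's share of stand carbon;
#' they are flagged `overstorey = FALSE` and are invisible to crown
#' delineation by construction.
#'
#' @param scenario a [forest_scenario()].
#' @param seed overrides the scenario seed.
#' @return a data frame of class `synthetic_forest`: one row per tree with
#'   `id`, `x`, `y`, `species`, `group`, `dbh_cm`, `height_m`,
#'   `crown_area_m2`, `crown_radius_m`, `agb_kg`, `carbon_kg`,
#'   `overstorey`; the scenario rides along as attribute `scenario`.
#' @export
simulate_forest <- function(scenario = forest_scenario(), seed = scenario$seed) {
  sc <- scenario
  set.seed(seed)
  ext <- sc$extent_m
  n <- stats::rpois(1, sc$stem_density_ha * ext^2 / 1e4)
  if (n == 0L) {
    f <- data.frame(id = integer(), x = numeric(), y = numeric(),
                    species = character(), group = character(),
                    dbh_cm = numeric(), height_m = numeric(),
                    crown_area_m2 = numeric(), crown_radius_m = numeric(),
                    agb_kg = numeric(), carbon_kg = numeric(),
                    overstorey = logical())
    class(f) <- c("synthetic_forest", "data.frame")
    attr(f, "scenario") <- sc
    return(f)
  }
  species <- sample(names(sc$species_props), n, replace = TRUE,
                    prob = sc$species_props)
  sz <- draw_tree_sizes(n, sc, species)
  r <- sqrt(sz$crown_area_m2 / pi)
  # hard-core placement, largest crowns first
  ord <- order(-r)
  x <- y <- numeric(n)
  placed_x <- placed_y <- placed_r <- numeric(0)
  for (k in ord) {
    ok <- FALSE
    for (try in 1:200) {
      px <- stats::runif(1, 0, ext); py <- stats::runif(1, 0, ext)
      if (!length(placed_x) ||
          all((placed_x - px)^2 + (placed_y - py)^2 >=
              (sc$min_spacing_factor * (placed_r + r[k]))^2)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("infeasible stem density for the requested crown spacing",
           call. = FALSE)
    x[k] <- px; y[k] <- py
    placed_x <- c(placed_x, px); placed_y <- c(placed_y, py)
    placed_r <- c(placed_r, r[k])
  }
  f <- data.frame(id = seq_len(n), x = x, y = y, species = species,
                  group = species_group(species),
                  dbh_cm = sz$dbh_cm, height_m = sz$height_m,
                  crown_area_m2 = sz$crown_area_m2, crown_radius_m = r,
                  overstorey = TRUE)
  f$agb_kg <- agb_tree(f$dbh_cm, f$height_m, sc$agb_coefficients, f$species)
  f$carbon_kg <- carbon_tree(f$agb_kg, f$group)
  # understorey trees beneath dominant crowns
  ufrac <- sc$understorey_carbon_fraction
  if (ufrac > 0 && n > 0L) {
    target <- ufrac / (1 - ufrac) * sum(f$carbon_kg)
    hosts <- which(f$height_m > 8)
    if (!length(hosts)) hosts <- seq_len(n)
    u <- list(); ucarb <- 0
    while (ucarb < target && length(u) < 60L * n) {
      host <- f[sample(hosts, 1L), ]
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.6 * host$crown_radius_m)
      h <- stats::runif(1, sc$understorey_rel_height[1],
                        sc$understorey_rel_height[2]) * host$height_m
      h <- max(h, sc$height_range[1])
      sp <- sample(names(sc$species_props), 1L, prob = sc$species_props)
      ca <- min(max(0.35 * h, sc$ca_range[1]), 12)
      i <- coeff_row(sc$dbh_coefficients, sp, "DBH")
      dbh <- sc$dbh_coefficients$epsilon[i] * h^sc$dbh_coefficients$rho[i] *
        (1 + sc$dbh_coefficients$theta[i] * ca)
      dbh <- max(dbh, sc$dbh_range[1])
      agb <- agb_tree(dbh, h, sc$agb_coefficients, sp)
      carb <- carbon_tree(agb, species_group(sp))
      u[[length(u) + 1L]] <- data.frame(
        x = min(max(host$x + rad * cos(ang), 0), ext),
        y = min(max(host$y + rad * sin(ang), 0), ext),
        species = sp, group = species_group(sp), dbh_cm = dbh, height_m = h,
        crown_area_m2 = ca, crown_radius_m = sqrt(ca / pi),
        overstorey = FALSE, agb_kg = agb, carbon_kg = carb)
      ucarb <- ucarb + carb
    }
    if (length(u)) {
      u <- do.call(rbind, u)
      u$id <- n + seq_len(nrow(u))
      f <- rbind(f, u[names(f)])
    }
  }
  class(f) <- c("synthetic_forest", "data.frame")
  attr(f, "scenario") <- sc
  f
}

#' @export
print.synthetic_forest <- function(x, ...) {
  cat(sprintf("synthetic_forest: %d trees (%d overstorey), %.1f kg C total\n",
              nrow(x), sum(x$overstorey), sum(x$carbon_kg)))
  invisible(x)
}

#' Simulate (H, CA, DBH) calibration triples
#'
#' Draws crown heights and areas from broad lognormals and diameters from
#' the stated allometry under multiplicative lognormal noise — the
#' parameter-recovery testbed for [fit_dbh_model()]. With symmetric noise on
#' the log scale the median of DBH given (H, CA) is exactly the allometry,
#' so the tau = 0.5 fit is consistent for the generating coefficients.
#'
#' @param n number of triples.
#' @param epsilon,rho,theta generating coefficients.
#' @param noise_sd sd of the multiplicative lognormal noise (0.15 = 15%).
#' @param seed random seed.
#' @return data frame with `h`, `ca`, `dbh`.
#' @export
simulate_dbh_triples <- function(n, epsilon, rho, theta, noise_sd = 0.15,
                                 seed = 1) {
  set.seed(seed)
  h <- pmin(pmax(stats::rlnorm(n, log(20), 0.45), 2), 48)
  ca <- pmin(pmax(stats::rlnorm(n, log(18), 0.55), 1.5), 55)
  dbh <- epsilon * h^rho * (1 + theta * ca) * stats::rlnorm(n, 0, noise_sd)
  data.frame(h = h, ca = ca, dbh = dbh)
}

#' Simulate an airborne laser-scanning point cloud
#'
#' Pulses fall on a jittered grid at the scenario's pulse density. Where a
#' pulse hits a crown, the first return samples the paraboloid crown surface
#' of the tallest intercepting tree plus Gaussian vertical noise; some
#' canopy pulses penetrate, yielding up to 4 returns with decreasing height
#' and occasionally a final ground return. Pulses missing all crowns return
#' from the ground. Understorey trees do not form surface (they sit beneath
#' dominant crowns).
#'
#' @param forest a [simulate_forest()] result.
#' @param scenario defaults to the forest's scenario.
#' @param seed overrides the scenario seed (offset internally so the cloud
#'   differs from the stem draw).
#' @return a [point_cloud()].
#' @export
simulate_point_cloud <- function(forest,
                                 scenario = attr(forest, "scenario"),
                                 seed = scenario$seed) {
  sc <- scenario
  set.seed(seed + 1L)
  ext <- sc$extent_m
  spacing <- 1 / sqrt(sc$pulse_density)
  g <- expand.grid(x = seq(spacing / 2, ext, by = spacing),
                   y = seq(spacing / 2, ext, by = spacing))
  np <- nrow(g)
  g$x <- pmin(pmax(g$x + stats::runif(np, -0.5, 0.5) * spacing, 0), ext)
  g$y <- pmin(pmax(g$y + stats::runif(np, -0.5, 0.5) * spacing, 0), ext)
  surf <- numeric(np)
  over <- forest[forest$overstorey, , drop = FALSE]
  for (i in seq_len(nrow(over))) {
    R <- over$crown_radius_m[i]; apex <- over$height_m[i]
    base <- apex * (1 - sc$crown_depth_frac)
    near <- which(abs(g$x - over$x[i]) <= R & abs(g$y - over$y[i]) <= R)
    if (!length(near)) next
    d2 <- (g$x[near] - over$x[i])^2 + (g$y[near] - over$y[i])^2
    hit <- d2 <= R^2
    z <- apex - (apex - base) * d2[hit] / R^2
    surf[near[hit]] <- pmax(surf[near[hit]], z)
  }
  canopy <- surf > 0.5
  zs <- numeric(0); xs <- numeric(0); ys <- numeric(0)
  rn <- integer(0); nrt <- integer(0); grd <- logical(0)
  # canopy pulses: first return at the crown surface, some penetrate
  if (any(canopy)) {
    idx <- which(canopy)
    z1 <- pmax(surf[idx] + stats::rnorm(length(idx), 0, sc$vertical_noise_sd),
               -0.4)
    pen <- stats::runif(length(idx)) < 0.35
    pg <- stats::runif(length(idx)) < 0.20
    nret <- 1L + pen + (pen & pg)
    xs <- c(xs, g$x[idx]); ys <- c(ys, g$y[idx]); zs <- c(zs, z1)
    rn <- c(rn, rep(1L, length(idx))); nrt <- c(nrt, nret)
    grd <- c(grd, rep(FALSE, length(idx)))
    if (any(pen)) {
      i2 <- idx[pen]
      z2 <- pmax(surf[i2] * stats::runif(length(i2), 0.25, 0.7), 0)
      xs <- c(xs, g$x[i2]); ys <- c(ys, g$y[i2]); zs <- c(zs, z2)
      rn <- c(rn, rep(2L, length(i2))); nrt <- c(nrt, nret[pen])
      grd <- c(grd, rep(FALSE, length(i2)))
      deep <- pen & pg
      if (any(deep)) {
        i3 <- idx[deep]
        z3 <- pmax(stats::rnorm(length(i3), 0, 0.05), -0.4)
        xs <- c(xs, g$x[i3]); ys <- c(ys, g$y[i3]); zs <- c(zs, z3)
        rn <- c(rn, rep(3L, length(i3))); nrt <- c(nrt, nret[deep])
        grd <- c(grd, rep(TRUE, length(i3)))
      }
    }
  }
  if (any(!canopy)) {
    idx <- which(!canopy)
    zg <- pmax(stats::rnorm(length(idx), 0, 0.05), -0.4)
    xs <- c(xs, g$x[idx]); ys <- c(ys, g$y[idx]); zs <- c(zs, zg)
    rn <- c(rn, rep(1L, length(idx))); nrt <- c(nrt, rep(1L, length(idx)))
    grd <- c(grd, rep(TRUE, length(idx)))
  }
  point_cloud(xs, ys, zs, rn, nrt, grd)
}

# Orthonormal cosine-contrast directions in band space (deterministic).
dct_directions <- function(k, n_bands) {
  stopifnot(k < n_bands)
  j <- seq_len(n_bands) - 0.5
  e <- t(vapply(seq_len(k), function(s) {
    v <- cos(pi * s * j / n_bands)
    v / sqrt(sum(v^2))
  }, numeric(n_bands)))
  e
}

#' Class mean spectra for a scenario
#'
#' Species means sit at equal pairwise distance in band space, the distance
#' chosen so two Gaussian classes with the scenario's within-class sd reach
#' the target Jeffries-Matusita separability.
#'
#' @param scenario a [forest_scenario()].
#' @return matrix (species x bands) of mean reflectances.
#' @export
scenario_spectra <- function(scenario) {
  sc <- scenario
  k <- length(sc$species_props)
  jm <- min(sc$target_jm, 1.999)
  bh <- -log(1 - jm / 2)
  d <- sc$spectral_sigma * sqrt(8 * bh)      # needed mean separation
  base <- sc$base_reflectance *
    (1 + 0.25 * sin(seq(0, 2 * pi, length.out = sc$n_bands)))
  e <- dct_directions(k, sc$n_bands)
  mu <- matrix(rep(base, each = k), k, sc$n_bands)
  mu <- mu + (d / sqrt(2)) * e
  rownames(mu) <- names(sc$species_props)
  pmax(mu, 0)
}

#' Simulate a hyperspectral cube over the synthetic stand
#'
#' One pixel per metre. Each pixel takes the spectrum of the tallest crown
#' covering its centre (Gaussian around the species' mean spectrum); pixels
#' near the crown edge are darkened by the shading factor to exercise the
#' sunlit-pixel extraction; crown-free pixels get a flat soil spectrum.
#'
#' @param forest a [simulate_forest()] result.
#' @param scenario defaults to the forest's scenario.
#' @param seed overrides the scenario seed (offset internally).
#' @return list with `cube` (a [hyper_cube()]) and `pixels`, a truth table
#'   (`row`, `col`, `tree_id`, `species`, `shaded`).
#' @export
simulate_hypercube <- function(forest,
                               scenario = attr(forest, "scenario"),
                               seed = scenario$seed) {
  sc <- scenario
  set.seed(seed + 2L)
  ext <- as.integer(round(sc$extent_m))
  nb <- sc$n_bands
  mu <- scenario_spectra(sc)
  over <- forest[forest$overstorey, , drop = FALSE]
  grid <- raster_grid(matrix(0, ext, ext), origin_x = 0, origin_y = ext,
                      resolution = 1)
  owner <- matrix(0L, ext, ext)
  shaded <- matrix(FALSE, ext, ext)
  height <- matrix(-Inf, ext, ext)
  cc <- pixel_to_world(grid, row = matrix(seq_len(ext), ext, ext),
                       col = matrix(seq_len(ext), ext, ext, byrow = TRUE))
  for (i in seq_len(nrow(over))) {
    R <- over$crown_radius_m[i]
    d2 <- (cc$x - over$x[i])^2 + (cc$y - over$y[i])^2
    hit <- d2 <= R^2 & over$height_m[i] > height
    owner[hit] <- i
    height[hit] <- over$height_m[i]
    shaded[hit] <- d2[hit] > (sc$shade_radius_frac * R)^2
  }
  vals <- array(0, dim = c(ext, ext, nb))
  flat <- matrix(0, ext * ext, nb)
  soil <- rep(0.5 * sc$base_reflectance, nb)
  noise <- matrix(stats::rnorm(ext * ext * nb, 0, sc$spectral_sigma),
                  ext * ext, nb)
  ow <- as.vector(owner)
  sh <- as.vector(shaded)
  bgi <- ow == 0L
  flat[bgi, ] <- rep(soil, each = sum(bgi))
  if (any(!bgi)) {
    sp <- over$species[ow[!bgi]]
    flat[!bgi, ] <- mu[sp, , drop = FALSE]
  }
  flat <- flat + noise
  flat[sh, ] <- flat[sh, ] * sc$shade_factor
  flat <- pmax(flat, 0)
  vals <- array(flat, dim = c(ext, ext, nb))
  cube <- hyper_cube(vals, origin_x = 0, origin_y = ext, resolution = 1,
                     wavelengths = seq(sc$band_range[1], sc$band_range[2],
                                       length.out = nb))
  pix <- which(ow > 0L)
  pixels <- data.frame(
    row = ((pix - 1L) %% ext) + 1L,
    col = ((pix - 1L) %/% ext) + 1L,
    tree_id = over$id[ow[pix]],
    species = over$species[ow[pix]],
    shaded = sh[pix])
  list(cube = cube, pixels = pixels)
}

#' Simulate a field inventory over the synthetic stand
#'
#' Fixed-radius plots include every tree whose stem falls inside the circle;
#' angle-count (Bitterlich) plots include a tree when
#' `dbh_cm >= 100 * sqrt(BAF) * distance / 50`. Measured DBH and height are
#' perturbed by the scenario's relative measurement errors.
#'
#' @param forest a [simulate_forest()] result.
#' @param plots data frame with `id`, `x`, `y` and either `radius_m` or
#'   `baf` (exactly one non-NA per plot).
#' @param scenario defaults to the forest's scenario.
#' @param seed overrides the scenario seed (offset internally).
#' @return data frame of measured trees with `plot_id` prepended.
#' @export
simulate_inventory <- function(forest, plots,
                               scenario = attr(forest, "scenario"),
                               seed = scenario$seed) {
  sc <- scenario
  set.seed(seed + 3L)
  out <- list()
  for (k in seq_len(nrow(plots))) {
    p <- plots[k, ]
    d <- sqrt((forest$x - p$x)^2 + (forest$y - p$y)^2)
    r_ok <- "radius_m" %in% names(p) && !is.na(p$radius_m)
    b_ok <- "baf" %in% names(p) && !is.na(p$baf)
    if (r_ok == b_ok)
      stop("plot ", p$id, ": exactly one of radius_m / baf must be set",
           call. = FALSE)
    inc <- if (r_ok) d <= p$radius_m
           else forest$dbh_cm >= 100 * sqrt(p$baf) * d / 50
    if (!any(inc)) next
    t <- forest[inc, , drop = FALSE]
    t$dbh_cm <- t$dbh_cm * (1 + stats::rnorm(nrow(t), 0, sc$dbh_error))
    t$height_m <- t$height_m * (1 + stats::rnorm(nrow(t), 0, sc$height_error))
    t$plot_id <- p$id
    out[[length(out) + 1L]] <- t
  }
  if (!length(out)) {
    t <- forest[0, , drop = FALSE]
    t$plot_id <- integer(0)
    return(as.data.frame(t))
  }
  as.data.frame(do.call(rbind, out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
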