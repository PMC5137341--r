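#' Run the tree-centric carbon pipeline end to end
#'
#' Orchestrates simulate (or load) -> CHM -> delineate -> classify ->
#' allometry -> carbon map on a synthetic scenario, writing every product
#' plus a JSON run manifest (parameters, seed, per-stage counts, file
#' checksums) that makes the run reproducible.
#'
#' @param config named list:
#'   \describe{
#'     \item{scenario}{a [forest_scenario()] or a packaged scenario name.}
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{chm}{arguments for [chm_params()].}
#'     \item{delineation}{arguments for [delineation_params()].}
#'     \item{n_features}{hyperspectral features kept by SFFS (default 8).}
#'     \item{cv}{tune the SVM by cross-validation (default FALSE: packaged
#'       defaults).}
#'     \item{cell_size}{carbon-map cell side in m (default 100).}
#'     \item{multiplier}{hidden-tree correction: `"fit"` (default, from
#'       simulated plots) or a fixed number.}
#'     \item{dbh_coefficients, agb_coefficients}{coefficient tables (or CSV
#'       paths) for the allometry stage; default to the scenario's tables.}
#'     \item{seed}{overrides the scenario seed.}
#'   }
#' @return the manifest (invisibly a list), with the itc_set in attribute
#'   `itcs`.
#' @export
run_pipeline <- function(config = list()) {
  sc <- config$scenario %||% forest_scenario()
  if (is.character(sc)) sc <- forest_scenario(sc)
  if (!is.null(config$seed)) sc$seed <- config$seed
  out_dir <- config$out_dir %||% tempfile("canopycarbon_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cp <- do.call(chm_params, config$chm %||% list())
  dp <- do.call(delineation_params, config$delineation %||% list())
  stage <- "simulate"
  manifest <- list(package_version = as.character(utils::packageVersion("canopycarbon")),
                   scenario = sc$name, seed = sc$seed,
                   chm_params = unclass(cp), delineation_params = unclass(dp))
  tryCatch({
    forest <- simulate_forest(sc)
    cloud <- simulate_point_cloud(forest, sc)
    hsi <- simulate_hypercube(forest, sc)
    manifest$n_trees <- nrow(forest)
    manifest$n_overstorey <- sum(forest$overstorey)
    manifest$n_returns <- nrow(cloud)

    stage <- "chm"
    chm <- smooth_chm(rasterize_chm(cloud, cp), cp)
    write_raster(chm, file.path(out_dir, "chm.asc"))

    stage <- "delineate"
    seeds <- find_local_maxima(chm, dp)
    labels <- grow_crowns(chm, seeds, dp)
    itcs <- hull_crowns(extract_crown_returns(labels, cloud, dp), seeds)
    write_raster(labels, file.path(out_dir, "crown_labels.asc"))
    manifest$n_itcs <- length(itcs)

    stage <- "classify"
    if (length(itcs) > 0 && nrow(hsi$pixels) > 0) {
      sun <- extract_sunlit_pixels(hsi$cube, itcs)
      key <- paste(hsi$pixels$row, hsi$pixels$col)
      lab <- hsi$pixels$species[match(paste(sun$row, sun$col), key)]
      train <- !is.na(lab)
      feat_cols <- grep("^b[0-9]+$", names(sun), value = TRUE)
      n_feat <- min(config$n_features %||% 8, length(feat_cols))
      if (length(unique(lab[train])) >= 2) {
        selected <- sffs_select(as.matrix(sun[train, feat_cols]), lab[train],
                                n_feat)
        h99 <- itcs$table$height_m[match(sun$itc_id, itcs$table$id)]
        x_all <- cbind(as.matrix(sun[, feat_cols[selected]]), als_h99 = h99)
        clf <- train_classifier(x_all[train, , drop = FALSE], lab[train],
                                cv = isTRUE(config$cv), seed = sc$seed)
        itcs$table$species <- unname(classify_itcs(clf, x_all, sun$itc_id,
                                                   itc_ids = itcs$table$id))
      }
    }
    manifest$n_classified <- sum(!is.na(itcs$table$species) &
                                   itcs$table$species != "unknown")

    stage <- "allometry"
    load_tab <- function(x, reader, what) {
      if (is.null(x)) stop("missing ", what, " coefficient table; supply one ",
                           "in the config or scenario", call. = FALSE)
      if (is.character(x)) {
        if (!file.exists(x)) stop(what, " coefficient table not found: ", x,
                                  call. = FALSE)
        return(reader(x))
      }
      x
    }
    dbh_co <- load_tab(config$dbh_coefficients %||% sc$dbh_coefficients,
                       read_dbh_coefficients, "DBH")
    agb_co <- load_tab(config$agb_coefficients %||% sc$agb_coefficients,
                       read_agb_coefficients, "AGB")
    if (length(itcs) > 0) {
      tab <- itcs$table
      spp <- ifelse(is.na(tab$species) | tab$species == "unknown",
                    "All", tab$species)
      tab$dbh_cm <- predict_dbh(tab$height_m, tab$crown_area_m2, dbh_co, spp)
      tab$agb_kg <- agb_tree(tab$dbh_cm, tab$height_m, agb_co, spp)
      tab$carbon_kg <- carbon_tree(tab$agb_kg, species_group(spp))
      itcs$table <- tab
    }
    write_itc_polygons(itcs, file.path(out_dir, "itcs.geojson"))
    manifest$total_carbon_kg <- sum(itcs$table$carbon_kg, na.rm = TRUE)

    stage <- "map"
    mult <- config$multiplier %||% "fit"
    if (identical(mult, "fit")) {
      ext <- sc$extent_m
      ctr <- expand.grid(x = seq(16, ext - 16, length.out = 4),
                         y = seq(16, ext - 16, length.out = 4))
      field <- vapply(seq_len(nrow(ctr)), function(k)
        plot_carbon_density(forest$x, forest$y, forest$carbon_kg,
                            ctr$x[k], ctr$y[k], 15), numeric(1))
      ars <- vapply(seq_len(nrow(ctr)), function(k)
        plot_carbon_density(itcs$table$x, itcs$table$y, itcs$table$carbon_kg,
                            ctr$x[k], ctr$y[k], 15), numeric(1))
      mult <- if (all(ars == 0)) 1 else
        fit_hidden_tree_correction(ars, field)$multiplier
    }
    manifest$multiplier <- mult
    cmap <- rasterize_carbon(itcs, config$cell_size %||% 100,
                             extent = c(0, 0, sc$extent_m, sc$extent_m),
                             multiplier = mult)
    write_raster(cmap, file.path(out_dir, "carbon.asc"))

    files <- c("chm.asc", "crown_labels.asc", "itcs.geojson", "carbon.asc")
    manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(sprintf("pipeline complete: %d ITCs, %.1f kg C, outputs in %s",
                    manifest$n_itcs, manifest$total_carbon_kg, out_dir))
    out <- manifest
    attr(out, "itcs") <- itcs
    attr(out, "forest") <- forest
    invisible(out)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
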