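#' Match delineated crowns to field-measured trees
#'
#' A field tree is inside an ITC when its stem position lies in the crown
#' polygon (boundary counts as inside). An ITC containing exactly one tree is
#' paired with it; with several candidates the tree whose field height is
#' closest to the ITC height wins (ties: larger DBH, then smaller tree id).
#' ITCs are processed in increasing id order and a tree is paired at most
#' once, so overlapping crowns cannot claim the same stem twice.
#'
#' @param itcs an [itc_set()] with `height_m` filled in.
#' @param trees data frame of field trees with `id`, `x`, `y`, `height_m`,
#'   `dbh_cm`.
#' @return an object of class `match_result`: list with `pairs`
#'   (`itc_id`, `tree_id`), `unmatched_field_trees` and `unmatched_itcs`
#'   (id vectors).
#' @export
match_itcs <- function(itcs, trees) {
  stopifnot(inherits(itcs, "itc_set"), is.data.frame(trees))
  tab <- itcs$table
  ord <- order(tab$id)
  taken <- rep(FALSE, nrow(trees))
  pairs <- list()
  for (i in ord) {
    ring <- itcs$polygons[[i]]
    inside <- point_in_polygon(trees$x, trees$y, ring) & !taken
    if (!any(inside)) next
    cand <- which(inside)
    if (length(cand) > 1L) {
      gap <- abs(trees$height_m[cand] - tab$height_m[i])
      cand <- cand[order(gap, -trees$dbh_cm[cand], trees$id[cand])]
    }
    pick <- cand[1L]
    taken[pick] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(itc_id = tab$id[i],
                                              tree_id = trees$id[pick])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(itc_id = integer(), tree_id = integer())
  structure(list(
    pairs = pairs,
    unmatched_field_trees = trees$id[!taken],
    unmatched_itcs = setdiff(tab$id, pairs$itc_id)),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d pairs, %d unmatched trees, %d unmatched ITCs\n",
              nrow(x$pairs), length(x$unmatched_field_trees),
              length(x$unmatched_itcs)))
  invisible(x)
}

#' Delineation accuracy metrics
#'
#' Detection rate DET = 100 * matched trees / field trees; omission error
#' OE = 100 - DET; commission error CE = 100 * unmatched ITCs / delineated
#' ITCs; accuracy index AI = 100 - (OE + CE). The per-class table bins field
#' trees by DBH; an unmatched ITC is attributed to the class of its own
#' estimated DBH (ITCs without a DBH estimate are not binned).
#'
#' @param match a [match_itcs()] result.
#' @param trees the field-tree table used for matching (needs `dbh_cm`).
#' @param itcs the [itc_set()] used for matching.
#' @param dbh_breaks DBH class edges in cm (default `seq(10, 80, 10)` giving
#'   classes <10, 10-20, ..., >=80).
#' @return an object of class `delineation_metrics`: list with `det_pct`,
#'   `oe_pct`, `ce_pct`, `ai_pct` and `by_class` data frame.
#' @export
delineation_metrics <- function(match, trees, itcs,
                                dbh_breaks = seq(10, 80, by = 10)) {
  if (nrow(trees) == 0L)
    stop("no field trees: delineation metrics undefined", call. = FALSE)
  n_itc <- length(itcs)
  matched <- trees$id %in% match$pairs$tree_id
  det <- 100 * sum(matched) / nrow(trees)
  ce <- if (n_itc > 0) 100 * length(match$unmatched_itcs) / n_itc else NA_real_
  out <- list(det_pct = det, oe_pct = 100 - det, ce_pct = ce,
              ai_pct = 100 - ((100 - det) + ce))
  edges <- c(-Inf, dbh_breaks, Inf)
  cls <- cut(trees$dbh_cm, edges, right = FALSE)
  by_cls <- data.frame(class = levels(cls))
  by_cls$n_field <- as.integer(table(cls))
  by_cls$n_matched <- as.integer(table(cls[matched]))
  itab <- itcs$table
  un_itc <- itab[itab$id %in% match$unmatched_itcs, , drop = FALSE]
  ucls <- cut(un_itc$dbh_cm, edges, right = FALSE)
  by_cls$n_unmatched_itc <- as.integer(table(ucls))
  itc_cls <- cut(itab$dbh_cm, edges, right = FALSE)
  by_cls$n_itc <- as.integer(table(itc_cls))
  by_cls$det_pct <- ifelse(by_cls$n_field > 0,
                           100 * by_cls$n_matched / by_cls$n_field, NA_real_)
  by_cls$oe_pct <- 100 - by_cls$det_pct
  by_cls$ce_pct <- ifelse(by_cls$n_itc > 0,
                          100 * by_cls$n_unmatched_itc / by_cls$n_itc, NA_real_)
  by_cls$ai_pct <- 100 - (by_cls$oe_pct + by_cls$ce_pct)
  out$by_class <- by_cls
  class(out) <- "delineation_metrics"
  out
}

#' @export
print.delineation_metrics <- function(x, ...) {
  cat(sprintf("DET %.1f%%  OE %.1f%%  CE %.1f%%  AI %.1f%%\n",
              x$det_pct, x$oe_pct, x$ce_pct, x$ai_pct))
  invisible(x)
}

#' Detected biomass by stem-diameter class
#'
#' For every DBH class: total field biomass, biomass of the field trees with
#' a matching ITC, biomass of all delineated ITCs falling in the class, and
#' the matched/field percentage. Large trees dominate stand biomass, so even
#' low stem-detection rates can capture most of it.
#'
#' @inheritParams delineation_metrics
#' @return data frame with columns `class`, `field_agb_kg`, `matched_agb_kg`,
#'   `itc_agb_kg`, `detected_pct`.
#' @export
biomass_detection_by_class <- function(match, trees, itcs,
                                       dbh_breaks = seq(10, 80, by = 10)) {
  stopifnot("agb_kg" %in% names(trees))
  edges <- c(-Inf, dbh_breaks, Inf)
  cls <- cut(trees$dbh_cm, edges, right = FALSE)
  matched <- trees$id %in% match$pairs$tree_id
  agg <- function(w, g) {
    out <- tapply(w, g, sum)
    out[is.na(out)] <- 0
    as.numeric(out)
  }
  out <- data.frame(class = levels(cls))
  out$field_agb_kg <- agg(trees$agb_kg, cls)
  out$matched_agb_kg <- agg(trees$agb_kg * matched, cls)
  itab <- itcs$table
  icls <- cut(itab$dbh_cm, edges, right = FALSE)
  iagb <- ifelse(is.na(itab$agb_kg), 0, itab$agb_kg)
  out$itc_agb_kg <- agg(iagb, icls)
  out$detected_pct <- ifelse(out$field_agb_kg > 0,
                             100 * out$matched_agb_kg / out$field_agb_kg,
                             NA_real_)
  out
}

#' Height agreement between matched ITCs and field trees
#'
#' @param match a [match_itcs()] result with at least 2 pairs.
#' @param trees,itcs the tables used for matching.
#' @return list with `rmse_m`, `r_squared` (OLS of field on ITC height) and
#'   `mean_bias_pct` (mean of 100 * (ITC - field) / field).
#' @export
height_agreement <- function(match, trees, itcs) {
  p <- match$pairs
  if (nrow(p) < 2L) stop("need at least 2 matched pairs", call. = FALSE)
  th <- trees$height_m[base::match(p$tree_id, trees$id)]
  ih <- itcs$table$height_m[base::match(p$itc_id, itcs$table$id)]
  fit <- stats::lm(th ~ ih)
  list(rmse_m = sqrt(mean((ih - th)^2)),
       r_squared = summary(fit)$r.squared,
       mean_bias_pct = mean(100 * (ih - th) / th))
}
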