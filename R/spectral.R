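#' Extract sunlit pixels per crown
#'
#' For every crown polygon, keeps the pixels whose centre lies inside it and
#' whose pre-normalization brightness (mean reflectance over bands) is at or
#' above a brightness quantile of the crown's own pixels (default the
#' median). Shaded crown-edge pixels carry weaker species signal and are
#' discarded this way. Crowns with fewer than 2 pixels keep all their pixels;
#' crowns with none are skipped with a warning.
#'
#' @param cube a raw (pre-normalization) [hyper_cube()]; features in the
#'   returned table are sum-normalized internally.
#' @param itcs an [itc_set()].
#' @param quantile brightness quantile defining "sunlit" (default 0.5).
#' @return data frame with `itc_id`, `row`, `col`, `brightness` and one
#'   `b<k>` column per normalized band.
#' @export
extract_sunlit_pixels <- function(cube, itcs, quantile = 0.5) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(itcs, "itc_set"))
  d <- dim(cube$values)
  grid <- cube_grid(cube)
  norm <- normalize_pixels(cube)
  flat_raw <- matrix(cube$values, d[1] * d[2], d[3])
  flat_norm <- matrix(norm$values, d[1] * d[2], d[3])
  bright <- rowMeans(flat_raw)
  out <- list()
  skipped <- 0L
  for (i in seq_along(itcs$polygons)) {
    ring <- itcs$polygons[[i]]
    bb_min <- world_to_pixel(grid, min(ring[, 1]), max(ring[, 2]))
    bb_max <- world_to_pixel(grid, max(ring[, 1]), min(ring[, 2]))
    rows <- max(1L, bb_min$row):min(d[1], bb_max$row)
    cols <- max(1L, bb_min$col):min(d[2], bb_max$col)
    px <- expand.grid(row = rows, col = cols)
    w <- pixel_to_world(grid, px$row, px$col)
    inside <- point_in_polygon(w$x, w$y, ring)
    px <- px[inside, , drop = FALSE]
    if (nrow(px) == 0L) {
      skipped <- skipped + 1L
      next
    }
    idx <- (px$col - 1L) * d[1] + px$row
    b <- bright[idx]
    keep <- if (nrow(px) < 2L) rep(TRUE, nrow(px)) else
      b >= stats::quantile(b, quantile, type = 7)
    idx <- idx[keep]
    feats <- flat_norm[idx, , drop = FALSE]
    colnames(feats) <- paste0("b", seq_len(d[3]))
    out[[length(out) + 1L]] <- cbind(
      data.frame(itc_id = itcs$table$id[i], row = px$row[keep],
                 col = px$col[keep], brightness = b[keep]),
      as.data.frame(feats))
  }
  if (skipped > 0L)
    warning("skipped ", skipped, " ITC(s) containing no pixel centres")
  if (!length(out)) stop("no pixels extracted for any ITC", call. = FALSE)
  do.call(rbind, out)
}

#' Jeffries-Matusita distance between two classes
#'
#' Separability of two Gaussian classes: `JM = 2 * (1 - exp(-B))` with `B`
#' the Bhattacharyya distance
#' `B = 1/8 (m1-m2)' S^-1 (m1-m2) + 1/2 log(|S| / sqrt(|S1||S2|))`,
#' `S = (S1+S2)/2`. JM is bounded in `[0, 2]`; 2 means complete
#' separability. Covariances are diagonally loaded by
#' `diag_load * mean(diag)` before inversion to tolerate small sample sizes.
#'
#' @param a,b numeric matrices (samples x features) for the two classes.
#' @param diag_load relative diagonal loading (default 1e-6).
#' @return JM distance in `[0, 2]`.
#' @export
jm_distance <- function(a, b, diag_load = 1e-6) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b))
  ma <- colMeans(a); mb <- colMeans(b)
  load_cov <- function(x) {
    s <- stats::cov(x)
    if (nrow(x) < 2L) s <- matrix(0, ncol(x), ncol(x))
    d <- mean(diag(s))
    if (!is.finite(d) || d <= 0) d <- 1
    s + diag(diag_load * d, ncol(x))
  }
  sa <- load_cov(a); sb <- load_cov(b)
  sp <- (sa + sb) / 2
  ch <- tryCatch(chol(sp), error = function(e)
    stop("singular pooled covariance for features ",
         paste(colnames(a), collapse = ", "), call. = FALSE))
  dm <- ma - mb
  quad <- sum(backsolve(ch, dm, transpose = TRUE)^2)
  logdet <- function(s) as.numeric(determinant(s, logarithm = TRUE)$modulus)
  bh <- quad / 8 + 0.5 * (logdet(sp) - 0.5 * (logdet(sa) + logdet(sb)))
  2 * (1 - exp(-bh))
}

# Mean (or minimum) pairwise JM over all class pairs for a feature subset.
jm_criterion <- function(x, labels, features, type = c("mean", "min")) {
  type <- match.arg(type)
  cls <- split(seq_len(nrow(x)), labels)
  k <- length(cls)
  vals <- c()
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    vals <- c(vals, jm_distance(x[cls[[i]], features, drop = FALSE],
                                x[cls[[j]], features, drop = FALSE]))
  if (type == "mean") mean(vals) else min(vals)
}

#' Sequential forward floating feature selection (SFFS)
#'
#' Pudil-style floating search maximizing class separability: greedily add
#' the feature that most improves the criterion (mean pairwise JM distance
#' over all class pairs, or the minimum pairwise JM), then conditionally
#' remove features while removal improves the criterion for the reduced
#' size. Deterministic: ties go to the lowest feature index.
#'
#' @param x numeric matrix (samples x features).
#' @param labels class labels (>= 2 classes).
#' @param n_features number of features to select.
#' @param criterion `"mean"` (default) or `"min"` pairwise JM.
#' @return integer vector of selected feature indices (sorted), with the
#'   criterion trajectory in attribute `criterion_value`.
#' @export
sffs_select <- function(x, labels, n_features,
                        criterion = c("mean", "min")) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("feature selection needs at least 2 classes", call. = FALSE)
  p <- ncol(x)
  stopifnot(n_features >= 1, n_features <= p)
  if (n_features == p) return(structure(1:p, criterion_value =
    jm_criterion(x, labels, 1:p, criterion)))
  crit <- function(f) jm_criterion(x, labels, f, criterion)
  sel <- integer(0)
  best_at <- rep(-Inf, n_features)    # best criterion seen at each size
  best_set <- vector("list", n_features)
  iter <- 0L
  while (length(sel) < n_features && (iter <- iter + 1L) <= 20L * p) {
    # forward step
    rest <- setdiff(1:p, sel)
    vals <- vapply(rest, function(f) crit(c(sel, f)), numeric(1))
    add <- rest[which.max(vals)]      # which.max takes first (lowest index) tie
    sel <- sort(c(sel, add))
    k <- length(sel)
    if (vals[match(add, rest)] > best_at[k]) {
      best_at[k] <- vals[match(add, rest)]
      best_set[[k]] <- sel
    }
    # conditional backward steps
    while (length(sel) > 2L) {
      drop_vals <- vapply(seq_along(sel),
                          function(i) crit(sel[-i]), numeric(1))
      i_best <- which.max(drop_vals)
      k1 <- length(sel) - 1L
      if (drop_vals[i_best] > best_at[k1]) {
        sel <- sel[-i_best]
        best_at[k1] <- drop_vals[i_best]
        best_set[[k1]] <- sel
      } else break
    }
  }
  structure(best_set[[n_features]], criterion_value = best_at[n_features])
}

#' Train the pixel-level species classifier
#'
#' One-vs-one soft-margin SVM with a radial-basis kernel
#' ([kernlab::ksvm()]); features are standardized internally. When `cv` is
#' `TRUE`, `C` and the kernel width `gamma` are chosen by stratified k-fold
#' cross-validation over a log grid. Classes with fewer than `min_pixels`
#' training pixels are excluded with a warning.
#'
#' @param x numeric feature matrix (selected normalized bands, plus the
#'   crown's 99th-percentile first-return height as an ALS feature when
#'   available).
#' @param labels class labels.
#' @param cv logical: tune hyperparameters by cross-validation?
#' @param c_grid,gamma_grid log grids searched when `cv = TRUE`.
#' @param folds number of CV folds.
#' @param min_pixels minimum training pixels per class (default 5).
#' @param seed integer seed fixing fold assignment and the SVM fit.
#' @param prob_model fit a probability model (used for majority-rule tie
#'   breaking).
#' @return an object of class `species_classifier`.
#' @export
train_classifier <- function(x, labels, cv = TRUE,
                             c_grid = 10^(-1:3), gamma_grid = 10^(-3:1),
                             folds = 5, min_pixels = 5, seed = 1,
                             prob_model = TRUE) {
  x <- as.matrix(x)
  labels <- as.factor(as.character(labels))
  small <- names(which(table(labels) < min_pixels))
  if (length(small)) {
    warning("excluding class(es) with < ", min_pixels, " pixels: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    x <- x[keep, , drop = FALSE]
    labels <- droplevels(labels[keep])
  }
  if (nlevels(labels) < 2L)
    stop("classifier training needs at least 2 classes", call. = FALSE)
  centre <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scale_, "/")
  best <- c(C = 10, gamma = 1 / ncol(x))
  if (cv) {
    set.seed(seed)
    fold <- unsplit(lapply(split(seq_along(labels), labels), function(i)
      sample(rep_len(seq_len(folds), length(i)))), labels)
    grid <- expand.grid(C = c_grid, gamma = gamma_grid)
    acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      hits <- 0L
      for (f in seq_len(folds)) {
        tr <- fold != f
        if (nlevels(droplevels(labels[tr])) < 2L) next
        fit <- kernlab::ksvm(xs[tr, , drop = FALSE], labels[tr],
                             kernel = "rbfdot",
                             kpar = list(sigma = grid$gamma[g]),
                             C = grid$C[g], scaled = FALSE)
        pred <- kernlab::predict(fit, xs[!tr, , drop = FALSE])
        hits <- hits + sum(pred == labels[!tr])
      }
      acc[g] <- hits / length(labels)
    }
    best <- c(C = grid$C[which.max(acc)], gamma = grid$gamma[which.max(acc)])
  }
  set.seed(seed)
  fit <- kernlab::ksvm(xs, labels, kernel = "rbfdot",
                       kpar = list(sigma = unname(best["gamma"])),
                       C = unname(best["C"]), scaled = FALSE,
                       prob.model = prob_model)
  structure(list(fit = fit, centre = centre, scale = scale_,
                 levels = levels(labels), C = unname(best["C"]),
                 gamma = unname(best["gamma"]), prob_model = prob_model,
                 n_train = as.integer(table(labels))),
            class = "species_classifier")
}

#' @export
print.species_classifier <- function(x, ...) {
  cat(sprintf("species_classifier: RBF SVM, %d classes, C = %g, gamma = %g\n",
              length(x$levels), x$C, x$gamma))
  cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Predict pixel classes
#'
#' @param object a [train_classifier()] fit.
#' @param newdata feature matrix with the training columns.
#' @param type `"class"` or `"prob"` (class-membership probabilities; needs
#'   `prob_model = TRUE` at training).
#' @param ... unused.
#' @export
predict.species_classifier <- function(object, newdata,
                                       type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- sweep(sweep(as.matrix(newdata), 2, object$centre), 2, object$scale, "/")
  if (type == "class") as.character(kernlab::predict(object$fit, xs))
  else kernlab::predict(object$fit, xs, type = "probabilities")
}

#' Label crowns by majority vote over their pixels
#'
#' Each crown receives the modal predicted class of its pixels. Vote ties
#' are broken by the greater mean class probability (when the classifier has
#' a probability model), then by lexicographic label order. Crowns with no
#' pixels are labelled `"unknown"`.
#'
#' @param classifier a [train_classifier()] fit.
#' @param x pixel feature matrix.
#' @param itc_id crown id per pixel row.
#' @param itc_ids optional vector of all crown ids expected in the output
#'   (ids absent from `itc_id` come back `"unknown"`).
#' @return named character vector: crown id -> species label.
#' @export
classify_itcs <- function(classifier, x, itc_id, itc_ids = NULL) {
  pred <- predict(classifier, x)
  probs <- if (classifier$prob_model)
    predict(classifier, x, type = "prob") else NULL
  ids <- if (is.null(itc_ids)) sort(unique(itc_id)) else itc_ids
  out <- stats::setNames(rep("unknown", length(ids)), as.character(ids))
  for (id in ids) {
    sel <- itc_id == id
    if (!any(sel)) next
    votes <- table(pred[sel])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      if (!is.null(probs)) {
        mp <- colMeans(probs[sel, top, drop = FALSE])
        top <- top[order(-mp, top)]
      } else top <- sort(top)
    }
    out[as.character(id)] <- top[1L]
  }
  out
}

#' Build a confusion matrix
#'
#' Rows are predicted classes, columns reference classes.
#'
#' @param predicted,reference label vectors of equal length.
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(predicted, reference) {
  lv <- sort(unique(c(as.character(predicted), as.character(reference))))
  cm <- table(factor(predicted, lv), factor(reference, lv))
  structure(unclass(as.matrix(cm)), class = "confusion_matrix")
}

#' Accuracy metrics from a confusion matrix
#'
#' Overall accuracy is `100 * trace / total`; the producer's accuracy of a
#' class is the correctly classified share of its reference column, the
#' user's accuracy the share of its prediction row; average accuracy is the
#' unweighted mean of producer's accuracies; kappa is the chance-corrected
#' agreement `(p_o - p_e) / (1 - p_e)` with `p_e` from the row and column
#' margins. Classes with an empty reference column are excluded from the
#' average with a warning.
#'
#' @param cm square numeric matrix, rows = predicted, columns = reference.
#' @return list with `overall_acc_pct`, `kappa`, `producers_acc`,
#'   `users_acc`, `average_acc_pct`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(unclass(cm))
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  rs <- rowSums(cm); cs <- colSums(cm)
  po <- sum(diag(cm)) / total
  pe <- sum(rs * cs) / total^2
  prod_acc <- ifelse(cs > 0, 100 * diag(cm) / cs, NA_real_)
  user_acc <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  names(prod_acc) <- names(user_acc) <- rownames(cm)
  if (anyNA(prod_acc))
    warning("class(es) with empty reference column excluded from the average: ",
            paste(rownames(cm)[is.na(prod_acc)], collapse = ", "))
  list(overall_acc_pct = 100 * po,
       kappa = (po - pe) / (1 - pe),
       producers_acc = prod_acc,
       users_acc = user_acc,
       average_acc_pct = mean(prod_acc, na.rm = TRUE))
}
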