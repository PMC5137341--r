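#' DBH coefficient table
#'
#' Coefficients of the crown-to-stem allometry `DBH = epsilon * H^rho *
#' (1 + theta * CA)` (DBH in cm, H in m, CA in m2), one row per species
#' group plus a pooled `"All"` row used as fallback.
#'
#' @param path CSV with columns `species, epsilon, rho, theta` and
#'   optionally `se_epsilon, se_rho, se_theta, rmse_cm, n`. Defaults to the
#'   table packaged for spruce/larch-dominated Alpine conifer stands.
#' @return data frame of class `dbh_coefficients`.
#' @export
read_dbh_coefficients <- function(path = system.file("extdata",
                                                     "dbh_coefficients_alpine.csv",
                                                     package = "canopycarbon")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "epsilon", "rho", "theta")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("DBH coefficient table lacks: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  stopifnot(all(d$epsilon > 0), all(d$rho > 0))
  class(d) <- c("dbh_coefficients", "data.frame")
  d
}

coeff_row <- function(coeffs, species, what) {
  i <- match(species, coeffs$species)
  fall <- match("All", coeffs$species)
  i[is.na(i)] <- fall
  if (anyNA(i))
    stop("no ", what, " coefficients for species ",
         paste(unique(species[is.na(match(species, coeffs$species))]),
               collapse = ", "), " and no 'All' fallback row", call. = FALSE)
  i
}

#' Predict stem diameter from crown height and area
#'
#' Evaluates `DBH = epsilon * H^rho * (1 + theta * CA)` with the species'
#' coefficient row, falling back to the pooled `"All"` row for species
#' without their own fit.
#'
#' @param h_m crown height (m), the 99th percentile of first returns.
#' @param ca_m2 crown area (m2); 0 reduces the model to `epsilon * H^rho`.
#' @param coeffs a [read_dbh_coefficients()] table or a fitted `dbh_model`.
#' @param species species label vector (recycled).
#' @return predicted DBH in cm.
#' @export
predict_dbh <- function(h_m, ca_m2, coeffs = read_dbh_coefficients(),
                        species = "All") {
  stopifnot(all(h_m > 0), all(ca_m2 >= 0))
  if (inherits(coeffs, "dbh_model")) {
    cf <- coef(coeffs)
    return(cf[["epsilon"]] * h_m^cf[["rho"]] * (1 + cf[["theta"]] * ca_m2))
  }
  i <- coeff_row(coeffs, rep_len(species, length(h_m)), "DBH")
  coeffs$epsilon[i] * h_m^coeffs$rho[i] * (1 + coeffs$theta[i] * ca_m2)
}

# ---- nonlinear median (pinball) regression ---------------------------------

# Smoothed pinball loss (Chen & Mangasarian): rho_tau(r) ~ tau*r +
# eta*log(1+exp(-r/eta)); recovers the check loss as eta -> 0.
pinball_smooth <- function(r, tau, eta) {
  # numerically safe log(1 + exp(-r/eta))
  a <- -r / eta
  lse <- ifelse(a > 30, a, log1p(exp(pmin(a, 30))))
  sum(tau * r + eta * lse)
}

pinball_smooth_grad_r <- function(r, tau, eta) {
  tau - stats::plogis(-r / eta)   # d/dr, bounded in (tau-1, tau)
}

pinball_loss <- function(r, tau) sum(r * (tau - (r < 0)))

dbh_objective <- function(theta, h, ca, dbh, tau, eta) {
  eps <- exp(theta[1]); rho <- theta[2]; th <- theta[3]
  f <- eps * h^rho * (1 + th * ca)
  r <- dbh - f
  list(value = pinball_smooth(r, tau, eta),
       gradient = {
         g <- -pinball_smooth_grad_r(r, tau, eta)
         c(sum(g * f),
           sum(g * f * log(h)),
           sum(g * eps * h^rho * ca))
       })
}

fit_dbh_once <- function(h, ca, dbh, tau, start, etas = c(1, 0.1, 0.01)) {
  theta <- start
  for (eta in etas) {
    o <- stats::optim(theta,
                      fn = function(p) dbh_objective(p, h, ca, dbh, tau, eta)$value,
                      gr = function(p) dbh_objective(p, h, ca, dbh, tau, eta)$gradient,
                      method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
    theta <- o$par
  }
  f <- exp(theta[1]) * h^theta[2] * (1 + theta[3] * ca)
  list(par = theta, loss = pinball_loss(dbh - f, tau),
       converged = o$convergence == 0)
}

#' Fit the crown-to-stem diameter model by nonlinear quantile regression
#'
#' Fits `DBH = epsilon * H^rho * (1 + theta * CA)` by minimizing the
#' tau-pinball (check) loss, by default the median (`tau = 0.5`), which is
#' robust to the heteroscedastic, right-skewed scatter typical of
#' diameter-height data. The check loss is smoothed (`log(1+exp)`
#' approximation) with a decreasing smoothing parameter and minimized by
#' BFGS from multiple starts around a log-scale least-squares
#' initialization. Standard errors come from a nonparametric bootstrap.
#'
#' @param h,ca,dbh numeric vectors: height (m), crown area (m2), observed
#'   DBH (cm); at least 10 triples.
#' @param tau target quantile in (0, 1), default 0.5 (median).
#' @param n_boot bootstrap resamples for standard errors (default 200; 0
#'   skips them).
#' @param n_starts number of multi-start initializations (default 8).
#' @param seed seed for the bootstrap resampling.
#' @return an object of class `dbh_model` with components `coefficients`
#'   (`epsilon`, `rho`, `theta`), `se`, `rmse_cm`, `loss`, `tau`, `n`,
#'   `fitted.values`, `residuals`, `data`.
#' @export
fit_dbh_model <- function(h, ca, dbh, tau = 0.5, n_boot = 200, n_starts = 8,
                          seed = 1) {
  stopifnot(length(h) == length(ca), length(h) == length(dbh))
  if (length(h) < 10L) stop("need at least 10 (H, CA, DBH) triples", call. = FALSE)
  stopifnot(all(h > 0), all(ca >= 0), all(dbh > 0), tau > 0, tau < 1)
  cl <- match.call()
  fit0 <- fit_dbh_core(h, ca, dbh, tau, n_starts)
  if (!fit0$converged)
    stop("DBH model fit did not converge from any start; inspect the data ",
         "(n = ", length(h), ", loss = ", signif(fit0$loss, 4), ")",
         call. = FALSE)
  par <- fit0$par
  cf <- c(epsilon = exp(par[1]), rho = par[2], theta = par[3])
  fitted <- cf[1] * h^cf[2] * (1 + cf[3] * ca)
  se <- c(epsilon = NA_real_, rho = NA_real_, theta = NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    bs <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      i <- sample.int(length(h), replace = TRUE)
      fb <- fit_dbh_once(h[i], ca[i], dbh[i], tau, start = par)
      bs[b, ] <- c(exp(fb$par[1]), fb$par[2], fb$par[3])
    }
    se <- stats::setNames(apply(bs, 2, stats::sd, na.rm = TRUE),
                          c("epsilon", "rho", "theta"))
  }
  structure(list(coefficients = cf, se = se, tau = tau,
                 rmse_cm = sqrt(mean((dbh - fitted)^2)),
                 loss = fit0$loss, n = length(h), n_boot = n_boot,
                 fitted.values = fitted, residuals = dbh - fitted,
                 data = data.frame(h = h, ca = ca, dbh = dbh),
                 converged = fit0$converged, call = cl),
            class = "dbh_model")
}

# Multi-start driver: log-scale OLS initialization plus a log-space grid.
fit_dbh_core <- function(h, ca, dbh, tau, n_starts) {
  ols <- stats::lm(log(dbh) ~ log(h))
  s0 <- c(stats::coef(ols)[1], stats::coef(ols)[2], 0.01)
  grid <- expand.grid(le = s0[1] + c(-1, 0, 1), rho = c(0.5, 0.9, 1.3),
                      th = c(0, 0.02))
  starts <- rbind(s0, as.matrix(grid))
  starts <- starts[seq_len(min(nrow(starts), max(1L, n_starts))), , drop = FALSE]
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    f <- tryCatch(fit_dbh_once(h, ca, dbh, tau, start = unname(starts[k, ])),
                  error = function(e) NULL)
    if (is.null(f) || !all(is.finite(f$par))) next
    if (is.null(best) || f$loss < best$loss) best <- f
  }
  if (is.null(best)) return(list(par = rep(NA_real_, 3), loss = Inf,
                                 converged = FALSE))
  best
}

#' @export
print.dbh_model <- function(x, ...) {
  cat(sprintf("Crown-to-stem diameter model (quantile tau = %.2f, n = %d)\n",
              x$tau, x$n))
  cat("  DBH = epsilon * H^rho * (1 + theta * CA)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  RMSE %.2f cm\n", x$rmse_cm))
  invisible(x)
}

#' @export
coef.dbh_model <- function(object, ...) object$coefficients

#' @export
fitted.dbh_model <- function(object, ...) object$fitted.values

#' @export
residuals.dbh_model <- function(object, ...) object$residuals

#' @export
summary.dbh_model <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(coefficients = tab, tau = object$tau, n = object$n,
                 n_boot = object$n_boot, rmse_cm = object$rmse_cm,
                 loss = object$loss),
            class = "summary.dbh_model")
}

#' @export
print.summary.dbh_model <- function(x, ...) {
  cat(sprintf("Nonlinear quantile regression, tau = %.2f, n = %d\n", x$tau, x$n))
  stats::printCoefmat(x$coefficients, digits = 4, na.print = "-")
  cat(sprintf("RMSE %.2f cm (pinball loss %.2f; SEs from %d bootstrap resamples)\n",
              x$rmse_cm, x$loss, x$n_boot))
  invisible(x)
}

#' Predict method for dbh_model
#'
#' @param object a fitted [fit_dbh_model()] object.
#' @param newdata data frame with columns `h` (m) and `ca` (m2); omitted,
#'   the training data are used.
#' @param ... unused.
#' @return predicted DBH (cm).
#' @export
predict.dbh_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  cf <- object$coefficients
  stopifnot(all(c("h", "ca") %in% names(newdata)))
  cf[["epsilon"]] * newdata$h^cf[["rho"]] * (1 + cf[["theta"]] * newdata$ca)
}

#' Simulate DBH observations from a fitted model
#'
#' Draws new diameters at the training (H, CA) by combining model
#' predictions with resampled observed relative residuals, preserving the
#' multiplicative error structure of diameter data.
#'
#' @param object a fitted `dbh_model`.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns.
#' @export
simulate.dbh_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ratio <- object$data$dbh / object$fitted.values
  out <- replicate(nsim, object$fitted.values *
                     sample(ratio, length(ratio), replace = TRUE))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Plot method for dbh_model
#'
#' Observed versus fitted DBH with the 1:1 line.
#'
#' @param x a fitted `dbh_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dbh_model <- function(x, ...) {
  graphics::plot(x$fitted.values, x$data$dbh,
                 xlab = "Fitted DBH (cm)", ylab = "Observed DBH (cm)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Fit species-specific and pooled DBH models
#'
#' Species with at least `n_min` triples get their own quantile-regression
#' fit; a pooled `"All"` model over every tree is always fitted and serves
#' as the fallback for sparse species.
#'
#' @param trees data frame with `species`, `h`, `ca`, `dbh`.
#' @param n_min minimum samples for a species-specific fit (default 100).
#' @param ... passed to [fit_dbh_model()].
#' @return a `dbh_coefficients` table (one row per fitted group) with the
#'   fitted `dbh_model` objects in attribute `models`.
#' @export
fit_dbh_models <- function(trees, n_min = 100, ...) {
  stopifnot(all(c("species", "h", "ca", "dbh") %in% names(trees)))
  groups <- names(which(table(trees$species) >= n_min))
  fits <- list(All = fit_dbh_model(trees$h, trees$ca, trees$dbh, ...))
  for (g in groups) {
    d <- trees[trees$species == g, ]
    fits[[g]] <- fit_dbh_model(d$h, d$ca, d$dbh, ...)
  }
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(species = nm, n = f$n,
               epsilon = unname(f$coefficients["epsilon"]),
               rho = unname(f$coefficients["rho"]),
               theta = unname(f$coefficients["theta"]),
               se_epsilon = unname(f$se["epsilon"]),
               se_rho = unname(f$se["rho"]),
               se_theta = unname(f$se["theta"]),
               rmse_cm = f$rmse_cm)
  }))
  class(tab) <- c("dbh_coefficients", "data.frame")
  attr(tab, "models") <- fits
  tab
}

# ---- above-ground biomass and carbon ---------------------------------------

#' AGB coefficient table
#'
#' Per-species coefficients of the biomass allometry
#' `AGB = alpha * WD^beta * (DBH - d0)^gamma * H^delta` (kg; DBH cm, H m,
#' WD g/cm3), with the carbon fraction and the conifer/angiosperm group.
#' The packaged default is a synthetic placeholder set with realistic
#' magnitudes (see the file's `source` column); replace it with a
#' region-appropriate table for real analyses.
#'
#' @param path CSV with columns `species, alpha, beta, gamma, delta, d0,
#'   wd, group, carbon_fraction, source`.
#' @return data frame of class `agb_coefficients`.
#' @export
read_agb_coefficients <- function(path = system.file("extdata",
                                                     "agb_coefficients_synthetic.csv",
                                                     package = "canopycarbon")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "alpha", "beta", "gamma", "delta", "d0", "wd",
            "group", "carbon_fraction")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("AGB coefficient table lacks: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  stopifnot(all(d$wd > 0), all(d$gamma > 0),
            all(d$carbon_fraction > 0 & d$carbon_fraction < 1))
  class(d) <- c("agb_coefficients", "data.frame")
  d
}

#' Above-ground biomass of a tree
#'
#' `AGB = alpha * WD^beta * (DBH - d0)^gamma * H^delta` in kg. Stems at or
#' below the allometry's diameter offset `d0` get 0 kg with a warning.
#'
#' @param dbh_cm stem diameter (cm).
#' @param h_m tree height (m).
#' @param coeffs a [read_agb_coefficients()] table.
#' @param species species label vector (recycled; fallback `"All"` row).
#' @return biomass in kg.
#' @export
agb_tree <- function(dbh_cm, h_m, coeffs = read_agb_coefficients(),
                     species = "All") {
  stopifnot(all(h_m > 0))
  species <- rep_len(species, length(dbh_cm))
  i <- coeff_row(coeffs, species, "AGB")
  below <- dbh_cm <= coeffs$d0[i]
  if (any(below))
    warning(sum(below), " stem(s) at or below the allometry offset d0; AGB set to 0")
  agb <- ifelse(below, 0,
                coeffs$alpha[i] * coeffs$wd[i]^coeffs$beta[i] *
                  (dbh_cm - coeffs$d0[i])^coeffs$gamma[i] * h_m^coeffs$delta[i])
  agb
}

#' Carbon content of a tree
#'
#' Biomass times the taxon's carbon fraction: 0.50 for conifers and 0.48
#' for angiosperms by default.
#'
#' @param agb_kg above-ground biomass (kg), >= 0.
#' @param group `"conifer"` or `"angiosperm"` (recycled).
#' @param fractions named numeric vector of carbon fractions per group.
#' @return carbon in kg.
#' @export
carbon_tree <- function(agb_kg, group,
                        fractions = c(conifer = 0.5, angiosperm = 0.48)) {
  stopifnot(all(agb_kg >= 0))
  group <- rep_len(as.character(group), length(agb_kg))
  unknown <- !(group %in% names(fractions))
  if (any(unknown))
    stop("unknown taxon group(s): ", paste(unique(group[unknown]), collapse = ", "),
         call. = FALSE)
  unname(agb_kg * fractions[group])
}
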