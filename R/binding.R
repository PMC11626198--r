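#' Construct a titration series
#'
#' Fluorescence anisotropy titration: a fixed concentration of labeled RNA
#' probe, ascending total titrant (protein) concentrations, and the measured
#' anisotropy (optionally with per-point replicate SD).
#'
#' @param probe_total molar concentration of the labeled probe
#' @param titrant_totals ascending molar titrant concentrations
#' @param anisotropy dimensionless anisotropy per point
#' @param replicate_sd optional per-point SD of replicate anisotropy
#' @return object of class `titration_series`
#' @export
titration_series <- function(probe_total, titrant_totals, anisotropy,
                             replicate_sd = NULL) {
  stopifnot_scalar_pos(probe_total, "probe_total")
  if (any(titrant_totals < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (is.unsorted(titrant_totals, strictly = TRUE))
    stop("`titrant_totals` must be strictly ascending", call. = FALSE)
  if (length(titrant_totals) != length(anisotropy))
    stop("titrant and anisotropy lengths differ", call. = FALSE)
  if (!all(is.finite(anisotropy)))
    stop("anisotropy values must be finite", call. = FALSE)
  if (!is.null(replicate_sd) && length(replicate_sd) != length(anisotropy))
    stop("replicate_sd length mismatch", call. = FALSE)
  structure(list(probe_total = probe_total,
                 titrant_totals = as.numeric(titrant_totals),
                 anisotropy = as.numeric(anisotropy),
                 replicate_sd = replicate_sd),
            class = "titration_series")
}

#' Read / write titration CSV (titrant_M, anisotropy, sd)
#' @param path CSV file
#' @param probe_total molar probe concentration (stored in the header comment
#'   on write; must be supplied on read)
#' @return a [titration_series]
#' @export
read_titration_csv <- function(path, probe_total = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*probe_total_M\\s*=", first) && is.null(probe_total))
    probe_total <- as.numeric(sub("^#\\s*probe_total_M\\s*=\\s*", "", first))
  if (is.null(probe_total))
    stop("probe_total not found in file header; supply it explicitly",
         call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  sd <- if ("sd" %in% names(df) && !all(is.na(df$sd))) df$sd else NULL
  titration_series(probe_total, df$titrant_M, df$anisotropy, sd)
}

#' @rdname read_titration_csv
#' @param ts a [titration_series] to write
#' @export
write_titration_csv <- function(ts, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# probe_total_M = %.10g", ts$probe_total), con)
  df <- data.frame(titrant_M = ts$titrant_totals, anisotropy = ts$anisotropy,
                   sd = if (is.null(ts$replicate_sd)) NA else ts$replicate_sd)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Exact 1:1 complex concentration from the mass-balance quadratic.
complex_1to1 <- function(probe_total, titrant_total, kd) {
  b <- probe_total + titrant_total + kd
  disc <- b * b - 4 * probe_total * titrant_total
  c_ <- (b - sqrt(pmax(disc, 0))) / 2
  pmin(pmax(c_, 0), pmin(probe_total, titrant_total))
}

# Species concentrations for the sequential 2:1 model (two proteins per RNA).
# K1 = [P][R]/[PR], K2 = [P][PR]/[P2R], both dissociation constants.
species_2to1 <- function(probe_total, titrant_total, k1, k2) {
  R_t <- probe_total
  one <- function(P_t) {
    if (P_t <= 0) return(c(R = R_t, PR = 0, P2R = 0))
    f <- function(P) {
      R <- R_t / (1 + P / k1 + P * P / (k1 * k2))
      P + R * P / k1 + 2 * R * P * P / (k1 * k2) - P_t
    }
    P <- stats::uniroot(f, c(0, P_t), tol = P_t * 1e-12 + 1e-25)$root
    R <- R_t / (1 + P / k1 + P * P / (k1 * k2))
    c(R = R, PR = R * P / k1, P2R = R * P * P / (k1 * k2))
  }
  t(vapply(titrant_total, one, numeric(3)))
}

#' Predicted anisotropy from an equilibrium binding model
#'
#' 1:1 model: the complex concentration is the exact root of the mass-balance
#' quadratic (ligand depletion included), and the anisotropy is the
#' bound-fraction-weighted mixture of the free and bound endpoints. 2:1 model:
#' sequential equilibria P+R = PR (K1) and P+PR = P2R (K2) solved by numeric
#' mass balance; both bound species share `r_bound` unless two endpoint values
#' are given.
#'
#' @param probe_total molar probe concentration (scalar)
#' @param titrant_total molar titrant concentration(s)
#' @param params named list: `kd` (molar; length 2 `c(K1, K2)` for 2:1),
#'   `r_free`, `r_bound` (length 1, or 2 for distinct PR / P2R endpoints)
#' @param model `"one_to_one"` or `"two_to_one"`
#' @return predicted anisotropy, same length as `titrant_total`
#' @export
anisotropy_model <- function(probe_total, titrant_total, params,
                             model = c("one_to_one", "two_to_one")) {
  model <- match.arg(model)
  if (any(titrant_total < 0) || probe_total < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  if (any(params$kd <= 0)) stop("kd must be > 0", call. = FALSE)
  if (model == "one_to_one") {
    cc <- complex_1to1(probe_total, titrant_total, params$kd[1L])
    fb <- cc / probe_total
    params$r_free + (params$r_bound[1L] - params$r_free) * fb
  } else {
    sp <- species_2to1(probe_total, titrant_total,
                       params$kd[1L], params$kd[2L])
    rb <- rep_len(params$r_bound, 2L)
    as.numeric(params$r_free * sp[, "R"] + rb[1L] * sp[, "PR"] +
                 rb[2L] * sp[, "P2R"]) / probe_total
  }
}

#' Fit a binding model to a titration series
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of the 1:1 or
#' sequential 2:1 anisotropy model. Dissociation constants are fit on the log
#' scale for positivity; confidence intervals come from the linearized
#' covariance (t quantiles at the residual degrees of freedom).
#'
#' @param data a [titration_series] with at least 5 points
#' @param model `"one_to_one"` or `"two_to_one"`
#' @param level confidence level for intervals
#' @param start optional named list of starting values (`kd`, `r_free`,
#'   `r_bound`)
#' @param shared_endpoint for the 2:1 model: one anisotropy endpoint shared
#'   by both bound states (default) or distinct PR / P2R endpoints
#' @return object of class `binding_fit`: `model`, `kd_app`, `r_free`,
#'   `r_bound`, `ci` (data.frame), `rss`, `fitted`, `n`, `n_par`, `aicc`
#' @export
fit_isotherm <- function(data, model = c("one_to_one", "two_to_one"),
                         level = 0.95, start = NULL, shared_endpoint = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(data, "titration_series"))
  x <- data$titrant_totals; y <- data$anisotropy
  n <- length(y)
  if (n < 5L) stop("need at least 5 titration points", call. = FALSE)
  span <- diff(range(y))
  noise <- if (!is.null(data$replicate_sd)) stats::median(data$replicate_sd)
           else stats::sd(diff(y)) / sqrt(2)
  if (span < max(4 * noise, 1e-12) || span == 0)
    stop("unidentifiable fit: anisotropy range (", signif(span, 3),
         ") indistinguishable from noise (", signif(noise, 3),
         "); no binding transition in the data", call. = FALSE)
  # Per-point SDs from few replicates are noisy; equal-weight shrinkage
  # toward the median SD prevents near-zero estimates from dominating the
  # weighted fit and keeps the linearized CIs calibrated.
  w <- if (!is.null(data$replicate_sd)) {
    sd_eff <- sqrt((data$replicate_sd^2 +
                      stats::median(data$replicate_sd)^2) / 2)
    1 / pmax(sd_eff, 1e-6)^2
  } else rep(1, n)

  kd0 <- start$kd %||% x[which.min(abs(y - (y[1L] + y[n]) / 2))]
  kd0 <- max(kd0, 1e-12)
  rf0 <- start$r_free %||% y[1L]
  rb0 <- start$r_bound %||% y[n]

  if (model == "one_to_one") {
    fo <- y ~ anisotropy_model(pt, x, list(kd = exp(lkd), r_free = rf,
                                           r_bound = rb), "one_to_one")
    st <- list(lkd = log(kd0), rf = rf0, rb = rb0)
    par_names <- c("kd_app", "r_free", "r_bound")
  } else if (shared_endpoint) {
    fo <- y ~ anisotropy_model(pt, x, list(kd = exp(c(lk1, lk2)), r_free = rf,
                                           r_bound = rb), "two_to_one")
    st <- list(lk1 = log(kd0), lk2 = log(kd0 * 4), rf = rf0, rb = rb0)
    par_names <- c("K1_app", "K2_app", "r_free", "r_bound")
  } else {
    fo <- y ~ anisotropy_model(pt, x, list(kd = exp(c(lk1, lk2)), r_free = rf,
                                           r_bound = c(rb1, rb2)),
                               "two_to_one")
    st <- list(lk1 = log(kd0), lk2 = log(kd0 * 4), rf = rf0,
               rb1 = (rf0 + rb0) / 2, rb2 = rb0)
    par_names <- c("K1_app", "K2_app", "r_free", "r_bound_PR",
                   "r_bound_P2R")
  }
  env <- list2env(list(x = x, y = y, pt = data$probe_total))
  fit <- tryCatch(
    minpack.lm::nlsLM(fo, start = st, weights = w, data = env,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("binding fit failed to converge: ", conditionMessage(e),
           call. = FALSE))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(cf)) else sqrt(diag(vc))
  tq <- stats::qt(1 - (1 - level) / 2, df = n - length(cf))
  lo <- cf - tq * se; hi <- cf + tq * se
  is_log <- grepl("^lk", names(cf))
  est <- cf
  est[is_log] <- exp(cf[is_log])
  ci <- data.frame(parameter = par_names,
                   estimate = unname(est),
                   lower = unname(ifelse(is_log, exp(lo), lo)),
                   upper = unname(ifelse(is_log, exp(hi), hi)))
  res <- y - stats::fitted(fit)
  rss <- sum(res^2)
  k <- length(cf) + 1  # + residual variance
  aicc <- n * log(rss / n) + 2 * k +
    if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  kd_app <- if (model == "one_to_one") est[["lkd"]] else
    c(K1 = est[["lk1"]], K2 = est[["lk2"]])
  structure(list(model = model, kd_app = unname(kd_app),
                 r_free = unname(est[grep("^rf", names(cf))]),
                 r_bound = unname(est[grep("^rb", names(cf))]),
                 ci = ci, rss = rss, fitted = as.numeric(stats::fitted(fit)),
                 n = n, n_par = length(cf), aicc = aicc, data = data),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %s model, n = %d points\n", x$model, x$n))
  cat(sprintf("  K_D,app: %s M\n",
              paste(signif(x$kd_app, 4), collapse = ", ")))
  cat(sprintf("  r_free = %.4f, r_bound = %s, RSS = %.3g, AICc = %.2f\n",
              x$r_free, paste(signif(x$r_bound, 4), collapse = ", "),
              x$rss, x$aicc))
  invisible(x)
}

#' Compare two binding-model fits on the same data
#'
#' Small-sample-corrected information criterion (AICc from the least-squares
#' likelihood); the lower value is preferred, with a tie flag at |delta| < 2.
#'
#' @param fit_a,fit_b [fit_isotherm()] results fitted to the same series
#' @return list with `preferred`, `tie`, `delta_aicc`, and the per-model AICc
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "binding_fit"), inherits(fit_b, "binding_fit"))
  same <- isTRUE(all.equal(fit_a$data$titrant_totals,
                           fit_b$data$titrant_totals)) &&
    isTRUE(all.equal(fit_a$data$anisotropy, fit_b$data$anisotropy))
  if (!same) stop("fits were not produced from the same data", call. = FALSE)
  aicc <- c(fit_a$aicc, fit_b$aicc)
  models <- c(fit_a$model, fit_b$model)
  delta <- aicc[1L] - aicc[2L]
  list(preferred = models[which.min(aicc)], tie = abs(delta) < 2,
       delta_aicc = delta, aicc = setNames(aicc, models))
}

#' Serialize a binding fit to JSON
#' @param fit a `binding_fit`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_binding_fit <- function(fit, path) {
  obj <- list(model = fit$model, kd_app_M = fit$kd_app, r_free = fit$r_free,
              r_bound = fit$r_bound, rss = fit$rss, n = fit$n,
              aicc = fit$aicc, ci = fit$ci)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
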