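#' Normalize per-slice aldosterone secretion
#'
#' Within-well normalization: each slice's fold change is its post-treatment
#' aldosterone divided by its own baseline (`fold_raw`), and each animal's
#' treated slices are further divided by the mean `fold_raw` of that animal's
#' vehicle slices (`fold_norm`), so vehicle slices average exactly 1 per
#' animal. Animals contributing no vehicle slice cannot be normalized and are
#' dropped with a warning.
#'
#' @param records Tibble with columns `slice_id`, `animal_id`, `treatment`,
#'   `baseline_pg_per_slice_h`, `post_pg_per_slice_h` (extra columns such as
#'   `osmolarity_mOsm` or `genotype` pass through).
#' @param vehicle Treatment label identifying vehicle slices
#'   (default `"vehicle"`).
#' @return The input tibble with `fold_raw` and `fold_norm` columns, vehicle
#'   animals only.
#' @export
normalize_secretion <- function(records, vehicle = "vehicle") {
  needed <- c("slice_id", "animal_id", "treatment",
              "baseline_pg_per_slice_h", "post_pg_per_slice_h")
  stopifnot(all(needed %in% names(records)))
  if (any(records$baseline_pg_per_slice_h <= 0)) {
    abort("baseline secretion must be positive to compute fold changes.",
          class = "calci_invalid_parameter")
  }
  if (any(records$post_pg_per_slice_h < 0)) {
    abort("post-treatment secretion must be nonnegative.",
          class = "calci_invalid_parameter")
  }
  out <- records |>
    dplyr::mutate(fold_raw = .data$post_pg_per_slice_h /
                    .data$baseline_pg_per_slice_h) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(
      vehicle_mean_fold = {
        v <- .data$fold_raw[.data$treatment == vehicle]
        if (length(v)) mean(v) else NA_real_
      },
      fold_norm = .data$fold_raw / .data$vehicle_mean_fold
    ) |>
    dplyr::ungroup()
  missing <- unique(out$animal_id[is.na(out$vehicle_mean_fold)])
  if (length(missing)) {
    warn(paste0("animal(s) without vehicle slices excluded: ",
                paste(missing, collapse = ", ")))
    out <- dplyr::filter(out, !is.na(.data$vehicle_mean_fold))
  }
  dplyr::select(out, -"vehicle_mean_fold")
}

#' Average replicate slices per animal and condition
#'
#' Each animal's 2-3 replicate slices per condition are averaged before group
#' statistics, so one animal contributes one value per condition; raw
#' per-slice folds remain available from [normalize_secretion()].
#'
#' @param normalized Output of [normalize_secretion()].
#' @param ... Additional grouping columns (e.g. `osmolarity_mOsm`), bare
#'   names.
#' @return Tibble with one row per animal x treatment (x extra groups) and
#'   columns `n_slices`, `fold_raw`, `fold_norm` (means over replicates).
#' @export
summarize_secretion <- function(normalized, ...) {
  normalized |>
    dplyr::group_by(.data$animal_id, .data$treatment, ...) |>
    dplyr::summarise(
      n_slices = dplyr::n(),
      fold_raw = mean(.data$fold_raw),
      fold_norm = mean(.data$fold_norm),
      .groups = "drop"
    )
}

fourpl <- function(x, top, bottom, mid, slope) {
  bottom + (top - bottom) / (1 + exp(-slope * (x - mid)))
}

hill_curve <- function(x, top, bottom, k, h) {
  bottom + (top - bottom) * x^h / (k^h + x^h)
}

#' Fit a four-parameter logistic (sigmoidal) curve
#'
#' `y = bottom + (top - bottom) / (1 + exp(-slope * (x - mid)))`, fitted by
#' Levenberg-Marquardt least squares with self-starting values from the data
#' quartiles and the midpoint bounded within the data range plus one span;
#' jittered restarts are tried on non-convergence. A saturating Hill form
#' (`form = "hill"`, for positive `x`) is available for activity-secretion
#' curves. Parameters are canonicalized so `top >= bottom`.
#'
#' @param data Optional data frame holding `x` and `y` columns.
#' @param x,y Column names (if `data` given) or numeric vectors.
#' @param form `"logistic4"` (default) or `"hill"`.
#' @param init Optional named list of starting values.
#' @param n_restarts Jittered restarts on failure (default 10).
#' @return A `sigmoid_fit` object with `coef` (named vector), `r_squared`,
#'   `converged`, `fitted`, `residuals`, `form`, and the data.
#' @export
fit_sigmoid <- function(data = NULL, x, y, form = c("logistic4", "hill"),
                        init = NULL, n_restarts = 10) {
  form <- match.arg(form)
  if (!is.null(data)) {
    x <- rlang::eval_tidy(rlang::enquo(x), data)
    y <- rlang::eval_tidy(rlang::enquo(y), data)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) {
    abort("need at least 5 (x, y) pairs.", class = "calci_invalid_parameter")
  }
  if (diff(range(x)) == 0) {
    abort("x values have no spread.", class = "calci_invalid_parameter")
  }
  sstot <- sum((y - mean(y))^2)
  degenerate_fit <- function() {
    structure(
      list(coef = c(top = mean(y), bottom = mean(y),
                    mid = mean(range(x)), slope = 0),
           r_squared = 0, converged = FALSE,
           fitted = rep(mean(y), length(y)), residuals = y - mean(y),
           form = form, x = x, y = y),
      class = "sigmoid_fit")
  }
  if (sstot == 0) return(degenerate_fit())

  span <- diff(range(x))
  start0 <- if (!is.null(init)) init else if (form == "logistic4") {
    list(top = max(y), bottom = min(y),
         mid = median(x),
         slope = if (cor(x, y) >= 0) 4 / span else -4 / span)
  } else {
    list(top = max(y), bottom = min(y), k = median(x), h = 2)
  }
  lower <- upper <- NULL
  if (form == "logistic4") {
    lower <- c(top = -Inf, bottom = -Inf, mid = min(x) - span, slope = -Inf)
    upper <- c(top = Inf, bottom = Inf, mid = max(x) + span, slope = Inf)
    fml <- y ~ bottom + (top - bottom) / (1 + exp(-slope * (x - mid)))
  } else {
    if (any(x <= 0)) {
      abort("the Hill form requires positive x.",
            class = "calci_invalid_parameter")
    }
    lower <- c(top = -Inf, bottom = -Inf, k = 1e-12, h = 0.1)
    upper <- c(top = Inf, bottom = Inf, k = max(x) * 100, h = 20)
    fml <- y ~ bottom + (top - bottom) * x^h / (k^h + x^h)
  }
  dat <- data.frame(x = x, y = y)
  try_fit <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(fml, data = dat, start = st,
                        lower = lower[names(st)], upper = upper[names(st)],
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
  }
  fit <- try_fit(start0)
  tries <- 0
  while (is.null(fit) && tries < n_restarts) {
    tries <- tries + 1
    st <- purrr::map(start0, function(v) v * exp(rnorm(1, 0, 0.3)) +
                       rnorm(1, 0, 0.05 * (abs(v) + 1e-6)))
    fit <- try_fit(st)
  }
  if (is.null(fit)) return(degenerate_fit())

  cf <- stats::coef(fit)
  if (form == "logistic4" && cf["top"] < cf["bottom"]) {
    # same curve under (top <-> bottom, slope <- -slope)
    cf[c("top", "bottom")] <- cf[c("bottom", "top")]
    cf["slope"] <- -cf["slope"]
  }
  fitted <- if (form == "logistic4") {
    fourpl(x, cf["top"], cf["bottom"], cf["mid"], cf["slope"])
  } else {
    hill_curve(x, cf["top"], cf["bottom"], cf["k"], cf["h"])
  }
  ssres <- sum((y - fitted)^2)
  structure(
    list(coef = cf, r_squared = 1 - ssres / sstot, converged = TRUE,
         fitted = fitted, residuals = y - fitted, form = form, x = x, y = y),
    class = "sigmoid_fit")
}

#' Evaluate a fitted sigmoid at new x
#' @param object A `sigmoid_fit`.
#' @param newdata Optional numeric vector of x values.
#' @param ... Unused.
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$x
  cf <- object$coef
  if (object$form == "logistic4") {
    fourpl(x, cf["top"], cf["bottom"], cf["mid"], cf["slope"])
  } else {
    hill_curve(x, cf["top"], cf["bottom"], cf["k"], cf["h"])
  }
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit>", x$form,
      if (x$converged) "(converged)" else "(DID NOT CONVERGE)", "\n")
  print(round(x$coef, 6))
  cat(sprintf("  R^2 = %.4f on %d points\n", x$r_squared, length(x$x)))
  invisible(x)
}

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, converged = x$converged,
                 n = length(x$x), form = x$form)
}
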