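#' Load concentration / biomass time series
#'
#' Reads a CSV (or takes a data.frame) with columns `component`,
#' `condition`, `replicate`, `day`, `value` and optionally
#' `water_content` (fraction of fresh weight that is water). Values are
#' amounts per gDW; when `water_content` is present, per-gFW values are
#' converted with [convert_fw_to_dw()] into a `value_dw` column.
#'
#' @param x path to a CSV file or a data.frame.
#' @return validated data.frame of class `concentration_series`.
#' @export
load_concentration_series <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else
    as.data.frame(x)
  need <- c("component", "condition", "replicate", "day", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("day", "value"))
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column '", col, "'")
  if (any(df$value < 0))
    stop("negative value in row(s): ",
         paste(utils::head(which(df$value < 0), 5L), collapse = ", "))
  key <- interaction(df$component, df$condition, df$replicate, df$day, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (component, condition, replicate, day) row(s): ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
  if ("water_content" %in% names(df)) {
    df$value_dw <- convert_fw_to_dw(df$value, df$water_content)
  }
  df <- df[order(df$component, df$condition, df$replicate, df$day), ]
  rownames(df) <- NULL
  class(df) <- c("concentration_series", "data.frame")
  df
}

#' Convert a per-gFW amount into per-gDW
#'
#' Divides by the dry fraction: `value / (1 - water_content)`. The water
#' content is the mass fraction lost on lyophilisation.
#'
#' @param value_per_gFW amount per gram fresh weight.
#' @param water_content_fraction water mass fraction, in `[0, 1)`.
#' @return amount per gram dry weight.
#' @export
#' @examples
#' convert_fw_to_dw(1.0, 0.9)  # 10
convert_fw_to_dw <- function(value_per_gFW, water_content_fraction) {
  if (any(water_content_fraction < 0 | water_content_fraction >= 1))
    stop("water_content_fraction must be in [0, 1)")
  value_per_gFW / (1 - water_content_fraction)
}

#' Replicate means of a series
#' @keywords internal
replicate_means <- function(series, component, condition, value_col = "value") {
  sel <- series[series$component == component & series$condition == condition, ]
  if (nrow(sel) == 0L)
    stop("no data for component '", component, "', condition '", condition, "'")
  agg <- stats::aggregate(sel[[value_col]], by = list(day = sel$day), FUN = mean)
  names(agg)[2L] <- "mean"
  agg$n_reps <- as.numeric(table(sel$day)[as.character(agg$day)])
  agg[order(agg$day), ]
}

#' Fit a smooth curve to a concentration time course
#'
#' Fits the replicate means (one mean per day) of one `(component,
#' condition)` series. The default `"spline"` method is a penalized cubic
#' regression: a full cubic polynomial basis plus truncated cubic terms at
#' the interior days, with a ridge penalty on the truncated coefficients
#' only, so every polynomial of degree <= 3 is reproduced exactly on
#' noiseless data while noisy data are smoothed. The penalty is chosen by
#' generalized cross-validation over a fixed grid, which makes the fit
#' deterministic and seedless. Series with fewer than 4 distinct days fall
#' back to a quadratic (3 days) or straight line (2 days).
#'
#' @param series a `concentration_series` (or compatible data.frame).
#' @param component,condition which series to fit.
#' @param method `"spline"`, `"quadratic"` or `"linear"`; `"auto"`
#'   (default) picks by the number of distinct days.
#' @param lambda optional fixed smoothing parameter overriding GCV.
#' @param value_col column to fit (`"value"` or `"value_dw"`).
#' @return object of class `fitted_curve` with `coefficients`, `knots`,
#'   `domain`, `method`, `residual_summary`, `n_reps`.
#' @export
fit_concentration_curve <- function(series, component, condition,
                                    method = c("auto", "spline", "quadratic", "linear"),
                                    lambda = NULL, value_col = "value") {
  method <- match.arg(method)
  means <- replicate_means(series, component, condition, value_col)
  x <- means$day; y <- means$mean
  nd <- length(unique(x))
  if (nd < 2L) stop("need >= 2 distinct days to fit a curve")
  if (method == "auto") method <- if (nd >= 4L) "spline" else
    if (nd == 3L) "quadratic" else "linear"
  if (method == "spline" && nd < 4L)
    stop("spline fit needs >= 4 distinct days; got ", nd)
  if (method == "quadratic" && nd < 3L)
    stop("quadratic fit needs >= 3 distinct days; got ", nd)

  if (method == "linear") {
    co <- unname(stats::coef(stats::lm(y ~ x)))
    fit <- list(poly = c(co, 0, 0), trunc = numeric(0L), knots = numeric(0L))
    fitted <- co[1L] + co[2L] * x
  } else if (method == "quadratic") {
    co <- unname(stats::coef(stats::lm(y ~ x + I(x^2))))
    fit <- list(poly = c(co, 0), trunc = numeric(0L), knots = numeric(0L))
    fitted <- co[1L] + co[2L] * x + co[3L] * x^2
  } else {
    knots <- sort(unique(x))
    knots <- knots[-c(1L, length(knots))]          # interior days
    B <- cbind(1, x, x^2, x^3,
               vapply(knots, function(k) pmax(0, x - k)^3, numeric(length(x))))
    npoly <- 4L; ntr <- length(knots)
    Dpen <- diag(c(rep(0, npoly), rep(1, ntr)))
    solve_pen <- function(lam) {
      # ridge only on truncated terms; polynomial part unpenalized
      co <- solve(crossprod(B) + lam * Dpen + diag(1e-12, ncol(B)), crossprod(B, y))
      as.numeric(co)
    }
    if (is.null(lambda)) {
      grid <- 10^seq(-6, 6, by = 0.5)
      gcv <- vapply(grid, function(lam) {
        H <- B %*% solve(crossprod(B) + lam * Dpen + diag(1e-12, ncol(B)), t(B))
        res <- y - as.numeric(H %*% y)
        edf <- sum(diag(H))
        n <- length(y)
        sum(res^2) / (n * (1 - min(edf, n - 0.5) / n)^2)
      }, numeric(1L))
      lambda <- grid[which.min(gcv)]
    }
    co <- solve_pen(lambda)
    fit <- list(poly = co[seq_len(npoly)], trunc = co[-seq_len(npoly)],
                knots = knots, lambda = lambda)
    fitted <- as.numeric(B %*% co)
  }
  structure(list(component_id = component, condition = condition,
                 method = method, coefficients = fit,
                 domain = range(x), n_reps = means$n_reps,
                 days = x,
                 residual_summary = c(rmse = sqrt(mean((y - fitted)^2)))),
            class = "fitted_curve")
}

#' Evaluate a fitted curve or its derivative
#'
#' @param object a `fitted_curve`.
#' @param day days at which to evaluate (must be inside the fit domain; no
#'   extrapolation).
#' @param deriv 0 for the value, 1 for the first derivative.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.fitted_curve <- function(object, day, deriv = 0, ...) {
  if (any(day < object$domain[1L] - 1e-9 | day > object$domain[2L] + 1e-9))
    stop("day outside the fitted domain [", object$domain[1L], ", ",
         object$domain[2L], "]; no extrapolation")
  p <- object$coefficients$poly
  k <- object$coefficients$knots
  tr <- object$coefficients$trunc
  if (deriv == 0) {
    out <- p[1L] + p[2L] * day + p[3L] * day^2 + p[4L] * day^3
    for (i in seq_along(k)) out <- out + tr[i] * pmax(0, day - k[i])^3
  } else if (deriv == 1) {
    out <- p[2L] + 2 * p[3L] * day + 3 * p[4L] * day^2
    for (i in seq_along(k)) out <- out + 3 * tr[i] * pmax(0, day - k[i])^2
  } else stop("deriv must be 0 or 1")
  out
}

#' @export
print.fitted_curve <- function(x, ...) {
  cat("Fitted curve for", x$component_id, "(", x$condition, ") method:",
      x$method, "; domain", x$domain[1L], "-", x$domain[2L],
      "; rmse", format(x$residual_summary[["rmse"]], digits = 3), "\n")
  invisible(x)
}

#' Turn a fitted concentration curve into an exchange-flux constraint
#'
#' The snapshot constraint for a day is the derivative of the fitted
#' content curve at that day, in mmol/gDW/day: positive means net
#' accumulation in the cells, mapped onto the component's exchange or
#' synthesis reaction. A standard error is attached when per-replicate
#' curves can be fitted (attribute `"se"`).
#'
#' @param curve a `fitted_curve`.
#' @param day snapshot day (inside the fit domain; boundary days use the
#'   one-sided derivative of the fitted curve).
#' @param reaction_id reaction the constraint maps to (default: the
#'   component id).
#' @param series optional original series; when given, one curve per
#'   replicate is fitted and the standard error of the derivative across
#'   replicates is attached.
#' @return one-row constraint data.frame (see [flux_constraint()]) with
#'   attribute `se`.
#' @export
estimate_exchange_flux <- function(curve, day, reaction_id = curve$component_id,
                                   series = NULL) {
  value <- predict(curve, day, deriv = 1)
  con <- flux_constraint(reaction_id, value, tolerance = 0, day = day,
                         condition = curve$condition)
  if (!is.null(series)) {
    sel <- series[series$component == curve$component_id &
                    series$condition == curve$condition, ]
    reps <- unique(sel$replicate)
    if (length(reps) >= 2L) {
      dvs <- vapply(reps, function(r) {
        one <- sel[sel$replicate == r, ]
        one$replicate <- 1L
        cv <- tryCatch(
          fit_concentration_curve(one, curve$component_id, curve$condition,
                                  method = curve$method),
          error = function(e) NULL)
        if (is.null(cv)) NA_real_ else predict(cv, day, deriv = 1)
      }, numeric(1L))
      dvs <- dvs[is.finite(dvs)]
      if (length(dvs) >= 2L)
        attr(con, "se") <- stats::sd(dvs) / sqrt(length(dvs))
    }
  }
  con
}

#' Round half away from zero
#'
#' Commercial rounding: exact halves go up (`1.25 -> 1.3` at one digit),
#' unlike [round()]'s round-half-to-even. Used for reported fold
#' changes. A tiny epsilon guards against values like `1.25` being
#' stored just below the half due to binary representation.
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-12) / m
}

#' Growth fold change between two days
#'
#' Ratio of the replicate-mean biomass at `day_to` over `day_from`,
#' rounded half-up to one decimal (so 197.6 / 160 = 1.235 reports as 1.2).
#'
#' @param series a `concentration_series` holding fresh-weight biomass.
#' @param component biomass component id (default `"FW"`).
#' @param condition condition label.
#' @param day_from,day_to the two days compared.
#' @return data.frame with `condition`, `day_from`, `day_to`, `mean_from`,
#'   `mean_to`, `fold_change`.
#' @export
summarize_growth <- function(series, condition, day_from, day_to,
                             component = "FW") {
  means <- replicate_means(series, component, condition)
  m_from <- means$mean[means$day == day_from]
  m_to <- means$mean[means$day == day_to]
  if (length(m_from) != 1L || length(m_to) != 1L)
    stop("both day_from and day_to must be present in the series")
  if (m_from == 0) stop("mean at day_from is zero; fold change undefined")
  data.frame(condition = condition, day_from = day_from, day_to = day_to,
             mean_from = m_from, mean_to = m_to,
             fold_change = round_half_up(m_to / m_from, 1L))
}
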