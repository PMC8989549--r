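#' Fit a Hill dose-response curve
#'
#' Least-squares fit of the four-parameter Hill model
#' \deqn{y(c) = baseline + (max - baseline) \cdot c^h / (EC_{50}^h + c^h)}
#' by Levenberg-Marquardt ([minpack.lm::nlsLM()]) with positivity bounds on
#' `ec50` and `hill`. In `repression` mode the response decreases with
#' concentration (`max < baseline`); the same parameterization is used, only
#' the starting values differ.
#'
#' @param data Tibble with columns `ligand_conc` (mM, must include 0 and at
#'   least 4 distinct values) and `response`.
#' @param mode `"activation"` or `"repression"`.
#' @param scale `"linear"` minimizes squared residuals of the response
#'   itself; `"log"` minimizes them on the log scale, which is the efficient
#'   choice when measurement error is multiplicative (constant CV), as
#'   fluorescence ratios typically are. Requires strictly positive
#'   responses.
#' @return A `dose_fit` object with [tidy()], [glance()], [autoplot()],
#'   `predict()` and `print()` methods.
#' @examples
#' concs <- c(0, 0.1, 0.3, 1, 3, 10)
#' d <- tibble::tibble(
#'   ligand_conc = concs,
#'   response = 1 + 19 * concs / (1.6 + concs)
#' )
#' fit <- fit_dose_response(d)
#' tidy(fit)
#' @export
fit_dose_response <- function(data, mode = c("activation", "repression"),
                              scale = c("linear", "log")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  if (!all(c("ligand_conc", "response") %in% names(data))) {
    abort("`data` must have columns `ligand_conc` and `response`.")
  }
  concs <- data$ligand_conc
  y <- data$response
  if (length(unique(concs)) < 4 || !any(concs == 0)) {
    abort("Need >= 4 distinct concentrations including 0.")
  }
  if (diff(range(y)) < 1e-12 * max(abs(y), 1)) {
    abort("Response is constant; the dose-response fit is degenerate.",
          class = "dropswitch_degenerate_fit")
  }
  y0 <- mean(y[concs == 0])
  start <- list(
    baseline = y0,
    max_response = if (mode == "activation") max(y) else min(y),
    ec50 = max(median(concs[concs > 0]), 1e-6),
    hill = 1
  )
  if (scale == "log" && any(y <= 0)) {
    abort("Log-scale fitting requires strictly positive responses.")
  }
  hill_curve <- response ~ baseline + (max_response - baseline) *
    ifelse(ligand_conc == 0, 0,
           ligand_conc^hill / (ec50^hill + ligand_conc^hill))
  log_hill_curve <- log_response ~ log(
    baseline + (max_response - baseline) *
      ifelse(ligand_conc == 0, 0,
             ligand_conc^hill / (ec50^hill + ligand_conc^hill))
  )
  fit_data <- as_tibble(data)
  fit_data$log_response <- log(pmax(y, .Machine$double.xmin))
  lo <- c(baseline = if (scale == "log") 1e-12 else 0,
          max_response = if (scale == "log") 1e-12 else 0,
          ec50 = 1e-9, hill = 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      if (scale == "log") log_hill_curve else hill_curve,
      data = fit_data, start = start,
      lower = lo,
      upper = c(baseline = Inf, max_response = Inf, ec50 = Inf, hill = 50),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      abort(paste0("Dose-response fit did not converge: ",
                   conditionMessage(e)),
            class = "dropswitch_fit_error")
    }
  )
  est <- coef(fit)
  direction_ok <- if (mode == "activation") {
    est["max_response"] >= est["baseline"]
  } else {
    est["max_response"] <= est["baseline"]
  }
  if (!direction_ok) {
    warn(sprintf("Fitted curve is not %s as requested; check `mode`.",
                 if (mode == "activation") "increasing" else "decreasing"))
  }
  structure(
    list(fit = fit, mode = mode, scale = scale, data = as_tibble(data),
         coef = est, residual_norm = sqrt(sum(resid(fit)^2))),
    class = "dose_fit"
  )
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_fit> %s Hill curve: baseline %.3g, max %.3g, EC50 %.3g mM, hill %.3g\n",
    x$mode, x$coef["baseline"], x$coef["max_response"], x$coef["ec50"],
    x$coef["hill"]
  ))
  cat(sprintf("  residual norm %.3g on %d points\n", x$residual_norm,
              nrow(x$data)))
  invisible(x)
}

#' @rdname fit_dose_response
#' @param x,object A `dose_fit`.
#' @param ... Unused.
#' @method tidy dose_fit
#' @export
tidy.dose_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_dose_response
#' @method glance dose_fit
#' @export
glance.dose_fit <- function(x, ...) {
  tibble(
    mode = x$mode,
    ec50 = unname(x$coef["ec50"]),
    hill = unname(x$coef["hill"]),
    baseline = unname(x$coef["baseline"]),
    max_response = unname(x$coef["max_response"]),
    residual_norm = x$residual_norm,
    n = nrow(x$data)
  )
}

#' @export
predict.dose_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  est <- object$coef
  cc <- newdata$ligand_conc
  frac <- ifelse(cc == 0, 0,
                 cc^est["hill"] / (est["ec50"]^est["hill"] + cc^est["hill"]))
  unname(est["baseline"] + (est["max_response"] - est["baseline"]) * frac)
}

#' @rdname fit_dose_response
#' @method autoplot dose_fit
#' @export
autoplot.dose_fit <- function(object, ...) {
  concs <- object$data$ligand_conc
  pos <- concs[concs > 0]
  grid_pos <- exp(seq(log(min(pos)) - 1, log(max(pos)) + 0.2,
                      length.out = 200))
  grid <- tibble(ligand_conc = c(0, grid_pos))
  grid$response <- predict(object, grid)
  shift <- min(pos) / 10  # plotting position for the zero-ligand points
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = pmax(.data$ligand_conc, shift),
                               y = .data$response)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "ligand (mM, log scale; leftmost points are 0)",
      y = "corrected response",
      title = sprintf("Hill fit: EC50 = %.3g mM, hill = %.2g",
                      object$coef["ec50"], object$coef["hill"])
    )
}
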