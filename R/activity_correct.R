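# The core correction: negative-control regressions, FC normalization,
# adjusted indel frequency X, activity-corrected viability v.
#
# FC_norm = FC_raw / FC_0,   FC_0 = intercept of OLS fc_raw ~ indel_obs
#                                   over negative controls
# X       = 1 - FC_norm + FC_norm * indel_obs
# v       = (FC_norm - (1 - X)) / (FC_v=1(X) - (1 - X)),
#           FC_v=1(X) = a*X + b from OLS fc_norm ~ X over controls,
#           FC_v=0    = 1 - X  (zero viability of edited cells).

#' Fit the two negative-control regression lines
#'
#' Regression 1 (fold change on observed indel frequency) yields `FC_0`, the
#' fold change of a hypothetical zero-activity control, as its intercept.
#' Controls are then normalized (`fc_norm = fc_raw / FC_0`) and converted to
#' X, and regression 2 (normalized fold change on X) defines the `v = 1`
#' reference line `FC_v=1(X) = slope2 * X + intercept2`, absorbing the mild
#' fitness cost of cutting itself (DNA damage response): its slope estimates
#' that cost.
#'
#' @param quant a quant tibble carrying a `role` column (see
#'   [correct_screen()], which joins it from the library), QC applied.
#' @return a `control_fit`: `fc0`, `slope1`, `intercept1`, `slope2`,
#'   `intercept2`, `n_controls`.
#' @details Errors when fewer than 3 usable controls remain, when control
#'   indel frequencies have zero variance (both regressions undefined), or
#'   when the fitted `FC_0` is not positive.
#' @export
fit_controls <- function(quant) {
  if (!"role" %in% names(quant)) {
    stop("quant must carry a 'role' column (join the library first)",
         call. = FALSE)
  }
  ctrl <- quant[quant$role == "negative_control" & quant$qc_pass &
                  !is.na(quant$indel_obs) & is.finite(quant$fc_raw), ,
                drop = FALSE]
  if (nrow(ctrl) < 3) {
    stop("need >= 3 QC-passing negative controls with defined indel_obs, got ",
         nrow(ctrl), call. = FALSE)
  }
  if (stats::var(ctrl$indel_obs) == 0) {
    stop("control indel frequencies have zero variance; regression undefined",
         call. = FALSE)
  }
  fit1 <- stats::lm(fc_raw ~ indel_obs, data = ctrl)
  c1 <- stats::coef(fit1)
  fc0 <- unname(c1[1])
  if (!is.finite(fc0) || fc0 <= 0) {
    stop("fitted FC_0 must be positive, got ", format(fc0), call. = FALSE)
  }
  fc_norm <- ctrl$fc_raw / fc0
  x <- 1 - fc_norm + fc_norm * ctrl$indel_obs
  fit2 <- stats::lm(fc_norm ~ x)
  c2 <- stats::coef(fit2)
  structure(list(fc0 = fc0,
                 slope1 = unname(c1[2]), intercept1 = fc0,
                 slope2 = unname(c2[2]), intercept2 = unname(c2[1]),
                 n_controls = nrow(ctrl)),
            class = "control_fit")
}

#' @export
print.control_fit <- function(x, ...) {
  cat("<control_fit> n =", x$n_controls, "controls\n")
  cat(sprintf("  FC_0 = %.4f (regression 1: fc_raw = %.4f + %.4f * indel_obs)\n",
              x$fc0, x$intercept1, x$slope1))
  cat(sprintf("  FC_v=1(X) = %.4f + %.4f * X\n", x$intercept2, x$slope2))
  invisible(x)
}

#' Manually specify a control fit
#'
#' Useful for the no-correction reference (`control_fit_identity()` is
#' `FC_0 = 1`, `FC_v=1(X) = 1`) and for testing.
#' @param fc0,slope1,slope2,intercept2,n_controls components; see
#'   [fit_controls()].
#' @return a `control_fit`.
#' @export
control_fit_manual <- function(fc0 = 1, slope1 = 0, slope2 = 0,
                               intercept2 = 1, n_controls = 0L) {
  if (fc0 <= 0) stop("fc0 must be positive", call. = FALSE)
  structure(list(fc0 = fc0, slope1 = slope1, intercept1 = fc0,
                 slope2 = slope2, intercept2 = intercept2,
                 n_controls = as.integer(n_controls)),
            class = "control_fit")
}

#' @rdname control_fit_manual
#' @export
control_fit_identity <- function() control_fit_manual()

#' Normalize a raw fold change by the zero-activity control fold change
#' @param fc_raw numeric vector of raw fold changes.
#' @param fit a `control_fit`.
#' @return `fc_raw / fit$fc0`.
#' @export
normalize_fc <- function(fc_raw, fit) {
  stopifnot(inherits(fit, "control_fit"))
  if (fit$fc0 <= 0) stop("FC_0 must be positive", call. = FALSE)
  fc_raw / fit$fc0
}

#' Adjusted ("actual") indel frequency X
#'
#' `X = 1 - fc_norm + fc_norm * indel_obs`: the observed indel frequency is
#' under-represented by `FC - 1` because edited cells drop out together with
#' their reporters; X undoes that depletion. With `fc_norm = 1` (no
#' dropout) X equals the observed indel frequency; with `indel_obs = 1` it
#' is 1 for any fold change.
#'
#' @param fc_norm normalized fold change(s), >= 0.
#' @param indel_obs observed indel frequency in `[0, 1]` (NA propagates).
#' @return tibble with `x_raw` (unclipped), `x_adj` (clipped to `[0, 1]`)
#'   and `clipped` flag.
#' @export
compute_x <- function(fc_norm, indel_obs) {
  x_raw <- 1 - fc_norm + fc_norm * indel_obs
  x_adj <- pmin(pmax(x_raw, 0), 1)
  tibble::tibble(x_raw = x_raw, x_adj = x_adj,
                 clipped = !is.na(x_raw) & x_raw != x_adj)
}

#' Activity-corrected viability v
#'
#' `v = (fc_norm - (1 - x)) / (FC_v=1(x) - (1 - x))` with
#' `FC_v=1(x) = slope2 * x + intercept2` from the control fit and
#' `FC_v=0 = 1 - x`. v = 0 at the theoretical-minimum fold change (all
#' edited cells die) and v = 1 on the control line (no fitness effect beyond
#' the cutting cost). v is deliberately not clipped: values above 1 indicate
#' enrichment.
#'
#' @param fc_norm normalized fold change(s).
#' @param x adjusted indel frequency (normally `x_adj` from [compute_x()]).
#' @param fit a `control_fit`.
#' @param x_min reliability threshold (default 0.05): below it the `v=0` and
#'   `v=1` reference lines converge and small fold-change noise is amplified
#'   into large v fluctuations, so v is flagged unreliable (kept, not
#'   removed). X > 0.44 is the moderate-to-high-activity range in which the
#'   correction is best behaved.
#' @param eps denominators smaller than `eps` in magnitude (default 1e-6 on
#'   the fold-change scale) make v undefined (`NA`, flagged `degenerate`).
#' @return tibble with `v`, `reliable` (`x >= x_min`), `degenerate`.
#' @export
compute_v <- function(fc_norm, x, fit, x_min = 0.05, eps = 1e-6) {
  stopifnot(inherits(fit, "control_fit"))
  fc_v1 <- fit$slope2 * x + fit$intercept2
  denom <- fc_v1 - (1 - x)
  degenerate <- !is.na(denom) & abs(denom) < eps
  v <- ifelse(degenerate, NA_real_, (fc_norm - (1 - x)) / denom)
  tibble::tibble(v = v,
                 reliable = !is.na(x) & x >= x_min & !degenerate,
                 degenerate = degenerate)
}

#' One-call correction pipeline over a quantified sample
#'
#' Joins guide roles from the library, fits the control regressions on
#' QC-passing negative controls, and computes `fc_norm`, X and v for every
#' QC-passing guide (controls included).
#'
#' @param quant output of [compute_quant()] (+ [apply_qc()]; if `qc_pass` is
#'   absent all guides pass).
#' @param library a `guide_library`, or any data frame with `guide_id`,
#'   `gene`, `role`.
#' @param x_min,eps see [compute_v()].
#' @param fit optional pre-computed `control_fit` (skips fitting).
#' @return list with `metrics` (tibble `guide_id`, `gene`, `role`, `fc_raw`,
#'   `fc_norm`, `indel_obs`, `x_raw`, `x_adj`, `clipped`, `v`, `reliable`,
#'   `qc_pass`) and `fit` (the `control_fit` used).
#' @export
correct_screen <- function(quant, library, x_min = 0.05, eps = 1e-6,
                           fit = NULL) {
  if (!"qc_pass" %in% names(quant)) quant$qc_pass <- TRUE
  ann <- as.data.frame(library)[, c("guide_id", "gene", "role")]
  missing_g <- setdiff(quant$guide_id, ann$guide_id)
  if (length(missing_g) > 0) {
    stop("guides absent from library: ",
         paste(utils::head(missing_g, 5), collapse = ", "), call. = FALSE)
  }
  quant <- dplyr::left_join(quant, ann, by = "guide_id")
  if (!any(quant$role == "negative_control")) {
    stop("library has no negative_control guides; declare neutral-gene ",
         "guides as controls to use this correction", call. = FALSE)
  }
  if (is.null(fit)) fit <- fit_controls(quant)
  fc_norm <- normalize_fc(quant$fc_raw, fit)
  xs <- compute_x(fc_norm, quant$indel_obs)
  vs <- compute_v(fc_norm, xs$x_adj, fit, x_min = x_min, eps = eps)
  metrics <- tibble::tibble(
    guide_id = quant$guide_id,
    gene = quant$gene,
    role = quant$role,
    fc_raw = quant$fc_raw,
    fc_norm = fc_norm,
    indel_obs = quant$indel_obs,
    x_raw = xs$x_raw,
    x_adj = xs$x_adj,
    clipped = xs$clipped,
    v = vs$v,
    reliable = vs$reliable,
    qc_pass = quant$qc_pass
  )
  blank <- !metrics$qc_pass
  metrics[blank, c("fc_norm", "x_raw", "x_adj", "v")] <- NA_real_
  metrics$reliable[blank] <- FALSE
  list(metrics = metrics, fit = fit)
}

#' Write screen metrics (TSV) and the control fit (JSON)
#' @param result output of [correct_screen()].
#' @param metrics_path TSV path for the per-guide metrics.
#' @param fit_path optional JSON path for the control fit.
#' @export
write_metrics <- function(result, metrics_path, fit_path = NULL) {
  utils::write.table(as.data.frame(result$metrics), metrics_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fit_path)) {
    jsonlite::write_json(unclass(result$fit), fit_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(metrics_path)
}
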