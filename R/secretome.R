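#' Assemble a multiplex immunoassay panel
#'
#' Container for raw bead-based multiplex (Luminex-style) readouts: median
#' fluorescence intensities (MFI) per analyte/donor/condition/day, together
#' with per-analyte blanks, standard series and limits of quantification.
#'
#' @param measurements data.frame `analyte, donor, condition, day, mfi`.
#' @param standards data.frame `analyte, concentration, mfi`.
#' @param blanks data.frame `analyte, mfi`.
#' @param loq data.frame `analyte, lloq, uloq` (lower/upper limits of
#'   quantification, concentration scale; `lloq < uloq`).
#' @return an object of class `secretome_panel`.
#' @export
secretome_panel <- function(measurements, standards, blanks, loq) {
  need <- function(df, cols, what) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (!all(cols %in% names(df))) {
      stop(what, " must have columns: ", paste(cols, collapse = ", "))
    }
    df
  }
  measurements <- need(measurements,
                       c("analyte", "donor", "condition", "day", "mfi"),
                       "measurements")
  standards <- need(standards, c("analyte", "concentration", "mfi"),
                    "standards")
  blanks <- need(blanks, c("analyte", "mfi"), "blanks")
  loq <- need(loq, c("analyte", "lloq", "uloq"), "loq")
  bad <- loq$analyte[loq$lloq >= loq$uloq]
  if (length(bad)) stop("lloq >= uloq for analyte: ", bad[1])
  structure(list(measurements = measurements, standards = standards,
                 blanks = blanks, loq = loq, blank_subtracted = FALSE),
            class = "secretome_panel")
}

#' @export
print.secretome_panel <- function(x, ...) {
  cat(sprintf("secretome_panel: %d analytes, %d measurements (%s)\n",
              length(unique(x$measurements$analyte)),
              nrow(x$measurements),
              if (x$blank_subtracted) "net MFI" else "raw MFI"))
  invisible(x)
}

#' Read / write a secretome panel as CSV files
#'
#' The CSV dialect is four files in one directory: `measurements.csv`
#' (`analyte, donor, condition, day, mfi`), `standards.csv`
#' (`analyte, concentration, mfi`), `blanks.csv` (`analyte, mfi`) and
#' `loq.csv` (`analyte, lloq, uloq`).
#'
#' @param dir directory containing (or to receive) the four CSVs.
#' @return `read_secretome_panel()` returns a `secretome_panel`;
#'   `write_secretome_panel()` returns `invisible(panel)`.
#' @export
read_secretome_panel <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing panel file: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  secretome_panel(rd("measurements.csv"), rd("standards.csv"),
                  rd("blanks.csv"), rd("loq.csv"))
}

#' @rdname read_secretome_panel
#' @param panel a `secretome_panel`.
#' @export
write_secretome_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(panel$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(panel$standards, file.path(dir, "standards.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(panel$blanks, file.path(dir, "blanks.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(panel$loq, file.path(dir, "loq.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(panel)
}

#' Subtract per-analyte blank MFI
#'
#' Replaces measurement MFIs by net MFI (`mfi - blank`, floored at 0; floored
#' values are flagged in a `floored` column).
#'
#' @param panel a `secretome_panel`.
#' @return the panel with net MFIs and `blank_subtracted = TRUE`.
#' @export
subtract_blank <- function(panel) {
  stopifnot(inherits(panel, "secretome_panel"))
  m <- panel$measurements
  missing <- setdiff(unique(m$analyte), panel$blanks$analyte)
  if (length(missing)) {
    stop("no blank for analyte: ", paste(missing, collapse = ", "))
  }
  bl <- stats::setNames(panel$blanks$mfi, panel$blanks$analyte)
  net <- m$mfi - bl[m$analyte]
  m$floored <- net < 0
  m$mfi <- pmax(net, 0)
  panel$measurements <- m
  panel$blank_subtracted <- TRUE
  panel
}

# five-parameter logistic, increasing in concentration:
# y = D + (A - D) / (1 + (x / C)^B)^G, lower asymptote A, upper D
pl5 <- function(conc, A, D, C, B, G) {
  D + (A - D) / (1 + (conc / C)^B)^G
}

#' Fit a five-parameter logistic standard curve
#'
#' Least-squares fit of the 5PL form
#' \deqn{y = D + \frac{A - D}{(1 + (x/C)^B)^G}}
#' (lower asymptote `A`, upper asymptote `D`, inflection-scale `C`, slope
#' `B`, asymmetry `G`) to a standard series, by Levenberg-Marquardt. With
#' fewer than 5 distinct concentrations the asymmetry is fixed at 1 (4PL)
#' and the curve is flagged `fallback_4pl`.
#'
#' Fitting is by weighted least squares with `1 / mfi^2` weights (constant
#' relative error, the usual immunoassay noise structure); a curve that
#' cannot be fitted (too few points for the parameter count, or a failed
#' optimization) is returned unfitted with `converged = FALSE`.
#'
#' @param standards data.frame with columns `concentration` and `mfi`
#'   (concentrations > 0).
#' @return an object of class `pl5_curve`: parameters, `converged` flag,
#'   residual norm, `fallback_4pl` flag and the data range fitted.
#' @export
fit_5pl <- function(standards) {
  standards <- as.data.frame(standards)
  stopifnot(all(c("concentration", "mfi") %in% names(standards)))
  x <- standards$concentration
  y <- standards$mfi
  stopifnot(all(x > 0), length(x) >= 3)
  fallback <- length(unique(x)) < 5
  w <- 1 / pmax(y, 1)^2

  a0 <- min(y); d0 <- max(y)
  c0 <- exp(stats::weighted.mean(log(x), w = 1 / (1 + abs(y - (a0 + d0) / 2))))
  start <- list(A = a0, D = d0, C = c0, B = 1, G = 1)
  lower <- c(A = -0.1 * d0, D = 0.5 * d0, C = min(x) / 1e3, B = 0.05, G = 0.02)
  upper <- c(A = a0 + 0.5 * (d0 - a0), D = 10 * d0, C = max(x) * 1e3,
             B = 20, G = 50)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14)

  npar <- if (fallback) 4L else 5L
  if (length(y) < npar) {
    return(structure(list(par = NULL, converged = FALSE,
                          residual_norm = NA_real_, fallback_4pl = fallback,
                          conc_range = range(x)), class = "pl5_curve"))
  }
  fit <- if (fallback) {
    try(minpack.lm::nlsLM(
      y ~ D + (A - D) / (1 + (x / C)^B),
      start = start[c("A", "D", "C", "B")],
      lower = lower[c("A", "D", "C", "B")],
      upper = upper[c("A", "D", "C", "B")],
      weights = w, control = ctrl), silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(
      y ~ D + (A - D) / (1 + (x / C)^B)^G,
      start = start, lower = lower, upper = upper,
      weights = w, control = ctrl), silent = TRUE)
  }

  if (inherits(fit, "try-error")) {
    return(structure(list(par = NULL, converged = FALSE,
                          residual_norm = NA_real_, fallback_4pl = fallback,
                          conc_range = range(x)), class = "pl5_curve"))
  }
  par <- as.list(stats::coef(fit))
  if (fallback) par$G <- 1
  res <- y - pl5(x, par$A, par$D, par$C, par$B, par$G)
  structure(list(par = par,
                 converged = par$D > par$A,
                 residual_norm = sqrt(sum(res^2)),
                 fallback_4pl = fallback,
                 conc_range = range(x)),
            class = "pl5_curve")
}

#' @export
print.pl5_curve <- function(x, ...) {
  if (is.null(x$par)) {
    cat("pl5_curve: fit failed\n")
    return(invisible(x))
  }
  cat(sprintf("pl5_curve%s: A=%.4g D=%.4g C=%.4g B=%.4g G=%.4g (rss %.3g)\n",
              if (x$fallback_4pl) " [4PL fallback]" else "",
              x$par$A, x$par$D, x$par$C, x$par$B, x$par$G, x$residual_norm^2))
  invisible(x)
}

#' @export
coef.pl5_curve <- function(object, ...) unlist(object$par)

#' Predicted MFI of a fitted standard curve
#' @param object a `pl5_curve`.
#' @param newdata numeric concentrations (or data.frame with a
#'   `concentration` column).
#' @param ... unused.
#' @return numeric predicted MFI.
#' @export
predict.pl5_curve <- function(object, newdata, ...) {
  conc <- if (is.data.frame(newdata)) newdata$concentration else newdata
  p <- object$par
  pl5(conc, p$A, p$D, p$C, p$B, p$G)
}

#' Invert a fitted 5PL curve (MFI to concentration)
#'
#' Closed-form inversion between the asymptotes, censored into the
#' quantification window: MFI at or below the lower asymptote, or
#' inverting below the lower LOQ, is reported as the lower LOQ with a
#' `"lower"` censor flag; symmetrically at the top. Censoring is flagged,
#' never thrown, and the reported concentration is non-decreasing in MFI.
#'
#' @param curve a fitted `pl5_curve`.
#' @param mfi numeric net MFI value(s).
#' @param lloq,uloq limits of quantification bounding the reported value.
#' @return data.frame with columns `conc` and `censor`
#'   (`"none"`, `"lower"` or `"upper"`).
#' @export
invert_5pl <- function(curve, mfi, lloq, uloq) {
  if (is.null(curve$par)) stop("cannot invert an unfitted curve")
  p <- curve$par
  conc <- rep(NA_real_, length(mfi))
  low <- mfi <= p$A
  high <- mfi >= p$D
  mid <- !low & !high
  conc[low] <- lloq
  conc[high] <- uloq
  y <- mfi[mid]
  conc[mid] <- p$C * (((p$A - p$D) / (y - p$D))^(1 / p$G) - 1)^(1 / p$B)
  censor <- ifelse(low | conc < lloq, "lower",
                   ifelse(high | conc > uloq, "upper", "none"))
  data.frame(conc = pmin(pmax(conc, lloq), uloq), censor = censor,
             stringsAsFactors = FALSE)
}

#' Normalize a concentration to the LOQ window
#'
#' Linear rescaling `x = (conc - lloq) / (uloq - lloq)`, clipped to \[0,1\],
#' so the lower and upper limits of quantification become 0 and 1.
#' A log-scale variant (linear in `log(conc)` between `log(lloq)` and
#' `log(uloq)`) is available.
#'
#' @param conc numeric concentration(s).
#' @param lloq,uloq limits of quantification (`lloq < uloq`; both > 0 for
#'   the log scale).
#' @param log_scale normalize on the log-concentration scale. Default FALSE.
#' @return numeric in \[0,1\].
#' @export
normalize_loq <- function(conc, lloq, uloq, log_scale = FALSE) {
  if (any(lloq >= uloq)) stop("lloq must be strictly below uloq")
  x <- if (log_scale) {
    (log(pmax(conc, .Machine$double.xmin)) - log(lloq)) / (log(uloq) - log(lloq))
  } else {
    (conc - lloq) / (uloq - lloq)
  }
  pmin(pmax(x, 0), 1)
}

#' Calibrate a raw panel to normalized concentrations
#'
#' Full per-measurement pipeline: blank subtraction (if not already done),
#' per-analyte 5PL standard-curve fit, closed-form inversion of each net MFI
#' to a concentration, and LOQ normalization to \[0,1\]. Analytes whose
#' standard curve fails to fit are excluded with a warning.
#'
#' @param panel a `secretome_panel`.
#' @param log_scale passed to [normalize_loq()].
#' @return data.frame with one row per measurement: `analyte, donor,
#'   condition, day, mfi, conc, x, censor, below_loq, above_loq`, with the
#'   fitted curves in attribute `curves` and excluded analytes in attribute
#'   `excluded`.
#' @export
calibrate_panel <- function(panel, log_scale = FALSE) {
  stopifnot(inherits(panel, "secretome_panel"))
  if (!panel$blank_subtracted) panel <- subtract_blank(panel)
  m <- panel$measurements
  loq <- panel$loq
  analytes <- unique(m$analyte)
  no_loq <- setdiff(analytes, loq$analyte)
  if (length(no_loq)) stop("no LOQ entry for analyte: ", no_loq[1])

  curves <- list()
  excluded <- character(0)
  out <- vector("list", length(analytes))
  for (i in seq_along(analytes)) {
    an <- analytes[i]
    st <- panel$standards[panel$standards$analyte == an, ]
    cv <- if (nrow(st) >= 3) fit_5pl(st) else NULL
    if (is.null(cv) || !isTRUE(cv$converged)) {
      excluded <- c(excluded, an)
      next
    }
    curves[[an]] <- cv
    rows <- m[m$analyte == an, ]
    lq <- loq[loq$analyte == an, ]
    inv <- invert_5pl(cv, rows$mfi, lq$lloq, lq$uloq)
    rows$conc <- inv$conc
    rows$x <- normalize_loq(inv$conc, lq$lloq, lq$uloq,
                            log_scale = log_scale)
    rows$censor <- inv$censor
    rows$below_loq <- inv$censor == "lower"
    rows$above_loq <- inv$censor == "upper"
    out[[i]] <- rows
  }
  if (length(excluded)) {
    warning("standard curve did not fit; analyte(s) excluded: ",
            paste(excluded, collapse = ", "))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  attr(res, "curves") <- curves
  attr(res, "excluded") <- excluded
  res
}

#' Aggregate calibrated values and subtract the reference condition
#'
#' Takes per-measurement normalized values, computes the median across donors
#' per (analyte, condition, day), optionally pools days by median (the
#' network model has no notion of time), and subtracts the reference
#' condition, positioning values on \[-1, 1\]. The reference condition's own
#' referenced value is exactly 0. Analytes missing the reference condition
#' are excluded with a warning.
#'
#' @param calibrated output of [calibrate_panel()] (or any data.frame with
#'   `analyte, donor, condition, day, x` and optional `below_loq`,
#'   `above_loq`).
#' @param reference reference condition name. Default `"control_unloaded"`.
#' @param pool_days pool day-7/day-14 medians into one value per condition.
#'   Default TRUE.
#' @return An object of class `calibrated_secretome`: data.frame with
#'   columns `analyte, condition` (and `day` when `pool_days = FALSE`),
#'   `x` (median normalized value in \[0,1\]), `x_ref` (reference-subtracted,
#'   in \[-1,1\]) and censoring summary columns `below_loq`/`above_loq`
#'   (all donor measurements censored on that side).
#' @export
aggregate_and_reference <- function(calibrated,
                                    reference = "control_unloaded",
                                    pool_days = TRUE) {
  df <- as.data.frame(calibrated)
  if (!"below_loq" %in% names(df)) df$below_loq <- FALSE
  if (!"above_loq" %in% names(df)) df$above_loq <- FALSE

  med <- stats::aggregate(x ~ analyte + condition + day, df, stats::median)
  cen <- stats::aggregate(cbind(below_loq, above_loq) ~
                            analyte + condition + day, df, all)
  med <- merge(med, cen, by = c("analyte", "condition", "day"))

  if (pool_days) {
    pooled <- stats::aggregate(x ~ analyte + condition, med, stats::median)
    cen2 <- stats::aggregate(cbind(below_loq, above_loq) ~
                               analyte + condition, med, all)
    med <- merge(pooled, cen2, by = c("analyte", "condition"))
    keys <- c("analyte", "condition")
  } else {
    keys <- c("analyte", "condition", "day")
  }

  ref <- med[med$condition == reference,
             c(setdiff(keys, "condition"), "x")]
  names(ref)[names(ref) == "x"] <- "x_reference"
  have_ref <- unique(ref$analyte)
  drop <- setdiff(unique(med$analyte), have_ref)
  if (length(drop)) {
    warning("no reference condition '", reference, "' for analyte(s): ",
            paste(drop, collapse = ", "), " (excluded)")
    med <- med[med$analyte %in% have_ref, ]
  }
  out <- merge(med, ref, by = setdiff(keys, "condition"))
  out$x_ref <- out$x - out$x_reference
  out$x_reference <- NULL
  out <- out[order(out$analyte, out$condition), ]
  rownames(out) <- NULL
  structure(out, class = c("calibrated_secretome", "data.frame"),
            reference = reference, pool_days = pool_days)
}

#' Write a calibrated secretome table to CSV
#'
#' @param calibrated a `calibrated_secretome`.
#' @param path output CSV path.
#' @return `invisible(calibrated)`.
#' @export
write_calibrated <- function(calibrated, path) {
  utils::write.csv(as.data.frame(calibrated), path, row.names = FALSE,
                   quote = FALSE)
  invisible(calibrated)
}
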