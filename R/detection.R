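#' Fit the gamma detection-limit model
#'
#' Pools all nonzero abundances across species and samples, log2-transforms
#' them (the input is expected on the per-million scale), and fits a gamma
#' distribution by maximum likelihood. The detection threshold is the gamma
#' quantile at `percentile` (default the 1st percentile): species whose
#' log2 per-million abundance does not exceed it are treated as undetected.
#' Values that are non-positive after the log2 transform fall outside the
#' gamma support and are excluded from the fit; such abundances can never
#' exceed a positive threshold, so calling remains conservative.
#'
#' @param abundances species x sample matrix on the per-million scale.
#' @param percentile quantile of the fitted gamma used as the detection
#'   threshold, in (0, 1).
#' @return object of class `detection_model` with `shape`, `rate`,
#'   `percentile`, `threshold` (log2 per-million units) and `n_fitted`.
#' @export
fit_detection_model <- function(abundances, percentile = 0.01) {
  stopifnot(percentile > 0, percentile < 1)
  x <- log2(abundances[abundances > 0])
  x <- x[x > 0]
  if (length(x) < 100)
    stop("need at least 100 positive log2 abundances to fit the detection ",
         "model (got ", length(x), "); simulate a larger cohort")
  if (stats::sd(x) == 0)
    stop("degenerate abundance data: all pooled log2 values identical")
  fit <- fitdistrplus::fitdist(as.numeric(x), "gamma")
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  model <- list(shape = shape, rate = rate, percentile = percentile,
                threshold = stats::qgamma(percentile, shape = shape, rate = rate),
                n_fitted = length(x))
  class(model) <- "detection_model"
  model
}

#' @export
print.detection_model <- function(x, ...) {
  cat("Gamma detection model\n",
      sprintf("  shape %.4f, rate %.4f (fitted on %d log2 per-million values)\n",
              x$shape, x$rate, x$n_fitted),
      sprintf("  threshold: log2 abundance > %.4f (gamma %.1f%% quantile)\n",
              x$threshold, 100 * x$percentile), sep = "")
  invisible(x)
}

#' Call species presence/absence from abundances
#'
#' A species is present in a sample iff its log2 per-million abundance
#' strictly exceeds the model threshold; zero abundances are always absent.
#'
#' @param abundances species x sample per-million matrix.
#' @param model a [fit_detection_model()] result.
#' @return integer 0/1 matrix with the same dimnames.
#' @export
call_presence <- function(abundances, model) {
  stopifnot(inherits(model, "detection_model"))
  pres <- abundances > 0 & log2(pmax(abundances, .Machine$double.xmin)) >
    model$threshold
  mode(pres) <- "integer"
  pres
}

#' Serialize / restore a detection model as JSON
#'
#' @param model a `detection_model`.
#' @param path JSON file.
#' @export
write_detection_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_detection_model
#' @export
read_detection_model <- function(path) {
  model <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(model) <- "detection_model"
  model
}
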