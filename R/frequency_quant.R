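#' Western-blot band quantification for one lane
#'
#' @param lane_id Lane identifier.
#' @param intensity_long,intensity_short Non-negative band intensities
#'   (arbitrary units) of the long and short protein variants.
#' @param slippage_product Which variant is produced *by* slippage: `"long"`
#'   when slippage restores a full-length product (the *tssM1* situation),
#'   `"short"` when slippage truncates (the *tssM3* situation).
#' @return A list of class `band_quant`.
#' @export
band_quant <- function(lane_id, intensity_long, intensity_short,
                       slippage_product = c("long", "short")) {
  slippage_product <- match.arg(slippage_product)
  if (intensity_long < 0 || intensity_short < 0)
    stop("intensities must be non-negative", call. = FALSE)
  if (intensity_long + intensity_short <= 0)
    stop("both band intensities are zero: frequency undefined", call. = FALSE)
  structure(list(lane_id = as.character(lane_id),
                 intensity_long = intensity_long,
                 intensity_short = intensity_short,
                 slippage_product = slippage_product),
            class = "band_quant")
}

new_estimate <- function(f_hat, method, ratio = NULL, se = NA_real_,
                         clamped = FALSE) {
  if (is.null(ratio)) ratio <- if (f_hat > 0) (1 - f_hat) / f_hat else Inf
  structure(list(f_hat = f_hat, method = method, ratio = ratio, se = se,
                 clamped = clamped),
            class = "frameshift_estimate")
}

#' @export
print.frameshift_estimate <- function(x, ...) {
  cat(sprintf("<frameshift_estimate> f = %.4f (%s)%s, other:slippage ratio %s\n",
              x$f_hat, x$method,
              if (is.na(x$se)) "" else sprintf(" +/- %.4f se", x$se),
              if (is.finite(x$ratio)) sprintf("%.2f:1", x$ratio) else "Inf"))
  invisible(x)
}

#' Frameshift frequency from western-blot band intensities
#'
#' Intensity is taken as proportional to molecule count (a single N-terminal
#' epitope per molecule regardless of length), so no length correction is
#' applied. The frequency is the slippage product's share of total signal:
#' `f = I_slip / (I_long + I_short)`; the ratio is reported as
#' other-product : slippage-product.
#'
#' @param b A [band_quant()].
#' @return A `frameshift_estimate` with `method = "western"`.
#' @examples
#' # high-MW band at ~1/3 the intensity of the low-MW band:
#' western_frequency(band_quant("wt", intensity_long = 1, intensity_short = 3,
#'                              slippage_product = "long"))  # f = 0.25, 3:1
#' @export
western_frequency <- function(b) {
  stopifnot(inherits(b, "band_quant"))
  total <- b$intensity_long + b$intensity_short
  i_slip <- if (b$slippage_product == "long") b$intensity_long else b$intensity_short
  f <- i_slip / total
  new_estimate(f, "western",
               ratio = if (i_slip > 0) (total - i_slip) / i_slip else Inf)
}

#' Blank-corrected relative fluorescence
#'
#' Reporter fluorescence normalized by culture density: fluorescence over
#' absorbance at 600 nm, each after subtraction of the blank-sample value.
#'
#' @param raw_f Raw fluorescence of the sample.
#' @param od600 Absorbance at 600 nm of the sample.
#' @param blank_f,blank_od Fluorescence and absorbance of the blank.
#' @return `(raw_f - blank_f) / (od600 - blank_od)`, vectorized.
#' @export
relative_fluorescence <- function(raw_f, od600, blank_f = 0, blank_od = 0) {
  if (any(od600 - blank_od <= 0))
    stop("blank-corrected OD600 must be positive", call. = FALSE)
  (raw_f - blank_f) / (od600 - blank_od)
}

#' A three-construct GFP reporter measurement set
#'
#' The reporter scheme compares three fusions: an in-frame-stop negative
#' control (no fusion protein possible), a +1 reporter (fusion produced only
#' when +1 frameshifting occurs), and a frame-restored reference in which
#' every transcript yields the fusion — the fluorescence expected if
#' frameshifting were 100% efficient.
#'
#' @param f_neg,f_test,f_max Normalized fluorescence of the negative control,
#'   the +1 reporter, and the 100% reference; vectors are treated as
#'   replicates and summarized by their mean.
#' @return A list of class `reporter_set` with per-construct means and the
#'   replicate count.
#' @export
reporter_set <- function(f_neg, f_test, f_max) {
  n <- length(f_test)
  structure(list(f_neg = mean(f_neg), f_test = mean(f_test),
                 f_max = mean(f_max), replicates = n,
                 raw = list(f_neg = f_neg, f_test = f_test, f_max = f_max)),
            class = "reporter_set")
}

#' Frameshift frequency from the three-construct GFP reporter
#'
#' `f = (f_test - f_neg) / (f_max - f_neg)`: the +1 reporter signal as a
#' fraction of the 100%-frameshift reference, both background-corrected by
#' the in-frame-stop control. Estimates pushed outside \[0, 1\] by reporter
#' noise are clamped, with a warning and `clamped = TRUE`.
#'
#' @param r A [reporter_set()].
#' @return A `frameshift_estimate` with `method = "gfp"`.
#' @export
gfp_frequency <- function(r) {
  stopifnot(inherits(r, "reporter_set"))
  if (r$f_max <= r$f_neg)
    stop("f_max must exceed f_neg: estimate undefined", call. = FALSE)
  f <- (r$f_test - r$f_neg) / (r$f_max - r$f_neg)
  clamped <- f < 0 || f > 1
  if (clamped) {
    warning(sprintf("estimate %.4f outside [0, 1]; clamped", f), call. = FALSE)
    f <- min(max(f, 0), 1)
  }
  new_estimate(f, "gfp", clamped = clamped)
}

#' Aggregate replicate frameshift estimates
#'
#' @param estimates A list of `frameshift_estimate`s of the same method
#'   (at least 2).
#' @return A `frameshift_estimate` whose `f_hat` is the mean and `se` the
#'   standard error of the mean.
#' @export
aggregate_estimates <- function(estimates) {
  if (!is.list(estimates) || length(estimates) < 2L)
    stop("need at least 2 estimates to aggregate", call. = FALSE)
  ok <- vapply(estimates, inherits, logical(1), "frameshift_estimate")
  if (!all(ok)) stop("all elements must be frameshift_estimates", call. = FALSE)
  methods <- unique(vapply(estimates, function(e) e$method, character(1)))
  if (length(methods) != 1L)
    stop("cannot aggregate estimates from different methods", call. = FALSE)
  f <- vapply(estimates, function(e) e$f_hat, numeric(1))
  new_estimate(mean(f), methods, se = stats::sd(f) / sqrt(length(f)))
}
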