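# Risk-function forms: the tagged union describing how a covariate enters the
# log-hazard. Five kinds are supported: linear, first/second degree fractional
# polynomial (FP1/FP2), threshold (step at a cutpoint, ">= cut" coding) and
# non-ordinal (an interior quartile range against the rest).

#' Fractional-polynomial power set
#'
#' The conventional FP power grid; power 0 denotes the natural logarithm.
#' @export
FP_POWERS <- c(-2, -1, 0, 0.5, 1, 2, 3)

#' Construct a risk-function form
#'
#' A `risk_form` describes how one covariate enters the log-hazard of a Cox
#' model: identity (`linear`), one or two fractional-polynomial power
#' transforms (`fp1`, `fp2`; power 0 means log, a repeated FP2 power `p` uses
#' the convention `(x^p, x^p log x)`), a step function at a cutpoint
#' (`threshold`, coded as `x >= cut`), or a non-ordinal quartile-range contrast
#' (`non_ordinal`).
#'
#' @param kind one of `"linear"`, `"fp1"`, `"fp2"`, `"threshold"`,
#'   `"non_ordinal"`.
#' @param powers FP powers from [FP_POWERS]: length 1 for `fp1`, length 2
#'   (sorted, repeats allowed) for `fp2`.
#' @param cut threshold cutpoint (threshold kind).
#' @param pattern non-ordinal pattern, one of `"R2"`, `"R3"`, `"R2R3"`,
#'   `"R1R3"` — the quartile range(s) contrasted against the remainder.
#' @param quartiles numeric length-3 vector of frozen quartile cutpoints
#'   (non-ordinal kind).
#' @param scaling numeric `c(shift, scale)` applied as `(x + shift)/scale`
#'   before any power transform; defaults to identity `c(0, 1)`.
#' @return an object of class `risk_form`.
#' @export
risk_form <- function(kind, powers = NULL, cut = NULL, pattern = NULL,
                      quartiles = NULL, scaling = c(0, 1)) {
  kind <- match.arg(kind, c("linear", "fp1", "fp2", "threshold", "non_ordinal"))
  stopifnot(is.numeric(scaling), length(scaling) == 2, is.finite(scaling),
            scaling[2] > 0)
  if (kind == "fp1") {
    stopifnot(length(powers) == 1, powers %in% FP_POWERS)
  } else if (kind == "fp2") {
    stopifnot(length(powers) == 2, all(powers %in% FP_POWERS))
    powers <- sort(powers)
  } else if (kind == "threshold") {
    stopifnot(is.numeric(cut), length(cut) == 1, is.finite(cut))
  } else if (kind == "non_ordinal") {
    pattern <- match.arg(pattern, c("R2", "R3", "R2R3", "R1R3"))
    stopifnot(is.numeric(quartiles), length(quartiles) == 3,
              !is.unsorted(quartiles))
  }
  structure(list(kind = kind, powers = powers, cut = cut, pattern = pattern,
                 quartiles = quartiles, scaling = as.numeric(scaling)),
            class = "risk_form")
}

#' @rdname risk_form
#' @export
form_linear <- function(scaling = c(0, 1)) risk_form("linear", scaling = scaling)

#' @rdname risk_form
#' @param p,p1,p2 FP powers.
#' @export
form_fp1 <- function(p, scaling = c(0, 1)) risk_form("fp1", powers = p, scaling = scaling)

#' @rdname risk_form
#' @export
form_fp2 <- function(p1, p2, scaling = c(0, 1))
  risk_form("fp2", powers = c(p1, p2), scaling = scaling)

#' @rdname risk_form
#' @export
form_threshold <- function(cut) risk_form("threshold", cut = cut)

#' @rdname risk_form
#' @export
form_nonordinal <- function(pattern, quartiles)
  risk_form("non_ordinal", pattern = pattern, quartiles = quartiles)

#' @export
format.risk_form <- function(x, ...) {
  switch(x$kind,
    linear = "linear",
    fp1 = sprintf("FP1(%g)", x$powers),
    fp2 = sprintf("FP2(%g, %g)", x$powers[1], x$powers[2]),
    threshold = sprintf("threshold(>= %g)", x$cut),
    non_ordinal = sprintf("non-ordinal(%s vs rest)", x$pattern))
}

#' @export
print.risk_form <- function(x, ...) {
  cat("<risk_form>", format(x), "\n"); invisible(x)
}

n_form_params <- function(form) {
  switch(form$kind, linear = 1L, fp1 = 1L, fp2 = 2L, threshold = 1L,
         non_ordinal = 1L)
}

#' Default fractional-polynomial pre-scaling for a covariate
#'
#' Standard FP practice: shift a variable with non-positive values by
#' `1 - min(x)` so all values are strictly positive, then divide by the power
#' of ten that brings the maximum into `(0, 10]`, so transformed magnitudes
#' are O(1). Histoscores on the 0-300 scale therefore get `shift = 1`,
#' `scale = 100`.
#'
#' @param x numeric vector (missing values ignored).
#' @return numeric `c(shift, scale)`.
#' @export
fp_scaling <- function(x) {
  x <- x[is.finite(x)]
  stopifnot(length(x) > 0)
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  scale <- 10^max(0, floor(log10(max(xs))))
  c(shift = shift, scale = scale)
}

fp_pow <- function(z, p) if (p == 0) log(z) else z^p

#' Apply a linear / fractional-polynomial transform
#'
#' Expands a covariate into the design column(s) implied by a `linear`, `fp1`
#' or `fp2` form. The form's `scaling` is applied first: `z = (x + shift) /
#' scale`. Power 0 is the natural log; a repeated FP2 power `p` yields the
#' pair `(z^p, z^p log z)`.
#'
#' @param x numeric vector; no missing values.
#' @param form a [risk_form] of kind `linear`, `fp1` or `fp2`.
#' @return numeric matrix with 1 column (linear, fp1) or 2 columns (fp2);
#'   attribute `"scaling"` records the scaling used.
#' @export
fp_transform <- function(x, form) {
  stopifnot(inherits(form, "risk_form"),
            form$kind %in% c("linear", "fp1", "fp2"))
  if (anyNA(x)) stop_config("fp_transform: missing values in input")
  z <- (x + form$scaling[1]) / form$scaling[2]
  if (form$kind != "linear" && any(form$powers <= 0) && any(z <= 0))
    stop_config(paste("fp_transform: non-positive values under a log or",
                      "negative power; supply an explicit positive shift in",
                      "the form's scaling"))
  out <- switch(form$kind,
    linear = cbind(z),
    fp1 = cbind(fp_pow(z, form$powers)),
    fp2 = {
      p <- form$powers
      if (any(z <= 0)) stop_config(
        "fp_transform: FP2 requires strictly positive scaled values")
      if (p[1] == p[2]) cbind(fp_pow(z, p[1]), fp_pow(z, p[1]) * log(z))
      else cbind(fp_pow(z, p[1]), fp_pow(z, p[2]))
    })
  colnames(out) <- if (ncol(out) == 2) c("t1", "t2") else "t1"
  attr(out, "scaling") <- form$scaling
  out
}

#' Indicator column for a threshold or non-ordinal form
#'
#' Threshold forms code `x >= cut` as 1. Non-ordinal forms assign patients to
#' quartile ranges R1..R4 using the form's frozen quartiles (R1: `x <= q1`,
#' R2: `q1 < x <= q2`, R3: `q2 < x <= q3`, R4: `x > q3`) and code membership
#' of the pattern's range(s) as 1.
#'
#' @param x numeric vector; no missing values.
#' @param form a [risk_form] of kind `threshold` or `non_ordinal`.
#' @return 0/1 numeric vector.
#' @export
form_indicator <- function(x, form) {
  stopifnot(inherits(form, "risk_form"))
  if (anyNA(x)) stop_config("form_indicator: missing values in input")
  if (form$kind == "threshold") return(as.numeric(x >= form$cut))
  if (form$kind != "non_ordinal") stop_config("form_indicator: wrong form kind")
  q <- form$quartiles
  rng <- 1L + (x > q[1]) + (x > q[2]) + (x > q[3])
  keep <- switch(form$pattern, R2 = 2L, R3 = 3L, R2R3 = c(2L, 3L),
                 R1R3 = c(1L, 3L))
  as.numeric(rng %in% keep)
}

#' Expand screened forms into a Cox design matrix
#'
#' Applies the frozen screened transformation of each variable to a completed
#' (no missing values among the used variables) cohort, producing the design
#' matrix for model fitting. Threshold and non-ordinal forms become 0/1
#' indicators (with cutpoints and quartiles frozen from screening); FP forms
#' expand via [fp_transform] with the frozen scaling.
#'
#' @param data a data frame holding the variables.
#' @param forms named list of [risk_form]s, one per variable to include.
#' @return numeric design matrix; attribute `"groups"` maps each column to
#'   its source variable (FP2 variables own two columns).
#' @export
apply_forms <- function(data, forms) {
  stopifnot(is.list(forms), length(names(forms)) == length(forms))
  missing_vars <- setdiff(names(forms), names(data))
  if (length(missing_vars))
    stop_config("apply_forms: variables not in data: %s",
                paste(missing_vars, collapse = ", "))
  cols <- list(); groups <- character(0)
  for (v in names(forms)) {
    f <- forms[[v]]
    if (!inherits(f, "risk_form")) stop_config("apply_forms: unknown form for %s", v)
    x <- data[[v]]
    if (f$kind %in% c("threshold", "non_ordinal")) {
      m <- cbind(form_indicator(x, f))
      colnames(m) <- v
    } else {
      m <- fp_transform(x, f)
      colnames(m) <- if (ncol(m) == 1) v else paste0(v, c(".1", ".2"))
    }
    cols[[v]] <- m
    groups <- c(groups, rep(v, ncol(m)))
  }
  out <- do.call(cbind, cols)
  attr(out, "groups") <- groups
  out
}
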