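#' Closed-form physiology metrics
#'
#' Vectorised pure functions for the standard indirect-calorimetry,
#' echocardiography, electrocardiography and mitochondrial-respirometry
#' indices:
#'
#' * `rer(vo2, vco2)` — respiratory exchange ratio, `VCO2 / VO2`.
#' * `energy_expenditure(vo2, vco2)` — `3.815 * VO2 + 1.232 * VCO2` (a
#'   Weir-type linear combination; unit-agnostic, the result scales with the
#'   units of the gas-exchange inputs).
#' * `fractional_shortening(lvdd, lvsd)` — `(LVDD - LVSD) / LVDD * 100`
#'   (percent), from M-mode left-ventricular end-diastolic and end-systolic
#'   diameters.
#' * `relative_wall_thickness(ivs_d, lvpw_d, lvdd)` —
#'   `(IVSD + LVPWD) / LVDD`, using the interventricular septum and
#'   posterior-wall thicknesses in diastole.
#' * `qtc_bazett(qt_s, rr_s)` — Bazett heart-rate-corrected QT interval,
#'   `QT / sqrt(RR)`, seconds in and out (see `qtc_bazett_ms()` for a
#'   millisecond wrapper).
#' * `respiratory_control_ratio(oxphos, leak)` — `OXPHOS / LEAK`, the
#'   coupling efficiency of mitochondrial respiration.
#'
#' @param vo2,vco2 Oxygen consumption and carbon dioxide production (same
#'   units; `vo2 > 0` for `rer`, both `>= 0` for `energy_expenditure`).
#' @param lvdd,lvsd Left-ventricular end-diastolic / end-systolic diameter
#'   (mm; `lvdd > 0`).
#' @param ivs_d,lvpw_d Interventricular septum and posterior-wall thickness
#'   in diastole (mm).
#' @param qt_s,rr_s QT and RR intervals in seconds (`rr_s > 0`).
#' @param qt_ms,rr_ms QT and RR intervals in milliseconds.
#' @param oxphos,leak ADP-saturated and proton-leak respiration rates
#'   (`leak > 0`).
#' @return Numeric vector.
#' @name physiology_metrics
#' @examples
#' rer(2, 1.6)
#' energy_expenditure(1, 1)
#' fractional_shortening(4, 2)
#' relative_wall_thickness(1, 1, 4)
#' qtc_bazett(0.04, 0.16)
#' respiratory_control_ratio(10, 2)
NULL

check_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    abort_input(sprintf("`%s` must be positive and finite.", name))
  }
}

check_nonnegative <- function(x, name) {
  if (any(!is.finite(x) | x < 0)) {
    abort_input(sprintf("`%s` must be nonnegative and finite.", name))
  }
}

#' @rdname physiology_metrics
#' @export
rer <- function(vo2, vco2) {
  check_positive(vo2, "vo2")
  vco2 / vo2
}

#' @rdname physiology_metrics
#' @export
energy_expenditure <- function(vo2, vco2) {
  check_nonnegative(vo2, "vo2")
  check_nonnegative(vco2, "vco2")
  3.815 * vo2 + 1.232 * vco2
}

#' @rdname physiology_metrics
#' @export
fractional_shortening <- function(lvdd, lvsd) {
  check_positive(lvdd, "lvdd")
  (lvdd - lvsd) / lvdd * 100
}

#' @rdname physiology_metrics
#' @export
relative_wall_thickness <- function(ivs_d, lvpw_d, lvdd) {
  check_positive(lvdd, "lvdd")
  (ivs_d + lvpw_d) / lvdd
}

#' @rdname physiology_metrics
#' @export
qtc_bazett <- function(qt_s, rr_s) {
  check_positive(rr_s, "rr_s")
  qt_s / sqrt(rr_s)
}

#' @rdname physiology_metrics
#' @export
qtc_bazett_ms <- function(qt_ms, rr_ms) {
  1000 * qtc_bazett(qt_ms / 1000, rr_ms / 1000)
}

#' @rdname physiology_metrics
#' @export
respiratory_control_ratio <- function(oxphos, leak) {
  check_positive(leak, "leak")
  oxphos / leak
}

#' Goodness of fit of genotype counts to a Mendelian ratio
#'
#' Chi-square test of observed offspring genotype counts against expected
#' segregation weights (default 1:2:1 for a heterozygote intercross):
#' `chisq = sum((obs - exp)^2 / exp)` with `exp = total * weight /
#' sum(weights)` and `df = classes - 1`. With `exact = TRUE` (totals <= 100)
#' an exact multinomial tail p is also computed by enumerating all outcome
#' tables no more probable than the observed one.
#'
#' @param observed Nonnegative integer counts per genotype class.
#' @param ratio Positive expected ratio weights, same length.
#' @param exact Also compute the exact multinomial p (default `FALSE`).
#' @return Object of class `mendelian_test`: list with `statistic`, `df`,
#'   `p.value`, `expected`, and `p.exact` when requested. Has a [tidy()]
#'   method.
#' @examples
#' mendelian_gof(c(39, 35, 0))
#' @export
mendelian_gof <- function(observed, ratio = c(1, 2, 1), exact = FALSE) {
  if (length(observed) != length(ratio) || length(observed) < 2) {
    abort_input("`observed` and `ratio` must be equal-length vectors (>= 2 classes).")
  }
  if (any(!is.finite(observed)) || any(observed < 0) ||
      any(observed != round(observed))) {
    abort_input("`observed` must be nonnegative integer counts.")
  }
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    abort_input("`ratio` weights must be positive.")
  }
  total <- sum(observed)
  if (total == 0) abort_input("Total count must be positive.")
  p_exp <- ratio / sum(ratio)
  expected <- total * p_exp
  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- pchisq(statistic, df, lower.tail = FALSE)

  res <- list(statistic = statistic, df = df, p.value = p,
              observed = observed, expected = expected)
  if (exact) {
    if (total > 100) {
      abort_config("Exact multinomial p is only computed for totals <= 100.")
    }
    res$p.exact <- multinomial_tail_p(observed, p_exp)
  }
  structure(res, class = "mendelian_test")
}

# exact multinomial goodness-of-fit tail: total probability of all outcome
# tables with probability <= that of the observed table
multinomial_tail_p <- function(observed, p_exp) {
  total <- sum(observed)
  k <- length(observed)
  tables <- compositions(total, k)
  probs <- apply(tables, 1, function(x) dmultinom(x, prob = p_exp))
  p_obs <- dmultinom(observed, prob = p_exp)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# all nonnegative integer k-tuples summing to n (small n, k <= 4)
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1)
    out[[length(out) + 1]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

#' @export
print.mendelian_test <- function(x, ...) {
  cat(sprintf("Mendelian goodness of fit: chi-square = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  if (!is.null(x$p.exact)) {
    cat(sprintf("  exact multinomial p = %.4g\n", x$p.exact))
  }
  invisible(x)
}

#' Compute physiology metrics for a measurement table
#'
#' Adds every metric whose input columns are present: `rer` and
#' `energy_expenditure` from `vo2`/`vco2`, `fractional_shortening` from
#' `lvdd`/`lvsd`, `relative_wall_thickness` from `ivs_d`/`lvpw_d`/`lvdd`,
#' `qtc` from `qt_s`/`rr_s`, and `rcr` from `oxphos`/`leak`. Beats with
#' `lvsd > lvdd` are flagged in `suspect_beat` rather than rejected.
#'
#' @param data Measurement tibble.
#' @return The tibble with metric columns appended.
#' @export
physiology_table <- function(data) {
  has <- function(...) all(c(...) %in% names(data))
  if (has("vo2", "vco2")) {
    data <- mutate(data, rer = rer(.data$vo2, .data$vco2),
                   energy_expenditure = energy_expenditure(.data$vo2, .data$vco2))
  }
  if (has("lvdd", "lvsd")) {
    data <- mutate(data,
                   fractional_shortening = fractional_shortening(.data$lvdd, .data$lvsd),
                   suspect_beat = .data$lvsd > .data$lvdd)
  }
  if (has("ivs_d", "lvpw_d", "lvdd")) {
    data <- mutate(data, relative_wall_thickness =
                     relative_wall_thickness(.data$ivs_d, .data$lvpw_d, .data$lvdd))
  }
  if (has("qt_s", "rr_s")) {
    data <- mutate(data, qtc = qtc_bazett(.data$qt_s, .data$rr_s))
  }
  if (has("oxphos", "leak")) {
    data <- mutate(data, rcr = respiratory_control_ratio(.data$oxphos, .data$leak))
  }
  data
}
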