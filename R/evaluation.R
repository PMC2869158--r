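# Model performance: Nottingham Prognostic Index scoring and grouping,
# Harrell's concordance index, risk-group reclassification against a standard
# model, and Kaplan-Meier event-free rates at fixed horizons. (Nagelkerke
# R-squared lives next to the Cox kernel: see nagelkerke_r2().)

#' Nottingham Prognostic Index
#'
#' `NPI = 0.2 x tumour size (cm) + grade (1-3) + nodal stage (1-3)`.
#'
#' @param size tumour size in cm (> 0).
#' @param grade Bloom-Richardson grade, 1-3.
#' @param nodes nodal stage, 1-3.
#' @return numeric NPI values.
#' @export
npi_score <- function(size, grade, nodes) {
  if (any(size <= 0, na.rm = TRUE)) stop_config("npi_score: size must be > 0")
  if (!all(grade %in% 1:3)) stop_config("npi_score: grade must be 1, 2 or 3")
  if (!all(nodes %in% 1:3)) stop_config("npi_score: nodal stage must be 1, 2 or 3")
  0.2 * size + grade + nodes
}

#' Group patients by NPI
#'
#' Schemes: `"standard"` — the conventional three groups (< 3.4 low,
#' 3.4-5.4 intermediate, > 5.4 high); `"quartile"` — four groups at the
#' cohort-calibrated splits 3.3 / 4.2 / 4.8 (for a fair four-group
#' comparison); `"tertile"` — three groups at the empirical tertiles of the
#' supplied values. Ties at a cutoff go to the lower group.
#'
#' @param npi numeric NPI values.
#' @param scheme grouping scheme.
#' @param cutoffs optional explicit cutoffs overriding the scheme.
#' @return integer group labels (1 = lowest risk) with attribute `"cutoffs"`.
#' @export
npi_group <- function(npi, scheme = c("standard", "quartile", "tertile"),
                      cutoffs = NULL) {
  scheme <- match.arg(scheme)
  cuts <- cutoffs %||% switch(scheme,
    standard = c(3.4, 5.4),
    quartile = c(3.3, 4.2, 4.8),
    tertile = qtl(npi, c(1, 2) / 3))
  g <- if (scheme == "standard" && is.null(cutoffs))
    1L + (npi >= cuts[1]) + (npi > cuts[2])   # < 3.4 | 3.4-5.4 | > 5.4
  else
    1L + rowSums(outer(npi, cuts, ">"))
  attr(g, "cutoffs") <- cuts
  g
}

#' Harrell's concordance index for censored survival
#'
#' Over all censoring-comparable pairs (the member with the shorter follow-up
#' had the event; tied event times are not comparable), the fraction in which
#' the higher risk score belongs to the earlier event, with half credit for
#' tied scores. Invariant to monotone transformations of the scores.
#'
#' @param scores risk scores (higher = higher risk).
#' @param time,event follow-up and 0/1 event indicator.
#' @return concordance in `[0, 1]`; 0.5 is chance level.
#' @export
harrell_c <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  if (anyNA(scores) || anyNA(time) || anyNA(event))
    stop_config("harrell_c: missing values")
  n <- length(time)
  # comparable pair (i, j): time_i < time_j and event_i = 1
  dt <- outer(time, time, "<")
  comp <- dt & (event == 1)           # recycles event over rows: event_i == 1
  concordant <- sum(comp & outer(scores, scores, ">"))
  tied <- sum(comp & outer(scores, scores, "=="))
  n_comp <- sum(comp)
  if (n_comp == 0) stop_config("harrell_c: no comparable pairs")
  (concordant + 0.5 * tied) / n_comp
}

#' Risk-group reclassification against a standard model
#'
#' Cross-classifies patients by standard-model and new-model risk groups,
#' separately for event cases and event-free cases. Movement to a higher
#' group is an improvement for events; movement to a lower group is an
#' improvement for event-free cases. Net gain (in percent of the stratum) is
#' `(up - down)/n` for events and `(down - up)/n` for event-free;
#' significance is an exact binomial test of up vs down among the movers.
#'
#' @param new_groups,std_groups integer risk-group labels (same grouping
#'   resolution, e.g. quartile vs quartile).
#' @param event_status 0/1 event indicator.
#' @return object of class `reclassification`: per-stratum `table`, `up`,
#'   `down`, `n`, `net_gain_pct`, `p_value`.
#' @export
reclassify <- function(new_groups, std_groups, event_status) {
  if (length(new_groups) != length(std_groups) ||
      length(new_groups) != length(event_status))
    stop_config("reclassify: mismatched lengths")
  strata <- list(events = event_status == 1, event_free = event_status == 0)
  out <- lapply(names(strata), function(s) {
    idx <- strata[[s]]
    ns <- sum(idx)
    up <- sum(new_groups[idx] > std_groups[idx])
    down <- sum(new_groups[idx] < std_groups[idx])
    gain <- if (ns == 0) NA_real_ else
      100 * (if (s == "events") up - down else down - up) / ns
    p <- if (up + down == 0) 1 else binom.test(up, up + down, 0.5)$p.value
    list(table = table(standard = std_groups[idx], new = new_groups[idx]),
         up = up, down = down, n = ns, net_gain_pct = gain, p_value = p)
  })
  names(out) <- names(strata)
  structure(out, class = "reclassification")
}

#' @export
print.reclassification <- function(x, ...) {
  for (s in names(x)) {
    r <- x[[s]]
    cat(sprintf("%s (n = %d): %d up, %d down, net gain %.1f%% (p = %.3g)\n",
                s, r$n, r$up, r$down, r$net_gain_pct, r$p_value))
  }
  invisible(x)
}

#' Kaplan-Meier event-free rates per risk group at fixed horizons
#'
#' @param time,event follow-up and 0/1 event indicator.
#' @param groups risk-group labels.
#' @param horizons evaluation times in years (default 3, 5, 7, 10).
#' @return data frame `group` x `horizon` with the KM event-free rate;
#'   horizons beyond a group's last follow-up are `NA` (flagged, not fatal).
#' @export
event_free_rate <- function(time, event, groups, horizons = c(3, 5, 7, 10)) {
  gs <- sort(unique(groups))
  rows <- lapply(gs, function(g) {
    idx <- groups == g
    if (!sum(idx)) return(NULL)
    km <- km_estimate(time[idx], event[idx])
    data.frame(group = g, horizon = horizons,
               event_free = km_surv(km, horizons), n = sum(idx))
  })
  do.call(rbind, rows)
}
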