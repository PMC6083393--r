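#' Pairwise cost-effectiveness comparison
#'
#' Computes incremental discounted cost and QALYs of an intervention over a
#' comparator, the incremental cost-effectiveness ratio (ICER, US$/QALY), the
#' net monetary benefit at a willingness-to-pay threshold, and a dominance
#' classification. The ICER is left undefined (NA, flagged) when the QALY
#' difference is zero; the net monetary benefit is still computed.
#'
#' @param intervention,comparator `bc_cohort_result` objects produced with the
#'   same parameters and life table.
#' @param wtp willingness-to-pay threshold, US$ per QALY.
#' @return an object of class `bc_ce_comparison` with `incremental_cost`,
#'   `incremental_qaly`, `icer`, `nmb`, `dominance` (one of `"dominant"`,
#'   `"dominated"`, `"trade-off"`) and `cost_effective`.
#' @export
compare_strategies <- function(intervention, comparator, wtp) {
  dC <- intervention$discounted_cost - comparator$discounted_cost
  dE <- intervention$discounted_qaly - comparator$discounted_qaly
  icer <- if (dE == 0) NA_real_ else dC / dE
  nmb <- wtp * dE - dC
  dominance <- if ((dC <= 0 && dE >= 0) && (dC < 0 || dE > 0)) {
    "dominant"
  } else if ((dC >= 0 && dE <= 0) && (dC > 0 || dE < 0)) {
    "dominated"
  } else {
    "trade-off"
  }
  # for trade-offs, positive net monetary benefit is the threshold rule
  # (equivalent to icer < wtp when dE > 0, and to icer > wtp when dE < 0)
  cost_effective <- dominance == "dominant" ||
    (dominance == "trade-off" && nmb > 0)
  structure(list(
    intervention = intervention$strategy, comparator = comparator$strategy,
    incremental_cost = dC, incremental_qaly = dE,
    icer = icer, icer_defined = dE != 0,
    nmb = nmb, wtp = wtp,
    dominance = dominance, cost_effective = cost_effective
  ), class = "bc_ce_comparison")
}

#' @export
print.bc_ce_comparison <- function(x, ...) {
  cat("<bc_ce_comparison>", x$intervention, "vs", x$comparator, "\n")
  cat(sprintf("  dCost US$ %.2f | dQALY %.4f | ICER %s | NMB %.2f at WTP %g\n",
              x$incremental_cost, x$incremental_qaly,
              if (x$icer_defined) sprintf("%.0f", x$icer) else "undefined",
              x$nmb, x$wtp))
  cat("  ", x$dominance,
      if (x$cost_effective) "- cost-effective" else "- not cost-effective", "\n")
  invisible(x)
}

#' Assemble a cost-effectiveness report table
#'
#' One row per strategy: discounted lifetime cost and QALYs per woman, and the
#' incremental quantities against the common comparator (first element unless
#' named `comparator`).
#'
#' @param results named list of `bc_cohort_result`, comparator first.
#' @param wtp willingness-to-pay threshold.
#' @return a data.frame mirroring the standard published layout.
#' @export
ce_table <- function(results, wtp) {
  comp <- results[[1]]
  rows <- lapply(results, function(res) {
    if (identical(res$strategy, comp$strategy)) {
      data.frame(strategy = res$strategy,
                 cost = res$discounted_cost, qaly = res$discounted_qaly,
                 incremental_cost = NA_real_, incremental_qaly = NA_real_,
                 icer = NA_real_, stringsAsFactors = FALSE)
    } else {
      cmp <- compare_strategies(res, comp, wtp)
      data.frame(strategy = res$strategy,
                 cost = res$discounted_cost, qaly = res$discounted_qaly,
                 incremental_cost = cmp$incremental_cost,
                 incremental_qaly = cmp$incremental_qaly,
                 icer = cmp$icer, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
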