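#' Exposure scenarios for risk characterization
#'
#' A scenario is a named airborne concentration at which risk is evaluated.
#' The conventional trio is the CTE (fitted median), the RME (fitted 95th
#' percentile) and the regulatory OEL; arbitrary custom scenarios can be
#' added.
#'
#' @param cte,rme,oel concentrations in mg/m3 (any may be omitted).
#' @param ... further named concentrations, e.g. `peak = 0.5`.
#' @return data frame with columns `name`, `concentration`.
#' @export
exposure_scenarios <- function(cte = NULL, rme = NULL, oel = NULL, ...) {
  vals <- c(if (!is.null(cte)) c(CTE = cte), if (!is.null(rme)) c(RME = rme),
            if (!is.null(oel)) c(OEL = oel), unlist(list(...)))
  if (length(vals) && any(vals < 0))
    stop("scenario concentrations must be non-negative", call. = FALSE)
  data.frame(name = names(vals) %||% character(0),
             concentration = as.numeric(vals),
             stringsAsFactors = FALSE)
}

#' Excess cancer risk
#'
#' `ECR = concentration (mg/m3) x UR_work (per mg/m3)`. The unrounded
#' product is returned; reports print it in units of 1e-4 rounded half-up
#' to two decimals ([report_ecr()]).
#'
#' @param conc airborne concentration, mg/m3, non-negative.
#' @param ur a [unit_risk_work()] result (the staged-rounded `ur_work` is
#'   used) or a bare numeric unit risk.
#' @return excess cancer risk, dimensionless.
#' @export
excess_cancer_risk <- function(conc, ur) {
  stopifnot(is.numeric(conc), all(conc >= 0))
  u <- if (inherits(ur, "unit_risk_result")) ur$ur_work else ur
  stopifnot(is.numeric(u), u > 0)
  conc * u
}

#' Hazard quotient
#'
#' `HQ = concentration (mg/m3) / RfC_work (mg/m3)`, using the reported
#' (rounded) reference concentration, since that is the value regulatory
#' chains publish and carry forward. The unrounded quotient is returned;
#' reports round it half-up to two decimals below 1 and one decimal above
#' ([report_hq()]).
#'
#' @param conc airborne concentration, mg/m3, non-negative.
#' @param rfc an [rfc_work()] result or a bare numeric RfC_work in mg/m3.
#' @return hazard quotient, dimensionless.
#' @export
hazard_quotient <- function(conc, rfc) {
  stopifnot(is.numeric(conc), all(conc >= 0))
  r <- if (inherits(rfc, "rfc_result")) rfc$rfc_work else rfc
  if (!is.numeric(r) || r <= 0)
    stop("'rfc' must be a positive reference concentration", call. = FALSE)
  conc / r
}

#' Reporting precision for risk values
#'
#' `report_ecr` expresses an excess cancer risk in units of 1e-4 rounded
#' half-up to two decimals (so 7.05e-4 prints as 7.05); `report_hq` rounds
#' a hazard quotient to two decimals below 1 and one decimal at or above 1.
#'
#' @param ecr,hq unrounded risk values.
#' @return rounded values (for `report_ecr`, back on the natural scale).
#' @export
report_ecr <- function(ecr) round_half_up(ecr * 1e4, 2) / 1e4

#' @rdname report_ecr
#' @export
report_hq <- function(hq) {
  ifelse(abs(hq) < 1, round_half_up(hq, 2), round_half_up(hq, 1))
}

#' Risk characterization report
#'
#' Evaluates excess cancer risk and per-endpoint hazard quotients at each
#' scenario and flags them against the acceptability limits (default
#' 1e-4 for ECR, 1.0 for HQ). Values exactly at a limit are acceptable
#' (a "<= limit" convention); flags are set on the unrounded values, not
#' the rounded reporting values.
#'
#' @param scenarios data frame from [exposure_scenarios()].
#' @param ur a [unit_risk_work()] result, or `NULL` to skip the cancer
#'   column.
#' @param rfcs named list of [rfc_work()] results, keyed by endpoint.
#' @param ecr_limit acceptable excess cancer risk, default 1e-4.
#' @param hq_limit acceptable hazard quotient, default 1.0.
#' @return data frame of class `risk_report`: one row per scenario with
#'   unrounded `ecr`, reported `ecr_reported`, per-endpoint `hq_*` and
#'   `hq_*_reported` columns and logical acceptability flags. The unit
#'   risk, reference values and limits are attached as attribute `audit`.
#' @export
build_report <- function(scenarios, ur = NULL, rfcs = list(),
                         ecr_limit = 1e-4, hq_limit = 1.0) {
  stopifnot(is.data.frame(scenarios),
            all(c("name", "concentration") %in% names(scenarios)),
            ecr_limit > 0, hq_limit > 0)
  out <- scenarios
  if (!is.null(ur)) {
    out$ecr <- excess_cancer_risk(out$concentration, ur)
    out$ecr_reported <- report_ecr(out$ecr)
    out$ecr_acceptable <- out$ecr <= ecr_limit
  }
  for (ep in names(rfcs)) {
    hq <- hazard_quotient(out$concentration, rfcs[[ep]])
    out[[paste0("hq_", ep)]] <- hq
    out[[paste0("hq_", ep, "_reported")]] <- report_hq(hq)
    out[[paste0("hq_", ep, "_acceptable")]] <- hq <= hq_limit
  }
  attr(out, "audit") <- list(
    ur = ur,
    rfc_work = vapply(rfcs, function(r)
      if (inherits(r, "rfc_result")) r$rfc_work else r, numeric(1)),
    rfcs = rfcs, ecr_limit = ecr_limit, hq_limit = hq_limit)
  class(out) <- c("risk_report", "data.frame")
  out
}

#' @export
print.risk_report <- function(x, ...) {
  audit <- attr(x, "audit")
  cat("Risk characterization\n")
  if (!is.null(audit$ur))
    cat(sprintf("  UR_work = %.3g per mg/m3; acceptable ECR <= %.3g\n",
                audit$ur$ur_work, audit$ecr_limit))
  if (length(audit$rfc_work))
    cat(sprintf("  RfC_work (mg/m3): %s; acceptable HQ <= %g\n",
                paste(sprintf("%s %.2f", names(audit$rfc_work),
                              audit$rfc_work), collapse = ", "),
                audit$hq_limit))
  if (nrow(x) == 0) { cat("  (no scenarios)\n"); return(invisible(x)) }
  eps <- names(audit$rfc_work)
  hdr <- c("Scenario", "mg/m3",
           if (!is.null(audit$ur)) "ECR(x1e-4)",
           paste0("HQ_", eps))
  rows <- lapply(seq_len(nrow(x)), function(i) {
    mark <- function(v, ok) sprintf("%s%s", v, ifelse(ok, "", " *"))
    c(x$name[i], format(x$concentration[i]),
      if (!is.null(audit$ur))
        mark(format(x$ecr_reported[i] * 1e4), x$ecr_acceptable[i]),
      vapply(eps, function(ep)
        mark(format(x[[paste0("hq_", ep, "_reported")]][i]),
             x[[paste0("hq_", ep, "_acceptable")]][i]), character(1)))
  })
  m <- rbind(hdr, do.call(rbind, rows))
  for (j in seq_len(ncol(m)))
    m[, j] <- formatC(m[, j], width = max(nchar(m[, j])), flag = "-")
  for (i in seq_len(nrow(m)))
    cat(paste(m[i, ], collapse = "  "), "\n")
  cat("  * exceeds the acceptability limit\n")
  invisible(x)
}

#' Write a risk report to CSV
#'
#' @param report a [build_report()] result.
#' @param path output CSV path.
#' @return the report, invisibly.
#' @export
write_risk_report <- function(report, path) {
  stopifnot(inherits(report, "risk_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(report)
}

#' End-to-end risk assessment for a substance dossier
#'
#' Chains the full pipeline: derives the workplace unit risk from the
#' dossier's slope factor, derives a workplace reference concentration for
#' each non-carcinogenic POD under the chosen schema, and characterizes
#' risk at the supplied scenarios (by default CTE, RME and the dossier's
#' OEL).
#'
#' @param dossier a [substance_dossier()].
#' @param estimates an `exposure_estimates` object (from
#'   [monte_carlo_estimates()] or [assess_exposure()]), or `NULL` when
#'   `scenarios` is given directly.
#' @param schema a [correction_schema()].
#' @param scenarios optional [exposure_scenarios()] data frame; by default
#'   built from the estimates' CTE/RME rounded to two decimals (their
#'   reporting precision) plus the dossier OEL.
#' @param ... passed to [build_report()].
#' @return a `risk_report`.
#' @export
assess_risk <- function(dossier, estimates = NULL,
                        schema = correction_schema("KOSHA"),
                        scenarios = NULL, ...) {
  stopifnot(inherits(dossier, "substance_dossier"))
  if (is.null(scenarios)) {
    if (is.null(estimates))
      stop("either 'estimates' or 'scenarios' must be supplied", call. = FALSE)
    scenarios <- exposure_scenarios(cte = round_half_up(estimates$cte, 2),
                                    rme = round_half_up(estimates$rme, 2),
                                    oel = dossier$oel_mgm3)
  }
  ur <- if (!is.null(dossier$slope_factor))
    derive_unit_risk(dossier$slope_factor) else NULL
  noncarc <- dossier$pods[vapply(dossier$pods, function(p)
    !identical(p$endpoint, "carcinogenic"), logical(1))]
  rfcs <- lapply(noncarc, rfc_work, schema = schema)
  build_report(scenarios, ur = ur, rfcs = rfcs, ...)
}
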