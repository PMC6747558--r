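#' Published validation summary tables for AgNP in E174 and confectionery
#'
#' Per-sample precision and uncertainty summaries from a five-day,
#' three-replicate validation of AgNP characterization by spICP-MS in an
#' aqueous colloidal dispersion (NM-300K), two pristine E174 silver food
#' additives (Ag-005 flakes, Ag-008 leaves), and two E174-containing
#' confectionery products (Ag-P-002 pearls, Ag-P-003 coated chocolates).
#' One table per measurand: median size (`"size"`, nm; includes the TEM
#' Feret-min reference row), particle number concentration (`"number"`,
#' kg^-1) and particle mass concentration (`"mass"`, g/kg).
#'
#' Columns: `sample`, `code`, `measurand`, `mean`, `stdev`, `s_r`, `s_d`,
#' `s_ip`, `u_t`, `u_r`, `u_d`, `U` (precision/uncertainty columns in
#' percent of the mean; `U` expanded with k = 2), plus the routine
#' conditions `n` (replicates) and `d` (days) each row's budget assumes.
#'
#' @param measurand `"size"`, `"number"` or `"mass"`.
#' @return a data.frame of the printed summary values.
#' @seealso [reproduce_budget_table()] to recompute the derived columns.
#' @export
validation_summary <- function(measurand = c("size", "number", "mass")) {
  measurand <- match.arg(measurand)
  path <- system.file("extdata",
                      sprintf("validation_%s.tsv", measurand),
                      package = "spicpms", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", check.names = FALSE)
}

#' Recompute the derived uncertainty columns of a validation summary
#'
#' From each row's printed precision components (`s_r`, `s_d`) and bias
#' uncertainty (`u_t`), recomputes the intermediate precision `s_ip`
#' (quadrature), the routine-condition contributions `u_r = s_r/sqrt(n)`
#' and `u_d = s_d/sqrt(d)`, and the expanded uncertainty
#' `U = k * sqrt(u_r^2 + u_d^2 + u_t^2)` rounded to 2 significant figures —
#' the consistency check that a reported budget follows from its own
#' components.
#'
#' @param table a data.frame as returned by [validation_summary()] (needs
#'   columns `s_r`, `s_d`, `u_t`, `n`, `d`).
#' @param k coverage factor (default 2).
#' @return the table with columns `s_ip_calc`, `u_r_calc`, `u_d_calc`,
#'   `U_calc` (unrounded) and `U_report` (2 significant figures) appended.
#' @export
reproduce_budget_table <- function(table, k = 2) {
  need <- c("s_r", "s_d", "u_t", "n", "d")
  stopifnot(all(need %in% names(table)))
  out <- table
  out$s_ip_calc <- sqrt(table$s_r^2 + table$s_d^2)
  budgets <- lapply(seq_len(nrow(table)), function(i) {
    routine_budget(table$s_r[i], table$s_d[i], table$u_t[i],
                   n = table$n[i], d = table$d[i], k = k)
  })
  out$u_r_calc <- vapply(budgets, `[[`, numeric(1), "u_r")
  out$u_d_calc <- vapply(budgets, `[[`, numeric(1), "u_d")
  out$U_calc <- vapply(budgets, `[[`, numeric(1), "U")
  out$U_report <- vapply(budgets, `[[`, numeric(1), "U_report")
  out
}
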