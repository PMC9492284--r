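# Oracle validation harness: re-runs the Monte-Carlo oracles on a committed
# grid of parameter sets and checks each analytic engine against the
# empirical rejection rate within 3 binomial standard errors.

#' Validate the analytic engines against their Monte-Carlo oracles
#'
#' Reads a parameter grid (by default the grid shipped in
#' `inst/extdata/oracle_grid.csv`, which also records the rate each oracle
#' produced at its committed seed), re-runs the matching oracle for every
#' row, and compares the analytic power with the fresh empirical rejection
#' rate. A row passes when the two agree within 3 binomial standard errors
#' of the oracle.
#'
#' @param grid_path Path to a CSV grid with columns `engine`
#'   (`slr`/`anova`/`sc_lmm`), the engine parameters (`n`, `m`, `rho`,
#'   `maf`, `slope`, `delta1`, `delta2`, `sigma_y`, `sigma`, `fwer`,
#'   `n_tests`), `n_reps` and `seed` (unused columns may be empty).
#' @param n_reps Optional replicate-count override applied to every row.
#' @param seed Optional seed override applied to every row; `NULL` keeps
#'   the per-row committed seeds.
#'
#' @return A data frame with one row per grid point: the parameters, the
#'   analytic power, the oracle rate and its SE, and a logical `pass`.
#' @export
validate_engines <- function(grid_path = system.file("extdata",
                                                     "oracle_grid.csv",
                                                     package = "eqtlpwr"),
                             n_reps = NULL, seed = NULL) {
  grid <- utils::read.csv(grid_path, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    reps <- if (is.null(n_reps)) g$n_reps else n_reps
    sd <- if (is.null(seed)) g$seed else seed
    if (g$engine == "slr") {
      analytic <- power_eqtl_slr(g$n, g$maf, g$slope, g$sigma_y, g$fwer,
                                 g$n_tests)$power
      orc <- oracle_slr(g$n, g$maf, g$slope, g$sigma_y, g$fwer, g$n_tests,
                        n_reps = reps, seed = sd)
    } else if (g$engine == "anova") {
      analytic <- power_eqtl_anova(g$n, g$maf, c(g$delta1, g$delta2),
                                   g$sigma, g$fwer, g$n_tests)$power
      orc <- oracle_anova(g$n, g$maf, c(g$delta1, g$delta2), g$sigma,
                          g$fwer, g$n_tests, n_reps = reps, seed = sd)
    } else if (g$engine == "sc_lmm") {
      analytic <- power_eqtl_sclmm(g$n, g$m, g$rho, g$maf, g$slope,
                                   g$sigma_y, g$fwer, g$n_tests)$power
      orc <- oracle_sclmm(g$n, g$m, g$rho, g$maf, g$slope, g$sigma_y,
                          g$fwer, g$n_tests, n_reps = reps, seed = sd)
    } else {
      stop("unknown engine '", g$engine, "' in ", grid_path, call. = FALSE)
    }
    se <- max(orc$se, 1 / orc$n_reps) # guard only the degenerate rate 0/1
    cbind(g[setdiff(names(g), c("oracle_rate", "analytic_power"))],
          data.frame(analytic_power = analytic,
                     oracle_rate = orc$rejection_rate, oracle_se = orc$se,
                     pass = abs(analytic - orc$rejection_rate) <= 3 * se))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
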