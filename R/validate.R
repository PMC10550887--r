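#' Compare model and reference spike trains statistically
#'
#' Pools per-current spike times from both rasters and applies the univariate
#' Mann-Whitney U test with continuity correction (normal approximation) to
#' each current and to the pooled samples. The null hypothesis is that model
#' and reference spike times share the same distribution; large p-values mean
#' the model is statistically indistinguishable from the reference.
#'
#' @param model,reference data.frames with columns \code{I_pA},
#'   \code{spike_time_ms}; they must cover the same currents.
#' @param alpha_level significance level; default 0.05.
#' @return An object of class \code{"aglif_validation"}: list with
#'   \code{per_current} (data.frame \code{I_pA, n_model, n_ref, U, p, pass}),
#'   \code{pooled} (one-row data.frame) and \code{pass} (overall: pooled and
#'   every per-current test accept).
#' @export
validate_spike_trains <- function(model, reference, alpha_level = 0.05) {
  for (df in list(model, reference))
    stopifnot(is.data.frame(df),
              all(c("I_pA", "spike_time_ms") %in% names(df)))
  cm <- sort(unique(model$I_pA)); cr <- sort(unique(reference$I_pA))
  if (!identical(cm, cr))
    stop("model and reference rasters must cover the same currents")
  utest <- function(x, y) {
    if (length(x) < 3L || length(y) < 3L)
      warning("fewer than 3 spikes on one side; U test is unreliable")
    if (length(x) == 0L || length(y) == 0L)
      return(c(U = NA_real_, p = NA_real_))
    w <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    c(U = unname(w$statistic), p = w$p.value)
  }
  rows <- lapply(cm, function(I) {
    x <- model$spike_time_ms[model$I_pA == I]
    y <- reference$spike_time_ms[reference$I_pA == I]
    u <- utest(x, y)
    data.frame(I_pA = I, n_model = length(x), n_ref = length(y),
               U = u[["U"]], p = u[["p"]],
               pass = !is.na(u[["p"]]) && u[["p"]] > alpha_level)
  })
  per_current <- do.call(rbind, rows)
  up <- utest(model$spike_time_ms, reference$spike_time_ms)
  pooled <- data.frame(n_model = nrow(model), n_ref = nrow(reference),
                       U = up[["U"]], p = up[["p"]],
                       pass = !is.na(up[["p"]]) && up[["p"]] > alpha_level)
  structure(list(per_current = per_current, pooled = pooled,
                 pass = pooled$pass && all(per_current$pass)),
            class = "aglif_validation")
}

#' @export
print.aglif_validation <- function(x, ...) {
  cat("spike-train validation (Mann-Whitney U, continuity corrected)\n")
  print(x$per_current, row.names = FALSE)
  cat("pooled: U =", format(x$pooled$U), " p =", format(x$pooled$p),
      if (x$pass) "-> indistinguishable\n" else "-> differs\n")
  invisible(x)
}
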