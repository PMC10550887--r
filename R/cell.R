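#' Assemble an A-GLIF cell
#'
#' A cell bundles the physiological parameters, the Monod after-spike update
#' rule and (optionally) a firing-block rule; this is the unit consumed by
#' the simulator and produced by the fitting pipeline and the synthetic
#' generator.
#'
#' @param params an \code{"aglif_parameters"} object.
#' @param monod an \code{"aglif_monod"} update rule.
#' @param block an \code{"aglif_block_rule"} or \code{NULL}.
#' @param phenotype optional label (\code{"adapting"}, \code{"non_adapting"},
#'   \code{"blocking"}, ...).
#' @param id optional cell identifier used in rasters.
#' @return An object of class \code{"aglif_cell"}.
#' @export
aglif_cell <- function(params, monod, block = NULL, phenotype = NA_character_,
                       id = "cell") {
  stopifnot(inherits(params, "aglif_parameters"), inherits(monod, "aglif_monod"))
  if (!is.null(block)) stopifnot(inherits(block, "aglif_block_rule"))
  structure(list(params = params, monod = monod, block = block,
                 phenotype = phenotype, id = id),
            class = "aglif_cell")
}

#' @export
print.aglif_cell <- function(x, ...) {
  cat("A-GLIF cell '", x$id, "'",
      if (!is.na(x$phenotype)) paste0(" (", x$phenotype, ")"), "\n", sep = "")
  n <- nondimensionalize(x$params, 0)
  cat(sprintf("  beta=%.4f delta=%.4f tau=%.3f ms alpha_th=%.4f\n",
              n$beta, n$delta, n$tau, n$alpha_th))
  cat(sprintf("  Monod: a=%.4g b=%.4g c=%.4g d=%.4g\n",
              x$monod$a, x$monod$b, x$monod$c, x$monod$d))
  if (!is.null(x$block) && length(x$block$lines))
    cat("  firing-block rule with", length(x$block$lines), "line(s)\n")
  invisible(x)
}
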