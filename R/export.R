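## Writing fit outputs to disk: a summary CSV per fit plus a JSON
## criteria block, mirroring the layout of the reference tables.

#' Write fit summaries to CSV/JSON
#'
#' Writes, into `dir`, a `summary.csv` with the fit's term-level
#' estimates (posterior mean/interval or estimate/interval columns) and,
#' where the fit carries information criteria or DIC components, a
#' `criteria.json`.  Joint fits additionally write
#' `hazard_ratios.csv`; ladders write the DIC table.
#'
#' @param x A fit object (`longitudinal_fit`, `parametric_survival_fit`,
#'   `cox_fit`, `joint_fit` or `jm_ladder`).
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix (default none).
#' @return Invisibly, the paths written.
#' @export
write_fit_outputs <- function(x, dir, prefix = "") {
  UseMethod("write_fit_outputs")
}

write_block <- function(dir, prefix, summary_df, criteria = NULL,
                        extra = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "summary.csv"))
  write.csv(summary_df, paths, row.names = FALSE, na = "")
  if (!is.null(criteria)) {
    p <- file.path(dir, paste0(prefix, "criteria.json"))
    writeLines(jsonlite::toJSON(criteria, auto_unbox = TRUE, digits = NA,
                                null = "null"), p)
    paths <- c(paths, p)
  }
  for (nm in names(extra)) {
    p <- file.path(dir, paste0(prefix, nm, ".csv"))
    write.csv(extra[[nm]], p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
write_fit_outputs.longitudinal_fit <- function(x, dir, prefix = "") {
  summ <- if (!is.null(x$summaries)) x$summaries else x$coef
  write_block(dir, prefix, summ, criteria = unclass(x$criteria))
}

#' @export
write_fit_outputs.parametric_survival_fit <- function(x, dir,
                                                      prefix = "") {
  summ <- if (is.null(x$coef)) data.frame(term = character(0)) else x$coef
  summ <- rbind(summ,
                data.frame(term = c("rho", "phi"),
                           estimate = c(x$shape[["estimate"]], x$scale),
                           se = NA, lower = c(x$shape[["lower"]], NA),
                           upper = c(x$shape[["upper"]], NA),
                           hr = NA))
  write_block(dir, prefix, summ, criteria = x$criteria)
}

#' @export
write_fit_outputs.cox_fit <- function(x, dir, prefix = "") {
  write_block(dir, prefix, x$coef, criteria = x$criteria)
}

#' @export
write_fit_outputs.joint_fit <- function(x, dir, prefix = "") {
  write_block(dir, prefix, x$summaries, criteria = x$dic,
              extra = if (is.null(x$hazard_ratios)) list() else
                list(hazard_ratios = x$hazard_ratios))
}

#' @export
write_fit_outputs.jm_ladder <- function(x, dir, prefix = "") {
  write_block(dir, prefix, x$table)
}
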