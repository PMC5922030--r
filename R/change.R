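## CD4 change construction and the per-visit mean-variance profile used to
## diagnose overdispersion.

#' Successive CD4 cell-count changes per patient
#'
#' Computes `change_j = count_j - count_{j-1}` within each patient from an
#' ordered series of observed counts.  Patients with fewer than two
#' observed counts are excluded with a warning; gaps are not imputed (the
#' change spans whatever observed visits are adjacent in the series).
#'
#' @param counts Either a numeric vector (single patient) or a data frame
#'   with columns `patient_id`, `visit_index` and a count column
#'   (`cd4_count`); rows with `observed == 0` are ignored when present.
#' @return For a vector input, the numeric change series; for a data
#'   frame, a data frame (`patient_id`, `visit_index`, `cd4_change`) where
#'   `visit_index` is the later visit of each pair.
#' @export
compute_cd4_change <- function(counts) {
  if (is.numeric(counts)) {
    if (length(counts) < 2)
      stop_validation("need at least two observed counts")
    return(diff(counts))
  }
  df <- counts
  if (!is.null(df$observed)) df <- df[df$observed == 1, , drop = FALSE]
  df <- df[order(df$patient_id, df$visit_index), , drop = FALSE]
  sizes <- table(df$patient_id)
  short <- names(sizes)[sizes < 2]
  if (length(short)) {
    warning(length(short),
            " patient(s) with fewer than two observed counts excluded")
    df <- df[!(df$patient_id %in% as.numeric(short)), , drop = FALSE]
  }
  parts <- split(seq_len(nrow(df)), df$patient_id)
  out <- lapply(parts, function(idx) {
    data.frame(patient_id = df$patient_id[idx[-1]],
               visit_index = df$visit_index[idx[-1]],
               cd4_change = diff(df$cd4_count[idx]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-visit mean and standard deviation of the CD4 change
#'
#' Tabulates, per visit index, the arithmetic mean and sample standard
#' deviation (n-1 denominator) of observed changes, together with the
#' per-visit overdispersion verdict `variance > mean`.  Visits with fewer
#' than two observations are dropped with a message.
#'
#' @param table Longitudinal table with `visit_index`, `cd4_change` and
#'   optionally `observed`.
#' @return Data frame of class `meanvar_profile` (`visit_index`, `n`,
#'   `mean`, `sd`, `overdispersed`).
#' @export
mean_variance_profile <- function(table) {
  df <- table
  if (!is.null(df$observed)) df <- df[df$observed == 1, , drop = FALSE]
  counts <- table(df$visit_index)
  keep <- names(counts)[counts >= 2]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped))
    message("dropped visit(s) with < 2 observations: ",
            paste(dropped, collapse = ", "))
  df <- df[df$visit_index %in% as.numeric(keep), , drop = FALSE]
  mm <- aggregate(cd4_change ~ visit_index, df,
                  function(z) c(n = length(z), mean = mean(z), sd = sd(z)))
  out <- data.frame(visit_index = mm$visit_index,
                    n = mm$cd4_change[, "n"],
                    mean = mm$cd4_change[, "mean"],
                    sd = mm$cd4_change[, "sd"])
  out$overdispersed <- out$sd^2 > out$mean
  class(out) <- c("meanvar_profile", "data.frame")
  out
}

#' @export
plot.meanvar_profile <- function(x, ...) {
  graphics::plot(x$visit_index, x$mean, type = "b", pch = 19,
                 ylim = range(0, x$mean, x$sd),
                 xlab = "Follow-up visit", ylab = "CD4 change", ...)
  graphics::lines(x$visit_index, x$sd, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", legend = c("mean", "SD"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
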