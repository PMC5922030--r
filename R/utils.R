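#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef dpois optim optimHess quantile rnorm runif
#'   rgamma rpois sd var median setNames glm binomial as.formula pnorm
#'   model.matrix rbinom qnorm p.adjust aggregate rexp vcov logLik rchisq
#'   dnorm
#' @importFrom utils write.csv read.csv
NULL

## Validation helpers -------------------------------------------------------

stop_validation <- function(...) {
  stop(structure(class = c("jmcd4_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(p, name, upper_open = FALSE) {
  ok <- is.numeric(p) && length(p) == 1L && is.finite(p) && p >= 0 &&
    (if (upper_open) p < 1 else p <= 1)
  if (!ok) stop_validation(name, " must be a probability in [0, 1",
                           if (upper_open) ")" else "]")
  invisible(p)
}

check_count <- function(n, name, min = 1L) {
  ok <- is.numeric(n) && length(n) == 1L && is.finite(n) && n >= min &&
    n == round(n)
  if (!ok) stop_validation(name, " must be an integer >= ", min)
  invisible(as.integer(n))
}

is_pd <- function(S, tol = 1e-10) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) return(FALSE)
  all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > tol)
}

## Percentages rounded half-up (ties away from zero), one decimal by default.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Row-wise log-sum-exp over the columns of a matrix.
logsumexp_rows <- function(L) {
  mx <- do.call(pmax, c(as.data.frame(L), list(na.rm = TRUE)))
  mx + log(rowSums(exp(L - mx)))
}

## Inverse-Wishart draw via the Bartlett decomposition of the Wishart.
rinvwishart <- function(df, S) {
  d <- nrow(S)
  Sinv <- chol2inv(chol(S))
  L <- chol(Sinv)
  A <- matrix(0, d, d)
  diag(A) <- sqrt(rchisq_vec(d, df - seq_len(d) + 1))
  A[upper.tri(A)] <- rnorm(d * (d - 1) / 2)
  W <- crossprod(A %*% L)        # Wishart(df, Sinv)
  chol2inv(chol(W))
}

rchisq_vec <- function(n, df) stats::rchisq(n, df)

## Gauss-Hermite nodes/weights, cached per order.
gh_rules <- new.env(parent = emptyenv())
gauss_hermite_rule <- function(k) {
  key <- as.character(k)
  if (is.null(gh_rules[[key]])) {
    r <- pracma::gaussHermite(k)
    gh_rules[[key]] <- list(x = r$x, logw = log(r$w) - 0.5 * log(pi))
  }
  gh_rules[[key]]
}
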