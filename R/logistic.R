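# Binary logistic regression of annotation status on association strength,
# with family-wise permutation calibration via the min-p (max-statistic)
# scheme.

# Fast intercept+slope logistic MLE via glm.fit; returns coefficients, their
# standard errors and the residual deviance, or NULL on failure.
logistic_core <- function(y, x) {
  X <- cbind(1, x)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) return(NULL)
  R <- qr.R(fit$qr)
  if (any(abs(diag(R)) < 1e-10)) return(NULL)
  vc <- chol2inv(R)
  list(coef = fit$coefficients, se = sqrt(diag(vc)),
       deviance = fit$deviance, null_deviance = fit$null.deviance)
}

# Complete-separation check for a single continuous predictor.
is_separated <- function(y, x) {
  x1 <- x[y == 1]; x0 <- x[y == 0]
  min(x1) > max(x0) || max(x1) < min(x0)
}

#' Fit a binary logistic regression of status on a score
#'
#' Maximum-likelihood intercept-and-slope fit of a binary annotation status
#' on a continuous association score (e.g. -log10 p or -log10 U). The odds
#' ratio is per one-unit increase in the score - one power of 10 in
#' association strength. The 95% confidence interval is Wald-type on the
#' log-odds scale.
#'
#' @param y Binary outcome vector (0/1), both classes present.
#' @param x Finite numeric score vector, same length as `y`.
#' @return Object of class `binary_logistic` with elements `beta`, `se`,
#'   `or`, `ci95`, `wald_p`, `intercept`, `n`, `deviance`, `null_deviance`.
#'   Use [tidy()] / [glance()] for tabular access.
#' @export
fit_binary_logistic <- function(y, x) {
  stopifnot(length(y) == length(x))
  if (!all(y %in% c(0, 1))) abort("y must be binary 0/1")
  if (!all(is.finite(x))) abort("x must be finite")
  if (length(unique(y)) < 2) abort("degenerate outcome: y is constant")
  if (is_separated(y, x)) {
    abort(paste0(
      "perfect separation: the score completely splits the two outcome ",
      "classes (all y=1 scores on one side of all y=0 scores); the MLE ",
      "does not exist"
    ))
  }
  core <- logistic_core(y, x)
  if (is.null(core)) abort("logistic fit failed to converge")
  beta <- core$coef[2]; se <- core$se[2]
  structure(
    list(
      beta = unname(beta), se = unname(se),
      or = exp(unname(beta)),
      ci95 = exp(unname(beta) + c(-1, 1) * 1.96 * unname(se)),
      wald_p = 2 * pnorm(-abs(beta / se)),
      intercept = unname(core$coef[1]),
      n = length(y),
      deviance = core$deviance, null_deviance = core$null_deviance
    ),
    class = "binary_logistic"
  )
}

#' @export
print.binary_logistic <- function(x, ...) {
  cat(sprintf(
    "<binary_logistic> n=%d  beta=%.4f (SE %.4f)  OR=%.3f [%.3f, %.3f]  p=%.3g\n",
    x$n, x$beta, x$se, x$or, x$ci95[1], x$ci95[2], x$wald_p))
  invisible(x)
}

#' @rdname fit_binary_logistic
#' @param x A `binary_logistic` object.
#' @param ... Unused.
#' @export
tidy.binary_logistic <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "score"),
    estimate = c(x$intercept, x$beta),
    std.error = c(NA_real_, x$se),
    statistic = c(NA_real_, x$beta / x$se),
    p.value = c(NA_real_, x$wald_p),
    or = c(NA_real_, x$or),
    conf.low = c(NA_real_, x$ci95[1]),
    conf.high = c(NA_real_, x$ci95[2])
  )
}

#' @rdname fit_binary_logistic
#' @export
glance.binary_logistic <- function(x, ...) {
  tibble(n = x$n, deviance = x$deviance, null.deviance = x$null_deviance,
         df.residual = x$n - 2L)
}

# Wald p for the slope only; NA on failure (used inside permutations).
wald_slope_p <- function(y, x) {
  core <- logistic_core(y, x)
  if (is.null(core)) return(NA_real_)
  2 * pnorm(-abs(core$coef[2] / core$se[2]))
}

#' Family-wise permutation adjustment for a family of logistic fits
#'
#' Calibrates the Wald p-values of a family of related logistic regressions
#' (one per tissue, or one per regulator) by the min-p / max-statistic
#' scheme: each permutation applies one shared shuffle to every member's
#' outcome vector, refits all members, and records the family-wide minimum
#' Wald p. The adjusted p-value of a member is
#' `(1 + #\{permutations with min-p <= observed p\}) / (n_perm + 1)`, which
#' controls the family-wise error rate and is never exactly 0. Permutations
#' in which any member fails to refit are redrawn (and counted in the
#' `n_redrawn` attribute).
#'
#' @param ys List of equal-length binary outcome vectors, one per family
#'   member (named by member).
#' @param xs Either a single score vector shared by all members, or a list
#'   parallel to `ys`.
#' @param n_perm Number of permutations (>= 100; the variant-level analyses
#'   use 10,000 and the gene-level analyses 1,000).
#' @param seed Integer seed; a fixed seed gives bit-identical adjusted
#'   p-values.
#' @return Tibble with one row per member: `unit`, `wald_p`, `p_perm`,
#'   `n_perm`; attribute `n_redrawn` counts redrawn permutations.
#' @export
permutation_family_adjust <- function(ys, xs, n_perm = 1000, seed = NULL) {
  if (length(ys) == 0) abort("family is empty")
  if (n_perm < 100) abort("n_perm must be >= 100")
  n <- length(ys[[1]])
  if (!all(lengths(ys) == n)) abort("all family outcomes must have equal length")
  if (!is.list(xs)) xs <- rep(list(xs), length(ys))
  units <- names(ys) %||% as.character(seq_along(ys))
  obs <- map_dbl(seq_along(ys), function(i) wald_slope_p(ys[[i]], xs[[i]]))
  if (anyNA(obs)) abort("observed fit failed for at least one family member")
  min_p <- numeric(n_perm)
  n_redrawn <- 0L
  with_local_seed(seed, {
    b <- 1L
    while (b <= n_perm) {
      idx <- sample.int(n)
      ps <- map_dbl(seq_along(ys), function(i) wald_slope_p(ys[[i]][idx], xs[[i]]))
      if (anyNA(ps)) {
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * n_perm) abort("too many failed permutation refits")
        next
      }
      min_p[b] <- min(ps)
      b <- b + 1L
    }
  })
  if (n_redrawn > 0) {
    inform(sprintf("%d permutation(s) redrawn after refit failure", n_redrawn))
  }
  out <- tibble(
    unit = units,
    wald_p = obs,
    p_perm = map_dbl(obs, function(p) (1 + sum(min_p <= p)) / (n_perm + 1)),
    n_perm = n_perm
  )
  attr(out, "n_redrawn") <- n_redrawn
  out
}
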