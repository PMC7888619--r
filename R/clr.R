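# Conditional logistic regression for 1:K matched sets.
#
# For family i with case exposure x_pi and control exposures x_s1i..x_sKi
# the conditional likelihood is
#   L = prod_i exp(x_pi'b) / (exp(x_pi'b) + sum_k exp(x_ski'b)),
# the likelihood of the transmission-disequilibrium model: b measures
# over-transmission of imputed expression (or allele count) to affected
# offspring.  Maximized by Newton-Raphson with step-halving; SE from the
# observed information.

#' Exclude the pseudo sibling closest to the proband
#'
#' Of the four recombined configurations, one must be genotype-identical
#' to the proband under error-free phasing; it is removed by dropping the
#' configuration whose exposure is closest to the proband's — smallest
#' absolute difference for a single exposure, smallest sum of squared
#' differences for multivariate exposures (fine-mapping).  Ties go to the
#' lowest configuration index.
#'
#' @param proband exposure of the proband: scalar, or length-q vector in
#'   multivariate mode.
#' @param configs exposures of the 4 configurations: length-4 vector, or
#'   4 x q matrix.
#' @return list with `controls` (the 3 retained exposures, vector or
#'   3 x q matrix) and `excluded` (dropped configuration index).
#' @export
select_controls <- function(proband, configs) {
  if (is.matrix(configs)) {
    stopifnot(nrow(configs) == 4, length(proband) == ncol(configs))
    d2 <- rowSums((configs - rep(proband, each = 4))^2)
    drop <- which.min(d2)
    list(controls = configs[-drop, , drop = FALSE], excluded = drop)
  } else {
    stopifnot(length(configs) == 4, length(proband) == 1)
    drop <- which.min(abs(configs - proband))
    list(controls = configs[-drop], excluded = drop)
  }
}

# Normalize exposures into an N x M x q array, member 1 = case.
clr_array <- function(x_case, x_ctrl) {
  if (is.list(x_ctrl)) {                       # list of K matrices (N x q)
    x_case <- as.matrix(x_case)
    K <- length(x_ctrl)
    N <- nrow(x_case); q <- ncol(x_case)
    A <- array(NA_real_, c(N, K + 1, q))
    A[, 1, ] <- x_case
    for (k in seq_len(K)) A[, k + 1, ] <- as.matrix(x_ctrl[[k]])
    A
  } else {                                      # scalar exposure, N x K ctrl
    x_ctrl <- as.matrix(x_ctrl)
    N <- length(x_case)
    stopifnot(nrow(x_ctrl) == N)
    A <- array(NA_real_, c(N, ncol(x_ctrl) + 1, 1))
    A[, 1, 1] <- x_case
    A[, -1, 1] <- x_ctrl
    A
  }
}

clr_loglik <- function(A, beta) {
  N <- dim(A)[1]; M <- dim(A)[2]
  eta <- matrix(0, N, M)
  for (j in seq_along(beta)) eta <- eta + matrix(A[, , j], N, M) * beta[j]
  mx <- apply(eta, 1, max)
  sum(eta[, 1] - mx - log(rowSums(exp(eta - mx))))
}

clr_score_info <- function(A, beta) {
  N <- dim(A)[1]; M <- dim(A)[2]; q <- dim(A)[3]
  eta <- matrix(0, N, M)
  for (j in seq_len(q)) eta <- eta + matrix(A[, , j], N, M) * beta[j]
  mx <- apply(eta, 1, max)
  P <- exp(eta - mx)
  P <- P / rowSums(P)
  xbar <- matrix(0, N, q)
  for (j in seq_len(q)) xbar[, j] <- rowSums(P * matrix(A[, , j], N, M))
  U <- colSums(matrix(A[, 1, ], N, q) - xbar)
  I <- matrix(0, q, q)
  for (m in seq_len(M)) {
    D <- matrix(A[, m, ], N, q) - xbar
    I <- I + crossprod(D * P[, m], D)
  }
  list(U = U, I = I, P = P)
}

#' Fit the matched conditional logistic transmission model
#'
#' Maximum conditional likelihood for 1 case + K matched controls per
#' family (K = 3 for the pseudo-sibling design, K = 2 for parent
#' controls, K = 1 for the matched-pair design).  Uninformative families
#' — all K+1 exposure vectors identical — contribute a constant and are
#' dropped (counted).  Complete separation (the case is the strict
#' extremum in every informative set, or the estimate runs past
#' `beta_cap`) is flagged and the p-value is taken from the score test at
#' beta = 0 instead of the Wald test.
#'
#' @param x_case case exposures: numeric length-N vector (single
#'   exposure) or N x q matrix (multivariate).
#' @param x_ctrl control exposures: N x K matrix (single exposure) or a
#'   list of K matrices, each N x q.
#' @param tol convergence tolerance on the maximum absolute score
#'   component (default 1e-8).
#' @param max_iter Newton-Raphson iteration cap (default 50).
#' @param beta_cap absolute bound past which an estimate is treated as
#'   separated (default 15, on standardized exposures).
#' @param ridge ridge added to the information when it is numerically
#'   singular (collinearity in fine-mapping); applied with a warning and
#'   flagged.
#' @return Object of class `clr_fit` with components `coefficients`,
#'   `se`, `z`, `p` (two-sided normal), `vcov`, `loglik`, `loglik0`
#'   (= -N_informative * log(K+1)), `n_total`, `n_informative`,
#'   `converged`, `separation`, `score_z`, `score_p`, `iterations`.
#' @seealso [select_controls()], [run_twas()]
#' @export
clr_fit <- function(x_case, x_ctrl, tol = 1e-8, max_iter = 50L,
                    beta_cap = 15, ridge = 1e-8) {
  A <- clr_array(x_case, x_ctrl)
  N_total <- dim(A)[1]; M <- dim(A)[2]; q <- dim(A)[3]
  cn <- if (is.matrix(x_case) && !is.null(colnames(x_case)))
    colnames(x_case) else if (q == 1) "exposure" else paste0("x", seq_len(q))

  # informative = not all members identical
  info <- rep(FALSE, N_total)
  for (j in seq_len(q)) {
    Xj <- matrix(A[, , j], N_total, M)
    info <- info | (apply(Xj, 1, max) - apply(Xj, 1, min) > 0)
  }
  A <- A[info, , , drop = FALSE]
  N <- sum(info)
  out <- structure(list(coefficients = stats::setNames(rep(NA_real_, q), cn),
                        se = stats::setNames(rep(NA_real_, q), cn),
                        z = stats::setNames(rep(NA_real_, q), cn),
                        p = stats::setNames(rep(NA_real_, q), cn),
                        vcov = matrix(NA_real_, q, q, dimnames = list(cn, cn)),
                        loglik = NA_real_, loglik0 = -N * log(M),
                        n_total = N_total, n_informative = N,
                        n_controls = M - 1L,
                        converged = FALSE, separation = FALSE,
                        ridged = FALSE,
                        score_z = NA_real_, score_p = NA_real_,
                        iterations = 0L),
                   class = "clr_fit")
  if (N == 0) {
    out$diagnostic <- "no informative matched sets"
    return(out)
  }

  s0 <- clr_score_info(A, rep(0, q))
  if (q == 1) {
    i0 <- s0$I[1, 1]
    out$score_z <- if (i0 > 0) s0$U[1] / sqrt(i0) else NA_real_
    out$score_p <- 2 * stats::pnorm(-abs(out$score_z))
  } else {
    chi <- tryCatch(drop(crossprod(s0$U, solve(s0$I, s0$U))),
                    error = function(e) NA_real_)
    out$score_z <- sqrt(max(chi, 0))
    out$score_p <- stats::pchisq(chi, df = q, lower.tail = FALSE)
  }

  # strict-extremum separation check (single exposure)
  if (q == 1) {
    Xc <- A[, 1, 1]
    Xs <- matrix(A[, -1, 1], N, M - 1)
    if (all(Xc > apply(Xs, 1, max)) || all(Xc < apply(Xs, 1, min)))
      out$separation <- TRUE
  }

  beta <- rep(0, q)
  ll <- clr_loglik(A, beta)
  conv <- FALSE
  it <- 0L
  ridged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    si <- clr_score_info(A, beta)
    if (max(abs(si$U)) < tol) { conv <- TRUE; break }
    I <- si$I
    step <- tryCatch(solve(I, si$U), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)) ||
        (q > 1 && rcond(I) < 1e-12)) {
      ridged <- TRUE
      I <- I + diag(max(diag(si$I)) * ridge + ridge, q)
      step <- solve(I, si$U)
    }
    # step-halving
    h <- 1
    repeat {
      cand <- beta + h * step
      llc <- clr_loglik(A, cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      h <- h / 2
      if (h < 1e-10) { cand <- beta; llc <- ll; break }
    }
    beta <- cand
    ll <- llc
    if (max(abs(beta)) > beta_cap) { out$separation <- TRUE; break }
  }
  if (ridged) {
    out$ridged <- TRUE
    warning("information matrix numerically singular (collinear ",
            "exposures); ridge-stabilized step used")
  }

  si <- clr_score_info(A, beta)
  conv <- conv || max(abs(si$U)) < tol
  V <- tryCatch(solve(si$I), error = function(e) {
    solve(si$I + diag(max(diag(si$I)) * ridge + ridge, q))
  })
  out$coefficients[] <- pmin(pmax(beta, -beta_cap), beta_cap)
  out$vcov[] <- V
  out$se[] <- sqrt(pmax(diag(as.matrix(V)), 0))
  out$z[] <- out$coefficients / out$se
  out$p[] <- 2 * stats::pnorm(-abs(out$z))
  out$loglik <- ll
  out$converged <- conv && !out$separation
  out$iterations <- it
  if (out$separation) {
    warning("complete separation detected; coefficient capped, ",
            "p-value from score test at beta = 0")
    out$p[] <- out$score_p
  }
  if (!conv && !out$separation)
    warning("conditional logistic fit did not converge in ", max_iter,
            " iterations (max |score| = ", format(max(abs(si$U))), ")")
  out
}

#' @export
print.clr_fit <- function(x, ...) {
  cat("Conditional logistic transmission model (1 case : ",
      x$n_controls, " matched controls)\n", sep = "")
  cat("Families:", x$n_informative, "informative of", x$n_total, "\n")
  if (all(is.na(x$coefficients))) {
    cat("No informative sets; no estimate.\n")
    return(invisible(x))
  }
  print(data.frame(beta = x$coefficients, se = x$se, z = x$z, p = x$p))
  if (x$separation)
    cat("NOTE: complete separation; p from score test at beta = 0\n")
  invisible(x)
}

#' @export
summary.clr_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$z, `Pr(>|z|)` = object$p)
  structure(list(coefficients = tab, loglik = object$loglik,
                 loglik0 = object$loglik0,
                 n_informative = object$n_informative,
                 n_total = object$n_total, converged = object$converged,
                 separation = object$separation),
            class = "summary.clr_fit")
}

#' @export
print.summary.clr_fit <- function(x, ...) {
  cat("Conditional logistic transmission model\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("Log-likelihood:", format(x$loglik), " (null:", format(x$loglik0),
      ")\n")
  cat("Informative families:", x$n_informative, "of", x$n_total, "\n")
  invisible(x)
}

#' @export
coef.clr_fit <- function(object, ...) object$coefficients

#' @export
vcov.clr_fit <- function(object, ...) object$vcov

#' @export
logLik.clr_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_informative, class = "logLik")
}

#' @export
confint.clr_fit <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * object$se,
              object$coefficients + zq * object$se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2,
                                       1 - (1 - level) / 2), trim = TRUE),
                        "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
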