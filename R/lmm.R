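# Family random-intercept linear mixed model, fitted by profiled REML.
#
# Model: y = X beta + u_family + e,  u ~ N(0, sigma_b^2), e ~ N(0, sigma_e^2),
# with families of size 1 or 2 (monozygotic co-twins share u).  Writing
# tau^2 = sigma_b^2 + sigma_e^2 and rho = sigma_b^2 / tau^2, the marginal
# covariance of a twin pair is tau^2 [[1, rho], [rho, 1]] and of a singleton
# tau^2.  An orthogonal within-pair rotation to (sum, difference) / sqrt(2)
# diagonalizes every block with eigenvalues tau^2 (1 + rho) and
# tau^2 (1 - rho), so for fixed rho the GLS fit is a weighted least squares
# in the rotated basis and tau^2 profiles out in closed form.  The restricted
# likelihood is then maximized over the single parameter rho in [0, 1) by
# bounded scalar optimization.

# Build the rotation for a family layout once; reused across bins in a scan.
family_transform <- function(family_ids) {
  family_ids <- as.character(family_ids)
  n <- length(family_ids)
  fam <- split(seq_len(n), family_ids)
  sizes <- lengths(fam)
  if (any(sizes > 2)) {
    input_error("family groups must have size 1 or 2.")
  }
  pairs <- fam[sizes == 2]
  singles <- unlist(fam[sizes == 1], use.names = FALSE)
  i1 <- vapply(pairs, `[`, integer(1), 1)
  i2 <- vapply(pairs, `[`, integer(1), 2)
  # Row k of the rotated data is: pair sums, then pair diffs, then singletons.
  list(i1 = i1, i2 = i2, singles = singles, n = n,
       n_pairs = length(i1),
       lam_type = c(rep(1L, length(i1)), rep(2L, length(i1)),
                    rep(0L, length(singles))))
}

rotate_rows <- function(M, tr) {
  M <- as.matrix(M)
  s2 <- sqrt(2)
  rbind((M[tr$i1, , drop = FALSE] + M[tr$i2, , drop = FALSE]) / s2,
        (M[tr$i1, , drop = FALSE] - M[tr$i2, , drop = FALSE]) / s2,
        M[tr$singles, , drop = FALSE])
}

# -2 * profiled restricted log-likelihood at rho (up to an additive
# constant): (n - p) log RSS(rho) + log|W| + log|X' W^-1 X|.
reml_objective <- function(rho, Xt, yt, lam_type, n, p) {
  lam <- rep(1, length(lam_type))
  lam[lam_type == 1L] <- 1 + rho
  lam[lam_type == 2L] <- 1 - rho
  w <- 1 / sqrt(lam)
  Xw <- Xt * w
  yw <- yt * w
  M <- crossprod(Xw)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xw, yw)))
  rss <- sum((yw - Xw %*% beta)^2)
  if (rss <= 0) return(Inf)
  (n - p) * log(rss) + sum(log(lam)) + 2 * sum(log(diag(ch)))
}

# Full GLS solution at a fixed rho; returns coefficients, covariance and
# variance components with tau^2 estimated by REML (RSS / (n - p)).
gls_at_rho <- function(rho, Xt, yt, lam_type, n, p) {
  lam <- rep(1, length(lam_type))
  lam[lam_type == 1L] <- 1 + rho
  lam[lam_type == 2L] <- 1 - rho
  w <- 1 / sqrt(lam)
  Xw <- Xt * w
  yw <- yt * w
  M <- crossprod(Xw)
  ch <- chol(M)
  beta <- drop(backsolve(ch, forwardsolve(t(ch), crossprod(Xw, yw))))
  rss <- sum((yw - Xw %*% beta)^2)
  tau2 <- rss / (n - p)
  Minv <- chol2inv(ch)
  se <- sqrt(tau2 * diag(Minv))
  list(beta = beta, se = se, tau2 = tau2, rss = rss)
}

#' Fit a family random-intercept linear mixed model
#'
#' Fits `y = X beta + u_family + e` by REML, profiling the restricted
#' likelihood over the intraclass correlation
#' `rho = sigma_family^2 / (sigma_family^2 + sigma_resid^2)` on `[0, 1)`
#' with closed-form generalized least squares at each `rho` (family blocks
#' of size at most two are diagonalized exactly).  Fixed effects are tested
#' with Wald statistics referred to a t distribution with between-within
#' denominator degrees of freedom (terms varying within families use the
#' within-family df, family-level terms the between-family df); set the
#' df to `Inf` mentally for the asymptotic z version -- at these sample
#' sizes the t reference is what keeps the type-I rate nominal.
#'
#' @param y Numeric response vector (one value per sample).
#' @param design Fixed-effect design matrix (including the intercept); must
#'   be of full column rank.
#' @param family_ids Family identifier per sample; groups of size 1 or 2.
#' @param rho Optional fixed value of the variance ratio; `NULL` (default)
#'   estimates it by REML.
#' @param tol Convergence tolerance of the scalar optimizer.
#'
#' @return An object of class `family_lmm` with the coefficient table,
#'   variance components (`sigma_family_sq`, `sigma_resid_sq`), the
#'   profiled `rho`, the REML objective value and a convergence flag.
#'   [tidy()] returns the coefficient table; [glance()] the model-level
#'   summary.
#' @export
fit_family_mixed_model <- function(y, design, family_ids, rho = NULL,
                                   tol = 1e-8) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || length(family_ids) != n) {
    input_error("`y`, `design` and `family_ids` must have matching length.")
  }
  if (qr(X)$rank < p) {
    abort("design matrix is rank deficient.", class = "twindmr_model_error")
  }
  if (length(unique(family_ids)) < 2) {
    input_error("at least 2 families are required.")
  }
  tr <- family_transform(family_ids)
  Xt <- rotate_rows(X, tr)
  yt <- drop(rotate_rows(matrix(y, ncol = 1), tr))
  fit_family_lmm_rotated(Xt, yt, tr$lam_type, n, p,
                         terms = colnames(X), rho = rho, tol = tol)
}

# Core fit on pre-rotated data (shared with the per-bin scan loop).
fit_family_lmm_rotated <- function(Xt, yt, lam_type, n, p, terms,
                                   rho = NULL, tol = 1e-8) {
  converged <- TRUE
  objective <- NA_real_
  if (is.null(rho)) {
    if (any(lam_type != 0L)) {
      opt <- tryCatch(
        optimize(reml_objective, interval = c(0, 1 - 1e-8),
                 Xt = Xt, yt = yt, lam_type = lam_type, n = n, p = p,
                 tol = tol),
        error = function(e) NULL
      )
      if (is.null(opt) || !is.finite(opt$objective)) {
        converged <- FALSE
        rho <- 0
      } else {
        # optimize() never lands exactly on the boundary; the null case
        # rho = 0 is common, so compare explicitly.
        at0 <- reml_objective(0, Xt, yt, lam_type, n, p)
        if (at0 <= opt$objective) {
          rho <- 0
          objective <- at0
        } else {
          rho <- opt$minimum
          objective <- opt$objective
        }
      }
    } else {
      # All singletons: rho is unidentifiable and the fit reduces to OLS.
      rho <- 0
      objective <- reml_objective(0, Xt, yt, lam_type, n, p)
    }
  } else {
    check_number(rho, "rho", 0, 1 - 1e-12)
    objective <- reml_objective(rho, Xt, yt, lam_type, n, p)
  }
  fit <- tryCatch(gls_at_rho(rho, Xt, yt, lam_type, n, p),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(
      list(coefficients = setNames(rep(NA_real_, p), terms),
           se = setNames(rep(NA_real_, p), terms),
           z = setNames(rep(NA_real_, p), terms),
           df = setNames(rep(NA_real_, p), terms),
           p.value = setNames(rep(NA_real_, p), terms),
           rho = NA_real_, sigma_family_sq = NA_real_,
           sigma_resid_sq = NA_real_, objective = NA_real_,
           n = n, converged = FALSE),
      class = "family_lmm"
    ))
  }
  z <- fit$beta / fit$se
  # Between-within denominator degrees of freedom (as in nlme / SAS
  # DDFM=BW): terms varying within at least one family are tested against
  # the within-family df, purely family-level terms against the
  # between-family df.
  n_pairs <- sum(lam_type == 1L)
  n_fam <- n_pairs + sum(lam_type == 0L)
  inner <- apply(abs(Xt[lam_type == 2L, , drop = FALSE]) > 1e-10, 2, any)
  p_inner <- sum(inner)
  p_outer <- p - p_inner
  df_inner <- n - n_fam - p_inner
  df_outer <- max(n_fam - p_outer, 1)
  df <- ifelse(inner, df_inner, df_outer)
  if (df_inner <= 0) df <- rep(df_outer, p)
  df[1] <- max(df)  # intercept
  structure(
    list(coefficients = setNames(fit$beta, terms),
         se = setNames(fit$se, terms),
         z = setNames(z, terms),
         df = setNames(df, terms),
         p.value = setNames(2 * pt(-abs(z), df), terms),
         rho = rho,
         sigma_family_sq = rho * fit$tau2,
         sigma_resid_sq = (1 - rho) * fit$tau2,
         objective = objective,
         n = n,
         converged = converged),
    class = "family_lmm"
  )
}

#' @export
print.family_lmm <- function(x, ...) {
  cat("<family_lmm> family random-intercept model (profiled REML)\n")
  print(tidy(x))
  cat(sprintf("sigma_family^2 = %.4g, sigma_resid^2 = %.4g (rho = %.4f)\n",
              x$sigma_family_sq, x$sigma_resid_sq, x$rho))
  invisible(x)
}

#' @method tidy family_lmm
#' @export
tidy.family_lmm <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(x$z),
         df = unname(x$df),
         p.value = unname(x$p.value))
}

#' @method glance family_lmm
#' @export
glance.family_lmm <- function(x, ...) {
  tibble(sigma_family_sq = x$sigma_family_sq,
         sigma_resid_sq = x$sigma_resid_sq,
         rho = x$rho,
         reml_objective = x$objective,
         nobs = x$n,
         converged = x$converged)
}
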