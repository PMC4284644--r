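# Causal inference test: does methylation (M) mediate the effect of a
# genetic locus (L) on a trait (T)?  Four component conditions are tested
# and combined as an intersection-union test: the omnibus p is the maximum
# of the four, so mediation is supported only when every condition holds.
#
#   1. L is associated with T            (p1: L in T ~ L + covariates)
#   2. L is associated with M given T    (p2: L in M ~ L + T + covariates)
#   3. M is associated with T given L    (p3: M in T ~ M + L + covariates)
#   4. L is NOT associated with T given M -- an equivalence-style
#      condition, assessed by permutation (p4, below).
#
# Condition 4 distinguishes full mediation (L -> M -> T, where
# conditioning on M removes the L-T association) from direct or reactive
# architectures (where it does not).  The permutation scheme preserves the
# marginal L-T association while destroying the M-T link: the trait is
# permuted within strata of L (for SNP dosages the strata are the
# genotype classes), and the F statistic for L in T ~ M + L + covariates
# is recomputed for each permuted trait.  Under full mediation the
# observed F collapses once M is in the model while the permuted F's
# retain the full marginal L-T signal, so
# p4 = (1 + #[F_perm <= F_obs]) / (B + 1) is small; under a direct L -> T
# effect the observed F is as large as the permuted ones and p4 is large.

# F statistic for the last q columns of X (vs the reduced model without
# them), computed for each column of Tmat via projections.
f_stat_cols <- function(Tmat, Q_full, Q_red, df_full, q = 1) {
  tot <- colSums(Tmat^2)
  rss_full <- tot - colSums((crossprod(Q_full, Tmat))^2)
  rss_red <- tot - colSums((crossprod(Q_red, Tmat))^2)
  ((rss_red - rss_full) / q) / (rss_full / df_full)
}

lm_term_p <- function(y, X, term) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort("collinear design in causal inference test.",
          class = "twindmr_model_error")
  }
  coef <- qr.coef(qrX, y)
  resid <- y - X %*% coef
  df <- length(y) - ncol(X)
  s2 <- sum(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  j <- match(term, colnames(X))
  se <- sqrt(s2 * XtXinv[j, j])
  tstat <- coef[j] / se
  2 * pt(-abs(tstat), df)
}

#' Causal inference test for methylation-mediated genetic effects
#'
#' Tests whether methylation `M` mediates the effect of locus `L` on trait
#' `T` by combining four component tests (association of L with T; of L
#' with M given T; of M with T given L; and a permutation-based test that
#' the residual L-T association given M is small) into an omnibus p-value,
#' the maximum of the four.  A binary trait is handled by linear
#' probability regressions throughout, keeping the permutation statistic
#' F-based.
#'
#' @param L Numeric locus vector (dosage 0-2, fractional allowed).
#' @param M Numeric methylation vector.
#' @param trait Numeric or 0/1 trait vector.
#' @param covariates Optional data frame / matrix of covariates.
#' @param B Number of trait permutations for the equivalence component.
#' @param seed Seed for the permutation stream.
#' @param n_strata Maximum number of L strata for the permutation (distinct
#'   dosage values are used when fewer).
#'
#' @return A one-row tibble of class `cit_result`: `p1`-`p4`, `p_omnibus`
#'   (their maximum), `B` and an `untestable` flag.
#' @export
causal_inference_test <- function(L, M, trait, covariates = NULL, B = 1000,
                                  seed = 1, n_strata = 10) {
  n <- length(L)
  if (length(M) != n || length(trait) != n) {
    input_error("`L`, `M` and `trait` must have equal length.")
  }
  if (n < 30) input_error("causal inference test requires >= 30 samples.")
  if (var(L) == 0) input_error("`L` is constant.")
  if (B < 100) warn("B < 100 permutations gives a coarse p4.")
  if (var(M) == 0 || var(as.numeric(trait)) == 0) {
    out <- tibble(p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
                  p4 = NA_real_, p_omnibus = NA_real_, B = B,
                  untestable = TRUE)
    class(out) <- c("cit_result", class(out))
    return(out)
  }
  trait <- as.numeric(trait)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  base <- cbind(`(Intercept)` = rep(1, n), C)
  p1 <- lm_term_p(trait, cbind(base, L = L), "L")
  p2 <- lm_term_p(M, cbind(base, trait = trait, L = L), "L")
  p3 <- lm_term_p(trait, cbind(base, L = L, M = M), "M")

  X_full <- cbind(base, M = M, L = L)
  X_red <- cbind(base, M = M)
  Q_full <- qr.Q(qr(X_full))
  Q_red <- qr.Q(qr(X_red))
  df_full <- n - ncol(X_full)
  f_obs <- f_stat_cols(matrix(trait, ncol = 1), Q_full, Q_red, df_full)
  strata <- if (length(unique(L)) <= n_strata) {
    match(L, sort(unique(L)))
  } else {
    as.integer(cut(L, breaks = unique(quantile(L, probs = seq(0, 1,
                     length.out = n_strata + 1))), include.lowest = TRUE))
  }
  Tperm <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      out <- trait
      for (s in unique(strata)) {
        idx <- which(strata == s)
        out[idx] <- trait[idx][sample.int(length(idx))]
      }
      out
    }, numeric(n))
  })
  f_perm <- f_stat_cols(Tperm, Q_full, Q_red, df_full)
  p4 <- (1 + sum(f_perm <= f_obs)) / (B + 1)
  out <- tibble(p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                p_omnibus = max(p1, p2, p3, p4), B = B, untestable = FALSE)
  class(out) <- c("cit_result", class(out))
  out
}
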