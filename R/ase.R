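# Beta-binomial allelic-imbalance test of RNA counts against the plasmid DNA
# proportion, plus genome-wide overdispersion estimation.

#' Estimate genome-wide beta-binomial overdispersion
#'
#' Two estimators of the single genome-wide overdispersion `rho` used by
#' [test_ase()]:
#'
#' * `"replicates"` (default, requires >= 2 replicates per SNP): a
#'   variance-decomposition estimator built on the between-replicate spread of
#'   the allele proportion. A true allelic effect shifts every replicate of a
#'   SNP by the same amount, so the across-replicate sample variance of
#'   `R/N` isolates overdispersion plus binomial noise and is immune both to
#'   true effects and to DNA-proportion error. Solves
#'   `sum_i s2_i = sum_i pq_i * (rho (1 - h_i) + h_i)` for `rho`, where
#'   `h_i = mean_j(1/N_ij)` and `pq_i` is the pooled-proportion variance
#'   factor (bias-corrected for the pooled estimate's own noise).
#' * `"moments"`: the single-replicate method-of-moments contrast against the
#'   DNA proportion,
#'   `rho = max(0, sum_i[(R_i - N_i p0_i)^2 - N_i p0_i q0_i] /
#'   sum_i[N_i (N_i - 1) p0_i q0_i])`. Simple, but biased upward by any true
#'   allelic effects present in the data (they enter the squared residual);
#'   use on null or effect-sparse data, or per replicate.
#'
#' @param counts RNA allele-count table (orientations pooled).
#' @param dna DNA proportions from [estimate_dna_proportion()] (required for
#'   `"moments"`, unused by `"replicates"`).
#' @param method `"replicates"` or `"moments"`.
#' @return object of class `dispersion_estimate`: `rho`, `n_snps_used`,
#'   `method`.
#' @export
estimate_overdispersion <- function(counts, dna = NULL,
                                    method = c("replicates", "moments")) {
  method <- match.arg(method)
  x <- as_dt(counts)
  require_cols(x, c("snp_id", "ref_count", "alt_count"), "count table")
  x <- x[ref_count + alt_count > 0L]
  if (nrow(x) == 0L) stop("no testable SNPs for dispersion estimation",
                          call. = FALSE)
  res <- if (method == "replicates") rho_replicates(x) else rho_moments(x, dna)
  if (res$n_snps_used < 50L) {
    warning("overdispersion estimated from fewer than 50 SNPs; ",
            "estimate may be unstable")
  }
  structure(list(rho = res$rho, n_snps_used = res$n_snps_used,
                 method = method),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("Overdispersion rho = %.4f (%s method, %d SNPs)\n",
              x$rho, x$method, x$n_snps_used))
  invisible(x)
}

rho_replicates <- function(x) {
  per <- x[, {
    N <- ref_count + alt_count
    k <- length(N)
    if (k < 2L) {
      list(s2 = NA_real_, pq = NA_real_, h = NA_real_, k = k)
    } else {
      phat <- ref_count / N
      ptil <- (sum(ref_count) + 0.5) / (sum(N) + 1)
      list(s2 = var(phat), pq = ptil * (1 - ptil), h = mean(1 / N), k = k)
    }
  }, by = snp_id]
  per <- per[!is.na(s2) & pq > 0]
  if (nrow(per) == 0L) {
    stop("the 'replicates' dispersion estimator needs >= 2 replicates per SNP",
         call. = FALSE)
  }
  model_var <- function(rho) {
    g <- rho * (1 - per$h) + per$h
    # pooled-proportion factor corrected for its own sampling noise
    pq1 <- per$pq / pmax(1 - g / per$k, 0.5)
    pq1 * g
  }
  f <- function(rho) sum(per$s2 - model_var(rho))
  rho <- if (f(0) <= 0) 0 else {
    if (f(0.49) > 0) 0.49 else uniroot(f, c(0, 0.49), tol = 1e-8)$root
  }
  list(rho = clamp(rho, 0, 0.49), n_snps_used = nrow(per))
}

rho_moments <- function(x, dna) {
  if (is.null(dna)) {
    stop("the 'moments' dispersion estimator needs DNA proportions", call. = FALSE)
  }
  m <- merge(x, as_dt(dna)[, .(snp_id, p0)], by = "snp_id")
  if (nrow(m) == 0L) stop("no testable SNPs for dispersion estimation",
                          call. = FALSE)
  N <- m$ref_count + m$alt_count
  R <- m$ref_count
  pq <- m$p0 * (1 - m$p0)
  num <- sum((R - N * m$p0)^2 - N * pq)
  den <- sum(N * (N - 1) * pq)
  if (den <= 0) {
    warning("all SNPs have N <= 1; overdispersion not identifiable, using 0")
    return(list(rho = 0, n_snps_used = length(unique(m$snp_id))))
  }
  list(rho = clamp(num / den, 0, 0.49),
       n_snps_used = length(unique(m$snp_id)))
}

#' Test allelic imbalance against the DNA proportion
#'
#' Per-record beta-binomial test on the logit scale: with `N = R + A`,
#' `p_hat = (R + 0.5) / (N + 1)`, the effect is
#' `beta = logit(p_hat) - logit(p0)` with variance
#' `(1 + (N - 1) rho) / (N p_hat (1 - p_hat))`, plus the delta-method DNA
#' term `var0 / (p0 (1 - p0))^2` when `propagate_dna_var = TRUE`. The DNA
#' component is returned separately (`var_dna`) because it is shared across
#' replicates of a SNP and [fixed_effects()] must not treat it as
#' independent. Records with `N` below `exact_min_n` get an exact two-sided
#' beta-binomial tail p-value instead of the normal approximation.
#'
#' @param counts allele-count table (any id columns among `snp_id`,
#'   `orientation`, `replicate`, `fraction`, `concentration` are preserved).
#' @param dna DNA proportions from [estimate_dna_proportion()].
#' @param rho overdispersion: a scalar, a `dispersion_estimate`, or a
#'   `data.table` with a `rho` column to be merged on its other columns
#'   (e.g. per fraction/concentration).
#' @param propagate_dna_var include the DNA-proportion variance in `se`?
#' @param stabilize_variance evaluate the variance's `p(1-p)` factor at the
#'   SNP's replicate-pooled proportion instead of the single replicate's
#'   `p_hat` (default `TRUE`). With one replicate the two coincide. Pooling
#'   decouples the inverse-variance meta-analysis weights from each
#'   replicate's own sampling noise; replicate-local weights are
#'   anticorrelated with the replicate's effect estimate and noticeably
#'   deflate the combined z (see the methods vignette).
#' @param exact_min_n records with fewer molecules than this use the exact
#'   beta-binomial test (set 0 to disable).
#' @return `data.table` with id columns plus `beta`, `se`, `var_dna`, `z`,
#'   `pvalue`, `n_rna`. Records with `N = 0` are dropped and listed in the
#'   `"untestable"` attribute.
#' @export
test_ase <- function(counts, dna, rho = 0, propagate_dna_var = TRUE,
                     stabilize_variance = TRUE, exact_min_n = 10) {
  x <- as_dt(counts)
  require_cols(x, c("snp_id", "ref_count", "alt_count"), "count table")
  d <- as_dt(dna)
  require_cols(d, c("snp_id", "p0", "var0"), "DNA proportion table")
  m <- merge(x, d[, .(snp_id, p0, var0)], by = "snp_id")

  if (inherits(rho, "dispersion_estimate")) rho <- rho$rho
  if (is.data.frame(rho)) {
    rt <- as_dt(rho)
    keys <- setdiff(names(rt), "rho")
    m <- merge(m, rt, by = keys)
  } else {
    stopifnot(is.numeric(rho), length(rho) == 1L, rho >= 0, rho < 0.5)
    set(m, j = "rho", value = rho)
  }

  untestable <- m[ref_count + alt_count == 0L, unique(snp_id)]
  m <- m[ref_count + alt_count > 0L]
  N <- m$ref_count + m$alt_count
  p_hat <- (m$ref_count + 0.5) / (N + 1)
  beta <- qlogis(p_hat) - qlogis(m$p0)
  if (stabilize_variance) {
    grp <- setdiff(intersect(ID_COLS, names(m)), "replicate")
    m[, p_var := (sum(ref_count) + 0.5) / (sum(ref_count + alt_count) + 1),
      by = grp]
    p_var <- m$p_var
    m[, p_var := NULL]
  } else {
    p_var <- p_hat
  }
  var_rep <- (1 + (N - 1) * m$rho) / (N * p_var * (1 - p_var))
  var_dna <- if (propagate_dna_var) m$var0 / (m$p0 * (1 - m$p0))^2 else 0
  se <- sqrt(var_rep + var_dna)
  z <- beta / se
  pvalue <- z_pvalue(z)

  if (exact_min_n > 0) {
    small <- which(N < exact_min_n)
    if (length(small) > 0L) {
      pvalue[small] <- mapply(exact_bb_pvalue,
                              m$ref_count[small], N[small],
                              m$p0[small], m$rho[small])
    }
  }

  keep_cols <- intersect(ID_COLS, names(m))
  res <- m[, keep_cols, with = FALSE]
  res[, `:=`(beta = beta, se = se,
             var_dna = if (propagate_dna_var) var_dna else 0,
             z = z, pvalue = pvalue, n_rna = N)]
  setattr(res, "untestable", untestable)
  res[]
}

# Exact two-sided beta-binomial tail probability (sum of outcome
# probabilities not exceeding the observed one, the binom.test convention).
exact_bb_pvalue <- function(R, N, p0, rho) {
  k <- 0:N
  if (rho <= 0) {
    pr <- dbinom(k, N, p0)
  } else {
    a <- p0 * (1 - rho) / rho
    b <- (1 - p0) * (1 - rho) / rho
    pr <- exp(lchoose(N, k) + lbeta(k + a, N - k + b) - lbeta(a, b))
    pr <- pr / sum(pr)
  }
  min(1, sum(pr[pr <= pr[R + 1] * (1 + 1e-7)]))
}

s2 <- pq <- h <- n_mol <- p_var <- NULL
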