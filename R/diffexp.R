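# Differential expression for three single-library samples: conditional
# binomial / quasi-binomial test, ln fold changes, BH correction, and the
# three-comparison orchestration.

COMPARISONS <- c("H_vs_P1", "H_vs_P2", "P1_vs_P2")

#' Conditional binomial test for two single-library counts
#'
#' Tests equal relative abundance of one transcript in two libraries by
#' conditioning on the fragment total: under the null, `count_a` given
#' `count_a + count_b` is binomial with success probability
#' `total_a / (total_a + total_b)`.  With `overdispersion = 1` the exact
#' two-sided binomial p-value is returned (summing all outcomes no more
#' probable than the observed one); with `overdispersion > 1` the binomial
#' variance is inflated by that factor and a two-sided quasi-binomial
#' normal approximation is used.  The result is exactly symmetric in the
#' two samples (arguments are canonicalized before computing).
#'
#' @param count_a,count_b fragment counts for the transcript.
#' @param total_a,total_b total mapped fragments per library (> 0).
#' @param overdispersion variance-inflation factor (>= 1).
#' @return two-sided p-value in `[0, 1]`; 1 when both counts are zero.
#' @examples
#' test_differential(0, 1e6, 100, 1e6) # ~2 * 0.5^100
#' @export
test_differential <- function(count_a, total_a, count_b, total_b,
                              overdispersion = 1) {
  if (total_a <= 0 || total_b <= 0) contract_error("totals must be positive")
  if (count_a < 0 || count_b < 0) contract_error("counts must be >= 0")
  if (count_a > total_a || count_b > total_b) {
    contract_error("counts cannot exceed totals")
  }
  if (overdispersion < 1) config_error("overdispersion must be >= 1")
  # canonical order => exact symmetry under argument swap
  if (total_a > total_b || (total_a == total_b && count_a > count_b)) {
    tmp <- count_a
    count_a <- count_b
    count_b <- tmp
    tmp <- total_a
    total_a <- total_b
    total_b <- tmp
  }
  n <- count_a + count_b
  if (n == 0) {
    return(1)
  }
  p0 <- total_a / (total_a + total_b)
  if (overdispersion > 1) {
    se <- sqrt(n * p0 * (1 - p0) * overdispersion)
    z <- (count_a - n * p0) / se
    return(min(1, 2 * stats::pnorm(-abs(z))))
  }
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[count_a + 1] * (1 + 1e-7)]))
}

# Vectorized quasi-binomial p for the pipeline path (rho > 1 everywhere).
.quasi_p <- function(a, b, ta, tb, rho) {
  n <- a + b
  p0 <- ta / (ta + tb)
  z <- ifelse(n == 0, 0, (a - n * p0) / sqrt(pmax(n, 1) * p0 * (1 - p0) * rho))
  pmin(1, 2 * stats::pnorm(-abs(z)))
}

#' Natural-log fold change
#'
#' `ln((fpkm_x + pseudo) / (fpkm_h + pseudo))`: the study's fold-change
#' convention `ln(x / hybrid)`, stabilized with a pseudo-FPKM so zero
#' expression stays finite.  Negative values mean the transcript is up in
#' the hybrid.
#'
#' @param fpkm_x parental FPKM (or first sample of the comparison).
#' @param fpkm_h hybrid FPKM (or second sample).
#' @param pseudo_fpkm positive stabilizer added to both (default 0.1).
#' @return ln ratio; vectorized.
#' @examples
#' compute_fold_change(0, 10, 0.1) # ln(0.1/10.1) ~ -4.615
#' @export
compute_fold_change <- function(fpkm_x, fpkm_h, pseudo_fpkm = 0.1) {
  if (pseudo_fpkm <= 0) config_error("pseudo_fpkm must be > 0")
  if (any(fpkm_x < 0) || any(fpkm_h < 0)) {
    contract_error("FPKM values must be >= 0")
  }
  log((fpkm_x + pseudo_fpkm) / (fpkm_h + pseudo_fpkm))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; each adjusted value is at
#' least its raw p-value.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    contract_error("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differential transcripts for the three comparisons
#'
#' Runs the conditional binomial / quasi-binomial test per transcript for
#' H vs P1, H vs P2 and P1 vs P2, computes the study's ln fold change
#' (`ln(x/H)` for the hybrid comparisons, `ln(P1/P2)` for the parental
#' one), adjusts FDR within each comparison separately, and flags
#' significance as `fdr <= alpha` and `|ln_ratio| >= min_abs_ln_ratio`.
#'
#' The count overdispersion `nb_dispersion` (phi) is mapped to the
#' conditional variance-inflation factor `rho = (n + 2/phi) / (1 + 2/phi)`
#' per transcript (the beta-binomial conditional of two gamma-Poisson
#' counts with common dispersion), clamped at >= 1; `phi = 0` uses the
#' exact conditional binomial test.
#'
#' @param expression table from [expression_table()] (counts + FPKM for
#'   samples H, P1, P2).
#' @param alpha FDR threshold (default 0.05).
#' @param min_abs_ln_ratio minimum absolute ln fold change (default 0).
#' @param pseudo_fpkm stabilizer for fold changes (default 0.1).
#' @param nb_dispersion count overdispersion phi (default 0).
#' @return data frame with one row per transcript per comparison:
#'   `transcript_id`, `comparison`, `ln_ratio`, `p_value`, `fdr`,
#'   `significant`, `direction`.
#' @export
call_de <- function(expression, alpha = 0.05, min_abs_ln_ratio = 0,
                    pseudo_fpkm = 0.1, nb_dispersion = 0) {
  need <- c(paste0("count_", c("H", "P1", "P2")),
    paste0("fpkm_", c("H", "P1", "P2")))
  if (!all(need %in% names(expression))) {
    config_error("expression table must have the three samples H, P1, P2")
  }
  totals <- c(
    H = sum(expression$count_H),
    P1 = sum(expression$count_P1),
    P2 = sum(expression$count_P2)
  )
  pairs <- list(
    H_vs_P1 = c("P1", "H"), # x = parent, h = hybrid
    H_vs_P2 = c("P2", "H"),
    P1_vs_P2 = c("P1", "P2")
  )
  phi <- nb_dispersion
  out <- lapply(names(pairs), function(cmp) {
    x <- pairs[[cmp]][1]
    h <- pairs[[cmp]][2]
    a <- expression[[paste0("count_", x)]]
    b <- expression[[paste0("count_", h)]]
    n <- a + b
    if (phi > 0) {
      rho <- pmax(1, (n + 2 / phi) / (1 + 2 / phi))
      p <- .quasi_p(a, b, totals[[x]], totals[[h]], rho)
    } else {
      p <- vapply(seq_along(a), function(i) {
        test_differential(a[i], totals[[x]], b[i], totals[[h]])
      }, numeric(1))
    }
    lr <- compute_fold_change(
      expression[[paste0("fpkm_", x)]],
      expression[[paste0("fpkm_", h)]],
      pseudo_fpkm
    )
    fdr <- adjust_fdr(p)
    sig <- fdr <= alpha & abs(lr) >= min_abs_ln_ratio
    dir <- if (cmp == "P1_vs_P2") {
      rep("n/a", length(lr))
    } else {
      ifelse(lr < 0, "up_in_hybrid", ifelse(lr > 0, "down_in_hybrid", "n/a"))
    }
    data.frame(
      transcript_id = expression$transcript_id,
      comparison = cmp,
      ln_ratio = lr,
      p_value = p,
      fdr = fdr,
      significant = sig,
      direction = dir,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
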