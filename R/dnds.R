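#' Codon mutation-model constants
#'
#' Under the Nei–Gojobori style site counting that the estimator assumes,
#' a codon carries on average 0.77 synonymous and 2.23 non-synonymous sites,
#' so the synonymous/non-synonymous site ratio S/N is the constant
#' 0.77/2.23 = 0.345 (3 significant figures). The estimator multiplies the
#' mutation-count ratio pN/pS by this constant; it is never recomputed per
#' sequence.
#'
#' @format Named list with `syn_sites_per_codon` (0.77),
#'   `nonsyn_sites_per_codon` (2.23) and `sn_ratio` (0.345).
#' @export
codon_model_constants <- list(
  syn_sites_per_codon = 0.77,
  nonsyn_sites_per_codon = 2.23,
  sn_ratio = 0.345
)

#' Mutation rate implied by a containment index
#'
#' Under the simple independent-mutation model, a k-mer survives mutation
#' with probability `(1-p)^k`, so the containment of the mutated sequence's
#' k-mer set in the original's satisfies `C = (1-p)^k` and the per-position
#' mutation rate is `p = 1 - C^(1/k)`. This is the ANI/AAI relationship:
#' `C^(1/k)` estimates average nucleotide (or amino-acid) identity.
#'
#' @param c Containment index in `[0,1]`; debiased estimates slightly above
#'   1 are clamped with a warning.
#' @param k K-mer length used for the sketch.
#' @return Mutation rate in `[0,1]`; `NA` propagates.
#' @export
#' @examples
#' mutation_rate_from_containment(1, 21)   # identical sequences: 0
#' mutation_rate_from_containment(0.5, 1)  # 0.5
mutation_rate_from_containment <- function(c, k) {
  stopifnot(k >= 1)
  if (any(!is.na(c) & c < 0)) stop("containment must be non-negative")
  over <- !is.na(c) & c > 1
  if (any(over)) {
    warning("debiased containment > 1 clamped to 1")
    c[over] <- 1
  }
  1 - c^(1 / k)
}

#' Ratio of expected non-synonymous to synonymous mutation counts
#'
#' Conditioning the codon Bernoulli mutation model on "some nucleotide in
#' the codon mutated" (probability `1-(1-p)^3`) splits that event into a
#' non-synonymous part, with probability `p_aa`, and a synonymous part,
#' `1 - p_aa - (1-p)^3`. Their ratio estimates pN/pS.
#'
#' @param p_aa Per-codon amino-acid mutation probability (1 − AAI).
#' @param p_nt Per-position nucleotide mutation probability (1 − ANI).
#' @return List with `ratio`, `p_N`, `p_S` and `status` (`"ok"`,
#'   `"undefined_identical"` when both rates are 0, or
#'   `"undefined_nonpositive_pS"` when the synonymous probability is <= 0).
#' @export
#' @examples
#' pn_ps_ratio(0.1, 1 - 0.729^(1/3))$ratio  # 0.1 / 0.171
pn_ps_ratio <- function(p_aa, p_nt) {
  stopifnot(p_aa >= 0, p_aa <= 1, p_nt >= 0, p_nt <= 1)
  p_any <- 1 - (1 - p_nt)^3   # P(codon has >= 1 nucleotide mutation)
  p_N <- p_aa
  p_S <- p_any - p_aa
  if (p_aa == 0 && p_any == 0) {
    status <- "undefined_identical"
    ratio <- NA_real_
  } else if (p_S <= 0) {
    status <- "undefined_nonpositive_pS"
    ratio <- NA_real_
  } else {
    status <- "ok"
    ratio <- p_N / p_S
  }
  list(ratio = ratio, p_N = p_N, p_S = p_S, status = status)
}

#' FracMinHash dN/dS estimate from a DNA/protein containment pair
#'
#' The core closed-form estimator: with `a = c_aa^(1/k_aa)` (observed AAI)
#' and `c_nt^(3/k_nt)` (probability a codon is nucleotide-identical,
#' `k_nt = 3 k_aa`),
#'
#' \deqn{dN/dS = \frac{1 - a}{a - c_{nt}^{3/k_{nt}}} \times 0.345}
#'
#' The numerator is the per-codon non-synonymous mutation probability `p_N`,
#' the denominator the synonymous probability `p_S`, and 0.345 the S/N site
#' ratio. Degenerate inputs give a status code instead of an error:
#' `c_aa = 0` (protein containment vanished), identical sequences
#' (`c_nt = c_aa = 1`), or a non-positive `p_S` (protein divergence
#' exceeding what the nucleotide divergence allows).
#'
#' @param c_nt DNA containment (k-mer length `3 * k_aa`).
#' @param c_aa Protein containment (k-mer length `k_aa`).
#' @param k_aa Amino-acid k-mer length.
#' @param query,target Optional pair labels carried into the result.
#' @return A one-row data frame of class `dnds_estimate` with columns
#'   `query`, `target`, `k_aa`, `k_nt`, `c_nt`, `c_aa`, `p_nt`, `p_aa`,
#'   `p_N`, `p_S`, `dnds`, `status`.
#' @export
#' @examples
#' fmh_dnds(c_nt = 0.8, c_aa = 0.9, k_aa = 7)
fmh_dnds <- function(c_nt, c_aa, k_aa, query = "", target = "") {
  stopifnot(k_aa >= 1)
  k_nt <- 3L * as.integer(k_aa)
  row <- data.frame(query = query, target = target,
                    k_aa = as.integer(k_aa), k_nt = k_nt,
                    c_nt = NA_real_, c_aa = NA_real_,
                    p_nt = NA_real_, p_aa = NA_real_,
                    p_N = NA_real_, p_S = NA_real_,
                    dnds = NA_real_, status = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.na(c_nt) || is.na(c_aa)) {
    row$status <- "undefined_zero_containment"
    class(row) <- c("dnds_estimate", class(row))
    return(row)
  }
  c_nt <- min(max(c_nt, 0), 1)
  c_aa <- min(max(c_aa, 0), 1)
  row$c_nt <- c_nt
  row$c_aa <- c_aa
  if (c_aa == 0 || c_nt == 0) {
    row$status <- "undefined_zero_containment"
    if (c_aa > 0 && c_nt == 0) {
      # DNA signal fully decayed but protein signal left: pS collapses to
      # a - 0; still computable, and finite
      a <- c_aa^(1 / k_aa)
      row$p_aa <- 1 - a
      row$p_nt <- 1
      row$p_N <- 1 - a
      row$p_S <- a
      row$dnds <- (1 - a) / a * codon_model_constants$sn_ratio
      row$status <- "ok"
    }
    class(row) <- c("dnds_estimate", class(row))
    return(row)
  }
  row$p_nt <- mutation_rate_from_containment(c_nt, k_nt)
  row$p_aa <- mutation_rate_from_containment(c_aa, k_aa)
  pp <- pn_ps_ratio(row$p_aa, row$p_nt)
  row$p_N <- pp$p_N
  row$p_S <- pp$p_S
  row$status <- pp$status
  if (pp$status == "ok") {
    row$dnds <- pp$ratio * codon_model_constants$sn_ratio
  }
  class(row) <- c("dnds_estimate", class(row))
  row
}

#' @export
print.dnds_estimate <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  print(y, ...)
  invisible(x)
}

#' Filter a table of dN/dS estimates by synonymous/non-synonymous signal
#'
#' Keeps rows with `status == "ok"`, `p_S >= min_pS` (enough synonymous
#' signal for a stable denominator) and `p_N <= max_pN` (protein divergence
#' still in the regime where containment tracks identity). Either rule can
#' be disabled by passing `-Inf`/`Inf`.
#'
#' @param estimates Data frame with `status`, `p_S`, `p_N` columns (rbind of
#'   [fmh_dnds()] rows).
#' @param min_pS Minimum synonymous per-codon probability (default 0.05).
#' @param max_pN Maximum non-synonymous per-codon probability (default 0.23).
#' @return The surviving rows.
#' @export
filter_estimates <- function(estimates, min_pS = 0.05, max_pN = 0.23) {
  if (!nrow(estimates)) return(estimates)
  keep <- estimates$status == "ok" &
    !is.na(estimates$p_S) & estimates$p_S >= min_pS &
    !is.na(estimates$p_N) & estimates$p_N <= max_pN
  out <- estimates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-wise median dN/dS
#'
#' Aggregates status-ok estimates to one median per group (e.g. genus). A
#' pair contributes only when both its members map to the same group; pairs
#' spanning two groups are dropped from the table (returned via the
#' `"crossing"` attribute for inspection).
#'
#' @param estimates Data frame of [fmh_dnds()] rows.
#' @param groups Named character vector mapping sequence/genome names to
#'   group labels.
#' @return Data frame with columns `group`, `median_dnds`, `n`; groups with
#'   no usable estimates are omitted. Even-sized groups use the mean of the
#'   two central values.
#' @export
aggregate_median <- function(estimates, groups) {
  ok <- estimates[estimates$status == "ok" & !is.na(estimates$dnds), ,
                  drop = FALSE]
  empty <- data.frame(group = character(0), median_dnds = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE)
  if (!nrow(ok)) return(empty)
  gq <- unname(groups[ok$query])
  gt <- unname(groups[ok$target])
  same <- !is.na(gq) & !is.na(gt) & gq == gt
  crossing <- ok[!same, , drop = FALSE]
  ok <- ok[same, , drop = FALSE]
  if (!nrow(ok)) return(empty)
  med <- tapply(ok$dnds, gq[same], stats::median)
  n <- tapply(ok$dnds, gq[same], length)
  out <- data.frame(group = names(med), median_dnds = as.numeric(med),
                    n = as.integer(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "crossing") <- crossing
  out
}
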