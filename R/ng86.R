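# Nei-Gojobori (1986) counting of synonymous/non-synonymous sites and
# differences, with Jukes-Cantor correction. Used as the alignment-based
# ground truth the sketch estimator is benchmarked against. Sequences must
# already be positionally comparable (equal length, same frame): this module
# never aligns.

BASES <- c("A", "C", "G", "T")

# memo caches, filled lazily: per-codon site fractions and per-codon-pair
# pathway-averaged differences
.ng86_env <- new.env(parent = emptyenv())

is_stop <- function(codon) {
  aa <- genetic_code()[codon]
  !is.na(aa) & aa == "*"
}

#' Synonymous and non-synonymous site fractions of a codon
#'
#' For each of the three positions, the fraction of the possible
#' single-nucleotide changes that are synonymous; changes creating a stop
#' codon are excluded and the remaining fractions renormalized, so the two
#' fractions always sum to 3 for a sense codon.
#'
#' @param codon A sense codon (3-mer over ACGT).
#' @return Numeric vector `c(syn, nonsyn)` with `syn + nonsyn == 3`.
#' @export
#' @examples
#' codon_sites("TTT")  # 1/3 synonymous (third-position T->C)
#' codon_sites("ATG")  # 0 synonymous sites
codon_sites <- function(codon) {
  code <- genetic_code()
  aa <- code[codon]
  if (is.na(aa)) stop("not an unambiguous codon: ", codon)
  if (aa == "*") {
    warning("stop codon ", codon, " excluded from site counting")
    return(c(syn = NA_real_, nonsyn = NA_real_))
  }
  key <- codon
  hit <- .ng86_env$sites[[key]]
  if (!is.null(hit)) return(hit)
  syn <- 0
  chars <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    n_syn <- 0L
    n_valid <- 0L
    for (b in setdiff(BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- b
      maa <- code[paste0(mut, collapse = "")]
      if (maa == "*") next  # neighbors through stops excluded
      n_valid <- n_valid + 1L
      if (maa == aa) n_syn <- n_syn + 1L
    }
    if (n_valid > 0L) syn <- syn + n_syn / n_valid
  }
  res <- c(syn = syn, nonsyn = 3 - syn)
  if (is.null(.ng86_env$sites)) .ng86_env$sites <- list()
  .ng86_env$sites[[key]] <- res
  res
}

#' Pathway-averaged synonymous/non-synonymous differences between two codons
#'
#' Codons differing at one position are classified directly against the
#' code table. For two or three differences, every ordering of the single
#' changes is walked; orderings passing through a stop codon are discarded
#' and the synonymous/non-synonymous step counts are averaged over the
#' remaining pathways. If every pathway is blocked by a stop (rare), all
#' pathways are used with stop-crossing steps counted as non-synonymous.
#'
#' @param a,b Sense codons (3-mers over ACGT).
#' @return Numeric vector `c(syn, nonsyn)`; the two always sum to the number
#'   of differing positions.
#' @export
#' @examples
#' codon_differences("GCT", "GCC")  # synonymous third-position change
codon_differences <- function(a, b) {
  code <- genetic_code()
  if (is.na(code[a]) || is.na(code[b])) stop("not unambiguous codons")
  if (code[a] == "*" || code[b] == "*") {
    stop("stop codon in pair (", a, ", ", b, ")")
  }
  if (a == b) return(c(syn = 0, nonsyn = 0))
  key <- paste0(a, b)
  hit <- .ng86_env$diffs[[key]]
  if (!is.null(hit)) return(hit)

  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  count_path <- function(order, allow_stops = FALSE) {
    cur <- ca
    syn <- 0L
    nonsyn <- 0L
    for (p in order) {
      nxt <- cur
      nxt[p] <- cb[p]
      aa1 <- code[paste0(cur, collapse = "")]
      aa2 <- code[paste0(nxt, collapse = "")]
      if (aa2 == "*" && !identical(paste0(nxt, collapse = ""), b)) {
        if (!allow_stops) return(NULL)  # pathway blocked
      }
      if (aa1 == aa2) syn <- syn + 1L else nonsyn <- nonsyn + 1L
      cur <- nxt
    }
    c(syn, nonsyn)
  }
  orders <- if (length(pos) == 1L) {
    list(pos)
  } else if (length(pos) == 2L) {
    list(pos, rev(pos))
  } else {
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    lapply(perms, function(i) pos[i])
  }
  counts <- Filter(Negate(is.null), lapply(orders, count_path))
  if (!length(counts)) {
    counts <- lapply(orders, count_path, allow_stops = TRUE)
  }
  m <- do.call(rbind, counts)
  res <- c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
  if (is.null(.ng86_env$diffs)) .ng86_env$diffs <- list()
  .ng86_env$diffs[[key]] <- res
  res
}

jukes_cantor <- function(p_raw) {
  ifelse(p_raw >= 0.75, NA_real_, -0.75 * log1p(-4 / 3 * p_raw))
}

#' NG86 dN/dS between two positionally comparable coding sequences
#'
#' Counts fractional synonymous/non-synonymous sites (averaged over both
#' sequences) and pathway-averaged differences codon by codon, converts the
#' raw proportions to substitution rates with the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)`, and reports their ratio. Codon pairs where
#' either codon contains `N` or is a stop are skipped (counted in
#' `n_skipped`).
#'
#' @param ref,query Equal-length nucleotide sequences, lengths divisible
#'   by 3. No alignment is performed.
#' @return Object of class `ng86_stats`: list with `S_sites`, `N_sites`,
#'   `S_diffs`, `N_diffs`, `pS_raw`, `pN_raw`, `dS`, `dN`, `dnds`, `status`
#'   (`"ok"`, `"undefined_dS_zero"`, or `"undefined_saturated"` when a raw
#'   proportion reaches the Jukes-Cantor singularity at 3/4), `n_codons`
#'   (used) and `n_skipped`.
#' @export
ng86_dnds <- function(ref, query) {
  if (nchar(ref) != nchar(query)) {
    stop("sequences must have equal length (no alignment is performed)")
  }
  cod_a <- codons(ref)
  cod_b <- codons(query)
  code <- genetic_code()
  aa_a <- code[cod_a]
  aa_b <- code[cod_b]
  usable <- !is.na(aa_a) & !is.na(aa_b) & aa_a != "*" & aa_b != "*"
  n_skipped <- sum(!usable)
  cod_a <- cod_a[usable]
  cod_b <- cod_b[usable]

  site_tab <- vapply(unique(c(cod_a, cod_b)), codon_sites,
                     c(syn = 0, nonsyn = 0))
  S_sites <- (sum(site_tab["syn", cod_a]) + sum(site_tab["syn", cod_b])) / 2
  N_sites <- (sum(site_tab["nonsyn", cod_a]) + sum(site_tab["nonsyn", cod_b])) / 2

  diff_idx <- which(cod_a != cod_b)
  S_diffs <- 0
  N_diffs <- 0
  for (i in diff_idx) {
    d <- codon_differences(cod_a[i], cod_b[i])
    S_diffs <- S_diffs + d[["syn"]]
    N_diffs <- N_diffs + d[["nonsyn"]]
  }

  pS_raw <- if (S_sites > 0) S_diffs / S_sites else NA_real_
  pN_raw <- if (N_sites > 0) N_diffs / N_sites else NA_real_
  dS <- jukes_cantor(pS_raw)
  dN <- jukes_cantor(pN_raw)
  if (is.na(pS_raw) || is.na(pN_raw) ||
      pS_raw >= 0.75 || pN_raw >= 0.75) {
    status <- "undefined_saturated"
    dnds <- NA_real_
  } else if (dS == 0) {
    status <- "undefined_dS_zero"
    dnds <- NA_real_
  } else {
    status <- "ok"
    dnds <- dN / dS
  }
  structure(
    list(S_sites = S_sites, N_sites = N_sites,
         S_diffs = S_diffs, N_diffs = N_diffs,
         pS_raw = pS_raw, pN_raw = pN_raw, dS = dS, dN = dN,
         dnds = dnds, status = status,
         n_codons = length(cod_a), n_skipped = n_skipped),
    class = "ng86_stats"
  )
}

#' @export
print.ng86_stats <- function(x, ...) {
  cat(sprintf(
    "NG86: %d codons (%d skipped)\n  S sites %.2f, N sites %.2f; S diffs %.2f, N diffs %.2f\n  dS = %.5f, dN = %.5f, dN/dS = %s [%s]\n",
    x$n_codons, x$n_skipped, x$S_sites, x$N_sites, x$S_diffs, x$N_diffs,
    ifelse(is.na(x$dS), NA, x$dS), ifelse(is.na(x$dN), NA, x$dN),
    ifelse(is.na(x$dnds), "NA", sprintf("%.4f", x$dnds)), x$status))
  invisible(x)
}
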