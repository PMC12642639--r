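# End-to-end pipeline: sketch every record at DNA (k = 3*k_aa) and protein
# (k = k_aa) level, compute pairwise containments at each level, join on the
# (query, target) pair and apply the closed-form estimator. Mirrors the
# manysketch -> multisearch -> estimate workflow of sketch-based genome
# comparison tools.

#' Sketch a set of coding sequences at DNA and protein level
#'
#' @param dna Named character vector of coding sequences.
#' @param protein Optional named character vector of matching protein
#'   sequences (same names); when `NULL`, proteins are obtained by in-frame
#'   translation of `dna` (sequences whose length is not a multiple of 3
#'   are truncated to the last full codon).
#' @param k_aa Amino-acid k-mer size; the DNA k is always `3 * k_aa`.
#' @param scaled Scale factor for both sketch sets.
#' @return List with `dna` and `protein`: lists of `fmh_sketch` objects in
#'   input order.
#' @export
sketch_records <- function(dna, protein = NULL, k_aa = 7L, scaled = 500L) {
  stopifnot(!is.null(names(dna)))
  if (is.null(protein)) {
    protein <- vapply(dna, function(s) {
      n <- nchar(s) - nchar(s) %% 3L
      if (n == 0L) "" else translate_cds(substr(s, 1L, n))
    }, "")
  } else {
    missing_ids <- setdiff(names(dna), names(protein))
    extra_ids <- setdiff(names(protein), names(dna))
    if (length(missing_ids) || length(extra_ids)) {
      stop("DNA/protein id mismatch; missing proteins: ",
           paste(missing_ids, collapse = ","), "; unmatched proteins: ",
           paste(extra_ids, collapse = ","))
    }
    protein <- protein[names(dna)]
  }
  k_nt <- 3L * as.integer(k_aa)
  list(
    dna = lapply(names(dna), function(id) {
      sketch_sequence(dna[[id]], k = k_nt, scaled = scaled,
                      molecule = "dna", name = id)
    }),
    protein = lapply(names(dna), function(id) {
      sketch_sequence(protein[[id]], k = as.integer(k_aa), scaled = scaled,
                      molecule = "protein", name = id)
    })
  )
}

#' Join DNA and protein containment tables into a dN/dS table
#'
#' Joins two [multisearch()] outputs on `(query, target)` and applies
#' [fmh_dnds()] to each matched pair. Pairs present in only one table are
#' reported with status `missing_containment`.
#'
#' @param dna_containments,protein_containments Data frames from
#'   [multisearch()] over the DNA and protein sketches respectively.
#' @param k_aa Amino-acid k-mer size used for the sketches.
#' @return Data frame, one row per pair, columns as in [fmh_dnds()].
#' @export
dnds_table <- function(dna_containments, protein_containments, k_aa) {
  empty <- fmh_dnds(0.5, 0.5, k_aa)[0, , drop = FALSE]
  if (!nrow(dna_containments) && !nrow(protein_containments)) {
    warning("empty join: no pairs in either containment table")
    return(empty)
  }
  key_d <- paste(dna_containments$query, dna_containments$target, sep = "\r")
  key_p <- paste(protein_containments$query, protein_containments$target,
                 sep = "\r")
  all_keys <- sort(union(key_d, key_p))
  rows <- lapply(all_keys, function(k) {
    id <- strsplit(k, "\r", fixed = TRUE)[[1]]
    di <- match(k, key_d)
    pi <- match(k, key_p)
    if (is.na(di) || is.na(pi)) {
      row <- fmh_dnds(NA, NA, k_aa, query = id[1], target = id[2])
      row$status <- "missing_containment"
      return(row)
    }
    fmh_dnds(dna_containments$containment[di],
             protein_containments$containment[pi],
             k_aa, query = id[1], target = id[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-call pairwise FracMinHash dN/dS over a set of coding sequences
#'
#' Sketches, compares (both directions, self-pairs excluded) and estimates.
#' The containment threshold is applied independently at the DNA and the
#' protein comparison stage, so a pair must clear it at both levels to
#' receive an estimate.
#'
#' @inheritParams sketch_records
#' @param threshold Minimum containment at each level (default 0).
#' @return Data frame of [fmh_dnds()] rows.
#' @export
pairwise_dnds <- function(dna, protein = NULL, k_aa = 7L, scaled = 500L,
                          threshold = 0) {
  sk <- sketch_records(dna, protein, k_aa = k_aa, scaled = scaled)
  cd <- multisearch(sk$dna, sk$dna, threshold = threshold)
  cp <- multisearch(sk$protein, sk$protein, threshold = threshold)
  dnds_table(cd, cp, k_aa = k_aa)
}

#' FracMinHash dN/dS of one reference/query sequence pair
#'
#' Convenience wrapper: exact sketches (`scaled` defaults to 1), containment
#' of the reference in the mutated/derived sequence at DNA and protein
#' level, then the closed-form estimator. The reference sits on the
#' denominator side of the containment index, matching the estimator's
#' derivation (the mutation model mutates the reference W into W', and the
#' containment is that of W's k-mer set in W''s).
#'
#' @param ref Reference coding sequence (length a multiple of 3).
#' @param query Derived/mutated coding sequence.
#' @param k_aa Amino-acid k-mer size.
#' @param scaled Scale factor (default 1: exact).
#' @return One [fmh_dnds()] row.
#' @export
fmh_dnds_pair <- function(ref, query, k_aa = 7L, scaled = 1L) {
  sk <- sketch_records(c(ref = ref, query = query), k_aa = k_aa,
                       scaled = scaled)
  c_nt <- containment(sk$dna[[1]], sk$dna[[2]])$containment
  c_aa <- containment(sk$protein[[1]], sk$protein[[2]])$containment
  fmh_dnds(c_nt, c_aa, k_aa, query = "ref", target = "query")
}

#' Benchmark the estimator against NG86 on simulated selection cohorts
#'
#' For each reference length, simulates `n_queries` positive-scheme
#' (first+second codon positions mutated) and `n_queries` negative-scheme
#' (third positions) queries at rate `p` from one shared random reference,
#' computes NG86 dN/dS and FracMinHash dN/dS (at `scaled`) per query, and
#' reports the pooled Pearson correlation per (length, k_aa) combination.
#'
#' @param lengths Reference lengths in nt (multiples of 3).
#' @param p Per-position mutation rate.
#' @param k_aa_list Amino-acid k-mer sizes to evaluate.
#' @param n_queries Queries per scheme (cohort size is twice this).
#' @param seed Integer seed.
#' @param scaled Scale factor (default 1: exact sketches).
#' @return List with `estimates` (long data frame: length, k_aa, scheme, id,
#'   ng86, fmh, statuses) and `correlations` (length, k_aa, pearson_r,
#'   n_used, low_n flag).
#' @export
selection_benchmark <- function(lengths = c(5001L, 10002L, 20001L),
                                p = 0.01, k_aa_list = c(5L, 7L, 15L, 21L),
                                n_queries = 100L, seed = 1L, scaled = 1L) {
  est_rows <- list()
  for (len in lengths) {
    neg <- simulate_cohort(len, p, "negative", n_queries, seed = seed)
    pos <- simulate_cohort(len, p, "positive", n_queries,
                           seed = seed + 10000L, reference = neg$reference)
    ref <- neg$reference
    queries <- c(neg$queries, pos$queries)
    schemes <- rep(c("negative", "positive"), each = n_queries)
    ng <- vapply(queries, function(q) ng86_dnds(ref, q)$dnds, 0)
    for (k_aa in k_aa_list) {
      fmh <- vapply(queries, function(q) {
        fmh_dnds_pair(ref, q, k_aa = k_aa, scaled = scaled)$dnds
      }, 0)
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        length = len, k_aa = k_aa, scheme = schemes, id = names(queries),
        ng86 = unname(ng), fmh = unname(fmh), stringsAsFactors = FALSE
      )
    }
  }
  estimates <- do.call(rbind, est_rows)
  rownames(estimates) <- NULL
  combos <- unique(estimates[, c("length", "k_aa")])
  correlations <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- estimates[estimates$length == combos$length[i] &
                       estimates$k_aa == combos$k_aa[i], ]
    use <- stats::complete.cases(sub$ng86, sub$fmh)
    r <- if (sum(use) >= 3) stats::cor(sub$ng86[use], sub$fmh[use]) else NA_real_
    data.frame(length = combos$length[i], k_aa = combos$k_aa[i],
               pearson_r = r, n_used = sum(use), low_n = sum(use) < 10)
  }))
  list(estimates = estimates, correlations = correlations)
}
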