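# Codon-position-targeted mutation simulator: generates a random stop-free
# reference CDS and query cohorts mutated at chosen codon positions. Mutating
# only third positions yields mostly synonymous changes (a negative-selection
# proxy); mutating first and second positions yields mostly non-synonymous
# changes (a positive-selection proxy).

SENSE_CODONS <- function() {
  names(genetic_code())[genetic_code() != "*"]
}

#' Random stop-free coding sequence
#'
#' Draws codons uniformly from the 61 sense codons (equivalently: uniform
#' over all 64 with in-frame stops resampled). Deterministic given `seed`.
#'
#' @param length_nt Sequence length, a positive multiple of 3.
#' @param seed Integer seed.
#' @return Nucleotide sequence (character scalar).
#' @export
#' @examples
#' nchar(random_reference(10002, seed = 1))  # 3334 codons
random_reference <- function(length_nt, seed) {
  if (length_nt < 3 || length_nt %% 3 != 0) {
    stop("length_nt must be a positive multiple of 3")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  paste0(sample(SENSE_CODONS(), length_nt / 3, replace = TRUE),
         collapse = "")
}

# save/restore global RNG state so simulator calls don't perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Mutate a coding sequence at selected codon positions
#'
#' Each targeted nucleotide position is mutated independently with
#' probability `p`; a mutation replaces the base with one of the other three
#' chosen uniformly. `scheme = "negative"` targets the third position of
#' each codon, `"positive"` the first and second, `"uniform"` every
#' position. Untargeted positions are never changed. Mutations may create
#' in-frame stop codons; downstream consumers (protein sketching, NG86)
#' handle those explicitly.
#'
#' @param ref Stop-free, frame-aligned coding sequence.
#' @param p Per-position mutation probability in `[0,1]`.
#' @param scheme `"negative"`, `"positive"` or `"uniform"`.
#' @param seed Integer seed.
#' @return Mutated sequence of the same length.
#' @export
mutate_selected <- function(ref, p, scheme = c("negative", "positive", "uniform"),
                            seed) {
  scheme <- match.arg(scheme)
  stopifnot(p >= 0, p <= 1)
  n <- nchar(ref)
  if (n %% 3 != 0) stop("reference length must be a multiple of 3")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chars <- strsplit(ref, "")[[1]]
  pos_in_codon <- rep_len(1:3, n)
  target <- switch(scheme,
    negative = pos_in_codon == 3L,
    positive = pos_in_codon != 3L,
    uniform = rep(TRUE, n)
  )
  idx <- which(target)
  hit <- idx[stats::runif(length(idx)) < p]
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  paste0(chars, collapse = "")
}

#' Simulate a selection cohort
#'
#' One shared random reference plus `n_queries` mutated queries under one
#' scheme; query i uses seed `seed + i`, so cohorts are reproducible and
#' individual queries can be regenerated in isolation.
#'
#' @param length_nt Reference length, multiple of 3 (ignored when `reference`
#'   is supplied).
#' @param p Per-position mutation probability.
#' @param scheme `"negative"`, `"positive"` or `"uniform"`.
#' @param n_queries Number of mutated queries.
#' @param seed Integer seed; the reference uses `seed`, query i `seed + i`.
#' @param reference Optional user-supplied CDS to mutate instead of a random
#'   reference (length must be a multiple of 3).
#' @param fasta Optional path: when given, reference + queries are written
#'   there as FASTA and a `<path>.manifest.csv` with columns
#'   `id,scheme,p,seed` is written alongside.
#' @return List with `reference` (character scalar) and `queries` (named
#'   character vector, ids like `neg_0001`).
#' @export
simulate_cohort <- function(length_nt, p, scheme = c("negative", "positive", "uniform"),
                            n_queries, seed, reference = NULL, fasta = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(reference)) {
    reference <- random_reference(length_nt, seed)
  } else if (nchar(reference) %% 3 != 0) {
    stop("user-supplied reference length must be a multiple of 3")
  }
  prefix <- c(negative = "neg", positive = "pos", uniform = "uni")[[scheme]]
  queries <- character(n_queries)
  qseeds <- seed + seq_len(n_queries)
  for (i in seq_len(n_queries)) {
    queries[i] <- mutate_selected(reference, p, scheme, seed = qseeds[i])
  }
  names(queries) <- sprintf("%s_%04d", prefix, seq_len(n_queries))
  if (!is.null(fasta)) {
    write_fasta(c(reference = reference, queries), fasta)
    manifest <- data.frame(
      id = c("reference", names(queries)),
      scheme = c("reference", rep(scheme, n_queries)),
      p = c(NA, rep(p, n_queries)),
      seed = c(seed, qseeds)
    )
    utils::write.csv(manifest, paste0(fasta, ".manifest.csv"),
                     row.names = FALSE)
  }
  list(reference = reference, queries = queries)
}
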