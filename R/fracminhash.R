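#' Hash a k-mer
#'
#' MurmurHash3 x64_128 (low 64 bits, seed 42 — the convention used by the
#' sourmash family of sketching tools) of the k-mer bytes. DNA k-mers are
#' canonicalized first: the lexicographically smaller of the k-mer and its
#' reverse complement is hashed, so sketches are strand-robust. Protein
#' k-mers are hashed as-is.
#'
#' Hash values are returned as fixed-width 16-character lowercase hex strings:
#' R has no unsigned 64-bit integer type, and hex strings preserve exactness
#' while sorting lexicographically in numeric order.
#'
#' @param kmer Character vector of k-mers (all over the molecule's alphabet).
#' @param molecule `"dna"` or `"protein"`.
#' @return Character vector of 16-hex-digit hash values.
#' @export
#' @examples
#' hash_kmer("AAAA", "dna") == hash_kmer("TTTT", "dna")  # canonical pair
hash_kmer <- function(kmer, molecule = c("dna", "protein")) {
  molecule <- match.arg(molecule)
  .hash_kmer_cpp(toupper(kmer), molecule == "dna")
}

#' Build a FracMinHash sketch of a sequence
#'
#' Retains the hash of every valid k-mer whose 64-bit hash falls below
#' `2^64 / scaled` — a uniform, size-proportional subsample keeping an
#' expected fraction `1/scaled` of the distinct k-mers. K-mers containing
#' characters outside the molecule's alphabet (`N`, `*`, `X`, ...) are
#' skipped, so translated ORF boundaries and ambiguity codes never
#' contribute hashes.
#'
#' @param s Sequence (character scalar).
#' @param k K-mer length in the sketch's own alphabet (nucleotides for DNA,
#'   residues for protein).
#' @param scaled Scale factor (positive integer); `scaled = 1` keeps every
#'   k-mer (an exact sketch).
#' @param molecule `"dna"` or `"protein"`.
#' @param name Sketch name (defaults to `""`).
#' @return An object of class `fmh_sketch`: a list with `name`, `molecule`,
#'   `k`, `scaled`, `hashes` (sorted unique hex strings) and `n_kmers`
#'   (number of valid k-mers processed, duplicates included).
#' @export
#' @examples
#' sk <- sketch_sequence("ACGTACGTAC", k = 4, scaled = 1, molecule = "dna")
#' length(sk$hashes)
sketch_sequence <- function(s, k, scaled = 1L, molecule = c("dna", "protein"),
                            name = "") {
  molecule <- match.arg(molecule)
  stopifnot(k >= 1, scaled >= 1)
  s <- toupper(s)
  if (nchar(s) < k) {
    warning("sequence '", name, "' shorter than k = ", k, "; empty sketch")
    hashes <- character(0)
    n_seen <- 0
  } else {
    raw <- .sketch_hashes_cpp(s, as.integer(k), as.double(scaled),
                              molecule == "dna")
    n_seen <- attr(raw, "n_kmers")
    hashes <- sort(unique(as.character(raw)))
  }
  structure(
    list(name = name, molecule = molecule, k = as.integer(k),
         scaled = as.integer(scaled), hashes = hashes, n_kmers = n_seen),
    class = "fmh_sketch"
  )
}

#' @export
print.fmh_sketch <- function(x, ...) {
  cat(sprintf("FracMinHash sketch '%s': %s, k=%d, scaled=%d, %d hashes\n",
              x$name, x$molecule, x$k, x$scaled, length(x$hashes)))
  invisible(x)
}

check_compatible <- function(a, b) {
  if (a$k != b$k || a$molecule != b$molecule || a$scaled != b$scaled) {
    stop("incompatible sketches: (k=", a$k, ", ", a$molecule, ", scaled=",
         a$scaled, ") vs (k=", b$k, ", ", b$molecule, ", scaled=", b$scaled,
         ")")
  }
}

#' Debiased fractional containment of one sketch in another
#'
#' Estimates the containment index `|A n B| / |A|` of the query k-mer set A
#' in the target set B from their FracMinHash sketches, divided by the
#' debiasing factor `1 - (1 - s)^Ahat` that corrects for the probability
#' that a non-empty set leaves an empty sketch. `s = 1/scaled` and `Ahat`
#' is the plug-in cardinality estimate `|sketch| * scaled` (exact when
#' `scaled = 1`); the factor is computed in log space and is indistinguishable
#' from 1 whenever `Ahat * s >> 1`.
#'
#' @param query,target `fmh_sketch` objects with matching `k`, `molecule`
#'   and `scaled`.
#' @return A one-row data frame with columns `query`, `target`,
#'   `containment`, `intersection`, `query_size` and `flag_empty_query`.
#'   The containment is `NA` (flagged) when the query sketch is empty.
#' @export
containment <- function(query, target) {
  check_compatible(query, target)
  qs <- length(query$hashes)
  inter <- length(intersect(query$hashes, target$hashes))
  if (qs == 0L) {
    cont <- NA_real_
  } else if (inter == 0L) {
    cont <- 0
  } else {
    s <- 1 / query$scaled
    a_hat <- qs * query$scaled
    bias <- if (query$scaled == 1L) 1 else -expm1(a_hat * log1p(-s))
    cont <- inter / (qs * bias)
  }
  data.frame(query = query$name, target = target$name,
             containment = cont, intersection = inter, query_size = qs,
             flag_empty_query = qs == 0L, stringsAsFactors = FALSE)
}

#' All-vs-all containment search over sketch collections
#'
#' Computes the debiased containment for every ordered (query, target) pair
#' and keeps those at or above `threshold`. Self-pairs (same name) are
#' excluded unless `include_self = TRUE`. Output rows are sorted by
#' (query, target) regardless of evaluation order.
#'
#' @param queries,targets Lists of `fmh_sketch` objects.
#' @param threshold Minimum containment to report (default 0).
#' @param include_self Keep pairs whose query and target names match?
#' @return Data frame as in [containment()], one row per reported pair.
#' @export
multisearch <- function(queries, targets, threshold = 0,
                        include_self = FALSE) {
  rows <- list()
  for (q in queries) {
    for (t in targets) {
      if (!include_self && identical(q$name, t$name)) next
      r <- containment(q, t)
      if (!is.na(r$containment) && r$containment >= threshold) {
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query = character(0), target = character(0),
                      containment = numeric(0), intersection = integer(0),
                      query_size = integer(0), flag_empty_query = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$query, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write sketches to a JSON file
#'
#' One JSON array of objects `{name, molecule, k, scaled, hashes}`; hashes
#' are sorted 16-hex-digit strings (64-bit values are not exactly
#' representable as JSON numbers), so serialization is deterministic.
#'
#' @param sketches A list of `fmh_sketch` objects (or a single sketch).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sketches <- function(sketches, path) {
  if (inherits(sketches, "fmh_sketch")) sketches <- list(sketches)
  payload <- lapply(sketches, function(sk) {
    list(name = sk$name, molecule = sk$molecule, k = sk$k,
         scaled = sk$scaled, n_kmers = sk$n_kmers, hashes = sk$hashes)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read sketches from a JSON file written by [write_sketches()]
#'
#' @param path Path to a sketch JSON file.
#' @return List of `fmh_sketch` objects.
#' @export
read_sketches <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(p) {
    structure(
      list(name = p$name, molecule = p$molecule, k = as.integer(p$k),
           scaled = as.integer(p$scaled),
           hashes = as.character(unlist(p$hashes)),
           n_kmers = as.numeric(p$n_kmers)),
      class = "fmh_sketch"
    )
  })
}
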