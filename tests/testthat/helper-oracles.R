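# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: set arithmetic on k-mer strings instead of
# hashes, and a second NG86 enumerator built around explicit neighbor /
# permutation tables.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# canonical k-mer set of a sequence, as strings
oracle_kmer_set <- function(s, k, canonical = TRUE) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, 1:(n - k + 1), k:n)
  km <- km[!grepl("[^ACGT]", km)]
  if (canonical) {
    rc <- vapply(km, oracle_revcomp, "")
    km <- ifelse(rc < km, rc, km)
  }
  unique(km)
}

# exact containment of the canonical k-mer set of a in that of b
oracle_containment <- function(a, b, k) {
  A <- oracle_kmer_set(a, k)
  B <- oracle_kmer_set(b, k)
  length(intersect(A, B)) / length(A)
}

# protein k-mer set (no canonicalization, '*'/'X' k-mers dropped)
oracle_aa_kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, 1:(n - k + 1), k:n)
  unique(km[!grepl("[^ACDEFGHIKLMNPQRSTVWY]", km)])
}

oracle_aa_containment <- function(a, b, k) {
  A <- oracle_aa_kmer_set(a, k)
  B <- oracle_aa_kmer_set(b, k)
  length(intersect(A, B)) / length(A)
}

# --- independent NG86 enumerator ------------------------------------------
# Written around precomputed tables rather than the package's lazy caches.

oracle_code <- Biostrings::GENETIC_CODE

oracle_neighbors <- function(codon) {
  # all 9 single-base neighbors with position labels
  out <- list()
  ch <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == ch[pos]) next
    m <- ch; m[pos] <- b
    out[[length(out) + 1L]] <- paste0(m, collapse = "")
  }
  unlist(out)
}

oracle_codon_sites <- function(codon) {
  aa <- oracle_code[codon]
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(c("A", "C", "G", "T"), ch[pos]), function(b) {
      m <- ch; m[pos] <- b; paste0(m, collapse = "")
    }, "")
    aas <- oracle_code[muts]
    keep <- aas != "*"
    if (any(keep)) syn <- syn + sum(aas[keep] == aa) / sum(keep)
  }
  c(syn, 3 - syn)
}

oracle_codon_diffs <- function(a, b) {
  if (a == b) return(c(0, 0))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  perms <- switch(length(pos),
                  list(pos),
                  list(pos, pos[2:1]),
                  {
                    p <- list()
                    for (i in 1:3) for (j in 1:3) for (l in 1:3) {
                      if (length(unique(c(i, j, l))) == 3) {
                        p[[length(p) + 1L]] <- pos[c(i, j, l)]
                      }
                    }
                    p
                  })
  walk <- function(order, allow_stop) {
    cur <- a
    sy <- ns <- 0
    for (p in order) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- cb[p]
      nxt <- paste0(ch, collapse = "")
      if (oracle_code[nxt] == "*" && !allow_stop) return(NULL)
      if (oracle_code[nxt] == oracle_code[cur]) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    c(sy, ns)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

oracle_ng86 <- function(ref, query) {
  n <- nchar(ref)
  ca <- substring(ref, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(query, seq(1, n, 3), seq(3, n, 3))
  keep <- oracle_code[ca] != "*" & oracle_code[cb] != "*"
  ca <- ca[keep]; cb <- cb[keep]
  sa <- rowSums(vapply(ca, oracle_codon_sites, numeric(2)))
  sb <- rowSums(vapply(cb, oracle_codon_sites, numeric(2)))
  S_sites <- (sa[1] + sb[1]) / 2
  N_sites <- (sa[2] + sb[2]) / 2
  d <- rowSums(vapply(seq_along(ca), function(i) oracle_codon_diffs(ca[i], cb[i]),
                      numeric(2)))
  pS <- d[1] / S_sites
  pN <- d[2] / N_sites
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 / 3 * p)
  list(S_sites = S_sites, N_sites = N_sites, S_diffs = d[1], N_diffs = d[2],
       dS = jc(pS), dN = jc(pN))
}

# short random CDS without in-frame stops
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  sense <- names(oracle_code)[oracle_code != "*"]
  paste0(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# hex retention threshold floor(2^64/scaled) for the scale factors the
# suite uses (frozen; hex strings compare lexicographically as numbers)
format_hex_threshold <- function(scaled) {
  switch(as.character(scaled),
         "10" = "1999999999999999",
         "100" = "028f5c28f5c28f5c",
         stop("no frozen threshold for scaled = ", scaled))
}
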