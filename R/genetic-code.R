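# Standard genetic code tables shared by codon usage, NG86 and the GY94 model.
# Plastid CDSs are translated with the standard code; GTG/ACG initiators are
# handled as audit exceptions, never as different amino acids.

# 64 codons in fixed lexicographic (A,C,G,T) order
CODONS <- local({
  b <- c("A", "C", "G", "T")
  out <- character(64)
  k <- 1
  for (x in b) for (y in b) for (z in b) {
    out[k] <- paste0(x, y, z)
    k <- k + 1
  }
  out
})

# amino acid (one letter, "*" for stop) per codon, standard code
CODON_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[CODONS])
  names(aa) <- CODONS
  aa
})

STOP_CODONS <- names(CODON_AA)[CODON_AA == "*"]
SENSE_CODONS <- names(CODON_AA)[CODON_AA != "*"]

#' Number of synonymous codons per amino acid (degeneracy)
#' @keywords internal
codon_degeneracy <- function() {
  tab <- table(CODON_AA[SENSE_CODONS])
  stats::setNames(as.integer(tab), names(tab))
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# 61x61 single-step change type between sense codons:
# 0 = not a single-nucleotide change, 1 = synonymous transversion,
# 2 = synonymous transition, 3 = nonsynonymous transversion,
# 4 = nonsynonymous transition.  Built once, consumed by the C++ kernel.
codon_pair_type <- function() {
  n <- length(SENSE_CODONS)
  sp <- strsplit(SENSE_CODONS, "", fixed = TRUE)
  m <- matrix(0L, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(sp[[i]] != sp[[j]])
      if (length(d) != 1L) next
      ts <- is_transition(sp[[i]][d], sp[[j]][d])
      syn <- CODON_AA[SENSE_CODONS[i]] == CODON_AA[SENSE_CODONS[j]]
      m[i, j] <- if (syn) (if (ts) 2L else 1L) else (if (ts) 4L else 3L)
    }
  }
  m
}

# cached
.pkg_cache <- new.env(parent = emptyenv())

get_pair_type <- function() {
  if (is.null(.pkg_cache$pair_type)) .pkg_cache$pair_type <- codon_pair_type()
  .pkg_cache$pair_type
}

split_codons <- function(s) {
  n <- nchar(s)
  stopifnot(n %% 3 == 0)
  if (n == 0) return(character(0))
  substring(s, seq(1, n, 3), seq(3, n, 3))
}
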