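#' @useDynLib plastocomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Presentation rounding used by all report tables (the convention of printed
#' summary tables in comparative plastome studies), as opposed to base R's
#' round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Rate per 100 bp
#'
#' @param count event count
#' @param length_bp span in bp
#' @param digits decimal places for presentation (`NULL` = full precision)
#' @return numeric rate
#' @export
rate_per_100bp <- function(count, length_bp, digits = 2) {
  stopifnot(length_bp > 0)
  r <- 100 * count / length_bp
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Percentage formatting used in reports
#'
#' @param count numerator
#' @param total denominator
#' @param digits decimal places (default 2)
#' @return numeric percentage, rounded half away from zero
#' @export
percent_of <- function(count, total, digits = 2) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, digits)
}

# Deterministic per-stage substream seeds from one root seed: toggling one
# stage must not shift another stage's draws.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1000003L + as.integer(h %% 2147480L)) %% 2147483647L
}

DNA_BASES <- c("A", "C", "G", "T")

# scalar string -> reverse complement (N fixed point)
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# character-vector form used in hot loops
revcomp_chars <- function(x) rev(chartr("ACGTN", "TGCAN", x))

complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

random_dna <- function(n, gc = 0.37) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

check_dna_alphabet <- function(s, where = "sequence") {
  bad <- gsub("[ACGTN]", "", s)
  if (nchar(bad) > 0) {
    stop(sprintf("non-DNA alphabet in %s: characters '%s' (only A/C/G/T/N allowed)",
                 where, paste(unique(strsplit(bad, "")[[1]]), collapse = "")),
         call. = FALSE)
  }
  invisible(TRUE)
}
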