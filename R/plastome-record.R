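#' Annotated plastid genome record
#'
#' Container for one (usually circular) plastid genome: the sequence, a feature
#' table and free-text provenance.  Internal coordinates are 0-based half-open
#' throughout the package; all file I/O converts at the boundary (GenBank is
#' 1-based inclusive).
#'
#' @param id accession or name
#' @param sequence DNA string; alphabet restricted to A/C/G/T/N
#' @param circular logical, default `TRUE`
#' @param features feature table as built by [feature_table()] / [add_feature()]
#' @param source free-text provenance
#' @return object of class `plastome_record`
#' @export
plastome_record <- function(id, sequence, circular = TRUE,
                            features = feature_table(), source = "") {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must be nonempty", call. = FALSE)
  check_dna_alphabet(sequence, where = id)
  rec <- structure(
    list(id = id, sequence = sequence, circular = circular,
         features = features, source = source),
    class = "plastome_record")
  validate_plastome_record(rec)
  rec
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("plastome_record '%s': %s bp, %s, %d feature(s)\n",
              x$id, format(genome_length(x), big.mark = ","),
              if (x$circular) "circular" else "linear",
              length(unique(x$features$feature_id))))
  invisible(x)
}

#' Genome length in bp
#' @param record a `plastome_record`
#' @return integer length
#' @export
genome_length <- function(record) nchar(record$sequence)

#' Empty feature table
#'
#' One row per feature part.  `parts` are 0-based half-open intervals listed in
#' reading order (for minus-strand features the first part has the highest
#' genome coordinate).  `wrap` flags features whose parts are contiguous
#' through the origin of a circular genome.
#'
#' @return zero-row data.frame with the feature-table schema
#' @export
feature_table <- function() {
  data.frame(feature_id = integer(0), name = character(0), kind = character(0),
             strand = character(0), codon_start = integer(0), part = integer(0),
             start = integer(0), end = integer(0), wrap = logical(0),
             stringsAsFactors = FALSE)
}

#' Append one feature to a feature table
#'
#' @param features existing feature table
#' @param name gene symbol (e.g. `"ycf1"`, `"ndhF"`)
#' @param kind one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"pseudogene"`
#' @param strand `"+"` or `"-"`
#' @param parts matrix/list of `[start, end)` intervals in reading order
#' @param codon_start phase offset in 0..2 (GenBank `/codon_start` minus 1)
#' @param wrap does the feature span the origin of a circular genome?
#' @return updated feature table
#' @export
add_feature <- function(features, name, kind, strand, parts, codon_start = 0L,
                        wrap = FALSE) {
  stopifnot(kind %in% c("CDS", "tRNA", "rRNA", "pseudogene"),
            strand %in% c("+", "-"), codon_start %in% 0:2)
  if (is.list(parts)) parts <- do.call(rbind, parts)
  parts <- matrix(as.integer(parts), ncol = 2)
  fid <- if (nrow(features)) max(features$feature_id) + 1L else 1L
  rbind(features, data.frame(
    feature_id = fid, name = name, kind = kind, strand = strand,
    codon_start = as.integer(codon_start), part = seq_len(nrow(parts)),
    start = parts[, 1], end = parts[, 2], wrap = wrap,
    stringsAsFactors = FALSE))
}

validate_plastome_record <- function(rec) {
  L <- genome_length(rec)
  f <- rec$features
  if (nrow(f)) {
    if (any(f$start < 0 | f$end > L | f$start >= f$end)) {
      stop("feature interval outside [0, genome length) or empty", call. = FALSE)
    }
    for (fid in unique(f$feature_id)) {
      p <- f[f$feature_id == fid, , drop = FALSE]
      if (nrow(p) > 1 && !p$wrap[1]) {
        o <- order(p$start)
        if (any(p$end[o][-nrow(p)] > p$start[o][-1])) {
          stop(sprintf("overlapping parts in feature '%s'", p$name[1]), call. = FALSE)
        }
      }
      if (p$kind[1] == "CDS") {
        len <- sum(p$end - p$start) - p$codon_start[1]
        if (len %% 3 != 0) {
          stop(sprintf("CDS '%s' length %d not divisible by 3 (use kind = 'pseudogene')",
                       p$name[1], len), call. = FALSE)
        }
      }
    }
  }
  invisible(rec)
}

# rows of the feature table belonging to one feature, in reading (part) order
feature_parts <- function(record, feature_id) {
  p <- record$features[record$features$feature_id == feature_id, , drop = FALSE]
  if (!nrow(p)) stop(sprintf("no feature with id %s", feature_id), call. = FALSE)
  p[order(p$part), , drop = FALSE]
}

# genome-order span [start, end) of a feature (ignoring wrap internals)
feature_span <- function(record, feature_id) {
  p <- feature_parts(record, feature_id)
  c(min(p$start), max(p$end))
}

#' GC content of a genome or interval
#'
#' Fraction (G+C)/(A+C+G+T); `N` bases are excluded from both numerator and
#' denominator.  On circular records the interval may wrap the origin
#' (`start > end`).
#'
#' @param record a `plastome_record`
#' @param interval optional `[start, end)` 0-based half-open interval
#' @return fraction in `[0, 1]`
#' @export
gc_content <- function(record, interval = NULL) {
  s <- record$sequence
  L <- nchar(s)
  if (!is.null(interval)) {
    a <- interval[1]; b <- interval[2]
    if (a == b) stop("empty interval", call. = FALSE)
    if (a < 0 || a >= L || b < 0 || b > L) stop("interval outside genome", call. = FALSE)
    if (a < b) {
      s <- substr(s, a + 1, b)
    } else {
      if (!record$circular) stop("wrapped interval on a linear record", call. = FALSE)
      s <- paste0(substr(s, a + 1, L), substr(s, 1, b))
    }
  }
  n <- nchar(s)
  gc <- n - nchar(gsub("[GC]", "", s))
  nn <- n - nchar(gsub("N", "", s))
  denom <- n - nn
  if (denom == 0) stop("interval contains no unambiguous bases", call. = FALSE)
  gc / denom
}

#' Extract a feature's sequence in reading direction
#'
#' Parts are concatenated in reading order; minus-strand parts are
#' reverse-complemented; for CDS features `codon_start` bases are trimmed so
#' the result starts in frame.
#'
#' @param record a `plastome_record`
#' @param feature feature id (integer) or gene name (first match)
#' @param trim_codon_start trim the phase offset for CDS features (default TRUE)
#' @return DNA string
#' @export
extract_feature_sequence <- function(record, feature, trim_codon_start = TRUE) {
  if (is.character(feature)) {
    hit <- record$features$feature_id[record$features$name == feature]
    if (!length(hit)) stop(sprintf("no feature named '%s'", feature), call. = FALSE)
    feature <- hit[1]
  }
  p <- feature_parts(record, feature)
  L <- genome_length(record)
  if (any(p$end > L)) stop("feature interval out of bounds", call. = FALSE)
  pieces <- vapply(seq_len(nrow(p)), function(i) {
    frag <- substr(record$sequence, p$start[i] + 1, p$end[i])
    if (p$strand[i] == "-") revcomp(frag) else frag
  }, character(1))
  out <- paste(pieces, collapse = "")
  if (trim_codon_start && p$kind[1] %in% c("CDS", "pseudogene") && p$codon_start[1] > 0) {
    out <- substr(out, p$codon_start[1] + 1, nchar(out))
  }
  out
}

#' Per-base CDS/intron/IGS classification
#'
#' Every base receives exactly one primary label: bases inside any
#' CDS/tRNA/rRNA/pseudogene exon are class `CDS` (owned by that gene); bases
#' between consecutive parts of one feature are `intron`; everything else is
#' `IGS`, named `geneA-geneB` from the flanking genes in genome order.
#' Overlaps are resolved with precedence CDS > intron > IGS.
#'
#' @param record a `plastome_record`
#' @return data.frame with columns `start`, `end`, `class`, `locus` whose
#'   intervals tile `[0, genome length)`
#' @export
region_class_map <- function(record) {
  L <- genome_length(record)
  cls <- integer(L)           # 0 IGS, 1 intron, 2 exon
  owner <- character(L)
  f <- record$features
  for (fid in unique(f$feature_id)) {
    p <- feature_parts(record, fid)
    for (i in seq_len(nrow(p))) {
      idx <- (p$start[i] + 1):p$end[i]
      take <- cls[idx] < 2L
      cls[idx[take]] <- 2L
      owner[idx[take]] <- p$name[1]
    }
    if (nrow(p) > 1 && !p$wrap[1]) {   # introns between genome-ordered parts
      o <- order(p$start)
      for (i in seq_len(nrow(p) - 1)) {
        gap <- if (p$end[o][i] < p$start[o][i + 1]) (p$end[o][i] + 1):p$start[o][i + 1] else integer(0)
        take <- gap[cls[gap] < 1L]
        cls[take] <- 1L
        owner[take] <- p$name[1]
      }
    }
  }
  # name IGS runs by flanking genes in genome order
  key <- paste(cls, owner, sep = "\r")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  out <- data.frame(start = starts, end = ends,
                    class = c("IGS", "intron", "CDS")[as.integer(sub("\r.*", "", r$values)) + 1L],
                    locus = sub("^[012]\r", "", r$values),
                    stringsAsFactors = FALSE)
  igs <- which(out$class == "IGS")
  if (length(igs)) {
    if (!nrow(f)) {
      out$locus[igs] <- "genome"
    } else {
      spans <- t(vapply(unique(f$feature_id), function(fid) feature_span(record, fid),
                        numeric(2)))
      nm <- vapply(unique(f$feature_id),
                   function(fid) feature_parts(record, fid)$name[1], character(1))
      for (i in igs) {
        a <- out$start[i]; b <- out$end[i]
        # previous feature: largest end <= a (circular fallback: global max end)
        prev_ok <- spans[, 2] <= a
        prev <- if (any(prev_ok)) nm[prev_ok][which.max(spans[prev_ok, 2])] else nm[which.max(spans[, 2])]
        nxt_ok <- spans[, 1] >= b
        nxt <- if (any(nxt_ok)) nm[nxt_ok][which.min(spans[nxt_ok, 1])] else nm[which.min(spans[, 1])]
        out$locus[i] <- paste(prev, nxt, sep = "-")
      }
    }
  }
  # merge adjacent runs that ended up with identical labels
  if (nrow(out) > 1) {
    same <- c(FALSE, out$class[-1] == out$class[-nrow(out)] &
                out$locus[-1] == out$locus[-nrow(out)])
    grp <- cumsum(!same)
    out <- data.frame(start = tapply(out$start, grp, min),
                      end = tapply(out$end, grp, max),
                      class = out$class[!same], locus = out$locus[!same],
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

# integer per-base class vector (0 IGS, 1 intron, 2 exon) from a region map
region_class_vector <- function(map, L) {
  v <- integer(L)
  code <- c(IGS = 0L, intron = 1L, CDS = 2L)
  for (i in seq_len(nrow(map))) v[(map$start[i] + 1):map$end[i]] <- code[[map$class[i]]]
  v
}

#' Write a per-base region table as TSV
#'
#' @param map output of [region_class_map()]
#' @param seq_id genome id for the first column
#' @param path output file
#' @return invisibly, the path
#' @export
write_region_table <- function(map, seq_id, path) {
  out <- cbind(seq_id = seq_id, map)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
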