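# GenBank flat-file reader/writer, restricted to the feature keys this
# package consumes (CDS/tRNA/rRNA, /pseudo, /gene, /codon_start).  Local
# flat-file parsing is done here because the installed tree ecosystem only
# fetches GenBank records over the network.

parse_location <- function(loc, line_no = NA) {
  loc <- gsub("[<> ]", "", loc)
  strand <- "+"
  if (startsWith(loc, "complement(")) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(")) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("[()]", loc)) {
    stop(sprintf("unsupported location string '%s' (line %s)", loc, line_no), call. = FALSE)
  }
  pieces <- strsplit(loc, ",", fixed = TRUE)[[1]]
  parts <- t(vapply(pieces, function(p) {
    if (grepl("\\.\\.", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      ab <- rep(as.integer(p), 2)
    }
    if (anyNA(ab)) stop(sprintf("malformed location '%s' (line %s)", p, line_no), call. = FALSE)
    c(ab[1] - 1L, ab[2])      # 1-based inclusive -> 0-based half-open
  }, integer(2)))
  dimnames(parts) <- NULL
  # GenBank lists join() parts in genome order inside complement(); reading
  # order for a minus-strand feature is therefore the reversed list
  if (strand == "-") parts <- parts[rev(seq_len(nrow(parts))), , drop = FALSE]
  wrap <- FALSE
  go <- if (strand == "-") parts[rev(seq_len(nrow(parts))), 1] else parts[, 1]
  if (nrow(parts) > 1 && is.unsorted(go)) wrap <- TRUE
  list(strand = strand, parts = parts, wrap = wrap)
}

#' Read an annotated plastid genome
#'
#' @param path file path
#' @param format `"genbank"` or `"fasta"` (guessed from the extension when
#'   missing)
#' @return a [plastome_record()]
#' @export
read_annotated_genome <- function(path, format = c("auto", "genbank", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gb", "gbk", "genbank")) "genbank" else "fasta"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    if (!length(ss)) stop(sprintf("no sequences in %s", path), call. = FALSE)
    return(plastome_record(id = sub("\\s.*", "", names(ss)[1]),
                           sequence = as.character(ss[[1]]),
                           source = paste("FASTA", path)))
  }
  read_genbank_record(path)
}

read_genbank_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop(sprintf("%s: no LOCUS line; not a GenBank flat file", path), call. = FALSE)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  circular <- any(grepl("circular", lines[locus_i[1]], ignore.case = TRUE))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop(sprintf("%s: no ORIGIN section", path), call. = FALSE)
  seq_lines <- lines[(orig_i[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  check_dna_alphabet(sequence, where = path)

  features <- feature_table()
  if (length(feat_i)) {
    fl <- lines[(feat_i[1] + 1):(orig_i[1] - 1)]
    # a new entry starts with a key in columns 6-20
    is_key <- grepl("^ {5}\\S", fl)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      block <- fl[idx[k]:(if (k < length(idx)) idx[k + 1] - 1 else length(fl))]
      key <- sub("^\\s+", "", substr(block[1], 1, 20))
      key <- sub("\\s.*", "", key)
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      body <- paste(trimws(c(substr(block[1], 21, nchar(block[1])), block[-1])), collapse = "\n")
      # location = everything before the first qualifier
      qual_start <- regexpr("\n?/", body)
      loc_str <- if (qual_start > 0) substr(body, 1, qual_start - 1) else body
      loc_str <- gsub("\n", "", loc_str)
      loc <- parse_location(loc_str, line_no = feat_i[1] + idx[k])
      quals <- regmatches(body, gregexpr("/[A-Za-z_]+(=(\"[^\"]*\"|[^\\s/]+))?", body,
                                         perl = TRUE))[[1]]
      getq <- function(nm) {
        hit <- grep(paste0("^/", nm, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("\"", "", sub(paste0("^/", nm, "="), "", hit[1]))
      }
      name <- getq("gene")
      if (is.na(name)) name <- getq("product") %||% key
      if (is.na(name)) name <- key
      pseudo <- any(grepl("^/pseudo(\\b|$)", quals) | grepl("^/pseudogene", quals))
      cstart <- getq("codon_start")
      cstart <- if (is.na(cstart)) 0L else as.integer(cstart) - 1L
      kind <- if (pseudo) "pseudogene" else key
      features <- add_feature(features, name = name, kind = kind,
                              strand = loc$strand, parts = loc$parts,
                              codon_start = cstart, wrap = loc$wrap)
    }
  }
  plastome_record(id = id, sequence = sequence, circular = circular,
                  features = features, source = paste("GenBank", path))
}

format_location <- function(parts, strand, L) {
  go <- if (strand == "-") parts[rev(seq_len(nrow(parts))), , drop = FALSE] else parts
  spans <- sprintf("%d..%d", go[, 1] + 1L, go[, 2])
  body <- if (nrow(go) > 1) sprintf("join(%s)", paste(spans, collapse = ",")) else spans
  if (strand == "-") sprintf("complement(%s)", body) else body
}

#' Write a plastome record as a GenBank flat file
#'
#' @param record a [plastome_record()]
#' @param path output file
#' @param date LOCUS date string (injectable for reproducible output)
#' @return invisibly, the path
#' @export
write_genbank <- function(record, path, date = format(Sys.Date(), "%d-%b-%Y")) {
  L <- genome_length(record)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (record$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     record$id, L, topo, date), con)
  writeLines(sprintf("DEFINITION  %s.", record$source), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  f <- record$features
  for (fid in unique(f$feature_id)) {
    p <- feature_parts(record, fid)
    key <- if (p$kind[1] == "pseudogene") "CDS" else p$kind[1]
    loc <- format_location(as.matrix(p[, c("start", "end")]), p$strand[1], L)
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", p$name[1]), con)
    if (p$kind[1] %in% c("CDS", "pseudogene")) {
      writeLines(sprintf("                     /codon_start=%d", p$codon_start[1] + 1L), con)
    }
    if (p$kind[1] == "pseudogene") writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  s <- record$sequence
  for (off in seq(1, L, by = 60)) {
    chunk <- substr(s, off, min(off + 59, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences (gaps allowed)
#' @param path output file
#' @return invisibly, the path
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an aligned FASTA into a character matrix
#'
#' @param path aligned FASTA file
#' @return character matrix (rows = sequences, columns = alignment columns)
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stop(sprintf("no sequences in %s", path), call. = FALSE)
  n <- unique(Biostrings::width(ss))
  if (length(n) != 1) stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(as.character(ss)), "", fixed = TRUE))
  rownames(m) <- sub("\\s.*", "", names(ss))
  m
}
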