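#' Annotated circular plastome record
#'
#' @param record_id Identifier (accession-style string).
#' @param sequence Nucleotide sequence over `A,C,G,T,N` (case-insensitive),
#'   interpreted as circular.
#' @param features Data frame with columns `name` (string), `type` (one of
#'   `gene`, `CDS`, `tRNA`, `rRNA`, `exon`), `strand` (`+1`/`-1`) and
#'   `parts` (list column: per feature an integer matrix with columns
#'   `start`, `end`, 1-based inclusive GenBank-style coordinates,
#'   non-overlapping within the feature). May have zero rows.
#' @return Object of class `"plastome_record"`.
#' @export
plastome_record <- function(record_id, sequence, features = NULL) {
  sequence <- toupper(as.character(sequence)[1L])
  n <- nchar(sequence)
  if (n < 1L) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence may contain only A, C, G, T, N", call. = FALSE)
  if (is.null(features))
    features <- data.frame(name = character(), type = character(),
                           strand = integer(), parts = I(list()))
  if (!all(c("name", "type", "strand", "parts") %in% names(features)))
    stop("features need columns name, type, strand, parts", call. = FALSE)
  ok_types <- c("gene", "CDS", "tRNA", "rRNA", "exon")
  if (nrow(features)) {
    if (!all(features$type %in% ok_types))
      stop("feature types must be one of: ",
           paste(ok_types, collapse = ", "), call. = FALSE)
    if (!all(features$strand %in% c(-1L, 1L)))
      stop("feature strands must be +1 or -1", call. = FALSE)
    for (i in seq_len(nrow(features))) {
      p <- features$parts[[i]]
      if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 1L)
        stop("feature '", features$name[i],
             "': parts must be a 2-column matrix", call. = FALSE)
      if (any(p < 1L) || any(p > n) || any(p[, 1L] > p[, 2L]))
        stop("feature '", features$name[i],
             "': coordinates out of [1, ", n, "]", call. = FALSE)
      if (nrow(p) > 1L) {
        o <- order(p[, 1L])
        if (any(p[o, 1L][-1L] <= p[o, 2L][-nrow(p)]))
          stop("feature '", features$name[i],
               "': overlapping parts", call. = FALSE)
      }
    }
  }
  structure(list(record_id = as.character(record_id)[1L],
                 sequence = sequence, features = features),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat("Plastome record ", x$record_id, ": circular, ",
      nchar(x$sequence), " bp, ", nrow(x$features), " feature(s)\n",
      sep = "")
  if (nrow(x$features))
    print(table(x$features$type))
  invisible(x)
}

#' Read a plastome from FASTA plus an optional feature table
#'
#' The sequence comes from the first FASTA record. Features may be supplied
#' as a GenBank flat file (the feature table and ORIGIN of which are parsed,
#' see [read_genbank()]) or as the minimal feature TSV dialect
#' ([read_feature_tsv()]); the format is sniffed from the file content.
#'
#' @param fasta_path FASTA file.
#' @param features_path Optional feature file (GenBank flat file or TSV).
#' @return A [plastome_record()].
#' @export
read_plastome <- function(fasta_path, features_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (!length(seqs)) stop("no sequence in ", fasta_path, call. = FALSE)
  id <- sub("\\s.*$", "", names(seqs)[1L])
  feats <- NULL
  if (!is.null(features_path)) {
    head1 <- readLines(features_path, n = 50L, warn = FALSE)
    if (any(grepl("^(LOCUS|FEATURES)", head1)))
      return(read_genbank(features_path,
                          sequence = as.character(seqs[[1L]]),
                          record_id = id))
    feats <- read_feature_tsv(features_path)
  }
  plastome_record(id, as.character(seqs[[1L]]), feats)
}

#' Read / write the minimal feature TSV dialect
#'
#' One feature per line: `name<TAB>type<TAB>strand<TAB>parts`, where
#' `strand` is `+`/`-` and `parts` is a comma-separated list of
#' `start..end` 1-based inclusive intervals. `#` lines are comments.
#'
#' @param path File path.
#' @return A features data frame suitable for [plastome_record()].
#' @export
read_feature_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  name <- character(); type <- character(); strand <- integer()
  parts <- list()
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L)
      stop("feature TSV parse error at line ", i,
           ": expected name\\ttype\\tstrand\\tparts", call. = FALSE)
    sgn <- switch(f[3L], "+" = 1L, "-" = -1L, "−" = -1L,
                  stop("feature TSV parse error at line ", i,
                       ": unknown strand '", f[3L], "'", call. = FALSE))
    iv <- strsplit(strsplit(f[4L], ",", fixed = TRUE)[[1L]], "..",
                   fixed = TRUE)
    if (any(lengths(iv) != 2L))
      stop("feature TSV parse error at line ", i,
           ": parts must look like start..end[,start..end]", call. = FALSE)
    m <- do.call(rbind, lapply(iv, function(x) as.integer(x)))
    colnames(m) <- c("start", "end")
    name <- c(name, f[1L]); type <- c(type, f[2L]); strand <- c(strand, sgn)
    parts[[length(parts) + 1L]] <- m
  }
  data.frame(name = name, type = type, strand = strand, parts = I(parts))
}

#' @rdname read_feature_tsv
#' @param features Features data frame (as in [plastome_record()]).
#' @export
write_feature_tsv <- function(features, path) {
  fmt_parts <- function(p)
    paste(sprintf("%d..%d", p[, 1L], p[, 2L]), collapse = ",")
  lines <- c("# name\ttype\tstrand\tparts",
             vapply(seq_len(nrow(features)), function(i)
               sprintf("%s\t%s\t%s\t%s", features$name[i], features$type[i],
                       if (features$strand[i] > 0) "+" else "-",
                       fmt_parts(features$parts[[i]])), character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a plastome record as FASTA (+ feature TSV)
#'
#' @param rec A [plastome_record()].
#' @param fasta_path Output FASTA.
#' @param features_path Optional output feature TSV.
#' @export
write_plastome <- function(rec, fasta_path, features_path = NULL) {
  x <- Biostrings::DNAStringSet(rec$sequence)
  names(x) <- rec$record_id
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(features_path)) write_feature_tsv(rec$features, features_path)
  invisible(fasta_path)
}

#' Minimal GenBank flat-file reader
#'
#' Parses the subset of the GenBank format needed for plastome work: the
#' LOCUS name, the FEATURES table (keys `gene`, `CDS`, `tRNA`, `rRNA`,
#' `exon`; locations with `complement()` and `join()`, possibly spanning
#' continuation lines; names taken from `/gene`, falling back to
#' `/product` then `/locus_tag`) and the ORIGIN sequence. Other feature
#' keys and qualifiers are ignored. Features whose location crosses the
#' origin are skipped with a warning.
#'
#' @param path GenBank flat file.
#' @param sequence Optional sequence overriding/substituting ORIGIN.
#' @param record_id Optional identifier overriding LOCUS.
#' @return A [plastome_record()].
#' @export
read_genbank <- function(path, sequence = NULL, record_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (is.null(record_id))
    record_id <- if (length(locus))
      strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
    else "genbank_record"

  f_start <- grep("^FEATURES", lines)
  o_start <- grep("^ORIGIN", lines)
  end_rec <- grep("^//", lines)
  if (is.null(sequence)) {
    if (!length(o_start)) stop("no ORIGIN and no sequence given",
                               call. = FALSE)
    stop_at <- if (length(end_rec)) end_rec[1L] - 1L else length(lines)
    seq_lines <- lines[(o_start[1L] + 1L):stop_at]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  name <- character(); type <- character(); strand <- integer()
  parts <- list()
  if (length(f_start)) {
    stop_at <- min(c(o_start, end_rec, length(lines) + 1L))
    flines <- lines[(f_start[1L] + 1L):(stop_at - 1L)]
    ok_types <- c("gene", "CDS", "tRNA", "rRNA", "exon")
    i <- 1L
    while (i <= length(flines)) {
      m <- regmatches(flines[i],
                      regexec("^ {5}(\\S+)\\s+(\\S.*)$", flines[i]))[[1L]]
      if (length(m) != 3L) { i <- i + 1L; next }
      key <- m[2L]; loc <- m[3L]
      i <- i + 1L
      # location continuation lines (start with 21 spaces, not a qualifier)
      while (i <= length(flines) &&
             grepl("^ {21}[^/]", flines[i]) &&
             !grepl("^ {5}\\S", flines[i])) {
        loc <- paste0(loc, trimws(flines[i])); i <- i + 1L
      }
      quals <- character()
      while (i <= length(flines) && !grepl("^ {5}\\S", flines[i])) {
        quals <- c(quals, trimws(flines[i])); i <- i + 1L
      }
      if (!key %in% ok_types) next
      get_q <- function(q) {
        hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("\"", "", sub(paste0("^/", q, "="), "", hit[1L]))
      }
      nm <- get_q("gene")
      if (is.na(nm)) nm <- get_q("product")
      if (is.na(nm)) nm <- get_q("locus_tag")
      if (is.na(nm)) nm <- paste0(key, "_", length(name) + 1L)
      sgn <- if (grepl("complement", loc)) -1L else 1L
      loc_clean <- gsub("complement\\(|join\\(|order\\(|\\)|<|>", "", loc)
      ivs <- strsplit(strsplit(loc_clean, ",", fixed = TRUE)[[1L]], "..",
                      fixed = TRUE)
      if (any(lengths(ivs) != 2L)) {
        warning("skipping feature '", nm, "' with unsupported location: ",
                loc, call. = FALSE)
        next
      }
      pm <- do.call(rbind, lapply(ivs, as.integer))
      colnames(pm) <- c("start", "end")
      if (any(pm[, 1L] > pm[, 2L])) {
        warning("skipping origin-crossing feature '", nm, "'",
                call. = FALSE)
        next
      }
      name <- c(name, nm); type <- c(type, key); strand <- c(strand, sgn)
      parts[[length(parts) + 1L]] <- pm
    }
  }
  plastome_record(record_id, sequence,
                  data.frame(name = name, type = type, strand = strand,
                             parts = I(parts)))
}

feature_span <- function(parts) c(min(parts[, 1L]), max(parts[, 2L]))

#' Gene order of one quadripartite region
#'
#' Extracts the genes whose full span lies inside the named region, ordered
#' by start coordinate along the region's forward direction (the circle's
#' forward direction, regions allowed to wrap past the origin), with their
#' strands. Genes straddling a region boundary are excluded with a warning.
#'
#' @param rec A [plastome_record()].
#' @param map A quadripartite map from [find_inverted_repeat()].
#' @param region One of `"LSC"`, `"SSC"`, `"IRa"`, `"IRb"`.
#' @param types Feature types to include (default `"gene"`).
#' @return A [gene_order()].
#' @export
gene_order_from_features <- function(rec, map, region = "LSC",
                                     types = "gene") {
  if (!inherits(map, "quadripartite_map"))
    stop("expected a quadripartite_map", call. = FALSE)
  slot <- match(tolower(region), c("lsc", "ssc", "ira", "irb"))
  if (is.na(slot))
    stop("unknown region '", region, "': use LSC, SSC, IRa or IRb",
         call. = FALSE)
  iv <- map[[c("lsc", "ssc", "ira", "irb")[slot]]]
  n <- map$genome_bp
  if (nchar(rec$sequence) != n)
    stop("record and quadripartite map disagree on sequence length",
         call. = FALSE)
  rlen <- circ_length(iv, n)
  feats <- rec$features[rec$features$type %in% types, , drop = FALSE]
  if (!nrow(feats))
    stop("record has no features of type ",
         paste(types, collapse = "/"), call. = FALSE)
  shift <- function(p) ((p - iv[1L]) %% n) + 1L  # region-local coordinate
  starts <- integer(); keep <- logical(nrow(feats))
  straddle <- character()
  for (i in seq_len(nrow(feats))) {
    sp <- feature_span(feats$parts[[i]])
    a <- shift(sp[1L]); b <- shift(sp[2L])
    inside <- a <= b && b <= rlen
    keep[i] <- inside
    if (inside) starts <- c(starts, a)
    else if (a <= rlen || b <= rlen)  # partially inside: boundary straddler
      straddle <- c(straddle, feats$name[i])
  }
  if (length(straddle))
    warning("excluded ", length(straddle), " feature(s) straddling a ",
            region, " boundary: ", paste(straddle, collapse = ", "),
            call. = FALSE)
  feats <- feats[keep, , drop = FALSE]
  if (!nrow(feats))
    stop("no features of type ", paste(types, collapse = "/"),
         " fully inside ", region, call. = FALSE)
  o <- order(starts)
  gene_order(feats$name[o], feats$strand[o], genome_id = rec$record_id,
             region = region)
}

#' Number of introns of a gene
#'
#' Counted as (number of coordinate parts - 1) of the gene's CDS/exon
#' structure: the feature's parts are its exons, the gaps between them its
#' introns. When several feature rows share the name (e.g. an IR-duplicated
#' gene, or both a `gene` and a `CDS` row), the row with type `CDS` is
#' preferred, then `gene`; among equals the first by coordinate is used.
#'
#' @param rec A [plastome_record()].
#' @param gene_name Gene symbol to look up.
#' @return Non-negative integer intron count.
#' @examples
#' rec <- plastome_record("toy", strrep("ACGT", 50), data.frame(
#'   name = "clpP", type = "CDS", strand = 1L,
#'   parts = I(list(cbind(start = c(10, 60, 120), end = c(40, 90, 150))))))
#' intron_count(rec, "clpP")  # 2
#' @export
intron_count <- function(rec, gene_name) {
  hits <- rec$features[rec$features$name == gene_name, , drop = FALSE]
  if (!nrow(hits))
    stop("gene '", gene_name, "' not found in record ", rec$record_id,
         call. = FALSE)
  pref <- match(hits$type, c("CDS", "gene", "exon", "tRNA", "rRNA"))
  starts <- vapply(hits$parts, function(p) min(p[, 1L]), 1)
  pick <- order(pref, starts)[1L]
  nrow(hits$parts[[pick]]) - 1L
}
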