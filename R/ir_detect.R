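## Quadripartite structure detection: the plastome circle is partitioned
## into LSC + IRa + SSC + IRb by locating the longest pair of disjoint,
## exactly reverse-complementary segments. Seeds are exact k-mer matches
## between the circular sequence and its reverse complement; on a fixed
## (position sum) diagonal consecutive seeds chain into maximal exact
## matches, so no per-base extension step is needed. k-mer codes are exact
## base-4 integers (k <= 20 fits a double exactly), hence collision-free.

circ_length <- function(iv, n) ((iv[2L] - iv[1L]) %% n) + 1L

circ_extract <- function(s, iv, n) {
  if (iv[1L] <= iv[2L]) substr(s, iv[1L], iv[2L])
  else paste0(substr(s, iv[1L], n), substr(s, 1L, iv[2L]))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

encode_nt <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  match(v, c("A", "C", "G", "T"))  # N and anything else -> NA (never matches)
}

circ_kmer_codes <- function(enc, k) {
  n <- length(enc)
  ext <- c(enc, enc[seq_len(k - 1L)])
  acc <- numeric(n)
  for (t in seq_len(k))
    acc <- acc + (ext[t:(t + n - 1L)] - 1) * 4^(k - t)
  acc
}

## maximal runs of consecutive values in sorted integer vector b (1..n),
## chained circularly across the n -> 1 boundary
circ_runs <- function(b, n) {
  brk <- c(0L, which(diff(b) != 1L), length(b))
  starts <- b[brk[-length(brk)] + 1L]
  lens <- diff(brk)
  if (length(starts) > 1L && b[1L] == 1L && b[length(b)] == n) {
    # last run wraps into the first
    k <- length(starts)
    starts[1L] <- starts[k]
    lens[1L] <- lens[1L] + lens[k]
    starts <- starts[-k]; lens <- lens[-k]
  }
  list(start = starts, len = pmin(lens, n))
}

#' Detect the quadripartite structure of a circular plastome
#'
#' Finds the longest pair of disjoint, exactly reverse-complementary
#' segments of length at least `min_ir_length` on the circle, maximally
#' extended while exact complementarity holds (no mismatch tolerance --
#' plastome IRs are perfect repeats; ambiguous `N` bases never match).
#' The two segments are the inverted repeats; the two arcs between them are
#' the single-copy regions, the larger being the LSC. `IRa` is the copy
#' immediately following the LSC in the forward direction. If two candidate
#' pairs tie in repeat length, the pair whose larger single-copy arc is
#' longest wins; remaining ties break on the smallest start coordinate.
#'
#' @param rec A [plastome_record()] (or a bare sequence string).
#' @param min_ir_length Minimum detectable repeat length in bp
#'   (default 1000).
#' @return Object of class `"quadripartite_map"`: 1-based inclusive
#'   circular intervals `lsc`, `ira`, `ssc`, `irb` (each `c(start, end)`,
#'   `end < start` meaning the interval wraps past the origin), plus
#'   `genome_bp` and per-region lengths.
#' @examples
#' p <- synth_plastome(lsc_bp = 3000, ir_bp = 600, ssc_bp = 800,
#'                     seed = 7, min_ir_length = 200)
#' find_inverted_repeat(p$record, min_ir_length = 200)
#' @export
find_inverted_repeat <- function(rec, min_ir_length = 1000L) {
  s <- if (inherits(rec, "plastome_record")) rec$sequence
       else toupper(as.character(rec)[1L])
  n <- nchar(s)
  min_ir_length <- as.integer(min_ir_length)
  if (min_ir_length < 2L)
    stop("min_ir_length must be at least 2", call. = FALSE)
  no_ir <- function() stop(
    "no inverted repeat of length >= ", min_ir_length, " bp found: ",
    "non-quadripartite or degraded plastome", call. = FALSE)
  if (n < 2L * min_ir_length) no_ir()

  enc <- encode_nt(s)
  k <- min(20L, min_ir_length)
  code_s <- circ_kmer_codes(enc, k)
  enc_r <- rev(5L - enc)                 # reverse complement, NA preserved
  code_r <- circ_kmer_codes(enc_r, k)

  dt_s <- data.table::data.table(code = code_s, b = seq_len(n))
  dt_s <- dt_s[!is.na(dt_s$code)]
  dt_r <- data.table::data.table(code = code_r, cc = seq_len(n))
  dt_r <- dt_r[!is.na(dt_r$code)]
  hits <- dt_s[dt_r, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) no_ir()
  hits[, "diag" := (hits$b - hits$cc) %% n]

  cand <- hits[, {
    o <- order(b)
    r <- circ_runs(b[o], n)
    list(b0 = r$start, len = r$len)
  }, by = "diag"]
  cand <- cand[cand$len + k - 1L >= min_ir_length]
  if (!nrow(cand)) no_ir()

  # convert each maximal match to an (a, b, L) reverse-complement pair on S
  L <- pmin(cand$len + k - 1L, n)
  b0 <- cand$b0
  c0 <- ((b0 - 1L - cand$diag) %% n) + 1L
  a0 <- ((n - c0 - L + 1L) %% n) + 1L

  p1 <- pmin(a0, b0); p2 <- pmax(a0, b0)
  keep <- !duplicated(data.frame(p1, p2, L))
  p1 <- p1[keep]; p2 <- p2[keep]; L <- L[keep]
  # disjoint on the circle: both inter-copy gaps must be >= 0 and arcs > 0
  gap12 <- (p2 - p1 - L) %% n
  gap21 <- (p1 - p2 - L) %% n
  disjoint <- ((p2 - p1) %% n) >= L & ((p1 - p2) %% n) >= L &
    gap12 + gap21 == n - 2L * L & gap12 > 0L & gap21 > 0L
  p1 <- p1[disjoint]; p2 <- p2[disjoint]; L <- L[disjoint]
  gap12 <- gap12[disjoint]; gap21 <- gap21[disjoint]
  if (!length(L)) no_ir()

  larger_sc <- pmax(gap12, gap21)
  best <- order(-L, -larger_sc, p1)[1L]
  p1 <- p1[best]; p2 <- p2[best]; L <- L[best]
  gap12 <- gap12[best]; gap21 <- gap21[best]

  wrap1 <- function(x) ((x - 1L) %% n) + 1L
  copy1 <- c(p1, wrap1(p1 + L - 1L))
  copy2 <- c(p2, wrap1(p2 + L - 1L))
  arc12 <- c(wrap1(p1 + L), wrap1(p2 - 1L))   # after copy1, before copy2
  arc21 <- c(wrap1(p2 + L), wrap1(p1 - 1L))
  if (gap12 >= gap21) {
    lsc <- arc12; ira <- copy2; ssc <- arc21; irb <- copy1
  } else {
    lsc <- arc21; ira <- copy1; ssc <- arc12; irb <- copy2
  }
  stopifnot(circ_extract(s, ira, n) == revcomp_chr(circ_extract(s, irb, n)))
  structure(list(lsc = lsc, ira = ira, ssc = ssc, irb = irb,
                 genome_bp = n,
                 region_bp = c(lsc = circ_length(lsc, n),
                               ira = L, ssc = circ_length(ssc, n),
                               irb = L)),
            class = "quadripartite_map")
}

#' @export
print.quadripartite_map <- function(x, ...) {
  cat("Quadripartite map (", x$genome_bp, " bp circle):\n", sep = "")
  for (r in c("lsc", "ira", "ssc", "irb")) {
    iv <- x[[r]]
    cat(sprintf("  %-4s %8d..%-8d (%d bp)\n", toupper(r), iv[1L], iv[2L],
                x$region_bp[[r]]))
  }
  invisible(x)
}

#' Export a quadripartite map as BED-like 0-based half-open intervals
#'
#' Explicit coordinate-convention conversion: internal coordinates are
#' 1-based inclusive; BED rows are 0-based half-open. Wrapped regions are
#' split into two rows.
#'
#' @param map A `quadripartite_map`.
#' @param chrom Chromosome/record name for the first BED column.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
quadripartite_bed <- function(map, chrom = "plastome") {
  rows <- list()
  for (r in c("lsc", "ira", "ssc", "irb")) {
    iv <- map[[r]]
    if (iv[1L] <= iv[2L]) {
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chrom, start = iv[1L] - 1L, end = iv[2L],
                   name = toupper(r))
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chrom, start = iv[1L] - 1L, end = map$genome_bp,
                   name = toupper(r))
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chrom, start = 0L, end = iv[2L],
                   name = toupper(r))
    }
  }
  do.call(rbind, rows)
}

region_of_feature <- function(parts, map) {
  n <- map$genome_bp
  sp <- feature_span(parts)
  for (r in c("lsc", "ira", "ssc", "irb")) {
    iv <- map[[r]]
    rlen <- circ_length(iv, n)
    a <- ((sp[1L] - iv[1L]) %% n) + 1L
    b <- ((sp[2L] - iv[1L]) %% n) + 1L
    if (a <= b && b <= rlen) return(toupper(r))
  }
  "junction"
}

#' Region statistics of a mapped plastome
#'
#' @param rec A [plastome_record()].
#' @param map Its quadripartite map ([find_inverted_repeat()]).
#' @return Object of class `"region_stats"`: total length, per-region
#'   lengths (which sum to the total), AT composition in percent to one
#'   decimal (A+T over all bases; `N` counts in the denominator only), and
#'   feature counts per region by type — both raw and IR-deduplicated
#'   (features sharing name and type counted once), since conventions
#'   differ on whether IR-borne duplicates are counted twice.
#' @export
region_stats <- function(rec, map) {
  if (!inherits(rec, "plastome_record"))
    stop("expected a plastome_record", call. = FALSE)
  if (!inherits(map, "quadripartite_map"))
    stop("expected a quadripartite_map", call. = FALSE)
  n <- nchar(rec$sequence)
  if (n != map$genome_bp)
    stop("record and quadripartite map disagree on sequence length",
         call. = FALSE)
  counts <- table(factor(strsplit(rec$sequence, "", fixed = TRUE)[[1L]],
                         levels = c("A", "C", "G", "T", "N")))
  at_percent <- round(100 * (counts[["A"]] + counts[["T"]]) / n, 1L)

  feats <- rec$features
  regions <- if (nrow(feats))
    vapply(feats$parts, region_of_feature, character(1), map = map)
  else character(0)
  lev_r <- c("LSC", "IRA", "SSC", "IRB", "junction")
  lev_t <- c("gene", "CDS", "tRNA", "rRNA", "exon")
  raw <- table(factor(regions, levels = lev_r),
               factor(feats$type, levels = lev_t))
  dedup_idx <- !duplicated(feats[c("name", "type")])
  dedup <- table(factor(feats$type[dedup_idx], levels = lev_t))

  structure(list(record_id = rec$record_id, total_bp = n,
                 region_bp = map$region_bp, at_percent = at_percent,
                 base_counts = stats::setNames(as.integer(counts),
                                               names(counts)),
                 feature_counts = raw,
                 feature_counts_dedup = stats::setNames(as.integer(dedup),
                                                        names(dedup))),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat("Plastome ", x$record_id, ": ", x$total_bp, " bp, AT ",
      sprintf("%.1f", x$at_percent), "%\n", sep = "")
  cat(sprintf("  LSC %d bp | IRa %d bp | SSC %d bp | IRb %d bp\n",
              x$region_bp[["lsc"]], x$region_bp[["ira"]],
              x$region_bp[["ssc"]], x$region_bp[["irb"]]))
  if (sum(x$feature_counts)) {
    cat("  feature counts by region (raw):\n")
    print(x$feature_counts[rowSums(x$feature_counts) > 0, , drop = FALSE])
    cat("  IR-deduplicated totals:",
        paste(sprintf("%s:%d", names(x$feature_counts_dedup),
                      x$feature_counts_dedup), collapse = "  "), "\n")
  }
  invisible(x)
}

#' @rdname region_stats
#' @param stats A `region_stats` object.
#' @return `region_stats_json()`: a plain list ready for
#'   [jsonlite::write_json()].
#' @export
region_stats_json <- function(stats) {
  list(record_id = stats$record_id, total_bp = stats$total_bp,
       region_bp = as.list(stats$region_bp),
       at_percent = stats$at_percent,
       feature_counts = as.data.frame(stats$feature_counts,
                                      stringsAsFactors = FALSE,
                                      responseName = "count"),
       feature_counts_dedup = as.list(stats$feature_counts_dedup))
}
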