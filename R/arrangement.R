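#' Signed block arrangement
#'
#' A plastome region (LSC or SSC, say) is represented as a linear, ordered
#' series of uniquely labelled colinear blocks, each carrying an orientation
#' sign. Block order runs left to right in ascending reference coordinates;
#' a sign of `-1` means the block lies reverse-complemented relative to its
#' reference orientation.
#'
#' @param labels Character vector of block labels, pairwise distinct and
#'   non-empty (e.g. `c("D-LSC3", "D-LSC1", "D-LSC2")`).
#' @param signs Integer vector of orientations, each exactly `+1` or `-1`.
#'   Defaults to all `+1`.
#' @param length_bp Optional numeric vector of approximate block lengths in
#'   base pairs (`NA` allowed per block); must be positive where present.
#' @param region Region name, e.g. `"LSC"` or `"SSC"`.
#'
#' @return An object of class `"signed_arrangement"`: a list with elements
#'   `region`, `labels`, `signs`, `length_bp`.
#' @examples
#' typha_lsc <- signed_arrangement(c("D-LSC3", "D-LSC1", "D-LSC2"),
#'                                 region = "LSC")
#' apply_inversion(typha_lsc, 2, 3)
#' @export
signed_arrangement <- function(labels, signs = rep(1L, length(labels)),
                               length_bp = rep(NA_real_, length(labels)),
                               region = "region") {
  labels <- as.character(labels)
  signs <- as.integer(signs)
  length_bp <- as.numeric(length_bp)
  if (length(labels) < 1L)
    stop("an arrangement needs at least one block", call. = FALSE)
  if (any(!nzchar(labels)) || anyNA(labels))
    stop("block labels must be non-empty strings", call. = FALSE)
  if (anyDuplicated(labels))
    stop("block labels must be pairwise distinct: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (length(signs) != length(labels) || !all(signs %in% c(-1L, 1L)))
    stop("signs must be +1 or -1, one per block", call. = FALSE)
  if (length(length_bp) != length(labels) ||
      any(!is.na(length_bp) & length_bp <= 0))
    stop("approximate block lengths must be positive where given",
         call. = FALSE)
  structure(list(region = as.character(region)[1L], labels = labels,
                 signs = signs, length_bp = length_bp),
            class = "signed_arrangement")
}

#' @export
print.signed_arrangement <- function(x, ...) {
  cat("Signed block arrangement [", x$region, "], ",
      length(x$labels), " block(s):\n  ", sep = "")
  cat(paste0(ifelse(x$signs > 0, "+", "-"), x$labels), sep = " ")
  cat("\n")
  invisible(x)
}

#' @export
length.signed_arrangement <- function(x) length(x$labels)

n_blocks <- function(arr) length(arr$labels)

stopifnot_arrangement <- function(arr) {
  if (!inherits(arr, "signed_arrangement"))
    stop("expected a signed_arrangement", call. = FALSE)
  invisible(arr)
}

check_same_labels <- function(a, b) {
  stopifnot_arrangement(a); stopifnot_arrangement(b)
  if (!setequal(a$labels, b$labels) ||
      length(a$labels) != length(b$labels))
    stop("incomparable arrangements: block label sets differ", call. = FALSE)
  invisible(TRUE)
}

#' Apply an inversion event to an arrangement
#'
#' Reverses the order of the blocks in positions `start..end` (1-based,
#' inclusive) and negates every sign inside the interval; blocks outside are
#' untouched. This is the block-level image of a genomic inversion: the
#' segment is excised and reinserted in place, reverse-complemented. The
#' operation is pure (the input is not modified) and is an involution.
#'
#' @param arr A [signed_arrangement()].
#' @param start,end 1-based inclusive block indices, `1 <= start <= end <= n`.
#' @return The rearranged `signed_arrangement`.
#' @examples
#' a <- signed_arrangement(c("B1", "B2", "B3"))
#' apply_inversion(a, 2, 3)  # +B1 -B3 -B2
#' @export
apply_inversion <- function(arr, start, end) {
  stopifnot_arrangement(arr)
  n <- n_blocks(arr)
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end) ||
      start < 1L || end > n || start > end)
    stop("invalid inversion event: need 1 <= start <= end <= ", n,
         call. = FALSE)
  idx <- seq_along(arr$labels)
  idx[start:end] <- rev(idx[start:end])
  out <- arr
  out$labels <- arr$labels[idx]
  out$signs <- arr$signs[idx]
  out$signs[start:end] <- -out$signs[start:end]
  out$length_bp <- arr$length_bp[idx]
  out
}

#' Replay a series of inversion events
#'
#' @param arr A [signed_arrangement()].
#' @param events A scenario: a data frame (or 2-column matrix) with columns
#'   `start` and `end`, one row per event, applied in row order. Zero rows
#'   replay the empty scenario.
#' @return The terminal `signed_arrangement`.
#' @export
apply_scenario <- function(arr, events) {
  events <- as_events(events)
  for (i in seq_len(nrow(events)))
    arr <- apply_inversion(arr, events$start[i], events$end[i])
  arr
}

as_events <- function(events) {
  if (is.matrix(events)) events <- data.frame(start = events[, 1L],
                                              end = events[, 2L])
  if (is.null(events)) events <- data.frame(start = integer(), end = integer())
  if (!is.data.frame(events) || !all(c("start", "end") %in% names(events)))
    stop("a scenario needs 'start' and 'end' columns", call. = FALSE)
  data.frame(start = as.integer(events$start), end = as.integer(events$end))
}

flip_arrangement <- function(arr) {
  out <- arr
  out$labels <- rev(arr$labels)
  out$signs <- -rev(arr$signs)
  out$length_bp <- rev(arr$length_bp)
  out
}

#' Compare two arrangements, optionally up to whole-segment flip
#'
#' Without flip equivalence, two arrangements are equal when their ordered,
#' signed block lists are identical. With flip equivalence they are also
#' equal when one is the whole-segment reverse complement of the other
#' (blocks reversed and every sign negated). Flip equivalence reflects the
#' biology of the small single-copy region: between its flanking inverted
#' repeats the SSC occurs in equimolar populations of both orientations, so
#' its absolute orientation carries no phylogenetic signal.
#'
#' @param a,b Arrangements over the same block label set.
#' @param flip_equivalence Treat `b` and its full flip as the same state?
#'   Off by default; turn it on for SSC analyses.
#' @return `TRUE` or `FALSE`.
#' @export
arrangements_equal <- function(a, b, flip_equivalence = FALSE) {
  check_same_labels(a, b)
  same <- function(x, y) identical(x$labels, y$labels) &&
    identical(x$signs, y$signs)
  same(a, b) || (isTRUE(flip_equivalence) && same(flip_arrangement(a), b))
}

#' Encode a target arrangement as a signed permutation of its source
#'
#' Relabels blocks so that `source` becomes the identity `+1..+n`, then
#' expresses `target` in that frame. This canonical signed-permutation
#' encoding is what the search and the oracle operate on.
#'
#' @param source,target Arrangements sharing one block label set.
#' @return An integer vector of signed block indices; the source labels, in
#'   frame order, are attached as attribute `"labels"` so the encoding
#'   round-trips.
#' @examples
#' typha <- signed_arrangement(c("D-LSC3", "D-LSC1", "D-LSC2"))
#' anomo <- signed_arrangement(c("D-LSC2", "D-LSC3", "D-LSC1"),
#'                             signs = c(1L, -1L, -1L))
#' relabel_against_reference(typha, anomo)  # +3 -1 -2
#' @export
relabel_against_reference <- function(source, target) {
  check_same_labels(source, target)
  pos <- match(target$labels, source$labels)
  perm <- as.integer(pos * (target$signs * source$signs[pos]))
  attr(perm, "labels") <- source$labels
  perm
}

perm_to_arrangement <- function(perm, labels = attr(perm, "labels"),
                                region = "region") {
  if (is.null(labels)) labels <- paste0("B", seq_along(perm))
  signed_arrangement(labels[abs(perm)], signs = as.integer(sign(perm)),
                     region = region)
}

#' Read / write a pair of block arrangements as TSV
#'
#' The block TSV dialect holds two sections (source arrangement first,
#' target second) separated by a blank line. Each section starts with a
#' comment header `# region=<name>\tgenome=<id>` and has one block per line:
#' `<label>\t<+|->\t[approx_length_bp]`. The minus sign may be ASCII `-` or
#' U+2212; files are UTF-8 and other `#` lines are comments.
#'
#' @param path File to read or write.
#' @return `read_blocks_tsv()` returns a list with elements `source` and
#'   `target` (each a [signed_arrangement()] with a `genome` attribute);
#'   `write_blocks_tsv()` returns `path` invisibly. Reading a written pair
#'   reproduces it.
#' @export
read_blocks_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sections <- list(); cur <- integer(0)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      if (length(cur)) { sections[[length(sections) + 1L]] <- cur; cur <- integer(0) }
    } else cur <- c(cur, i)
  }
  if (length(cur)) sections[[length(sections) + 1L]] <- cur
  if (length(sections) != 2L)
    stop("block TSV must contain exactly two sections separated by a blank ",
         "line (found ", length(sections), ")", call. = FALSE)
  pair <- lapply(sections, function(ln) parse_block_section(lines, ln))
  if (!setequal(pair[[1L]]$labels, pair[[2L]]$labels))
    stop("block TSV parse error: the two sections carry different block ",
         "label sets", call. = FALSE)
  list(source = pair[[1L]], target = pair[[2L]])
}

parse_block_section <- function(lines, line_nos) {
  region <- "region"; genome <- NA_character_
  labels <- character(); signs <- integer(); lens <- numeric()
  for (i in line_nos) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("region=([^\t ]+)", ln))[[1L]]
      if (length(m) == 2L) region <- m[2L]
      m <- regmatches(ln, regexec("genome=([^\t ]+)", ln))[[1L]]
      if (length(m) == 2L) genome <- m[2L]
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop("block TSV parse error at line ", i,
           ": expected <label>\\t<sign>[\\t<bp>]", call. = FALSE)
    sgn <- switch(f[2L], "+" = 1L, "-" = -1L, "−" = -1L,
                  stop("block TSV parse error at line ", i,
                       ": unknown sign token '", f[2L], "'", call. = FALSE))
    bp <- NA_real_
    if (length(f) >= 3L && nzchar(f[3L])) {
      bp <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(bp) || bp <= 0)
        stop("block TSV parse error at line ", i,
             ": bad approx_length_bp '", f[3L], "'", call. = FALSE)
    }
    if (f[1L] %in% labels)
      stop("block TSV parse error at line ", i, ": duplicate label '",
           f[1L], "'", call. = FALSE)
    labels <- c(labels, f[1L]); signs <- c(signs, sgn); lens <- c(lens, bp)
  }
  if (!length(labels))
    stop("block TSV parse error: empty section", call. = FALSE)
  arr <- signed_arrangement(labels, signs, lens, region = region)
  attr(arr, "genome") <- genome
  arr
}

#' @rdname read_blocks_tsv
#' @param pair A list with `source` and `target` arrangements (as returned
#'   by [read_blocks_tsv()] or [collinear_blocks()]).
#' @export
write_blocks_tsv <- function(pair, path) {
  if (!all(c("source", "target") %in% names(pair)))
    stop("pair must have 'source' and 'target' arrangements", call. = FALSE)
  fmt <- function(arr) {
    genome <- attr(arr, "genome"); if (is.null(genome) || is.na(genome)) genome <- "NA"
    bp <- ifelse(is.na(arr$length_bp), "", format(arr$length_bp, trim = TRUE,
                                                  scientific = FALSE))
    c(sprintf("# region=%s\tgenome=%s", arr$region, genome),
      sprintf("%s\t%s%s", arr$labels, ifelse(arr$signs > 0, "+", "-"),
              ifelse(nzchar(bp), paste0("\t", bp), "")))
  }
  writeLines(c(fmt(pair$source), "", fmt(pair$target)), path, useBytes = TRUE)
  invisible(path)
}
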