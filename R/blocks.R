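#' Gene order of one plastome region
#'
#' @param symbols Character vector of gene symbols in coordinate order.
#' @param strands Integer vector of strands (`+1`/`-1`), one per gene.
#' @param genome_id Genome identifier.
#' @param region Region name ("LSC", "SSC", ...).
#' @return Object of class `"gene_order"`.
#' @export
gene_order <- function(symbols, strands = rep(1L, length(symbols)),
                       genome_id = "genome", region = "region") {
  symbols <- as.character(symbols); strands <- as.integer(strands)
  if (length(symbols) < 1L)
    stop("a gene order needs at least one gene", call. = FALSE)
  if (length(strands) != length(symbols) || !all(strands %in% c(-1L, 1L)))
    stop("strands must be +1 or -1, one per gene", call. = FALSE)
  structure(list(genome_id = as.character(genome_id)[1L],
                 region = as.character(region)[1L],
                 symbols = symbols, strands = strands),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("Gene order [", x$genome_id, "/", x$region, "], ",
      length(x$symbols), " gene(s):\n  ", sep = "")
  cat(paste0(x$symbols, ifelse(x$strands > 0, "(+)", "(-)")), sep = " ")
  cat("\n")
  invisible(x)
}

#' Read a gene order from a two-column TSV (symbol, strand)
#'
#' @param path TSV file; `#` lines are comments. Strand tokens `+`/`-`
#'   (U+2212 accepted).
#' @inheritParams gene_order
#' @return A [gene_order()].
#' @export
read_gene_order_tsv <- function(path, genome_id = basename(path),
                                region = "region") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  symbols <- character(); strands <- integer()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop("gene order parse error at line ", i,
           ": expected <symbol>\\t<strand>", call. = FALSE)
    sgn <- switch(f[2L], "+" = 1L, "-" = -1L, "−" = -1L,
                  stop("gene order parse error at line ", i,
                       ": unknown strand token '", f[2L], "'", call. = FALSE))
    symbols <- c(symbols, f[1L]); strands <- c(strands, sgn)
  }
  gene_order(symbols, strands, genome_id = genome_id, region = region)
}

#' Restrict two gene orders to their shared single-copy genes
#'
#' Keeps exactly the gene symbols that occur precisely once in each order
#' (genes duplicated within a region — IR-borne copies, ambiguous symbols —
#' are dropped from both, since unique anchors are needed for a well-defined
#' permutation). Relative order and strands are preserved.
#'
#' @param a,b [gene_order()] objects.
#' @return List of the two restricted gene orders.
#' @export
restrict_to_shared <- function(a, b) {
  if (!inherits(a, "gene_order") || !inherits(b, "gene_order"))
    stop("expected gene_order objects", call. = FALSE)
  once <- function(x) { tb <- table(x$symbols); names(tb)[tb == 1L] }
  shared <- intersect(once(a), once(b))
  if (!length(shared))
    stop("no shared single-copy gene anchors between ", a$genome_id,
         " and ", b$genome_id, call. = FALSE)
  sub <- function(x) {
    keep <- x$symbols %in% shared
    gene_order(x$symbols[keep], x$strands[keep], x$genome_id, x$region)
  }
  list(sub(a), sub(b))
}

#' Shared locally colinear blocks from two gene orders
#'
#' A desk-scale surrogate for sequence-level synteny block detection (Mauve
#' style): after [restrict_to_shared()], the shared genes are partitioned
#' into maximal runs that are consecutive in both orders with a consistent
#' joint orientation — either same order and same strands, or exactly
#' reversed order with every strand flipped. Blocks fall on gene boundaries
#' by construction and are labelled `B1..Bk` in source coordinate order, so
#' the source arrangement is the identity frame; a reversed singleton run
#' takes the sign of its strand comparison.
#'
#' @param a Source [gene_order()] (becomes the identity frame).
#' @param b Target [gene_order()].
#' @return A list of class `"block_pair"`: `source` and `target`
#'   [signed_arrangement()]s over labels `B1..Bk`, and `block_members`,
#'   a named list mapping each label to its member gene symbols in source
#'   order.
#' @examples
#' a <- gene_order(c("w", "x", "y", "z"))
#' b <- gene_order(c("w", "y", "x", "z"), c(1L, -1L, -1L, 1L))
#' collinear_blocks(a, b)$target$signs  # +1 -1 +1
#' @export
collinear_blocks <- function(a, b) {
  r <- restrict_to_shared(a, b)
  a <- r[[1L]]; b <- r[[2L]]
  m <- length(b$symbols)
  pos <- match(b$symbols, a$symbols)
  rel <- b$strands * a$strands[pos]

  # scan b, extending runs while consecutive in a with consistent orientation
  run_id <- integer(m); run_sign <- integer(0)
  cur <- 1L; run_id[1L] <- 1L
  cur_sign <- 0L  # 0 = undecided singleton so far
  for (i in seq_len(m)[-1L]) {
    step <- pos[i] - pos[i - 1L]
    extend <- (step == 1L && rel[i] == 1L && rel[i - 1L] == 1L &&
                 cur_sign >= 0L) ||
              (step == -1L && rel[i] == -1L && rel[i - 1L] == -1L &&
                 cur_sign <= 0L)
    if (extend) {
      cur_sign <- if (step == 1L) 1L else -1L
    } else {
      run_sign <- c(run_sign, if (cur_sign != 0L) cur_sign else rel[i - 1L])
      cur <- cur + 1L
      cur_sign <- 0L
    }
    run_id[i] <- cur
  }
  run_sign <- c(run_sign, if (cur_sign != 0L) cur_sign else rel[m])

  k <- cur
  first_pos <- vapply(seq_len(k), function(r) min(pos[run_id == r]), 1L)
  # blocks labelled in source coordinate order
  src_rank <- rank(first_pos)
  labels_b <- paste0("B", src_rank)            # label of run r (b order)
  members <- lapply(order(src_rank), function(r)
    a$symbols[sort(pos[run_id == r])])
  names(members) <- paste0("B", seq_len(k))

  source_arr <- signed_arrangement(paste0("B", seq_len(k)),
                                   region = a$region)
  attr(source_arr, "genome") <- a$genome_id
  target_arr <- signed_arrangement(labels_b, signs = run_sign,
                                   region = b$region)
  attr(target_arr, "genome") <- b$genome_id
  structure(list(source = source_arr, target = target_arr,
                 block_members = members),
            class = "block_pair")
}

#' @export
print.block_pair <- function(x, ...) {
  cat("Block pair:", length(x$source$labels), "shared colinear block(s)\n")
  cat("  source ["
      , attr(x$source, "genome"), "]: ",
      paste0(ifelse(x$source$signs > 0, "+", "-"), x$source$labels,
             collapse = " "), "\n", sep = "")
  cat("  target ["
      , attr(x$target, "genome"), "]: ",
      paste0(ifelse(x$target$signs > 0, "+", "-"), x$target$labels,
             collapse = " "), "\n", sep = "")
  for (lab in names(x$block_members))
    cat("  ", lab, ": ", paste(x$block_members[[lab]], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
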