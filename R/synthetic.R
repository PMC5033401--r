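## Seeded generators: random arrangements, planted inversion histories, and
## plastome-like records with planted quadripartite structure. Everything is
## a pure function of its parameters and seed, so every other module can be
## scored offline against known ground truth.

#' Uniformly random signed arrangement
#'
#' @param n Number of blocks (labelled `B1..Bn`).
#' @param seed Integer seed; the same seed always yields the same
#'   arrangement.
#' @param region Region name for the result.
#' @return A [signed_arrangement()]: a uniformly random permutation of the
#'   labels with independent fair orientation signs.
#' @export
random_arrangement <- function(n, seed = 1L, region = "region") {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  set.seed(as.integer(seed))
  signed_arrangement(paste0("B", sample.int(n)),
                     signs = sample(c(-1L, 1L), n, replace = TRUE),
                     region = region)
}

#' Plant a random inversion history on an arrangement
#'
#' Applies `k` inversion events drawn uniformly at random from all valid
#' contiguous block intervals, sequentially, and returns both the final
#' arrangement and the exact event list — the ground truth against which
#' the search and oracle are scored (the true minimal distance is at most
#' `k`; it is less when planted events are redundant).
#'
#' @param arr Starting [signed_arrangement()].
#' @param k Number of events to plant (`k >= 0`).
#' @param seed Integer seed.
#' @return List with `arrangement` (terminal state) and `scenario` (data
#'   frame of `start`, `end` events in application order).
#' @export
plant_inversions <- function(arr, k, seed = 1L) {
  stopifnot_arrangement(arr)
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop("k must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  n <- n_blocks(arr)
  iv <- all_intervals(n)
  ids <- if (k > 0L) sample.int(nrow(iv), k, replace = TRUE) else integer(0)
  events <- data.frame(start = iv[ids, 1L], end = iv[ids, 2L])
  list(arrangement = apply_scenario(arr, events), scenario = events)
}

## A single-copy region whose first base complements its last would let the
## exact repeat match extend past the planted boundary (the IR copies flank
## both region ends on the circle), so boundary recovery would not be exact;
## sealing replaces the first base with the last (never self-complementary).
seal_junction <- function(x) {
  first <- substr(x, 1L, 1L); last <- substr(x, nchar(x), nchar(x))
  if (first == chartr("ACGT", "TGCA", last)) substr(x, 1L, 1L) <- last
  x
}

random_dna <- function(len, at_fraction = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(at_fraction / 2, (1 - at_fraction) / 2,
                        (1 - at_fraction) / 2, at_fraction / 2)),
        collapse = "")
}

place_genes <- function(region_start, region_len, n_genes, prefix,
                        strands) {
  slot <- region_len %/% n_genes
  if (slot < 10L)
    stop("region too short for ", n_genes, " genes (", region_len,
         " bp): need >= 10 bp per gene slot", call. = FALSE)
  lo <- floor(slot * 0.2); hi <- floor(slot * 0.8)
  data.frame(
    name = sprintf("%s_g%02d", prefix, seq_len(n_genes)),
    type = "gene",
    strand = strands,
    parts = I(lapply(seq_len(n_genes), function(i) {
      s <- region_start + (i - 1L) * slot + lo
      e <- region_start + (i - 1L) * slot + hi
      cbind(start = as.integer(s), end = as.integer(e))
    })))
}

#' Generate a synthetic plastome with planted quadripartite structure
#'
#' Builds a circular record laid out as `LSC + IRa + SSC + IRb`, where IRb
#' is the exact reverse complement of IRa (features mirrored with the same
#' names, strands flipped). Region sequences are i.i.d. nucleotides with
#' the given AT fraction; gene features are evenly spaced, never overlap
#' and never straddle a region boundary, so [gene_order_from_features()]
#' round-trips exactly. Single-copy junction bases are adjusted so the
#' planted repeat cannot be coincidentally extended, making
#' [find_inverted_repeat()] boundary recovery exact. Optionally a sibling record is emitted whose LSC
#' carries a known planted series of block-level inversions, together with
#' the full ground truth.
#'
#' Default dimensions are those of a typical graminid-clade plastome
#' (LSC 85,526 bp, SSC 12,907 bp, IRs 25,447 bp — about 149 kbp in total).
#'
#' @param lsc_bp,ir_bp,ssc_bp Region lengths in bp.
#' @param n_genes Named integer vector: genes to plant in the LSC, each IR
#'   copy, and the SSC.
#' @param at_fraction Expected A+T fraction of the random sequence
#'   (default 0.5).
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param min_ir_length Detector floor the planted IR must exceed;
#'   `ir_bp >= min_ir_length` is enforced.
#' @param n_blocks,k_events When `k_events > 0`, the LSC genes are cut into
#'   `n_blocks` contiguous blocks at intergenic midpoints and `k_events`
#'   uniformly random block-interval inversions are applied to produce the
#'   sibling record.
#' @return List with `record` (a [plastome_record()]), `map_truth` (the
#'   planted region intervals, same shape as a quadripartite map),
#'   `sibling` (rearranged record, or `NULL`), and `truth` (for a sibling:
#'   `scenario`, `source_arr`, `target_arr`, `block_members`).
#' @export
synth_plastome <- function(lsc_bp = 85526L, ir_bp = 25447L, ssc_bp = 12907L,
                           n_genes = c(lsc = 60L, ir = 15L, ssc = 10L),
                           at_fraction = 0.5, seed = 1L,
                           min_ir_length = 1000L,
                           n_blocks = 4L, k_events = 0L) {
  lsc_bp <- as.integer(lsc_bp); ir_bp <- as.integer(ir_bp)
  ssc_bp <- as.integer(ssc_bp)
  if (any(c(lsc_bp, ir_bp, ssc_bp) < 1L))
    stop("region lengths must be positive", call. = FALSE)
  if (ir_bp < min_ir_length)
    stop("planted IR (", ir_bp, " bp) shorter than min_ir_length (",
         min_ir_length, " bp)", call. = FALSE)
  if (lsc_bp < ssc_bp)
    stop("the LSC must be at least as long as the SSC", call. = FALSE)
  if (!all(c("lsc", "ir", "ssc") %in% names(n_genes)))
    stop("n_genes needs entries 'lsc', 'ir', 'ssc'", call. = FALSE)
  k_events <- as.integer(k_events)
  if (is.na(k_events) || k_events < 0L)
    stop("k_events must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))

  lsc_seq <- seal_junction(random_dna(lsc_bp, at_fraction))
  ira_seq <- random_dna(ir_bp, at_fraction)
  ssc_seq <- seal_junction(random_dna(ssc_bp, at_fraction))
  irb_seq <- revcomp_chr(ira_seq)
  n <- lsc_bp + 2L * ir_bp + ssc_bp
  seq_full <- paste0(lsc_seq, ira_seq, ssc_seq, irb_seq)

  lsc_iv <- c(1L, lsc_bp)
  ira_iv <- c(lsc_bp + 1L, lsc_bp + ir_bp)
  ssc_iv <- c(lsc_bp + ir_bp + 1L, lsc_bp + ir_bp + ssc_bp)
  irb_iv <- c(lsc_bp + ir_bp + ssc_bp + 1L, n)

  g_lsc <- place_genes(0L, lsc_bp, n_genes[["lsc"]], "lsc",
                       sample(c(-1L, 1L), n_genes[["lsc"]], replace = TRUE))
  g_ira <- place_genes(ira_iv[1L] - 1L, ir_bp, n_genes[["ir"]], "ir",
                       sample(c(-1L, 1L), n_genes[["ir"]], replace = TRUE))
  g_ssc <- place_genes(ssc_iv[1L] - 1L, ssc_bp, n_genes[["ssc"]], "ssc",
                       sample(c(-1L, 1L), n_genes[["ssc"]], replace = TRUE))
  # IRb carries the mirror image of the IRa genes: same names, reflected
  # coordinates, flipped strands
  g_irb <- g_ira
  g_irb$strand <- -g_ira$strand
  g_irb$parts <- I(lapply(g_ira$parts, function(p)
    cbind(start = irb_iv[1L] + (ira_iv[2L] - p[, 2L]),
          end = irb_iv[1L] + (ira_iv[2L] - p[, 1L]))))
  g_irb <- g_irb[rev(seq_len(nrow(g_irb))), , drop = FALSE]
  feats <- rbind(g_lsc, g_ira, g_ssc, g_irb)
  rownames(feats) <- NULL

  record <- plastome_record("synthetic_plastome", seq_full, feats)
  map_truth <- structure(list(lsc = lsc_iv, ira = ira_iv, ssc = ssc_iv,
                              irb = irb_iv, genome_bp = n,
                              region_bp = c(lsc = lsc_bp, ira = ir_bp,
                                            ssc = ssc_bp, irb = ir_bp)),
                         class = "quadripartite_map")

  sibling <- NULL; truth <- NULL
  if (k_events > 0L) {
    n_blocks <- as.integer(n_blocks)
    if (n_blocks < 2L || n_blocks > n_genes[["lsc"]])
      stop("n_blocks must be in [2, number of LSC genes]", call. = FALSE)
    sib <- build_sibling(record, g_lsc, lsc_bp, n_blocks, k_events)
    sibling <- sib$record; truth <- sib$truth
  }
  list(record = record, map_truth = map_truth, sibling = sibling,
       truth = truth,
       params = list(lsc_bp = lsc_bp, ir_bp = ir_bp, ssc_bp = ssc_bp,
                     n_genes = n_genes, at_fraction = at_fraction,
                     seed = as.integer(seed), n_blocks = n_blocks,
                     k_events = k_events))
}

## Cut the LSC into n_blocks contiguous gene groups at intergenic midpoints,
## apply k random block-interval inversions, and reassemble sequence and
## features. Uses the ambient RNG stream (called from synth_plastome).
build_sibling <- function(record, g_lsc, lsc_bp, n_blocks, k_events) {
  ng <- nrow(g_lsc)
  grp <- sort(rep_len(seq_len(n_blocks), ng))  # contiguous, near-equal
  gene_start <- vapply(g_lsc$parts, function(p) p[1L, 1L], 1L)
  gene_end <- vapply(g_lsc$parts, function(p) p[1L, 2L], 1L)
  cuts <- integer(n_blocks + 1L); cuts[1L] <- 0L; cuts[n_blocks + 1L] <- lsc_bp
  for (b in seq_len(n_blocks - 1L)) {
    last_in <- max(which(grp == b)); first_next <- last_in + 1L
    cuts[b + 1L] <- (gene_end[last_in] + gene_start[first_next]) %/% 2L
  }

  segs <- lapply(seq_len(n_blocks), function(b) {
    s <- cuts[b] + 1L; e <- cuts[b + 1L]
    idx <- which(grp == b)
    list(seq = substr(record$sequence, s, e),
         len = e - s + 1L,
         genes = data.frame(name = g_lsc$name[idx],
                            strand = g_lsc$strand[idx],
                            start = gene_start[idx] - s + 1L,
                            end = gene_end[idx] - s + 1L),
         flipped = FALSE)
  })

  src_arr <- signed_arrangement(paste0("B", seq_len(n_blocks)),
                                region = "LSC")
  attr(src_arr, "genome") <- record$record_id
  planted <- plant_block_events(n_blocks, k_events)
  order_state <- seq_len(n_blocks); flip_state <- rep(FALSE, n_blocks)
  for (i in seq_len(nrow(planted))) {
    s <- planted$start[i]; e <- planted$end[i]
    order_state[s:e] <- rev(order_state[s:e])
    flip_state[s:e] <- !rev(flip_state[s:e])
  }

  # reassemble the sibling LSC
  new_seq <- character(n_blocks); offset <- 0L
  g_rows <- list()
  for (pos in seq_len(n_blocks)) {
    seg <- segs[[order_state[pos]]]
    fl <- flip_state[pos]
    new_seq[pos] <- if (fl) revcomp_chr(seg$seq) else seg$seq
    g <- seg$genes
    if (nrow(g)) {
      if (fl) {
        g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
        new_start <- seg$len - g$end + 1L
        g$end <- seg$len - g$start + 1L
        g$start <- new_start
        g$strand <- -g$strand
      }
      g$start <- g$start + offset; g$end <- g$end + offset
      g_rows[[length(g_rows) + 1L]] <- g
    }
    offset <- offset + seg$len
  }
  sib_lsc_genes <- do.call(rbind, g_rows)
  sib_lsc <- seal_junction(paste(new_seq, collapse = ""))
  sib_seq <- paste0(sib_lsc,
                    substr(record$sequence, lsc_bp + 1L,
                           nchar(record$sequence)))
  other <- record$features[!record$features$name %in% g_lsc$name, ,
                           drop = FALSE]
  sib_feats <- rbind(
    data.frame(name = sib_lsc_genes$name, type = "gene",
               strand = sib_lsc_genes$strand,
               parts = I(lapply(seq_len(nrow(sib_lsc_genes)), function(i)
                 cbind(start = sib_lsc_genes$start[i],
                       end = sib_lsc_genes$end[i])))),
    other)
  rownames(sib_feats) <- NULL
  sib_record <- plastome_record("synthetic_sibling", sib_seq, sib_feats)

  tgt_arr <- apply_scenario(src_arr, planted)
  attr(tgt_arr, "genome") <- "synthetic_sibling"
  members <- split(g_lsc$name, grp)
  names(members) <- paste0("B", seq_len(n_blocks))
  list(record = sib_record,
       truth = list(scenario = planted, source_arr = src_arr,
                    target_arr = tgt_arr, block_members = members))
}

plant_block_events <- function(n_blocks, k_events) {
  iv <- all_intervals(n_blocks)
  ids <- sample.int(nrow(iv), k_events, replace = TRUE)
  data.frame(start = iv[ids, 1L], end = iv[ids, 2L])
}

#' Worked plastome inversion instances as block-pair fixtures
#'
#' The named block configurations of the graminid-clade LSC and SSC
#' rearrangements, encoded as source/target arrangement pairs:
#'
#' * `lsc_typha_anomochloa` — the *Typha latifolia* LSC frame
#'   `(+D-LSC3, +D-LSC1, +D-LSC2)` versus the *Anomochloa marantoidea*
#'   arrangement `(+D-LSC2, -D-LSC3, -D-LSC1)` (the ~23 kbp D-LSC1 and
#'   ~5 kbp D-LSC2 laterally exchanged with D-LSC1 inverted, and the
#'   ~750 bp D-LSC3 moved to a reverse-complemented position between
#'   them); two inversions explain it.
#' * `lsc_anomochloa_joinvillea` — the two-block *Anomochloa* to
#'   *Joinvillea ascendens* LSC instance: Ja-LSC1 (~33 kbp) and Ja-LSC2
#'   (~19.5 kbp) laterally exchanged with Ja-LSC2 reverse-complemented,
#'   i.e. target `(-Ja-LSC2, +Ja-LSC1)`.
#' * `lsc_anomochloa_joinvillea_mirror` — the mirror reading of the same
#'   outcome, `(+Ja-LSC2, -Ja-LSC1)` (Ja-LSC2 restored by the second
#'   event, Ja-LSC1 left inverted). The two readings are
#'   flip-equivalent two-block outcomes and both need two inversions.
#' * `ssc_pojo` — the shared Poaceae–Joinvilleaceae SSC instance:
#'   PoJo-SSC1 (~14 kbp) and PoJo-SSC2 (~3 kbp) laterally exchanged with
#'   PoJo-SSC2 reverse-complemented, target `(-PoJo-SSC2, +PoJo-SSC1)`;
#'   two inversions without flip equivalence, one with it (the SSC's
#'   absolute orientation between its flanking IRs is indeterminate).
#'
#' @param dir If non-`NULL`, also write each pair as a block TSV file
#'   `<name>.tsv` under `dir`.
#' @return Named list of block pairs (each a list with `source` and
#'   `target` [signed_arrangement()]s).
#' @export
plastome_fixtures <- function(dir = NULL) {
  mk <- function(labels, src_genome, tgt_genome, tgt_order, tgt_signs,
                 length_bp, region) {
    src <- signed_arrangement(labels, length_bp = length_bp, region = region)
    attr(src, "genome") <- src_genome
    tgt <- signed_arrangement(labels[tgt_order],
                              signs = as.integer(tgt_signs),
                              length_bp = length_bp[tgt_order],
                              region = region)
    attr(tgt, "genome") <- tgt_genome
    list(source = src, target = tgt)
  }
  fx <- list(
    lsc_typha_anomochloa = mk(
      c("D-LSC3", "D-LSC1", "D-LSC2"), "T_latifolia", "A_marantoidea",
      tgt_order = c(3L, 1L, 2L), tgt_signs = c(1L, -1L, -1L),
      length_bp = c(750, 23000, 5000), region = "LSC"),
    lsc_anomochloa_joinvillea = mk(
      c("Ja-LSC1", "Ja-LSC2"), "A_marantoidea", "J_ascendens",
      tgt_order = c(2L, 1L), tgt_signs = c(-1L, 1L),
      length_bp = c(33000, 19500), region = "LSC"),
    lsc_anomochloa_joinvillea_mirror = mk(
      c("Ja-LSC1", "Ja-LSC2"), "A_marantoidea", "J_ascendens",
      tgt_order = c(2L, 1L), tgt_signs = c(1L, -1L),
      length_bp = c(33000, 19500), region = "LSC"),
    ssc_pojo = mk(
      c("PoJo-SSC1", "PoJo-SSC2"), "T_latifolia", "PoJo_ancestor",
      tgt_order = c(2L, 1L), tgt_signs = c(-1L, 1L),
      length_bp = c(14000, 3000), region = "SSC"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(fx))
      write_blocks_tsv(fx[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  fx
}
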