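## Stochastic inversion-scenario search (DIMSUM) and the exact BFS oracle.
## Both operate on the signed-permutation encoding produced by
## relabel_against_reference(): source == identity, target == a signed perm.

all_intervals <- function(n) {
  s <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  e <- unlist(lapply(seq_len(n), function(i) i:n))
  cbind(start = s, end = e)
}

perm_invert <- function(p, s, e) {
  p[s:e] <- -rev(p[s:e])
  p
}

perm_key <- function(p) paste(p, collapse = " ")

perm_flip <- function(p) -rev(p)

perm_canon_key <- function(p, flip_equivalence) {
  k <- perm_key(p)
  if (!flip_equivalence) return(k)
  kf <- perm_key(perm_flip(p))
  if (kf < k) kf else k
}

#' Monte Carlo search for inversion series between two block arrangements
#'
#' DIMSUM (Detection of Inversion Modes through the Simulation of Unifying
#' Mutations) runs `replicates` independent random walks. Each walk starts
#' at `source` and repeatedly applies an inversion event drawn uniformly at
#' random from all `n(n+1)/2` contiguous block intervals (single-block flips
#' and the full segment included), checking for equality with `target` after
#' every event and stopping at the first hit or after `max_steps` events.
#' The event prefix up to the hit is recorded as a solution. The endpoint is
#' also checked before the first event, so `source == target` yields the
#' empty scenario immediately.
#'
#' One seeded generator drives the whole run: at each step one proposal is
#' drawn for every replicate in index order (whether or not that replicate
#' has already hit), so a given seed always yields a bit-identical result.
#'
#' @param source,target Arrangements over the same block label set
#'   ([signed_arrangement()]).
#' @param replicates Number of random walks (default 10,000 at desk scale;
#'   studies certifying parsimony have used 1,000,000).
#' @param max_steps Inversion cap per replicate (default 100).
#' @param seed Integer seed for the run's random-number stream.
#' @param flip_equivalence Count a hit when the walk reaches `target` or its
#'   whole-segment reverse complement (see [arrangements_equal()]).
#' @param record_all_solutions Keep the deduplicated list of solution event
#'   sequences (default). Turn off to save memory on very large runs;
#'   `min_length` and `hits_by_length` are always kept.
#' @return An object of class `"dimsum_result"`: a list with `min_length`
#'   (smallest scenario length found, `NA` if no replicate reached the
#'   endpoint), `hits_by_length` (named count of replicate hits per length,
#'   pre-deduplication), `replicates_run`, `solutions` (list of event data
#'   frames, deduplicated by exact event sequence, ordered by length then
#'   lexicographically), `exact_min` (`NA` until certified, see
#'   [certify_parsimony()]), and the run configuration.
#' @examples
#' src <- signed_arrangement(c("PoJo-SSC1", "PoJo-SSC2"), region = "SSC")
#' tgt <- signed_arrangement(c("PoJo-SSC2", "PoJo-SSC1"),
#'                           signs = c(-1L, 1L), region = "SSC")
#' dimsum(src, tgt, replicates = 2000, seed = 1)$min_length          # 2
#' dimsum(src, tgt, replicates = 2000, seed = 1,
#'        flip_equivalence = TRUE)$min_length                        # 1
#' @export
dimsum <- function(source, target, replicates = 10000L, max_steps = 100L,
                   seed = 1L, flip_equivalence = FALSE,
                   record_all_solutions = TRUE) {
  check_same_labels(source, target)
  replicates <- as.integer(replicates); max_steps <- as.integer(max_steps)
  if (is.na(replicates) || replicates < 1L)
    stop("replicates must be a positive integer", call. = FALSE)
  if (is.na(max_steps) || max_steps < 1L)
    stop("max_steps must be a positive integer", call. = FALSE)
  n <- n_blocks(source)
  tperm <- relabel_against_reference(source, target)
  cfg <- list(replicates = replicates, max_steps = max_steps,
              seed = as.integer(seed), flip_equivalence = isTRUE(flip_equivalence),
              record_all_solutions = isTRUE(record_all_solutions))

  if (arrangements_equal(source, target, flip_equivalence)) {
    hits <- stats::setNames(replicates, "0")
    return(new_dimsum_result(0L, hits, list(empty_scenario()), cfg, source,
                             target))
  }

  iv <- all_intervals(n)
  K <- nrow(iv)
  tvec <- as.integer(tperm)
  tflip <- perm_flip(tvec)
  states <- matrix(rep(seq_len(n), replicates), nrow = n)
  alive <- rep(TRUE, replicates)
  hit_step <- rep(NA_integer_, replicates)
  hist <- if (cfg$record_all_solutions)
    matrix(NA_integer_, nrow = max_steps, ncol = replicates) else NULL

  set.seed(cfg$seed)
  for (t in seq_len(max_steps)) {
    draws <- sample.int(K, replicates, replace = TRUE)
    if (!is.null(hist)) hist[t, ] <- draws
    act <- which(alive)
    if (!length(act)) next
    dact <- draws[act]
    for (id in unique(dact)) {
      cols <- act[dact == id]
      s <- iv[id, 1L]; e <- iv[id, 2L]
      if (s == e) states[s, cols] <- -states[s, cols]
      else states[s:e, cols] <- -states[e:s, cols, drop = FALSE]
    }
    sub <- states[, act, drop = FALSE]
    eq <- colSums(sub == tvec) == n
    if (cfg$flip_equivalence) eq <- eq | colSums(sub == tflip) == n
    if (any(eq)) {
      newly <- act[eq]
      hit_step[newly] <- t
      alive[newly] <- FALSE
      if (!any(alive)) break
    }
  }

  hits <- table(factor(hit_step, levels = sort(unique(hit_step))))
  hits <- stats::setNames(as.integer(hits), names(hits))
  min_len <- if (all(is.na(hit_step))) NA_integer_ else
    min(hit_step, na.rm = TRUE)

  solutions <- list()
  if (cfg$record_all_solutions && !all(is.na(hit_step))) {
    hit_r <- which(!is.na(hit_step))
    keys <- vapply(hit_r, function(r)
      paste(hist[seq_len(hit_step[r]), r], collapse = ","), character(1))
    uniq <- !duplicated(keys)
    sol_r <- hit_r[uniq]
    solutions <- lapply(sol_r, function(r) {
      ids <- hist[seq_len(hit_step[r]), r]
      data.frame(start = iv[ids, 1L], end = iv[ids, 2L])
    })
    ord <- order(hit_step[sol_r], keys[uniq], method = "radix")
    solutions <- solutions[ord]
  }

  new_dimsum_result(min_len, hits, solutions, cfg, source, target)
}

empty_scenario <- function() data.frame(start = integer(0), end = integer(0))

new_dimsum_result <- function(min_length, hits_by_length, solutions, cfg,
                              source, target) {
  structure(list(min_length = min_length, exact_min = NA_integer_,
                 hits_by_length = hits_by_length,
                 replicates_run = cfg$replicates, solutions = solutions,
                 config = cfg, source = source, target = target),
            class = "dimsum_result")
}

#' @export
print.dimsum_result <- function(x, ...) {
  cat("DIMSUM search:", x$replicates_run, "replicates, max",
      x$config$max_steps, "steps, seed", x$config$seed,
      if (x$config$flip_equivalence) "(flip equivalence)" else "", "\n")
  cat("  shortest series found:",
      if (is.na(x$min_length)) "none (no replicate reached the endpoint)"
      else paste(x$min_length, "inversion(s)"), "\n")
  if (length(x$hits_by_length)) {
    cat("  replicate hits by length:",
        paste(sprintf("%s:%d", names(x$hits_by_length), x$hits_by_length),
              collapse = "  "), "\n")
  }
  cat("  distinct solutions recorded:", length(x$solutions), "\n")
  if (!is.na(x$exact_min))
    cat("  certified exact minimum:", x$exact_min, "\n")
  invisible(x)
}

#' Exact minimal inversion distance between two arrangements
#'
#' Breadth-first exploration of the full signed-arrangement space (2^n * n!
#' states) from `source` until `target` is reached; returns the length of
#' the shortest series of inversions. This is the exact oracle against
#' which [dimsum()] results are certified as most parsimonious. With
#' `flip_equivalence` the search runs over flip-equivalence classes, which
#' can only shorten the distance.
#'
#' @inheritParams dimsum
#' @param max_blocks Refuse instances with more blocks than this (default 8,
#'   about 10.3 million states); beyond it, use the stochastic [dimsum()]
#'   search instead.
#' @return Non-negative integer distance.
#' @examples
#' typha <- signed_arrangement(c("D-LSC3", "D-LSC1", "D-LSC2"))
#' anomo <- signed_arrangement(c("D-LSC2", "D-LSC3", "D-LSC1"),
#'                             signs = c(1L, -1L, -1L))
#' exact_min_distance(typha, anomo)  # 2
#' @export
exact_min_distance <- function(source, target, flip_equivalence = FALSE,
                               max_blocks = 8L) {
  check_same_labels(source, target)
  n <- n_blocks(source)
  if (n > max_blocks)
    stop("exact search capped at ", max_blocks, " blocks (", n,
         " given); use the stochastic dimsum() search for larger instances",
         call. = FALSE)
  tperm <- as.integer(relabel_against_reference(source, target))
  bfs_levels(n, tperm, flip_equivalence)$distance
}

## BFS from the target permutation over (canonicalised) states until the
## identity is discovered. Distances from target equal distances to target:
## every inversion is its own inverse, so the state graph is undirected.
## Returns the distance and the dist-keyed environment for complete levels
## 0..distance-1 (plus the partially-discovered level at `distance`).
bfs_levels <- function(n, tperm, flip_equivalence) {
  id <- seq_len(n)
  id_key <- perm_canon_key(id, flip_equivalence)
  t_key <- perm_canon_key(tperm, flip_equivalence)
  dist <- new.env(hash = TRUE, parent = emptyenv())
  assign(t_key, 0L, envir = dist)
  if (id_key == t_key)
    return(list(distance = 0L, dist = dist, n = n))
  iv <- all_intervals(n)
  frontier <- list(tperm)
  level <- 0L
  repeat {
    level <- level + 1L
    nxt <- list()
    found <- FALSE
    for (p in frontier) {
      for (k in seq_len(nrow(iv))) {
        q <- perm_invert(p, iv[k, 1L], iv[k, 2L])
        key <- perm_canon_key(q, flip_equivalence)
        if (is.null(dist[[key]])) {
          assign(key, level, envir = dist)
          nxt[[length(nxt) + 1L]] <- q
          if (key == id_key) found <- TRUE
        }
      }
    }
    if (found) return(list(distance = level, dist = dist, n = n))
    if (!length(nxt))
      stop("state space exhausted without reaching the target ",
           "(internal error)", call. = FALSE)
    frontier <- nxt
  }
}

#' Enumerate every most parsimonious inversion scenario
#'
#' Returns all distinct event sequences of length exactly
#' [exact_min_distance()] that transform `source` into `target`, found by
#' breadth-first search with distance-decreasing backtracking. Output order
#' is deterministic: scenarios are generated with events tried in
#' (start, end) order, giving a lexicographic canonical ordering.
#'
#' @inheritParams exact_min_distance
#' @return A list of scenarios, each a data frame with columns `start`,
#'   `end` (zero rows for the empty scenario when `source` already equals
#'   `target`).
#' @examples
#' a <- signed_arrangement(c("B1", "B2"))
#' b <- signed_arrangement(c("B2", "B1"), signs = c(-1L, -1L))
#' enumerate_minimal_scenarios(a, b)  # single event: invert 1..2
#' @export
enumerate_minimal_scenarios <- function(source, target,
                                        flip_equivalence = FALSE,
                                        max_blocks = 8L) {
  check_same_labels(source, target)
  n <- n_blocks(source)
  if (n > max_blocks)
    stop("exact search capped at ", max_blocks, " blocks (", n,
         " given); use the stochastic dimsum() search for larger instances",
         call. = FALSE)
  tperm <- as.integer(relabel_against_reference(source, target))
  bfs <- bfs_levels(n, tperm, flip_equivalence)
  D <- bfs$distance
  if (D == 0L) return(list(empty_scenario()))
  iv <- all_intervals(n)
  out <- list()
  path <- matrix(NA_integer_, nrow = D, ncol = 2L)
  recurse <- function(p, depth) {
    remaining <- D - depth
    for (k in seq_len(nrow(iv))) {
      q <- perm_invert(p, iv[k, 1L], iv[k, 2L])
      key <- perm_canon_key(q, flip_equivalence)
      d_q <- bfs$dist[[key]]
      if (is.null(d_q) || d_q != remaining - 1L) next
      path[depth + 1L, ] <<- iv[k, ]
      if (remaining == 1L) {
        out[[length(out) + 1L]] <<- data.frame(start = path[, 1L],
                                               end = path[, 2L])
      } else {
        recurse(q, depth + 1L)
      }
    }
  }
  recurse(seq_len(n), 0L)
  out
}

#' Certify a DIMSUM result against the exact oracle
#'
#' Fills the `exact_min` slot of a [dimsum()] result by running
#' [exact_min_distance()] on the same instance, so the stochastic minimum
#' can be compared with the true one.
#'
#' @param result A `dimsum_result`.
#' @inheritParams exact_min_distance
#' @return The result with `exact_min` set.
#' @export
certify_parsimony <- function(result, max_blocks = 8L) {
  if (!inherits(result, "dimsum_result"))
    stop("expected a dimsum_result", call. = FALSE)
  result$exact_min <- exact_min_distance(result$source, result$target,
                                         result$config$flip_equivalence,
                                         max_blocks = max_blocks)
  result
}

#' Breakpoint count between two arrangements
#'
#' Number of signed adjacencies (block ends framed by fixed terminals
#' included) present in the source frame but absent in the target. The
#' classical reversal bound `distance >= ceiling(breakpoints / 2)` holds:
#' one inversion can heal at most two breakpoints.
#'
#' @inheritParams dimsum
#' @return Non-negative integer.
#' @export
breakpoint_count <- function(source, target) {
  check_same_labels(source, target)
  n <- n_blocks(source)
  p <- c(0L, as.integer(relabel_against_reference(source, target)), n + 1L)
  sum(diff(p) != 1L)
}

#' Serialise a DIMSUM result for JSON output
#'
#' @param result A `dimsum_result`.
#' @return A list mirroring the result (`exact_min`, `min_length`,
#'   `hits_by_length`, `replicates_run`, `config`, `solutions` as arrays of
#'   \{start, end\} events), ready for [jsonlite::write_json()].
#' @export
dimsum_result_json <- function(result) {
  if (!inherits(result, "dimsum_result"))
    stop("expected a dimsum_result", call. = FALSE)
  list(exact_min = if (is.na(result$exact_min)) NULL else result$exact_min,
       min_length = if (is.na(result$min_length)) NULL else result$min_length,
       hits_by_length = as.list(stats::setNames(
         as.integer(result$hits_by_length), names(result$hits_by_length))),
       replicates_run = result$replicates_run,
       config = result$config[c("replicates", "max_steps", "seed",
                                "flip_equivalence")],
       solutions = lapply(result$solutions, function(s)
         lapply(seq_len(nrow(s)), function(i)
           list(start = s$start[i], end = s$end[i]))))
}
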