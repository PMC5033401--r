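# Independent brute-force oracle: exhaustive enumeration over all event
# sequences by increasing length, with no state deduplication or canonical
# forms, deliberately kept separate from the package's BFS implementation.

brute_intervals <- function(n) {
  out <- list()
  for (s in seq_len(n)) for (e in s:n) out[[length(out) + 1L]] <- c(s, e)
  out
}

brute_min_distance <- function(source, target, flip_equivalence = FALSE,
                               max_depth = 6L) {
  if (arrangements_equal(source, target, flip_equivalence)) return(0L)
  ivs <- brute_intervals(length(source))
  frontier <- list(source)
  for (d in seq_len(max_depth)) {
    nxt <- vector("list", length(frontier) * length(ivs))
    k <- 0L
    for (a in frontier) for (iv in ivs) {
      b <- apply_inversion(a, iv[1L], iv[2L])
      if (arrangements_equal(b, target, flip_equivalence)) return(d)
      k <- k + 1L
      nxt[[k]] <- b
    }
    frontier <- nxt
  }
  NA_integer_
}

# every event sequence of exactly length d transforming source into target
brute_scenarios <- function(source, target, d, flip_equivalence = FALSE) {
  ivs <- brute_intervals(length(source))
  out <- list()
  recurse <- function(a, path) {
    if (nrow(path) == d) {
      if (arrangements_equal(a, target, flip_equivalence))
        out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (iv in ivs)
      recurse(apply_inversion(a, iv[1L], iv[2L]),
              rbind(path, data.frame(start = iv[1L], end = iv[2L])))
  }
  recurse(source, data.frame(start = integer(0), end = integer(0)))
  out
}

# all 2^n * n! signed arrangements over labels B1..Bn
all_signed_arrangements <- function(n, region = "region") {
  perms <- if (n == 1L) matrix(1L) else {
    g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    g[apply(g, 1L, function(r) length(unique(r)) == n), , drop = FALSE]
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  out <- list()
  for (i in seq_len(nrow(perms))) for (j in seq_len(nrow(signs)))
    out[[length(out) + 1L]] <- signed_arrangement(
      paste0("B", perms[i, ]), signs = as.integer(signs[j, ]),
      region = region)
  out
}

arr_key <- function(a) paste(ifelse(a$signs > 0, "+", "-"), a$labels,
                             sep = "", collapse = " ")

scenario_key <- function(s) paste(s$start, s$end, sep = ".", collapse = ";")
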