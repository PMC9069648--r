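# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shuffle the characters of each string (mononucleotide permutation).
shuffle_strings <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(ch[sample.int(length(ch))], collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Shuffle preserving dinucleotide composition (Altschul-Erickson: sample a
# random arborescence toward the terminal state, fix those transitions as
# each state's last exit, randomize the rest, then walk the Eulerian path).
shuffle_dinuc <- function(x) {
  vapply(x, shuffle_dinuc_one, character(1L), USE.NAMES = FALSE)
}

shuffle_dinuc_one <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 4L || length(unique(ch)) == 1L) return(s)
  first <- ch[1L]
  last <- ch[n]
  succ <- split(ch[-1L], ch[-n])      # multiset of successors per state
  states <- names(succ)
  # random-walk (Wilson) arborescence rooted at `last`
  parent <- setNames(rep(NA_character_, length(states)), states)
  in_tree <- setNames(states == last | !(states %in% states), states)
  in_tree[last] <- TRUE
  for (st in setdiff(states, last)) {
    u <- st
    while (!isTRUE(in_tree[u])) {
      nxt <- succ[[u]][sample.int(length(succ[[u]]), 1L)]
      parent[u] <- nxt
      u <- nxt
      if (!(u %in% states)) break   # reached terminal-only state
    }
    u <- st
    while (!isTRUE(in_tree[u])) {
      in_tree[u] <- TRUE
      u <- parent[u]
      if (!(u %in% states)) break
    }
  }
  # order each state's exits: shuffled, with the arborescence edge last
  ordered <- lapply(states, function(u) {
    e <- succ[[u]]
    if (u != last && !is.na(parent[u])) {
      i <- match(parent[u], e)
      e <- c(e[-i][sample.int(max(length(e) - 1L, 0L))], parent[u])
    } else {
      e <- e[sample.int(length(e))]
    }
    e
  })
  names(ordered) <- states
  ptr <- setNames(rep(1L, length(states)), states)
  out <- character(n)
  out[1L] <- first
  u <- first
  for (i in 2:n) {
    v <- ordered[[u]][ptr[u]]
    ptr[u] <- ptr[u] + 1L
    out[i] <- v
    u <- v
  }
  paste(out, collapse = "")
}
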