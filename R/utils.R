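# internal helpers shared across modules

# Order individuals so that parents always precede children (Kahn's
# algorithm); errors on cycles, which also catches self-ancestry.
topo_order <- function(id, father, mother) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  fa <- ifelse(is.na(father), NA_integer_, idx[father])
  mo <- ifelse(is.na(mother), NA_integer_, idx[mother])
  if (any(!is.na(father) & is.na(fa)) || any(!is.na(mother) & is.na(mo))) {
    stop("pedigree references a parent id that does not exist")
  }
  indeg <- as.integer(!is.na(fa)) + as.integer(!is.na(mo))
  children <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(fa[j], mo[j])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], j)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    j <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, j)
    for (ch in children[[j]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) stop("pedigree contains a cycle")
  out
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
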