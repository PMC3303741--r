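# shared internal helpers

# all unordered pairs of a gene vector, in lexicographic index order (i < j)
gene_pairs <- function(genes) {
  n <- length(genes)
  if (n < 2) {
    return(tibble(from = character(), to = character()))
  }
  idx <- combn(n, 2)
  tibble(from = genes[idx[1, ]], to = genes[idx[2, ]])
}

# Derive a reproducible sub-seed (< 2^31) from a global seed and a label, so
# each stochastic stage gets its own stream without seed collisions.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 2017L + (h %% 99991L) * 13L + 1L
}

# Run an expression with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Kahan-free log-sum-exp; -Inf-safe.
log_sum_exp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(-Inf)
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# acyclicity of a logical/0-1 adjacency matrix by repeated sink elimination
adjacency_is_acyclic <- function(adj) {
  n <- nrow(adj)
  alive <- rep(TRUE, n)
  repeat {
    indeg <- colSums(adj[alive, alive, drop = FALSE])
    src <- which(indeg == 0)
    if (length(src) == 0) break
    alive[which(alive)[src]] <- FALSE
    if (!any(alive)) break
  }
  !any(alive)
}

# topological order of an acyclic adjacency matrix (parents before children)
adjacency_topo_order <- function(adj) {
  n <- nrow(adj)
  order <- integer(0)
  alive <- rep(TRUE, n)
  while (any(alive)) {
    indeg <- colSums(adj[alive, alive, drop = FALSE])
    src <- which(alive)[which(indeg == 0)]
    if (length(src) == 0) {
      abort("graph is cyclic; no topological order exists")
    }
    order <- c(order, src[1])
    alive[src[1]] <- FALSE
  }
  order
}
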