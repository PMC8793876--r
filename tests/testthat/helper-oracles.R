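# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, where the package delegates, the library it
# delegates to).

# random rooted bifurcating tree with positive branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 1e-3
  tr
}

# Brownian covariance by explicit root-to-tip path intersection: shared path
# length = sum of edge lengths common to both root paths.
brute_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  edge_len <- function(a, b) {
    tree$edge.length[which(tree$edge[, 1] == a & tree$edge[, 2] == b)]
  }
  paths <- lapply(seq_len(n), function(tip) ape::nodepath(tree, root, tip))
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      pi_ <- paths[[i]]; pj <- paths[[j]]
      m <- 1L
      while (m < min(length(pi_), length(pj)) && pi_[m + 1L] == pj[m + 1L]) {
        m <- m + 1L
      }
      shared <- 0
      if (m > 1L) {
        for (k in seq_len(m - 1L)) {
          shared <- shared + edge_len(pi_[k], pi_[k + 1L])
        }
      }
      if (i == j) {
        shared <- 0
        for (k in seq_len(length(pi_) - 1L)) {
          shared <- shared + edge_len(pi_[k], pi_[k + 1L])
        }
      }
      V[i, j] <- V[j, i] <- shared
    }
  }
  V
}

# all-subsets OLS AICc by direct lm() + formula arithmetic
brute_aicc <- function(dat, response, candidates) {
  z <- as.data.frame(scale(dat[, c(response, candidates)]))
  n <- nrow(z)
  subsets <- unlist(lapply(0:length(candidates), function(k) {
    utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
  out <- lapply(subsets, function(vars) {
    f <- if (length(vars)) stats::reformulate(vars, response) else
      stats::as.formula(paste(response, "~ 1"))
    fit <- stats::lm(f, data = z)
    rss <- sum(stats::residuals(fit)^2)
    k <- length(vars) + 2
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    data.frame(model = if (length(vars)) paste(vars, collapse = " + ")
               else "(null)",
               AICc = -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  })
  do.call(rbind, out)
}

# total effects in a DAG by exhaustive directed-path enumeration
brute_path_effects <- function(B, outcome) {
  vars <- colnames(B)
  total <- stats::setNames(numeric(length(vars)), vars)
  # depth-first enumeration of all directed paths ending at `outcome`
  recurse <- function(node, product) {
    parents <- vars[B[node, ] != 0]
    for (p in parents) {
      contrib <- product * B[node, p]
      total[p] <<- total[p] + contrib
      recurse(p, contrib)
    }
  }
  recurse(outcome, 1)
  total[setdiff(vars, outcome)]
}

# tiny trait table with a known structure for model-selection tests
planted_table <- function(n = 28, beta = 0.6, sigma = 0.5, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  data.frame(y = beta * x1 + rnorm(n, sd = sigma), x1 = x1, x2 = x2, x3 = x3)
}
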