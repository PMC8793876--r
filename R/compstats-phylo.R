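#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node of a bifurcating
#' tree the contrast `(x_i - x_j) / sqrt(v_i + v_j)` is recorded, the
#' ancestral value is the `1/v`-weighted mean of the children, and the
#' parent edge is lengthened by `v_i * v_j / (v_i + v_j)`. Polytomies are
#' resolved arbitrarily with zero-length branches (with a warning), matching
#' common practice; `strict = TRUE` errors instead.
#'
#' @param tree A rooted `phylo` object.
#' @param x Named numeric vector of tip values (names must match tip labels
#'   exactly).
#' @param strict Error on polytomies instead of resolving them.
#' @return list with `contrasts` (length tips - 1), `variances` (the sum of
#'   adjusted child branch lengths per contrast), and `node` ids (on the
#'   resolved tree).
#' @export
pic_contrasts <- function(tree, x, strict = FALSE) {
  tree <- validate_tree(tree)
  if (is.null(names(x))) stop("tip values must be named", call. = FALSE)
  miss <- setdiff(tree$tip.label, names(x))
  extra <- setdiff(names(x), tree$tip.label)
  if (length(miss) || length(extra)) {
    stop("species mismatch — missing values for {",
         paste(miss, collapse = ", "), "}; values without tips: {",
         paste(extra, collapse = ", "), "}", call. = FALSE)
  }
  if (!ape::is.binary(tree)) {
    if (strict) stop("tree has polytomies", call. = FALSE)
    warning("polytomies resolved arbitrarily with zero-length branches",
            call. = FALSE)
    tree <- ape::multi2di(tree, random = FALSE)
  }
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  val <- numeric(nn)
  val[seq_len(n)] <- x[tree$tip.label]
  vadj <- numeric(nn)                     # extra variance carried upward
  edge <- tree$edge
  elen <- tree$edge.length
  # children of each internal node
  kids <- split(seq_len(nrow(edge)), edge[, 1L])
  n_children <- lengths(kids)
  seen <- integer(nn)
  contrasts <- variances <- numeric(tree$Nnode)
  nodes <- integer(tree$Nnode)
  m <- 0L
  # a node's contrast is computed when its LAST child edge is visited:
  # postorder guarantees every child's subtree is then complete
  for (e in ape::postorder(tree)) {
    parent <- edge[e, 1L]
    seen[parent] <- seen[parent] + 1L
    if (seen[parent] < n_children[[as.character(parent)]]) next
    ke <- kids[[as.character(parent)]]
    ci <- edge[ke, 2L]
    v <- elen[ke] + vadj[ci]
    m <- m + 1L
    contrasts[m] <- (val[ci[1L]] - val[ci[2L]]) / sqrt(sum(v))
    variances[m] <- sum(v)
    nodes[m] <- parent
    val[parent] <- sum(val[ci] / v) / sum(1 / v)
    vadj[parent] <- prod(v) / sum(v)
  }
  contrasts <- contrasts[seq_len(m)]
  variances <- variances[seq_len(m)]
  nodes <- nodes[seq_len(m)]
  list(contrasts = contrasts, variances = variances, node = nodes,
       root_value = val[n + 1L], tree = tree)
}

#' Through-origin correlation of two contrast sets
#'
#' Contrasts have arbitrary sign, so their association is measured through
#' the origin: `r = sum(c1 c2) / sqrt(sum(c1^2) sum(c2^2))`, with the
#' two-sided p from a t distribution on `n_contrasts - 1` df.
#'
#' @param tree Rooted `phylo`.
#' @param x,y Named tip-value vectors for the two traits.
#' @return list with `r`, `p`, `df`, and the two contrast sets.
#' @export
pic_correlation <- function(tree, x, y) {
  cx <- pic_contrasts(tree, x)
  cy <- pic_contrasts(tree, y)
  c1 <- cx$contrasts
  c2 <- cy$contrasts
  r <- sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2))
  df <- length(c1) - 1L
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = df), df = df,
       contrasts_x = cx, contrasts_y = cy)
}

#' Correlation matrix on independent contrasts
#'
#' PIC analogue of [pearson_matrix()]: every pairwise through-origin
#' contrast correlation across the trait columns.
#'
#' @param tree Rooted `phylo` with tips matching `table$species`.
#' @param table Species trait data.frame with a `species` column.
#' @param traits Optional trait subset.
#' @param alpha Significance level for the flag matrix.
#' @return list with matrices `r`, `p`, `significant`.
#' @export
pic_matrix <- function(tree, table, traits = NULL, alpha = 0.05) {
  m <- match_tree_species(tree, table$species)
  tab <- table[match(m$species, table$species), , drop = FALSE]
  x <- tab[, vapply(tab, is.numeric, logical(1)), drop = FALSE]
  if (!is.null(traits)) x <- x[, traits, drop = FALSE]
  nm <- names(x)
  p <- ncol(x)
  r <- pv <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  cons <- lapply(x, function(col) {
    pic_contrasts(m$tree, stats::setNames(col, m$species))$contrasts
  })
  for (i in seq_len(p)) {
    for (j in seq_len(i)) {
      c1 <- cons[[i]]; c2 <- cons[[j]]
      rij <- sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2))
      df <- length(c1) - 1L
      tt <- rij * sqrt(df / max(1 - rij^2, .Machine$double.eps))
      r[i, j] <- r[j, i] <- rij
      pv[i, j] <- pv[j, i] <-
        if (i == j) 0 else 2 * stats::pt(-abs(tt), df = df)
    }
  }
  list(r = r, p = pv, significant = pv < alpha)
}

#' Blomberg's K phylogenetic signal with permutation test
#'
#' Observed-versus-Brownian-expected ratio of trait variance explained by the
#' phylogeny. With `V` the Brownian tip covariance from [phylo_vcv()] and
#' `a = (1' V^-1 x) / (1' V^-1 1)` the phylogenetic mean,
#' `MSE0 = sum((x - a)^2) / (n - 1)`,
#' `MSE = (x - a)' V^-1 (x - a) / (n - 1)`, and
#' `K = (MSE0 / MSE) / ((tr(V) - n / (1' V^-1 1)) / (n - 1))`.
#' K near 1 is Brownian-like signal, near 0 no signal, above 1 stronger
#' conservation than Brownian. Significance comes from shuffling tip values:
#' the p-value is the observed-inclusive rank of the observed MSE among
#' `n_perm` permuted MSEs (smaller MSE = more signal), resolution
#' `1 / (n_perm + 1)`.
#'
#' @param tree Rooted `phylo`.
#' @param x Named tip-value vector.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility).
#' @return list with `K`, `p`, `n_perm`, `seed`, `MSE0`, `MSE`.
#' @export
blomberg_k <- function(tree, x, n_perm = 999L, seed = 1L) {
  tree <- validate_tree(tree)
  V <- phylo_vcv(tree)
  x <- x[rownames(V)]
  if (anyNA(x)) stop("tip values missing or unnamed", call. = FALSE)
  n <- length(x)
  Vi <- tryCatch(solve(V), error = function(e) {
    stop("singular phylogenetic covariance (zero-length cherries?)",
         call. = FALSE)
  })
  one <- rep(1, n)
  viOne <- Vi %*% one
  denom_a <- sum(viOne)
  expected <- (sum(diag(V)) - n / denom_a) / (n - 1)
  mse_stat <- function(xx) {
    a <- sum(viOne * xx) / denom_a
    d <- xx - a
    drop(crossprod(d, Vi %*% d)) / (n - 1)
  }
  a <- sum(viOne * x) / denom_a
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- mse_stat(x)
  K <- (mse0 / mse) / expected
  # private permutation stream; the caller's RNG state is untouched
  local_rng()
  set.seed(seed)
  perm_mse <- vapply(seq_len(n_perm), function(i) mse_stat(sample(x)),
                     numeric(1))
  p <- (1 + sum(perm_mse <= mse)) / (n_perm + 1)
  list(K = K, p = p, n_perm = n_perm, seed = seed, MSE0 = mse0, MSE = mse)
}

#' Phylogenetic signal table over all traits
#'
#' Runs [blomberg_k()] for every numeric trait column, the layout used when
#' reporting signal alongside group ANOVAs.
#'
#' @param tree Rooted `phylo`.
#' @param table Species trait data.frame with `species` column.
#' @param traits Optional trait subset.
#' @param n_perm,seed Passed to [blomberg_k()] (the seed is offset per trait
#'   so traits get independent permutation streams).
#' @return data.frame with `trait`, `K`, `p`, `n_perm`.
#' @export
signal_table <- function(tree, table, traits = NULL, n_perm = 999L,
                         seed = 1L) {
  m <- match_tree_species(tree, table$species)
  tab <- table[match(m$species, table$species), , drop = FALSE]
  x <- tab[, vapply(tab, is.numeric, logical(1)), drop = FALSE]
  if (!is.null(traits)) x <- x[, traits, drop = FALSE]
  rows <- lapply(seq_along(x), function(i) {
    res <- blomberg_k(m$tree, stats::setNames(x[[i]], m$species),
                      n_perm = n_perm, seed = substream_seed(seed, names(x)[i]))
    data.frame(trait = names(x)[i], K = res$K, p = res$p,
               n_perm = n_perm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
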