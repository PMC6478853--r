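# Independent oracles and small fixtures shared across test files.

# Brute-force patristic distance: walk parent pointers tip -> root on both
# sides, find the first shared ancestor, and sum edge lengths along the two
# walks. Deliberately naive and independent of the package's distance code.
oracle_patristic <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  ancestors <- function(i) {
    path <- i
    repeat {
      row <- which(tree$edge[, 2] == i)
      if (!length(row)) break
      i <- tree$edge[row, 1]
      path <- c(path, i)
    }
    path
  }
  pa <- ancestors(ia)
  lca <- pa[which(pa %in% ancestors(ib))[1]]
  walk <- function(i) {
    s <- 0
    while (i != lca) {
      row <- which(tree$edge[, 2] == i)
      s <- s + tree$edge.length[row]
      i <- tree$edge[row, 1]
    }
    s
  }
  walk(ia) + walk(ib)
}

oracle_dm <- function(tree, tips = tree$tip.label) {
  n <- length(tips)
  d <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- oracle_patristic(tree, tips[i], tips[j])
  }
  d
}

# 3- and 4-tip worked-example trees
tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")
tree4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# Dense multivariate-normal log-density: full covariance assembled
# explicitly and solved densely. Oracle for lmm_loglik.
dense_mvn_loglik <- function(y, X, beta, groups, s2s, s2e, rho = NULL,
                             coords = NULL) {
  n <- length(y)
  groups <- as.factor(groups)
  V <- matrix(0, n, n)
  for (g in levels(groups)) {
    i <- which(groups == g)
    m <- length(i)
    R <- if (is.null(rho)) diag(m) else
      exp(-as.matrix(stats::dist(coords[i, , drop = FALSE])) / rho)
    V[i, i] <- s2s * matrix(1, m, m) + s2e * R
  }
  r <- y - X %*% beta
  -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% solve(V, r)))
}

# Minimal lmm_fit stand-in for formula-level checks
fake_fit <- function(logLik = -100, k = 3, n = 20, converged = TRUE) {
  structure(list(logLik = logLik, k = k, n = n, converged = converged),
            class = "lmm_fit")
}

make_community_table <- function(members, covariates = NULL) {
  if (is.null(covariates)) {
    key <- unique(members[, c("study_id", "community_id")])
    covariates <- data.frame(
      key, latitude = 0, longitude = 0, size = 100,
      realm = "Palearctic", vegetation = "closed",
      stringsAsFactors = FALSE
    )
  }
  read_communities(members, covariates)
}
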