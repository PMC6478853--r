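#' Mean pairwise phylogenetic distance of a community
#'
#' Average patristic distance over all unordered pairs of community members:
#' the deep-phylogeny relatedness signal (opposite in sign to the net
#' relatedness index).
#'
#' @param species Character vector of community members (>= 2), all present
#'   in `dm`.
#' @param dm Patristic distance matrix with species as dimnames
#'   (see [pairwise_distances()]).
#' @return Mean pairwise distance (numeric scalar).
#' @export
mpd <- function(species, dm) {
  idx <- community_index(species, dm)
  m <- dm[idx, idx]
  mean(m[upper.tri(m)])
}

#' Mean nearest taxon distance of a community
#'
#' Average, over community members, of the distance to the nearest other
#' member: the tip-level relatedness signal (opposite in sign to the nearest
#' taxon index).
#'
#' @inheritParams mpd
#' @return Mean nearest-taxon distance (numeric scalar).
#' @export
mntd <- function(species, dm) {
  idx <- community_index(species, dm)
  m <- dm[idx, idx]
  diag(m) <- Inf
  mean(row_mins(m))
}

community_index <- function(species, dm) {
  species <- unique(as.character(species))
  if (length(species) < 2L)
    stop("community must contain at least 2 species", call. = FALSE)
  idx <- match(species, rownames(dm))
  if (anyNA(idx))
    stop("species not in distance matrix: ",
         paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

row_mins <- function(m) m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]

# Both metrics from a row of pool indices; used by the null machinery where
# one subset draw serves both mpd and mntd.
metrics_from_index <- function(idx, dm) {
  m <- dm[idx, idx]
  mpd_v <- mean(m[upper.tri(m)])
  diag(m) <- Inf
  c(mpd = mpd_v, mntd = mean(row_mins(m)))
}

#' Null distribution of a diversity metric under richness-matched assembly
#'
#' The null model draws communities of the observed richness uniformly at
#' random from the species pool (equivalent, for presence/absence data, to
#' shuffling tip labels). In `"exhaustive"` mode every richness-subset of
#' the pool is evaluated exactly once, which is feasible for small pools and
#' documents the sampled mode's target distribution.
#'
#' @param richness Community size (2 <= richness <= pool size).
#' @param pool Character vector: the stratum species pool.
#' @param dm Patristic distance matrix covering the pool.
#' @param metric `"mpd"` or `"mntd"`.
#' @param n_rand Number of randomizations in sampled mode (default 999).
#' @param mode `"sampled"` or `"exhaustive"`.
#' @param seed Optional integer seed (sampled mode is reproducible given it).
#' @param exhaustive_threshold Maximum number of subsets tolerated in
#'   exhaustive mode.
#' @return Numeric vector of metric values under the null.
#' @export
null_distribution <- function(richness, pool, dm, metric = c("mpd", "mntd"),
                              n_rand = 999L, mode = c("sampled", "exhaustive"),
                              seed = NULL, exhaustive_threshold = 1e5) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  pool <- unique(as.character(pool))
  pidx <- match(pool, rownames(dm))
  if (anyNA(pidx))
    stop("pool species not in distance matrix: ",
         paste(pool[is.na(pidx)], collapse = ", "), call. = FALSE)
  if (richness < 2L) stop("richness must be >= 2", call. = FALSE)
  if (richness > length(pool))
    stop("richness (", richness, ") exceeds pool size (", length(pool), ")",
         call. = FALSE)
  draws <- null_metric_draws(richness, pidx, dm, n_rand, mode, seed,
                             exhaustive_threshold)
  draws[, metric]
}

# Shared engine: matrix of (mpd, mntd) values over null subsets.
null_metric_draws <- function(richness, pidx, dm, n_rand, mode, seed,
                              exhaustive_threshold) {
  if (mode == "exhaustive") {
    n_subsets <- choose(length(pidx), richness)
    if (n_subsets > exhaustive_threshold)
      stop("exhaustive mode infeasible: ", n_subsets, " subsets exceeds ",
           "threshold ", exhaustive_threshold, call. = FALSE)
    subsets <- utils::combn(pidx, richness)
    out <- t(apply(subsets, 2L, metrics_from_index, dm = dm))
  } else {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    out <- t(vapply(
      seq_len(n_rand),
      function(i) metrics_from_index(sample(pidx, richness), dm),
      numeric(2)
    ))
  }
  colnames(out) <- c("mpd", "mntd")
  out
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Standardized effect size against a null sample
#'
#' `ses = (obs - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation. Negative values indicate phylogenetic clustering (lower
#' diversity than the richness-matched null), positive values
#' overdispersion. A null with zero spread (e.g. community = whole pool)
#' yields a degenerate flag and an undefined SES.
#'
#' @param obs Observed metric value.
#' @param null_sample Numeric vector of null metric values (non-empty).
#' @return List: `ses`, `null_mean`, `null_sd`, `degenerate`.
#' @export
ses <- function(obs, null_sample) {
  if (length(null_sample) == 0L) stop("empty null sample", call. = FALSE)
  mu <- mean(null_sample)
  sd_ <- stats::sd(null_sample)
  if (!is.finite(sd_) || sd_ == 0)
    return(list(ses = NA_real_, null_mean = mu, null_sd = 0, degenerate = TRUE))
  list(ses = (obs - mu) / sd_, null_mean = mu, null_sd = sd_, degenerate = FALSE)
}

#' SES_mpd and SES_mntd for every community in a table
#'
#' The species pool is the tip set of `tree` (prune the stratum tree to the
#' union of the stratum's species first; see [species_pool()] and
#' [prune_to_tips()]). One subset draw per randomization serves both
#' metrics. Per-community RNG seeds are derived deterministically from the
#' master seed and the community id, so results do not depend on community
#' order and are reproducible community-by-community.
#'
#' @param ct A `community_table` (filtered; single stratum).
#' @param tree Phylogeny pruned to the stratum pool.
#' @param n_rand Randomizations per community (default 999).
#' @param seed Master seed.
#' @param mode `"sampled"` or `"exhaustive"` nulls.
#' @param exhaustive_threshold See [null_distribution()].
#' @return Data frame with one row per community: ids, `richness`,
#'   `mpd_obs`, `mntd_obs`, null means/sds, `ses_mpd`, `ses_mntd`,
#'   `degenerate`.
#' @export
ses_table <- function(ct, tree, n_rand = 999L, seed = 1L,
                      mode = c("sampled", "exhaustive"),
                      exhaustive_threshold = 1e5) {
  mode <- match.arg(mode)
  stopifnot(inherits(ct, "community_table"))
  m <- ct$members
  pool <- tree$tip.label
  absent <- setdiff(unique(m$species), pool)
  if (length(absent))
    stop("community species absent from tree: ",
         paste(utils::head(absent, 10), collapse = ", "),
         if (length(absent) > 10) sprintf(" (+%d more)", length(absent) - 10),
         call. = FALSE)
  dm <- pairwise_distances(tree)
  pidx <- seq_len(nrow(dm))

  ckey <- paste(m$study_id, m$community_id, sep = "\r")
  groups <- split(m$species, ckey)
  ids <- strsplit(names(groups), "\r", fixed = TRUE)

  rows <- lapply(seq_along(groups), function(i) {
    sp <- unique(groups[[i]])
    r <- length(sp)
    obs <- metrics_from_index(match(sp, rownames(dm)), dm)
    comm_seed <- derive_seed(seed, names(groups)[i])
    draws <- null_metric_draws(r, pidx, dm, n_rand, mode, comm_seed,
                               exhaustive_threshold)
    s_mpd <- ses(obs[["mpd"]], draws[, "mpd"])
    s_mntd <- ses(obs[["mntd"]], draws[, "mntd"])
    data.frame(
      study_id = ids[[i]][1], community_id = ids[[i]][2], richness = r,
      mpd_obs = obs[["mpd"]], mntd_obs = obs[["mntd"]],
      null_mean_mpd = s_mpd$null_mean, null_sd_mpd = s_mpd$null_sd,
      null_mean_mntd = s_mntd$null_mean, null_sd_mntd = s_mntd$null_sd,
      ses_mpd = s_mpd$ses, ses_mntd = s_mntd$ses,
      degenerate = s_mpd$degenerate || s_mntd$degenerate,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Deterministic 31-bit seed from a master seed and a community key.
derive_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) + h) %% 2147483647)
}
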